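# One-command pipeline runner and report assembler: generate (optional) ->
# harmonize -> collinearity -> pairwise/enrichment -> CATA -> feature space,
# with structured logging, per-stage seeds and a reproducible manifest.

#' Pipeline configuration
#'
#' @param generator a [generator_config()] to synthesise inputs, or `NULL`
#'   to read `registration.csv`, `results.csv`, `lab.csv` from `input_dir`.
#' @param input_dir directory with input CSVs when generation is disabled.
#' @param outdir output directory.
#' @param stages named logical toggles: `generate`, `harmonize`,
#'   `collinearity`, `pairwise`, `enrichment`, `cata`, `feature_space`.
#' @param alpha FDR level; `epsilon` enrichment regulariser;
#'   `collinearity_threshold` association cut; `n_perm` permutation count.
#' @param epsilon,collinearity_threshold,n_perm thresholds (see above).
#' @param seed master seed; per-stage seeds are derived deterministically
#'   from it and the stage name.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            input_dir = NULL, outdir = tempfile("sourveyor_"),
                            stages = NULL, alpha = 0.05, epsilon = 1e-4,
                            collinearity_threshold = 0.7, n_perm = 199,
                            seed = 1L) {
  default_stages <- c(generate = !is.null(generator), harmonize = TRUE,
                      collinearity = TRUE, pairwise = TRUE, enrichment = TRUE,
                      cata = TRUE, feature_space = TRUE)
  if (!is.null(stages)) default_stages[names(stages)] <- unlist(stages)
  if (is.null(generator) && !is.null(input_dir)) {
    needed <- file.path(input_dir, c("registration.csv", "results.csv", "lab.csv"))
    if (!all(file.exists(needed))) {
      stop("input_dir must contain registration.csv, results.csv, lab.csv",
           call. = FALSE)
    }
  }
  structure(list(generator = generator, input_dir = input_dir,
                 outdir = outdir, stages = default_stages, alpha = alpha,
                 epsilon = epsilon,
                 collinearity_threshold = collinearity_threshold,
                 n_perm = n_perm, seed = as.integer(seed)),
            class = "pipeline_config")
}

log_line <- function(con, stage, event, ...) {
  rec <- c(list(stage = stage, event = event), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order, writing per-stage CSV/JSON outputs,
#' a JSON-lines log with record counts in/out of every filter, and a run
#' manifest (package version, seed, thresholds, QC counts, md5 of each
#' output). Identical config and seed give identical manifest hashes. A
#' stage failure aborts with the stage name in the error.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  logfile <- file.path(outdir, "run_log.jsonl")
  con <- file(logfile, open = "wt")
  on.exit(close(con), add = TRUE)
  qc_all <- list()
  outputs <- character()
  in_stage <- function(name, enabled, code) {
    if (!enabled) return(NULL)
    tryCatch(code, error = function(e) {
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # --- generate / load -------------------------------------------------
  study <- in_stage("generate", TRUE, {
    if (config$stages[["generate"]]) {
      gen <- config$generator
      gen$seed <- stage_seed(config$seed, "generate")
      st <- generate_study(gen)
      paths <- write_study(st, file.path(outdir, "input"))
      outputs <- c(outputs, paths)
      log_line(con, "generate", "done", n_registration = nrow(st$registration),
               n_results = nrow(st$results), n_lab = nrow(st$lab))
      st
    } else {
      rd <- function(f) utils::read.csv(file.path(config$input_dir, f),
                                        stringsAsFactors = FALSE)
      st <- list(registration = rd("registration.csv"),
                 results = rd("results.csv"), lab = rd("lab.csv"))
      log_line(con, "generate", "loaded_from_disk", dir = config$input_dir)
      st
    }
  })

  # --- harmonize -------------------------------------------------------
  tab <- in_stage("harmonize", config$stages[["harmonize"]], {
    t <- harmonize_study(study)
    qc_all$harmonize <- attr(t, "qc")
    f <- file.path(outdir, "integrated.csv")
    utils::write.csv(as.data.frame(t), f, row.names = FALSE, na = "")
    outputs <- c(outputs, f)
    log_line(con, "harmonize", "done", n_rows = nrow(t),
             n_density_excluded = attr(t, "qc")$n_density_excluded %||% 0)
    t
  })
  if (is.null(tab)) {
    stop("stage harmonize failed: downstream stages need the integrated table",
         call. = FALSE)
  }
  tab <- add_flour_proportions(tab)

  numeric_vars <- intersect(
    c("backslop_frequency", "ferment_temp_C", "ferment_time_h",
      "storage_temp_C", "dough_yield", "flour_g", "sourdough_age_y",
      "ph_home", "ph_bread_home", "bread_density", "tta", "latitude"),
    names(tab))
  categorical_vars <- intersect(
    c("grain_base", "milling_grade_grouped", "organic_flour", "source", "skill"),
    names(tab))

  # --- collinearity ----------------------------------------------------
  kept_vars <- numeric_vars
  in_stage("collinearity", config$stages[["collinearity"]], {
    spec <- c(stats::setNames(rep("numeric", length(numeric_vars)), numeric_vars),
              stats::setNames(rep("categorical", length(categorical_vars)),
                              categorical_vars))
    am <- suppressWarnings(association_matrix(tab, spec))
    kept <- select_representatives(am, config$collinearity_threshold)
    kept_vars <- intersect(kept, numeric_vars)
    f1 <- file.path(outdir, "association_matrix.csv")
    utils::write.csv(am$values, f1, na = "")
    f2 <- file.path(outdir, "collinearity_decisions.json")
    jsonlite::write_json(attr(kept, "decisions"), f2, auto_unbox = TRUE)
    outputs <- c(outputs, f1, f2)
    log_line(con, "collinearity", "done", n_variables = length(spec),
             n_kept = length(kept))
  })

  # --- pairwise --------------------------------------------------------
  in_stage("pairwise", config$stages[["pairwise"]], {
    sc <- source_contrast(tab)
    log_line(con, "pairwise", "source_filter", n_in = nrow(tab),
             n_out = nrow(sc), n_excluded = attr(sc, "n_excluded"))
    pw <- pairwise_table(sc, intersect(numeric_vars, names(sc)), "source",
                         levels = c("bakery", "household"))
    f <- file.path(outdir, "pairwise_source.csv")
    utils::write.csv(pw, f, row.names = FALSE, na = "")
    outputs <- c(outputs, f)
    wr <- tab[!is.na(tab$grain_base) & tab$grain_base %in% c("wheat", "rye"), ]
    pw2 <- pairwise_table(wr, intersect(c("dough_yield", "ph_home", "tta",
                                          "bread_density"), names(wr)),
                          "grain_base", levels = c("rye", "wheat"))
    f2 <- file.path(outdir, "pairwise_substrate.csv")
    utils::write.csv(pw2, f2, row.names = FALSE, na = "")
    outputs <- c(outputs, f2)
    log_line(con, "pairwise", "done", n_source_tests = nrow(pw),
             n_substrate_tests = nrow(pw2))
  })

  # --- enrichment ------------------------------------------------------
  in_stage("enrichment", config$stages[["enrichment"]], {
    ecfg <- enrichment_config(epsilon = config$epsilon, alpha = config$alpha)
    geo <- suppressWarnings(geo_filter(tab, ecfg$geo_bounds))
    log_line(con, "enrichment", "geo_filter", n_in = nrow(tab),
             n_out = nrow(geo), n_excluded = attr(geo, "n_excluded"))
    part <- cluster_partition(
      "country",
      stats::setNames(as.character(geo$country), geo$sample_code),
      min_cluster_size = 5L)
    enr <- list()
    for (v in intersect(c("flour_type", "grain_base", "milling_grade_grouped",
                          "organic_flour"), names(geo))) {
      labels <- stats::setNames(bin_rare_levels(geo[[v]]), geo$sample_code)
      e <- tryCatch(suppressWarnings(category_enrichment(labels, part, ecfg)),
                    error = function(err) NULL)
      if (!is.null(e)) {
        e$variable <- v
        enr[[v]] <- as.data.frame(e)
      }
    }
    for (v in intersect(c("tta", "dough_yield", "backslop_frequency", "ph_home"),
                        names(geo))) {
      vals <- stats::setNames(geo[[v]], geo$sample_code)
      e <- tryCatch(suppressWarnings(numeric_enrichment(vals, part, ecfg)),
                    error = function(err) NULL)
      if (!is.null(e)) {
        e$feature <- v
        e$variable <- v
        enr[[paste0("num_", v)]] <- as.data.frame(e)
      }
    }
    all_enr <- do.call(rbind, lapply(enr, function(d) {
      d[, c("variable", "feature", "cluster", "score", "log2_score", "p", "q",
            "effect_size", "direction", "multiplicity")]
    }))
    f <- file.path(outdir, "enrichment.csv")
    utils::write.csv(all_enr, f, row.names = FALSE, na = "")
    outputs <- c(outputs, f)
    log_line(con, "enrichment", "done", n_records = nrow(all_enr))
  })

  # --- CATA ------------------------------------------------------------
  in_stage("cata", config$stages[["cata"]], {
    cata_cols <- grep("^cata_", names(tab), value = TRUE)
    if (!length(cata_cols)) {
      log_line(con, "cata", "skipped", reason = "no CATA columns")
    } else {
      sub <- tab[, c("sample_code", cata_cols)]
      complete <- stats::complete.cases(sub[, cata_cols])
      sub <- sub[complete, ]
      cm_raw <- as.matrix(sub[, cata_cols])
      rownames(cm_raw) <- sub$sample_code
      cm <- cata_matrix(cm_raw)
      d <- jaccard_matrix(cm)
      ord <- pcoa(d)
      pc12 <- sum(ord$proportion_explained[1:2]) * 100
      f_coord <- file.path(outdir, "cata_pcoa_coordinates.csv")
      utils::write.csv(data.frame(sample_code = rownames(ord$coordinates),
                                  ord$coordinates[, 1:2]),
                       f_coord, row.names = FALSE)
      tf <- top_features(cm, ord, k = 10)
      f_top <- file.path(outdir, "cata_top_features.csv")
      utils::write.csv(tf, f_top, row.names = FALSE)
      pb <- permanova_batch(d, tab, intersect(categorical_vars, names(tab)),
                            n_perm = config$n_perm,
                            seed = stage_seed(config$seed, "cata_permanova"))
      mb <- mantel_batch(d, tab, intersect(kept_vars, names(tab)),
                         n_perm = config$n_perm,
                         seed = stage_seed(config$seed, "cata_mantel"))
      f_perm <- file.path(outdir, "cata_permanova.csv")
      f_mant <- file.path(outdir, "cata_mantel.csv")
      utils::write.csv(pb, f_perm, row.names = FALSE, na = "")
      utils::write.csv(mb, f_mant, row.names = FALSE, na = "")
      jsonlite::write_json(list(
        eigenvalues = ord$eigenvalues,
        proportion_explained = ord$proportion_explained,
        pc1_pc2_percent = pc12,
        negative = ord$negative_eigenvalue_report),
        file.path(outdir, "cata_eigen_report.json"), auto_unbox = TRUE,
        digits = NA)
      outputs <- c(outputs, f_coord, f_top, f_perm, f_mant,
                   file.path(outdir, "cata_eigen_report.json"))
      log_line(con, "cata", "done", n_samples = nrow(cm),
               pc1_pc2_percent = pc12)
    }
  })

  # --- feature space ---------------------------------------------------
  in_stage("feature_space", config$stages[["feature_space"]], {
    for (variant in c("geographic", "substrate")) {
      vars <- intersect(pca_variant_variables(variant), names(tab))
      vars <- intersect(vars, union(kept_vars,
                                    c("latitude", "prop_wheat", "prop_rye",
                                      "prop_spelt")))
      res <- tryCatch(pca(tab, vars), error = function(e) NULL)
      if (is.null(res)) {
        log_line(con, "feature_space", "skipped", variant = variant)
        next
      }
      codes <- rownames(res$scores)
      grp <- tab$source[match(codes, tab$sample_code)]
      ell <- suppressWarnings(
        confidence_ellipse(res$scores[, 1:2, drop = FALSE], grp))
      f_s <- file.path(outdir, paste0("pca_scores_", variant, ".csv"))
      f_l <- file.path(outdir, paste0("pca_loadings_", variant, ".csv"))
      f_e <- file.path(outdir, paste0("pca_ellipses_", variant, ".csv"))
      utils::write.csv(data.frame(sample_code = codes,
                                  res$scores[, 1:2, drop = FALSE]),
                       f_s, row.names = FALSE)
      utils::write.csv(res$loadings, f_l, na = "")
      utils::write.csv(ell, f_e, row.names = FALSE)
      outputs <- c(outputs, f_s, f_l, f_e)
      log_line(con, "feature_space", "done", variant = variant,
               n = nrow(res$scores),
               evr1 = res$explained_variance_ratio[1])
    }
  })

  manifest <- list(
    package = "sourveyor",
    version = as.character(utils::packageVersion("sourveyor")),
    seed = config$seed,
    thresholds = list(alpha = config$alpha, epsilon = config$epsilon,
                      collinearity_threshold = config$collinearity_threshold,
                      n_perm = config$n_perm),
    stages = as.list(config$stages),
    qc = qc_all,
    outputs = as.list(tools::md5sum(sort(unique(outputs[file.exists(outputs)]))))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `generate` (synthetic tables only), `analyze` (full
#' pipeline), `report` (print a run's manifest). Flags: `--config <path>`
#' (JSON or YAML pipeline/generator settings), `--seed <int>`, `--outdir
#' <path>`. Returns 0 on success and 2 on validation failure.
#'
#' @param args character vector, default the command line.
#' @return integer exit code, invisibly.
#' @export
pipeline_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  fail <- function(...) { message(...); return(invisible(2L)) }
  if (!length(args)) {
    return(fail("usage: sourveyor <generate|analyze|report> [--config f] ",
                "[--seed n] [--outdir d]"))
  }
  cmd <- args[1]
  opt <- list(seed = 1L, outdir = "sourveyor_out", config = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args)) {
      return(fail("unknown or incomplete flag: ", args[i]))
    }
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  opt$seed <- suppressWarnings(as.integer(opt$seed))
  if (is.na(opt$seed)) return(fail("--seed must be an integer"))

  cfg_list <- list()
  if (!is.null(opt$config)) {
    if (!file.exists(opt$config)) return(fail("config file not found: ", opt$config))
    cfg_list <- if (grepl("\\.ya?ml$", opt$config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        return(fail("yaml package required for YAML configs"))
      }
      yaml::read_yaml(opt$config)
    } else {
      jsonlite::fromJSON(opt$config, simplifyVector = TRUE)
    }
  }
  gen_args <- cfg_list$generator %||% list()
  gen_args$seed <- opt$seed          # --seed overrides config
  gen <- tryCatch(do.call(generator_config, gen_args),
                  error = function(e) e)
  if (inherits(gen, "error")) return(fail("invalid config: ", conditionMessage(gen)))

  if (cmd == "generate") {
    study <- generate_study(gen)
    write_study(study, opt$outdir)
    message("wrote synthetic study to ", opt$outdir)
    return(invisible(0L))
  }
  if (cmd == "analyze") {
    pc_args <- cfg_list$pipeline %||% list()
    pc_args$generator <- gen
    pc_args$outdir <- opt$outdir
    pc_args$seed <- opt$seed
    pc <- tryCatch(do.call(pipeline_config, pc_args), error = function(e) e)
    if (inherits(pc, "error")) return(fail("invalid config: ", conditionMessage(pc)))
    run_pipeline(pc)
    message("pipeline complete: ", opt$outdir)
    return(invisible(0L))
  }
  if (cmd == "report") {
    mf <- file.path(opt$outdir, "manifest.json")
    if (!file.exists(mf)) return(fail("no manifest at ", mf))
    cat(readLines(mf), sep = "\n")
    return(invisible(0L))
  }
  fail("unknown subcommand: ", cmd)
}
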