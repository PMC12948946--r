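# Synthetic citizen-science sourdough study generator.
#
# Emulates the statistical structure the downstream analyses assume: three
# linked tables (registration survey, at-home results survey, laboratory
# measurements) keyed by 5-character sample codes and person IDs, plus a
# ground-truth registry of planted effects for recovery testing.

#' Load the aroma descriptor inventory
#'
#' 56 check-all-that-apply (CATA) descriptors organised into 13 flavour
#' categories, shipped as an editable JSON resource.
#'
#' @return named list: category -> character vector of descriptors.
#' @export
aroma_descriptors <- function() {
  path <- system.file("extdata", "aroma_descriptors.json", package = "sourveyor")
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

# flat descriptor -> category map
descriptor_category_map <- function(inv = aroma_descriptors()) {
  cats <- rep(names(inv), lengths(inv))
  stats::setNames(cats, unlist(inv, use.names = FALSE))
}

#' Default country inventory
#'
#' Hub countries plus the strongest non-hub contributor (Germany), a smaller
#' European country and one non-European country so that the European
#' bounding-box filter is exercised. Coordinates are country centroids in
#' degrees; weights are registration shares and sum to 1.
#'
#' @return data.frame with columns `name`, `latitude`, `longitude`, `weight`.
#' @export
default_countries <- function() {
  data.frame(
    name = c("Switzerland", "Finland", "Belgium", "Italy", "Romania",
             "Germany", "Austria", "Australia"),
    latitude = c(46.80, 61.92, 50.50, 42.83, 45.94, 51.17, 47.52, -25.27),
    longitude = c(8.23, 25.75, 4.47, 12.83, 24.97, 10.45, 14.55, 133.78),
    weight = c(0.20, 0.15, 0.14, 0.12, 0.12, 0.17, 0.05, 0.05),
    stringsAsFactors = FALSE
  )
}

#' Default flour profile
#'
#' Marginal distributions of grain base and milling grade, shared across
#' countries by default: country-specific flour structure is planted through
#' the effect registry so that a registry-free configuration is a clean null.
#' Semi-wholemeal is restricted to wheat downstream (the only grain it was
#' available for).
#'
#' @return list with `grain_base` and `milling_grade` probability vectors.
#' @export
default_flour_profile <- function() {
  list(
    grain_base = c(wheat = 0.53, rye = 0.30, spelt = 0.10, mixture = 0.07),
    milling_grade = c(wholemeal = 0.35, `semi-wholemeal` = 0.08,
                      endosperm = 0.30, unspecified = 0.27)
  )
}

#' Construct a planted effect
#'
#' One entry of the generator's effect registry. `magnitude` is on the
#' feature's natural scale: an odds multiplier for `categorical_enrichment`,
#' a standardised (SD-unit) shift for `mean_shift`, a probability delta for
#' `aroma_association`, and a correlation coefficient for `correlation`
#' (where `cluster_variable` names the partner numeric feature and
#' `cluster_level` is unused).
#'
#' @param kind one of `"categorical_enrichment"`, `"mean_shift"`,
#'   `"aroma_association"`, `"correlation"`.
#' @param target_feature field (or CATA descriptor) the effect acts on.
#' @param cluster_variable field defining the affected subgroup.
#' @param cluster_level level of `cluster_variable` receiving the effect.
#' @param magnitude effect size on the natural scale (see Details).
#' @param target_level for categorical targets, the level whose odds are
#'   multiplied.
#' @return object of class `planted_effect`.
#' @export
planted_effect <- function(kind, target_feature, cluster_variable,
                           cluster_level = NULL, magnitude = 1,
                           target_level = NULL) {
  kind <- match.arg(kind, c("categorical_enrichment", "mean_shift",
                            "aroma_association", "correlation"))
  if (!is.finite(magnitude)) stop("effect magnitude must be finite", call. = FALSE)
  structure(list(kind = kind, target_feature = target_feature,
                 cluster_variable = cluster_variable,
                 cluster_level = cluster_level, magnitude = magnitude,
                 target_level = target_level),
            class = "planted_effect")
}

#' Default planted-effect registry
#'
#' Encodes, as generator ground truth, the practice/substrate effects the
#' analysis is designed to detect: rye substrates raise TTA, dough yield and
#' bread density and lower home pH; bakery sourdoughs are refreshed more
#' often, stored warmer, fermented warmer, larger and older; rye sourdoughs
#' smell sour more often while wheat associates with chemical notes; and
#' German-speaking countries over-select wholemeal rye and organic flour.
#'
#' @return list of [planted_effect()] objects.
#' @export
default_effect_registry <- function() {
  list(
    planted_effect("mean_shift", "tta", "grain_base", "rye", 0.75),
    planted_effect("mean_shift", "dough_yield", "grain_base", "rye", 0.60),
    planted_effect("mean_shift", "ph_home", "grain_base", "rye", -0.25),
    planted_effect("mean_shift", "bread_density", "grain_base", "rye", 0.70),
    planted_effect("mean_shift", "backslop_frequency", "source", "bakery", 1.00),
    planted_effect("mean_shift", "storage_temp_C", "source", "bakery", 0.80),
    planted_effect("mean_shift", "sourdough_age_y", "source", "bakery", 0.80),
    planted_effect("mean_shift", "flour_g", "source", "bakery", 0.80),
    planted_effect("mean_shift", "ferment_temp_C", "source", "bakery", 0.60),
    planted_effect("aroma_association", "sour", "grain_base", "rye", 0.25),
    planted_effect("aroma_association", "chemical", "grain_base", "wheat", 0.12),
    planted_effect("categorical_enrichment", "flour_type", "country", "Germany",
                   2.5, target_level = "wholemeal rye"),
    planted_effect("categorical_enrichment", "organic_flour", "country",
                   "Switzerland", 2.0, target_level = "yes")
  )
}

# fields eligible for MCAR missingness (keys and country/coords excluded by
# default missingness = 0 there)
generator_fields <- function() {
  c("latitude", "longitude", "source", "flour_type", "organic_flour",
    "flour_g", "water_g", "backslop_frequency", "ferment_temp_C",
    "ferment_time_h", "storage_temp_C", "sourdough_age_y", "skill",
    "motivations", "benefits", "n_sourdoughs_maintained",
    "ph_home", "ph_bread_home", "bread_density", "cata",
    "ph_lab", "tta")
}

#' Generator configuration
#'
#' The stated world of the synthetic study. Defaults emulate the deposited
#' study's headline structure: ~12.8% bakery sourdoughs (87.2% household),
#' a shared flour profile across countries (country structure is planted via
#' the effect registry), home pH reported on a 0.25-unit strip scale while
#' laboratory pH is continuous and on average `ph_lab_offset` units lower,
#' 56 CATA descriptors in 13 categories, and MCAR per-field missingness.
#'
#' @param n_participants number of persons; each owns 1-5 samples.
#' @param countries data.frame with `name`, `latitude`, `longitude`, `weight`
#'   (weights sum to 1 within 1e-9).
#' @param p_bakery probability a sample is of bakery (non-household) origin.
#' @param flour_profile list with `grain_base` and `milling_grade`
#'   probability vectors (see [default_flour_profile()]); may instead be a
#'   named list of such lists keyed by country name for per-country profiles.
#' @param effect_registry list of [planted_effect()]; `list()` for a null
#'   world.
#' @param missingness either a single probability applied to all non-key
#'   fields or a named list/vector of per-field probabilities in [0, 1).
#' @param p_submit probability a registered sample was actually submitted
#'   (and therefore has results and laboratory rows).
#' @param ph_lab_offset systematic lab-minus-home pH offset (default -0.73,
#'   further acidification during shipping plus strip-vs-metre bias).
#' @param ph_strip_step quantisation step of the home pH strip scale.
#' @param n_aroma_descriptors,n_aroma_categories size of the CATA inventory.
#' @param aroma_prevalence_range range from which per-descriptor base
#'   prevalence is drawn.
#' @param seed integer RNG seed; identical config + seed gives byte-identical
#'   tables.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_participants = 600,
                             countries = default_countries(),
                             p_bakery = 0.128,
                             flour_profile = default_flour_profile(),
                             effect_registry = default_effect_registry(),
                             missingness = NULL,
                             p_submit = 0.62,
                             ph_lab_offset = -0.73,
                             ph_strip_step = 0.25,
                             n_aroma_descriptors = 56,
                             n_aroma_categories = 13,
                             aroma_prevalence_range = c(0.02, 0.45),
                             seed = 1L) {
  if (!is.numeric(n_participants) || length(n_participants) != 1 ||
      is.na(n_participants) || n_participants < 1) {
    stop("n_participants must be a positive integer", call. = FALSE)
  }
  stopifnot(is.data.frame(countries),
            all(c("name", "latitude", "longitude", "weight") %in% names(countries)))
  if (abs(sum(countries$weight) - 1) > 1e-9) {
    stop("country weights must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  assert_prob(p_bakery, "p_bakery")
  assert_prob(p_submit, "p_submit")
  assert_prob(aroma_prevalence_range, "aroma_prevalence_range")

  default_miss <- list(
    latitude = 0.01, longitude = 0.01, source = 0.005, flour_type = 0.02,
    organic_flour = 0.05, flour_g = 0.08, water_g = 0.08,
    backslop_frequency = 0.05, ferment_temp_C = 0.08, ferment_time_h = 0.08,
    storage_temp_C = 0.08, sourdough_age_y = 0.05, skill = 0.03,
    motivations = 0.02, benefits = 0.10, n_sourdoughs_maintained = 0.03,
    ph_home = 0.15, ph_bread_home = 0.25, bread_density = 0.25, cata = 0.15,
    ph_lab = 0.02, tta = 0.03
  )
  miss <- stats::setNames(rep(0, length(generator_fields())), generator_fields())
  if (is.null(missingness)) {
    miss[names(default_miss)] <- unlist(default_miss)
  } else if (length(missingness) == 1 && is.null(names(missingness))) {
    miss[] <- as.numeric(missingness)
  } else {
    m <- unlist(missingness)
    unknown <- setdiff(names(m), names(miss))
    if (length(unknown)) {
      stop("unknown missingness fields: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    miss[names(m)] <- m
  }
  if (any(miss < 0 | miss >= 1)) stop("missingness must be in [0, 1)", call. = FALSE)

  per_country <- !is.null(names(flour_profile)) &&
    all(names(flour_profile) %in% countries$name)
  check_profile <- function(p) {
    stopifnot(is.list(p), all(c("grain_base", "milling_grade") %in% names(p)))
    assert_prob(p$grain_base, "grain_base profile")
    assert_prob(p$milling_grade, "milling_grade profile")
  }
  if (per_country) lapply(flour_profile, check_profile) else check_profile(flour_profile)

  cfg <- structure(list(
    n_participants = as.integer(n_participants), countries = countries,
    p_bakery = p_bakery, flour_profile = flour_profile,
    flour_profile_per_country = per_country,
    effect_registry = effect_registry, missingness = miss,
    p_submit = p_submit, ph_lab_offset = ph_lab_offset,
    ph_strip_step = ph_strip_step,
    n_aroma_descriptors = as.integer(n_aroma_descriptors),
    n_aroma_categories = as.integer(n_aroma_categories),
    aroma_prevalence_range = aroma_prevalence_range,
    seed = as.integer(seed)
  ), class = "generator_config")
  validate_effects(cfg)
  cfg
}

# effect targets must exist in the generated world
validate_effects <- function(cfg) {
  numeric_fields <- c("tta", "dough_yield", "ph_home", "ph_bread_home",
                      "bread_density", "backslop_frequency", "ferment_temp_C",
                      "ferment_time_h", "storage_temp_C", "sourdough_age_y",
                      "flour_g", "water_g", "ph_lab",
                      "n_sourdoughs_maintained")
  categorical_fields <- c("flour_type", "grain_base", "milling_grade",
                          "organic_flour", "source", "country", "skill")
  descriptors <- names(descriptor_category_map())
  for (e in cfg$effect_registry) {
    if (!inherits(e, "planted_effect")) stop("effect_registry entries must be planted_effect objects", call. = FALSE)
    ok <- switch(e$kind,
      categorical_enrichment = e$target_feature %in% categorical_fields,
      mean_shift = e$target_feature %in% numeric_fields,
      aroma_association = e$target_feature %in% descriptors,
      correlation = e$target_feature %in% numeric_fields &&
        e$cluster_variable %in% numeric_fields)
    if (!isTRUE(ok)) {
      stop("unknown effect target: ", e$target_feature, " (kind ", e$kind, ")",
           call. = FALSE)
    }
    if (e$kind != "correlation" && !e$cluster_variable %in%
          c(categorical_fields, "country")) {
      stop("unknown effect cluster variable: ", e$cluster_variable, call. = FALSE)
    }
  }
  invisible(cfg)
}

# encode integers as 5-char [A-Z0-9] codes; sampled without replacement from
# the 36^5 space so codes are collision-free by construction
encode_codes <- function(idx) {
  alphabet <- c(LETTERS, 0:9)
  idx <- idx - 1
  out <- character(length(idx))
  for (pos in 5:1) {
    out <- paste0(alphabet[idx %% 36 + 1], out)
    idx <- idx %/% 36
  }
  out
}

draw_categorical <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# multiply the odds of one level within a probability vector; the remaining
# levels are rescaled proportionally so the realised odds ratio is exact
apply_odds <- function(probs, level, mult) {
  p <- probs[[level]]
  odds <- mult * p / (1 - p)
  p_new <- odds / (1 + odds)
  out <- probs * (1 - p_new) / (1 - p)
  out[level] <- p_new
  out
}

quantise <- function(x, step) round(x / step) * step

#' Generate a synthetic sourdough study
#'
#' Draws registration, results and laboratory tables linked by unique
#' 5-character sample codes, applies every effect in the configuration's
#' registry, injects MCAR missingness, and returns the ground-truth registry
#' alongside the tables. Identical configuration and seed give byte-identical
#' tables; the caller's RNG state is left untouched.
#'
#' @param config a [generator_config()].
#' @return list of class `sourdough_study` with elements `registration`,
#'   `results`, `lab` (data.frames) and `truth` (class `synthetic_truth`:
#'   `effects`, `null_features`).
#' @export
generate_study <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop("config must be a generator_config", call. = FALSE)
  }
  with_seed(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(cfg) {
  np <- cfg$n_participants
  # 1-5 samples per person, ~90% single-sample owners
  n_per <- ifelse(stats::runif(np) < 0.90, 1L, sample(2:5, np, replace = TRUE))
  person_id <- rep(sprintf("P%05d", seq_len(np)), n_per)
  n <- length(person_id)
  sample_code <- encode_codes(sample.int(36L^5L, n))

  # geography: person-level country, per-sample jittered coordinates
  ctry <- cfg$countries
  person_country <- sample(ctry$name, np, replace = TRUE, prob = ctry$weight)
  country <- rep(person_country, n_per)
  ci <- match(country, ctry$name)
  latitude <- round(ctry$latitude[ci] + stats::rnorm(n, 0, 1.5), 2)
  longitude <- round(ctry$longitude[ci] + stats::rnorm(n, 0, 2.0), 2)

  # source: mostly household; one rare industrial label and rare unknowns
  src_p <- c(household = 1 - cfg$p_bakery - 0.008,
             bakery = cfg$p_bakery, industrial = 0.003, unknown = 0.005)
  source <- draw_categorical(n, src_p)

  effects <- cfg$effect_registry

  # flour: grain base and milling grade, composed into a survey-style label
  grain_base <- character(n)
  milling_grade <- character(n)
  for (cn in unique(country)) {
    rows <- which(country == cn)
    prof <- if (cfg$flour_profile_per_country) cfg$flour_profile[[cn]] else cfg$flour_profile
    gb <- prof$grain_base
    mg <- prof$milling_grade
    for (e in effects) {
      if (e$kind == "categorical_enrichment" && e$cluster_variable == "country" &&
          identical(e$cluster_level, cn)) {
        if (e$target_feature == "grain_base" && e$target_level %in% names(gb)) {
          gb <- apply_odds(gb, e$target_level, e$magnitude)
        }
        if (e$target_feature == "milling_grade" && e$target_level %in% names(mg)) {
          mg <- apply_odds(mg, e$target_level, e$magnitude)
        }
      }
    }
    grain_base[rows] <- draw_categorical(length(rows), gb)
    milling_grade[rows] <- draw_categorical(length(rows), mg)
  }
  # semi-wholemeal only existed for wheat
  milling_grade[milling_grade == "semi-wholemeal" & grain_base != "wheat"] <- "wholemeal"
  flour_type <- ifelse(milling_grade == "unspecified", grain_base,
                       paste(milling_grade, grain_base))

  # composite-label odds effects (e.g. wholemeal rye in one country) are
  # applied by resampling the affected rows' labels
  for (e in effects) {
    if (e$kind == "categorical_enrichment" && e$target_feature == "flour_type") {
      rows <- which(get_cluster_vector(e$cluster_variable, country, source,
                                       grain_base, milling_grade, NULL) ==
                      e$cluster_level)
      if (!length(rows)) next
      tab <- table(flour_type)
      probs <- tab / sum(tab)
      if (!e$target_level %in% names(probs)) {
        probs <- c(probs, stats::setNames(0.02, e$target_level))
        probs <- probs / sum(probs)
      }
      probs <- apply_odds(probs, e$target_level, e$magnitude)
      flour_type[rows] <- draw_categorical(length(rows), probs)
      dec <- decompose_flour(flour_type[rows])
      grain_base[rows] <- dec$grain_base
      milling_grade[rows] <- dec$milling_grade
    }
  }

  organic_p <- c(yes = 0.60, no = 0.36, unknown = 0.04)
  organic_flour <- character(n)
  for (cn in unique(country)) {
    rows <- which(country == cn)
    op <- organic_p
    for (e in effects) {
      if (e$kind == "categorical_enrichment" && e$target_feature == "organic_flour" &&
          e$cluster_variable == "country" && identical(e$cluster_level, cn)) {
        op <- apply_odds(op, e$target_level, e$magnitude)
      }
    }
    organic_flour[rows] <- draw_categorical(length(rows), op)
  }
  for (e in effects) {
    if (e$kind == "categorical_enrichment" && e$target_feature == "organic_flour" &&
        e$cluster_variable != "country") {
      clu <- get_cluster_vector(e$cluster_variable, country, source, grain_base,
                                milling_grade, NULL)
      rows <- which(clu == e$cluster_level)
      if (length(rows)) {
        organic_flour[rows] <- draw_categorical(length(rows),
                                                apply_odds(organic_p, e$target_level, e$magnitude))
      }
    }
  }

  # numeric baselines (units: g, events/week, deg C, hours, years, pH, g/cm3)
  flour_g <- exp(stats::rnorm(n, log(100), 0.5))
  dy_target <- pmin(pmax(stats::rnorm(n, 200, 30), 105), 350)
  water_g <- flour_g * (dy_target / 100 - 1)
  backslop_frequency <- pmax(exp(stats::rnorm(n, log(1.5), 0.7)), 0.05)
  ferment_temp_C <- stats::rnorm(n, 21, 2.5)
  ferment_time_h <- exp(stats::rnorm(n, log(12), 0.6))
  storage_temp_C <- pmax(stats::rnorm(n, 8, 4), -2)
  sourdough_age_y <- exp(stats::rnorm(n, log(2), 1.0))
  n_sourdoughs_maintained <- 1L + stats::rpois(n, 0.6)
  ph_home_true <- pmin(pmax(stats::rnorm(n, 3.9, 0.35), 3.0), 5.5)
  ph_bread_true <- 1.6 + 0.9 * ph_home_true + stats::rnorm(n, 0, 0.25)
  bread_density <- pmin(pmax(stats::rnorm(n, 0.45, 0.12), 0.15), 0.95)
  # ~2% physically impossible densities (> 1 g/cm3), the QC filter's target
  bad <- stats::runif(n) < 0.02
  bread_density[bad] <- stats::runif(sum(bad), 1.01, 1.6)
  tta <- pmax(stats::rnorm(n, 11, 3), 2)

  num <- list(flour_g = flour_g, water_g = water_g,
              backslop_frequency = backslop_frequency,
              ferment_temp_C = ferment_temp_C, ferment_time_h = ferment_time_h,
              storage_temp_C = storage_temp_C, sourdough_age_y = sourdough_age_y,
              n_sourdoughs_maintained = n_sourdoughs_maintained,
              ph_home = ph_home_true, ph_bread_home = ph_bread_true,
              bread_density = bread_density, tta = tta)

  # planted standardised mean shifts; dough_yield shifts act on water_g so the
  # derived DY remains consistent with the reported ingredient masses
  for (e in effects) {
    if (e$kind != "mean_shift") next
    clu <- get_cluster_vector(e$cluster_variable, country, source, grain_base,
                              milling_grade, NULL)
    rows <- which(clu == e$cluster_level)
    if (!length(rows)) next
    if (e$target_feature == "dough_yield") {
      dy <- (flour_g + num$water_g) / flour_g * 100
      num$water_g[rows] <- flour_g[rows] *
        ((dy[rows] + e$magnitude * stats::sd(dy)) / 100 - 1)
    } else {
      v <- num[[e$target_feature]]
      num[[e$target_feature]][rows] <- v[rows] + e$magnitude * stats::sd(v)
    }
  }
  # planted numeric-numeric correlations: blend the target with the partner's
  # z-scores, preserving the target's first two moments
  for (e in effects) {
    if (e$kind != "correlation") next
    x <- num[[e$cluster_variable]]
    y <- num[[e$target_feature]]
    zx <- (x - mean(x)) / stats::sd(x)
    zy <- (y - mean(y)) / stats::sd(y)
    r <- e$magnitude
    num[[e$target_feature]] <- mean(y) + stats::sd(y) *
      (r * zx + sqrt(1 - r^2) * zy)
  }

  ph_home_true <- num$ph_home
  ph_bread_true <- num$ph_bread_home

  # CATA: per-descriptor base prevalence, aroma effects shift Bernoulli p
  dmap <- descriptor_category_map()
  descriptors <- names(dmap)[seq_len(min(cfg$n_aroma_descriptors, length(dmap)))]
  base_prev <- stats::runif(length(descriptors), cfg$aroma_prevalence_range[1],
                            cfg$aroma_prevalence_range[2])
  names(base_prev) <- descriptors
  prominent <- c(fermented = 0.62, grain = 0.55, sour = 0.45, yoghurt = 0.40,
                 apple = 0.35, ocean = 0.02, animal = 0.03, body_odour = 0.02)
  keep <- intersect(names(prominent), descriptors)
  base_prev[keep] <- prominent[keep]
  pmat <- matrix(base_prev, nrow = n, ncol = length(descriptors), byrow = TRUE)
  colnames(pmat) <- descriptors
  for (e in effects) {
    if (e$kind != "aroma_association") next
    clu <- get_cluster_vector(e$cluster_variable, country, source, grain_base,
                              milling_grade, NULL)
    rows <- which(clu == e$cluster_level)
    shifted <- pmat[rows, e$target_feature] + e$magnitude
    out_of_range <- shifted < 0 | shifted > 1
    if (any(out_of_range)) {
      message("aroma_association on '", e$target_feature,
              "': ", sum(out_of_range), " probabilities clipped to [0, 1]")
    }
    pmat[rows, e$target_feature] <- pmin(pmax(shifted, 0), 1)
  }
  cata <- matrix(as.integer(stats::runif(n * length(descriptors)) <
                              as.vector(pmat)), nrow = n)
  colnames(cata) <- paste0("cata_", descriptors)

  # measurement layer: strip-quantised home pH, continuous lab pH with the
  # systematic shipping/instrument offset, lab TTA
  ph_home <- quantise(ph_home_true, cfg$ph_strip_step)
  ph_bread_home <- quantise(ph_bread_true, cfg$ph_strip_step)
  ph_lab <- ph_home_true + cfg$ph_lab_offset + stats::rnorm(n, 0, 0.08)

  skill_levels <- c("beginner", "intermediate", "advanced", "professional")
  skill <- ifelse(source == "bakery",
                  sample(skill_levels, n, replace = TRUE, prob = c(0.02, 0.08, 0.30, 0.60)),
                  sample(skill_levels, n, replace = TRUE, prob = c(0.25, 0.40, 0.30, 0.05)))

  motivation_opts <- c(taste = 0.70, enjoyment = 0.65, health = 0.35,
                       tradition = 0.20, sustainability = 0.25,
                       financial = 0.10, curiosity = 0.40)
  benefit_opts <- c(gastrointestinal = 0.45, digestibility = 0.35,
                    gut_health = 0.30, nutrition = 0.25,
                    general_wellbeing = 0.20, fewer_intolerances = 0.15,
                    glucose_control = 0.08, none = 0.10)
  multiselect <- function(opts) {
    hits <- matrix(stats::runif(n * length(opts)) < rep(opts, each = n), nrow = n)
    apply(hits, 1, function(h) paste(names(opts)[h], collapse = ";"))
  }
  motivations <- multiselect(motivation_opts)
  benefits <- multiselect(benefit_opts)

  registration <- data.frame(
    sample_code = sample_code, person_id = person_id, country = country,
    latitude = latitude, longitude = longitude, source = source,
    flour_type = flour_type, organic_flour = organic_flour,
    flour_g = round(num$flour_g, 1), water_g = round(num$water_g, 1),
    backslop_frequency = round(num$backslop_frequency, 2),
    ferment_temp_C = round(num$ferment_temp_C, 1),
    ferment_time_h = round(num$ferment_time_h, 1),
    storage_temp_C = round(num$storage_temp_C, 1),
    sourdough_age_y = round(num$sourdough_age_y, 2),
    n_sourdoughs_maintained = num$n_sourdoughs_maintained,
    skill = skill, motivations = motivations, benefits = benefits,
    stringsAsFactors = FALSE
  )

  submitted <- stats::runif(n) < cfg$p_submit
  results <- data.frame(
    sample_code = sample_code, person_id = person_id,
    ph_home = ph_home, ph_bread_home = ph_bread_home,
    bread_density = round(num$bread_density, 3),
    backslop_frequency = registration$backslop_frequency,
    ferment_temp_C = registration$ferment_temp_C,
    stringsAsFactors = FALSE
  )
  results <- cbind(results, as.data.frame(cata))
  results <- results[submitted, , drop = FALSE]
  rownames(results) <- NULL

  lab <- data.frame(
    sample_code = sample_code, ph_lab = round(ph_lab, 2),
    tta = round(num$tta, 2), stringsAsFactors = FALSE
  )[submitted, , drop = FALSE]
  rownames(lab) <- NULL

  # MCAR missingness, per field; "cata" blanks the whole descriptor block
  miss <- cfg$missingness
  inject <- function(df, field, col = field) {
    if (!col %in% names(df) || miss[[field]] <= 0) return(df)
    df[[col]][stats::runif(nrow(df)) < miss[[field]]] <- NA
    df
  }
  for (f in c("latitude", "longitude", "source", "flour_type", "organic_flour",
              "flour_g", "water_g", "backslop_frequency", "ferment_temp_C",
              "ferment_time_h", "storage_temp_C", "sourdough_age_y", "skill",
              "motivations", "benefits", "n_sourdoughs_maintained")) {
    registration <- inject(registration, f)
  }
  for (f in c("ph_home", "ph_bread_home", "bread_density")) {
    results <- inject(results, f)
  }
  if (miss[["cata"]] > 0 && nrow(results)) {
    gone <- stats::runif(nrow(results)) < miss[["cata"]]
    results[gone, grep("^cata_", names(results))] <- NA
  }
  for (f in c("ph_lab", "tta")) lab <- inject(lab, f)

  affected <- unique(vapply(effects, function(e) e$target_feature, character(1)))
  truth <- structure(list(
    effects = effects,
    null_features = setdiff(c(names(num), "dough_yield", "flour_type",
                              "organic_flour", "skill", descriptors), affected)
  ), class = "synthetic_truth")

  structure(list(registration = registration, results = results, lab = lab,
                 truth = truth),
            class = "sourdough_study")
}

# resolve a cluster variable name to its generated vector
get_cluster_vector <- function(variable, country, source, grain_base,
                               milling_grade, skill) {
  switch(variable,
    country = country, source = source, grain_base = grain_base,
    milling_grade = milling_grade, skill = skill,
    stop("unknown cluster variable: ", variable, call. = FALSE))
}

#' Draw one CATA descriptor vector
#'
#' Single-sample counterpart of the generator's CATA layer: per-descriptor
#' base prevalence is drawn from `prevalence_range`, aroma-association
#' effects matching the sample's flour profile shift the Bernoulli
#' probability of their target descriptor (clipped to [0, 1], with a logged
#' message when clipping occurs), and one binary vector is returned.
#'
#' @param flour_profile list with `grain_base` (and optionally
#'   `milling_grade`) labels for the sample.
#' @param effect_registry list of [planted_effect()] (only
#'   `aroma_association` entries are used).
#' @param seed integer seed.
#' @param prevalence_range base prevalence range.
#' @return named integer vector in {0,1}, one entry per descriptor.
#' @export
sample_cata <- function(flour_profile, effect_registry = list(), seed = 1L,
                        prevalence_range = c(0.02, 0.45)) {
  dmap <- descriptor_category_map()
  descriptors <- names(dmap)
  with_seed(seed, {
    p <- stats::runif(length(descriptors), prevalence_range[1], prevalence_range[2])
    names(p) <- descriptors
    for (e in effect_registry) {
      if (!inherits(e, "planted_effect") || e$kind != "aroma_association") next
      matches <- identical(flour_profile[[e$cluster_variable]], e$cluster_level)
      if (!matches) next
      shifted <- p[e$target_feature] + e$magnitude
      if (shifted < 0 || shifted > 1) {
        message("aroma_association on '", e$target_feature,
                "': probability clipped to [0, 1]")
      }
      p[e$target_feature] <- min(max(shifted, 0), 1)
    }
    stats::setNames(as.integer(stats::runif(length(p)) < p), descriptors)
  })
}

#' Write a generated study to disk
#'
#' Three UTF-8 CSV files (RFC 4180 quoting) plus a `truth.json` ground-truth
#' registry.
#'
#' @param study a `sourdough_study`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sourdough_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("registration.csv", "results.csv", "lab.csv",
                            "truth.json"))
  utils::write.csv(study$registration, paths[1], row.names = FALSE, na = "")
  utils::write.csv(study$results, paths[2], row.names = FALSE, na = "")
  utils::write.csv(study$lab, paths[3], row.names = FALSE, na = "")
  truth <- list(
    effects = lapply(study$truth$effects, function(e) unclass(e)),
    null_features = study$truth$null_features
  )
  jsonlite::write_json(truth, paths[4], auto_unbox = TRUE, null = "null")
  invisible(paths)
}
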