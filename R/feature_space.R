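# PCA of non-collinear numeric metadata with group confidence ellipses,
# supporting the household-versus-bakery separation analysis.

#' PCA of numeric metadata
#'
#' Z-score standardisation followed by eigendecomposition of the correlation
#' structure (via `prcomp(scale. = TRUE)`); samples with a missing value in
#' any selected variable are excluded and recorded. A deterministic sign
#' convention is applied per axis: the loading with the largest absolute
#' value is made positive.
#'
#' @param data data.frame.
#' @param variables numeric columns entering the PCA (these should have
#'   passed collinearity selection).
#' @return object of class `pca_result`: `scores`, `loadings`,
#'   `explained_variance_ratio`, `dropped_samples` (row indices or sample
#'   codes), `variables`.
#' @export
pca <- function(data, variables) {
  stopifnot(all(variables %in% names(data)))
  x <- as.matrix(data[, variables, drop = FALSE])
  storage.mode(x) <- "double"
  complete <- stats::complete.cases(x)
  dropped <- if ("sample_code" %in% names(data)) {
    data$sample_code[!complete]
  } else which(!complete)
  x <- x[complete, , drop = FALSE]
  if (nrow(x) < 3) stop("pca needs at least 3 complete samples", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant variable(s): ", paste(variables[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  # sign convention: largest-|loading| entry positive on every axis
  for (j in seq_len(ncol(pc$rotation))) {
    lead <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[lead, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  if ("sample_code" %in% names(data)) {
    rownames(pc$x) <- data$sample_code[complete]
  }
  structure(list(
    scores = pc$x,
    loadings = pc$rotation,
    explained_variance_ratio = pc$sdev^2 / sum(pc$sdev^2),
    dropped_samples = dropped,
    variables = variables
  ), class = "pca_result")
}

#' Group confidence ellipses on a 2-D score plane
#'
#' Data ellipse from each group's 2x2 covariance of scores: semi-axes are
#' sqrt(eigenvalue x chi-square quantile at the confidence level, 2 df) and
#' the angle comes from the leading eigenvector. Groups with fewer than 5
#' samples are excluded (logged); singular covariances are skipped with a
#' warning.
#'
#' @param scores_2d n x 2 matrix of scores.
#' @param groups group labels aligned with rows.
#' @param level confidence level (default 0.95).
#' @param min_group_size groups below this size are dropped (default 5).
#' @return data.frame of `EllipseSpec` rows: group, center_x, center_y,
#'   semi_major, semi_minor, angle (radians), level, n; attribute
#'   `dropped_groups`.
#' @export
confidence_ellipse <- function(scores_2d, groups, level = 0.95,
                               min_group_size = 5) {
  s <- as.matrix(scores_2d)[, 1:2, drop = FALSE]
  g <- as.character(groups)
  ok <- !is.na(g)
  s <- s[ok, , drop = FALSE]; g <- g[ok]
  sizes <- table(g)
  small <- names(sizes)[sizes < min_group_size]
  rows <- list()
  for (lev in setdiff(names(sizes), small)) {
    sub <- s[g == lev, , drop = FALSE]
    cv <- stats::cov(sub)
    eig <- eigen(cv, symmetric = TRUE)
    if (min(eig$values) <= .Machine$double.eps * max(1, max(eig$values))) {
      warning("degenerate ellipse for group '", lev, "', skipped", call. = FALSE)
      next
    }
    scale_q <- stats::qchisq(level, df = 2)
    rows[[lev]] <- data.frame(
      group = lev,
      center_x = mean(sub[, 1]), center_y = mean(sub[, 2]),
      semi_major = sqrt(eig$values[1] * scale_q),
      semi_minor = sqrt(eig$values[2] * scale_q),
      angle = atan2(eig$vectors[2, 1], eig$vectors[1, 1]),
      level = level, n = nrow(sub), stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(group = character(), center_x = numeric(),
                      center_y = numeric(), semi_major = numeric(),
                      semi_minor = numeric(), angle = numeric(),
                      level = numeric(), n = integer())
  }
  rownames(out) <- NULL
  attr(out, "dropped_groups") <- small
  out
}

#' Variable sets for the two shipped PCA variants
#'
#' `"geographic"`: feeding parameters, home experiment results, TTA and
#' latitude (substrate excluded). `"substrate"`: the same plus flour
#' proportions, with geography excluded.
#'
#' @param variant `"geographic"` or `"substrate"`.
#' @return character vector of column names.
#' @export
pca_variant_variables <- function(variant = c("geographic", "substrate")) {
  variant <- match.arg(variant)
  feeding <- c("backslop_frequency", "ferment_temp_C", "ferment_time_h",
               "storage_temp_C", "dough_yield", "flour_g", "sourdough_age_y")
  home <- c("ph_home", "ph_bread_home", "bread_density")
  if (variant == "geographic") {
    c(feeding, home, "tta", "latitude")
  } else {
    c(feeding, home, "tta", "prop_wheat", "prop_rye", "prop_spelt")
  }
}

#' Flour proportion columns
#'
#' Expands the grain base into per-grain proportions (mixtures are split
#' evenly across the three grains; the deposited data records exact mixture
#' maps, which the survey tables here do not carry).
#'
#' @param table integrated table with a `grain_base` column.
#' @return the table with `prop_wheat`, `prop_rye`, `prop_spelt` columns.
#' @export
add_flour_proportions <- function(table) {
  gb <- table$grain_base
  for (grain in c("wheat", "rye", "spelt")) {
    table[[paste0("prop_", grain)]] <-
      ifelse(is.na(gb), NA_real_,
             ifelse(gb == grain, 1, ifelse(gb == "mixture", 1 / 3, 0)))
  }
  table
}
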