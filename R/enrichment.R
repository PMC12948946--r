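# Fold-enrichment scoring of categorical and numeric features across sample
# clusters (countries, sources, flour types), with epsilon regularisation,
# log2 normalisation, BH-FDR control, and PE/NE/U/M flagging.

#' Cluster partition
#'
#' Assignment of samples to mutually exclusive clusters of one variable.
#'
#' @param variable name of the clustering variable (e.g. `"country"`).
#' @param assignment named character vector: sample code -> cluster label.
#' @param min_cluster_size clusters smaller than this are dropped (with a
#'   warning) before scoring.
#' @return object of class `cluster_partition`.
#' @export
cluster_partition <- function(variable, assignment, min_cluster_size = 1L) {
  stopifnot(is.character(assignment), !is.null(names(assignment)))
  if (anyDuplicated(names(assignment))) {
    stop("each sample must be assigned exactly one cluster", call. = FALSE)
  }
  structure(list(variable = variable, assignment = assignment,
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "cluster_partition")
}

#' Enrichment configuration
#'
#' @param epsilon regularising constant added to numerator and denominator
#'   means of the numeric score (guards division by zero).
#' @param alpha FDR level used for significance flags.
#' @param log2_numeric log2-normalise numeric scores (scale-independent
#'   comparisons)?
#' @param geo_bounds European bounding box, inclusive:
#'   `c(lon_min, lon_max, lat_min, lat_max)`.
#' @return object of class `enrichment_config`.
#' @export
enrichment_config <- function(epsilon = 1e-4, alpha = 0.05,
                              log2_numeric = TRUE,
                              geo_bounds = c(lon_min = -50, lon_max = 70,
                                             lat_min = 0, lat_max = 70)) {
  stopifnot(epsilon > 0, alpha > 0, alpha < 1)
  structure(list(epsilon = epsilon, alpha = alpha,
                 log2_numeric = log2_numeric, geo_bounds = geo_bounds),
            class = "enrichment_config")
}

#' European bounding-box filter
#'
#' Retains records with longitude in [-50, 70] and latitude in [0, 70]
#' (bounds inclusive). Records with missing coordinates are excluded with a
#' warning.
#'
#' @param records data.frame with `latitude` and `longitude` columns.
#' @param bounds named vector `lon_min`, `lon_max`, `lat_min`, `lat_max`.
#' @return retained records with attribute `n_excluded`.
#' @export
geo_filter <- function(records, bounds = enrichment_config()$geo_bounds) {
  lon <- records$longitude
  lat <- records$latitude
  miss <- is.na(lon) | is.na(lat)
  if (any(miss)) {
    warning(sum(miss), " record(s) with missing coordinates excluded",
            call. = FALSE)
  }
  keep <- !miss & lon >= bounds[["lon_min"]] & lon <= bounds[["lon_max"]] &
    lat >= bounds[["lat_min"]] & lat <= bounds[["lat_max"]]
  out <- records[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

# align a named sample vector with a partition; drops missing values
# (per-variable exclusion) and undersized clusters
align_partition <- function(values, partition) {
  assignment <- partition$assignment
  if (!is.null(names(values))) {
    common <- intersect(names(values), names(assignment))
    values <- values[common]
    clusters <- assignment[common]
  } else {
    if (length(values) != length(assignment)) {
      stop("unnamed values must match the partition assignment in length",
           call. = FALSE)
    }
    clusters <- unname(assignment)
  }
  ok <- !is.na(values) & !is.na(clusters)
  values <- values[ok]; clusters <- clusters[ok]
  sizes <- table(clusters)
  small <- names(sizes)[sizes < partition$min_cluster_size]
  if (length(small)) {
    warning("dropping undersized cluster(s): ", paste(small, collapse = ", "),
            call. = FALSE)
    keep <- !clusters %in% small
    values <- values[keep]; clusters <- clusters[keep]
  }
  list(values = values, clusters = clusters)
}

#' Categorical enrichment scores
#'
#' For every (category level, cluster) pair, the fold-enrichment score
#'
#'   score = (count of category in cluster / total count in cluster) /
#'           (total count of category / total samples),
#'
#' i.e. the within-cluster share of the category relative to its overall
#' share. Significance comes from a chi-square test on the 2x2 collapse
#' (focal category vs rest, focal cluster vs rest), Cramer's V quantifies
#' effect size, q-values are BH-FDR over all pairs of the partition, and
#' PE/NE (score above/below 1) and U/M (significant in one vs several
#' clusters) flags are assigned. Scores are reported on the raw ratio scale;
#' `log2_score` is provided as a display companion (0 counts give `-Inf`).
#'
#' @param labels named character vector of category labels (names = sample
#'   codes), or unnamed and aligned with the partition.
#' @param partition a [cluster_partition()].
#' @param config an [enrichment_config()].
#' @return data.frame of class `enrichment_table`: feature, cluster, score,
#'   log2_score, p, q, effect_size (V), direction, multiplicity, counts.
#' @export
category_enrichment <- function(labels, partition,
                                config = enrichment_config()) {
  al <- align_partition(labels, partition)
  values <- al$values; clusters <- al$clusters
  if (length(unique(clusters)) < 2) stop("need >= 2 clusters", call. = FALSE)
  if (length(unique(values)) < 2) {
    stop("need >= 2 category levels after binning", call. = FALSE)
  }
  tab <- table(values, clusters)
  n_total <- sum(tab)
  n_cluster <- colSums(tab)
  n_feature <- rowSums(tab)
  grid <- expand.grid(feature = rownames(tab), cluster = colnames(tab),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    k <- grid$feature[i]; cl <- grid$cluster[i]
    n_kc <- tab[k, cl]
    score <- (n_kc / n_cluster[[cl]]) / (n_feature[[k]] / n_total)
    two_by_two <- matrix(c(n_kc, n_feature[[k]] - n_kc,
                           n_cluster[[cl]] - n_kc,
                           n_total - n_feature[[k]] - n_cluster[[cl]] + n_kc),
                         nrow = 2)
    stat <- tryCatch(chi_square_cramers_v(two_by_two),
                     error = function(e) NULL)
    data.frame(feature = k, cluster = cl, score = unname(score),
               log2_score = unname(log2(score)),
               p = if (is.null(stat)) NA_real_ else stat$p,
               effect_size = if (is.null(stat)) NA_real_ else stat$effect_size,
               n_in_cluster = as.integer(n_kc),
               n_cluster = as.integer(n_cluster[[cl]]),
               n_feature = as.integer(n_feature[[k]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  out$direction <- ifelse(out$score > 1, "PE", ifelse(out$score < 1, "NE", ""))
  out <- flag_multiplicity(out, alpha = config$alpha)
  structure(out, class = c("enrichment_table", "data.frame"),
            n_total = n_total, variable = partition$variable,
            kind = "categorical", alpha = config$alpha)
}

#' Numeric enrichment scores
#'
#' For every (numeric feature, cluster) pair,
#'
#'   score = (mean in cluster + epsilon) / (mean overall + epsilon),
#'
#' log2-normalised for scale-independent comparison. Significance comes from
#' a Mann-Whitney U test of within-cluster values against all other
#' clusters; q-values are BH-FDR over the partition's pairs. The score
#' assumes a non-negative variable; a variable with negative values is
#' shifted by its global minimum first (noted in attribute `shifted`).
#'
#' @param values named numeric vector (names = sample codes) or unnamed and
#'   aligned with the partition.
#' @inheritParams category_enrichment
#' @return `enrichment_table` data.frame.
#' @export
numeric_enrichment <- function(values, partition,
                               config = enrichment_config()) {
  al <- align_partition(values, partition)
  vals <- al$values; clusters <- al$clusters
  if (length(unique(clusters)) < 2) stop("need >= 2 clusters", call. = FALSE)
  shifted <- FALSE
  if (any(vals < 0)) {
    vals <- vals - min(vals)
    shifted <- TRUE
    message("numeric_enrichment: negative values shifted by the global minimum")
  }
  eps <- config$epsilon
  overall <- mean(vals)
  res <- lapply(sort(unique(clusters)), function(cl) {
    inside <- vals[clusters == cl]
    outside <- vals[clusters != cl]
    if (!length(inside)) return(NULL)
    score <- (mean(inside) + eps) / (overall + eps)
    p <- tryCatch(mann_whitney_rank_biserial(inside, outside)$p,
                  error = function(e) NA_real_)
    data.frame(cluster = cl, score = score, log2_score = log2(score), p = p,
               n_in_cluster = length(inside), n_cluster = length(inside),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- cbind(feature = "numeric", out)
  out$q <- bh_fdr(out$p)
  out$effect_size <- NA_real_
  out$direction <- ifelse(out$score > 1, "PE", ifelse(out$score < 1, "NE", ""))
  out$n_feature <- length(vals)
  out <- flag_multiplicity(out, alpha = config$alpha)
  structure(out, class = c("enrichment_table", "data.frame"),
            n_total = length(vals), variable = partition$variable,
            kind = "numeric", shifted = shifted, alpha = config$alpha)
}

#' Flag uniquely/multiply enriched features
#'
#' Per feature: `"U"` when significant (q < alpha) in exactly one cluster,
#' `"M"` when in two or more; features significant nowhere stay unflagged.
#'
#' @param records enrichment data.frame with `feature` and `q` columns.
#' @param alpha FDR significance level.
#' @return the records with a `multiplicity` column.
#' @export
flag_multiplicity <- function(records, alpha = 0.05) {
  sig <- !is.na(records$q) & records$q < alpha
  n_sig <- tapply(sig, records$feature, sum)
  records$multiplicity <- ifelse(!sig, "",
    ifelse(n_sig[records$feature] == 1, "U", "M"))
  records
}

#' Order clusters and features by their signed-V association profiles
#'
#' Builds the feature x cluster matrix of directional Cramer's V (sign from
#' the enrichment direction, 0 where q >= alpha), then average-linkage
#' hierarchical clustering on Euclidean distances of the profiles, returning
#' dendrogram leaf orders for rows (features) and columns (clusters).
#'
#' @param records an `enrichment_table` from [category_enrichment()].
#' @param alpha significance level zeroing non-significant cells.
#' @return list with `feature_order`, `cluster_order`, the signed matrix and
#'   the two `hclust` objects (NULL for fewer than 2 leaves).
#' @export
cluster_enrichment_profiles <- function(records,
                                        alpha = attr(records, "alpha") %||% 0.05) {
  features <- sort(unique(records$feature))
  clusters <- sort(unique(records$cluster))
  m <- matrix(0, length(features), length(clusters),
              dimnames = list(features, clusters))
  sig <- !is.na(records$q) & records$q < alpha
  sgn <- ifelse(records$direction == "PE", 1, ifelse(records$direction == "NE", -1, 0))
  v <- ifelse(is.na(records$effect_size), 0, records$effect_size)
  m[cbind(records$feature, records$cluster)] <- ifelse(sig, sgn * v, 0)
  order_of <- function(mat) {
    if (nrow(mat) < 2) return(list(order = seq_len(nrow(mat)), hc = NULL))
    hc <- stats::hclust(stats::dist(mat), method = "average")
    list(order = hc$order, hc = hc)
  }
  fo <- order_of(m)
  co <- order_of(t(m))
  list(feature_order = features[fo$order], cluster_order = clusters[co$order],
       matrix = m, feature_hclust = fo$hc, cluster_hclust = co$hc)
}

#' Enrichment score conservation check
#'
#' For a complete partition, the cluster-size-weighted mean of categorical
#' enrichment scores is exactly 1 for every feature (the within-cluster
#' shares recompose the overall share). Returns the weighted mean per
#' feature; used by the property tests.
#'
#' @param records an `enrichment_table` from [category_enrichment()].
#' @return named numeric vector, one weighted mean per feature.
#' @export
enrichment_score_conservation <- function(records) {
  n_total <- attr(records, "n_total")
  w <- records$n_cluster / n_total
  vapply(split(seq_len(nrow(records)), records$feature), function(i) {
    sum(w[i] * records$score[i])
  }, numeric(1))
}
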