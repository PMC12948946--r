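# Sensory pipeline over check-all-that-apply (CATA) aroma data: Jaccard
# distances on the full descriptor spectrum, principal coordinates analysis,
# PERMANOVA over categorical metadata, Mantel tests against numeric
# metadata, and top-feature extraction for biplot annotation.

#' Construct a CATA matrix
#'
#' Binary samples x descriptors matrix with a descriptor -> category map
#' (by default the shipped 56-descriptor / 13-category inventory).
#'
#' @param mat matrix or data.frame with entries in {0, 1}; column names are
#'   descriptor names (a `cata_` prefix is stripped).
#' @param categories named character vector descriptor -> category.
#' @return object of class `cata_matrix`.
#' @export
cata_matrix <- function(mat, categories = descriptor_category_map()) {
  m <- as.matrix(mat)
  colnames(m) <- sub("^cata_", "", colnames(m))
  if (any(!m[!is.na(m)] %in% c(0, 1))) {
    stop("CATA entries must be binary (0/1)", call. = FALSE)
  }
  unmapped <- setdiff(colnames(m), names(categories))
  if (length(unmapped)) {
    stop("descriptor(s) without a category: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  structure(m, class = c("cata_matrix", class(m)),
            categories = categories[colnames(m)])
}

#' Jaccard distance matrix over CATA profiles
#'
#' d(i, j) = 1 - |intersection| / |union| of the descriptor sets. Two
#' all-zero profiles are at distance 0 by convention (logged in attribute
#' `zero_rows`); an all-zero profile against a non-empty one is at distance
#' 1.
#'
#' @param cata a [cata_matrix()] or binary matrix (rows with any missing
#'   entry are dropped first).
#' @return symmetric distance matrix with zero diagonal, entries in [0, 1].
#' @export
jaccard_matrix <- function(cata) {
  m <- unclass(as.matrix(cata))
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 2) stop("need at least 2 complete samples", call. = FALSE)
  if (any(!m %in% c(0, 1))) stop("non-binary CATA entry", call. = FALSE)
  storage.mode(m) <- "double"
  inter <- tcrossprod(m)
  sizes <- rowSums(m)
  union <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / union
  d[union == 0] <- 0          # both profiles empty: identical by convention
  diag(d) <- 0
  if (!is.null(rownames(m))) dimnames(d) <- list(rownames(m), rownames(m))
  attr(d, "zero_rows") <- sum(sizes == 0)
  d
}

#' Principal coordinates analysis
#'
#' Gower double-centring of -d^2/2 followed by eigendecomposition.
#' Coordinates are eigenvectors scaled by the square root of their positive
#' eigenvalues; variance explained uses the sum of positive eigenvalues as
#' denominator. Negative eigenvalues (non-Euclidean distances) are reported,
#' not corrected.
#'
#' @param dist symmetric distance matrix (n >= 3).
#' @return object of class `pcoa_result`: `coordinates` (n x k over positive
#'   axes), `eigenvalues` (all n, descending), `proportion_explained` (per
#'   positive axis), `negative_eigenvalue_report`.
#' @export
pcoa <- function(dist) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 3) stop("pcoa needs at least 3 samples", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric", call. = FALSE)
  a <- -0.5 * d^2
  centre <- diag(n) - matrix(1 / n, n, n)
  b <- centre %*% a %*% centre
  eig <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-9
  pos <- which(eig$values > tol)
  coords <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), length(pos))
  colnames(coords) <- paste0("PC", seq_along(pos))
  rownames(coords) <- rownames(d)
  neg <- eig$values[eig$values < -tol]
  structure(list(
    coordinates = coords,
    eigenvalues = eig$values,
    proportion_explained = eig$values[pos] / sum(eig$values[pos]),
    negative_eigenvalue_report = list(
      n_negative = length(neg),
      sum_negative = sum(neg),
      most_negative = if (length(neg)) min(neg) else 0)
  ), class = "pcoa_result")
}

# one-way pseudo-F from a distance matrix and a grouping factor
permanova_f <- function(d2, g) {
  n <- length(g)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (lev in unique(g)) {
    idx <- which(g == lev)
    if (length(idx) > 1) {
      sub <- d2[idx, idx]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  a <- length(unique(g))
  ss_between <- ss_total - ss_within
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  list(F = f, R2 = ss_between / ss_total)
}

#' One-way PERMANOVA
#'
#' Permutational multivariate ANOVA: pseudo-F from total and within-group
#' sums of squared distances, with a permutation null over group labels.
#' Levels with fewer than 3 samples are dropped first; if fewer than 2
#' usable levels remain the test is skipped with a warning (returning
#' `NULL`) so batch runs can proceed. With `n_perm = "exact"` all label
#' permutations are enumerated (n <= 8); otherwise p uses the add-one rule
#' p = (1 + #(F_perm >= F_obs)) / (1 + n_perm) and is never 0.
#'
#' @param dist distance matrix.
#' @param grouping vector of group labels aligned with `dist` rows (missing
#'   labels excluded pairwise).
#' @param n_perm number of permutations (default 999) or `"exact"`.
#' @param seed optional integer fixing the permutation stream.
#' @param min_level_size per-level sample filter (default 3).
#' @return list `pseudo_F`, `R2`, `p`, `n`, `n_levels`, `n_perm`, or `NULL`
#'   when skipped.
#' @export
permanova <- function(dist, grouping, n_perm = 999, seed = NULL,
                      min_level_size = 3) {
  d <- as.matrix(dist)
  g <- as.character(grouping)
  ok <- !is.na(g)
  d <- d[ok, ok, drop = FALSE]; g <- g[ok]
  sizes <- table(g)
  keep_lev <- names(sizes)[sizes >= min_level_size]
  keep <- g %in% keep_lev
  d <- d[keep, keep, drop = FALSE]; g <- g[keep]
  if (length(unique(g)) < 2) {
    warning("permanova skipped: fewer than 2 usable levels", call. = FALSE)
    return(NULL)
  }
  d2 <- d^2
  obs <- permanova_f(d2, g)
  run <- function() {
    if (identical(n_perm, "exact")) {
      n <- length(g)
      if (n > 8) stop("exact enumeration limited to n <= 8", call. = FALSE)
      perms <- permutations_of(n)
      fs <- apply(perms, 1, function(idx) permanova_f(d2, g[idx])$F)
      p <- mean(fs >= obs$F - 1e-12)
      list(p = p, n_perm = nrow(perms))
    } else {
      count <- 0L
      for (b in seq_len(n_perm)) {
        if (permanova_f(d2, sample(g))$F >= obs$F - 1e-12) count <- count + 1L
      }
      list(p = (1 + count) / (1 + n_perm), n_perm = n_perm)
    }
  }
  pr <- if (is.null(seed)) run() else with_seed(seed, run())
  list(pseudo_F = obs$F, R2 = obs$R2, p = pr$p, n = length(g),
       n_levels = length(unique(g)), n_perm = pr$n_perm)
}

# all permutations of 1..n as a matrix (n! rows); recursion fine for n <= 8
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Mantel test between two distance matrices
#'
#' Correlation (Pearson or Spearman) of the off-diagonal distance vectors,
#' with a permutation p-value obtained by co-permuting rows and columns of
#' the second matrix. `n_perm = "exact"` enumerates all n! permutations
#' (n <= 8).
#'
#' @param dist_a,dist_b distance matrices over the same samples.
#' @param method `"pearson"` or `"spearman"`.
#' @param n_perm permutation count or `"exact"`.
#' @param seed optional integer seed.
#' @return list `r`, `p`, `n`, `method`, `n_perm`.
#' @export
mantel <- function(dist_a, dist_b, method = c("pearson", "spearman"),
                   n_perm = 999, seed = NULL) {
  method <- match.arg(method)
  a <- as.matrix(dist_a); b <- as.matrix(dist_b)
  stopifnot(nrow(a) == nrow(b))
  lt <- lower.tri(a)
  va <- a[lt]; vb <- b[lt]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("undefined correlation: zero variance in a distance vector",
         call. = FALSE)
  }
  r_obs <- stats::cor(va, vb, method = method)
  n <- nrow(a)
  run <- function() {
    if (identical(n_perm, "exact")) {
      if (n > 8) stop("exact enumeration limited to n <= 8", call. = FALSE)
      perms <- permutations_of(n)
      rs <- apply(perms, 1, function(idx) {
        stats::cor(va, b[idx, idx][lt], method = method)
      })
      list(p = mean(rs >= r_obs - 1e-12), n_perm = nrow(perms))
    } else {
      count <- 0L
      for (k in seq_len(n_perm)) {
        idx <- sample.int(n)
        if (stats::cor(va, b[idx, idx][lt], method = method) >= r_obs - 1e-12) {
          count <- count + 1L
        }
      }
      list(p = (1 + count) / (1 + n_perm), n_perm = n_perm)
    }
  }
  pr <- if (is.null(seed)) run() else with_seed(seed, run())
  list(r = r_obs, p = pr$p, n = n, method = method, n_perm = pr$n_perm)
}

#' Top aroma features by correlation with principal coordinates
#'
#' Pearson correlation of each descriptor with the PC1 and PC2 scores;
#' descriptors are ranked by max(|r_PC1|, |r_PC2|) and the top k returned
#' with signed loadings for biplot arrows. Constant descriptors are excluded
#' with a warning.
#'
#' @param cata binary CATA matrix over the ordination's samples.
#' @param ordination a [pcoa()] result (or any object with 2+ coordinate
#'   columns in `$coordinates`).
#' @param k number of features to return (default 10).
#' @return data.frame: descriptor, category, r_pc1, r_pc2, strength.
#' @export
top_features <- function(cata, ordination, k = 10) {
  stopifnot(k >= 1)
  m <- unclass(as.matrix(cata))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  scores <- ordination$coordinates
  stopifnot(nrow(m) == nrow(scores))
  const <- apply(m, 2, function(col) stats::sd(col) == 0)
  if (any(const)) {
    warning("constant descriptor(s) excluded: ",
            paste(colnames(m)[const], collapse = ", "), call. = FALSE)
    m <- m[, !const, drop = FALSE]
  }
  r1 <- suppressWarnings(stats::cor(m, scores[, 1]))
  r2 <- if (ncol(scores) >= 2) suppressWarnings(stats::cor(m, scores[, 2])) else r1 * 0
  strength <- pmax(abs(r1), abs(r2))
  ord <- order(-strength)
  cats <- attr(cata, "categories")
  out <- data.frame(
    descriptor = colnames(m)[ord],
    category = if (is.null(cats)) NA_character_ else unname(cats[colnames(m)[ord]]),
    r_pc1 = r1[ord], r_pc2 = as.numeric(r2)[ord], strength = strength[ord],
    stringsAsFactors = FALSE
  )
  utils::head(out, k)
}

#' Batch PERMANOVA over categorical metadata
#'
#' One-way PERMANOVA per variable with the per-level >= 3 sample filter,
#' pairwise exclusion of missing labels and BH-FDR correction across
#' variables.
#'
#' @param dist distance matrix with sample codes as dimnames.
#' @param metadata data.frame carrying `sample_code` and the variables.
#' @param variables categorical column names to test.
#' @param n_perm,seed forwarded to [permanova()].
#' @return data.frame: variable, pseudo_F, R2, p, q, n, n_levels.
#' @export
permanova_batch <- function(dist, metadata, variables, n_perm = 999,
                            seed = NULL) {
  codes <- rownames(as.matrix(dist))
  idx <- match(codes, metadata$sample_code)
  rows <- lapply(seq_along(variables), function(i) {
    v <- variables[i]
    res <- suppressWarnings(
      permanova(dist, metadata[[v]][idx], n_perm = n_perm,
                seed = if (is.null(seed)) NULL else stage_seed(seed, v)))
    if (is.null(res)) return(NULL)
    data.frame(variable = v, pseudo_F = res$pseudo_F, R2 = res$R2, p = res$p,
               n = res$n, n_levels = res$n_levels, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$q <- bh_fdr(out$p)
  out
}

#' Batch Mantel tests against numeric metadata
#'
#' For each numeric variable: samples missing that variable are dropped from
#' both matrices (dynamic exclusion), the variable is z-scored, its
#' Euclidean distance matrix is formed, and Pearson and Spearman Mantel
#' tests are run; BH-FDR across all variable/method pairs.
#'
#' @inheritParams permanova_batch
#' @param variables numeric column names to test.
#' @return data.frame: variable, method, r, p, q, n.
#' @export
mantel_batch <- function(dist, metadata, variables, n_perm = 999,
                         seed = NULL) {
  d <- as.matrix(dist)
  codes <- rownames(d)
  idx <- match(codes, metadata$sample_code)
  rows <- list()
  for (v in variables) {
    vals <- metadata[[v]][idx]
    keep <- !is.na(vals)
    if (sum(keep) < 4) next
    sub <- d[keep, keep]
    z <- scale(vals[keep])[, 1]
    dv <- as.matrix(stats::dist(z))
    for (m in c("pearson", "spearman")) {
      res <- tryCatch(
        mantel(sub, dv, method = m, n_perm = n_perm,
               seed = if (is.null(seed)) NULL else stage_seed(seed, paste(v, m))),
        error = function(e) NULL)
      if (is.null(res)) next
      rows[[paste(v, m)]] <- data.frame(variable = v, method = m, r = res$r,
                                        p = res$p, n = res$n,
                                        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}
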