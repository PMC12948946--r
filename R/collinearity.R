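# Mixed-type association matrix and representative-variable selection, used
# to exclude collinear predictors before multivariate analyses.

# numeric-numeric association: max of |Pearson|, |Spearman| and the cosine
# similarity of mean-centred vectors (the latter equals |Pearson| exactly;
# computed anyway so the three-measure contract is explicit)
numeric_association <- function(x, y) {
  r_p <- suppressWarnings(stats::cor(x, y, method = "pearson"))
  r_s <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  cx <- x - mean(x); cy <- y - mean(y)
  cos_c <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  vals <- c(pearson = abs(r_p), spearman = abs(r_s), cosine = abs(cos_c))
  best <- names(which.max(vals))
  p <- if (best == "spearman") {
    suppressWarnings(stats::cor.test(x, y, method = "spearman")$p.value)
  } else {
    suppressWarnings(stats::cor.test(x, y, method = "pearson")$p.value)
  }
  list(value = unname(max(vals)), p = p, method = paste0("numeric:", best))
}

# mixed-type association: Kruskal-Wallis epsilon-squared = H / (n - 1), in [0, 1]
mixed_association <- function(num, cat) {
  g <- factor(cat)
  if (nlevels(g) < 2) return(list(value = NA_real_, p = NA_real_, method = "mixed:kruskal"))
  kw <- stats::kruskal.test(num, g)
  n <- length(num)
  eps2 <- min(1, max(0, as.numeric(kw$statistic) / (n - 1)))
  list(value = eps2, p = kw$p.value, method = "mixed:kruskal")
}

categorical_association <- function(x, y) {
  res <- tryCatch(chi_square_cramers_v(table(x, y)), error = function(e) NULL)
  if (is.null(res)) return(list(value = NA_real_, p = NA_real_, method = "cat:cramers_v"))
  list(value = res$effect_size, p = res$p, method = "cat:cramers_v")
}

#' Mixed-type association matrix
#'
#' Symmetric matrix of association strengths in [0, 1]: numeric pairs store
#' the max of |Pearson|, |Spearman| and centred cosine similarity;
#' categorical pairs store Cramer's V; mixed pairs a normalised Kruskal-
#' Wallis epsilon-squared. Per-cell p-values are BH-FDR corrected across the
#' upper triangle. Constant variables get missing cells with a warning;
#' pairs with fewer than 3 complete cases are missing.
#'
#' @param data data.frame of variables.
#' @param variable_spec named character vector mapping each variable to
#'   `"numeric"` or `"categorical"`.
#' @return object of class `association_matrix`: `values`, `p`, `q`,
#'   `method` matrices plus the spec.
#' @export
association_matrix <- function(data, variable_spec) {
  vars <- names(variable_spec)
  stopifnot(length(vars) >= 2, all(vars %in% names(data)),
            all(variable_spec %in% c("numeric", "categorical")))
  k <- length(vars)
  values <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  method <- matrix(NA_character_, k, k, dimnames = list(vars, vars))
  diag(values) <- 1

  is_constant <- vapply(vars, function(v) {
    x <- data[[v]][!is.na(data[[v]])]
    length(unique(x)) < 2
  }, logical(1))
  if (any(is_constant)) {
    warning("constant variable(s), cells set to missing: ",
            paste(vars[is_constant], collapse = ", "), call. = FALSE)
  }

  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (is_constant[i] || is_constant[j]) next
      xi <- data[[vars[i]]]; xj <- data[[vars[j]]]
      ok <- !is.na(xi) & !is.na(xj)
      if (sum(ok) < 3) next
      ti <- variable_spec[[vars[i]]]; tj <- variable_spec[[vars[j]]]
      cell <- if (ti == "numeric" && tj == "numeric") {
        numeric_association(xi[ok], xj[ok])
      } else if (ti == "categorical" && tj == "categorical") {
        categorical_association(xi[ok], xj[ok])
      } else if (ti == "numeric") {
        mixed_association(xi[ok], xj[ok])
      } else {
        mixed_association(xj[ok], xi[ok])
      }
      values[i, j] <- values[j, i] <- cell$value
      p[i, j] <- p[j, i] <- cell$p
      method[i, j] <- method[j, i] <- cell$method
    }
  }
  q <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  ut <- upper.tri(q)
  q[ut] <- bh_fdr(p[ut])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  structure(list(values = values, p = p, q = q, method = method,
                 variable_spec = variable_spec),
            class = "association_matrix")
}

#' Select representative variables from an association matrix
#'
#' Average-linkage hierarchical clustering on distance 1 - association; the
#' tree is cut so that variables with association >= `threshold` share a
#' cluster (cut height 1 - threshold), and one representative is kept per
#' cluster: the variable with the highest mean association to the other
#' cluster members, ties broken lexicographically. Every exclusion is
#' recorded in the attached decision log.
#'
#' @param matrix an [association_matrix()].
#' @param threshold association threshold in (0, 1); default 0.7.
#' @return character vector of kept variables (original order), with
#'   attribute `decisions` (per-cluster membership and representative).
#' @export
select_representatives <- function(matrix, threshold = 0.7) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  a <- matrix$values
  a[is.na(a)] <- 0            # unrelatable cells treated as no association
  d <- stats::as.dist(1 - a)
  vars <- rownames(a)
  if (length(vars) < 2) return(vars)
  hc <- stats::hclust(d, method = "average")
  membership <- stats::cutree(hc, h = 1 - threshold)
  decisions <- lapply(split(names(membership), membership), function(members) {
    rep_var <- if (length(members) == 1) members else {
      mean_assoc <- vapply(members, function(v) {
        mean(a[v, setdiff(members, v)])
      }, numeric(1))
      best <- members[mean_assoc == max(mean_assoc)]
      sort(best)[1]
    }
    list(members = sort(members), representative = rep_var,
         excluded = sort(setdiff(members, rep_var)))
  })
  kept <- vapply(decisions, `[[`, character(1), "representative")
  kept <- vars[vars %in% kept]
  attr(kept, "decisions") <- unname(decisions)
  kept
}
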