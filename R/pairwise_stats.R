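# Pairwise testing and effect-size layer: chi-square / Cramer's V,
# Mann-Whitney / rank-biserial, t-test / Cohen's d, BH-FDR, and the signed
# (directional) Cramer's V used for clustering association profiles.

assoc_result <- function(statistic, p, effect_size, effect_kind,
                         direction = 0L, method = NA_character_, n = NA_integer_) {
  structure(list(statistic = statistic, p = p, q = NA_real_,
                 effect_size = effect_size, effect_kind = effect_kind,
                 direction = direction, method = method, n = n),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g, %s = %.4g (n = %s)\n",
              x$method %||% "association", x$statistic, x$p,
              x$effect_kind, x$effect_size, x$n))
  invisible(x)
}

# drop all-zero rows/columns; error if fewer than 2x2 remain
clean_contingency <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || sum(counts) <= 0) {
    stop("contingency table must be non-negative with positive total",
         call. = FALSE)
  }
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("degenerate contingency table: fewer than 2 rows/columns with data",
         call. = FALSE)
  }
  counts
}

#' Chi-square test with Cramer's V
#'
#' Pearson chi-square without continuity correction (a correction would bias
#' the effect size, which is the quantity of interest), with
#' V = sqrt(chi2 / (n * (min(r, c) - 1))). Empty rows/columns are dropped
#' first; a table degenerating below 2x2 is an error.
#'
#' @param table contingency matrix of counts.
#' @return `assoc_result` with `effect_kind = "cramers_v"`.
#' @export
chi_square_cramers_v <- function(table) {
  counts <- clean_contingency(table)
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  n <- sum(counts)
  v <- sqrt(as.numeric(ct$statistic) /
              (n * (min(dim(counts)) - 1)))
  assoc_result(as.numeric(ct$statistic), ct$p.value, v, "cramers_v",
               direction = 0L, method = "chi-square", n = n)
}

#' Directional Cramer's V
#'
#' |V| as in [chi_square_cramers_v()]; the sign is +1 when the focal cell's
#' observed count exceeds its expected count under independence, -1 when
#' below, 0 at equality. Used to cluster association profiles by direction.
#'
#' @param table contingency matrix.
#' @param focal_row,focal_col focal cell (index or dimname).
#' @return signed Cramer's V (numeric scalar).
#' @export
directional_cramers_v <- function(table, focal_row, focal_col) {
  counts <- clean_contingency(table)
  res <- chi_square_cramers_v(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  obs <- counts[focal_row, focal_col]
  exp_ <- expected[focal_row, focal_col]
  sign(obs - exp_) * res$effect_size
}

#' Mann-Whitney U test with rank-biserial correlation
#'
#' Two-sided test with tie-corrected normal approximation; the exact
#' distribution is used automatically when there are no ties and
#' n1 * n2 <= 10000. The reported statistic U counts pairs where x < y (plus
#' half-ties), so that rank-biserial = 1 - 2U/(n1 n2) is positive when x is
#' stochastically larger; it equals the mean of sign(xi - yj) over all
#' pairs.
#'
#' @param x,y numeric samples (missing values dropped).
#' @return `assoc_result` with `effect_kind = "rank_biserial"`.
#' @export
mann_whitney_rank_biserial <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    stop("insufficient data: a group is empty after missing-data exclusion",
         call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && n1 * n2 <= 10000
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = FALSE))
  w_x <- as.numeric(wt$statistic)      # pairs with x > y (+ half-ties)
  u <- n1 * n2 - w_x                   # pairs with x < y (+ half-ties)
  rb <- 1 - 2 * u / (n1 * n2)
  assoc_result(u, wt$p.value, rb, "rank_biserial",
               direction = as.integer(sign(rb)),
               method = if (use_exact) "mann-whitney (exact)" else
                 "mann-whitney (normal approx.)",
               n = n1 + n2)
}

#' Welch/pooled t-test with Cohen's d
#'
#' Cohen's d with the pooled standard deviation using (n - 1) denominators.
#'
#' @param x,y numeric samples with at least 2 values each.
#' @return `assoc_result` with `effect_kind = "cohens_d"`.
#' @export
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("cohens_d needs at least 2 values per group", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  if (sp == 0) stop("undefined effect size: zero pooled standard deviation",
                    call. = FALSE)
  d <- (mean(x) - mean(y)) / sp
  tt <- stats::t.test(x, y)
  assoc_result(as.numeric(tt$statistic), tt$p.value, d, "cohens_d",
               direction = as.integer(sign(d)), method = "t-test",
               n = n1 + n2)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: q(i) = min over j >= i of p(j) * m / j on the
#' sorted p-values, capped at 1, so q is monotone non-decreasing in p.
#' Missing p-values are excluded from the family and restored as missing.
#'
#' @param pvalues numeric vector in [0, 1] (NAs allowed).
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (length(p) && (any(p < 0) || any(p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(pvalues))
  m <- length(p)
  if (m) {
    o <- order(p)
    q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
    q <- numeric(m)
    q[o] <- q_sorted
    out[ok] <- q
  }
  out
}

# Brown-Forsythe variance-homogeneity test (Levene on deviations from the
# group median); base-R implementation, no extra dependency.
levene_p <- function(x, y) {
  z <- c(abs(x - stats::median(x)), abs(y - stats::median(y)))
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  stats::anova(stats::lm(z ~ g))[["Pr(>F)"]][1]
}

#' Gated two-group comparison
#'
#' Chooses between the t-test (Cohen's d) and the Mann-Whitney U test
#' (rank-biserial) from the data: both groups must pass Shapiro-Wilk
#' normality at alpha = 0.05 and the Brown-Forsythe homoscedasticity test
#' for the t-test to be used. The decision is recorded in the result's
#' `method` field and in attribute `gate`.
#'
#' @param x,y numeric samples.
#' @param alpha gate level.
#' @return `assoc_result`, with attribute `gate` documenting the decision.
#' @export
pairwise_compare <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  shapiro_ok <- function(v) {
    if (length(v) < 3) return(FALSE)
    if (length(v) > 5000) v <- v[seq_len(5000)]
    if (stats::sd(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value >= alpha
  }
  normal <- shapiro_ok(x) && shapiro_ok(y)
  homosc <- length(x) >= 2 && length(y) >= 2 &&
    !is.na(levene_p(x, y)) && levene_p(x, y) >= alpha
  res <- if (normal && homosc) cohens_d(x, y) else mann_whitney_rank_biserial(x, y)
  attr(res, "gate") <- list(normal = normal, homoscedastic = homosc,
                            chosen = res$method)
  res
}

#' Tidy pairwise comparison table
#'
#' Compares each named numeric variable between the two levels of a grouping
#' column, using the gated test choice, and returns one row per variable
#' with BH-FDR q-values and significance stars.
#'
#' @param data data.frame.
#' @param variables numeric column names to compare.
#' @param group grouping column name (must have exactly 2 non-missing
#'   levels, or `levels` must pick two).
#' @param levels optional two group levels to contrast (first vs second).
#' @return data.frame: variable, method, statistic, effect_kind,
#'   effect_size, p, q, stars, n.
#' @export
pairwise_table <- function(data, variables, group, levels = NULL) {
  g <- as.character(data[[group]])
  lev <- levels %||% sort(unique(g[!is.na(g)]))
  if (length(lev) != 2) stop("group must resolve to exactly 2 levels", call. = FALSE)
  rows <- lapply(variables, function(v) {
    x <- data[[v]][!is.na(g) & g == lev[1]]
    y <- data[[v]][!is.na(g) & g == lev[2]]
    res <- tryCatch(pairwise_compare(x, y), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(variable = v, method = res$method, statistic = res$statistic,
               effect_kind = res$effect_kind, effect_size = res$effect_size,
               p = res$p, n = res$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$q <- bh_fdr(out$p)
  out$stars <- significance_stars(out$q)
  out[, c("variable", "method", "statistic", "effect_kind", "effect_size",
          "p", "q", "stars", "n")]
}
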