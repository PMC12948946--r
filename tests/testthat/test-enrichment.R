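# Fold-enrichment scoring, flags, geographic filter and profile clustering.

make_labels <- function(tab) {
  # labels and partition from explicit counts: cluster c1 has 10 samples of
  # which 5 are category A; 90 more samples hold the remaining 15 As
  codes <- sprintf("S%03d", 1:100)
  labels <- c(rep("A", 5), rep("B", 5), rep("A", 15), rep("B", 75))
  clusters <- c(rep("c1", 10), rep("c2", 45), rep("c3", 45))
  list(labels = setNames(labels, codes),
       part = cluster_partition("toy", setNames(clusters, codes)))
}

test_that("the European bounding box is inclusive and handles missing coords", {
  rec <- data.frame(latitude = c(47.38, -33.9, 0, 70.0001, NA),
                    longitude = c(8.54, 151.2, 70, 10, 5))
  expect_warning(out <- geo_filter(rec), "missing coordinates")
  expect_equal(nrow(out), 2)                     # Zurich + exact corner
  expect_equal(attr(out, "n_excluded"), 3)
  expect_true(all(out$longitude <= 70 & out$latitude >= 0))
})

test_that("categorical enrichment reproduces the fold-score definition", {
  fx <- make_labels(NULL)
  enr <- category_enrichment(fx$labels, fx$part)
  a_c1 <- enr[enr$feature == "A" & enr$cluster == "c1", ]
  expect_equal(a_c1$score, (5 / 10) / (20 / 100))   # 2.5, hand arithmetic
  expect_identical(a_c1$direction, "PE")
  expect_equal(a_c1$log2_score, log2(2.5))
  # identical shares -> score 1, no direction flag
  codes <- sprintf("T%03d", 1:40)
  labels <- setNames(rep(c("A", "B"), 20), codes)
  part <- cluster_partition("toy", setNames(rep(c("x", "y"), each = 20), codes))
  e2 <- category_enrichment(labels, part)
  expect_true(all(e2$score == 1))
  expect_true(all(e2$direction == ""))
  # absent from cluster but present overall -> score 0, NE
  labels3 <- setNames(c(rep("A", 10), rep("B", 30)), codes)
  part3 <- cluster_partition("toy", setNames(rep(c("x", "y"), each = 20), codes))
  e3 <- category_enrichment(labels3, part3)
  a_y <- e3[e3$feature == "A" & e3$cluster == "y", ]
  expect_equal(a_y$score, 0)
  expect_identical(a_y$direction, "NE")
})

test_that("cluster-share-weighted mean of category scores is exactly 1", {
  set.seed(8)
  for (i in 1:10) {
    codes <- sprintf("R%04d", 1:300)
    labels <- setNames(sample(letters[1:4], 300, TRUE, prob = c(4, 3, 2, 1)), codes)
    part <- cluster_partition("toy",
      setNames(sample(c("u", "v", "w"), 300, TRUE), codes))
    enr <- category_enrichment(labels, part)
    cons <- enrichment_score_conservation(enr)
    expect_true(all(abs(cons - 1) < 1e-9))
  }
})

test_that("numeric enrichment applies the epsilon-regularised mean ratio", {
  codes <- sprintf("N%03d", 1:60)
  vals <- setNames(c(rep(3, 20), rep(0.75, 40)), codes)   # overall mean 1.5
  part <- cluster_partition("toy",
    setNames(rep(c("hi", "lo", "lo2"), each = 20), codes))
  enr <- numeric_enrichment(vals, part)
  hi <- enr[enr$cluster == "hi", ]
  expect_equal(hi$score, (3 + 1e-4) / (1.5 + 1e-4))
  expect_equal(hi$log2_score, log2((3 + 1e-4) / (1.5 + 1e-4)))
  expect_lt(abs(hi$log2_score - 1), 1e-4)
  # equal means -> score exactly 1, log2 0
  vals2 <- setNames(rep(2, 60), codes)
  e2 <- numeric_enrichment(vals2, part)
  expect_true(all(e2$score == 1))
  expect_true(all(e2$log2_score == 0))
  # all-zero variable: epsilon guards 0/0 -> score 1
  vals3 <- setNames(rep(0, 60), codes)
  e3 <- numeric_enrichment(vals3, part)
  expect_true(all(e3$score == 1))
})

test_that("epsilon vanishes in the limit for nonzero means", {
  codes <- sprintf("E%02d", 1:30)
  vals <- setNames(c(rep(4, 10), rep(1, 20)), codes)       # ratio limit 2
  part <- cluster_partition("toy", setNames(rep(c("a", "b", "c"), each = 10), codes))
  scores <- vapply(c(1e-1, 1e-2, 1e-3, 1e-4, 1e-6), function(eps) {
    e <- numeric_enrichment(vals, part, enrichment_config(epsilon = eps))
    e$score[e$cluster == "a"]
  }, numeric(1))
  err <- abs(scores - 2)
  expect_true(all(diff(err) < 0))                          # monotone convergence
  expect_lt(err[length(err)], 1e-5)
})

test_that("negative numeric variables are min-shifted before scoring", {
  codes <- sprintf("G%02d", 1:20)
  vals <- setNames(c(rnorm(10, -5), rnorm(10, -1)), codes)
  part <- cluster_partition("toy", setNames(rep(c("a", "b"), each = 10), codes))
  expect_message(e <- numeric_enrichment(vals, part), "shifted")
  expect_true(all(e$score >= 0))
})

test_that("U/M multiplicity flags follow significant-cluster counts", {
  rec <- data.frame(feature = c("f1", "f1", "f1", "f2", "f2", "f3", "f3"),
                    q = c(0.01, 0.2, 0.9, 0.01, 0.03, 0.5, 0.6))
  out <- flag_multiplicity(rec, alpha = 0.05)
  expect_identical(out$multiplicity, c("U", "", "", "M", "M", "", ""))
  # flag-count bound: #U + #features-with-M <= #features with any q < alpha
  n_u <- sum(out$multiplicity == "U")
  m_feats <- length(unique(out$feature[out$multiplicity == "M"]))
  sig_feats <- length(unique(out$feature[out$q < 0.05]))
  expect_lte(n_u + m_feats, sig_feats)
})

test_that("profile clustering merges identical profiles first, opposites last", {
  rec <- data.frame(
    feature = rep(c("f1", "f2"), each = 4),
    cluster = rep(c("c1", "c2", "c3", "c4"), 2),
    q = rep(0.01, 8),
    direction = c("PE", "PE", "NE", "PE", "NE", "NE", "PE", "NE"),
    effect_size = c(0.5, 0.5, 0.5, 0.2, 0.4, 0.4, 0.4, 0.3))
  out <- cluster_enrichment_profiles(rec, alpha = 0.05)
  hc <- out$cluster_hclust
  # c1 and c2 have identical signed profiles -> first merge at height 0
  first <- sort(abs(hc$merge[1, ]))
  expect_equal(hc$height[1], 0)
  expect_setequal(colnames(out$matrix)[first], c("c1", "c2"))
  # c3 is sign-opposed to c1/c2 -> joins last
  expect_equal(which.max(hc$height), nrow(hc$merge))
  # 3-leaf ordering matches brute-force average-linkage heights
  m <- out$matrix[, c("c1", "c3", "c4")]
  d <- as.matrix(dist(t(m)))
  pairs <- combn(3, 2)
  dists <- apply(pairs, 2, function(ij) d[ij[1], ij[2]])
  closest <- pairs[, which.min(dists)]
  hc3 <- hclust(dist(t(m)), method = "average")
  expect_setequal(abs(hc3$merge[1, ]), closest)
  # non-significant records contribute zeros
  rec$q[1] <- 0.9
  out2 <- cluster_enrichment_profiles(rec, alpha = 0.05)
  expect_equal(out2$matrix["f1", "c1"], 0)
})

test_that("undersized clusters are dropped with a warning", {
  codes <- sprintf("U%02d", 1:41)
  labels <- setNames(sample(c("A", "B"), 41, TRUE), codes)
  part <- cluster_partition("toy",
    setNames(c(rep("big1", 20), rep("big2", 20), "tiny"), codes),
    min_cluster_size = 5L)
  expect_warning(e <- category_enrichment(labels, part), "undersized")
  expect_false("tiny" %in% e$cluster)
})
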