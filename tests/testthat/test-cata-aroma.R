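# Jaccard distances, PCoA, PERMANOVA, Mantel and top-feature extraction.

test_that("Jaccard distances follow the set definition", {
  m <- rbind(a = c(1, 1, 0), b = c(1, 0, 1), c = c(1, 1, 0), d = c(0, 0, 1))
  d <- jaccard_matrix(m)
  expect_equal(d["a", "b"], 2 / 3)          # one shared of three in union
  expect_equal(d["a", "c"], 0)              # identical profiles
  expect_equal(d["a", "d"], 1)              # disjoint non-empty profiles
  expect_equal(diag(d), setNames(rep(0, 4), rownames(m)))
  expect_equal(d, t(d))
  expect_error(jaccard_matrix(rbind(c(1, 2), c(0, 1))), "binary")
})

test_that("Jaccard agrees with the vegan oracle on random binary data", {
  skip_if_not_installed("vegan")
  set.seed(31)
  m <- matrix(rbinom(20 * 15, 1, 0.4), 20, 15)
  m <- m[rowSums(m) > 0, ]                  # vegan's binary Jaccard needs non-empty rows
  mine <- jaccard_matrix(m)
  ref <- as.matrix(vegan::vegdist(m, method = "jaccard", binary = TRUE))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("all-zero profiles follow the stated convention", {
  m <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 1))
  d <- jaccard_matrix(m)
  expect_equal(d[1, 2], 0)                  # two empty profiles: identical
  expect_equal(d[1, 3], 1)                  # empty vs non-empty: maximal
  expect_equal(attr(d, "zero_rows"), 2)
})

test_that("PCoA of the unit equilateral triangle gives two axes at 50%", {
  d <- matrix(1, 3, 3); diag(d) <- 0
  res <- pcoa(d)
  expect_length(res$proportion_explained, 2)
  expect_equal(res$proportion_explained, c(0.5, 0.5))
  expect_equal(res$eigenvalues[1], res$eigenvalues[2])
  expect_equal(sum(res$proportion_explained), 1)
})

test_that("PCoA handles duplicates, collinear points, and inverts distances", {
  # duplicated sample -> identical coordinate rows
  pts <- c(0, 1, 1, 4)
  d <- as.matrix(dist(pts))
  res <- pcoa(d)
  expect_equal(res$coordinates[2, ], res$coordinates[3, ], tolerance = 1e-10)
  # points on a line: one positive eigenvalue, 100% on PC1
  expect_length(res$proportion_explained, 1)
  expect_equal(res$proportion_explained[1], 1)
  # metric case: pairwise Euclidean distances over all axes reproduce input
  set.seed(12)
  x <- matrix(rnorm(6 * 3), 6, 3)
  dd <- as.matrix(dist(x))
  r2 <- pcoa(dd)
  expect_equal(as.matrix(dist(r2$coordinates)), unname(dd), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(r2$negative_eigenvalue_report$n_negative, 0)
  expect_error(pcoa(matrix(0, 2, 2)), "at least 3")
})

test_that("PCoA matches the cmdscale oracle on a non-Euclidean matrix", {
  set.seed(13)
  m <- matrix(rbinom(8 * 10, 1, 0.5), 8, 10)
  m <- m[rowSums(m) > 0, ]
  d <- jaccard_matrix(m)
  res <- pcoa(d)
  ref <- cmdscale(as.dist(d), k = 2, eig = TRUE)
  expect_equal(abs(res$coordinates[, 1:2]), abs(ref$points), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(sort(res$eigenvalues), sort(ref$eig), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("PERMANOVA separates blobs and matches exhaustive enumeration", {
  set.seed(20)
  blob <- rbind(matrix(rnorm(30, 0, 0.1), 15), matrix(rnorm(30, 5, 0.1), 15))
  d <- as.matrix(dist(blob))
  g <- rep(c("a", "b"), each = 15)
  res <- permanova(d, g, n_perm = 199, seed = 1)
  expect_equal(res$p, 1 / 200)              # maximal separation, add-one rule
  expect_gt(res$R2, 0.9)
  # relabelling invariance
  res2 <- permanova(d, ifelse(g == "a", "Group One", "Group Two"),
                    n_perm = 199, seed = 1)
  expect_equal(res2$p, res$p)
  expect_equal(res2$pseudo_F, res$pseudo_F)
  # exhaustive enumeration on a 4-sample 2+2 toy vs brute-force oracle
  pts <- c(0, 1.2, 3.1, 4)
  d4 <- as.matrix(dist(pts))^2
  g4 <- c("x", "x", "y", "y")
  f_oracle <- function(gg) {
    n <- 4; a <- 2
    sst <- sum(d4[upper.tri(d4)]) / n
    ssw <- 0
    for (lev in unique(gg)) {
      i <- which(gg == lev)
      ssw <- ssw + sum(d4[i, i][upper.tri(d4[i, i])]) / length(i)
    }
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  fs <- vapply(all_perms(4), function(p) f_oracle(g4[p]), numeric(1))
  p_oracle <- mean(fs >= f_oracle(g4) - 1e-12)
  res4 <- permanova(sqrt(d4), g4, n_perm = "exact", min_level_size = 2)
  expect_equal(res4$p, p_oracle)
  expect_equal(res4$pseudo_F, f_oracle(g4))
})

test_that("PERMANOVA agrees with vegan::adonis2 on the pseudo-F and R2", {
  skip_if_not_installed("vegan")
  set.seed(22)
  x <- matrix(rnorm(24 * 4), 24)
  g <- sample(c("a", "b", "c"), 24, TRUE)
  d <- as.matrix(dist(x))
  res <- permanova(d, g, n_perm = 99, seed = 2)
  ref <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(res$R2, ref$R2[1], tolerance = 1e-10)
})

test_that("PERMANOVA drops small levels and skips unusable groupings", {
  set.seed(25)
  d <- as.matrix(dist(rnorm(10)))
  g <- c(rep("a", 5), rep("b", 3), "rare", "rare2")   # two levels below 3
  res <- permanova(d, g, n_perm = 49, seed = 3)
  expect_equal(res$n, 8)
  expect_equal(res$n_levels, 2)
  expect_warning(out <- permanova(d, rep("one", 10), n_perm = 49),
                 "skipped")
  expect_null(out)
})

test_that("Mantel statistics and exact p-values match the brute-force oracle", {
  set.seed(30)
  x <- rnorm(5)
  da <- as.matrix(dist(x))
  expect_equal(mantel(da, da, "pearson", n_perm = 99, seed = 1)$r, 1)
  expect_equal(mantel(da, da, "spearman", n_perm = 99, seed = 1)$r, 1)
  expect_equal(mantel(da, 3 * da + 0.5, "pearson", n_perm = 9, seed = 1)$r, 1)
  y <- rnorm(5)
  db <- as.matrix(dist(y))
  lt <- lower.tri(da)
  r_obs <- cor(da[lt], db[lt])
  rs <- vapply(all_perms(5), function(p) cor(da[lt], db[p, p][lt]), numeric(1))
  p_oracle <- mean(rs >= r_obs - 1e-12)
  res <- mantel(da, db, "pearson", n_perm = "exact")
  expect_equal(res$r, r_obs)
  expect_equal(res$p, p_oracle)
  expect_equal(res$n_perm, 120)
  expect_error(mantel(da, da * 0, n_perm = 9), "zero variance")
})

test_that("top features rank by max |correlation| with PC1/PC2", {
  set.seed(40)
  n <- 60
  scores <- cbind(PC1 = rnorm(n), PC2 = rnorm(n))
  ord <- list(coordinates = scores)
  m <- cbind(
    marker = as.integer(scores[, 1] > 0),       # tracks PC1's sign pattern
    always = rep(1L, n),                         # constant -> excluded
    noise1 = rbinom(n, 1, 0.5),
    noise2 = rbinom(n, 1, 0.5))
  expect_warning(tf <- top_features(m, ord, k = 3), "constant")
  expect_identical(tf$descriptor[1], "marker")
  expect_false("always" %in% tf$descriptor)
  expect_true(all(tf$strength == pmax(abs(tf$r_pc1), abs(tf$r_pc2))))
})

test_that("batch PERMANOVA and Mantel run over metadata with BH correction", {
  st <- small_study(n = 250, seed = 17)
  tab <- harmonize_study(st)
  cata_cols <- grep("^cata_", names(tab), value = TRUE)
  sub <- tab[complete.cases(tab[, cata_cols]), ]
  m <- as.matrix(sub[, cata_cols])
  rownames(m) <- sub$sample_code
  d <- jaccard_matrix(m)
  pb <- permanova_batch(d, sub, c("grain_base", "organic_flour"),
                        n_perm = 49, seed = 5)
  expect_true(all(c("variable", "pseudo_F", "R2", "p", "q") %in% names(pb)))
  expect_true(all(pb$q >= pb$p))
  mb <- mantel_batch(d, sub, c("tta", "dough_yield"), n_perm = 49, seed = 5)
  expect_setequal(unique(mb$method), c("pearson", "spearman"))
  expect_true(all(mb$q >= mb$p))
})
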