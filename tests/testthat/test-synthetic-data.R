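# Generator: determinism, linkage structure, config validation, planted
# effects, CATA sampling.

test_that("same config and seed give byte-identical tables", {
  cfg <- generator_config(n_participants = 150, seed = 42)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1, s2)
  s3 <- generate_study(generator_config(n_participants = 150, seed = 43))
  expect_false(identical(s1$registration, s3$registration))
})

test_that("tables are linked by unique 5-char codes and 1-5 samples per person", {
  st <- small_study(n = 400, seed = 3)
  codes <- st$registration$sample_code
  expect_false(anyDuplicated(codes) > 0)
  expect_true(all(nchar(codes) == 5))
  expect_true(all(grepl("^[A-Z0-9]{5}$", codes)))
  expect_true(all(st$results$sample_code %in% codes))
  expect_true(all(st$lab$sample_code %in% codes))
  mult <- table(st$registration$person_id)
  expect_true(all(mult >= 1 & mult <= 5))
  expect_gt(sum(mult > 1), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(n_participants = 0), "positive")
  expect_error(generator_config(n_participants = -5), "positive")
  expect_error(
    generator_config(effect_registry = list(
      planted_effect("mean_shift", "no_such_field", "source", "bakery", 1))),
    "unknown effect target")
  bad_w <- default_countries()
  bad_w$weight[1] <- bad_w$weight[1] + 0.01
  expect_error(generator_config(countries = bad_w), "sum to 1")
  expect_error(generator_config(missingness = list(nonfield = 0.1)),
               "unknown missingness")
})

test_that("zero missingness yields complete tables", {
  st <- small_study(n = 150, seed = 9)
  expect_false(anyNA(st$registration))
  expect_false(anyNA(st$results))
  expect_false(anyNA(st$lab))
})

test_that("missingness injects roughly the configured per-field rate", {
  cfg <- generator_config(n_participants = 800, effect_registry = list(),
                          missingness = list(tta = 0.3), seed = 5)
  st <- generate_study(cfg)
  rate <- mean(is.na(st$lab$tta))
  expect_gt(rate, 0.22)
  expect_lt(rate, 0.38)
  expect_false(anyNA(st$registration$flour_type))
})

test_that("lab pH reproduces home pH plus the systematic offset", {
  st <- small_study(n = 500, seed = 11)
  merged <- merge(st$results[, c("sample_code", "ph_home")], st$lab)
  diff <- mean(merged$ph_lab - merged$ph_home)
  expect_lt(abs(diff - (-0.73)), 0.05)
  # home pH is strip-quantised, lab pH continuous
  expect_true(all(abs(merged$ph_home / 0.25 - round(merged$ph_home / 0.25)) < 1e-9))
  expect_gt(length(unique(merged$ph_lab)), length(unique(merged$ph_home)))
})

test_that("planted aroma association shifts descriptor prevalence", {
  eff <- list(planted_effect("aroma_association", "sour", "grain_base",
                             "rye", 0.35))
  cfg <- generator_config(n_participants = 800, effect_registry = eff,
                          missingness = 0, seed = 21)
  st <- generate_study(cfg)
  dec <- decompose_flour(st$registration$flour_type)
  gb <- dec$grain_base[match(st$results$sample_code,
                             st$registration$sample_code)]
  p_rye <- mean(st$results$cata_sour[gb == "rye"])
  p_other <- mean(st$results$cata_sour[gb != "rye"])
  expect_gt(p_rye - p_other, 0.2)
})

test_that("planted mean shift of 1 SD is detected in >= 90% of replicates", {
  # module invariant, scaled to 25 replicates to stay inside the test budget
  eff <- list(planted_effect("mean_shift", "tta", "source", "bakery", 1))
  hits <- vapply(1:25, function(i) {
    cfg <- generator_config(n_participants = 500, effect_registry = eff,
                            missingness = 0, seed = 1000 + i)
    st <- generate_study(cfg)
    tta <- st$lab$tta[match(st$registration$sample_code, st$lab$sample_code)]
    src <- st$registration$source
    res <- mann_whitney_rank_biserial(tta[src == "bakery"],
                                      tta[src == "household"])
    res$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("sample_cata honours effect shifts, clipping and base rates", {
  eff <- list(planted_effect("aroma_association", "sour", "grain_base",
                             "rye", 1.0))
  # delta +1 clips to p = 1: present in every rye draw
  for (s in 1:20) {
    v <- suppressMessages(
      sample_cata(list(grain_base = "rye"), eff, seed = s))
    expect_identical(v[["sour"]], 1L)
  }
  expect_length(sample_cata(list(grain_base = "wheat"), seed = 1), 56)
  # zero base prevalence everywhere: all-zero vector
  v0 <- sample_cata(list(grain_base = "wheat"), seed = 2,
                    prevalence_range = c(0, 0))
  expect_true(all(v0 == 0))
  # no effect: prevalence matches the base rate within a binomial CI
  draws <- vapply(1:1000, function(s) {
    sample_cata(list(grain_base = "wheat"), list(), seed = s,
                prevalence_range = c(0.3, 0.3))[["grain"]]
  }, integer(1))
  expect_lt(abs(mean(draws) - 0.3), 3 * sqrt(0.3 * 0.7 / 1000))
})

test_that("truth registry separates planted and null features", {
  st <- generate_study(generator_config(n_participants = 50, seed = 2))
  planted <- vapply(st$truth$effects, `[[`, character(1), "target_feature")
  expect_length(intersect(planted, st$truth$null_features), 0)
  expect_s3_class(st$truth, "synthetic_truth")
})

test_that("written study round-trips through CSV/JSON", {
  st <- small_study(n = 60, seed = 8)
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  expect_true(all(file.exists(paths)))
  reg <- read.csv(paths[1], stringsAsFactors = FALSE)
  expect_identical(reg$sample_code, st$registration$sample_code)
  truth <- jsonlite::fromJSON(paths[4], simplifyVector = FALSE)
  expect_length(truth$effects, length(st$truth$effects))
})
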