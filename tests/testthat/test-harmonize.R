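# Table merging with back-filling, derivations and recoding rules.

reg3 <- data.frame(
  sample_code = c("AAAAA", "BBBBB", "CCCCC"),
  person_id = c("P1", "P1", "P2"),
  backslop_frequency = c(7, 2, 3),
  stringsAsFactors = FALSE
)

test_that("result variables missing in results are back-filled from registration", {
  res <- data.frame(sample_code = c("AAAAA", "BBBBB"),
                    person_id = c("P1", "P1"),
                    backslop_frequency = c(NA, 5), ph_home = c(4, 4.25))
  out <- merge_tables(reg3, res)
  expect_equal(out$backslop_frequency, c(7, 5, 3))
  prov <- attr(out, "provenance")$backslop_frequency
  expect_identical(prov[1], "registration_backfill")
  expect_identical(prov[2], "results")
  expect_true(is.na(prov[3]))
})

test_that("outer merge keeps all registered samples; lab fields attach to matches", {
  reg <- data.frame(sample_code = sprintf("S%04d", 1:10),
                    person_id = sprintf("P%02d", 1:10))
  res <- data.frame(sample_code = reg$sample_code[1:6],
                    person_id = reg$person_id[1:6], ph_home = runif(6, 3, 5))
  lab <- data.frame(sample_code = reg$sample_code[1:6],
                    ph_lab = runif(6, 3, 4), tta = runif(6, 5, 20))
  out <- merge_tables(reg, res, lab)
  expect_equal(nrow(out), 10)
  expect_equal(sum(!is.na(out$ph_lab)), 6)
  expect_equal(sum(!is.na(out$tta)), 6)
})

test_that("duplicate codes error; orphan results are quarantined with a warning", {
  dup <- reg3
  dup$sample_code[2] <- "AAAAA"
  expect_error(merge_tables(dup), "duplicate sample_code")
  res <- data.frame(sample_code = c("AAAAA", "ZZZZZ"), person_id = c("P1", "PX"),
                    ph_home = c(4, 4.5))
  expect_warning(out <- merge_tables(reg3, res), "quarantined")
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "quarantine")$sample_code, "ZZZZZ")
  lab <- data.frame(sample_code = c("AAAAA", "YYYYY"), ph_lab = c(3.2, 3.4))
  expect_warning(out2 <- merge_tables(reg3, lab = lab), "no registration match")
  expect_equal(attr(out2, "qc")$lab_orphans, "YYYYY")
})

test_that("merge is idempotent under empty updates", {
  res <- data.frame(sample_code = "AAAAA", person_id = "P1", ph_home = 4)
  once <- merge_tables(reg3, res)
  again <- merge_tables(as.data.frame(once))
  expect_equal(as.data.frame(again), as.data.frame(once), ignore_attr = TRUE)
})

test_that("person multiplicity survives harmonisation", {
  st <- small_study(n = 300, seed = 14)
  tab <- harmonize_study(st)
  expect_equal(nrow(tab), nrow(st$registration))
  expect_identical(table(tab$person_id), table(st$registration$person_id))
})

test_that("dough yield follows (flour + water)/flour * 100", {
  expect_equal(compute_dough_yield(100, 100), 200)
  expect_equal(compute_dough_yield(100, 0), 100)
  expect_equal(compute_dough_yield(50, 75), 250)
  expect_error(compute_dough_yield(0, 10), "undefined")
  expect_error(compute_dough_yield(-1, 10), "undefined")
  # scale invariance
  for (k in c(0.5, 2, 17.3)) {
    expect_equal(compute_dough_yield(k * 80, k * 120),
                 compute_dough_yield(80, 120))
  }
})

test_that("flour labels decompose into grain base and milling grade", {
  expect_equal(decompose_flour("wholemeal rye"),
               data.frame(grain_base = "rye", milling_grade = "wholemeal",
                          stringsAsFactors = FALSE))
  expect_equal(decompose_flour("semi-wholemeal wheat", grouped = TRUE)$milling_grade,
               "wholemeal")
  expect_equal(decompose_flour("semi-wholemeal wheat")$milling_grade,
               "semi-wholemeal")
  expect_equal(decompose_flour("wheat"),
               data.frame(grain_base = "wheat", milling_grade = "unspecified",
                          stringsAsFactors = FALSE))
  expect_error(decompose_flour("stone-ground einkorn"), "einkorn")
  # NA propagates
  out <- decompose_flour(c(NA, "rye"))
  expect_true(is.na(out$grain_base[1]) && is.na(out$milling_grade[1]))
})

test_that("rare levels bin to Other with an inclusive 1% threshold", {
  x <- c(rep("a", 197), "b", "c", "c")          # b: 0.5%, c: 1.0%
  out <- bin_rare_levels(x)
  expect_true(all(out[x == "b"] == "Other"))
  expect_true(all(out[x == "c"] == "Other"))    # 1.0% is inclusive
  y <- c(rep("a", 197), rep("d", 3))            # d: 1.5%
  expect_true(all(bin_rare_levels(y)[y == "d"] == "d"))
  # never increases the number of distinct levels; missing untouched
  set.seed(1)
  for (i in 1:20) {
    z <- sample(letters[1:8], 150, replace = TRUE,
                prob = c(0.5, 0.3, rep(0.2 / 6, 6)))
    z[sample(150, 10)] <- NA
    b <- bin_rare_levels(z)
    expect_lte(length(unique(na.omit(b))), length(unique(na.omit(z))))
    expect_identical(is.na(b), is.na(z))
  }
})

test_that("bread densities above 1 are excluded, boundary retained", {
  expect_equal(as.numeric(filter_bread_density(c(0.4, 0.9, 1.2))), c(0.4, 0.9))
  expect_equal(attr(filter_bread_density(c(0.4, 0.9, 1.2)), "n_excluded"), 1)
  expect_equal(as.numeric(filter_bread_density(1.0)), 1.0)
  expect_length(filter_bread_density(numeric(0)), 0)
})

test_that("numeric categorisation uses lower-inclusive half-open bins", {
  f <- categorize_numeric(c(5, 10, 0.5, 3), c(1, 5, 10))
  expect_equal(as.character(f), c("[5,10)", ">=10", "<1", "[1,5)"))
  expect_true(is.ordered(f))
  expect_error(categorize_numeric(1:3, c(5, 5, 10)), "strictly increasing")
})

test_that("source contrast drops unknown and industrial samples", {
  tab <- data.frame(source = c("household", "bakery", "industrial", "unknown", NA))
  out <- source_contrast(tab)
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "n_excluded"), 3)
})
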