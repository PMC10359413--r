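test_that("derived sums, indices and chain length follow the recipe arithmetic", {
  p <- make_profiles(list(`14:0` = c(50, 40), `18:0` = c(50, 60)))
  d <- suppressWarnings(compute_derived(p, missing_as_zero = TRUE))
  expect_equal(d[["SFA sum"]], c(100, 100))
  expect_equal(d[["MUFA sum"]], c(0, 0))
  expect_equal(d[["double bond index"]], c(0, 0))
  expect_equal(d[["average chain length"]], c(16, 16.4))
  # raw columns untouched
  expect_equal(d[["14:0"]], p[["14:0"]])

  p2 <- make_profiles(list(`22:6n-3` = c(100, 100)))
  d2 <- suppressWarnings(compute_derived(p2, missing_as_zero = TRUE))
  expect_equal(d2[["double bond index"]], c(6, 6))
  expect_equal(d2[["average chain length"]], c(22, 22))
  expect_equal(d2[["n-3 PUFA sum"]], c(100, 100))
})

test_that("product/precursor ratio divides C20-22 products by the precursor", {
  p <- make_profiles(list(`18:2n-6` = c(50, 25), `20:4n-6` = c(50, 75)))
  d <- suppressWarnings(compute_derived(p, missing_as_zero = TRUE))
  # hand-evaluated: (C20-22 n-6 PUFA) / 18:2n-6
  expect_equal(d[["n-6 product/precursor ratio"]], c(1, 3))
})

test_that("recipes referencing absent FAs are rejected unless relaxed", {
  p <- make_profiles(list(`14:0` = c(60, 60), `16:0` = c(40, 40)))
  expect_error(compute_derived(p), "18:2n-6")
  # absent precursors become zero denominators, reported NA with warnings
  w <- capture_warnings(d <- compute_derived(p, missing_as_zero = TRUE))
  expect_true(any(grepl("zero denominator", w)))
  expect_true(is.na(d[["n-3/n-6 ratio"]][1]))
})

test_that("Z-scores use the population standard deviation", {
  p <- make_profiles(list(v = c(1, 2, 3)), diagnosis = c("OA", "OA", "RA"))
  names(p)[3] <- "14:0"
  z <- zscore_profiles(p)
  expect_equal(z[["14:0"]], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
})

test_that("Z-scoring is location invariant and idempotent", {
  set.seed(4)
  p <- make_profiles(list(`14:0` = rnorm(10), `16:0` = rnorm(10),
                          `18:0` = rnorm(10)))
  z <- zscore_profiles(p)
  shifted <- p
  shifted[3:5] <- shifted[3:5] + 7
  expect_equal(zscore_profiles(shifted), z, tolerance = 1e-9)
  expect_equal(zscore_profiles(z), z, tolerance = 1e-9)
  M <- as.matrix(z[3:5])
  expect_equal(colMeans(M), c(`14:0` = 0, `16:0` = 0, `18:0` = 0),
               tolerance = 1e-9)
  expect_equal(apply(M, 2, function(x) sqrt(mean((x - mean(x))^2))),
               c(`14:0` = 1, `16:0` = 1, `18:0` = 1), tolerance = 1e-9)
})

test_that("zero-variance variables are rejected by name, not NaN-ed", {
  p <- make_profiles(list(`14:0` = c(1, 2, 3), `16:0` = c(5, 5, 5)))
  expect_error(zscore_profiles(p), "16:0")
})

test_that("two-group comparison uses the exact Mann-Whitney branch at small n", {
  p <- make_profiles(list(`14:0` = c(1, 2, 3, 4, 5, 6)),
                     diagnosis = rep(c("OA", "RA"), each = 3))
  st <- compare_groups(p)
  expect_equal(st$method, "exact")
  expect_true(st$U %in% c(0, 9))
  expect_equal(st$p_value, 0.1, tolerance = 1e-12)
  expect_equal(st$mean_OA, 2)
  expect_equal(st$se_OA, stats::sd(1:3) / sqrt(3))
})

test_that("tied data fall back to the corrected normal approximation", {
  p <- make_profiles(list(`14:0` = c(1, 2, 3, 1, 2, 3)),
                     diagnosis = rep(c("OA", "RA"), each = 3))
  st <- compare_groups(p)
  expect_equal(st$method, "approximate")
  expect_equal(st$p_value, 1)
})

test_that("comparison requires exactly two groups of at least 2 samples", {
  p <- make_profiles(list(`14:0` = c(1, 2, 3)),
                     diagnosis = c("OA", "OA", "RA"))
  expect_error(compare_groups(p), "at least 2 samples")
  p2 <- make_profiles(list(`14:0` = 1:4),
                      diagnosis = c("OA", "RA", "IFP", "OA"))
  expect_error(compare_groups(p2), "two levels")
})

test_that("Fisher 2x2 matches the hypergeometric enumeration", {
  # the study cohort's sex ratio: 2 men, 6 women in both groups
  expect_equal(fisher_exact_2x2(matrix(c(2, 2, 6, 6), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(0, 3, 0, 5), 2)), 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("per-sample raw mol-% sums are preserved through the module", {
  p <- study_shaped_fixture(3)
  raw <- profile_variables(p)
  before <- rowSums(as.matrix(p[raw]))
  d <- compute_derived(p, missing_as_zero = TRUE)
  expect_equal(rowSums(as.matrix(d[raw])), before, tolerance = 1e-12)
  # dropping derived columns recovers the original table
  expect_equal(d[c("sample_id", "diagnosis", raw)],
               tibble::as_tibble(p)[c("sample_id", "diagnosis", raw)],
               ignore_attr = TRUE)
})

test_that("profile validation flags closure violations and bad structure", {
  p <- make_profiles(list(`14:0` = c(60, 60), `16:0` = c(41, 40)))
  expect_warning(validate_profiles(p), "s01")
  fixed <- validate_profiles(p, renormalize = TRUE)
  expect_equal(rowSums(as.matrix(fixed[c("14:0", "16:0")])), c(100, 100))
  dup <- p; dup$sample_id <- c("a", "a")
  expect_error(validate_profiles(dup), "duplicated sample")
})

test_that("the shipped YAML recipe set matches the built-in defaults", {
  path <- system.file("extdata", "derived_recipes.yaml", package = "fasig")
  expect_identical(read_recipe(path), fa_recipe())
})
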