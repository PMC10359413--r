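# a 16-sample Z-style dataset where slot-4's variable alone separates the
# classes and the other four variables are pure noise
separable_z <- function(seed = 1, sep = 2) {
  set.seed(seed)
  cls <- rep(c("OA", "RA"), each = 8)
  vals <- list(v1 = rnorm(16), v2 = rnorm(16), v3 = rnorm(16),
               v4 = ifelse(cls == "RA", sep, -sep) + rnorm(16, sd = 0.1),
               v5 = rnorm(16))
  make_profiles(vals, diagnosis = cls)
}

singleton_groups <- tibble::tibble(variable = paste0("v", 1:5), group = 1:5)

test_that("enrichment emits B x n rows with copied labels", {
  fx <- study_shaped_fixture(2)
  z <- zscore_profiles(fx)
  groups <- attr(fx, "truth")$groups
  e <- enrich(z, groups, iterations = 1000, seed = 1)
  expect_equal(nrow(e), 16000)  # 1000 x 16
  expect_equal(ncol(e), 3 + 5)
  # per-iteration class proportions equal the source proportions
  tab <- dplyr::count(e, iteration, diagnosis)
  expect_true(all(tab$n == 8))
})

test_that("singleton groups make every iteration identical", {
  z <- separable_z()
  e <- enrich(z, singleton_groups, iterations = 7, seed = 3)
  expect_equal(nrow(e), 7 * 16)
  first <- as.matrix(e[e$iteration == 1, paste0("group_", 1:5)])
  for (b in 2:7) {
    expect_equal(as.matrix(e[e$iteration == b, paste0("group_", 1:5)]),
                 first)
  }
})

test_that("every enriched cell traces back to its source Z value", {
  fx <- study_shaped_fixture(4)
  z <- zscore_profiles(fx)
  groups <- attr(fx, "truth")$groups
  e <- enrich(z, groups, iterations = 2, seed = 9)
  prov <- attr(e, "provenance")
  expect_equal(nrow(prov), 2 * 5)
  for (i in seq_len(nrow(prov))) {
    rows <- e[e$iteration == prov$iteration[i], ]
    expect_equal(rows[[paste0("group_", prov$group[i])]],
                 z[[prov$variable[i]]][match(rows$sample_id, z$sample_id)])
  }
})

test_that("empty or mismatched groups are rejected", {
  z <- separable_z()
  bad <- tibble::tibble(variable = c("v1", "nonesuch"), group = c(1, 2))
  expect_error(enrich(z, bad, 2), "nonesuch")
})

test_that("a perfectly separating slot drives accuracy and tops importance", {
  accs <- numeric(5)
  for (s in 1:5) {
    e <- enrich(separable_z(s), singleton_groups, iterations = 50,
                seed = 100 + s)
    run <- train_rf(e, repeats = 3, seed = 200 + s)
    accs[s] <- run$mean_accuracy
    expect_equal(which.max(run$mean_importance), 4L,
                 ignore_attr = TRUE)
    # per-forest importances are normalized
    expect_equal(rowSums(run$importance), rep(1, 3), tolerance = 1e-9)
  }
  expect_gte(mean(accs), 0.99)
})

test_that("permuted labels give chance-level accuracy on held-out samples", {
  # non-enriched run: test samples are disjoint from training samples, so
  # breaking the label-feature link must drop accuracy to chance
  set.seed(42)
  z <- separable_z(11)
  z$diagnosis <- sample(z$diagnosis)
  run <- train_rf(z, repeats = 25, seed = 6)
  expect_lt(abs(run$mean_accuracy - 0.5), 0.25)
})

test_that("runs are reproducible given the seed", {
  e <- enrich(separable_z(3), singleton_groups, iterations = 30, seed = 8)
  r1 <- train_rf(e, repeats = 3, seed = 21)
  r2 <- train_rf(e, repeats = 3, seed = 21)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$importance, r2$importance)
})

test_that("duplicating every row leaves the importance ranking unchanged", {
  e <- enrich(separable_z(6), singleton_groups, iterations = 40, seed = 13)
  r1 <- train_rf(e, repeats = 3, seed = 31)
  r2 <- train_rf(dplyr::bind_rows(e, e), repeats = 3, seed = 31)
  expect_equal(which.max(r1$mean_importance),
               which.max(r2$mean_importance))
})

test_that("importance tables map slots to groups and variables to kinds", {
  e <- enrich(separable_z(2), singleton_groups, iterations = 30, seed = 4)
  run <- train_rf(e, repeats = 2, seed = 3)
  tab <- importance_by_group(run, singleton_groups)
  expect_equal(sort(tab$group), 1:5)
  expect_equal(tab$group[tab$rank == 1], 4)
  expect_equal(sum(tab$importance), 1, tolerance = 1e-9)

  # full-variable run: per-variable scores and the raw-only variant
  fx <- study_shaped_fixture(5)
  d <- compute_derived(fx, missing_as_zero = TRUE)
  z <- zscore_profiles(d)
  hc <- cluster_profiles(z)
  groups <- assign_groups(hc, 5)
  full <- train_rf(z, repeats = 2, seed = 7)
  out <- importance_by_group(full, groups)
  expect_named(out, c("by_variable", "by_group", "raw_only"))
  expect_equal(nrow(out$by_variable), length(profile_variables(z)))
  expect_true(all(out$raw_only$kind == "raw_fa"))
  expect_equal(sum(out$raw_only$importance), 1, tolerance = 1e-9)
  expect_error(importance_by_group(full), "group assignment")
})

test_that("glance and tidy summarize a run", {
  e <- enrich(separable_z(8), singleton_groups, iterations = 20, seed = 2)
  run <- train_rf(e, repeats = 2, seed = 5)
  g <- glance(run)
  expect_equal(g$repeats, 2)
  expect_true(g$mean_accuracy >= 0 && g$mean_accuracy <= 1)
  td <- tidy(run)
  expect_equal(nrow(td), 5)
  expect_equal(td$rank[1], 1)
})
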