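test_that("level change is the relative mean difference against the reference", {
  p <- make_profiles(list(`14:0` = c(1, 1, 1.5, 1.5),
                          `16:0` = c(2, 2, 2, 2)),
                     diagnosis = c("OA", "OA", "RA", "RA"))
  lc <- level_change(p)
  expect_equal(lc$level_change[lc$variable == "14:0"], 0.5,
               tolerance = 1e-12)
  expect_equal(lc$level_change[lc$variable == "16:0"], 0)
  # reference against itself is zero everywhere
  self <- level_change(p, ref = "OA", alt = "OA")
  expect_equal(self$level_change, c(0, 0))
})

test_that("exchanging diagnoses maps the score to -lc / (1 + lc)", {
  set.seed(21)
  p <- make_profiles(list(`14:0` = runif(8, 1, 3), `16:0` = runif(8, 1, 3)),
                     diagnosis = rep(c("OA", "RA"), each = 4))
  fwd <- level_change(p, ref = "OA", alt = "RA")
  rev <- level_change(p, ref = "RA", alt = "OA")
  expect_equal(rev$level_change, -fwd$level_change / (1 + fwd$level_change),
               tolerance = 1e-12)
})

test_that("zero reference means are reported missing with a warning", {
  p <- make_profiles(list(`14:0` = c(0, 0, 1, 2), `16:0` = c(1, 2, 1, 2)),
                     diagnosis = c("OA", "OA", "RA", "RA"))
  expect_warning(lc <- level_change(p), "14:0")
  expect_true(is.na(lc$level_change[lc$variable == "14:0"]))
})

test_that("the default reaction table obeys reaction chemistry", {
  tbl <- reaction_table()
  expect_true(all(tbl$delta_carbons[tbl$kind == "elongation"] == 2))
  expect_true(all(tbl$delta_carbons[tbl$kind == "chain_shortening"] == -2))
  expect_true(all(tbl$delta_db[tbl$kind == "desaturation"] == 1))
  expect_true(all(tbl$delta_db[tbl$kind != "desaturation"] == 0))
  # invalid reactions are rejected
  expect_error(validate_reaction_table(
    tibble::tibble(substrate = "14:0", product = "18:0",
                   kind = "elongation")), "invalid elongation")
  expect_error(validate_reaction_table(
    tibble::tibble(substrate = "18:2n-6", product = "18:3n-3",
                   kind = "desaturation")), "invalid desaturation")
})

test_that("the shipped TSV reaction table matches the built-in one", {
  path <- system.file("extdata", "reactions.tsv", package = "fasig")
  expect_equal(read_reaction_table(path), reaction_table())
})

test_that("network assembly links measured FAs and contracts unmeasured chains", {
  net <- build_network(c("14:0", "16:0"))
  direct <- net$edges[!net$edges$effective, ]
  expect_equal(nrow(direct), 1)
  expect_equal(direct$from, "14:0")
  expect_equal(direct$to, "16:0")
  expect_equal(direct$kind, "elongation")

  # n-3 tail without the C24 intermediates: effective 22:5n-3 -> 22:6n-3
  meas <- c("18:3n-3", "18:4n-3", "20:4n-3", "20:5n-3", "22:5n-3", "22:6n-3")
  net3 <- build_network(meas)
  eff <- net3$edges[net3$edges$effective, ]
  expect_equal(nrow(eff), 1)
  expect_equal(eff$from, "22:5n-3")
  expect_equal(eff$to, "22:6n-3")
  expect_equal(eff$delta_carbons, 0L)
  expect_equal(eff$delta_db, 1L)
  expect_equal(eff$kind, "elongation+desaturation+chain_shortening")

  # nothing measured: hollow nodes only, no edges
  net0 <- build_network(character(0))
  expect_false(any(net0$nodes$measured))
  expect_equal(nrow(net0$edges), 0)

  expect_warning(build_network(c("14:0", "16:0", "17:0")), "17:0")
})

test_that("effective-edge deltas equal the sums along their contracted chains", {
  # drop alternating nodes from the n-6 chain to force several contractions
  meas <- c("18:2n-6", "20:3n-6", "22:4n-6")
  net <- build_network(meas)
  parsed <- parse_fa_name(c(net$edges$from, net$edges$to))
  k <- nrow(net$edges)
  expect_equal(net$edges$delta_carbons,
               parsed$carbons[(k + 1):(2 * k)] - parsed$carbons[1:k])
  expect_equal(net$edges$delta_db,
               parsed$double_bonds[(k + 1):(2 * k)] - parsed$double_bonds[1:k])
  expect_true(all(net$edges$effective))
})

test_that("edge annotation classifies within-diagnosis correlation patterns", {
  set.seed(31)
  x <- abs(rnorm(16, 5))
  p <- make_profiles(list(`14:0` = x, `16:0` = x * 2),
                     diagnosis = rep(c("OA", "RA"), each = 8))
  net <- build_network(c("14:0", "16:0"))
  ann <- annotate_edges(net, p)
  expect_equal(ann$class, "sig_both")
  expect_equal(ann$r_OA, 1, tolerance = 1e-9)

  # independent product: usually not significant in either group
  set.seed(32)
  p2 <- make_profiles(list(`14:0` = abs(rnorm(16, 5)),
                           `16:0` = abs(rnorm(16, 5))),
                      diagnosis = rep(c("OA", "RA"), each = 8))
  ann2 <- annotate_edges(net, p2)
  expect_true(ann2$class %in% c("sig_neither", "sig_OA_only",
                                "sig_RA_only", "sig_both"))
  expect_true(all(c("r_OA", "p_OA", "r_RA", "p_RA") %in% names(ann2)))

  # missing endpoint: edge skipped with a warning
  p3 <- p2[, names(p2) != "16:0"]
  expect_warning(ann3 <- annotate_edges(net, p3), "skipped")
  expect_equal(nrow(ann3), 0)
})

test_that("a planted RA-only relation is usually detected as sig_RA_only", {
  hits <- 0L
  for (s in 1:25) {
    ee <- tibble::tibble(substrate = "g1.v1", product = "g1.v2",
                         diagnosis = "RA", r = 0.9)
    g <- generate_profiles(
      synth_spec(n_groups = 1, vars_per_group = 2, rho = 0,
                 effect = 0, closure = FALSE, edge_effects = ee),
      seed = s)
    net <- list(nodes = NULL,
                edges = tibble::tibble(from = "g1.v1", to = "g1.v2",
                                       kind = "elongation",
                                       effective = FALSE))
    class(net) <- "fa_network"
    ann <- annotate_edges(net, g$profiles)
    hits <- hits + (ann$class == "sig_RA_only")
  }
  expect_gte(hits, 18)  # ~95% power x 95% specificity at n = 8, r = 0.9
})

test_that("network export round-trips through GraphML", {
  fx <- study_shaped_fixture(8)
  vars <- profile_variables(fx)
  net <- suppressWarnings(build_network(vars[is_fa_label(vars)]))
  ann <- annotate_edges(net, fx)
  lc <- level_change(fx)
  prefix <- tempfile()
  paths <- export_network(net, ann, lc, prefix)
  expect_true(all(file.exists(paths)))
  g <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(ann))
  expect_setequal(igraph::V(g)$name, net$nodes$label)
  expect_setequal(igraph::E(g)$class, ann$class)
  edges_tsv <- readr::read_tsv(paths[["edges"]], show_col_types = FALSE)
  expect_equal(nrow(edges_tsv), nrow(ann))
  # an empty network still produces a valid document
  net0 <- build_network(character(0))
  p0 <- export_network(net0, path_prefix = tempfile())
  g0 <- igraph::read_graph(p0[["graphml"]], format = "graphml")
  expect_equal(igraph::ecount(g0), 0)
})
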