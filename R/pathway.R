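#' Level-change score between diagnoses
#'
#' For each FA, the relative change of the mean mol-% in the alternative
#' diagnosis with respect to the reference diagnosis:
#' `(mean_alt - mean_ref) / mean_ref`. With OA as reference and RA as
#' alternative this is the node color scale of the reaction-network view.
#'
#' @param profiles Profile tibble.
#' @param ref,alt Reference and alternative diagnosis levels (defaults
#'   `"OA"` and `"RA"`).
#' @param variables Variables to score; default all raw FA columns.
#' @return A tibble (`variable`, `mean_ref`, `mean_alt`, `level_change`).
#'   FAs with a zero reference mean get `NA` with a warning.
#' @export
level_change <- function(profiles, ref = "OA", alt = "RA", variables = NULL) {
  profiles <- tibble::as_tibble(profiles)
  d <- as.character(profiles$diagnosis)
  if (!all(c(ref, alt) %in% d)) {
    stop("both diagnoses must be present in the data", call. = FALSE)
  }
  if (is.null(variables)) {
    vars <- profile_variables(profiles)
    variables <- vars[variable_kind(vars) == "raw_fa"]
    if (!length(variables)) variables <- vars
  }
  m_ref <- colMeans(profiles[d == ref, variables, drop = FALSE])
  m_alt <- colMeans(profiles[d == alt, variables, drop = FALSE])
  lc <- (m_alt - m_ref) / m_ref
  zero <- m_ref == 0
  if (any(zero)) {
    warning("zero reference mean; level change undefined for: ",
            paste(sQuote(variables[zero]), collapse = ", "), call. = FALSE)
    lc[zero] <- NA_real_
  }
  tibble::tibble(variable = variables, mean_ref = unname(m_ref),
                 mean_alt = unname(m_alt), level_change = unname(lc))
}

#' Default FA elongation/desaturation reaction table
#'
#' The mammalian FA biosynthesis reactions over the chains measured by
#' GC-FID, with double-bond positions (n-series) distinguished throughout:
#' the even-chain SFA elongation ladder, the delta-9 desaturation branches
#' into the n-7 and n-9 MUFA series with their elongations, and the n-6
#' and n-3 PUFA desaturation/elongation chains including the C24
#' intermediates and the peroxisomal chain-shortening steps that produce
#' 22:5n-6 and 22:6n-3.
#'
#' The same table ships as a plain TSV in
#' `system.file("extdata", "reactions.tsv", package = "fasig")` and can be
#' edited and re-read with [read_reaction_table()].
#'
#' @return A validated tibble (`substrate`, `product`, `kind`) with kinds
#'   `elongation` (+2 carbons), `chain_shortening` (-2 carbons) and
#'   `desaturation` (+1 double bond).
#' @export
reaction_table <- function() {
  tbl <- tibble::tribble(
    ~substrate, ~product, ~kind,
    # SFA elongation ladder
    "14:0", "16:0", "elongation",
    "16:0", "18:0", "elongation",
    "18:0", "20:0", "elongation",
    "20:0", "22:0", "elongation",
    "22:0", "24:0", "elongation",
    # delta-9 desaturation and MUFA elongation, n-7 branch
    "16:0", "16:1n-7", "desaturation",
    "16:1n-7", "18:1n-7", "elongation",
    # n-9 branch
    "18:0", "18:1n-9", "desaturation",
    "18:1n-9", "20:1n-9", "elongation",
    "20:1n-9", "22:1n-9", "elongation",
    "22:1n-9", "24:1n-9", "elongation",
    # n-6 PUFA chain
    "18:2n-6", "18:3n-6", "desaturation",
    "18:3n-6", "20:3n-6", "elongation",
    "20:3n-6", "20:4n-6", "desaturation",
    "20:4n-6", "22:4n-6", "elongation",
    "22:4n-6", "24:4n-6", "elongation",
    "24:4n-6", "24:5n-6", "desaturation",
    "24:5n-6", "22:5n-6", "chain_shortening",
    # n-3 PUFA chain
    "18:3n-3", "18:4n-3", "desaturation",
    "18:4n-3", "20:4n-3", "elongation",
    "20:4n-3", "20:5n-3", "desaturation",
    "20:5n-3", "22:5n-3", "elongation",
    "22:5n-3", "24:5n-3", "elongation",
    "24:5n-3", "24:6n-3", "desaturation",
    "24:6n-3", "22:6n-3", "chain_shortening"
  )
  validate_reaction_table(tbl)
}

#' Read a reaction table from TSV
#'
#' @param path TSV file with columns `substrate`, `product`, `kind`.
#' @return A validated reaction tibble.
#' @export
read_reaction_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  validate_reaction_table(tbl)
}

#' Validate a reaction table
#'
#' Checks reaction chemistry: elongation changes carbons by +2 and double
#' bonds by 0, chain shortening by -2/0, desaturation by 0/+1; no
#' self-reactions; the n-series is preserved along every reaction except a
#' delta-9 desaturation of a saturated chain, which legitimately creates
#' the n-7 (from 16:0) or n-9 (from 18:0) series.
#'
#' @param reactions Tibble with columns `substrate`, `product`, `kind`.
#' @return The validated tibble, invisibly augmented with parsed deltas
#'   (`delta_carbons`, `delta_db`).
#' @export
validate_reaction_table <- function(reactions) {
  reactions <- tibble::as_tibble(reactions)
  stopifnot(all(c("substrate", "product", "kind") %in% names(reactions)))
  if (any(reactions$substrate == reactions$product)) {
    stop("self-reaction in table", call. = FALSE)
  }
  s <- parse_fa_name(reactions$substrate)
  p <- parse_fa_name(reactions$product)
  dc <- p$carbons - s$carbons
  db <- p$double_bonds - s$double_bonds
  expect <- list(elongation = c(2L, 0L), chain_shortening = c(-2L, 0L),
                 desaturation = c(0L, 1L))
  bad_kind <- !reactions$kind %in% names(expect)
  if (any(bad_kind)) {
    stop("unknown reaction kind(s): ",
         paste(unique(reactions$kind[bad_kind]), collapse = ", "),
         call. = FALSE)
  }
  exp_mat <- do.call(rbind, expect[reactions$kind])
  bad <- dc != exp_mat[, 1L] | db != exp_mat[, 2L]
  series_ok <- s$series == p$series |
    (reactions$kind == "desaturation" & s$double_bonds == 0L &
       p$series %in% c("n-7", "n-9"))
  if (any(bad | !series_ok)) {
    i <- which(bad | !series_ok)[1L]
    stop("invalid ", reactions$kind[i], ": ", reactions$substrate[i],
         " -> ", reactions$product[i], call. = FALSE)
  }
  reactions$delta_carbons <- dc
  reactions$delta_db <- db
  reactions
}

#' Assemble the FA reaction network over measured FAs
#'
#' Builds a directed network whose nodes are all FAs of the reaction table
#' plus any measured FAs absent from it (isolated, with a warning). Direct
#' edges connect pairs of measured FAs related by a single reaction.
#' Where a reaction chain passes through unmeasured intermediates, the
#' maximal unmeasured stretch is contracted into a single *effective* edge
#' between its measured endpoints (e.g. 22:5n-3 to 22:6n-3 via the
#' unmeasured 24:5n-3 and 24:6n-3), flagged `effective = TRUE` and
#' carrying the summed carbon/double-bond deltas and the concatenated
#' reaction kinds of the contracted chain.
#'
#' @param measured Character vector of measured FA labels. DMA variables
#'   and derived sums/ratios do not take part in the network; labels that
#'   do not parse as acyl chains are dropped with a warning.
#' @param reactions Reaction table, default [reaction_table()].
#' @return An object of class `fa_network`: a list with `nodes`
#'   (`label`, `carbons`, `double_bonds`, `series`, `measured`) and
#'   `edges` (`from`, `to`, `kind`, `effective`, `delta_carbons`,
#'   `delta_db`) tibbles.
#' @export
build_network <- function(measured, reactions = reaction_table()) {
  reactions <- validate_reaction_table(reactions)
  measured <- unique(measured)
  parseable <- is_fa_label(measured)
  if (any(!parseable)) {
    measured <- measured[parseable]
  }
  if (length(measured)) {
    dma <- parse_fa_name(measured)$is_dma
    measured <- measured[!dma]
  }
  labels <- unique(c(reactions$substrate, reactions$product))
  extra <- setdiff(measured, labels)
  if (length(extra)) {
    warning("measured FA(s) absent from the reaction table kept as ",
            "isolated node(s): ", paste(sQuote(extra), collapse = ", "),
            call. = FALSE)
  }
  all_labels <- c(labels, extra)
  parsed <- parse_fa_name(all_labels)
  nodes <- tibble::tibble(
    label = all_labels,
    carbons = parsed$carbons,
    double_bonds = parsed$double_bonds,
    series = parsed$series,
    measured = all_labels %in% measured
  )
  is_meas <- stats::setNames(nodes$measured, nodes$label)
  direct <- reactions |>
    dplyr::filter(is_meas[.data$substrate] & is_meas[.data$product]) |>
    dplyr::transmute(from = .data$substrate, to = .data$product,
                     kind = .data$kind, effective = FALSE,
                     delta_carbons = .data$delta_carbons,
                     delta_db = .data$delta_db)
  # adjacency for path contraction
  succ <- split(seq_len(nrow(reactions)), reactions$substrate)
  effective <- list()
  walk <- function(start, at, kinds, dc, db) {
    for (i in succ[[at]] %||% integer(0)) {
      nxt <- reactions$product[i]
      k <- c(kinds, reactions$kind[i])
      dc2 <- dc + reactions$delta_carbons[i]
      db2 <- db + reactions$delta_db[i]
      if (is_meas[nxt]) {
        if (length(k) > 1L) {
          effective[[length(effective) + 1L]] <<- tibble::tibble(
            from = start, to = nxt, kind = paste(k, collapse = "+"),
            effective = TRUE, delta_carbons = dc2, delta_db = db2
          )
        }
      } else {
        walk(start, nxt, k, dc2, db2)
      }
    }
  }
  for (s in nodes$label[nodes$measured]) {
    walk(s, s, character(0), 0L, 0L)
  }
  edges <- dplyr::bind_rows(direct, effective)
  structure(list(nodes = nodes, edges = edges), class = "fa_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fa_network <- function(x, ...) {
  cat("FA reaction network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$measured), "measured ),", nrow(x$edges), "edges (",
      sum(x$edges$effective), "effective )\n")
  invisible(x)
}

#' Within-diagnosis correlation significance of network edges
#'
#' For every network edge whose endpoints are both present in the profile
#' table, computes the Pearson correlation between substrate and product
#' mol-% values separately within each diagnosis group, and classifies the
#' edge by which diagnoses show a significant correlation at level
#' `alpha`: `sig_both`, `sig_<level>_only`, or `sig_neither`. A
#' significant within-diagnosis correlation is read as the reaction being
#' a candidate dominant route of product biosynthesis in that diagnosis.
#'
#' @param network An `fa_network` from [build_network()].
#' @param profiles Profile tibble of mol-% values with a two-level
#'   `diagnosis` column (at least 3 samples per level).
#' @param alpha Per-edge significance threshold (default 0.05; no
#'   multiplicity correction over edges).
#' @return The edge tibble augmented with `r_<level>`, `p_<level>` for
#'   both levels and `class`.
#' @export
annotate_edges <- function(network, profiles, alpha = 0.05) {
  stopifnot(inherits(network, "fa_network"))
  profiles <- tibble::as_tibble(profiles)
  d <- as.character(profiles$diagnosis)
  lev <- sort(unique(d))
  if (length(lev) != 2L) stop("need exactly two diagnosis levels",
                              call. = FALSE)
  if (any(table(d) < 3L)) {
    stop("each diagnosis needs at least 3 samples", call. = FALSE)
  }
  edges <- network$edges
  have <- edges$from %in% names(profiles) & edges$to %in% names(profiles)
  if (any(!have)) {
    warning(sum(!have), " edge(s) skipped: endpoint not in the profile ",
            "table", call. = FALSE)
    edges <- edges[have, , drop = FALSE]
  }
  ann <- purrr::map_dfr(seq_len(nrow(edges)), function(i) {
    out <- list()
    for (lv in lev) {
      x <- profiles[[edges$from[i]]][d == lv]
      y <- profiles[[edges$to[i]]][d == lv]
      ct <- stats::cor.test(x, y, method = "pearson")
      out[[paste0("r_", lv)]] <- unname(ct$estimate)
      out[[paste0("p_", lv)]] <- ct$p.value
    }
    tibble::as_tibble(out)
  })
  sig1 <- ann[[paste0("p_", lev[1])]] <= alpha
  sig2 <- ann[[paste0("p_", lev[2])]] <= alpha
  cls <- dplyr::case_when(
    sig1 & sig2 ~ "sig_both",
    sig1 & !sig2 ~ paste0("sig_", lev[1], "_only"),
    !sig1 & sig2 ~ paste0("sig_", lev[2], "_only"),
    TRUE ~ "sig_neither"
  )
  dplyr::bind_cols(edges, ann, tibble::tibble(class = cls))
}

#' Export the annotated reaction network
#'
#' Writes the network as GraphML and DOT (node attributes: carbons, double
#' bonds, measured flag, level-change score; edge attributes: reaction
#' kind, effective flag, significance class and within-diagnosis r/p) plus
#' a TSV edge table.
#'
#' @param network An `fa_network`.
#' @param annotations Optional annotated edge tibble from
#'   [annotate_edges()]; must cover the network's edges.
#' @param level_changes Optional tibble from [level_change()].
#' @param path_prefix Output path prefix; writes
#'   `<prefix>.graphml`, `<prefix>.dot` and `<prefix>_edges.tsv`.
#' @return Invisibly, the named vector of written file paths.
#' @export
export_network <- function(network, annotations = NULL,
                           level_changes = NULL, path_prefix) {
  stopifnot(inherits(network, "fa_network"))
  nodes <- network$nodes
  edges <- if (is.null(annotations)) network$edges else annotations
  if (!is.null(annotations)) {
    key <- function(e) paste(e$from, e$to)
    if (!all(key(network$edges) %in% key(annotations)) &&
        nrow(network$edges) > 0 && nrow(annotations) < nrow(network$edges)) {
      warning("annotations do not cover every network edge", call. = FALSE)
    }
  }
  if (!is.null(level_changes)) {
    nodes <- dplyr::left_join(nodes, level_changes[c("variable", "level_change")],
                              by = c("label" = "variable"))
  } else {
    nodes$level_change <- NA_real_
  }
  nodes$level_change[is.na(nodes$level_change)] <- NaN
  nodes$measured <- as.integer(nodes$measured)
  gedges <- edges
  if (nrow(gedges)) gedges$effective <- as.integer(gedges$effective)
  g <- igraph::graph_from_data_frame(
    d = gedges,
    directed = TRUE,
    vertices = dplyr::rename(nodes, name = "label")
  )
  paths <- c(graphml = paste0(path_prefix, ".graphml"),
             dot = paste0(path_prefix, ".dot"),
             edges = paste0(path_prefix, "_edges.tsv"))
  igraph::write_graph(g, paths["graphml"], format = "graphml")
  igraph::write_graph(g, paths["dot"], format = "dot")
  readr::write_tsv(edges, paths["edges"])
  invisible(paths)
}

#' Plot the annotated reaction network
#'
#' A ggplot rendering of the reaction network: node size proportional to
#' chain length, node color the level-change score, solid/dashed edges for
#' direct/effective reactions and line width encoding the significance
#' class.
#'
#' @inheritParams export_network
#' @return A ggplot object.
#' @export
plot_network <- function(network, annotations = NULL, level_changes = NULL) {
  nodes <- network$nodes
  edges <- if (is.null(annotations)) network$edges else annotations
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = dplyr::rename(nodes, name = "label")
  )
  set.seed(42)  # layout only
  xy <- igraph::layout_with_fr(g)
  nd <- dplyr::mutate(nodes, x = xy[, 1], y = xy[, 2])
  if (!is.null(level_changes)) {
    nd <- dplyr::left_join(nd, level_changes[c("variable", "level_change")],
                           by = c("label" = "variable"))
  } else {
    nd$level_change <- NA_real_
  }
  ed <- dplyr::left_join(edges, nd[c("label", "x", "y")],
                         by = c("from" = "label")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(nd[c("label", "x", "y")], by = c("to" = "label"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y, linetype = .data$effective),
      color = "grey40",
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::geom_point(
      data = nd,
      ggplot2::aes(.data$x, .data$y, size = .data$carbons,
                   color = .data$level_change,
                   shape = .data$measured)
    ) +
    ggplot2::geom_text(
      data = nd, ggplot2::aes(.data$x, .data$y, label = .data$label),
      vjust = -1, size = 3
    ) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::scale_color_gradient2(low = "blue", mid = "grey80",
                                   high = "red", midpoint = 0) +
    ggplot2::theme_void()
  p
}
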