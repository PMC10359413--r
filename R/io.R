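#' Read a FA profile table
#'
#' Reads TSV, CSV or XLSX profile tables in either orientation:
#' `samples_in_rows` (canonical: one row per sample, metadata columns
#' `sample_id`, `diagnosis`, optional `tissue`, then variable columns) or
#' `variables_in_rows` (the supplementary-spreadsheet layout: first column
#' holds variable labels, remaining columns one sample each, with
#' metadata rows labeled `diagnosis` / `tissue`).
#'
#' @param path Input file; the format is chosen by extension
#'   (`.tsv`/`.txt`, `.csv`, `.xlsx`). XLSX requires the readxl package.
#' @param orientation Table layout, see above.
#' @param tolerance,renormalize Passed to [validate_profiles()].
#' @return A validated profile tibble.
#' @export
read_profile_table <- function(path,
                               orientation = c("samples_in_rows",
                                               "variables_in_rows"),
                               tolerance = 0.5, renormalize = FALSE) {
  orientation <- match.arg(orientation)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tsv = , txt = readr::read_tsv(path, col_types = readr::cols(),
                                  show_col_types = FALSE),
    csv = readr::read_csv(path, col_types = readr::cols(),
                          show_col_types = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading .xlsx requires the readxl package", call. = FALSE)
      }
      readxl::read_excel(path)
    },
    stop("unsupported file extension: ", ext, call. = FALSE)
  )
  if (orientation == "variables_in_rows") {
    labels <- as.character(raw[[1L]])
    samples <- names(raw)[-1L]
    meta_rows <- tolower(labels) %in% c("diagnosis", "tissue")
    meta <- tibble::tibble(sample_id = samples)
    for (i in which(meta_rows)) {
      meta[[tolower(labels[i])]] <- as.character(unlist(raw[i, -1L]))
    }
    body <- raw[!meta_rows, , drop = FALSE]
    vals <- purrr::map(seq_len(nrow(body)), function(i) {
      v <- unlist(body[i, -1L])
      num <- suppressWarnings(as.numeric(v))
      if (anyNA(num) & !anyNA(v)) {
        stop("non-numeric cell(s) in variable row ", sQuote(labels[!meta_rows][i]),
             call. = FALSE)
      }
      num
    })
    names(vals) <- labels[!meta_rows]
    raw <- dplyr::bind_cols(meta, tibble::as_tibble(vals))
  }
  if (!"diagnosis" %in% names(raw)) {
    stop("no 'diagnosis' metadata found in ", path, call. = FALSE)
  }
  if (any(is.na(raw$diagnosis) | !nzchar(as.character(raw$diagnosis)))) {
    stop("missing diagnosis label(s)", call. = FALSE)
  }
  vars <- setdiff(names(raw), c("sample_id", "diagnosis", "tissue"))
  for (v in vars) {
    if (!is.numeric(raw[[v]])) {
      num <- suppressWarnings(as.numeric(raw[[v]]))
      bad <- which(is.na(num) & !is.na(raw[[v]]))
      if (length(bad)) {
        stop("non-numeric cell(s) in column ", sQuote(v), ", row(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      raw[[v]] <- num
    }
  }
  validate_profiles(raw, tolerance = tolerance, renormalize = renormalize)
}

#' Write a profile table as TSV
#'
#' Sample-major TSV is the canonical interchange format (diff-able and
#' version-controllable); [read_profile_table()] of the written file is
#' the identity.
#'
#' @param profiles Profile tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profiles, path) {
  readr::write_tsv(tibble::as_tibble(profiles), path)
  invisible(path)
}

#' Run the full FA-signature pipeline
#'
#' Executes the analysis end to end: per-FA group statistics, derived
#' variables (optional), Z-score normalization, correlation matrix and
#' hierarchical grouping, group-sampling enrichment with repeated
#' random-forest classification, a full-variable (no-enrichment) forest
#' run, linear discriminant analysis with leave-one-out accuracy,
#' level-change scores and the annotated reaction network. All randomness
#' flows from `seed`; two runs with identical inputs and seed produce
#' identical results.
#'
#' @param profiles Profile tibble of mol-% values.
#' @param seed Integer seed.
#' @param k Number of FA groups to cut (default 5).
#' @param derive Append derived sums/ratios/indices before analysis
#'   (default TRUE; requires recipe FAs to be present unless
#'   `missing_as_zero`).
#' @param missing_as_zero Passed to [compute_derived()].
#' @param enrichment Run the enriched forest (default TRUE). With
#'   `FALSE`, only the full-variable run is performed and the importance
#'   table has one row per variable rather than per group.
#' @param exclude_derived Drop sum/ratio/index columns from the forest
#'   features (robustness variant).
#' @param iterations Enrichment iterations B (default 1000).
#' @param repeats Forests per run (default 100).
#' @param ref,alt Reference/alternative diagnosis for level changes
#'   (defaults `"OA"`/`"RA"`; ignored if absent from the data).
#' @param alpha Significance level used throughout (default 0.05).
#' @param out_dir Optional output directory; when given, all tables, the
#'   GraphML/DOT network and a JSON run manifest are written there.
#' @return A list of class `fa_pipeline` with components `stats`, `z`,
#'   `correlations`, `dendrogram`, `groups`, `rf_enriched` (or NULL),
#'   `rf_full`, `importance`, `lda`, `loo_accuracy`, `level_changes`,
#'   `network`, `edges`, `params`.
#' @export
run_pipeline <- function(profiles, seed = 1, k = 5, derive = TRUE,
                         missing_as_zero = TRUE, enrichment = TRUE,
                         exclude_derived = FALSE, iterations = 1000,
                         repeats = 100, ref = "OA", alt = "RA",
                         alpha = 0.05, out_dir = NULL) {
  profiles <- validate_profiles(profiles)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  with_derived <- if (derive) {
    stage("derive", compute_derived(profiles, missing_as_zero = missing_as_zero))
  } else {
    profiles
  }
  stats_tbl <- stage("stats", compare_groups(with_derived, alpha = alpha))
  z <- stage("zscore", zscore_profiles(with_derived))
  corr <- stage("correlate", correlation_matrix(z))
  hc <- stage("cluster", cluster_profiles(z))
  groups <- stage("group", assign_groups(hc, k = k))

  feat_z <- z
  if (exclude_derived) {
    vars <- profile_variables(z)
    keep <- vars[variable_kind(vars) == "raw_fa"]
    feat_z <- z[c(profile_meta_cols(z), keep)]
    groups_used <- dplyr::filter(groups, .data$variable %in% keep)
  } else {
    groups_used <- groups
  }

  rf_enriched <- NULL
  if (enrichment) {
    enriched <- stage("enrich",
                      enrich(feat_z, groups_used, iterations = iterations,
                             seed = seed))
    rf_enriched <- stage("rf_enriched",
                         train_rf(enriched, repeats = repeats,
                                  seed = seed + 1L))
  }
  rf_full <- stage("rf_full",
                   train_rf(feat_z, repeats = repeats, seed = seed + 2L))
  importance <- if (enrichment) {
    importance_by_group(rf_enriched, groups_used)
  } else {
    importance_by_group(rf_full, groups_used)$by_variable
  }

  lda_fit <- stage("lda", fit_lda(profiles))
  loo <- stage("loo", loo_accuracy(profiles))

  lc <- NULL; network <- NULL; edges <- NULL
  if (all(c(ref, alt) %in% profiles$diagnosis)) {
    lc <- stage("level_change", level_change(profiles, ref = ref, alt = alt))
    vars <- profile_variables(profiles)
    measured <- vars[variable_kind(vars) == "raw_fa"]
    network <- stage("network", suppressWarnings(build_network(measured)))
    edges <- stage("annotate",
                   suppressWarnings(annotate_edges(network, profiles,
                                                   alpha = alpha)))
  }

  result <- structure(
    list(stats = stats_tbl, z = z, correlations = corr, dendrogram = hc,
         groups = groups, rf_enriched = rf_enriched, rf_full = rf_full,
         importance = importance, lda = lda_fit, loo_accuracy = loo,
         level_changes = lc, network = network, edges = edges,
         params = list(seed = seed, k = k, derive = derive,
                       enrichment = enrichment,
                       exclude_derived = exclude_derived,
                       iterations = iterations, repeats = repeats,
                       alpha = alpha)),
    class = "fa_pipeline"
  )
  if (!is.null(out_dir)) {
    write_pipeline(result, out_dir, profiles)
  }
  result
}

#' @export
print.fa_pipeline <- function(x, ...) {
  cat("FA-signature pipeline result\n")
  cat(sprintf("  %d variables tested; %d significant at alpha = %g\n",
              nrow(x$stats), sum(x$stats$significant), x$params$alpha))
  if (!is.null(x$rf_enriched)) {
    cat(sprintf("  enriched RF accuracy:  %.3f\n",
                x$rf_enriched$mean_accuracy))
  }
  cat(sprintf("  full-data RF accuracy: %.3f\n", x$rf_full$mean_accuracy))
  cat(sprintf("  LDA: %d function(s), %.1f%% variance on function 1; LOO accuracy %.3f\n",
              x$lda$n_functions, x$lda$pct_variance[1L], x$loo_accuracy))
  if (!is.null(x$edges)) {
    cat(sprintf("  network: %d annotated edges (%s)\n", nrow(x$edges),
                paste(names(table(x$edges$class)),
                      table(x$edges$class), sep = "=", collapse = ", ")))
  }
  invisible(x)
}

# write every pipeline output plus a run manifest
write_pipeline <- function(result, out_dir, profiles) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(name) file.path(out_dir, name)
  readr::write_tsv(result$stats, f("stats.tsv"))
  readr::write_tsv(result$z, f("zscores.tsv"))
  readr::write_tsv(result$groups, f("groups.tsv"))
  acc <- tibble::tibble(
    run = c(if (!is.null(result$rf_enriched)) "enriched", "full"),
    mean_accuracy = c(if (!is.null(result$rf_enriched))
      result$rf_enriched$mean_accuracy, result$rf_full$mean_accuracy)
  )
  readr::write_tsv(acc, f("rf_accuracy.tsv"))
  imp <- result$importance
  if (is.data.frame(imp)) readr::write_tsv(imp, f("rf_importance.tsv"))
  readr::write_tsv(augment(result$lda), f("lda_scores.tsv"))
  if (!is.null(result$level_changes)) {
    readr::write_tsv(result$level_changes, f("level_change.tsv"))
    export_network(result$network, result$edges, result$level_changes,
                   f("network"))
  }
  manifest <- list(
    command = "run_pipeline",
    package_version = as.character(utils::packageVersion("fasig")),
    seed = result$params$seed,
    params = result$params[setdiff(names(result$params), "seed")],
    input = list(
      n_samples = nrow(profiles),
      n_variables = length(profile_variables(profiles)),
      md5 = .hash_object(profiles)
    ),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}

# md5 of a serialized object via a temp file (content hash for manifests)
.hash_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2)
  unname(tools::md5sum(tmp))
}
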