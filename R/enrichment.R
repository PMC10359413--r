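#' Random-forest parameter block
#'
#' The forest configuration used throughout: 100 trees, depth cap 16,
#' minimum node size 1, 5 candidate features per split, bootstrap
#' resampling with replacement at full sample size, Gini impurity as the
#' split criterion, and normalized impurity-based feature importance. The
#' 5-feature `mtry` is kept also for full-variable runs (where it is far
#' below the feature count), so enriched and full runs share one
#' configuration.
#'
#' @param num_trees,max_depth,min_node_size,mtry,replace,sample_fraction
#'   Overrides for individual fields.
#' @return A named list.
#' @export
rf_params <- function(num_trees = 100, max_depth = 16, min_node_size = 1,
                      mtry = 5, replace = TRUE, sample_fraction = 1) {
  list(num_trees = num_trees, max_depth = max_depth,
       min_node_size = min_node_size, mtry = mtry, replace = replace,
       sample_fraction = sample_fraction, splitrule = "gini",
       importance = "impurity")
}

#' Group-sampling data enrichment
#'
#' Expands an n-sample Z-score table into a `B * n`-row dataset with one
#' feature slot per FA group: at each of the `B` iterations, one variable
#' is drawn uniformly (with replacement across iterations) from every
#' group, and all n samples are emitted with the K drawn Z-values and their
#' copied diagnosis labels. With the study-shaped 16 samples and B = 1000
#' this yields 16,000 rows of 5 features.
#'
#' @param z Z-score tibble (metadata columns plus variable columns).
#' @param groups Group assignment tibble (`variable`, `group`) from
#'   [assign_groups()]; every group must be non-empty and every listed
#'   variable present in `z`.
#' @param iterations Number of sampling iterations B (default 1000).
#' @param seed Integer seed for the draws.
#' @return A tibble with `B * n` rows: `iteration`, `sample_id`,
#'   `diagnosis`, and one `group_<k>` column per group. The per-iteration
#'   draws are recorded in the `"provenance"` attribute, a tibble of
#'   (`iteration`, `group`, `variable`).
#' @export
enrich <- function(z, groups, iterations = 1000, seed = 1) {
  z <- tibble::as_tibble(z)
  groups <- tibble::as_tibble(groups)
  stopifnot(iterations >= 1)
  absent <- setdiff(groups$variable, names(z))
  if (length(absent)) {
    stop("group assignment names variable(s) absent from the data: ",
         paste(sQuote(absent), collapse = ", "), call. = FALSE)
  }
  gids <- sort(unique(groups$group))
  members <- lapply(gids, function(g) groups$variable[groups$group == g])
  if (any(lengths(members) == 0L)) stop("empty FA group", call. = FALSE)

  n <- nrow(z)
  K <- length(gids)
  set.seed(seed)
  # picks[b, k]: variable representing group k at iteration b
  picks <- matrix("", iterations, K)
  for (k in seq_len(K)) {
    picks[, k] <- sample(members[[k]], iterations, replace = TRUE)
  }
  M <- as.matrix(z[unique(groups$variable)])
  blocks <- lapply(seq_len(iterations), function(b) M[, picks[b, ], drop = FALSE])
  values <- do.call(rbind, blocks)
  colnames(values) <- paste0("group_", gids)
  out <- tibble::tibble(
    iteration = rep(seq_len(iterations), each = n),
    sample_id = rep(z$sample_id, iterations),
    diagnosis = rep(z$diagnosis, iterations)
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(values))
  attr(out, "provenance") <- tibble::tibble(
    iteration = rep(seq_len(iterations), times = K),
    group = rep(gids, each = iterations),
    variable = as.vector(picks)
  )
  out
}

# stratified train/test split; returns logical train mask
.stratified_split <- function(labels, train_fraction, max_retries = 10L) {
  n <- length(labels)
  for (i in seq_len(max_retries)) {
    train <- logical(n)
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      k <- max(1L, round(train_fraction * length(idx)))
      k <- min(k, length(idx) - 1L)  # keep test rows in every class
      train[sample(idx, k)] <- TRUE
    }
    if (length(unique(labels[train])) == length(unique(labels)) &&
        any(!train)) {
      return(train)
    }
  }
  stop("could not draw a split with all classes in training", call. = FALSE)
}

#' Repeated random-forest classification
#'
#' Fits `repeats` random forests, each on a fresh stratified train/test
#' split, and records the test accuracy and normalized impurity-based
#' feature importances (estimated on training data only) of every repeat.
#' The returned object carries per-repeat values and their means; use
#' [generics::tidy()] for the importance table and [generics::glance()]
#' for run-level summaries.
#'
#' @param data A tibble with a label column and numeric feature columns
#'   (e.g. the output of [enrich()], or a Z-score table for the
#'   no-enrichment run). Columns `iteration` and `sample_id` are treated as
#'   bookkeeping and excluded from the features.
#' @param label Name of the class column, default `"diagnosis"`.
#' @param repeats Number of forests (default 100).
#' @param train_fraction Fraction of rows in each training split (0.8).
#' @param params Forest configuration from [rf_params()]; `mtry` is capped
#'   at the number of features.
#' @param seed Integer seed; fans out to one sub-seed per repeat, so runs
#'   are reproducible and repeats independent.
#' @return An object of class `rf_run`.
#' @export
train_rf <- function(data, label = "diagnosis", repeats = 100,
                     train_fraction = 0.8, params = rf_params(), seed = 1) {
  data <- tibble::as_tibble(data)
  stopifnot(train_fraction > 0, train_fraction < 1, repeats >= 1)
  features <- setdiff(names(data), c(label, "iteration", "sample_id", "tissue"))
  X <- as.matrix(data[features])
  y <- factor(data[[label]])
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  mtry <- min(params$mtry, ncol(X))

  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, repeats)
  acc <- numeric(repeats)
  imp <- matrix(NA_real_, repeats, ncol(X),
                dimnames = list(NULL, features))
  for (r in seq_len(repeats)) {
    set.seed(sub_seeds[r])
    train <- .stratified_split(y, train_fraction)
    fit <- ranger::ranger(
      x = X[train, , drop = FALSE], y = y[train],
      num.trees = params$num_trees, mtry = mtry,
      max.depth = params$max_depth, min.node.size = params$min_node_size,
      splitrule = params$splitrule, replace = params$replace,
      sample.fraction = params$sample_fraction,
      importance = params$importance,
      num.threads = 1, seed = sub_seeds[r]
    )
    pred <- stats::predict(fit, X[!train, , drop = FALSE],
                           num.threads = 1)$predictions
    acc[r] <- mean(pred == y[!train])
    vi <- fit$variable.importance
    imp[r, ] <- if (sum(vi) > 0) vi / sum(vi) else rep(1 / length(vi), length(vi))
  }
  structure(
    list(
      accuracy = acc,
      mean_accuracy = mean(acc),
      importance = imp,
      mean_importance = colMeans(imp),
      params = params, mtry = mtry, label = label,
      classes = levels(y), n = nrow(X), n_features = ncol(X),
      features = features, repeats = repeats,
      seed = seed, sub_seeds = sub_seeds
    ),
    class = "rf_run"
  )
}

#' @export
print.rf_run <- function(x, ...) {
  cat("Repeated random-forest classification\n")
  cat(sprintf("  %d repeats, %d rows, %d features (%s)\n",
              x$repeats, x$n, x$n_features,
              paste(x$classes, collapse = " vs ")))
  cat(sprintf("  mean test accuracy: %.4f\n", x$mean_accuracy))
  top <- sort(x$mean_importance, decreasing = TRUE)
  cat("  top features by mean importance:\n")
  for (i in seq_len(min(5, length(top)))) {
    cat(sprintf("    %-28s %.4f\n", names(top)[i], top[i]))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @rdname train_rf
#' @param x An `rf_run` object.
#' @param ... Unused.
#' @method tidy rf_run
#' @export
tidy.rf_run <- function(x, ...) {
  tibble::tibble(
    feature = x$features,
    mean_importance = unname(x$mean_importance),
    sd_importance = apply(x$importance, 2, stats::sd),
    rank = unname(rank(-x$mean_importance, ties.method = "min"))
  ) |>
    dplyr::arrange(.data$rank)
}

#' @rdname train_rf
#' @method glance rf_run
#' @export
glance.rf_run <- function(x, ...) {
  tibble::tibble(
    mean_accuracy = x$mean_accuracy,
    sd_accuracy = stats::sd(x$accuracy),
    repeats = x$repeats,
    n = x$n,
    n_features = x$n_features,
    num_trees = x$params$num_trees,
    mtry = x$mtry
  )
}

#' Feature importance by FA group and by variable
#'
#' For an enriched run (features are group slots), returns one importance
#' score per group. For a full-variable run, returns per-variable scores
#' joined with their group and kind, plus group-level sums, and a variant
#' restricted to raw FA columns (sums/ratios/indices excluded,
#' renormalized) as a robustness view, since impurity importance spreads
#' over correlated features.
#'
#' @param run An `rf_run` object.
#' @param groups Group assignment tibble; required for full-variable runs,
#'   optional for enriched runs.
#' @return For enriched runs, a tibble (`group`, `importance`, `rank`).
#'   Otherwise a list with `by_variable`, `by_group` and `raw_only`
#'   tibbles.
#' @export
importance_by_group <- function(run, groups = NULL) {
  stopifnot(inherits(run, "rf_run"))
  feats <- run$features
  if (all(grepl("^group_", feats))) {
    gid <- as.integer(sub("^group_", "", feats))
    if (!is.null(groups) && !all(gid %in% groups$group)) {
      stop("group ids in the run do not match the assignment", call. = FALSE)
    }
    return(tibble::tibble(
      group = gid,
      importance = unname(run$mean_importance),
      rank = rank(-run$mean_importance, ties.method = "min")
    ) |> dplyr::arrange(.data$rank))
  }
  if (is.null(groups)) {
    stop("a group assignment is required for full-variable runs",
         call. = FALSE)
  }
  groups <- tibble::as_tibble(groups)
  unknown <- setdiff(feats, groups$variable)
  if (length(unknown)) {
    stop("run features missing from the group assignment: ",
         paste(sQuote(unknown), collapse = ", "), call. = FALSE)
  }
  by_var <- tibble::tibble(
    variable = feats,
    importance = unname(run$mean_importance),
    kind = variable_kind(feats)
  ) |>
    dplyr::left_join(groups, by = "variable") |>
    dplyr::arrange(dplyr::desc(.data$importance))
  by_group <- by_var |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(importance = sum(.data$importance), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$importance))
  raw_only <- by_var |>
    dplyr::filter(.data$kind == "raw_fa") |>
    dplyr::mutate(importance = .data$importance / sum(.data$importance))
  list(by_variable = by_var, by_group = by_group, raw_only = raw_only)
}
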