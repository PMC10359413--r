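#' @importFrom rlang .data
NULL

# metadata columns recognized in a profile table
.meta_cols <- c("sample_id", "diagnosis", "tissue")

#' Metadata and variable columns of a profile table
#'
#' A profile table is an ordinary tibble with one row per sample: the
#' metadata columns `sample_id`, `diagnosis` and (optionally) `tissue`,
#' followed by one numeric column per measured FA or derived variable.
#'
#' @param profiles A profile tibble.
#' @return `profile_meta_cols()` returns the metadata column names present;
#'   `profile_variables()` the variable column names.
#' @export
profile_variables <- function(profiles) {
  setdiff(names(profiles), .meta_cols)
}

#' @rdname profile_variables
#' @export
profile_meta_cols <- function(profiles) {
  intersect(.meta_cols, names(profiles))
}

#' Classify profile columns as raw FAs or derived variables
#'
#' Raw FA columns are those whose label parses under the chain nomenclature
#' (see [parse_fa_name()]); remaining columns are tagged by their label as a
#' `sum`, `ratio` or `index` (anything else is `unknown`).
#'
#' @param labels Character vector of variable labels.
#' @return Character vector of kinds: `raw_fa`, `sum`, `ratio`, `index` or
#'   `unknown`.
#' @export
variable_kind <- function(labels) {
  kind <- rep("unknown", length(labels))
  kind[is_fa_label(labels)] <- "raw_fa"
  kind[grepl("sum$", labels) & kind == "unknown"] <- "sum"
  kind[grepl("ratio|product/precursor", labels) & kind == "unknown"] <- "ratio"
  kind[grepl("index|chain length", labels) & kind == "unknown"] <- "index"
  kind
}

#' Validate a FA profile table
#'
#' Checks the structural invariants of a mol-% profile table: metadata
#' columns present, numeric variable columns, unique sample IDs, unique
#' variable labels, non-negative raw mol-% values, and per-sample closure
#' (raw FA columns summing to 100 within `tolerance`).
#'
#' @param profiles Profile tibble (samples in rows).
#' @param tolerance Allowed deviation of each per-sample raw mol-% sum from
#'   100 (default 0.5, accommodating published tables rounded to two
#'   decimals). Violations raise a warning listing the offending samples.
#' @param renormalize If `TRUE`, rescale each sample's raw FA columns to sum
#'   to exactly 100.
#' @return The (possibly renormalized) profile tibble, invisibly classed as
#'   a plain tibble.
#' @export
validate_profiles <- function(profiles, tolerance = 0.5, renormalize = FALSE) {
  stopifnot(is.data.frame(profiles))
  profiles <- tibble::as_tibble(profiles)
  if (!all(c("sample_id", "diagnosis") %in% names(profiles))) {
    stop("profile table must have 'sample_id' and 'diagnosis' columns",
         call. = FALSE)
  }
  if (anyDuplicated(profiles$sample_id)) {
    stop("duplicated sample IDs: ",
         paste(unique(profiles$sample_id[duplicated(profiles$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  vars <- profile_variables(profiles)
  if (anyDuplicated(vars)) {
    stop("duplicated variable labels", call. = FALSE)
  }
  not_num <- vars[!vapply(profiles[vars], is.numeric, logical(1))]
  if (length(not_num)) {
    stop("non-numeric variable column(s): ",
         paste(sQuote(not_num), collapse = ", "), call. = FALSE)
  }
  raw <- vars[variable_kind(vars) == "raw_fa"]
  if (length(raw)) {
    M <- as.matrix(profiles[raw])
    if (any(M < 0)) {
      stop("negative mol-% values in raw FA columns", call. = FALSE)
    }
    sums <- rowSums(M)
    off <- abs(sums - 100) > tolerance
    if (any(off) && !renormalize) {
      warning("raw mol-% does not sum to 100 (+/- ", tolerance,
              ") for sample(s): ",
              paste(profiles$sample_id[off], collapse = ", "), call. = FALSE)
    }
    if (renormalize) {
      profiles[raw] <- as.data.frame(100 * M / sums)
    }
  }
  profiles
}

# ---- derived-variable recipes ------------------------------------------

#' Default derived-variable recipe set
#'
#' Declarative recipes for the FA sums, ratios and indices appended by
#' [compute_derived()]. Each recipe is a list with a `name`, a `type`
#' (`"sum"`, `"ratio"` or `"index"`), and selectors over the parsed chain
#' fields. Selector fields: `is_dma` (logical), `series` (character vector),
#' `min_db`/`max_db` and `min_carbons`/`max_carbons` (integers), `labels`
#' (explicit label set). Ratios take `numerator`/`denominator` selectors;
#' indices take a `weight` field (`"double_bonds"` or `"carbons"`) and
#' compute `sum(mol% * weight) / 100`.
#'
#' The recipe set is data, not code: it can be serialized to/loaded from
#' YAML with [read_recipe()] and freely overridden.
#'
#' @return A named list of recipes.
#' @export
fa_recipe <- function() {
  list(
    list(name = "SFA sum", type = "sum",
         select = list(is_dma = FALSE, max_db = 0)),
    list(name = "MUFA sum", type = "sum",
         select = list(is_dma = FALSE, min_db = 1, max_db = 1)),
    list(name = "PUFA sum", type = "sum",
         select = list(is_dma = FALSE, min_db = 2)),
    list(name = "n-3 PUFA sum", type = "sum",
         select = list(series = "n-3", min_db = 2)),
    list(name = "n-6 PUFA sum", type = "sum",
         select = list(series = "n-6", min_db = 2)),
    list(name = "DMA sum", type = "sum",
         select = list(is_dma = TRUE)),
    list(name = "C20-24 SFA sum", type = "sum",
         select = list(is_dma = FALSE, max_db = 0,
                       min_carbons = 20, max_carbons = 24)),
    list(name = "n-3/n-6 ratio", type = "ratio",
         numerator = list(series = "n-3", min_db = 2),
         denominator = list(series = "n-6", min_db = 2)),
    list(name = "n-6 product/precursor ratio", type = "ratio",
         numerator = list(series = "n-6", min_db = 2,
                          min_carbons = 20, max_carbons = 22),
         denominator = list(labels = "18:2n-6")),
    list(name = "n-3 product/precursor ratio", type = "ratio",
         numerator = list(series = "n-3", min_db = 2,
                          min_carbons = 20, max_carbons = 22),
         denominator = list(labels = "18:3n-3")),
    list(name = "double bond index", type = "index", weight = "double_bonds"),
    list(name = "average chain length", type = "index", weight = "carbons")
  )
}

#' Read a derived-variable recipe set from YAML
#'
#' @param path Path to a YAML file with the same structure as [fa_recipe()].
#' @return A recipe list.
#' @export
read_recipe <- function(path) {
  yaml::read_yaml(path)
}

# logical mask of parsed FAs matched by a selector
match_selector <- function(parsed, sel) {
  keep <- rep(TRUE, nrow(parsed))
  if (!is.null(sel$labels)) keep <- keep & parsed$label %in% sel$labels
  if (!is.null(sel$is_dma)) keep <- keep & parsed$is_dma == sel$is_dma
  if (!is.null(sel$series)) keep <- keep & parsed$series %in% sel$series
  if (!is.null(sel$min_db)) keep <- keep & parsed$double_bonds >= sel$min_db
  if (!is.null(sel$max_db)) keep <- keep & parsed$double_bonds <= sel$max_db
  if (!is.null(sel$min_carbons)) keep <- keep & parsed$carbons >= sel$min_carbons
  if (!is.null(sel$max_carbons)) keep <- keep & parsed$carbons <= sel$max_carbons
  keep
}

#' Append derived FA sums, ratios and indices
#'
#' Computes class sums (SFA, MUFA, PUFA, n-3/n-6 PUFA, DMA, C20-24 SFA),
#' the n-3/n-6 ratio, product/precursor ratios, the double bond index and
#' the average chain length from the raw FA mol-% columns, and appends them
#' as new columns. Raw columns are left untouched.
#'
#' Recipes referencing FAs absent from the table raise an error listing the
#' missing labels unless `missing_as_zero = TRUE`, in which case absent FAs
#' contribute 0. A zero-valued ratio denominator yields `NA` with a warning.
#'
#' @param profiles Profile tibble with parseable raw FA columns.
#' @param recipe Recipe list, default [fa_recipe()].
#' @param missing_as_zero Treat FAs named by a recipe but absent from the
#'   table as zero instead of erroring.
#' @return The profile tibble with derived columns appended.
#' @examples
#' p <- tibble::tibble(sample_id = "s1", diagnosis = "OA",
#'                     `14:0` = 50, `18:0` = 50)
#' compute_derived(p)[["average chain length"]]  # 16
#' @export
compute_derived <- function(profiles, recipe = fa_recipe(),
                            missing_as_zero = FALSE) {
  profiles <- tibble::as_tibble(profiles)
  vars <- profile_variables(profiles)
  raw <- vars[variable_kind(vars) == "raw_fa"]
  if (!length(raw)) stop("no parseable raw FA columns found", call. = FALSE)
  parsed <- parse_fa_name(raw)
  M <- as.matrix(profiles[raw])

  # explicit labels demanded by recipes must be present unless relaxed
  wanted <- unlist(lapply(recipe, function(rc) {
    c(rc$select$labels, rc$numerator$labels, rc$denominator$labels)
  }))
  missing <- setdiff(wanted, raw)
  if (length(missing) && !missing_as_zero) {
    stop("recipe references FA(s) absent from the table: ",
         paste(sQuote(missing), collapse = ", "),
         " (set missing_as_zero = TRUE to treat them as 0)", call. = FALSE)
  }

  sel_sum <- function(sel) {
    keep <- match_selector(parsed, sel)
    if (!any(keep)) return(rep(0, nrow(M)))
    rowSums(M[, keep, drop = FALSE])
  }
  out <- profiles
  for (rc in recipe) {
    value <- switch(rc$type,
      sum = sel_sum(rc$select),
      ratio = {
        num <- sel_sum(rc$numerator)
        den <- sel_sum(rc$denominator)
        if (any(den == 0)) {
          warning("zero denominator for ", sQuote(rc$name),
                  "; reporting NA", call. = FALSE)
        }
        ifelse(den == 0, NA_real_, num / den)
      },
      index = as.vector(M %*% parsed[[rc$weight]]) / 100,
      stop("unknown recipe type: ", rc$type, call. = FALSE)
    )
    out[[rc$name]] <- value
  }
  out
}

# ---- Z-scores -----------------------------------------------------------

#' Z-score normalize profile variables
#'
#' Standardizes each variable across samples: `Z = (x - mean) / sd`, with
#' the population standard deviation (no Bessel correction) by default, so
#' that each variable has mean 0 and population SD exactly 1 over the
#' sample set used for standardization.
#'
#' @param profiles Profile tibble.
#' @param ddof Delta degrees of freedom for the SD denominator `n - ddof`;
#'   0 (population, default) or 1 (sample).
#' @return A tibble with the same shape: metadata columns unchanged,
#'   variable columns replaced by their Z-scores.
#' @export
zscore_profiles <- function(profiles, ddof = 0) {
  profiles <- tibble::as_tibble(profiles)
  vars <- profile_variables(profiles)
  n <- nrow(profiles)
  if (n < 2L) stop("need at least 2 samples to standardize", call. = FALSE)
  M <- as.matrix(profiles[vars])
  mu <- colMeans(M)
  sdv <- sqrt(colSums(sweep(M, 2, mu)^2) / (n - ddof))
  zero <- sdv <= 0 | !is.finite(sdv)
  if (any(zero)) {
    stop("zero-variance variable(s): ",
         paste(sQuote(vars[zero]), collapse = ", "), call. = FALSE)
  }
  Z <- sweep(sweep(M, 2, mu), 2, sdv, "/")
  out <- profiles
  out[vars] <- as.data.frame(Z)
  out
}

# ---- per-variable group statistics -------------------------------------

#' Per-variable two-group comparison (Mann-Whitney U)
#'
#' For each variable, compares the two diagnosis groups with the
#' Mann-Whitney U test: exact two-sided p by enumeration when both groups
#' have at most `exact_max` samples and the pooled values are tie-free;
#' otherwise the normal approximation with continuity and tie correction.
#' Means and standard errors per group are reported alongside, with a
#' Benjamini-Hochberg adjusted column for reference (significance flags use
#' the unadjusted p, mirroring per-FA testing practice in this field).
#'
#' @param profiles Profile tibble.
#' @param by Grouping metadata column, default `"diagnosis"`; must have
#'   exactly two levels, each with at least 2 samples.
#' @param alpha Significance level for the flag column (default 0.05).
#' @param exact_max Largest per-group size for the exact branch (default 12).
#' @return A tibble with one row per variable: per-group mean and SE, the
#'   U statistic, `p_value`, `p_adjust` (BH), `method` (`"exact"` or
#'   `"approximate"`) and `significant`.
#' @export
compare_groups <- function(profiles, by = "diagnosis", alpha = 0.05,
                           exact_max = 12) {
  profiles <- tibble::as_tibble(profiles)
  g <- profiles[[by]]
  lev <- sort(unique(as.character(g)))
  if (length(lev) != 2L) {
    stop("grouping column ", sQuote(by), " must have exactly two levels",
         call. = FALSE)
  }
  n1 <- sum(g == lev[1]); n2 <- sum(g == lev[2])
  if (min(n1, n2) < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  vars <- profile_variables(profiles)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  res <- purrr::map_dfr(vars, function(v) {
    x <- profiles[[v]][g == lev[1]]
    y <- profiles[[v]][g == lev[2]]
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- !ties && n1 <= exact_max && n2 <= exact_max
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE)
    )
    tibble::tibble(
      variable = v,
      mean_1 = mean(x), se_1 = se(x),
      mean_2 = mean(y), se_2 = se(y),
      U = unname(wt$statistic),
      p_value = wt$p.value,
      method = if (exact) "exact" else "approximate"
    )
  })
  names(res)[match(c("mean_1", "se_1", "mean_2", "se_2"), names(res))] <-
    c(paste0("mean_", lev[1]), paste0("se_", lev[1]),
      paste0("mean_", lev[2]), paste0("se_", lev[2]))
  res$p_adjust <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$p_value <= alpha
  res
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger than
#' that of the observed table (the classical two-sided rule used for, e.g.,
#' sex-ratio comparisons between diagnosis groups).
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(2, 2, 6, 6), 2))  # identical margins: p = 1
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) {
    stop("expected a 2x2 table", call. = FALSE)
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  stats::fisher.test(table)$p.value
}
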