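#' Pairwise Pearson correlations between profile variables
#'
#' Computes the Pearson correlation coefficient and two-sided p-value
#' (t distribution on n - 2 degrees of freedom) for every unordered pair of
#' variables, across samples.
#'
#' @param data Profile or Z-score tibble (metadata columns are ignored).
#' @return A tibble with columns `var1`, `var2`, `r`, `p` covering every
#'   unordered pair including the diagonal (`r = 1`, `p = 0`).
#' @seealso [corr_matrix()] to pivot the result to a square matrix.
#' @export
correlation_matrix <- function(data) {
  data <- tibble::as_tibble(data)
  vars <- profile_variables(data)
  n <- nrow(data)
  if (n < 3L) stop("need at least 3 samples for correlation p-values",
                   call. = FALSE)
  R <- stats::cor(as.matrix(data[vars]))
  tstat <- R * sqrt((n - 2) / pmax(1 - R^2, 0))
  P <- 2 * stats::pt(-abs(tstat), df = n - 2)
  P[!is.finite(tstat)] <- 0  # |r| = 1
  idx <- which(upper.tri(R, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(
    var1 = vars[idx[, 1L]],
    var2 = vars[idx[, 2L]],
    r = R[idx],
    p = P[idx]
  )
}

#' Pivot a pairwise correlation tibble to a square matrix
#'
#' @param corr Output of [correlation_matrix()].
#' @param value Which column to spread, `"r"` (default) or `"p"`.
#' @return A symmetric matrix with variables as dimnames.
#' @export
corr_matrix <- function(corr, value = "r") {
  vars <- unique(c(corr$var1, corr$var2))
  M <- matrix(NA_real_, length(vars), length(vars),
              dimnames = list(vars, vars))
  M[cbind(corr$var1, corr$var2)] <- corr[[value]]
  M[cbind(corr$var2, corr$var1)] <- corr[[value]]
  M
}

#' Hierarchical clustering on correlation distance
#'
#' Agglomerative clustering of variables (or samples) with the distance
#' `d = 1 - r` (Pearson correlation across the other axis) and Ward linkage
#' applied to unsquared distances (`hclust` method `"ward.D"`), matching
#' the ClustVis "correlation" distance / Ward configuration. The result is
#' deterministic given the input column order.
#'
#' @param data Profile or Z-score tibble.
#' @param axis Cluster `"variables"` (default) or `"samples"`.
#' @return An object of class [stats::hclust].
#' @export
cluster_profiles <- function(data, axis = c("variables", "samples")) {
  axis <- match.arg(axis)
  data <- tibble::as_tibble(data)
  vars <- profile_variables(data)
  M <- as.matrix(data[vars])
  if (axis == "samples") {
    rownames(M) <- data$sample_id
    M <- t(M)
  }
  if (ncol(M) < 2L) stop("need at least 2 items to cluster", call. = FALSE)
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance item(s), correlation distance undefined: ",
         paste(sQuote(colnames(M)[sds == 0]), collapse = ", "), call. = FALSE)
  }
  d <- stats::as.dist(1 - stats::cor(M))
  stats::hclust(d, method = "ward.D")
}

#' Assign variables to FA groups
#'
#' Either cuts a dendrogram into `k` groups, or passes through a manual
#' mapping (as published group rosters are fixed by visual assessment of
#' the clustering, a manual table always overrides the cut).
#'
#' @param dendrogram An [stats::hclust] object from [cluster_profiles()].
#' @param k Number of groups to cut (default 5).
#' @param manual Optional tibble with columns `variable` and `group`
#'   covering every clustered variable exactly once; overrides `k`.
#' @return A tibble with columns `variable` and `group` (integer 1..K).
#' @export
assign_groups <- function(dendrogram, k = 5, manual = NULL) {
  leaves <- dendrogram$labels
  if (!is.null(manual)) {
    manual <- tibble::as_tibble(manual)
    stopifnot(all(c("variable", "group") %in% names(manual)))
    unknown <- setdiff(manual$variable, leaves)
    absent <- setdiff(leaves, manual$variable)
    if (length(unknown)) {
      stop("manual mapping names unknown variable(s): ",
           paste(sQuote(unknown), collapse = ", "), call. = FALSE)
    }
    if (length(absent)) {
      stop("manual mapping misses variable(s): ",
           paste(sQuote(absent), collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(manual$variable)) {
      stop("manual mapping assigns a variable twice", call. = FALSE)
    }
    return(manual[c("variable", "group")])
  }
  if (k > length(leaves)) {
    stop("k exceeds the number of clustered variables", call. = FALSE)
  }
  ct <- stats::cutree(dendrogram, k = k)
  tibble::tibble(variable = names(ct), group = unname(ct))
}
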