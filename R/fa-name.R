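#' Parse fatty-acid chain nomenclature
#'
#' Parses labels written in the shorthand used for gas-chromatographic FA
#' profiles: `"<carbons>:<double bonds>"` with an optional `"n-<k>"` series
#' suffix for unsaturated chains and an optional `"DMA "` prefix for
#' dimethyl acetals (alkenyl chains of plasmalogen phospholipids detected as
#' DMA derivatives after transmethylation). Examples: `"14:0"`, `"20:4n-6"`,
#' `"DMA 18:0"`.
#'
#' The grammar is strict: an unsaturated non-DMA chain must carry a series
#' suffix (one of n-3, n-6, n-7, n-9), a saturated chain must not, and chain
#' lengths outside `carbon_range` are rejected. This keeps raw-FA columns
#' distinguishable from derived sums/ratios, whose labels do not parse.
#'
#' @param label Character vector of FA labels.
#' @param carbon_range Accepted chain-length range, default `c(12, 26)`.
#' @return A tibble with one row per label and columns `label`, `carbons`,
#'   `double_bonds`, `series` (`"n-3"`, `"n-6"`, `"n-7"`, `"n-9"` or
#'   `"none"`) and `is_dma`.
#' @examples
#' parse_fa_name(c("20:4n-6", "DMA 18:0", "14:0"))
#' @export
parse_fa_name <- function(label, carbon_range = c(12, 26)) {
  stopifnot(is.character(label), length(label) >= 1L)
  if (any(is.na(label) | !nzchar(label))) {
    stop("FA labels must be non-empty strings", call. = FALSE)
  }
  pattern <- "^(DMA )?([0-9]+):([0-9]+)(n-([0-9]+))?$"
  m <- regmatches(label, regexec(pattern, label))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("unparseable FA label(s): ",
         paste(sQuote(label[bad]), collapse = ", "), call. = FALSE)
  }
  parts <- do.call(rbind, m)
  out <- tibble::tibble(
    label = label,
    carbons = as.integer(parts[, 3L]),
    double_bonds = as.integer(parts[, 4L]),
    series = ifelse(nzchar(parts[, 5L]), parts[, 5L], "none"),
    is_dma = nzchar(parts[, 2L])
  )
  ok_series <- out$series %in% c("n-3", "n-6", "n-7", "n-9", "none")
  if (any(!ok_series)) {
    stop("unrecognized double-bond series in label(s): ",
         paste(sQuote(label[!ok_series]), collapse = ", "),
         " (expected one of n-3, n-6, n-7, n-9)", call. = FALSE)
  }
  # saturated chains carry no series; unsaturated chains must name one
  sat_with_series <- out$double_bonds == 0L & out$series != "none"
  unsat_no_series <- out$double_bonds > 0L & out$series == "none"
  if (any(sat_with_series)) {
    stop("saturated chain labeled with a series: ",
         paste(sQuote(label[sat_with_series]), collapse = ", "), call. = FALSE)
  }
  if (any(unsat_no_series)) {
    stop("unsaturated chain without a series suffix: ",
         paste(sQuote(label[unsat_no_series]), collapse = ", "), call. = FALSE)
  }
  in_range <- out$carbons >= carbon_range[1L] & out$carbons <= carbon_range[2L]
  if (any(!in_range)) {
    stop("chain length outside [", carbon_range[1L], ", ", carbon_range[2L],
         "] in label(s): ", paste(sQuote(label[!in_range]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Render parsed FA fields back to the canonical label
#'
#' Inverse of [parse_fa_name()]: `fa_label(parse_fa_name(x))` equals `x`.
#'
#' @param parsed A tibble with columns `carbons`, `double_bonds`, `series`,
#'   `is_dma` (as returned by [parse_fa_name()]).
#' @return Character vector of canonical labels.
#' @export
fa_label <- function(parsed) {
  paste0(ifelse(parsed$is_dma, "DMA ", ""),
         parsed$carbons, ":", parsed$double_bonds,
         ifelse(parsed$series == "none", "", parsed$series))
}

#' Is a label a parseable raw FA name?
#'
#' Vectorized predicate used to separate raw FA columns from derived
#' sum/ratio/index columns by their labels.
#'
#' @inheritParams parse_fa_name
#' @return Logical vector.
#' @export
is_fa_label <- function(label, carbon_range = c(12, 26)) {
  vapply(label, function(l) {
    !inherits(try(parse_fa_name(l, carbon_range), silent = TRUE), "try-error")
  }, logical(1), USE.NAMES = FALSE)
}
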