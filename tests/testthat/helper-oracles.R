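# small profile builders and independent oracles used across tests

make_profiles <- function(values, diagnosis = NULL) {
  # values: named list of variable -> numeric vector
  n <- length(values[[1L]])
  if (is.null(diagnosis)) diagnosis <- rep(c("OA", "RA"), length.out = n)
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%02d", seq_len(n)),
                   diagnosis = diagnosis),
    tibble::as_tibble(values)
  )
}

# exact two-sided Mann-Whitney p by full enumeration of label assignments
mw_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  obs_u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(obs_u - mu) - 1e-9)
}

# two-sided Fisher p by hypergeometric enumeration
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b          # row 1 total
  n <- c_ + d         # row 2 total
  k <- a + c_         # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pearson r from raw sums (independent arithmetic)
pearson_direct <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - sum(x) * sum(y) / n
  den <- sqrt((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
  num / den
}
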