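# MCMC convergence diagnostics: rank-normalized split R-hat and a
# multi-chain autocorrelation effective sample size with Geyer's initial
# monotone positive sequence. Draws for one parameter are handled as an
# iterations x chains matrix.

split_in_half <- function(mat) {
  n <- nrow(mat)
  half <- n %/% 2L
  cbind(mat[seq_len(half), , drop = FALSE],
        mat[(n - half + 1L):n, , drop = FALSE])
}

rank_normalize <- function(mat) {
  r <- rank(c(mat), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow = nrow(mat))
}

# classic potential scale reduction factor on an iterations x chains matrix
rhat_basic <- function(mat) {
  n <- nrow(mat)
  means <- colMeans(mat)
  vars <- apply(mat, 2L, stats::var)
  w <- mean(vars)
  b <- n * stats::var(means)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Rank-normalized split R-hat
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half and rank-normalizing the pooled draws; the reported value is the
#' larger of the bulk statistic and the statistic of the folded (absolute
#' deviation from median) draws, the modern default. Chains with zero
#' variance return 1 with attribute `zero_variance = TRUE`.
#'
#' @param draws An iterations x chains numeric matrix (at least 2 chains of
#'   equal length), or a list of equal-length numeric vectors.
#' @return A single R-hat value (>= 1 up to floating point).
#' @export
compute_rhat <- function(draws) {
  mat <- as_chain_matrix(draws)
  if (ncol(mat) < 2L) stop("R-hat requires at least 2 chains")
  if (stats::sd(c(mat)) == 0) {
    return(structure(1, zero_variance = TRUE))
  }
  sm <- split_in_half(mat)
  bulk <- rhat_basic(rank_normalize(sm))
  folded <- rhat_basic(rank_normalize(abs(sm - stats::median(sm))))
  max(bulk, folded)
}

# biased autocovariance estimates at lags 0..n-1 via FFT
acov_fft <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  m <- stats::nextn(2L * n)
  f <- stats::fft(c(x, rep(0, m - n)))
  Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / m / n
}

#' Multi-chain effective sample size
#'
#' Autocorrelation-based effective sample size pooled across split chains:
#' per-chain autocovariances are combined with the between-chain variance,
#' and the autocorrelation sum is truncated by Geyer's initial monotone
#' positive sequence. For independent draws the value approaches the total
#' draw count; a zero-variance input returns 0.
#'
#' @inheritParams compute_rhat
#' @return A single effective sample size (capped at the total draw count).
#' @export
compute_neff <- function(draws) {
  mat <- as_chain_matrix(draws)
  if (ncol(mat) < 2L) stop("effective sample size requires at least 2 chains")
  mat <- split_in_half(mat)
  n <- nrow(mat); m <- ncol(mat)
  if (stats::sd(c(mat)) == 0) return(0)
  acov <- apply(mat, 2L, acov_fft)            # n x m
  chain_var <- acov[1L, ] * n / (n - 1)
  w <- mean(chain_var)
  b <- n * stats::var(colMeans(mat))
  var_plus <- (n - 1) / n * w + b / n
  rho <- 1 - (w - rowMeans(acov)) / var_plus  # rho[1] is lag 0
  # Geyer: sum successive pairs while positive, enforce monotone decrease
  tau <- 1
  prev_pair <- Inf
  max_pairs <- (n - 1) %/% 2L
  for (p in seq_len(max_pairs)) {
    pair <- rho[2 * p] + rho[2 * p + 1]
    if (!is.finite(pair) || pair < 0) break
    if (pair > prev_pair) pair <- prev_pair
    tau <- tau + 2 * pair
    prev_pair <- pair
  }
  min(n * m, n * m / tau)
}

as_chain_matrix <- function(draws) {
  if (is.list(draws)) {
    lens <- lengths(draws)
    if (length(unique(lens)) != 1L) stop("chains must have equal lengths")
    draws <- do.call(cbind, draws)
  }
  if (!is.matrix(draws)) stop("draws must be a matrix or list of chains")
  draws
}
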