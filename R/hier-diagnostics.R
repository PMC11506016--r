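# MCMC convergence diagnostics: split R-hat, effective sample size and
# autocorrelation profiles computed on the post-burn-in draws.

.split_rhat <- function(x) {
  n <- length(x) %/% 2L
  if (n < 2L) return(NA_real_)
  m <- cbind(x[seq_len(n)], x[seq_len(n) + n])
  W <- mean(apply(m, 2, var))
  if (W <= .Machine$double.eps) return(1)
  B <- n * var(colMeans(m))
  sqrt(((n - 1) / n * W + B / n) / W)
}

.ess <- function(x, max_lag = 100L) {
  n <- length(x)
  if (var(x) <= .Machine$double.eps) return(n)
  ac <- acf(x, lag.max = min(max_lag, n - 1L), plot = FALSE)$acf[-1]
  # sum positive-autocorrelation prefix
  neg <- which(ac < 0)
  if (length(neg) > 0L) ac <- ac[seq_len(neg[1] - 1L)]
  n / (1 + 2 * sum(ac))
}

#' Convergence diagnostics for a draw matrix
#'
#' Computes split R-hat (the single chain is split into two halves),
#' autocorrelation-based effective sample size, and autocorrelation profiles
#' for every column of a draws matrix.
#'
#' @param draws Numeric matrix, iterations x parameters.
#' @param ac_lags Number of autocorrelation lags to keep in the profile.
#' @return List with `summary` (data.frame: parameter, mean, sd, rhat, ess)
#'   and `autocorr` (lags x parameters matrix).
#' @export
chain_diagnostics <- function(draws, ac_lags = 20L) {
  draws <- as.matrix(draws)
  nm <- colnames(draws)
  summary <- data.frame(
    parameter = nm,
    mean = colMeans(draws),
    sd = apply(draws, 2, sd),
    rhat = apply(draws, 2, .split_rhat),
    ess = apply(draws, 2, .ess),
    row.names = NULL
  )
  autocorr <- sapply(seq_len(ncol(draws)), function(j) {
    x <- draws[, j]
    if (var(x) <= .Machine$double.eps) return(rep(0, ac_lags))
    acf(x, lag.max = ac_lags, plot = FALSE)$acf[-1]
  })
  colnames(autocorr) <- nm
  list(summary = summary, autocorr = autocorr)
}
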