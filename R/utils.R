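#' Round half away from zero
#'
#' Presentation rounding for percentage tables: exact halves round up
#' (47.25 -> 47.3), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Effective sample size of an MCMC chain
#'
#' Initial positive sequence estimator based on the sample autocorrelation
#' function: sums consecutive pairs of autocorrelations until the pair sum
#' turns negative.
#'
#' @param x numeric vector of draws.
#' @return estimated effective sample size (capped at `length(x)`).
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4L || sd(x) == 0) return(n)
  lag_max <- min(n - 1L, max(20L, floor(10 * log10(n))))
  rho <- as.numeric(acf(x, lag.max = lag_max, plot = FALSE)$acf)[-1]
  s <- 0
  k <- 1L
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  min(n, n / (1 + 2 * s))
}

# mean/sd/2.5%/97.5% summary of a draws matrix (iterations x parameters)
summarize_draws <- function(draws, names = NULL) {
  draws <- as.matrix(draws)
  out <- data.frame(
    mean  = colMeans(draws),
    sd    = apply(draws, 2L, sd),
    q2.5  = apply(draws, 2L, quantile, probs = 0.025, names = FALSE),
    q97.5 = apply(draws, 2L, quantile, probs = 0.975, names = FALSE)
  )
  if (!is.null(names)) rownames(out) <- names
  out
}

# cheap content fingerprint used to refuse DIC comparisons across datasets
data_fingerprint <- function(y) {
  y <- as.numeric(y)
  sprintf("n%d-s%d-h%.0f", length(y), sum(y),
          sum(y * seq_along(y)) %% 1e9)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
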