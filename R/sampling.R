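#' Normalized empirical autocorrelation of a scalar series
#'
#' Mean-subtracted, variance-normalized autocorrelation
#' `rho(t) = C(t)/C(0)`, with `rho(0) = 1`, used on the squared end-to-end
#' distance series of a Monte Carlo run to judge equilibration.
#'
#' @param series numeric vector, length >= 2.
#' @param lag_max largest lag to compute (default `min(n - 1, 2000)`).
#' @return numeric vector of `rho(t)` for `t = 0..lag_max`.
#' @export
autocorrelation <- function(series, lag_max = NULL) {
  series <- as.numeric(series)
  n <- length(series)
  stopifnot(n >= 2L, all(is.finite(series)))
  if (var(series) == 0) stop("degenerate input: series has zero variance")
  if (is.null(lag_max)) lag_max <- min(n - 1L, 2000L)
  lag_max <- min(lag_max, n - 1L)
  # FFT autocovariance: identical to the direct estimator with 1/n
  # normalization (as stats::acf), but O(n log n) at any lag range
  x <- series - mean(series)
  m <- stats::nextn(2L * n)
  f <- stats::fft(c(x, rep(0, m - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(lag_max + 1L)] / m
  ac / ac[1L]
}

#' Integrated autocorrelation time by Sokal self-consistent windowing
#'
#' `tau_int(W) = 1/2 + sum_{t=1}^{W} rho(t)`, summed up to the smallest
#' window `W` satisfying `W >= c * tau_int(W)`.  The window factor `c`
#' trades truncation bias against noise from summing far-lag estimates.
#'
#' @param acf_values autocorrelation from [autocorrelation()] (index 1 is
#'   lag 0).
#' @param c window factor (default 6).
#' @return list with `tau_int` (sweeps), `window` (lag at which summation
#'   stopped) and `n_lags` available.
#' @export
integrated_autocorrelation_time <- function(acf_values, c = 6) {
  stopifnot(c > 0, length(acf_values) >= 1L, abs(acf_values[1L] - 1) < 1e-8)
  tau <- 0.5
  max_w <- length(acf_values) - 1L
  if (max_w == 0L) return(list(tau_int = 0.5, window = 0L, n_lags = 0L))
  for (w in seq_len(max_w)) {
    tau <- tau + acf_values[w + 1L]
    if (w >= c * tau)
      return(list(tau_int = max(tau, 0.5), window = w, n_lags = max_w))
  }
  stop("insufficient data: no self-consistent Sokal window within ",
       max_w, " lags")
}

#' Autocorrelation diagnostics of a series
#'
#' Convenience wrapper combining [autocorrelation()] and
#' [integrated_autocorrelation_time()], growing the lag range until a
#' self-consistent window is found.
#'
#' @param series numeric vector.
#' @param c Sokal window factor.
#' @return object of class `acf_result`: `lags`, `acf`, `tau_int`,
#'   `window`, `n`.
#' @export
acf_diagnostics <- function(series, c = 6) {
  n <- length(series)
  lag_max <- min(n - 1L, 200L)
  repeat {
    rho <- autocorrelation(series, lag_max)
    res <- tryCatch(integrated_autocorrelation_time(rho, c),
                    error = function(e) NULL)
    if (!is.null(res) || lag_max >= n - 1L) break
    lag_max <- min(n - 1L, lag_max * 4L)
  }
  if (is.null(res))
    stop("insufficient data: no self-consistent Sokal window in a series of length ", n)
  structure(list(lags = 0:(length(rho) - 1L), acf = rho,
                 tau_int = res$tau_int, window = res$window, n = n),
            class = "acf_result")
}

#' @export
print.acf_result <- function(x, ...) {
  cat(sprintf("<acf_result: n = %d, tau_int = %.3g (window %d)>\n",
              x$n, x$tau_int, x$window))
  invisible(x)
}

#' Extract decorrelated conformations from a trajectory
#'
#' Discards a burn-in of `burn_in_factor * tau_int` sweeps, then keeps
#' recorded conformations spaced at least `ceiling(spacing_factor *
#' tau_int)` sweeps apart, treating states that far apart as statistically
#' independent.
#'
#' @param conformations list of recorded conformations.
#' @param sweeps sweep index of each recorded conformation.
#' @param tau_int integrated autocorrelation time, sweeps.
#' @param n_target desired ensemble size; when fewer are available, all are
#'   returned with a warning and `short = TRUE`.
#' @param spacing_factor,burn_in_factor multiples of `tau_int` for spacing
#'   and burn-in.
#' @return list with `conformations`, `sweeps`, `spacing` and `short`.
#' @export
decorrelated_ensemble <- function(conformations, sweeps, tau_int,
                                  n_target = length(conformations),
                                  spacing_factor = 2, burn_in_factor = 10) {
  stopifnot(length(conformations) == length(sweeps), tau_int >= 0.5)
  burn <- burn_in_factor * tau_int
  spacing <- ceiling(spacing_factor * tau_int)
  keep <- integer(0)
  last <- -Inf
  for (i in seq_along(sweeps)) {
    if (sweeps[i] <= burn) next
    if (sweeps[i] - last >= spacing) {
      keep <- c(keep, i)
      last <- sweeps[i]
    }
  }
  short <- length(keep) < n_target
  if (short)
    warning("only ", length(keep), " decorrelated conformations available (",
            n_target, " requested)")
  keep <- keep[seq_len(min(n_target, length(keep)))]
  list(conformations = conformations[keep], sweeps = sweeps[keep],
       spacing = spacing, short = short)
}

#' Effective ("quasi") persistence length from tangent correlations
#'
#' Fits the orientational correlation `<u(s) . u(s + d)> = exp(-d / l_p)`
#' by least squares on the log scale, with the fit range capped at a
#' quarter of the contour so confinement-induced anticorrelation does not
#' contaminate the decay.  For chains under excluded volume or confinement
#' the result is an effective quasi persistence length describing global
#' conformational flexibility, not local intrinsic stiffness.
#'
#' @param traces list of `sc_trace` objects or point matrices (>= 10 bonds
#'   each recommended).
#' @param max_frac fit range as a fraction of the (segment-count) contour.
#' @param corr_floor lags whose correlation has decayed below this value
#'   are dropped from the fit; far-lag log-correlations are dominated by
#'   sampling noise and would bias the equal-weight log-scale fit.
#' @return list with `l_p` (in the traces' length units), `se` (standard
#'   error from the fit), `censored` (`TRUE` when the correlation does not
#'   decay within the fit range, so `l_p` is only a lower bound) and
#'   `floor` (`TRUE` when correlations are non-positive everywhere,
#'   flexible-limit floor `l_p <= ` one bond length).
#' @export
effective_persistence_length <- function(traces, max_frac = 0.25,
                                         corr_floor = 0.05) {
  if (inherits(traces, "nucleus_dataset")) traces <- traces$traces
  mats <- lapply(traces, trace_points)
  nseg <- vapply(mats, nrow, 0L) - 1L
  stopifnot(length(mats) >= 1L, all(nseg >= 2L))
  dmax <- max(1L, floor(min(nseg) * max_frac))
  bond_lengths <- unlist(lapply(mats, function(p) sqrt(rowSums(diff(p)^2))))
  b <- mean(bond_lengths)

  corr <- vapply(seq_len(dmax), function(d) {
    acc <- 0; cnt <- 0
    for (p in mats) {
      bv <- diff(p)
      u <- bv / sqrt(rowSums(bv^2))
      n <- nrow(u)
      if (n <= d) next
      acc <- acc + sum(rowSums(u[1:(n - d), , drop = FALSE] *
                                 u[(1 + d):n, , drop = FALSE]))
      cnt <- cnt + (n - d)
    }
    acc / cnt
  }, 0)

  if (all(corr <= 0))
    return(list(l_p = b, se = NA_real_, censored = FALSE, floor = TRUE))
  first_low <- which(corr <= max(0, corr_floor))[1L]  # leading run only
  pos <- seq_len(if (is.na(first_low)) dmax else first_low - 1L)
  if (length(pos) == 0L)
    return(list(l_p = b, se = NA_real_, censored = FALSE, floor = TRUE))
  x <- pos
  y <- log(corr[pos])
  if (length(x) < 2L || all(y > -1e-4)) {
    # no measurable decay within the fit range: censored estimate
    lp_min <- -dmax / min(y, -1e-12)
    return(list(l_p = lp_min * b, se = NA_real_, censored = TRUE,
                floor = FALSE))
  }
  fit <- lm(y ~ 0 + x)
  slope <- coef(fit)[[1L]]
  se_slope <- summary(fit)$coefficients[1L, 2L]
  lp_bonds <- -1 / slope
  list(l_p = lp_bonds * b, se = se_slope / slope^2 * b,
       censored = FALSE, floor = FALSE)
}
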