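#' Edge-corrected hit and false-alarm rates from response counts
#'
#' Converts the four cells of a yes/no signal-detection table into a pair of
#' rates suitable for `dprime()` and `sdt_criterion()`. A rate that comes out
#' exactly 0 or 1 would send the normal quantile to infinity, so such rates
#' are pulled inside the unit interval by half a trial: 0 becomes `1/(2N)`
#' and 1 becomes `1 - 1/(2N)`, where `N` is the number of trials of the
#' relevant stimulus class. The same correction is applied everywhere in the
#' package (type 1 d', the second-step statistic, and every permutation
#' replicate) so that comparisons between observed and null values are not
#' biased by differential clamping.
#'
#' @param hits,misses Counts of signal trials answered "signal" / "noise".
#' @param fas,crs Counts of noise trials answered "signal" / "noise".
#' @return An object of class `rate_pair`: a list with elements `hr`, `far`
#'   (both strictly inside (0, 1)), `n_signal` and `n_noise`.
#' @examples
#' rates_from_counts(10, 10, 5, 15)   # hr 0.5, far 0.25
#' rates_from_counts(20, 0, 5, 15)    # hr corrected to 1 - 1/40
#' @export
rates_from_counts <- function(hits, misses, fas, crs) {
  stopifnot(hits >= 0, misses >= 0, fas >= 0, crs >= 0)
  n_signal <- hits + misses
  n_noise <- fas + crs
  if (n_signal < 1) stop("no signal trials: hit rate undefined")
  if (n_noise < 1) stop("no noise trials: false-alarm rate undefined")
  hr <- correct_rate(hits / n_signal, n_signal)
  far <- correct_rate(fas / n_noise, n_noise)
  structure(list(hr = hr, far = far, n_signal = n_signal, n_noise = n_noise),
            class = "rate_pair")
}

correct_rate <- function(rate, n) {
  if (rate <= 0) return(1 / (2 * n))
  if (rate >= 1) return(1 - 1 / (2 * n))
  rate
}

#' Equal-variance signal-detection sensitivity (d')
#'
#' The conventional sensitivity index \eqn{d' = \Phi^{-1}(HR) -
#' \Phi^{-1}(FAR)}, with \eqn{\Phi^{-1}} the standard normal quantile.
#'
#' @param rates A `rate_pair` from [rates_from_counts()], or a list with
#'   numeric elements `hr` and `far` strictly inside (0, 1).
#' @return The sensitivity d' (numeric scalar).
#' @seealso [sdt_criterion()] for the matching bias measure.
#' @export
dprime <- function(rates) {
  check_rates(rates)
  stats::qnorm(rates$hr) - stats::qnorm(rates$far)
}

#' Equal-variance signal-detection criterion (c)
#'
#' The bias index \eqn{c = -\tfrac{1}{2}(\Phi^{-1}(HR) + \Phi^{-1}(FAR))}:
#' the distance of the decision cut-off from the neutral point, positive for
#' a conservative ("noise"-leaning) observer.
#'
#' @inheritParams dprime
#' @return The criterion c (numeric scalar).
#' @export
sdt_criterion <- function(rates) {
  check_rates(rates)
  -0.5 * (stats::qnorm(rates$hr) + stats::qnorm(rates$far))
}

check_rates <- function(rates) {
  if (!is.list(rates) || is.null(rates$hr) || is.null(rates$far))
    stop("`rates` must have elements `hr` and `far`")
  if (rates$hr <= 0 || rates$hr >= 1 || rates$far <= 0 || rates$far >= 1)
    stop("rates must lie strictly inside (0, 1); apply rates_from_counts()")
  invisible(TRUE)
}

#' @export
print.rate_pair <- function(x, ...) {
  cat(sprintf("rate_pair: HR = %.4f (n = %d), FAR = %.4f (n = %d)\n",
              x$hr, x$n_signal, x$far, x$n_noise))
  invisible(x)
}
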