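#' Response-conditional confidence counts for the type 2 analysis
#'
#' Tabulates one participant's trials into the 2 x 2 x K table (stimulus x
#' response x confidence bin) that the meta-d' fit consumes. Confidence
#' values are mapped to `n_bins` equal-width bins spanning `(0, scale_max]`,
#' so with `n_bins` equal to the number of scale levels the bin index equals
#' the rating index, and the half-step values produced by trial-averaged
#' confidence fall unambiguously inside bins.
#'
#' Extreme trials (no second rating) must be removed before calling, so
#' that the first-, second- and averaged-confidence tables are built on the
#' identical trial set and remain comparable.
#'
#' @param trials Trial data.frame for one participant with columns
#'   `stimulus`, `response`, `conf1`, `conf2`, `shift`. Rows with
#'   `shift == "EXTREME"` are rejected.
#' @param which Confidence stream: `"first"`, `"second"`, or `"combined"`
#'   (the per-trial mean of the two ratings).
#' @param n_bins Number of confidence bins K (default 5).
#' @param scale_max Top of the confidence scale (default 100).
#' @param stimulus_levels Length-2 character vector naming the two stimulus
#'   classes, in the order (class 1, class 2); defaults to the sorted
#'   unique values.
#' @return An object of class `type2_counts`: a list with `n_bins`, and
#'   `counts_s1`, `counts_s2` — each a length-`2K` integer vector ordered
#'   from highest-confidence class-1 response down to confidence 1, then
#'   confidence 1 up to highest-confidence class-2 response.
#' @export
build_type2_counts <- function(trials,
                               which = c("first", "second", "combined"),
                               n_bins = 5L,
                               scale_max = 100,
                               stimulus_levels = NULL) {
  which <- match.arg(which)
  stopifnot(n_bins >= 2L)
  if (any(trials$shift == "EXTREME"))
    stop("remove EXTREME trials before building type 2 counts")
  conf <- switch(which,
                 first = trials$conf1,
                 second = trials$conf2,
                 combined = average_confidence(trials$conf1, trials$conf2))
  if (anyNA(conf)) stop("missing confidence values in stream '", which, "'")
  bin <- pmin(pmax(ceiling(conf / (scale_max / n_bins)), 1L), n_bins)
  if (is.null(stimulus_levels)) stimulus_levels <- sort(unique(trials$stimulus))
  stopifnot(length(stimulus_levels) == 2L)
  type2_counts_from_vectors(trials$stimulus, trials$response, bin,
                            n_bins, stimulus_levels)
}

#' Assemble type 2 counts from raw stimulus/response/bin vectors
#'
#' Lower-level constructor used by [build_type2_counts()] and available for
#' data that do not come from the two-step paradigm (e.g. a plain
#' single-report confidence experiment).
#'
#' @param stimulus,response Character/factor vectors over the two classes.
#' @param bin Integer confidence bin per trial, in `1..n_bins`.
#' @param n_bins Number of confidence bins.
#' @param stimulus_levels Class labels in order (class 1, class 2).
#' @return A `type2_counts` object (see [build_type2_counts()]).
#' @export
type2_counts_from_vectors <- function(stimulus, response, bin, n_bins,
                                      stimulus_levels = sort(unique(stimulus))) {
  stopifnot(all(stimulus %in% stimulus_levels),
            all(response %in% stimulus_levels),
            all(bin >= 1L & bin <= n_bins))
  k <- as.integer(n_bins)
  cell <- function(stim) {
    sel <- stimulus == stim
    r1 <- response[sel] == stimulus_levels[1]
    b <- bin[sel]
    # response class 1 with conf K..1, then response class 2 with conf 1..K
    c(rev(tabulate(b[r1], nbins = k)), tabulate(b[!r1], nbins = k))
  }
  structure(list(n_bins = k,
                 counts_s1 = cell(stimulus_levels[1]),
                 counts_s2 = cell(stimulus_levels[2]),
                 stimulus_levels = stimulus_levels),
            class = "type2_counts")
}

#' @export
print.type2_counts <- function(x, ...) {
  k <- x$n_bins
  lab <- c(paste0("R1c", k:1), paste0("R2c", 1:k))
  m <- rbind(x$counts_s1, x$counts_s2)
  dimnames(m) <- list(paste0("S", 1:2), lab)
  cat("type2_counts (K =", k, "bins):\n")
  print(m)
  invisible(x)
}

# Type 1 marginals of a counts table, with edge correction.
type1_from_counts <- function(counts) {
  k <- counts$n_bins
  resp2 <- (k + 1L):(2L * k)
  rates_from_counts(hits = sum(counts$counts_s2[resp2]),
                    misses = sum(counts$counts_s2[1:k]),
                    fas = sum(counts$counts_s1[resp2]),
                    crs = sum(counts$counts_s1[1:k]))
}

# Conditional type 2 cell probabilities under the meta-level SDT observer.
# Returns a list of four probability vectors (stim x response), each of
# length K summing to 1, given meta_d, the scaled type 1 criterion and the
# 2(K-1) type 2 criteria (t2_low decreasing below theta, t2_hi increasing
# above). Probabilities are floored at a tiny value to keep the log finite.
type2_cell_probs <- function(meta_d, theta, t2_low, t2_hi) {
  k <- length(t2_low) + 1L
  mus <- c(-meta_d / 2, meta_d / 2)
  out <- vector("list", 2L)
  for (s in 1:2) {
    mu <- mus[s]
    # response class 1: x < theta; bounds theta > t2_low[1] > ... > -Inf
    b_low <- c(theta, t2_low, -Inf)
    area_low <- stats::pnorm(b_low[1:k], mu) - stats::pnorm(b_low[2:(k + 1)], mu)
    # response class 2: x > theta; bounds theta < t2_hi[1] < ... < Inf
    b_hi <- c(theta, t2_hi, Inf)
    area_hi <- stats::pnorm(b_hi[2:(k + 1)], mu) - stats::pnorm(b_hi[1:k], mu)
    p_low <- area_low / sum(area_low)
    p_hi <- area_hi / sum(area_hi)
    out[[s]] <- list(resp1 = pmax(p_low, 1e-12), resp2 = pmax(p_hi, 1e-12))
  }
  out
}

# Negative log-likelihood of padded type 2 counts given (meta_d, psi),
# where psi are log-spacings of the type 2 criteria away from the scaled
# type 1 criterion theta = c1 * meta_d / d1.
meta_d_negll <- function(par, padded, c_ratio) {
  k <- padded$n_bins
  meta_d <- par[1]
  theta <- c_ratio * meta_d
  t2_low <- theta - cumsum(exp(par[2:k]))
  t2_hi <- theta + cumsum(exp(par[(k + 1):(2 * k - 1)]))
  pr <- type2_cell_probs(meta_d, theta, t2_low, t2_hi)
  ll <- 0
  for (s in 1:2) {
    cs <- if (s == 1) padded$counts_s1 else padded$counts_s2
    n_r1 <- cs[k:1]            # response 1, conf 1..K
    n_r2 <- cs[(k + 1):(2 * k)]
    ll <- ll + sum(n_r1 * log(pr[[s]]$resp1)) + sum(n_r2 * log(pr[[s]]$resp2))
  }
  -ll
}

pad_counts <- function(counts) {
  pad <- 1 / (2 * counts$n_bins)
  counts$counts_s1 <- counts$counts_s1 + pad
  counts$counts_s2 <- counts$counts_s2 + pad
  counts
}

# Empirical-quantile initial spacings for the type 2 criteria, treating the
# pooled evidence as standard normal. Falls back to equal spacing when the
# data are too sparse to give ordered quantiles.
init_spacings <- function(padded, theta) {
  k <- padded$n_bins
  tot <- sum(padded$counts_s1) + sum(padded$counts_s2)
  pooled_r1 <- (padded$counts_s1[1:k] + padded$counts_s2[1:k])      # conf K..1
  pooled_r2 <- (padded$counts_s1[(k + 1):(2 * k)] +
                  padded$counts_s2[(k + 1):(2 * k)])                # conf 1..K
  # low side: P(x < c_low_j) = P(resp1 & conf > j)
  p_low <- rev(cumsum(pooled_r1))[-1] / tot        # j = 1..K-1, decreasing
  c_low <- stats::qnorm(pmin(pmax(p_low, 1e-4), 1 - 1e-4))
  # high side: P(x > c_hi_j) = P(resp2 & conf > j)
  p_hi <- rev(cumsum(rev(pooled_r2)))[-1] / tot
  c_hi <- stats::qnorm(1 - pmin(pmax(p_hi, 1e-4), 1 - 1e-4))
  sp_low <- -diff(c(theta, c_low))
  sp_hi <- diff(c(theta, c_hi))
  if (any(sp_low <= 0) || any(sp_hi <= 0))
    return(rep(log(2 / (k - 1)), 2 * (k - 1)))
  c(log(sp_low), log(sp_hi))
}

#' Maximum-likelihood meta-d' fit
#'
#' Estimates metacognitive sensitivity in type 1 d' units from
#' response-conditional confidence counts. The type 1 sensitivity `d1` and
#' criterion `c1` are computed from the type 1 marginals of the table (with
#' edge correction). The fit then asks what sensitivity `meta_d` an
#' equal-variance SDT observer would need for its confidence ratings to
#' reproduce the observed type 2 data, holding its type 1 criterion at the
#' same relative position `c1 * meta_d / d1`. The free parameters —
#' `meta_d` and `2(K-1)` ordered type 2 criteria — maximise the multinomial
#' likelihood of the confidence counts conditional on stimulus and
#' response.
#'
#' Each of the `2K` cells is padded with `1/(2K)` before fitting to
#' stabilise empty cells; the optimiser (BFGS on log-spacing-transformed
#' criteria, which enforces their ordering) is restarted from three
#' deterministic initialisations (`meta_d` at 0.5, 1 and 1.5 times `d1`,
#' criteria at empirical quantiles) and the best likelihood wins. Tables
#' whose confidence ratings all fall in one bin carry no type 2 information
#' and return `meta_d = 0` with a warning.
#'
#' @param counts A `type2_counts` object from [build_type2_counts()].
#' @return An object of class `meta_d_fit`: a list with `d1`, `c1`,
#'   `meta_d`, `type2_criteria` (ascending, length `2(K-1)`),
#'   `log_likelihood`, `converged`, and `degenerate`.
#' @references Maniscalco, B., & Lau, H. (2012). A signal detection
#'   theoretic approach for estimating metacognitive sensitivity from
#'   confidence ratings. Consciousness and Cognition, 21(1), 422-430.
#' @export
fit_meta_d <- function(counts) {
  stopifnot(inherits(counts, "type2_counts"))
  k <- counts$n_bins
  t1 <- type1_from_counts(counts)
  d1 <- dprime(t1)
  c1 <- sdt_criterion(t1)

  # degenerate: every observed rating in a single bin
  bin_tot <- numeric(k)
  for (cs in list(counts$counts_s1, counts$counts_s2))
    bin_tot <- bin_tot + cs[k:1] + cs[(k + 1):(2 * k)]
  if (sum(bin_tot > 0) <= 1L) {
    warning("all confidence ratings fall in one bin; meta_d set to 0")
    return(structure(list(d1 = d1, c1 = c1, meta_d = 0,
                          type2_criteria = rep(NA_real_, 2 * (k - 1)),
                          log_likelihood = NA_real_, converged = TRUE,
                          degenerate = TRUE),
                     class = "meta_d_fit"))
  }

  padded <- pad_counts(counts)
  c_ratio <- c1 / d1
  best <- NULL
  for (f in c(0.5, 1, 1.5)) {
    m0 <- f * d1
    psi0 <- init_spacings(padded, c_ratio * m0)
    fit <- stats::optim(c(m0, psi0), meta_d_negll, padded = padded,
                        c_ratio = c_ratio, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  theta <- c_ratio * best$par[1]
  t2_low <- theta - cumsum(exp(best$par[2:k]))
  t2_hi <- theta + cumsum(exp(best$par[(k + 1):(2 * k - 1)]))
  structure(list(d1 = d1, c1 = c1, meta_d = best$par[1],
                 type2_criteria = c(rev(t2_low), t2_hi),
                 log_likelihood = -best$value,
                 converged = best$convergence == 0,
                 degenerate = FALSE),
            class = "meta_d_fit")
}

#' Profile likelihood at a fixed meta-d'
#'
#' Re-optimises only the type 2 criteria with `meta_d` held fixed, and
#' returns the maximised log-likelihood. Useful for profile-likelihood
#' inspection and for validating the full optimiser against a grid search.
#'
#' @inheritParams fit_meta_d
#' @param meta_d Fixed sensitivity value.
#' @return A list with `meta_d`, `log_likelihood` and `type2_criteria`.
#' @export
fit_meta_d_fixed <- function(counts, meta_d) {
  stopifnot(inherits(counts, "type2_counts"))
  k <- counts$n_bins
  t1 <- type1_from_counts(counts)
  d1 <- dprime(t1)
  c_ratio <- sdt_criterion(t1) / d1
  padded <- pad_counts(counts)
  nll <- function(psi) meta_d_negll(c(meta_d, psi), padded, c_ratio)
  psi0 <- init_spacings(padded, c_ratio * meta_d)
  fit <- stats::optim(psi0, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  theta <- c_ratio * meta_d
  t2_low <- theta - cumsum(exp(fit$par[1:(k - 1)]))
  t2_hi <- theta + cumsum(exp(fit$par[k:(2 * k - 2)]))
  list(meta_d = meta_d, log_likelihood = -fit$value,
       type2_criteria = c(rev(t2_low), t2_hi))
}

#' @export
print.meta_d_fit <- function(x, ...) {
  cat(sprintf("meta_d_fit: d' = %.3f, c = %.3f, meta-d' = %.3f (%s)\n",
              x$d1, x$c1, x$meta_d,
              if (x$degenerate) "degenerate" else
                if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Meta-d' for the first, second and averaged confidence streams
#'
#' Fits meta-d' three times on the identical trial set of one participant
#' (extreme trials removed): once with the first rating, once with the
#' second, once with the per-trial mean of the two. Differences between the
#' three fits therefore isolate the confidence stream itself.
#'
#' @param trials One participant's trial data.frame (columns `stimulus`,
#'   `response`, `conf1`, `conf2`, `shift`).
#' @param n_bins Confidence bins K shared by all three fits.
#' @param scale_max Top of the confidence scale.
#' @return Named list of three `meta_d_fit` objects: `first`, `second`,
#'   `combined`.
#' @export
meta_d_profile <- function(trials, n_bins = 5L, scale_max = 100) {
  tr <- trials[trials$shift != "EXTREME", , drop = FALSE]
  if (nrow(tr) == 0) stop("no non-extreme trials")
  lv <- sort(unique(trials$stimulus))
  fits <- lapply(c("first", "second", "combined"), function(w) {
    fit_meta_d(build_type2_counts(tr, which = w, n_bins = n_bins,
                                  scale_max = scale_max,
                                  stimulus_levels = lv))
  })
  names(fits) <- c("first", "second", "combined")
  fits
}

#' Per-participant meta-d' table for a cohort
#'
#' Runs [meta_d_profile()] for each participant and stacks the results in
#' long format, one row per participant x stream.
#'
#' @param trials Cohort trial data.frame with a `participant_id` column.
#' @inheritParams meta_d_profile
#' @return A data.frame with columns `participant_id`, `stream`, `d`, `c`,
#'   `meta_d`, `converged`.
#' @export
meta_d_table <- function(trials, n_bins = 5L, scale_max = 100) {
  split_tr <- split(trials, trials$participant_id)
  out <- do.call(rbind, lapply(names(split_tr), function(id) {
    fits <- meta_d_profile(split_tr[[id]], n_bins = n_bins,
                           scale_max = scale_max)
    do.call(rbind, lapply(names(fits), function(w) {
      f <- fits[[w]]
      data.frame(participant_id = id, stream = w, d = f$d1, c = f$c1,
                 meta_d = f$meta_d, converged = f$converged,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
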