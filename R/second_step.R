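#' Hit/false-alarm rates of the second-step metacognitive discrimination
#'
#' Treats the up/down confidence shift as a second discrimination task on
#' the type 1 outcome: a hit is a correct type 1 response followed by an
#' up-shift, a false alarm an incorrect response followed by an up-shift.
#' Extreme trials (no second rating) are removed; rates get the standard
#' edge correction via [rates_from_counts()].
#'
#' @param trials One participant's trial data.frame with columns `correct`
#'   and `shift`.
#' @return A `rate_pair` with `hr = P(UP | correct)` and
#'   `far = P(UP | incorrect)`.
#' @export
second_step_rates <- function(trials) {
  tr <- trials[trials$shift != "EXTREME", , drop = FALSE]
  if (nrow(tr) == 0) stop("no up/down-shift trials")
  up <- tr$shift == "UP"
  rates_from_counts(hits = sum(tr$correct & up),
                    misses = sum(tr$correct & !up),
                    fas = sum(!tr$correct & up),
                    crs = sum(!tr$correct & !up))
}

#' Permutation-based empirical chance level for the second-step d'
#'
#' Shuffling the correct/incorrect labels across a participant's up/down
#' trials (shift labels held fixed) destroys any association between
#' re-evaluation and accuracy while preserving both margins, so the d'
#' recomputed on each shuffle samples the statistic's chance distribution.
#'
#' @param trials One participant's trial data.frame (`correct`, `shift`).
#' @param n_permutations Number of shuffles (default 1000).
#' @param seed Integer seed; the null is deterministic given it.
#' @return A list with `d2_null` (vector of permuted d' values),
#'   `null_mean`, `null_sd`, `n_permutations`, `seed`.
#' @export
empirical_chance <- function(trials, n_permutations = 1000L, seed = 1L) {
  tr <- trials[trials$shift != "EXTREME", , drop = FALSE]
  if (nrow(tr) == 0) stop("no up/down-shift trials")
  up <- tr$shift == "UP"
  correct <- tr$correct
  if (!any(correct) || !any(!correct))
    stop("need both correct and incorrect trials for the permutation null")
  set.seed(as.integer(seed))
  d2_null <- vapply(seq_len(n_permutations), function(i) {
    perm <- sample(correct)
    dprime(rates_from_counts(hits = sum(perm & up),
                             misses = sum(perm & !up),
                             fas = sum(!perm & up),
                             crs = sum(!perm & !up)))
  }, numeric(1))
  list(d2_null = d2_null, null_mean = mean(d2_null), null_sd = stats::sd(d2_null),
       n_permutations = as.integer(n_permutations), seed = as.integer(seed))
}

#' Second-step analysis for one participant
#'
#' @inheritParams empirical_chance
#' @return An object of class `second_step_result`: `hr`, `far`, `d2`,
#'   `c2`, `null_mean`, `null_sd`, `perm_p` (one-sided permutation p-value
#'   of the observed d2, with the +1 correction), `n_permutations`, `seed`.
#' @export
second_step_participant <- function(trials, n_permutations = 1000L, seed = 1L) {
  rates <- second_step_rates(trials)
  d2 <- dprime(rates)
  c2 <- sdt_criterion(rates)
  null <- empirical_chance(trials, n_permutations = n_permutations, seed = seed)
  structure(list(hr = rates$hr, far = rates$far, d2 = d2, c2 = c2,
                 null_mean = null$null_mean, null_sd = null$null_sd,
                 perm_p = (sum(null$d2_null >= d2) + 1) /
                   (null$n_permutations + 1),
                 n_permutations = null$n_permutations, seed = null$seed),
            class = "second_step_result")
}

#' @export
print.second_step_result <- function(x, ...) {
  cat(sprintf(paste0("second_step_result: HR = %.3f, FAR = %.3f, ",
                     "d2 = %.3f, c2 = %.3f\n  null %.3f +/- %.3f ",
                     "(%d permutations), perm p = %.4f\n"),
              x$hr, x$far, x$d2, x$c2, x$null_mean, x$null_sd,
              x$n_permutations, x$perm_p))
  invisible(x)
}

#' Cohort-level second-step analysis
#'
#' Computes the second-step d' and criterion for every participant, each
#' with its own permutation null (per-participant seeds are derived
#' deterministically from the master seed), then compares the observed d'
#' values to the per-participant null means with a paired t test, and the
#' criteria to zero with a one-sample t test (any up/down response bias).
#'
#' @param trials Cohort trial data.frame with a `participant_id` column.
#' @param n_permutations Permutations per participant.
#' @param seed Master seed.
#' @param tails Tail convention for the group tests.
#' @return A list with `table` (one row per participant: `participant_id`,
#'   `hr`, `far`, `d2`, `c2`, `null_mean`, `null_sd`, `perm_p`),
#'   `d2_vs_chance` and `c2_vs_zero` (both [paired_t()] results).
#' @export
second_step_analysis <- function(trials, n_permutations = 1000L, seed = 1L,
                                 tails = "two") {
  ids <- unique(trials$participant_id)
  if (length(ids) < 2) stop("group comparison needs >= 2 participants")
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, length(ids))
  rows <- lapply(seq_along(ids), function(i) {
    r <- second_step_participant(
      trials[trials$participant_id == ids[i], , drop = FALSE],
      n_permutations = n_permutations, seed = seeds[i])
    data.frame(participant_id = ids[i], hr = r$hr, far = r$far, d2 = r$d2,
               c2 = r$c2, null_mean = r$null_mean, null_sd = r$null_sd,
               perm_p = r$perm_p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       d2_vs_chance = paired_t(tab$d2, tab$null_mean, tails = tails),
       c2_vs_zero = paired_t(tab$c2, rep(0, nrow(tab)), tails = tails))
}
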