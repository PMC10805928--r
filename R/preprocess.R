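#' Classify a trial's confidence shift
#'
#' Labels a trial `"UP"` when the second rating exceeds the first, `"DOWN"`
#' when it is lower, and `"EXTREME"` when there is no second rating (the
#' first rating hit an endpoint of the scale and the trial ended early).
#' Equal ratings are a data error: the paradigm forbids repeating the first
#' confidence in the second interval.
#'
#' @param conf1 First confidence rating (scale value). Vectorised.
#' @param conf2 Second confidence rating, or `NA` when absent.
#' @return Character vector in `c("UP", "DOWN", "EXTREME")`.
#' @export
classify_shift <- function(conf1, conf2) {
  if (length(conf1) != length(conf2)) stop("conf1 and conf2 lengths differ")
  bad <- !is.na(conf2) & conf2 == conf1
  if (any(bad))
    stop("conf2 equals conf1 at position(s) ",
         paste(which(bad), collapse = ", "),
         ": repeated confidence is not a valid trial")
  ifelse(is.na(conf2), "EXTREME", ifelse(conf2 > conf1, "UP", "DOWN"))
}

#' Mid-point of the two confidence ratings
#'
#' The trial-averaged confidence stream: the arithmetic mean of the two
#' scale values, which may fall between scale levels (e.g. 40 and 60 give
#' 50; 90 and 100 give 95). Undefined on extreme trials — callers must
#' filter those out first.
#'
#' @param conf1,conf2 Confidence scale values; `conf2` must be present.
#' @return Numeric vector of mid-values.
#' @export
average_confidence <- function(conf1, conf2) {
  if (any(is.na(conf2)))
    stop("average_confidence is undefined when conf2 is absent")
  (conf1 + conf2) / 2
}

#' Per-participant summaries of a trial table
#'
#' Computes, for each participant, the trial count, type 1 accuracy and the
#' up/down/extreme shift counts. If the table has no `shift` column it is
#' derived with [classify_shift()].
#'
#' @param trials Trial data.frame with columns `participant_id`, `correct`,
#'   `conf1`, `conf2` and optionally `shift`.
#' @return A data.frame with one row per participant: `participant_id`,
#'   `n_trials`, `type1_accuracy`, `n_up`, `n_down`, `n_extreme`, plus
#'   placeholder columns `included` (TRUE) and `exclusion_reason` (`""`).
#' @export
participant_summaries <- function(trials) {
  stopifnot(all(c("participant_id", "correct", "conf1", "conf2") %in%
                  names(trials)))
  if (is.null(trials$shift))
    trials$shift <- classify_shift(trials$conf1, trials$conf2)
  split_tr <- split(trials, trials$participant_id)
  out <- do.call(rbind, lapply(split_tr, function(tr) {
    data.frame(participant_id = tr$participant_id[1],
               n_trials = nrow(tr),
               type1_accuracy = mean(tr$correct),
               n_up = sum(tr$shift == "UP"),
               n_down = sum(tr$shift == "DOWN"),
               n_extreme = sum(tr$shift == "EXTREME"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$included <- TRUE
  out$exclusion_reason <- ""
  out
}

#' Exclude participants far from the group-level accuracy
#'
#' Flags participants whose type 1 accuracy lies more than `z_cut` sample
#' standard deviations from the group mean accuracy. Mean and SD are
#' computed over all submitted participants (before any exclusion), with
#' the sample (n - 1) SD. If every accuracy is identical the SD is zero and
#' nobody is excluded.
#'
#' @param summaries Output of [participant_summaries()] (>= 2 rows).
#' @param z_cut Cut-off in standard deviations (default 2.5).
#' @return `summaries` with `included` / `exclusion_reason` updated.
#' @export
exclude_by_group_accuracy <- function(summaries, z_cut = 2.5) {
  if (nrow(summaries) < 2) stop("need at least 2 participants")
  acc <- summaries$type1_accuracy
  mu <- mean(acc)
  sdev <- stats::sd(acc)
  out <- abs(acc - mu) > z_cut * sdev & sdev > 0
  summaries$included <- summaries$included & !out
  summaries$exclusion_reason[out] <- paste0(
    "accuracy beyond ", z_cut, " SD of group mean")
  summaries
}

#' Exclude participants with too few up- or down-shift trials
#'
#' Signal-detection measures on the second interval need enough trials in
#' both shift classes; participants with fewer than `min_count` up-shift or
#' fewer than `min_count` down-shift trials are flagged excluded.
#'
#' @param summaries Output of [participant_summaries()].
#' @param min_count Minimum count per shift class (default 50).
#' @return `summaries` with `included` / `exclusion_reason` updated.
#' @export
exclude_by_shift_counts <- function(summaries, min_count = 50L) {
  out <- summaries$n_up < min_count | summaries$n_down < min_count
  hit <- out & summaries$included
  summaries$included <- summaries$included & !out
  summaries$exclusion_reason[hit] <- paste0(
    "fewer than ", min_count, " up- or down-shift trials")
  summaries
}

#' Apply both exclusion rules in order
#'
#' Group-accuracy rule first (statistics over all submitted participants),
#' then the shift-count rule, so per-rule removal counts match the
#' reporting convention.
#'
#' @param trials Trial data.frame (see [participant_summaries()]).
#' @param z_cut Accuracy cut-off in SDs.
#' @param min_count Minimum up- and down-shift count.
#' @return A list with `summaries` (flagged summary table), `included_ids`,
#'   and `trials` filtered to included participants.
#' @export
apply_exclusions <- function(trials, z_cut = 2.5, min_count = 50L) {
  summaries <- participant_summaries(trials)
  summaries <- exclude_by_group_accuracy(summaries, z_cut = z_cut)
  summaries <- exclude_by_shift_counts(summaries, min_count = min_count)
  ids <- summaries$participant_id[summaries$included]
  list(summaries = summaries,
       included_ids = ids,
       trials = trials[trials$participant_id %in% ids, , drop = FALSE])
}
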