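#' Paired t test with within-subject effect size
#'
#' Classic paired comparison on matched per-participant values:
#' \eqn{t = \bar{d} / (s_d / \sqrt{n})} on the differences `d = x - y`
#' (sample SD), with `n - 1` degrees of freedom, Cohen's
#' \eqn{d_z = \bar{d} / s_d}, and the 95% CI of the mean difference.
#'
#' @param x,y Equal-length numeric vectors of matched values (n >= 2).
#' @param tails `"two"` for a two-sided p-value, `"one"` for the
#'   directional test of `mean(x - y) > 0`.
#' @return An object of class `paired_t_result`: `t_stat`, `df`, `p_value`,
#'   `cohen_dz`, `mean_diff`, `ci95` (length-2 vector), `tails`, `n`.
#' @export
paired_t <- function(x, y, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs")
  d <- x - y
  sd_d <- stats::sd(d)
  if (sd_d == 0) stop("zero-variance differences: paired t undefined")
  se <- sd_d / sqrt(n)
  t_stat <- mean(d) / se
  df <- n - 1L
  p <- if (tails == "two") 2 * stats::pt(-abs(t_stat), df)
       else stats::pt(t_stat, df, lower.tail = FALSE)
  ci <- mean(d) + c(-1, 1) * stats::qt(0.975, df) * se
  structure(list(t_stat = t_stat, df = df, p_value = p,
                 cohen_dz = mean(d) / sd_d, mean_diff = mean(d),
                 ci95 = ci, tails = tails, n = n),
            class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf("paired t(%d) = %.3f, p = %.4g (%s-tailed), dz = %.3f\n",
              x$df, x$t_stat, x$p_value, x$tails, x$cohen_dz))
  cat(sprintf("  mean diff %.4f, 95%% CI [%.4f, %.4f]\n",
              x$mean_diff, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Power of a paired t test at a given sample size
#'
#' Exact power from the noncentral t distribution: with `n` pairs and
#' within-subject effect size `dz`, the test statistic is noncentral t with
#' `n - 1` df and noncentrality `dz * sqrt(n)`; power is the probability it
#' exceeds the central-t critical value at `alpha`.
#'
#' @param n Number of pairs (>= 2).
#' @param effect_dz Within-subject effect size Cohen's dz (> 0).
#' @param alpha Significance level.
#' @param tails `"one"` or `"two"`.
#' @return Power in (0, 1).
#' @export
paired_t_power <- function(n, effect_dz, alpha = 0.05,
                           tails = c("one", "two")) {
  tails <- match.arg(tails)
  stopifnot(n >= 2, effect_dz > 0, alpha > 0, alpha < 1)
  df <- n - 1
  ncp <- effect_dz * sqrt(n)
  if (tails == "one") {
    stats::pt(stats::qt(1 - alpha, df), df, ncp = ncp, lower.tail = FALSE)
  } else {
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-crit, df, ncp = ncp)
  }
}

#' Minimum sample size for a paired t test
#'
#' Smallest `n` at which [paired_t_power()] reaches the requested power,
#' found by iterating `n` upward from 2 with the exact noncentral-t
#' evaluation (no normal approximation).
#'
#' @inheritParams paired_t_power
#' @param power Requested power, in (alpha, 1).
#' @param n_max Safety cap on the search.
#' @return Integer sample size.
#' @examples
#' required_sample_size(0.62, alpha = 0.05, power = 0.95, tails = "one") # 30
#' @export
required_sample_size <- function(effect_dz, alpha = 0.05, power = 0.95,
                                 tails = c("one", "two"), n_max = 1e5) {
  tails <- match.arg(tails)
  stopifnot(effect_dz > 0, alpha > 0, alpha < 1, power > 0, power < 1,
            power > alpha)
  n <- 2L
  while (paired_t_power(n, effect_dz, alpha, tails) < power) {
    n <- n + 1L
    if (n > n_max) stop("no n <= n_max reaches the requested power")
  }
  n
}

# Stimulus-class-conditional type 1 d' of a trial subset: signal = second
# sorted stimulus class, hits = P(respond signal | signal).
type1_dprime <- function(trials, stimulus_levels = sort(unique(trials$stimulus))) {
  s2 <- trials$stimulus == stimulus_levels[2]
  r2 <- trials$response == stimulus_levels[2]
  dprime(rates_from_counts(hits = sum(s2 & r2), misses = sum(s2 & !r2),
                           fas = sum(!s2 & r2), crs = sum(!s2 & !r2)))
}

#' Type 1 sensitivity split by confidence shift direction
#'
#' For each participant, computes the type 1 d' separately on up-shift and
#' down-shift trials. If re-evaluation tracks accuracy, up-shift trials
#' should carry higher type 1 sensitivity.
#'
#' @param trials Cohort trial data.frame (`participant_id`, `stimulus`,
#'   `response`, `shift`).
#' @return A data.frame with columns `participant_id`, `d_up`, `d_down`.
#' @export
shift_split_type1 <- function(trials) {
  lv <- sort(unique(trials$stimulus))
  split_tr <- split(trials, trials$participant_id)
  out <- do.call(rbind, lapply(names(split_tr), function(id) {
    tr <- split_tr[[id]]
    data.frame(participant_id = id,
               d_up = type1_dprime(tr[tr$shift == "UP", , drop = FALSE], lv),
               d_down = type1_dprime(tr[tr$shift == "DOWN", , drop = FALSE], lv),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Full group-level report for an analysed cohort
#'
#' Runs the complete battery of group comparisons on an included cohort:
#' the three pairwise meta-d' contrasts (second vs first, combined vs
#' first, combined vs second), type 1 d' on up- vs down-shift trials, the
#' second-step d' against its permutation chance level, the second-step
#' criterion against zero, and the up- vs down-shift trial counts. Also
#' returns cohort descriptives (accuracy mean +/- SE, extreme-trial
#' percentage, mean up/down counts).
#'
#' @param trials Included cohort trial data.frame.
#' @param n_bins Confidence bins for the meta-d' fits.
#' @param n_permutations Permutations per participant for the chance level.
#' @param seed Master seed for the permutation streams.
#' @param tails Tail convention for every comparison.
#' @return A list of class `cohort_report`: `comparisons` (one row per
#'   comparison: `comparison`, `t`, `df`, `p`, `cohen_dz`, `mean_diff`,
#'   `ci_lo`, `ci_hi`), `descriptives`, and the underlying tables
#'   (`meta_d`, `second_step`, `shift_split`, `summaries`).
#' @export
full_report <- function(trials, n_bins = 5L, n_permutations = 1000L,
                        seed = 1L, tails = "two") {
  summaries <- participant_summaries(trials)
  md <- meta_d_table(trials, n_bins = n_bins)
  ss <- second_step_analysis(trials, n_permutations = n_permutations,
                             seed = seed, tails = tails)
  sp <- shift_split_type1(trials)

  md_w <- stats::reshape(md[c("participant_id", "stream", "meta_d")],
                         idvar = "participant_id", timevar = "stream",
                         direction = "wide")
  names(md_w) <- sub("^meta_d\\.", "", names(md_w))

  comparisons <- list(
    `meta-d' second vs first` = paired_t(md_w$second, md_w$first, tails),
    `meta-d' combined vs first` = paired_t(md_w$combined, md_w$first, tails),
    `meta-d' combined vs second` = paired_t(md_w$combined, md_w$second, tails),
    `type 1 d' up vs down shifts` = paired_t(sp$d_up, sp$d_down, tails),
    `second-step d' vs chance` = ss$d2_vs_chance,
    `second-step c vs zero` = ss$c2_vs_zero,
    `up vs down shift counts` = paired_t(summaries$n_up, summaries$n_down,
                                         tails)
  )
  comp_tab <- do.call(rbind, lapply(names(comparisons), function(nm) {
    r <- comparisons[[nm]]
    data.frame(comparison = nm, t = r$t_stat, df = r$df, p = r$p_value,
               cohen_dz = r$cohen_dz, mean_diff = r$mean_diff,
               ci_lo = r$ci95[1], ci_hi = r$ci95[2],
               stringsAsFactors = FALSE)
  }))

  n <- nrow(summaries)
  desc <- data.frame(
    n_participants = n,
    accuracy_mean = mean(summaries$type1_accuracy),
    accuracy_se = stats::sd(summaries$type1_accuracy) / sqrt(n),
    extreme_pct = 100 * sum(summaries$n_extreme) / sum(summaries$n_trials),
    mean_n_up = mean(summaries$n_up),
    mean_n_down = mean(summaries$n_down))

  structure(list(comparisons = comp_tab, descriptives = desc,
                 meta_d = md, second_step = ss$table, shift_split = sp,
                 summaries = summaries),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  d <- x$descriptives
  cat(sprintf(paste0("cohort_report: %d participants, accuracy %.3f +/- ",
                     "%.3f (SE), %.1f%% extreme trials\n"),
              d$n_participants, d$accuracy_mean, d$accuracy_se,
              d$extreme_pct))
  print(x$comparisons, digits = 3)
  invisible(x)
}
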