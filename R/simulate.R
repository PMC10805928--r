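#' Session configuration for the two-step confidence paradigm
#'
#' Bundles the structural constants of one experimental session: an ensemble
#' discrimination between two shape classes on a square grid, a
#' two-up-one-down staircase on the class ratio, and a discrete confidence
#' scale used twice per trial. Defaults reproduce the reference design:
#' 450 trials in 9 blocks of 50, a 7x7 (49-element) array, and a 0-100
#' confidence scale in steps of 10 treated as ten rating levels
#' {10, 20, ..., 100}.
#'
#' @param n_trials Total trials per session; must be divisible by `n_blocks`.
#' @param n_blocks Number of blocks.
#' @param grid_total Number of elements in the stimulus array.
#' @param scale_values Strictly increasing numeric vector of confidence
#'   scale positions; its length defines the number of rating levels.
#' @param staircase_start_majority Majority-class count at the start of the
#'   staircase.
#' @param staircase_step Elements added/removed per staircase adjustment.
#' @param min_majority Floor for the majority count; must exceed
#'   `grid_total / 2` so a majority always exists.
#' @param max_majority Ceiling for the majority count. The default leaves at
#'   least 10 minority elements visible.
#' @return An object of class `session_config` (a validated list).
#' @export
session_config <- function(n_trials = 450L,
                           n_blocks = 9L,
                           grid_total = 49L,
                           scale_values = seq(10, 100, by = 10),
                           staircase_start_majority = 32L,
                           staircase_step = 1L,
                           min_majority = 25L,
                           max_majority = grid_total - 10L) {
  cfg <- list(n_trials = as.integer(n_trials),
              n_blocks = as.integer(n_blocks),
              grid_total = as.integer(grid_total),
              n_scale_levels = length(scale_values),
              scale_values = as.numeric(scale_values),
              staircase_start_majority = as.integer(staircase_start_majority),
              staircase_step = as.integer(staircase_step),
              min_majority = as.integer(min_majority),
              max_majority = as.integer(max_majority))
  class(cfg) <- "session_config"
  validate_session_config(cfg)
}

validate_session_config <- function(cfg) {
  with(cfg, {
    if (n_trials < 1L || n_blocks < 1L || n_trials %% n_blocks != 0L)
      stop("n_trials must be a positive multiple of n_blocks")
    if (n_scale_levels < 2L || any(diff(scale_values) <= 0))
      stop("scale_values must be strictly increasing with length >= 2")
    if (min_majority * 2L <= grid_total)
      stop("min_majority must exceed grid_total / 2")
    if (staircase_start_majority < min_majority ||
        staircase_start_majority > max_majority)
      stop("staircase_start_majority must lie in [min_majority, max_majority]")
    if (max_majority > grid_total)
      stop("max_majority cannot exceed grid_total")
    if (staircase_step < 1L) stop("staircase_step must be >= 1")
  })
  cfg
}

#' Generative observer parameters
#'
#' Parameters of the signal-detection observer used to simulate sessions.
#' The observer sees Gaussian evidence whose mean grows with the stimulus
#' ratio imbalance, makes the type 1 choice against a criterion, and forms
#' each confidence report from the same evidence corrupted by its own
#' metacognitive noise draw. The two noise draws may be correlated, so the
#' two reports can be made partially independent — the mechanism under
#' study: a less noisy second report yields higher second-interval
#' metacognitive sensitivity downstream.
#'
#' @param sensitivity_slope Type 1 d' contributed per element of ratio
#'   imbalance (majority minus minority count). The default 0.22 puts the
#'   staircase equilibrium near a 27:22 ratio on a 49-element grid, i.e.
#'   around 70% accuracy.
#' @param type1_criterion Decision criterion on the evidence axis.
#' @param meta_noise_sd_1,meta_noise_sd_2 SDs of the zero-mean Gaussian
#'   noise added to the evidence before the first / second confidence
#'   report. Defaults make the second report the less noisy one.
#' @param meta_noise_corr Correlation of the two noise draws, in [-1, 1].
#' @param confidence_criteria Strictly increasing thresholds partitioning
#'   the noise-normalised absolute decision evidence
#'   `|y_i - type1_criterion| / sqrt(1 + sd_i^2)` into the rating levels
#'   (each report is calibrated to its own evidence spread); length must be
#'   one less than the number of scale levels.
#' @param criteria_scale_2 Multiplier applied to `confidence_criteria` for
#'   the second report only — the confidence-mapping calibration of the
#'   re-evaluation. The default 0.9 makes the default observer's expected
#'   second-step criterion zero, i.e. no systematic bias towards up- or
#'   down-shifts.
#' @param lapse_rate Probability of a uniformly random type 1 response.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(sensitivity_slope = 0.22,
                            type1_criterion = 0,
                            meta_noise_sd_1 = 1.0,
                            meta_noise_sd_2 = 0.5,
                            meta_noise_corr = 0.4,
                            confidence_criteria = seq(0.2, 2.6, by = 0.3),
                            criteria_scale_2 = 0.9,
                            lapse_rate = 0) {
  obs <- list(sensitivity_slope = sensitivity_slope,
              type1_criterion = type1_criterion,
              meta_noise_sd_1 = meta_noise_sd_1,
              meta_noise_sd_2 = meta_noise_sd_2,
              meta_noise_corr = meta_noise_corr,
              confidence_criteria = as.numeric(confidence_criteria),
              criteria_scale_2 = criteria_scale_2,
              lapse_rate = lapse_rate)
  class(obs) <- "observer_params"
  validate_observer_params(obs)
}

validate_observer_params <- function(obs) {
  with(obs, {
    if (sensitivity_slope < 0) stop("sensitivity_slope must be >= 0")
    if (meta_noise_sd_1 < 0 || meta_noise_sd_2 < 0)
      stop("metacognitive noise SDs must be >= 0")
    if (abs(meta_noise_corr) > 1)
      stop("meta_noise_corr must lie in [-1, 1]")
    if (any(diff(confidence_criteria) <= 0))
      stop("confidence_criteria must be strictly increasing")
    if (criteria_scale_2 <= 0)
      stop("criteria_scale_2 must be > 0")
    if (lapse_rate < 0 || lapse_rate >= 1)
      stop("lapse_rate must lie in [0, 1)")
  })
  obs
}

#' Create a staircase state
#'
#' @param majority_count Current majority-class element count.
#' @param consecutive_correct Running streak of correct responses.
#' @return An object of class `staircase_state`.
#' @export
staircase_state <- function(majority_count, consecutive_correct = 0L) {
  structure(list(majority_count = as.integer(majority_count),
                 consecutive_correct = as.integer(consecutive_correct)),
            class = "staircase_state")
}

#' Two-up-one-down staircase update
#'
#' After two consecutive correct responses the majority count shrinks by
#' `step` (the task gets harder) and the streak resets; after any error the
#' majority count grows by `step` and the streak resets. The count is
#' clamped to `[floor, ceiling]`. This rule converges on the ~70.7%-correct
#' point of the psychometric function.
#'
#' @param state A [staircase_state()].
#' @param correct Logical: was the type 1 response correct?
#' @param step,floor,ceiling Staircase step size and majority-count bounds
#'   (defaults match [session_config()]).
#' @return The updated `staircase_state`.
#' @export
staircase_update <- function(state, correct, step = 1L, floor = 25L,
                             ceiling = 39L) {
  maj <- state$majority_count
  if (isTRUE(correct)) {
    streak <- state$consecutive_correct + 1L
    if (streak >= 2L) {
      maj <- maj - as.integer(step)
      streak <- 0L
    }
  } else {
    maj <- maj + as.integer(step)
    streak <- 0L
  }
  maj <- min(max(maj, as.integer(floor)), as.integer(ceiling))
  staircase_state(maj, streak)
}

# Map absolute confidence evidence to a rating level in 1..K through the
# K-1 ordered thresholds.
conf_level <- function(abs_evidence, criteria) {
  findInterval(abs_evidence, criteria) + 1L
}

#' Simulate one trial of the two-step paradigm
#'
#' Draws sensory evidence, the type 1 response, and the two confidence
#' reports for a single trial, consuming the current R random stream (seed
#' management belongs to [simulate_session()]). Evidence is
#' `x ~ N(+/- slope * imbalance / 2, 1)` with the sign set by the stimulus
#' class. Each confidence report i forms `y_i = x + eps_i`, where
#' `(eps_1, eps_2)` is a zero-mean bivariate Gaussian with the observer's
#' noise SDs and correlation, and thresholds the noise-normalised absolute
#' evidence `|y_i - c| / sqrt(1 + sd_i^2)` through the confidence criteria
#' (scaled by `criteria_scale_2` for the second report) — an observer
#' calibrated to the spread of its own confidence evidence.
#'
#' If the first rating lands on either endpoint of the scale the trial ends
#' early: `conf2` is `NA` and the shift label is `"EXTREME"`. Otherwise the
#' second rating may not repeat the first: on a collision it is nudged one
#' level in the direction of the raw second-evidence strength (ties nudge
#' down), mimicking a forced re-evaluation with minimal distortion.
#'
#' Per-trial random draws, in fixed order: lapse uniform, lapse-response
#' uniform, evidence normal, two standard-normal noise factors. All five are
#' consumed every trial so the stream position is branch-independent.
#'
#' @param config A [session_config()].
#' @param observer An [observer_params()].
#' @param state A [staircase_state()]; supplies the current majority count.
#' @param stimulus_class `"X"` or `"O"` (which class predominates).
#' @return A one-row data.frame with columns `majority_count`, `stimulus`,
#'   `response`, `correct`, `conf1`, `conf2` (scale values; `conf2` `NA` on
#'   extreme trials) and `shift` (`"UP"`, `"DOWN"` or `"EXTREME"`).
#' @export
sample_trial <- function(config, observer, state, stimulus_class) {
  imbalance <- 2L * state$majority_count - config$grid_total
  if (imbalance < 1L) stop("invalid stimulus: majority count gives imbalance < 1")
  stopifnot(stimulus_class %in% c("X", "O"))

  u_lapse <- stats::runif(1)
  u_resp <- stats::runif(1)
  z_x <- stats::rnorm(1)
  z1 <- stats::rnorm(1)
  z2 <- stats::rnorm(1)

  sign_mu <- if (stimulus_class == "X") 1 else -1
  mu <- sign_mu * observer$sensitivity_slope * imbalance / 2
  x <- mu + z_x

  if (u_lapse < observer$lapse_rate) {
    response <- if (u_resp < 0.5) "X" else "O"
  } else {
    response <- if (x > observer$type1_criterion) "X" else "O"
  }
  correct <- response == stimulus_class

  rho <- observer$meta_noise_corr
  sd1 <- observer$meta_noise_sd_1
  sd2 <- observer$meta_noise_sd_2
  y1 <- x + sd1 * z1
  y2 <- x + sd2 * (rho * z1 + sqrt(1 - rho^2) * z2)

  crit <- observer$confidence_criteria
  c1 <- observer$type1_criterion
  k <- config$n_scale_levels
  # criterion-relative confidence strengths, each normalised by its own
  # evidence SD; the second report additionally rescaled by its mapping
  a1 <- abs(y1 - c1) / sqrt(1 + sd1^2)
  a2 <- abs(y2 - c1) / sqrt(1 + sd2^2) / observer$criteria_scale_2
  lev1 <- conf_level(a1, crit)

  if (lev1 == 1L || lev1 == k) {
    lev2 <- NA_integer_
    shift <- "EXTREME"
  } else {
    lev2 <- conf_level(a2, crit)
    if (lev2 == lev1) {
      dir <- if (a2 > a1) 1L else -1L
      lev2 <- lev1 + dir
    }
    shift <- if (lev2 > lev1) "UP" else "DOWN"
  }

  data.frame(majority_count = state$majority_count,
             stimulus = stimulus_class,
             response = response,
             correct = correct,
             conf1 = config$scale_values[lev1],
             conf2 = if (is.na(lev2)) NA_real_ else config$scale_values[lev2],
             shift = shift,
             stringsAsFactors = FALSE)
}

#' Simulate a full session
#'
#' Runs `n_trials` trials for one simulated participant: stimulus classes
#' are balanced-random across the session, the staircase state is threaded
#' through every trial, and blocks are assigned in order. One seeded stream
#' drives the whole session (stimulus order first, then the per-trial draws
#' of [sample_trial()] in their documented order), so identical
#' `(config, observer, seed)` give byte-identical output.
#'
#' @inheritParams sample_trial
#' @param participant_id Identifier recorded on every row.
#' @param seed Integer seed for the session stream.
#' @return A data.frame of trial records with columns `participant_id`,
#'   `block`, `trial`, `majority_count`, `stimulus`, `response`, `correct`,
#'   `conf1`, `conf2`, `shift`.
#' @examples
#' s <- simulate_session(session_config(), observer_params(), "p01", seed = 7)
#' nrow(s)              # 450
#' table(s$block)       # 9 blocks of 50
#' @export
simulate_session <- function(config = session_config(),
                             observer = observer_params(),
                             participant_id = "sim01",
                             seed = 1L) {
  validate_session_config(config)
  validate_observer_params(observer)
  if (length(observer$confidence_criteria) != config$n_scale_levels - 1L)
    stop("confidence_criteria length must be n_scale_levels - 1")
  set.seed(as.integer(seed))

  n <- config$n_trials
  half <- n %/% 2L
  classes <- sample(c(rep("X", half), rep("O", n - half)))
  state <- staircase_state(config$staircase_start_majority)
  per_block <- n %/% config$n_blocks

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- sample_trial(config, observer, state, classes[i])
    tr$participant_id <- participant_id
    tr$block <- ((i - 1L) %/% per_block) + 1L
    tr$trial <- i
    rows[[i]] <- tr
    state <- staircase_update(state, tr$correct,
                              step = config$staircase_step,
                              floor = config$min_majority,
                              ceiling = config$max_majority)
  }
  out <- do.call(rbind, rows)
  out[c("participant_id", "block", "trial", "majority_count", "stimulus",
        "response", "correct", "conf1", "conf2", "shift")]
}

#' Simulate a cohort of participants
#'
#' Fans a master seed out into one independent session seed per participant
#' (drawn from a stream seeded with the master seed), so individual
#' participants can be re-simulated stably.
#'
#' @inheritParams simulate_session
#' @param n_participants Cohort size.
#' @param observer Either a single [observer_params()] applied to everyone,
#'   or a list of one `observer_params` per participant (individual
#'   differences).
#' @param seed Master seed.
#' @return A data.frame of trial records for the whole cohort.
#' @export
simulate_cohort <- function(n_participants = 20L,
                            config = session_config(),
                            observer = observer_params(),
                            seed = 1L) {
  stopifnot(n_participants >= 1L)
  observers <- if (inherits(observer, "observer_params")) {
    rep(list(observer), n_participants)
  } else {
    stopifnot(length(observer) == n_participants)
    observer
  }
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_participants)
  ids <- sprintf("sim%02d", seq_len(n_participants))
  do.call(rbind, lapply(seq_len(n_participants), function(i) {
    simulate_session(config, observers[[i]], ids[i], seeds[i])
  }))
}
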