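# Shared fixtures, all generated in code at test time.

# Hand-built trial table with known shift structure (no simulator involved).
make_trials <- function(correct, shift, participant_id = "p1",
                        stimulus = NULL, response = NULL) {
  n <- length(correct)
  stopifnot(length(shift) == n)
  conf1 <- rep(50, n)
  conf2 <- ifelse(shift == "UP", 60, ifelse(shift == "DOWN", 40, NA_real_))
  conf1[shift == "EXTREME"] <- 100
  if (is.null(stimulus)) stimulus <- rep(c("X", "O"), length.out = n)
  if (is.null(response))
    response <- ifelse(correct, stimulus, ifelse(stimulus == "X", "O", "X"))
  data.frame(participant_id = participant_id, block = 1L, trial = seq_len(n),
             majority_count = 27L, stimulus = stimulus, response = response,
             correct = correct, conf1 = conf1, conf2 = conf2, shift = shift,
             stringsAsFactors = FALSE)
}

# Type 2 counts simulated from the equal-variance SDT observer itself:
# confidence is a deterministic function of the decision variable, so the
# generative meta-d' equals the generative d'.
sim_sdt_counts <- function(n, d, criterion = 0, t2 = c(0.5, 1.2),
                           seed = 1) {
  set.seed(seed)
  stim <- sample(rep(c("a", "b"), length.out = n))
  x <- rnorm(n, ifelse(stim == "b", d / 2, -d / 2))
  resp <- ifelse(x > criterion, "b", "a")
  bin <- findInterval(abs(x - criterion), t2) + 1L
  type2_counts_from_vectors(stim, resp, bin, length(t2) + 1L,
                            stimulus_levels = c("a", "b"))
}

# Memoised small default cohort shared across test files.
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(6, session_config(), observer_params(),
                                seed = 42)
    cache
  }
})
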