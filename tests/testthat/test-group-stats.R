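test_that("paired t follows the hand formulas", {
  r <- paired_t(c(2, 3, 4), c(1, 1, 1))   # differences 1, 2, 3
  expect_equal(r$t_stat, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(r$df, 2)
  expect_equal(r$cohen_dz, 2)
  expect_equal(r$mean_diff, 2)

  # antisymmetry under exchanging the roles
  rr <- paired_t(c(1, 1, 1), c(2, 3, 4))
  expect_equal(rr$t_stat, -r$t_stat)
  expect_equal(rr$cohen_dz, -r$cohen_dz)

  expect_error(paired_t(1:3, 1:3), "zero-variance")
  expect_error(paired_t(1:3, 1:2), "equal length")
})

test_that("paired t matches the reference implementation on random inputs", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n, 0.3)
    y <- rnorm(n)
    two <- paired_t(x, y, "two")
    ref2 <- t.test(x, y, paired = TRUE)
    expect_equal(two$t_stat, unname(ref2$statistic), tolerance = 1e-8)
    expect_equal(two$p_value, ref2$p.value, tolerance = 1e-8)
    expect_equal(two$ci95, as.numeric(ref2$conf.int), tolerance = 1e-8)
    one <- paired_t(x, y, "one")
    ref1 <- t.test(x, y, paired = TRUE, alternative = "greater")
    expect_equal(one$p_value, ref1$p.value, tolerance = 1e-8)
  }
})

test_that("required_sample_size satisfies its defining power property", {
  cases <- expand.grid(dz = c(0.3, 0.62, 1.0), power = c(0.8, 0.95),
                       tails = c("one", "two"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    dz <- cases$dz[i]; pw <- cases$power[i]; tl <- cases$tails[i]
    n <- required_sample_size(dz, 0.05, pw, tl)
    expect_gte(paired_t_power(n, dz, 0.05, tl), pw)
    if (n > 2) expect_lt(paired_t_power(n - 1, dz, 0.05, tl), pw)
  }
  # monotone: larger effects need no more participants
  ns <- vapply(seq(0.2, 1.2, by = 0.1), required_sample_size,
               integer(1), alpha = 0.05, power = 0.95, tails = "one")
  expect_true(all(diff(ns) <= 0))

  expect_error(required_sample_size(0), "effect_dz")
})

test_that("the directional power analysis reproduces the planning n of 30", {
  expect_identical(required_sample_size(0.62, alpha = 0.05, power = 0.95,
                                        tails = "one"), 30L)
})

test_that("type 1 d' split by shift direction behaves as expected", {
  # identical subsets -> identical d'
  sub <- make_trials(rep(c(TRUE, TRUE, TRUE, FALSE), 25), rep("UP", 100))
  tr <- rbind(sub, transform(sub, shift = "DOWN"))
  sp <- shift_split_type1(tr)
  expect_equal(sp$d_up, sp$d_down)

  # shifts assigned at random -> d' approximately equal across subsets
  set.seed(29)
  n <- 20000
  stim <- sample(c("X", "O"), n, replace = TRUE)
  x <- rnorm(n, ifelse(stim == "X", 0.55, -0.55))
  resp <- ifelse(x > 0, "X", "O")
  tr2 <- make_trials(resp == stim, ifelse(runif(n) < 0.5, "UP", "DOWN"),
                     stimulus = stim, response = resp)
  sp2 <- shift_split_type1(tr2)
  expect_lt(abs(sp2$d_up - sp2$d_down), 0.1)
})

test_that("up/down count comparison is calibrated under equal propensity", {
  # shifts assigned by fair coin, independently per trial: up- and
  # down-shift propensities are equal by construction
  set.seed(37)
  p_vals <- vapply(1:10, function(i) {
    s <- participant_summaries(do.call(rbind, lapply(1:8, function(j) {
      make_trials(runif(400) < 0.7, ifelse(runif(400) < 0.5, "UP", "DOWN"),
                  participant_id = sprintf("p%d", j))
    })))
    paired_t(s$n_up, s$n_down)$p_value
  }, numeric(1))
  expect_lte(sum(p_vals < 0.05), 2)
})

test_that("the full report enumerates all seven comparisons and is
           deterministic given the cohort", {
  co <- default_cohort()
  rep1 <- full_report(co, n_permutations = 200, seed = 6)
  expect_equal(nrow(rep1$comparisons), 7)
  expect_setequal(
    rep1$comparisons$comparison,
    c("meta-d' second vs first", "meta-d' combined vs first",
      "meta-d' combined vs second", "type 1 d' up vs down shifts",
      "second-step d' vs chance", "second-step c vs zero",
      "up vs down shift counts"))
  expect_true(all(is.finite(rep1$comparisons$t)))
  expect_equal(rep1$descriptives$n_participants, 6)
  expect_true(rep1$descriptives$extreme_pct > 0 &&
                rep1$descriptives$extreme_pct < 100)

  rep2 <- full_report(co, n_permutations = 200, seed = 6)
  expect_identical(rep1$comparisons, rep2$comparisons)
})
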