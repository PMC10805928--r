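test_that("staircase follows the two-up-one-down rule with clamping", {
  s <- staircase_state(27, 1)
  up2 <- staircase_update(s, TRUE)
  expect_equal(up2$majority_count, 26)     # second correct in a row: harder
  expect_equal(up2$consecutive_correct, 0)

  s0 <- staircase_state(27, 0)
  expect_equal(staircase_update(s0, TRUE)$consecutive_correct, 1)
  expect_equal(staircase_update(s0, TRUE)$majority_count, 27)

  err <- staircase_update(s0, FALSE)       # any error: easier
  expect_equal(err$majority_count, 28)
  expect_equal(err$consecutive_correct, 0)

  floor_hit <- staircase_update(staircase_state(25, 1), TRUE)
  expect_equal(floor_hit$majority_count, 25)   # clamped at floor
  ceil_hit <- staircase_update(staircase_state(39, 0), FALSE)
  expect_equal(ceil_hit$majority_count, 39)    # clamped at ceiling
})

test_that("session structure and shift partition hold", {
  s <- simulate_session(seed = 11)
  expect_equal(nrow(s), 450)
  expect_equal(as.vector(table(s$block)), rep(50, 9))
  expect_setequal(unique(s$shift), c("UP", "DOWN", "EXTREME"))
  expect_equal(sum(s$shift %in% c("UP", "DOWN", "EXTREME")), 450)

  # extreme <=> conf1 at an endpoint <=> no second rating
  ext <- s$shift == "EXTREME"
  expect_true(all(is.na(s$conf2[ext])))
  expect_true(all(s$conf1[ext] %in% c(10, 100)))
  expect_true(all(!is.na(s$conf2[!ext])))
  expect_true(all(s$conf1[!ext] > 10 & s$conf1[!ext] < 100))

  # the second rating never repeats the first, and UP/DOWN match the signs
  expect_true(all(s$conf2[!ext] != s$conf1[!ext]))
  expect_true(all((s$conf2 > s$conf1)[s$shift == "UP"]))
  expect_true(all((s$conf2 < s$conf1)[s$shift == "DOWN"]))

  expect_true(all(s$majority_count >= 25 & s$majority_count <= 39))
})

test_that("same seed gives identical sessions, different seeds differ", {
  a <- simulate_session(seed = 5)
  b <- simulate_session(seed = 5)
  expect_identical(a, b)
  c <- simulate_session(seed = 6)
  expect_false(identical(a, c))
})

test_that("a zero-sensitivity observer performs at chance", {
  cfg <- session_config(n_trials = 10000L, n_blocks = 1L)
  obs <- observer_params(sensitivity_slope = 0)
  s <- simulate_session(cfg, obs, seed = 21)
  # binomial 99.9% band around 0.5 at n = 10000 is about +/- 0.0165
  expect_lt(abs(mean(s$correct) - 0.5), 0.017)
})

test_that("accuracy is monotone in sensitivity at a fixed ratio", {
  # staircase pinned: floor = start = ceiling, so the ratio never moves;
  # a common seed gives common evidence draws, making the comparison exact
  cfg <- session_config(n_trials = 2000L, n_blocks = 1L,
                        staircase_start_majority = 27L, min_majority = 27L,
                        max_majority = 27L)
  accs <- vapply(c(0, 0.1, 0.22, 0.5), function(sl) {
    mean(simulate_session(cfg, observer_params(sensitivity_slope = sl),
                          seed = 31)$correct)
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("with zero metacognitive noise and a shared mapping, the forced
           re-evaluation moves exactly one level", {
  obs <- observer_params(meta_noise_sd_1 = 0, meta_noise_sd_2 = 0,
                         criteria_scale_2 = 1)
  s <- simulate_session(observer = obs, seed = 41)
  ne <- s$shift != "EXTREME"
  expect_true(all(abs(s$conf2[ne] - s$conf1[ne]) == 10))
})

test_that("lapses drive accuracy toward chance and invalid stimuli are rejected", {
  cfg <- session_config(n_trials = 4000L, n_blocks = 1L,
                        staircase_start_majority = 35L, min_majority = 35L,
                        max_majority = 35L)
  acc_lapse <- mean(simulate_session(cfg, observer_params(lapse_rate = 0.5),
                                     seed = 51)$correct)
  acc_clean <- mean(simulate_session(cfg, observer_params(), seed = 51)$correct)
  expect_lt(acc_lapse, acc_clean - 0.05)

  bad_cfg <- session_config()
  expect_error(
    sample_trial(bad_cfg, observer_params(), staircase_state(24), "X"),
    "imbalance")
})

test_that("cohort simulation threads one seed into stable per-participant data", {
  co <- simulate_cohort(3, seed = 9)
  expect_equal(length(unique(co$participant_id)), 3)
  expect_equal(nrow(co), 3 * 450)
  co2 <- simulate_cohort(3, seed = 9)
  expect_identical(co, co2)
})
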