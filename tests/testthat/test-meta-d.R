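test_that("type 2 counts land in the documented cells", {
  # two class-1 trials answered class 1 at top confidence fill the first
  # cell of counts_s1 (highest-confidence class-1 response)
  tr <- data.frame(stimulus = c("O", "O"), response = c("O", "O"),
                   conf1 = c(100, 100), conf2 = c(90, 90),
                   shift = c("DOWN", "DOWN"), stringsAsFactors = FALSE)
  cnt <- build_type2_counts(tr, "first", n_bins = 5,
                            stimulus_levels = c("O", "X"))
  expect_equal(cnt$counts_s1[1], 2)
  expect_equal(sum(cnt$counts_s1), 2)
  expect_equal(sum(cnt$counts_s2), 0)

  # K equal to the number of scale levels: bin index = rating index
  tr2 <- data.frame(stimulus = "O", response = "X", conf1 = 30, conf2 = 40,
                    shift = "UP", stringsAsFactors = FALSE)
  cnt2 <- build_type2_counts(tr2, "first", n_bins = 10,
                             stimulus_levels = c("O", "X"))
  expect_equal(cnt2$counts_s1[10 + 3], 1)   # response class 2, conf bin 3

  # a trial-averaged half-step value falls in the right 20-wide bin
  tr3 <- data.frame(stimulus = "X", response = "X", conf1 = 90, conf2 = 100,
                    shift = "UP", stringsAsFactors = FALSE)
  cnt3 <- build_type2_counts(tr3, "combined", n_bins = 5,
                             stimulus_levels = c("O", "X"))
  expect_equal(cnt3$counts_s2[5 + 5], 1)    # (90+100)/2 = 95 -> bin 5

  expect_error(build_type2_counts(make_trials(TRUE, "EXTREME"), "first"),
               "EXTREME")
})

test_that("meta-d' recovers d' when confidence is a deterministic function
           of the decision variable", {
  cnt <- sim_sdt_counts(6000, d = 1.4, criterion = 0.1, seed = 7)
  fit <- fit_meta_d(cnt)
  expect_true(fit$converged)
  expect_lt(abs(fit$meta_d - fit$d1), 0.15)
})

test_that("shuffling confidence within response groups destroys meta-d'", {
  set.seed(8)
  n <- 6000; d <- 1.4
  stim <- sample(rep(c("a", "b"), length.out = n))
  x <- rnorm(n, ifelse(stim == "b", d / 2, -d / 2))
  resp <- ifelse(x > 0, "b", "a")
  bin <- findInterval(abs(x), c(0.5, 1.2)) + 1L
  for (r in c("a", "b")) bin[resp == r] <- sample(bin[resp == r])
  fit <- fit_meta_d(type2_counts_from_vectors(stim, resp, bin, 3,
                                              stimulus_levels = c("a", "b")))
  expect_lt(abs(fit$meta_d), 0.15)
})

test_that("optimiser beats the naive fit and matches a grid-search oracle", {
  for (s in 1:2) {
    cnt <- sim_sdt_counts(250, d = 1.2, criterion = 0.1, seed = 100 + s)
    fit <- fit_meta_d(cnt)
    # likelihood at the optimum is at least that of meta_d fixed at d1
    expect_gte(fit$log_likelihood + 1e-6,
               fit_meta_d_fixed(cnt, fit$d1)$log_likelihood)
    # coarse grid (0.05) cross-check; the fine grid runs in the acceptance suite
    grid <- seq(0.05, 3, by = 0.05)
    ll <- vapply(grid, function(m) fit_meta_d_fixed(cnt, m)$log_likelihood,
                 numeric(1))
    expect_lt(abs(fit$meta_d - grid[which.max(ll)]), 0.051)
  }
})

test_that("relabelling the stimulus classes negates c1 and preserves meta-d'", {
  cnt <- sim_sdt_counts(400, d = 1.3, criterion = 0.25, seed = 13)
  mirrored <- structure(list(n_bins = cnt$n_bins,
                             counts_s1 = rev(cnt$counts_s2),
                             counts_s2 = rev(cnt$counts_s1),
                             stimulus_levels = rev(cnt$stimulus_levels)),
                        class = "type2_counts")
  f1 <- fit_meta_d(cnt)
  f2 <- fit_meta_d(mirrored)
  expect_equal(f2$c1, -f1$c1, tolerance = 1e-9)
  expect_equal(f2$d1, f1$d1, tolerance = 1e-9)
  expect_equal(f2$meta_d, f1$meta_d, tolerance = 1e-4)
})

test_that("predicted type 2 cell probabilities are proper distributions", {
  pr <- metashift:::type2_cell_probs(1.3, 0.2, c(-0.3, -0.9), c(0.8, 1.5))
  for (s in 1:2) {
    expect_equal(sum(pr[[s]]$resp1), 1, tolerance = 1e-8)
    expect_equal(sum(pr[[s]]$resp2), 1, tolerance = 1e-8)
    expect_true(all(pr[[s]]$resp1 > 0) && all(pr[[s]]$resp2 > 0))
  }
})

test_that("degenerate one-bin tables return meta_d = 0 with a warning", {
  cnt <- type2_counts_from_vectors(
    stimulus = rep(c("a", "b"), each = 20),
    response = rep(c("a", "b", "b", "a"), each = 10),
    bin = rep(2L, 40), n_bins = 3, stimulus_levels = c("a", "b"))
  expect_warning(fit <- fit_meta_d(cnt), "one bin")
  expect_equal(fit$meta_d, 0)
  expect_true(fit$degenerate)
})

test_that("the three profile fits share the trial set and type 1 summary", {
  co <- default_cohort()
  tr <- co[co$participant_id == "sim01", ]
  fits <- meta_d_profile(tr, n_bins = 5)
  expect_named(fits, c("first", "second", "combined"))
  expect_equal(fits$first$d1, fits$second$d1)
  expect_equal(fits$first$d1, fits$combined$d1)
  expect_equal(fits$first$c1, fits$second$c1)
  expect_true(all(vapply(fits, `[[`, logical(1), "converged")))

  # identical confidence streams give identical fits
  tr_same <- tr[tr$shift != "EXTREME", ]
  tr_same$conf2 <- tr_same$conf1  # counts builder does not forbid equality
  c_first <- build_type2_counts(tr_same, "first", 5)
  c_second <- build_type2_counts(tr_same, "second", 5)
  expect_identical(c_first$counts_s1, c_second$counts_s1)
  expect_identical(c_first$counts_s2, c_second$counts_s2)
  expect_equal(fit_meta_d(c_first)$meta_d, fit_meta_d(c_second)$meta_d,
               tolerance = 1e-8)
})

test_that("meta_d_table stacks per-participant fits in long format", {
  co <- default_cohort()
  tab <- meta_d_table(co[co$participant_id %in% c("sim01", "sim02"), ])
  expect_equal(nrow(tab), 6)
  expect_setequal(tab$stream, c("first", "second", "combined"))
})
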