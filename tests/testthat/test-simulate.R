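test_that("sampled parameters respect their ranges and degenerate ranges pin values", {
  set.seed(1)
  draws <- sample_params("value", n = 1000)
  rng <- param_ranges()
  expect_true(all(draws$lam >= rng$lam[1] & draws$lam <= rng$lam[2]))
  expect_true(all(draws$alpha >= rng$alpha[1] & draws$alpha <= rng$alpha[2]))
  expect_true(all(draws$omega %in% c(0, 1)))
  fixed <- sample_params("value", n = 5, ranges = list(lam = c(3, 3)))
  expect_equal(fixed$lam, rep(3, 5))
  expect_error(sample_params("perceptual", ranges = list(rho = c(-0.1, 0.5))),
               "outside the model bounds")
  d1 <- sample_params("perceptual", n = 4, seed = 99)
  d2 <- sample_params("perceptual", n = 4, seed = 99)
  expect_identical(d1, d2)
})

test_that("learning blocks use exact reinforcement counts and biased ratings", {
  l <- simulate_learning(0.25, seed = 1)
  expect_equal(sum(l$reinforced), 6)
  expect_equal(nrow(l), 24)
  expect_true(all(is.na(l$rating[-c(12, 24)])))
  expect_false(anyNA(l$rating[c(12, 24)]))
  expect_error(simulate_learning(0.3), "not an integer")
  # bernoulli mode allows off-design rates
  expect_silent(simulate_learning(0.3, bernoulli = TRUE, seed = 1))
  # zero noise, zero bias: the final rating is the reinforcement rate itself
  l0 <- simulate_learning(0.5, bias = 0, noise_sd = 0, seed = 2)
  expect_equal(l0$rating[24], 0.5)
})

test_that("cohort-mean final learning ratings land near the observed group means", {
  set.seed(4)
  means <- vapply(c(0.25, 0.5, 0.75), function(rr) {
    mean(vapply(1:400, function(i) {
      l <- simulate_learning(rr)
      l$rating[24]
    }, numeric(1)))
  }, numeric(1))
  expect_equal(means, c(0.31, 0.54, 0.77), tolerance = 0.03)
})

test_that("generalisation blocks reproduce the mechanism-specific signatures", {
  sp <- test_space()
  # perceptual: bimodal ratings at the GSs, clustering at alpha and v + alpha;
  # a d = 1 neighbour is mistaken for the CS+ with probability rho = 0.3
  per <- simulate_generalisation("perceptual",
                                 perceptual_params(0.3, alpha = 0, sigma = 0.02),
                                 v = 0.8, sp, n_reps = 60, seed = 2)
  gs <- dplyr::filter(per, stimulus %in% c(4, 6))
  near0 <- mean(gs$rating < 0.1)
  near_v <- mean(gs$rating > 0.7)
  expect_gt(near0 + near_v, 0.95)
  expect_gt(near0, 0.5)
  expect_gt(near_v, 0.15)
  # value, sigma -> 0: ratings equal the kernel curve exactly
  va <- simulate_generalisation("value",
                                value_params(3, alpha = 0.05, sigma = 1e-12),
                                v = 0.6, sp, seed = 3)
  pred <- predict_value(value_params(3, alpha = 0.05), v = 0.6, sp)
  expect_equal(va$rating, pred$prediction[va$stimulus], tolerance = 1e-9)
  # monotonic peak-left: mean ratings strictly decreasing left to right
  mono <- simulate_generalisation("value",
                                  value_params(4, omega = 0, sigma = 1e-6),
                                  v = 0.5, sp, seed = 4)
  m <- vapply(1:9, function(s) mean(mono$rating[mono$stimulus == s]),
              numeric(1))
  expect_true(all(diff(m) < 0))
})

test_that("cohorts have the full design structure and are reproducible", {
  cfg <- generative_config(n_participants = 2, seed = 77)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$participants), 2)
  # 6 conditions x (24 learning + 36 generalisation) per participant
  counts <- dplyr::count(co$trials, participant, condition_rr, condition_disc,
                         phase)
  expect_equal(nrow(counts), 2 * 6 * 2)
  expect_true(all(counts$n[counts$phase == "learning"] == 24))
  expect_true(all(counts$n[counts$phase == "generalisation"] == 36))
  expect_true(all(co$trials$rating >= 0 & co$trials$rating <= 1, na.rm = TRUE))
  expect_true(all(co$truth$delta_kappa > 0 & co$truth$delta_kappa <= 0.125))
  co2 <- simulate_cohort(cfg)
  expect_identical(co$trials, co2$trials)
  expect_identical(co$participants, co2$participants)
})

test_that("mechanism and pattern frequencies converge to the configured mixes", {
  cfg <- generative_config(n_participants = 800, seed = 11,
                           anxiety_mechanism_coupling = 0)
  co <- simulate_cohort(cfg)
  p_val <- mean(co$participants$mechanism == "value")
  expect_equal(p_val, 0.8476, tolerance = 0.05)
  p_mono <- mean(co$participants$base_omega == 0)
  expect_equal(p_mono, 0.5512, tolerance = 0.08)
  # anxiety distribution: floored at 21, right-skewed, mean near 29.3
  anx <- co$participants$anxiety
  expect_true(all(anx >= 21))
  expect_equal(mean(anx), 29.4, tolerance = 0.05 * 29.4)
  expect_gt(mean(anx) - stats::median(anx), 0)
  # null coupling: anxiety unrelated to mechanism
  r_pb <- cor(anx, as.numeric(co$participants$mechanism == "value"))
  expect_lt(abs(r_pb), 0.1)
})

test_that("cohort mean gradients show the qualitative mechanism shapes", {
  cfg <- generative_config(n_participants = 40, seed = 13)
  co <- simulate_cohort(cfg)
  gen <- dplyr::filter(co$trials, phase == "generalisation")
  lab <- co$truth[, c("participant", "condition_rr", "condition_disc",
                      "mechanism", "omega", "peak_side")]
  df <- dplyr::left_join(gen, lab,
                         by = c("participant", "condition_rr", "condition_disc"))
  prof <- function(sub) {
    vapply(1:9, function(s) mean(sub$rating[sub$stimulus == s]), numeric(1))
  }
  per <- prof(dplyr::filter(df, mechanism == "perceptual"))
  expect_equal(which.max(per), 5)
  gaus <- prof(dplyr::filter(df, mechanism == "value", omega == 1))
  expect_equal(which.max(gaus), 5)
  monoL <- prof(dplyr::filter(df, mechanism == "value", omega == 0,
                              peak_side == "left"))
  expect_gt(mean(monoL[1:3]), mean(monoL[7:9]))
})
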