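test_that("right-peaked gradients are flipped and flipping is an involution", {
  inc <- seq(0.1, 0.9, by = 0.1)
  res <- flip_and_standardise(inc, cs_mean = 0.5, pattern = "gaussian")
  expect_true(res$flipped)
  expect_equal(res$gradient, rev(inc))
  # flipping the flipped gradient restores the original
  res2 <- flip_and_standardise(res$gradient, cs_mean = 0.5, pattern = "gaussian")
  expect_false(res2$flipped)
  expect_equal(res2$gradient, res$gradient)
  expect_equal(rev(res$gradient), inc)
  # symmetric gaussian gradient passes through untouched
  sym <- c(0.1, 0.2, 0.4, 0.7, 0.9, 0.7, 0.4, 0.2, 0.1)
  res3 <- flip_and_standardise(sym, cs_mean = 0.9, pattern = "gaussian")
  expect_false(res3$flipped)
  expect_equal(res3$gradient, sym)
  expect_error(flip_and_standardise(sym[1:5], 0.5), "9 values")
})

test_that("the CS+-referenced transform rewrites the left-of-CS+ stimuli", {
  mono <- c(0.8, 0.75, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1)
  res <- flip_and_standardise(mono, cs_mean = 0.5, pattern = "monotonic")
  expect_false(res$flipped)
  # literal rule: cs_mean - rating for stimuli 1..4
  expect_equal(res$gradient[1], 0.5 - 0.8)
  expect_equal(res$gradient[1:4], 0.5 - mono[1:4])
  expect_equal(res$gradient[5:9], mono[5:9])
  # reflection alternative
  refl <- flip_and_standardise(mono, cs_mean = 0.5, pattern = "monotonic",
                               method = "reflect")
  expect_equal(refl$gradient[1:4], 2 * 0.5 - mono[1:4])
})

test_that("AUC follows the trapezoidal rule", {
  expect_equal(gradient_auc(rep(1, 9)), 8)
  expect_equal(gradient_auc(c(0, 0, 0, 0, 1, 0, 0, 0, 0)), 1)
  g <- c(0.2, 0.5, 0.3, 0.8, 0.9, 0.6, 0.4, 0.3, 0.1)
  expect_equal(gradient_auc(3 * g), 3 * gradient_auc(g))
  expect_error(gradient_auc(0.5), "at least 2")
  # fine-grid riemann oracle on the piecewise-linear interpolant
  xs <- seq(0, 8, length.out = 400001)
  riemann <- mean(approx(0:8, g, xout = xs)$y[-1] +
                    approx(0:8, g, xout = xs)$y[-length(xs)]) / 2 * 8
  expect_equal(gradient_auc(g), riemann, tolerance = 1e-10)
})

test_that("pattern classification reads Omega and majorities handle ties", {
  trials <- make_block("value", value_params(3, omega = 1, sigma = 0.05),
                       seed = 8)
  fit <- fast_fit(trials, "value", v = 0.7, seed = 1)
  expect_equal(classify_pattern(fit), "gaussian")
  fitp <- fast_fit(trials, "perceptual", v = 0.7, seed = 1)
  expect_error(classify_pattern(fitp), "value-model")
  expect_equal(
    majority_pattern(c("monotonic", "monotonic", "monotonic", "monotonic",
                       "gaussian", "gaussian"))$pattern,
    "monotonic"
  )
  tie <- majority_pattern(rep(c("monotonic", "gaussian"), 3))
  expect_true(is.na(tie$pattern))
  expect_true(tie$tie)
})

test_that("anxiety association returns a seeded bootstrap interval", {
  set.seed(2)
  x <- rnorm(60)
  y <- 0.3 * x + rnorm(60)
  a1 <- anxiety_association(x, y, n_boot = 500, seed = 4)
  a2 <- anxiety_association(x, y, n_boot = 500, seed = 4)
  expect_identical(a1, a2)
  expect_equal(a1$r, cor(x, y))
  expect_lt(a1$ci_lower, a1$r)
  expect_gt(a1$ci_upper, a1$r)
  expect_equal(anxiety_association(x, x, n_boot = 200, seed = 1)$r, 1)
  expect_error(anxiety_association(x, rep(1, 60)), "Zero variance")
  expect_error(anxiety_association(x, y[1:10]), "equal length")
})

test_that("null-coupling bootstrap intervals cover zero at the nominal rate", {
  # coverage spot-check: independent vectors, the 95% CI should cover 0 in
  # most replicates (binomial slack at 25 replicates)
  set.seed(6)
  covered <- vapply(1:25, function(i) {
    x <- rnorm(40)
    y <- rnorm(40)
    ci <- anxiety_association(x, y, n_boot = 300, seed = i)
    ci$ci_lower <= 0 && ci$ci_upper >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.8)
})

test_that("gradient summaries join AUC, winner, pattern and estimates", {
  co <- simulate_cohort(generative_config(n_participants = 2, seed = 19))
  sub <- dplyr::filter(co$trials, condition_disc == 0.8)
  fits <- fit_models(sub, models = c("perceptual", "value"), n_restarts = 2,
                     seed = 1, maxeval_global = 100)
  anx <- co$participants[, c("participant", "anxiety")]
  summ <- summarise_gradients(sub, fits, anxiety = anx)
  expect_equal(nrow(summ), 2 * 3)  # 2 participants x 3 conditions
  expect_true(all(c("auc", "winner", "relative_fit", "pattern", "anxiety",
                    "value_lam", "perceptual_rho") %in% names(summ)))
  expect_true(all(summ$auc >= 0))
  expect_true(all(is.na(summ$pattern) | summ$winner == "value"))
})

test_that("fitted lam and AUC correlate positively across synthetic gradients", {
  sp <- test_space()
  set.seed(14)
  n <- 50
  lams <- runif(n, 0.3, 8)
  res <- vapply(seq_len(n), function(i) {
    tr <- simulate_generalisation("value",
                                  value_params(lams[i], omega = 1, sigma = 0.1),
                                  v = 0.7, sp)
    fit <- fit_gradient(tr, "value", v = 0.7, sp, n_restarts = 1, omega = 1,
                        seed = i, maxeval_global = 80)
    grad <- vapply(1:9, function(s) mean(tr$rating[tr$stimulus == s]),
                   numeric(1))
    c(lam = fit$params$lam, auc = gradient_auc(grad))
  }, numeric(2))
  expect_gt(cor(res["lam", ], res["auc", ], method = "spearman"), 0)
})
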