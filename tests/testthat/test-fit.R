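test_that("near-noiseless value data are recovered to high precision", {
  sp <- test_space()
  params <- value_params(3, omega = 1, alpha = 0.1, sigma = 1e-3)
  trials <- make_block("value", params, v = 0.7, seed = 11)
  fit <- fast_fit(trials, "value", v = 0.7, seed = 1)
  expect_equal(fit$params$omega, 1)
  expect_lt(abs(fit$params$lam - 3), 1e-2)
  expect_lt(abs(fit$params$alpha - 0.1), 1e-3)
})

test_that("perceptual data with no confusion yield a near-zero fitted rho", {
  sp <- test_space()
  params <- perceptual_params(0, alpha = 0.05, sigma = 0.08)
  trials <- make_block("perceptual", params, v = 0.7, seed = 5)
  fit <- fast_fit(trials, "perceptual", v = 0.7, seed = 1)
  expect_lt(fit$params$rho, 0.05)
})

test_that("fitting is deterministic given the seed", {
  trials <- make_block("value", value_params(2, omega = 0, sigma = 0.15),
                       seed = 9)
  f1 <- fast_fit(trials, "value", v = 0.6, seed = 123)
  f2 <- fast_fit(trials, "value", v = 0.6, seed = 123)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$nll, f2$nll)
  expect_identical(f1$best_restart, f2$best_restart)
})

test_that("omega is enumerated and the better kernel shape wins", {
  mono <- make_block("value", value_params(3, omega = 0, sigma = 0.05),
                     seed = 21)
  fit <- fast_fit(mono, "value", v = 0.7, seed = 1)
  expect_equal(fit$params$omega, 0)
  expect_equal(nrow(fit$omega_trace), 2)
  gauss <- make_block("value", value_params(3, omega = 1, sigma = 0.05),
                      seed = 22)
  fit2 <- fast_fit(gauss, "value", v = 0.7, seed = 1)
  expect_equal(fit2$params$omega, 1)
})

test_that("comparison picks the lowest BIC and reports relative fit", {
  trials <- make_block("value", value_params(3, sigma = 0.1), seed = 31)
  fv <- fast_fit(trials, "value", v = 0.7, seed = 1)
  fp <- fast_fit(trials, "perceptual", v = 0.7, seed = 1)
  cmp <- compare_fits(list(fp, fv))
  expect_equal(cmp$winner, "value")
  expect_equal(cmp$relative_fit, fp$bic - fv$bic)
  expect_gt(cmp$relative_fit, 0)
  expect_false(cmp$tie)
  # three models give a single winner and all pairwise differences
  fh <- fast_fit(trials, "hybrid", v = 0.7, seed = 1)
  cmp3 <- compare_fits(list(fp, fv, fh))
  expect_length(cmp3$winner, 1)
  expect_equal(nrow(cmp3$pairwise), 6)
})

test_that("comparison refuses fits of different data", {
  t1 <- make_block("value", value_params(3, sigma = 0.1), seed = 1)
  t2 <- make_block("value", value_params(3, sigma = 0.1), seed = 2)
  f1 <- fast_fit(t1, "value", v = 0.7, seed = 1)
  f2 <- fast_fit(t2, "perceptual", v = 0.7, seed = 1)
  expect_error(compare_fits(list(f1, f2)), "different data")
  expect_error(compare_fits(list(f1)), "at least two")
})

test_that("BIC selection is invariant to a constant shift of all log densities", {
  # shifting every per-trial log density by c adds 2 * n * c to every model's
  # BIC, so the argmin is unchanged
  nlls <- c(perceptual = 40, value = 35)
  n <- 36
  shift <- 7.3
  b0 <- c(bic(nlls[1], 3, n), bic(nlls[2], 3, n))
  b1 <- c(bic(nlls[1] + n * shift, 3, n), bic(nlls[2] + n * shift, 3, n))
  expect_equal(which.min(b0), which.min(b1))
  expect_equal(unname(b1 - b0), rep(2 * n * shift, 2))
})

test_that("fit_models extracts CS+ values, flips right-peaked gradients and fits", {
  co <- simulate_cohort(generative_config(n_participants = 2, seed = 33))
  one <- dplyr::filter(co$trials, participant == "sub001",
                       condition_rr == 0.5, condition_disc == 0.8)
  tbl <- fit_models(one, models = c("perceptual", "value"), n_restarts = 2,
                    seed = 1, maxeval_global = 100)
  expect_equal(nrow(tbl), 2)
  expect_true(all(c("nll", "bic", "v", "flipped") %in% names(tbl)))
  truth_v <- dplyr::filter(co$truth, participant == "sub001",
                           condition_rr == 0.5, condition_disc == 0.8)$v
  expect_equal(unique(tbl$v), truth_v)
  cmp <- compare_models(tbl)
  expect_equal(nrow(cmp), 1)
  expect_true(cmp$winner %in% c("perceptual", "value"))
})
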