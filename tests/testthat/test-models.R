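test_that("parameter constructors enforce bounds", {
  expect_error(perceptual_params(1.2), "rho")
  expect_error(perceptual_params(0.5, alpha = 1.5), "alpha")
  expect_error(perceptual_params(0.5, sigma = 0), "sigma")
  expect_error(value_params(0), "lam")
  expect_error(value_params(11), "lam")
  expect_error(value_params(3, omega = 0.5), "omega")
  expect_s3_class(hybrid_params(0.3, 2), "gen_params")
})

test_that("misperception matrix has the stated diagonal and decay", {
  sp <- test_space()
  expect_equal(misperception_matrix(0, sp), diag(9))
  for (rho in c(0.1, 0.5, 0.9, 1)) {
    P <- misperception_matrix(rho, sp)
    expect_equal(rowSums(P), rep(1, 9))
    expect_equal(unname(diag(P)), rep(1 - rho, 9))
  }
  # hand-derived: rho = 0.5, shown = 5; off-diagonal weights 0.5^d over
  # d in 1..4 on both sides sum to 1.875, so each d = 1 neighbour gets
  # 0.5 * 0.5 / 1.875
  P <- misperception_matrix(0.5, sp)
  expect_equal(P[5, 4], 0.5 * 0.5 / 1.875)
  expect_equal(P[5, 6], 0.5 * 0.5 / 1.875)
  # confusion decays with distance
  expect_true(all(diff(P[5, 6:9]) < 0))
  expect_error(misperception_matrix(1.1, sp), "rho")
})

test_that("value-model predictions follow y = alpha + v * G", {
  sp <- test_space()
  # stick limit: kernel collapses onto the CS+
  p <- predict_value(value_params(1e-9, omega = 1), v = 0.5, sp)
  expect_equal(p$prediction, c(0, 0, 0, 0, 0.5, 0, 0, 0, 0), tolerance = 1e-6)
  # gaussian value at d = 4 with v = 1
  p2 <- predict_value(value_params(10, omega = 1), v = 1, sp)
  expect_equal(p2$prediction[1], 2 / (1 + exp(1.6)))
  # value term vanishes at v = 0
  p3 <- predict_value(value_params(3, alpha = 0.2), v = 0, sp)
  expect_equal(p3$prediction, rep(0.2, 9))
})

test_that("perceptual-model mixtures weight the CS+ component by P(cs|s)", {
  sp <- test_space()
  # no confusion: single components
  p <- predict_perceptual(perceptual_params(0), v = 0.6, sp)
  cs_row <- dplyr::filter(p, stimulus == 5)
  expect_equal(nrow(cs_row), 1)
  expect_equal(cs_row$mean, 0.6)
  gs_row <- dplyr::filter(p, stimulus == 2)
  expect_equal(gs_row$mean, 0)
  # rho = 0.5, shown at d = 1 (stimulus 4): the CS+ is perceived with
  # probability rho^1, the literal distance-decay rule
  p2 <- predict_perceptual(perceptual_params(0.5), v = 0.6, sp)
  w_cs <- dplyr::filter(p2, stimulus == 4, perceived == 5)$weight
  expect_equal(w_cs, 0.5)
  # weights per shown stimulus sum to 1
  sums <- dplyr::summarise(dplyr::group_by(p2, stimulus), s = sum(weight))$s
  expect_equal(sums, rep(1, 9))
})

test_that("hybrid model nests the value and perceptual models", {
  sp <- test_space()
  grid <- expand.grid(lam = c(0.5, 3, 8), alpha = c(-0.2, 0, 0.3),
                      v = c(0.3, 0.8), omega = c(0, 1))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    hy <- predict_hybrid(hybrid_params(0, g$lam, omega = g$omega,
                                       alpha = g$alpha), v = g$v, sp)
    va <- predict_value(value_params(g$lam, omega = g$omega, alpha = g$alpha),
                        v = g$v, sp)
    # rho = 0: hybrid collapses to the value model exactly
    expect_equal(hy$mean, va$prediction, tolerance = 1e-10)
    expect_equal(hy$weight, rep(1, 9), tolerance = 1e-10)
  }
  for (rho in c(0.2, 0.6)) {
    hy <- predict_hybrid(hybrid_params(rho, 1e-12, alpha = 0), v = 0.7, sp)
    pe <- predict_perceptual(perceptual_params(rho), v = 0.7, sp)
    # lam -> 0, alpha = 0: the value function becomes the CS+ stick
    expect_equal(hy$weight, pe$weight, tolerance = 1e-10)
    expect_equal(hy$mean, pe$mean, tolerance = 1e-10)
  }
})

test_that("the perceptual model's average profile is unimodal at the CS+", {
  sp <- test_space()
  p <- predict_perceptual(perceptual_params(0.4, alpha = 0.05), v = 0.7, sp)
  avg <- dplyr::summarise(dplyr::group_by(p, stimulus),
                          m = sum(weight * mean))$m
  expect_equal(which.max(avg), 5)
  expect_true(all(diff(avg[1:5]) > 0))
  expect_true(all(diff(avg[5:9]) < 0))
})
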