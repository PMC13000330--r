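# independent censored-normal mass via numerical integration of the normal pdf
cens_mass_below0 <- function(mu, sigma) {
  stats::integrate(function(x) dnorm(x, mu, sigma), -Inf, 0,
                   rel.tol = 1e-12)$value
}
cens_mass_above1 <- function(mu, sigma) {
  stats::integrate(function(x) dnorm(x, mu, sigma), 1, Inf,
                   rel.tol = 1e-12)$value
}

# brute-force per-trial density of a mixture model, written independently of
# the package's vectorised path
oracle_nll <- function(trials, model, params, v, space) {
  P <- if (model == "value") diag(9) else misperception_matrix(params$rho, space)
  means <- switch(model,
    value = ,
    hybrid = predict_value(params, v, space)$prediction,
    perceptual = pmin(pmax(params$alpha +
      ifelse(1:9 == space$cs_index, v, 0), 0), 1)
  )
  ll <- 0
  for (t in seq_len(nrow(trials))) {
    s <- trials$stimulus[t]
    r <- trials$rating[t]
    dens <- 0
    for (q in 1:9) {
      w <- P[s, q]
      if (w == 0) next
      f <- if (r <= 0) cens_mass_below0(means[q], params$sigma)
      else if (r >= 1) cens_mass_above1(means[q], params$sigma)
      else dnorm(r, means[q], params$sigma)
      dens <- dens + w * f
    }
    ll <- ll + log(dens)
  }
  -ll
}

test_that("nll matches brute-force numerical evaluation of the censored mixture", {
  sp <- test_space()
  ratings <- c(0, 0.25, 0.5, 0.75, 1)
  trials <- tibble::tibble(
    stimulus = rep(c(1, 3, 5, 7, 9), each = 5),
    rating = rep(ratings, 5)
  )
  cases <- list(
    list(model = "perceptual", params = perceptual_params(0.4, alpha = 0.1,
                                                          sigma = 0.15)),
    list(model = "value", params = value_params(3, omega = 1, alpha = -0.05,
                                                sigma = 0.2)),
    list(model = "value", params = value_params(2, omega = 0, alpha = 0.1,
                                                sigma = 0.1)),
    list(model = "hybrid", params = hybrid_params(0.3, 2, omega = 1,
                                                  alpha = 0, sigma = 0.12))
  )
  for (cs in cases) {
    expect_equal(
      nll_gradient(trials, cs$model, cs$params, v = 0.65, sp),
      oracle_nll(trials, cs$model, cs$params, v = 0.65, sp),
      tolerance = 1e-8
    )
  }
})

test_that("zero residuals leave only the gaussian normalising constants", {
  sp <- test_space()
  sigma <- 0.1
  # alpha-only predictions: flat interior profile at 0.2
  params <- value_params(3, alpha = 0.2, sigma = sigma)
  trials <- tibble::tibble(stimulus = rep(1:9, 2), rating = rep(0.2, 18))
  expect_equal(nll_gradient(trials, "value", params, v = 0, sp),
               nrow(trials) * log(sigma * sqrt(2 * pi)))
})

test_that("censored mass at the bound is a half for a mean-zero component", {
  sp <- test_space()
  # rho = 0, shown GS, alpha = 0: prediction 0; a rating of exactly 0 carries
  # the clipped lower-tail mass Phi(0) = 0.5
  params <- perceptual_params(0, alpha = 0, sigma = 0.2)
  trials <- tibble::tibble(stimulus = 2, rating = 0)
  expect_equal(nll_gradient(trials, "perceptual", params, v = 0.7, sp), log(2))
})

test_that("a single-component mixture equals the plain model likelihood", {
  sp <- test_space()
  trials <- make_block("value", value_params(3, sigma = 0.1), seed = 3)
  val <- value_params(2.5, alpha = 0.05, sigma = 0.12)
  hyb <- hybrid_params(0, 2.5, alpha = 0.05, sigma = 0.12)
  expect_equal(nll_gradient(trials, "hybrid", hyb, v = 0.7, sp),
               nll_gradient(trials, "value", val, v = 0.7, sp))
})

test_that("likelihood rejects empty or out-of-range input", {
  sp <- test_space()
  empty <- tibble::tibble(stimulus = integer(), rating = numeric())
  expect_error(nll_gradient(empty, "value", value_params(3), 0.5, sp), "empty")
  bad <- tibble::tibble(stimulus = 1, rating = 1.5)
  expect_error(nll_gradient(bad, "value", value_params(3), 0.5, sp), "0, 1")
})

test_that("bic follows k log n + 2 nll and validates its inputs", {
  expect_equal(bic(10, 3, 36), 3 * log(36) + 20)
  expect_error(bic(10, 0, 36), "k")
  expect_error(bic(10, 3, 0), "n")
  # linear in nll at fixed k, n
  expect_equal(bic(20, 3, 36) - bic(10, 3, 36), 20)
})
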