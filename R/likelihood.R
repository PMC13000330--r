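# Censored-normal observation stage -----------------------------------------
#
# Ratings come from a 0-100% slider, rescaled to [0, 1]. A large share of
# ratings sits exactly at 0, so the observation density is a normal
# censored at the slider bounds: interior ratings get the normal density,
# ratings of exactly 0 or 1 get the probability mass of the clipped tail.

# log censored-normal density, vectorised over (r, mu); sigma scalar
log_dcensnorm <- function(r, mu, sigma) {
  out <- dnorm(r, mu, sigma, log = TRUE)
  at0 <- r <= 0
  at1 <- r >= 1
  if (any(at0)) out[at0] <- pnorm(0, mu[at0], sigma, log.p = TRUE)
  if (any(at1)) out[at1] <- pnorm(1, mu[at1], sigma, lower.tail = FALSE, log.p = TRUE)
  out
}

# row-wise log-sum-exp for an n x K matrix of log terms (pmax across columns
# rather than apply(): this sits on the optimiser's hot path)
logsumexp_rows <- function(m) {
  mx <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}

#' Negative log likelihood of generalisation ratings
#'
#' Trial-level likelihood of ratings under a generalisation model. The
#' observation density is a normal censored at the slider bounds \[0, 1\]
#' (point masses at 0 and 1 from the clipped tails) with scale `sigma`;
#' for the perceptual and hybrid models the density is marginalised over the
#' perceived-stimulus mixture (log-sum-exp guarded).
#'
#' @param trials A tibble of generalisation-phase trials with columns
#'   `stimulus` (1..9) and `rating` (in \[0, 1\]).
#' @param model `"perceptual"`, `"value"` or `"hybrid"`.
#' @param params Matching `gen_params` object.
#' @param v Learned CS+ outcome expectancy in \[0, 1\].
#' @param space A `stimulus_space` (only index distances enter the models).
#' @return The negative log likelihood (scalar).
#' @examples
#' sp <- build_space(0.05)
#' tr <- tibble::tibble(stimulus = rep(1:9, 2), rating = rep(0.2, 18))
#' nll_gradient(tr, "value", value_params(lam = 3, sigma = 0.1), v = 0.6, sp)
#' @export
nll_gradient <- function(trials, model, params, v, space) {
  model <- match.arg(model, c("perceptual", "value", "hybrid"))
  if (nrow(trials) == 0) abort("Cannot evaluate the likelihood of an empty trial set.")
  if (any(trials$rating < 0 | trials$rating > 1)) {
    abort("Ratings must lie in [0, 1] (rescale 0-100 slider values first).")
  }
  comp <- mixture_components(model, params, v, space)
  s <- trials$stimulus
  mu <- comp$mean[s, , drop = FALSE]       # n_trials x K component means
  ld <- log_dcensnorm(trials$rating, mu, params$sigma)
  dim(ld) <- dim(mu)
  if (ncol(mu) == 1) return(-sum(ld))      # single-component models
  lw <- log(comp$weight[s, , drop = FALSE])
  -sum(logsumexp_rows(lw + ld))
}

#' Bayesian Information Criterion
#'
#' `BIC = k * log(n) + 2 * nll`, the model-selection score used to compare
#' the perceptual, value and hybrid fits.
#'
#' @param nll Minimised negative log likelihood.
#' @param k Number of free parameters (>= 1; every model has at least one).
#' @param n Number of fitted trials (>= 1).
#' @return The BIC (scalar).
#' @examples
#' bic(10, k = 3, n = 36)
#' @export
bic <- function(nll, k, n) {
  if (k < 1) abort("`k` must be >= 1: every model has at least one free parameter.")
  if (n < 1) abort("`n` must be >= 1.")
  k * log(n) + 2 * nll
}
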