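#' Parameter sets for the generalisation models
#'
#' Constructors validate parameter bounds and return classed lists used by
#' the prediction, likelihood and simulation functions.
#'
#' * **Perceptual model**: `rho` in \[0, 1\] controls the probability of
#'   misidentifying the shown stimulus; responses reflect the value of the
#'   *perceived* stimulus (the CS+ value `v` if the CS+ is perceived, else 0),
#'   plus a constant offset `alpha` in \[-1, 1\].
#' * **Value model**: the learned CS+ value transfers to neighbours through a
#'   similarity kernel of strength `lam` in (0, 10\], Gaussian-like
#'   (`omega = 1`) or monotonic (`omega = 0`, peaking on `peak_side`).
#' * **Hybrid model**: value transfer plus misidentification (union of both
#'   parameter sets).
#'
#' All models share an observation-noise scale `sigma > 0` of the
#' censored-normal rating stage.
#'
#' @param rho Confusion parameter in \[0, 1\].
#' @param lam Generalisation strength in (0, 10].
#' @param omega Kernel shape: 1 = Gaussian-like, 0 = monotonic.
#' @param alpha Constant offset in \[-1, 1\].
#' @param peak_side `"left"` or `"right"`; used only when `omega = 0`.
#' @param sigma Rating-noise scale, > 0 (floored at 1e-3 during fitting).
#' @return A list of class `gen_params` (and a model-specific subclass).
#' @name model_params
NULL

#' @rdname model_params
#' @export
perceptual_params <- function(rho, alpha = 0, sigma = 0.1) {
  assert_scalar_in(rho, 0, 1, "rho")
  assert_scalar_in(alpha, -1, 1, "alpha")
  assert_scalar_in(sigma, 0, Inf, "sigma", open_lo = TRUE)
  structure(list(rho = rho, alpha = alpha, sigma = sigma),
            class = c("perceptual_params", "gen_params"))
}

#' @rdname model_params
#' @export
value_params <- function(lam, omega = 1, alpha = 0, peak_side = "left", sigma = 0.1) {
  assert_scalar_in(lam, 0, 10, "lam", open_lo = TRUE)
  if (!omega %in% c(0, 1)) abort("`omega` must be 0 (monotonic) or 1 (Gaussian-like).")
  assert_scalar_in(alpha, -1, 1, "alpha")
  assert_scalar_in(sigma, 0, Inf, "sigma", open_lo = TRUE)
  peak_side <- match.arg(peak_side, c("left", "right"))
  structure(list(lam = lam, omega = omega, alpha = alpha,
                 peak_side = peak_side, sigma = sigma),
            class = c("value_params", "gen_params"))
}

#' @rdname model_params
#' @export
hybrid_params <- function(rho, lam, omega = 1, alpha = 0, peak_side = "left",
                          sigma = 0.1) {
  assert_scalar_in(rho, 0, 1, "rho")
  assert_scalar_in(lam, 0, 10, "lam", open_lo = TRUE)
  if (!omega %in% c(0, 1)) abort("`omega` must be 0 (monotonic) or 1 (Gaussian-like).")
  assert_scalar_in(alpha, -1, 1, "alpha")
  assert_scalar_in(sigma, 0, Inf, "sigma", open_lo = TRUE)
  peak_side <- match.arg(peak_side, c("left", "right"))
  structure(list(rho = rho, lam = lam, omega = omega, alpha = alpha,
                 peak_side = peak_side, sigma = sigma),
            class = c("hybrid_params", "gen_params"))
}

#' @export
print.gen_params <- function(x, ...) {
  cat("<", class(x)[1], "> ", sep = "")
  vals <- unlist(x[vapply(x, is.numeric, logical(1))])
  cat(paste(names(vals), format(vals, digits = 4), sep = "="), sep = "  ")
  cat("\n")
  invisible(x)
}

#' Stimulus misidentification probabilities
#'
#' The 9 x 9 table `P(q | s)` giving the probability of perceiving stimulus
#' `q` when stimulus `s` is shown. The table honours both statements of the
#' confusion model exactly: the shown stimulus is perceived correctly with
#' probability `1 - rho`, and a generalisation stimulus is mistaken for the
#' CS+ with probability `rho^d` decaying in stimulus distance `d`. The
#' confusion mass left over in each row (`rho - rho^d(s, cs)`) is spread
#' over the remaining stimuli with the same `rho^d` distance weights,
#' renormalised so every row sums to 1; for the CS+ row itself the whole
#' mass `rho` is distance-weighted over the 8 generalisation stimuli.
#' `rho = 0` yields the identity table (no confusion).
#'
#' Only the CS+ column drives the perceptual model's predictions (perceiving
#' any generalisation stimulus predicts the same zero value), so the
#' CS+-anchored entries carry all of the behavioural signal; the spread of
#' the remainder matters only for the hybrid model.
#'
#' @param rho Confusion parameter in \[0, 1\].
#' @param space A `stimulus_space`.
#' @return A 9 x 9 numeric matrix; rows index the shown stimulus `s`,
#'   columns the perceived stimulus `q`. Rows sum to 1.
#' @examples
#' sp <- build_space(0.05)
#' rowSums(misperception_matrix(0.3, sp))
#' @export
misperception_matrix <- function(rho, space) {
  assert_scalar_in(rho, 0, 1, "rho")
  stopifnot(inherits(space, "stimulus_space"))
  n <- length(space$kappa_values)
  cs <- space$cs_index
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  if (rho == 0) return(diag(n))
  W <- rho^d
  diag(W) <- 0
  # rows other than the CS+: the CS+ column gets the literal rho^d entry and
  # the remaining confusion mass is spread over the rest by the same weights
  restW <- W
  restW[, cs] <- 0
  rest_mass <- pmax(rho - W[, cs], 0)
  denom <- rowSums(restW)
  P <- restW * ifelse(denom > 0, rest_mass / denom, 0)
  P[, cs] <- W[, cs]
  # CS+ row: all confusion mass rho, distance-weighted
  P[cs, ] <- rho * W[cs, ] / sum(W[cs, ])
  diag(P) <- 1 - rho
  P
}

# per-stimulus kernel profile over the whole continuum (length 9)
kernel_profile <- function(params, space) {
  pos <- seq_along(space$kappa_values) - space$cs_index
  if (params$omega == 1) {
    gaussian_kernel(abs(pos), params$lam)
  } else {
    monotonic_kernel(pos, params$lam, params$peak_side)
  }
}

#' Mean rating predictions of the value model
#'
#' Trial-wise prediction `y_s = alpha + v * G(s)` where `G` is the
#' Gaussian-like or monotonic kernel. Predictions are clamped to \[0, 1\]
#' before the observation stage, since ratings live on a bounded slider.
#'
#' @param params A `value_params` (or `hybrid_params`; only the kernel part
#'   is used).
#' @param v Learned CS+ outcome expectancy in \[0, 1\] (the participant's
#'   final learning-phase rating).
#' @param space A `stimulus_space`.
#' @return A tibble with columns `stimulus`, `prediction`.
#' @examples
#' sp <- build_space(0.05)
#' predict_value(value_params(lam = 3), v = 0.7, sp)
#' @export
predict_value <- function(params, v, space) {
  assert_scalar_in(v, 0, 1, "v")
  g <- kernel_profile(params, space)
  tibble(
    stimulus = seq_along(space$kappa_values),
    prediction = clamp(params$alpha + v * g)
  )
}

#' Mixture predictions of the perceptual model
#'
#' For each shown stimulus `s` the model predicts a two-point mixture: with
#' probability `P(cs | s)` the CS+ is perceived and the rating centres on
#' `v + alpha`; otherwise a generalisation stimulus is perceived and the
#' rating centres on `alpha`. Component means are clamped to \[0, 1\].
#'
#' @param params A `perceptual_params`.
#' @inheritParams predict_value
#' @return A tibble with columns `stimulus`, `perceived`, `weight`, `mean`:
#'   one row per (shown, perceived) pair with positive weight.
#' @export
predict_perceptual <- function(params, v, space) {
  assert_scalar_in(v, 0, 1, "v")
  P <- misperception_matrix(params$rho, space)
  n <- length(space$kappa_values)
  comp_mean <- clamp(params$alpha + ifelse(seq_len(n) == space$cs_index, v, 0))
  out <- tidyr::expand_grid(stimulus = seq_len(n), perceived = seq_len(n))
  out$weight <- as.vector(t(P))[(out$stimulus - 1) * n + out$perceived]
  out$mean <- comp_mean[out$perceived]
  dplyr::filter(out, .data$weight > 0)
}

#' Mixture predictions of the hybrid model
#'
#' Value transfer plus misidentification: a perceived stimulus `q` is drawn
#' from the misperception row of the shown stimulus, and the rating centres
#' on the value-model prediction evaluated at `q`. With `rho = 0` this
#' reduces exactly to the value model; with `lam -> 0` and `alpha = 0` to
#' the perceptual model.
#'
#' @param params A `hybrid_params`.
#' @inheritParams predict_value
#' @return A tibble with columns `stimulus`, `perceived`, `weight`, `mean`.
#' @export
predict_hybrid <- function(params, v, space) {
  assert_scalar_in(v, 0, 1, "v")
  P <- misperception_matrix(params$rho, space)
  n <- length(space$kappa_values)
  comp_mean <- predict_value(params, v, space)$prediction
  out <- tidyr::expand_grid(stimulus = seq_len(n), perceived = seq_len(n))
  out$weight <- as.vector(t(P))[(out$stimulus - 1) * n + out$perceived]
  out$mean <- comp_mean[out$perceived]
  dplyr::filter(out, .data$weight > 0)
}

# internal: component means and mixture weights as matrices (rows = shown
# stimulus, cols = perceived stimulus) for the likelihood fast path
mixture_components <- function(model, params, v, space) {
  n <- length(space$kappa_values)
  switch(model,
    value = {
      mu <- clamp(params$alpha + v * kernel_profile(params, space))
      list(mean = matrix(mu, n, 1), weight = matrix(1, n, 1))
    },
    perceptual = {
      P <- misperception_matrix(params$rho, space)
      mu <- clamp(params$alpha + ifelse(seq_len(n) == space$cs_index, v, 0))
      list(mean = matrix(mu, n, n, byrow = TRUE), weight = P)
    },
    hybrid = {
      P <- misperception_matrix(params$rho, space)
      mu <- clamp(params$alpha + v * kernel_profile(params, space))
      list(mean = matrix(mu, n, n, byrow = TRUE), weight = P)
    },
    abort(sprintf("Unknown model '%s'.", model))
  )
}
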