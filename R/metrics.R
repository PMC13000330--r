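# Behavioural gradient summaries --------------------------------------------

#' Flip and standardise a generalisation gradient
#'
#' Standard pre-processing across the two generalisation patterns. First, a
#' gradient whose right-half mean exceeds its left-half mean (a monotonic
#' gradient peaking right) is flipped horizontally so all monotonic gradients
#' peak left. Second, for monotonic gradients the stimuli left of the CS+ are
#' transformed against the condition CS+ mean: the literal subtraction rule
#' `t_s = cs_mean - rating_s` (default), which preserves each stimulus's
#' distance from the CS+ in magnitude, or the reflection alternative
#' `t_s = 2 * cs_mean - rating_s` (`method = "reflect"`). Gaussian-pattern
#' gradients pass through unchanged apart from flipping.
#'
#' @param gradient Nine mean ratings in \[0, 1\] (stimulus order 1..9).
#' @param cs_mean Mean CS+ rating of the matching reinforcement-rate
#'   condition.
#' @param pattern `"gaussian"` or `"monotonic"`.
#' @param method Transform rule for the left-of-CS+ stimuli of monotonic
#'   gradients: `"subtract"` (literal) or `"reflect"`.
#' @return A list with `gradient` (transformed 9 values) and `flipped`.
#' @examples
#' flip_and_standardise(seq(0.1, 0.9, by = 0.1), cs_mean = 0.5,
#'                      pattern = "monotonic")
#' @export
flip_and_standardise <- function(gradient, cs_mean,
                                 pattern = c("gaussian", "monotonic"),
                                 method = c("subtract", "reflect")) {
  pattern <- match.arg(pattern)
  method <- match.arg(method)
  if (length(gradient) != 9) abort("`gradient` must have exactly 9 values.")
  flipped <- flip_needed(gradient)
  g <- if (flipped) rev(gradient) else gradient
  if (pattern == "monotonic") {
    left <- 1:4
    g[left] <- switch(method,
      subtract = cs_mean - g[left],
      reflect = 2 * cs_mean - g[left]
    )
  }
  list(gradient = g, flipped = flipped)
}

#' Area under a generalisation gradient
#'
#' Trapezoidal-rule integral of the gradient over the equally spaced
#' stimulus continuum; a summary of overall generalisation strength.
#'
#' @param gradient Mean ratings (>= 2 points).
#' @param spacing Distance between neighbouring stimuli (1 index unit).
#' @return The AUC (scalar).
#' @examples
#' gradient_auc(rep(1, 9))  # 8
#' @export
gradient_auc <- function(gradient, spacing = 1) {
  if (length(gradient) < 2) abort("Need at least 2 points for the trapezoidal rule.")
  pracma::trapz(spacing * (seq_along(gradient) - 1), gradient)
}

#' Classify the generalisation pattern of a value-model fit
#'
#' The fitted kernel-shape parameter Omega classifies each gradient:
#' Omega = 1 is Gaussian-like, Omega = 0 monotonic.
#'
#' @param fit A `gen_fit` of the value model.
#' @return `"gaussian"` or `"monotonic"`.
#' @export
classify_pattern <- function(fit) {
  stopifnot(inherits(fit, "gen_fit"))
  if (fit$model != "value") {
    abort("Pattern classification by Omega applies to value-model fits only.")
  }
  if (fit$params$omega == 1) "gaussian" else "monotonic"
}

#' Majority pattern across conditions
#'
#' Participant-level pattern: the majority of the per-condition
#' classifications, `NA` (with a tie flag) when the split is even.
#'
#' @param patterns Character vector of `"gaussian"` / `"monotonic"` labels
#'   (one per condition).
#' @return A list with `pattern` (`"gaussian"`, `"monotonic"` or `NA`) and
#'   `tie`.
#' @export
majority_pattern <- function(patterns) {
  patterns <- patterns[!is.na(patterns)]
  if (!length(patterns)) return(list(pattern = NA_character_, tie = FALSE))
  n_g <- sum(patterns == "gaussian")
  n_m <- sum(patterns == "monotonic")
  if (n_g == n_m) return(list(pattern = NA_character_, tie = TRUE))
  list(pattern = if (n_g > n_m) "gaussian" else "monotonic", tie = FALSE)
}

#' Min-max rescale ratings within a condition
#'
#' Rescales ratings to \[0, 1\] within each outcome-probability condition,
#' used when pooling trial-level responses across reinforcement rates.
#'
#' @param trials Trial tibble with `condition_rr` and `rating`.
#' @return The tibble with an added `rating_rescaled` column.
#' @export
rescale_condition <- function(trials) {
  dplyr::mutate(
    dplyr::group_by(trials, .data$condition_rr),
    rating_rescaled = {
      rng <- range(.data$rating)
      if (diff(rng) == 0) rep(0, length(.data$rating))
      else (.data$rating - rng[1]) / diff(rng)
    }
  ) |> dplyr::ungroup()
}

#' Association of relative model fit with trait anxiety
#'
#' Pearson correlation of participant-mean relative model fit
#' (`BIC(perceptual) - BIC(value)`; positive favours value transfer) with
#' trait-anxiety scores, with a percentile bootstrap confidence interval
#' over participants. Deterministic given `seed`.
#'
#' @param relative_fits Participant-level relative fits.
#' @param anxiety Matching trait-anxiety scores.
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return A tibble with `r`, `ci_lower`, `ci_upper`, `n`, `n_boot`.
#' @export
anxiety_association <- function(relative_fits, anxiety, n_boot = 10000,
                                conf = 0.95, seed = 1) {
  if (length(relative_fits) != length(anxiety)) {
    abort("`relative_fits` and `anxiety` must have equal length.")
  }
  keep <- stats::complete.cases(relative_fits, anxiety)
  x <- relative_fits[keep]
  y <- anxiety[keep]
  if (length(x) < 3) abort("Need at least 3 complete pairs.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Zero variance in `relative_fits` or `anxiety`; correlation undefined.")
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "anxiety_boot"))
  b <- boot::boot(cbind(x, y), function(d, idx) {
    xs <- d[idx, 1]
    ys <- d[idx, 2]
    # tiny resamples can be degenerate; drop them from the percentile CI
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
    cor(xs, ys)
  }, R = n_boot)
  qs <- stats::quantile(b$t[, 1], c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  tibble(r = unname(b$t0), ci_lower = qs[1], ci_upper = qs[2],
         n = length(x), n_boot = n_boot)
}

#' Per-gradient summary table
#'
#' Joins the behavioural and model-based summaries into one row per
#' participant x condition: the mean gradient's AUC (computed after flipping
#' right-peaked gradients), the winning model, the relative model fit, the
#' value-model pattern classification and parameter estimates, and (if
#' supplied) the participant's trait anxiety.
#'
#' @param trials A trial table.
#' @param fits_tbl Output of [fit_models()] on those trials.
#' @param anxiety Optional tibble with `participant`, `anxiety`.
#' @return A tibble, one row per participant x condition.
#' @export
summarise_gradients <- function(trials, fits_tbl, anxiety = NULL) {
  cmp <- compare_models(fits_tbl)
  gen <- dplyr::filter(trials, .data$phase == "generalisation")
  auc_tbl <- purrr::map_dfr(
    dplyr::group_split(gen, .data$participant, .data$condition_rr,
                       .data$condition_disc),
    function(g) {
      grad <- stimulus_means(g)
      if (flip_needed(grad)) grad <- rev(grad)
      dplyr::bind_cols(
        g[1, c("participant", "condition_rr", "condition_disc")],
        tibble(auc = gradient_auc(grad))
      )
    }
  )
  est_cols <- intersect(c("rho", "lam", "alpha", "sigma"), names(fits_tbl))
  ests <- fits_tbl |>
    dplyr::select(dplyr::all_of(c("participant", "condition_rr",
                                  "condition_disc", "model", est_cols))) |>
    tidyr::pivot_longer(dplyr::all_of(est_cols), names_to = "term",
                        values_drop_na = TRUE) |>
    dplyr::mutate(term = paste(.data$model, .data$term, sep = "_")) |>
    dplyr::select(-"model") |>
    tidyr::pivot_wider(names_from = "term", values_from = "value")
  out <- cmp |>
    dplyr::left_join(auc_tbl, by = c("participant", "condition_rr",
                                     "condition_disc")) |>
    dplyr::left_join(ests, by = c("participant", "condition_rr",
                                  "condition_disc")) |>
    dplyr::mutate(pattern = dplyr::case_when(
      .data$winner != "value" ~ NA_character_,
      .data$omega_value == 1 ~ "gaussian",
      .data$omega_value == 0 ~ "monotonic"
    ))
  if (!is.null(anxiety)) {
    out <- dplyr::left_join(out, anxiety, by = "participant")
  }
  out
}
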