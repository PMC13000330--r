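# Weighted up-down staircase for perceptual titration ------------------------
#
# The titration task finds the kappa step (delta_kappa) at which two
# neighbouring shapes are judged "different" at a target rate (60% or 80%).
# Only different-trials move the staircase: a correct response shrinks
# delta_kappa by step_down, an incorrect one grows it by step_up. The steps
# satisfy the equilibrium condition p * step_down = (1 - p) * step_up, with
# the smaller step pinned to the 0.005 kappa-unit base step, so the expected
# drift vanishes exactly where P(correct | delta_kappa) = target.

#' Initialise a titration staircase
#'
#' @param target_p Target different-trial accuracy, 0.60 or 0.80 in the study
#'   design (other values in (0.5, 1) are accepted).
#' @param start_delta Initial step size in kappa units (defaults to
#'   mid-range, 0.0625).
#' @param base_step Base adjustment step; 0.005 kappa units in the task.
#' @return A `staircase` object holding the current `delta_kappa`, the
#'   up/down steps, and an empty trial history.
#' @export
staircase_init <- function(target_p, start_delta = 0.0625, base_step = 0.005) {
  assert_scalar_in(target_p, 0.5, 1, "target_p", open_lo = TRUE, open_hi = TRUE)
  if (start_delta <= 0) abort("`start_delta` must be positive.")
  # equilibrium: p * step_down = (1 - p) * step_up; smaller step = base_step.
  # For targets above 50% correct, step_down is the smaller step.
  step_down <- base_step
  step_up <- base_step * target_p / (1 - target_p)
  structure(
    list(
      delta_kappa = start_delta, target_p = target_p, base_step = base_step,
      step_down = step_down, step_up = step_up, n_trials = 0L,
      history = tibble(trial = integer(), delta_kappa = numeric(),
                       different = logical(), correct = logical())
    ),
    class = "staircase"
  )
}

#' Advance the staircase by one trial
#'
#' Applies the weighted up-down rule: only different-trials adjust
#' `delta_kappa` (down by `step_down` after a correct response, up by
#' `step_up` after an incorrect one); same-trials are recorded but never move
#' the staircase. `delta_kappa` is floored at one base step.
#'
#' @param state A `staircase`.
#' @param trial_was_different Was this a different-pair trial?
#' @param response_correct Was the response correct?
#' @return The updated `staircase`.
#' @export
staircase_update <- function(state, trial_was_different, response_correct) {
  stopifnot(inherits(state, "staircase"))
  state$n_trials <- state$n_trials + 1L
  state$history <- dplyr::bind_rows(
    state$history,
    tibble(trial = state$n_trials, delta_kappa = state$delta_kappa,
           different = trial_was_different, correct = response_correct)
  )
  if (trial_was_different) {
    delta <- if (response_correct) -state$step_down else state$step_up
    state$delta_kappa <- max(state$delta_kappa + delta, state$base_step)
  }
  state
}

#' @export
print.staircase <- function(x, ...) {
  cat(sprintf("<staircase> target %.0f%%, delta_kappa = %.4f after %d trials\n",
              100 * x$target_p, x$delta_kappa, x$n_trials))
  invisible(x)
}

#' A simulated observer for the titration task
#'
#' Psychometric observer used to exercise the staircase: on different-trials
#' the probability of a correct "different" response rises from chance (0.5)
#' to `1 - lapse` with `delta_kappa`, following a Weibull function with the
#' given `threshold` (kappa units) and `slope`. On same-trials the observer
#' responds "same" correctly with probability `p_same_correct`.
#'
#' @param threshold Delta-kappa at which performance reaches ~81% of its
#'   range above chance.
#' @param slope Weibull slope (steepness); larger is steeper.
#' @param lapse Lapse rate in \[0, 0.1\].
#' @param p_same_correct Accuracy on same-trials (does not affect titration).
#' @return A `sim_observer` object.
#' @export
sim_observer <- function(threshold = 0.04, slope = 3, lapse = 0.02,
                         p_same_correct = 0.9) {
  assert_scalar_in(lapse, 0, 0.1, "lapse")
  if (threshold <= 0 || slope <= 0) abort("`threshold` and `slope` must be positive.")
  structure(list(threshold = threshold, slope = slope, lapse = lapse,
                 p_same_correct = p_same_correct),
            class = "sim_observer")
}

#' @rdname sim_observer
#' @param observer A `sim_observer`.
#' @param delta_kappa Step size(s) at which to evaluate the psychometric
#'   function.
#' @return `p_correct_different()`: P(correct "different" response), strictly
#'   increasing in `delta_kappa`.
#' @export
p_correct_different <- function(observer, delta_kappa) {
  stopifnot(inherits(observer, "sim_observer"))
  0.5 + (0.5 - observer$lapse) *
    (1 - exp(-(delta_kappa / observer$threshold)^observer$slope))
}

#' Run a simulated titration session
#'
#' Simulates `n_trials` staircase trials for a simulated observer: trial
#' type (same/different) is drawn with probability `p_different`, responses
#' are drawn from the observer's psychometric function, and the weighted
#' up-down rule is applied. If the final step size exceeds 0.125 the result
#' is flagged: such a space would leave the defined kappa range and the
#' participant would be excluded.
#'
#' @param observer A `sim_observer`.
#' @param target_p Target different-trial accuracy (0.60 or 0.80).
#' @param n_trials Number of trials (40 in session 1, 20 in the short form).
#' @param p_different Proportion of different-trials (half, by design).
#' @param seed Integer seed; the run is deterministic given it.
#' @param start_delta,base_step Passed to [staircase_init()].
#' @return A `titration_result`: final `delta_kappa`, realised
#'   different-trial `accuracy`, the exclusion flag, and the full trace.
#' @examples
#' run_titration(sim_observer(), target_p = 0.8, seed = 1)
#' @export
run_titration <- function(observer, target_p, n_trials = 40,
                          p_different = 0.5, seed = 1,
                          start_delta = 0.0625, base_step = 0.005) {
  stopifnot(inherits(observer, "sim_observer"))
  if (n_trials < 1) abort("`n_trials` must be >= 1.")
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, paste("titration", target_p)))
  st <- staircase_init(target_p, start_delta = start_delta,
                       base_step = base_step)
  for (t in seq_len(n_trials)) {
    different <- runif(1) < p_different
    p_corr <- if (different) {
      p_correct_different(observer, st$delta_kappa)
    } else {
      observer$p_same_correct
    }
    correct <- runif(1) < p_corr
    st <- staircase_update(st, different, correct)
  }
  diff_trials <- dplyr::filter(st$history, .data$different)
  acc <- if (nrow(diff_trials)) mean(diff_trials$correct) else NA_real_
  structure(
    list(
      delta_kappa = st$delta_kappa,
      target_p = target_p,
      accuracy = acc,
      excluded = st$delta_kappa > 0.125,
      n_trials = n_trials,
      history = st$history
    ),
    class = "titration_result"
  )
}

#' @export
print.titration_result <- function(x, ...) {
  cat(sprintf(
    "<titration_result> target %.0f%%: delta_kappa = %.4f, accuracy = %.3f%s\n",
    100 * x$target_p, x$delta_kappa, x$accuracy,
    if (x$excluded) "  [EXCLUDED: delta_kappa > 0.125]" else ""
  ))
  invisible(x)
}

#' Apply the study's titration-based inclusion criteria
#'
#' Participants continue to the main task only if (i) different-trial
#' accuracy is above chance in every condition, (ii) the accuracy gap
#' between the high (80%) and low (60%) discriminability conditions exceeds
#' 10 percentage points, and (iii) no condition finished with
#' `delta_kappa > 0.125`.
#'
#' @param results A tibble with one row per condition: columns
#'   `discriminability` (0.6 / 0.8), `delta_kappa`, `accuracy`. Both
#'   discriminability levels must be present.
#' @return A list with `include` (logical) and a `criteria` tibble of
#'   per-criterion verdicts and reasons.
#' @export
check_inclusion <- function(results) {
  needed <- c("discriminability", "delta_kappa", "accuracy")
  if (!all(needed %in% names(results))) {
    abort(paste("`results` must have columns:", paste(needed, collapse = ", ")))
  }
  if (!all(c(0.6, 0.8) %in% results$discriminability)) {
    abort("Both discriminability conditions (0.6 and 0.8) are required.")
  }
  above_chance <- all(results$accuracy > 0.5)
  gap <- mean(results$accuracy[results$discriminability == 0.8]) -
    mean(results$accuracy[results$discriminability == 0.6])
  gap_ok <- gap > 0.10
  step_ok <- all(results$delta_kappa <= 0.125)
  criteria <- tibble(
    criterion = c("above_chance", "uncertainty_gap", "step_size"),
    pass = c(above_chance, gap_ok, step_ok),
    detail = c(
      sprintf("min accuracy %.3f (must exceed 0.5)", min(results$accuracy)),
      sprintf("high - low accuracy gap %.3f (must exceed 0.10)", gap),
      sprintf("max delta_kappa %.4f (must not exceed 0.125)",
              max(results$delta_kappa))
    )
  )
  list(include = all(criteria$pass), criteria = criteria)
}
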