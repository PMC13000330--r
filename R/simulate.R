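# Synthetic-cohort generator -------------------------------------------------
#
# Emulates the full task design so every downstream stage is testable without
# participant data: 9-stimulus personalised spaces, probabilistic learning at
# 25/50/75% reinforcement over 24 trials, generalisation ratings (9 stimuli x
# 4 repetitions) produced by a perceptual-confusion, value-transfer or hybrid
# process, mixed Gaussian/monotonic value patterns, and an optional
# anxiety -> value-mechanism linkage.

#' Default generative parameter ranges
#'
#' Uniform sampling ranges per parameter used by [sample_params()] and the
#' recovery protocols. They stand in for the 5th-95th percentile range of
#' empirical parameter estimates (not published); each range sits well inside
#' the fitting bounds.
#'
#' @return Named list of `c(lower, upper)` ranges.
#' @export
param_ranges <- function() {
  list(
    lam = c(0.1, 8),
    rho = c(0.05, 0.6),
    alpha = c(-0.3, 0.3),
    sigma = c(0.05, 0.25)
  )
}

model_par_names <- function(model) {
  switch(model,
    perceptual = c("rho", "alpha", "sigma"),
    value = c("lam", "alpha", "sigma"),
    hybrid = c("rho", "lam", "alpha", "sigma"),
    abort(sprintf("Unknown model '%s'.", model))
  )
}

#' Sample generative parameters
#'
#' Draws parameter sets uniformly within the configured ranges for the given
#' model. For the value and hybrid models the kernel shape Omega is drawn as
#' a Bernoulli with `P(monotonic) = p_monotonic` (the study-level pattern
#' mix), and the monotonic peak side defaults to the canonical left.
#'
#' @param model `"perceptual"`, `"value"` or `"hybrid"`.
#' @param n Number of parameter sets.
#' @param ranges Named list of ranges as in [param_ranges()]; must lie within
#'   the model's fitting bounds.
#' @param p_monotonic Probability that a sampled value/hybrid kernel is
#'   monotonic (Omega = 0).
#' @param peak_side Peak side for monotonic draws.
#' @param seed Optional integer seed (uses the current RNG stream if `NULL`).
#' @return A tibble with one row per draw and one column per parameter.
#' @export
sample_params <- function(model, n = 1, ranges = param_ranges(),
                          p_monotonic = 0.5512, peak_side = "left",
                          seed = NULL) {
  model <- match.arg(model, c("perceptual", "value", "hybrid"))
  full <- param_ranges()
  bounds <- list(lam = c(LAM_MIN, LAM_MAX), rho = c(0, 1), alpha = c(-1, 1),
                 sigma = c(SIGMA_MIN, SIGMA_MAX))
  ranges <- utils::modifyList(full, ranges)
  for (p in names(bounds)) {
    r <- ranges[[p]]
    if (r[1] > r[2] || r[1] < bounds[[p]][1] || r[2] > bounds[[p]][2]) {
      abort(sprintf("Range for `%s` (%g, %g) is outside the model bounds (%g, %g).",
                    p, r[1], r[2], bounds[[p]][1], bounds[[p]][2]))
    }
  }
  if (!is.null(seed)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_restore(old))
    set.seed(derive_seed(seed, paste("sample_params", model)))
  }
  pars <- model_par_names(model)
  out <- purrr::map_dfc(setNames(pars, pars), function(p) {
    runif(n, ranges[[p]][1], ranges[[p]][2])
  })
  if (model %in% c("value", "hybrid")) {
    out$omega <- as.numeric(runif(n) >= p_monotonic)
    out$peak_side <- peak_side
  }
  out
}

# one row of a sample_params() tibble -> gen_params object
row_to_params <- function(model, row) {
  switch(model,
    perceptual = perceptual_params(row$rho, alpha = row$alpha, sigma = row$sigma),
    value = value_params(row$lam, omega = row$omega, alpha = row$alpha,
                         peak_side = row$peak_side, sigma = row$sigma),
    hybrid = hybrid_params(row$rho, row$lam, omega = row$omega,
                           alpha = row$alpha, peak_side = row$peak_side,
                           sigma = row$sigma)
  )
}

#' Simulate a learning block
#'
#' Simulates the 24-trial probabilistic conditioning block: exactly
#' `rr * n_trials` reinforced trials in shuffled order (the design uses exact
#' counts; set `bernoulli = TRUE` for independent coin flips), with
#' expectancy ratings collected halfway and at the end. Ratings are
#' `clamp(rr + bias + noise, 0, 1)`; the default biases and noise scales
#' reproduce the slight overestimation of the true reinforcement rate seen in
#' behaviour (cohort mean final ratings near 0.31 / 0.54 / 0.77 for
#' rr = 0.25 / 0.50 / 0.75).
#'
#' @param rr Reinforcement rate (0.25, 0.50 or 0.75 in the design).
#' @param n_trials Number of learning trials (24 in the task).
#' @param bias Additive rating bias; default depends on `rr`.
#' @param noise_sd Rating noise SD; default depends on `rr`.
#' @param bernoulli Draw reinforcement per-trial instead of exact counts.
#' @param seed Optional integer seed.
#' @return A tibble of `n_trials` rows: `trial`, `reinforced`, `rating`
#'   (`NA` except at the halfway and final trials).
#' @export
simulate_learning <- function(rr, n_trials = 24, bias = NULL, noise_sd = NULL,
                              bernoulli = FALSE, seed = NULL) {
  defaults_bias <- c("0.25" = 0.055, "0.5" = 0.04, "0.75" = 0.02)
  defaults_sd <- c("0.25" = 0.18, "0.5" = 0.14, "0.75" = 0.11)
  key <- as.character(rr)
  bias <- bias %||% unname(defaults_bias[key]) %||% 0.04
  noise_sd <- noise_sd %||% unname(defaults_sd[key]) %||% 0.14
  if (is.na(bias)) bias <- 0.04
  if (is.na(noise_sd)) noise_sd <- 0.14
  if (!is.null(seed)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_restore(old))
    set.seed(derive_seed(seed, "learning"))
  }
  if (bernoulli) {
    reinforced <- runif(n_trials) < rr
  } else {
    n_reinf <- rr * n_trials
    if (abs(n_reinf - round(n_reinf)) > 1e-9) {
      abort(sprintf("rr * n_trials = %g is not an integer; use `bernoulli = TRUE` for off-design rates.",
                    n_reinf))
    }
    reinforced <- sample(rep(c(TRUE, FALSE), c(round(n_reinf), n_trials - round(n_reinf))))
  }
  rating <- rep(NA_real_, n_trials)
  mid <- floor(n_trials / 2)
  rating[mid] <- clamp(rr + bias + rnorm(1, 0, noise_sd))
  rating[n_trials] <- clamp(rr + bias + rnorm(1, 0, noise_sd))
  tibble(trial = seq_len(n_trials), reinforced = reinforced, rating = rating)
}

#' Simulate a generalisation block
#'
#' Simulates the 36 generalisation trials (9 stimuli x `n_reps` repetitions,
#' shuffled). Under the value model each rating is a censored-normal draw
#' around the kernel prediction; under the perceptual and hybrid models a
#' perceived stimulus is first drawn from the misperception row of the shown
#' stimulus and the rating is then drawn around that component's mean — which
#' reproduces the bimodal (perceptual) versus graded (value) trial-level
#' response distributions.
#'
#' @param model `"perceptual"`, `"value"` or `"hybrid"`.
#' @param params Matching `gen_params`.
#' @param v Learned CS+ outcome expectancy in \[0, 1\].
#' @param space A `stimulus_space`.
#' @param n_reps Repetitions per stimulus (4 in the task).
#' @param seed Optional integer seed.
#' @return A tibble of `9 * n_reps` rows: `trial`, `stimulus`, `rating`.
#' @examples
#' sp <- build_space(0.05)
#' simulate_generalisation("perceptual", perceptual_params(0.4, sigma = 0.05),
#'                         v = 0.7, sp, seed = 1)
#' @export
simulate_generalisation <- function(model, params, v, space, n_reps = 4,
                                    seed = NULL) {
  model <- match.arg(model, c("perceptual", "value", "hybrid"))
  assert_scalar_in(v, 0, 1, "v")
  if (!is.null(seed)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_restore(old))
    set.seed(derive_seed(seed, paste("generalisation", model)))
  }
  n <- length(space$kappa_values)
  stimulus <- sample(rep(seq_len(n), n_reps))
  comp <- mixture_components(model, params, v, space)
  mu <- vapply(stimulus, function(s) {
    w <- comp$weight[s, ]
    q <- if (length(w) == 1) 1 else sample.int(length(w), 1, prob = w)
    comp$mean[s, q]
  }, numeric(1))
  rating <- clamp(rnorm(length(stimulus), mu, params$sigma))
  tibble(trial = seq_along(stimulus), stimulus = stimulus, rating = rating)
}

#' Generative configuration for a synthetic cohort
#'
#' Bundles all knobs of the cohort generator. Defaults emulate the study
#' conditions: 140 participants; mechanism mix of 84.76% value-based and
#' 15.24% perceptual gradients (no hybrid generators by default); 55.12%
#' monotonic patterns among value generalisers; 75% of participants using the
#' same pattern across all six conditions; trait anxiety floored at the
#' questionnaire minimum of 21 with a right-skewed tail (cohort mean near
#' 29.3); and an anxiety -> value-mechanism log-odds coupling.
#'
#' @param n_participants Cohort size.
#' @param mechanism_mix Named probabilities for `value`, `perceptual`,
#'   `hybrid`; must sum to 1.
#' @param p_monotonic P(monotonic pattern) among value/hybrid generalisers.
#' @param p_consistent Probability a participant keeps one pattern across all
#'   conditions.
#' @param ranges Generative parameter ranges, as in [param_ranges()].
#' @param anxiety_shape,anxiety_scale Gamma parameters of the anxiety score
#'   above its floor of 21.
#' @param anxiety_mechanism_coupling Log-odds increase in P(value mechanism)
#'   per anxiety point above the cohort mean.
#' @param anxiety_lam_coupling Additive shift in the generalisation strength
#'   `lam` per anxiety SD above the mean (0 disables the linkage).
#' @param n_learning,n_reps Trials per learning block / repetitions per
#'   generalisation stimulus.
#' @param observer_threshold_range Range of simulated-observer perceptual
#'   thresholds used for titration.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `gen_config` list.
#' @export
generative_config <- function(n_participants = 140,
                              mechanism_mix = c(value = 0.8476,
                                                perceptual = 0.1524,
                                                hybrid = 0),
                              p_monotonic = 0.5512,
                              p_consistent = 0.75,
                              ranges = param_ranges(),
                              anxiety_shape = 1.4,
                              anxiety_scale = 6,
                              anxiety_mechanism_coupling = 0.08,
                              anxiety_lam_coupling = 0,
                              n_learning = 24,
                              n_reps = 4,
                              observer_threshold_range = c(0.02, 0.05),
                              seed = 1) {
  if (abs(sum(mechanism_mix) - 1) > 1e-9) abort("`mechanism_mix` must sum to 1.")
  if (any(mechanism_mix < 0)) abort("`mechanism_mix` probabilities must be non-negative.")
  if (!all(c("value", "perceptual", "hybrid") %in% names(mechanism_mix))) {
    abort("`mechanism_mix` needs named entries value, perceptual, hybrid.")
  }
  assert_scalar_in(p_monotonic, 0, 1, "p_monotonic")
  assert_scalar_in(p_consistent, 0, 1, "p_consistent")
  structure(
    list(
      n_participants = n_participants, mechanism_mix = mechanism_mix,
      p_monotonic = p_monotonic, p_consistent = p_consistent, ranges = ranges,
      anxiety_shape = anxiety_shape, anxiety_scale = anxiety_scale,
      anxiety_mechanism_coupling = anxiety_mechanism_coupling,
      anxiety_lam_coupling = anxiety_lam_coupling,
      n_learning = n_learning, n_reps = n_reps,
      observer_threshold_range = observer_threshold_range, seed = seed
    ),
    class = "gen_config"
  )
}

#' Simulate a full synthetic cohort
#'
#' Generates a cohort with the study's complete data structure. Each
#' participant gets a trait-anxiety score, a generalisation mechanism
#' (anxiety-coupled log-odds, so higher anxiety raises the probability of
#' value-based generalisation), a pattern that is consistent across
#' conditions for `p_consistent` of participants, simulated titrated step
#' sizes per discriminability level, and full learning + generalisation
#' trial tables for all six conditions.
#'
#' @param config A [generative_config()].
#' @return A `syn_cohort`: list with `participants` (anxiety, mechanism,
#'   observer), `truth` (per participant x condition generative parameters,
#'   CS+ value, titrated delta-kappa), `trials` (the full trial table) and
#'   the `config`.
#' @examples
#' co <- simulate_cohort(generative_config(n_participants = 2, seed = 7))
#' dplyr::count(co$trials, phase)
#' @export
simulate_cohort <- function(config = generative_config()) {
  stopifnot(inherits(config, "gen_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, "cohort"))

  n <- config$n_participants
  anxiety <- 21 + stats::rgamma(n, shape = config$anxiety_shape,
                                scale = config$anxiety_scale)
  mean_anx <- 21 + config$anxiety_shape * config$anxiety_scale
  sd_anx <- sqrt(config$anxiety_shape) * config$anxiety_scale

  mix <- config$mechanism_mix
  # anxiety shifts the log-odds of the value mechanism; the complement is
  # split between perceptual and hybrid in their base proportions
  p_value <- stats::plogis(stats::qlogis(clamp(mix[["value"]], 1e-6, 1 - 1e-6)) +
                             config$anxiety_mechanism_coupling * (anxiety - mean_anx))
  other <- mix[c("perceptual", "hybrid")]
  other <- if (sum(other) > 0) other / sum(other) else c(perceptual = 1, hybrid = 0)
  mechanism <- vapply(p_value, function(pv) {
    if (runif(1) < pv) "value"
    else sample(c("perceptual", "hybrid"), 1, prob = other)
  }, character(1))

  consistent <- runif(n) < config$p_consistent
  base_pattern <- ifelse(runif(n) < config$p_monotonic, 0, 1)  # omega
  peak_side_p <- sample(c("left", "right"), n, replace = TRUE)
  obs_thr <- runif(n, config$observer_threshold_range[1],
                   config$observer_threshold_range[2])

  conds <- study_conditions()
  participants <- tibble(
    participant = sprintf("sub%03d", seq_len(n)),
    anxiety = anxiety, mechanism = mechanism,
    consistent_pattern = consistent, base_omega = base_pattern,
    peak_side = peak_side_p, observer_threshold = obs_thr
  )

  truth <- vector("list", n)
  trials <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- participants$participant[i]
    obs <- sim_observer(threshold = obs_thr[i])
    titr <- lapply(c(0.6, 0.8), function(tp) {
      run_titration(obs, tp, n_trials = 40,
                    seed = derive_seed(config$seed, paste("titr", pid, tp)))
    })
    dk <- setNames(vapply(titr, `[[`, numeric(1), "delta_kappa"),
                   c("0.6", "0.8"))
    dk <- clamp(dk, 0.005, 0.124)  # keep simulated spaces constructible

    truth_i <- vector("list", nrow(conds))
    trials_i <- vector("list", nrow(conds))
    for (ci in seq_len(nrow(conds))) {
      rr <- conds$reinforcement_rate[ci]
      disc <- conds$discriminability[ci]
      space <- build_space(dk[[as.character(disc)]],
                           condition_label = conds$condition[ci])
      pars <- sample_params(mechanism[i], n = 1, ranges = config$ranges,
                            p_monotonic = config$p_monotonic)
      if (mechanism[i] != "perceptual") {
        pars$omega <- if (consistent[i]) base_pattern[i] else
          as.numeric(runif(1) >= config$p_monotonic)
        pars$peak_side <- peak_side_p[i]
        if (config$anxiety_lam_coupling != 0) {
          pars$lam <- clamp(pars$lam + config$anxiety_lam_coupling *
                              (anxiety[i] - mean_anx) / sd_anx,
                            config$ranges$lam[1], config$ranges$lam[2])
        }
      }
      learn <- simulate_learning(rr, n_trials = config$n_learning)
      v <- learn$rating[config$n_learning]
      gen <- simulate_generalisation(mechanism[i], row_to_params(mechanism[i], pars),
                                     v, space, n_reps = config$n_reps)
      truth_i[[ci]] <- dplyr::bind_cols(
        tibble(participant = pid, condition_rr = rr, condition_disc = disc,
               mechanism = mechanism[i], v = v,
               delta_kappa = dk[[as.character(disc)]]),
        pars
      )
      trials_i[[ci]] <- dplyr::bind_rows(
        tibble(participant = pid, condition_rr = rr, condition_disc = disc,
               phase = "learning", trial = learn$trial, stimulus = 5L,
               rating = learn$rating, reinforced = learn$reinforced),
        tibble(participant = pid, condition_rr = rr, condition_disc = disc,
               phase = "generalisation", trial = gen$trial,
               stimulus = gen$stimulus, rating = gen$rating, reinforced = NA)
      )
    }
    truth[[i]] <- dplyr::bind_rows(truth_i)
    trials[[i]] <- dplyr::bind_rows(trials_i)
  }

  structure(
    list(participants = participants,
         truth = dplyr::bind_rows(truth),
         trials = dplyr::bind_rows(trials),
         config = config),
    class = "syn_cohort"
  )
}

#' @export
print.syn_cohort <- function(x, ...) {
  cat("<syn_cohort>", nrow(x$participants), "participants,",
      nrow(x$trials), "trials\n")
  print(table(x$participants$mechanism))
  invisible(x)
}
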