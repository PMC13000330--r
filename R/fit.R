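# Fitting protocol: DIRECT-L global search over the bounded parameter box,
# then bounded L-BFGS-B polish from the global solution and from randomised
# interior starts; the minimum-NLL restart wins. lambda is optimised in log
# space for resolution near 0; sigma is floored at 1e-3.

SIGMA_MIN <- 1e-3
SIGMA_MAX <- 1
LAM_MIN <- 1e-3
LAM_MAX <- 10

# lambda and sigma are optimised in log space: both act multiplicatively and
# their likelihood basins near 0 are far wider on the log scale
model_box <- function(model) {
  switch(model,
    perceptual = list(names = c("rho", "alpha", "log_sigma"),
                      lb = c(0, -1, log(SIGMA_MIN)),
                      ub = c(1, 1, log(SIGMA_MAX)), k = 3L),
    value = list(names = c("log_lam", "alpha", "log_sigma"),
                 lb = c(log(LAM_MIN), -1, log(SIGMA_MIN)),
                 ub = c(log(LAM_MAX), 1, log(SIGMA_MAX)), k = 3L),
    hybrid = list(names = c("rho", "log_lam", "alpha", "log_sigma"),
                  lb = c(0, log(LAM_MIN), -1, log(SIGMA_MIN)),
                  ub = c(1, log(LAM_MAX), 1, log(SIGMA_MAX)), k = 4L),
    abort(sprintf("Unknown model '%s'.", model))
  )
}

theta_to_params <- function(model, theta, omega = 1, peak_side = "left") {
  # exp(log-bound) can overshoot the bound by a few ulps; pin it back
  from_log <- function(x, lo, hi) min(max(exp(x), lo), hi)
  switch(model,
    perceptual = perceptual_params(
      theta[1], alpha = theta[2],
      sigma = from_log(theta[3], SIGMA_MIN, SIGMA_MAX)),
    value = value_params(
      from_log(theta[1], LAM_MIN, LAM_MAX), omega = omega, alpha = theta[2],
      peak_side = peak_side, sigma = from_log(theta[3], SIGMA_MIN, SIGMA_MAX)),
    hybrid = hybrid_params(
      theta[1], from_log(theta[2], LAM_MIN, LAM_MAX), omega = omega,
      alpha = theta[3], peak_side = peak_side,
      sigma = from_log(theta[4], SIGMA_MIN, SIGMA_MAX))
  )
}

# deterministic moment-based warm starts; the mixture likelihood is
# multimodal and rating clamping creates flat plateaus, so a start placed
# near the data-implied offset/noise scale guards the polish stage
informed_starts <- function(trials, model, v, space) {
  r <- trials$rating
  s <- trials$stimulus
  d <- abs(s - space$cs_index)
  m <- tapply(r, factor(s, levels = seq_along(space$kappa_values)), mean)
  q10 <- stats::quantile(r, 0.1, names = FALSE)
  q90 <- stats::quantile(r, 0.9, names = FALSE)
  within_sd <- tapply(r, s, stats::sd)
  lsig <- log(clamp(mean(within_sd, na.rm = TRUE), 2 * SIGMA_MIN, 0.3))
  perc <- function() {
    # upper rating cluster sits at v + alpha; GS trials above the cluster
    # midpoint look like CS+ confusions
    alpha_hi <- clamp(q90 - v, -1, 1)
    alpha_md <- clamp(stats::median(r[d >= 3]), -1, 1)
    if (is.na(alpha_md)) alpha_md <- 0
    rho0 <- clamp(2 * mean(r[d >= 1] > (q90 + q10) / 2), 0.05, 0.9)
    rbind(c(rho0, alpha_hi), c(rho0, alpha_md))
  }
  val <- function() {
    # far stimuli approach alpha; the d = 1 kernel height gives a lam guess
    alpha0 <- clamp(min(m, na.rm = TRUE), -1, 1)
    g1 <- (mean(m[c(4, 6)], na.rm = TRUE) - alpha0) / max(v, 0.05)
    lam0 <- if (is.finite(g1) && g1 > 0.01 && g1 < 0.99) {
      1 / log(2 / g1 - 1)
    } else 2
    cbind(log(clamp(lam0, 2 * LAM_MIN, 0.99 * LAM_MAX)), alpha0)
  }
  starts <- switch(model,
    perceptual = perc(),
    value = val(),
    hybrid = {
      p <- perc()[1, ]
      vv <- val()[1, ]
      rbind(c(p[1], vv[1], vv[2]), c(p[1] / 2, vv[1], p[2]))
    }
  )
  cbind(starts, lsig)
}

# key identifying the fitted data, so comparisons across different data error
data_key <- function(trials) {
  paste(nrow(trials), format(sum(trials$rating), digits = 15),
        format(sum(trials$rating * trials$stimulus), digits = 15))
}

# one global + multistart-polish optimisation at fixed model structure
fit_one_variant <- function(trials, model, v, space, omega, peak_side,
                            n_restarts, seed, maxeval_global) {
  box <- model_box(model)
  obj <- function(theta) {
    nll_gradient(trials, model, theta_to_params(model, theta, omega, peak_side),
                 v, space)
  }
  glob <- nloptr::nloptr(
    x0 = (box$lb + box$ub) / 2, eval_f = obj, lb = box$lb, ub = box$ub,
    opts = list(algorithm = "NLOPT_GN_DIRECT_L", maxeval = maxeval_global,
                xtol_rel = 1e-10)
  )
  inf <- informed_starts(trials, model, v, space)
  inf <- pmin(pmax(inf, matrix(box$lb, nrow(inf), length(box$lb),
                               byrow = TRUE)),
              matrix(box$ub, nrow(inf), length(box$ub), byrow = TRUE))
  starts <- rbind(matrix(glob$solution, nrow = 1), inf)
  if (n_restarts > 1) {
    old <- .Random.seed_get()
    set.seed(derive_seed(seed, paste("fit", model, omega, peak_side)))
    rand <- matrix(runif((n_restarts - 1) * length(box$lb)),
                   ncol = length(box$lb))
    .Random.seed_restore(old)
    rand <- sweep(sweep(rand, 2, box$ub - box$lb, "*"), 2, box$lb, "+")
    starts <- rbind(starts, rand)
  }
  best <- NULL
  conv <- integer(nrow(starts))
  fails <- character(0)
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[i, ], obj, method = "L-BFGS-B",
            lower = box$lb, upper = box$ub,
            control = list(maxit = 200, factr = 1e6)),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      fails <- c(fails, conditionMessage(res))
      conv[i] <- -1L
      next
    }
    conv[i] <- res$convergence
    if (is.null(best) || res$value < best$value) {
      best <- res
      best$restart <- i
    }
  }
  if (is.null(best)) {
    abort(paste0("All ", nrow(starts), " restarts failed for the ", model,
                 " model. First error: ", fails[1]))
  }
  list(theta = unname(best$par), nll = best$value, restart = best$restart,
       n_starts = nrow(starts), convergence = conv, n_failed = length(fails),
       global_nll = glob$objective)
}

# save/restore the global RNG state so fitting does not disturb user streams
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Fit a generalisation model to one participant-condition gradient
#'
#' Fits the perceptual, value or hybrid model to the 36 generalisation-phase
#' ratings of one participant in one condition, by minimising the
#' censored-normal (mixture) negative log likelihood. The search runs the
#' DIRECT-L global optimisation algorithm over the bounded parameter box,
#' then polishes with bounded quasi-Newton (L-BFGS-B) from the global
#' solution, from a couple of deterministic moment-based warm starts derived
#' from the data, and from `n_restarts - 1` randomised interior starts,
#' keeping the best restart. For the value and hybrid models the binary kernel-shape
#' parameter Omega is enumerated: both the Gaussian-like and the monotonic
#' variant are fitted and the better (lower NLL) kept, because a binary
#' switch inside a continuous optimiser is ill-posed.
#'
#' @param trials Generalisation-phase trials: tibble with `stimulus`,
#'   `rating` columns (ratings in \[0, 1\]).
#' @param model `"perceptual"`, `"value"` or `"hybrid"`.
#' @param v Learned CS+ outcome expectancy in \[0, 1\] (final learning-phase
#'   rating; fixed, not fitted).
#' @param space A `stimulus_space`; defaults to a generic one (only index
#'   distances enter the likelihood).
#' @param n_restarts Number of local polish runs (first is seeded from the
#'   global solution).
#' @param seed Integer seed controlling the randomised starts.
#' @param omega Fix the kernel shape (0 or 1) instead of enumerating both.
#' @param peak_side Canonical peak side for monotonic kernels; pre-processed
#'   gradients peak left.
#' @param maxeval_global Function-evaluation budget of the DIRECT-L stage.
#' @return A `gen_fit` object: estimated `params`, `nll`, `bic`, `k`, `n`,
#'   restart diagnostics, and the NLL of each enumerated Omega variant.
#' @examples
#' sp <- build_space(0.05)
#' set.seed(1)
#' tr <- simulate_generalisation("value", value_params(lam = 3, sigma = 0.1),
#'                               v = 0.7, sp)
#' fit_gradient(tr, "value", v = 0.7, sp, n_restarts = 3, seed = 1)
#' @export
fit_gradient <- function(trials, model = c("value", "perceptual", "hybrid"),
                         v, space = build_space(0.05), n_restarts = 30,
                         seed = 1, omega = NULL, peak_side = "left",
                         maxeval_global = 200) {
  model <- match.arg(model)
  assert_scalar_in(v, 0, 1, "v")
  if (nrow(trials) == 0) abort("No generalisation trials to fit.")
  omegas <- if (model == "perceptual") NA_real_ else (omega %||% c(1, 0))
  variants <- lapply(omegas, function(om) {
    fit_one_variant(trials, model, v, space,
                    omega = if (is.na(om)) 1 else om, peak_side = peak_side,
                    n_restarts = n_restarts, seed = seed,
                    maxeval_global = maxeval_global)
  })
  nlls <- vapply(variants, `[[`, numeric(1), "nll")
  best_i <- which.min(nlls)
  best <- variants[[best_i]]
  om <- omegas[best_i]
  params <- theta_to_params(model, best$theta,
                            omega = if (is.na(om)) 1 else om,
                            peak_side = peak_side)
  box <- model_box(model)
  n <- nrow(trials)
  structure(
    list(
      model = model,
      params = params,
      nll = best$nll,
      k = box$k,              # sigma counted; omega is a structure switch, not counted
      n = n,
      bic = bic(best$nll, box$k, n),
      n_restarts = n_restarts,
      n_starts = best$n_starts,
      best_restart = best$restart,
      convergence = best$convergence,
      n_failed = best$n_failed,
      omega_trace = tibble(omega = omegas, nll = nlls),
      v = v,
      seed = seed,
      data_key = data_key(trials)
    ),
    class = "gen_fit"
  )
}

#' @export
print.gen_fit <- function(x, ...) {
  cat("<gen_fit> ", x$model, " model, n = ", x$n, " trials\n", sep = "")
  print(x$params)
  cat(sprintf("  nll = %.4f  bic = %.4f  (k = %d, best start %d of %d)\n",
              x$nll, x$bic, x$k, x$best_restart, x$n_starts))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a generalisation-model fit
#'
#' @param x A `gen_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per estimated parameter (`term`, `estimate`);
#'   `glance()`: a one-row model summary (`model`, `omega`, `nll`, `bic`,
#'   `k`, `n`, restart diagnostics).
#' @method tidy gen_fit
#' @export
tidy.gen_fit <- function(x, ...) {
  p <- x$params
  est <- unlist(p[vapply(p, is.numeric, logical(1))])
  tibble(term = names(est), estimate = unname(est))
}

#' @rdname tidy.gen_fit
#' @method glance gen_fit
#' @export
glance.gen_fit <- function(x, ...) {
  tibble(
    model = x$model,
    omega = if (x$model == "perceptual") NA_real_ else x$params$omega,
    nll = x$nll, bic = x$bic, k = x$k, n = x$n,
    n_restarts = x$n_restarts, best_restart = x$best_restart,
    n_failed_restarts = x$n_failed
  )
}

#' Compare fitted models by BIC
#'
#' Selects the winning model (lowest BIC) among fits of the *same* data and
#' computes the relative model fit, `BIC(perceptual) - BIC(value)`: positive
#' values favour value-based generalisation. BICs within 1e-6 of the minimum
#' are treated as tied: differences at that scale are optimiser noise, and
#' models can mimic each other exactly (e.g. confusion-free perceptual data
#' against a collapsed value kernel), reaching numerically identical
#' likelihoods. Ties are broken toward the model with fewer parameters, then
#' by the fixed order perceptual, value, hybrid, and flagged.
#'
#' @param fits A list of two or more `gen_fit` objects for the same trials.
#' @return A `gen_comparison`: list with `$table` (per-model tibble),
#'   `$winner`, `$relative_fit`, `$tie`, and `$pairwise` BIC differences.
#' @export
compare_fits <- function(fits) {
  if (length(fits) < 2) abort("Need at least two fits to compare.")
  stopifnot(all(vapply(fits, inherits, logical(1), "gen_fit")))
  keys <- vapply(fits, `[[`, character(1), "data_key")
  if (length(unique(keys)) != 1) {
    abort("Fits were computed on different data; comparison is not meaningful.")
  }
  model_order <- c("perceptual", "value", "hybrid")
  tab <- dplyr::bind_rows(lapply(fits, glance))
  if (anyDuplicated(tab$model)) abort("Multiple fits of the same model supplied.")
  tol <- 1e-6
  near_min <- tab$bic - min(tab$bic) <= tol
  cand <- which(near_min)
  cand <- cand[order(tab$k[cand], match(tab$model[cand], model_order))]
  winner <- tab$model[cand[1]]
  tie <- sum(near_min) > 1
  rel <- if (all(c("perceptual", "value") %in% tab$model)) {
    tab$bic[tab$model == "perceptual"] - tab$bic[tab$model == "value"]
  } else NA_real_
  pw <- tidyr::expand_grid(model_a = tab$model, model_b = tab$model)
  pw <- dplyr::filter(pw, .data$model_a != .data$model_b)
  pw$delta_bic <- tab$bic[match(pw$model_a, tab$model)] -
    tab$bic[match(pw$model_b, tab$model)]
  structure(
    list(table = tab, winner = winner, relative_fit = rel, tie = tie,
         pairwise = pw),
    class = "gen_comparison"
  )
}

#' @export
print.gen_comparison <- function(x, ...) {
  cat("<gen_comparison> winner:", x$winner,
      if (x$tie) "(BIC tie, broken by parsimony/order)" else "", "\n")
  print(x$table[, c("model", "omega", "nll", "bic", "k")])
  if (!is.na(x$relative_fit)) {
    cat(sprintf("  relative fit BIC(perceptual) - BIC(value) = %.3f\n",
                x$relative_fit))
  }
  invisible(x)
}

#' Fit models across a whole trial table
#'
#' Tibble-first wrapper: takes a trial table covering any number of
#' participants and conditions, extracts each participant-condition CS+
#' value from the final learning-phase rating, optionally flips gradients
#' peaking on the right (standard pre-processing), fits the requested models
#' to each generalisation block, and returns one row per
#' participant x condition x model.
#'
#' @param trials A trial table (see [read_trials()]): columns `participant`,
#'   `condition_rr`, `condition_disc`, `phase`, `trial`, `stimulus`,
#'   `rating`, `reinforced`.
#' @param models Character vector of models to fit.
#' @param flip Flip gradients whose right-half mean exceeds the left-half
#'   mean before fitting, so monotonic gradients peak left.
#' @param n_restarts,seed,maxeval_global Passed to [fit_gradient()].
#' @param space A `stimulus_space`.
#' @return A tibble with identifying columns, `flipped`, `v`, parameter
#'   estimates, `nll`, `bic`, and a `fit` list-column of `gen_fit` objects.
#' @export
fit_models <- function(trials, models = c("perceptual", "value"),
                       flip = TRUE, n_restarts = 30, seed = 1,
                       space = build_space(0.05), maxeval_global = 200) {
  models <- match.arg(models, c("perceptual", "value", "hybrid"),
                      several.ok = TRUE)
  vtab <- cs_values(trials)
  gen <- dplyr::filter(trials, .data$phase == "generalisation")
  if (nrow(gen) == 0) abort("No generalisation-phase trials in `trials`.")
  groups <- dplyr::group_split(gen, .data$participant, .data$condition_rr,
                               .data$condition_disc)
  purrr::map_dfr(groups, function(g) {
    id <- g[1, c("participant", "condition_rr", "condition_disc")]
    v <- vtab$v[vtab$participant == id$participant &
                  vtab$condition_rr == id$condition_rr &
                  vtab$condition_disc == id$condition_disc]
    if (length(v) != 1 || is.na(v)) {
      abort(sprintf("No CS+ value (final learning rating) for participant %s, rr=%s, disc=%s.",
                    id$participant, id$condition_rr, id$condition_disc))
    }
    flipped <- FALSE
    if (flip) {
      grad <- stimulus_means(g)
      if (flip_needed(grad)) {
        g$stimulus <- 10L - g$stimulus
        flipped <- TRUE
      }
    }
    purrr::map_dfr(models, function(m) {
      f <- fit_gradient(g, m, v = v, space = space, n_restarts = n_restarts,
                        seed = derive_seed(seed, paste(id$participant,
                                                       id$condition_rr,
                                                       id$condition_disc)),
                        maxeval_global = maxeval_global)
      dplyr::bind_cols(
        id,
        tibble(model = m, flipped = flipped, v = v),
        tidyr::pivot_wider(tidy(f), names_from = "term",
                           values_from = "estimate"),
        tibble(nll = f$nll, bic = f$bic, k = f$k, n = f$n, fit = list(f))
      )
    })
  })
}

#' Per-gradient model comparison across a fitted table
#'
#' @param fits_tbl Output of [fit_models()].
#' @return One row per participant x condition: winning model, relative fit
#'   (`BIC(perceptual) - BIC(value)`), tie flag, and the fitted Omega of the
#'   value model (for pattern classification).
#' @export
compare_models <- function(fits_tbl) {
  groups <- dplyr::group_split(fits_tbl, .data$participant,
                               .data$condition_rr, .data$condition_disc)
  purrr::map_dfr(groups, function(g) {
    cmp <- compare_fits(g$fit)
    omega_value <- if ("value" %in% g$model) {
      g$fit[[which(g$model == "value")]]$params$omega
    } else NA_real_
    dplyr::bind_cols(
      g[1, c("participant", "condition_rr", "condition_disc")],
      tibble(winner = cmp$winner, relative_fit = cmp$relative_fit,
             tie = cmp$tie, omega_value = omega_value)
    )
  })
}

# condition-mean rating per stimulus (vector of 9)
stimulus_means <- function(gen_trials) {
  out <- rep(NA_real_, 9)
  agg <- dplyr::summarise(dplyr::group_by(gen_trials, .data$stimulus),
                          m = mean(.data$rating), .groups = "drop")
  out[agg$stimulus] <- agg$m
  out
}

# right-half mean above left-half mean => gradient peaks right, flip it
flip_needed <- function(grad9) {
  mean(grad9[6:9], na.rm = TRUE) > mean(grad9[1:4], na.rm = TRUE)
}

#' CS+ values from the learning phase
#'
#' Extracts each participant-condition learned CS+ outcome expectancy: the
#' rating given on the final learning trial (trial 24), which anchors the
#' generalisation models and is not itself fitted.
#'
#' @param trials A trial table including learning-phase rows.
#' @return Tibble with `participant`, `condition_rr`, `condition_disc`, `v`.
#' @export
cs_values <- function(trials) {
  learn <- dplyr::filter(trials, .data$phase == "learning", !is.na(.data$rating))
  dplyr::summarise(
    dplyr::group_by(learn, .data$participant, .data$condition_rr,
                    .data$condition_disc),
    v = .data$rating[which.max(.data$trial)],
    .groups = "drop"
  )
}
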