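# Model- and parameter-recovery protocols ------------------------------------
#
# Simulation checks that BIC-based selection identifies the generating model
# and that fitting recovers generative parameters. Each synthetic dataset is
# a single condition (36 trials: 9 stimuli x 4 repetitions), mirroring
# per-condition fitting; the CS+ value is sampled within [0.2, 0.9].

#' Model recovery by BIC
#'
#' For each candidate generating model, draws `n_datasets` parameter sets
#' from the generative ranges, simulates one 36-trial generalisation dataset
#' each, fits all candidate models, and classifies every dataset by lowest
#' BIC. Fills the generative-model x best-fitting-model confusion matrix.
#' Fully deterministic given `seed`.
#'
#' @param n_datasets Datasets per generating model (120 in the recovery
#'   protocol).
#' @param models Candidate models (generating and fitted). The hybrid model
#'   can be added, but the default two-model recovery excludes it.
#' @param ranges Generative parameter ranges ([param_ranges()]).
#' @param v_range Sampling range of the CS+ value.
#' @param n_restarts Local restarts per fit; the default is a fast mode, use
#'   30 to reproduce the full protocol.
#' @param p_monotonic P(monotonic kernel) among value/hybrid draws.
#' @param seed Integer seed.
#' @param maxeval_global DIRECT-L evaluation budget per fit.
#' @return A `recovery_report`: `confusion` (counts matrix), `accuracy`
#'   (percent correct per generating model), `results` (one row per dataset
#'   with generative and recovered parameters of the generating model),
#'   `n_ties`, `n_failed`.
#' @examples
#' rep <- model_recovery(n_datasets = 2, n_restarts = 2, seed = 1,
#'                       maxeval_global = 40)
#' rep$confusion
#' @export
model_recovery <- function(n_datasets = 120,
                           models = c("perceptual", "value"),
                           ranges = param_ranges(), v_range = c(0.2, 0.9),
                           n_restarts = 5, p_monotonic = 0.5512, seed = 1,
                           maxeval_global = 200) {
  if (n_datasets < 2) abort("`n_datasets` must be >= 2.")
  models <- match.arg(models, c("perceptual", "value", "hybrid"),
                      several.ok = TRUE)
  space <- build_space(0.05)
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))

  results <- purrr::map_dfr(models, function(gen_model) {
    set.seed(derive_seed(seed, paste("model_recovery", gen_model)))
    draws <- sample_params(gen_model, n = n_datasets, ranges = ranges,
                           p_monotonic = p_monotonic)
    vs <- runif(n_datasets, v_range[1], v_range[2])
    purrr::map_dfr(seq_len(n_datasets), function(i) {
      row <- draws[i, ]
      pars <- row_to_params(gen_model, row)
      trials <- simulate_generalisation(
        gen_model, pars, vs[i], space,
        seed = derive_seed(seed, paste("sim", gen_model, i)))
      fits <- lapply(models, function(m) {
        tryCatch(
          fit_gradient(trials, m, v = vs[i], space = space,
                       n_restarts = n_restarts,
                       seed = derive_seed(seed, paste(gen_model, i, m)),
                       maxeval_global = maxeval_global),
          error = function(e) e
        )
      })
      failed <- vapply(fits, inherits, logical(1), "error")
      if (any(failed)) {
        return(dplyr::bind_cols(
          tibble(generative = gen_model, dataset = i, best = NA_character_,
                 tie = NA, failed = TRUE, v = vs[i]),
          stats::setNames(row, paste0("gen_", names(row)))
        ))
      }
      cmp <- compare_fits(fits)
      own <- fits[[which(models == gen_model)]]
      rec <- tidy(own)
      rec_wide <- stats::setNames(as.list(rec$estimate), paste0("rec_", rec$term))
      if (gen_model != "perceptual") rec_wide$rec_omega <- own$params$omega
      dplyr::bind_cols(
        tibble(generative = gen_model, dataset = i, best = cmp$winner,
               tie = cmp$tie, failed = FALSE, v = vs[i],
               relative_fit = cmp$relative_fit),
        stats::setNames(row, paste0("gen_", names(row))),
        tibble::as_tibble(rec_wide)
      )
    })
  })

  ok <- dplyr::filter(results, !.data$failed)
  confusion <- table(factor(ok$generative, levels = models),
                     factor(ok$best, levels = models))
  accuracy <- 100 * diag(as.matrix(confusion)) / rowSums(as.matrix(confusion))
  structure(
    list(confusion = confusion, accuracy = accuracy, results = results,
         n_datasets = n_datasets, models = models,
         n_ties = sum(ok$tie), n_failed = sum(results$failed), seed = seed,
         config = list(ranges = ranges, v_range = v_range,
                       n_restarts = n_restarts, p_monotonic = p_monotonic,
                       maxeval_global = maxeval_global)),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>", x$n_datasets, "datasets per generating model\n")
  print(x$confusion)
  cat("accuracy (%):", paste(sprintf("%s %.2f", names(x$accuracy), x$accuracy),
                             collapse = ", "), "\n")
  if (x$n_ties) cat("BIC ties:", x$n_ties, "\n")
  if (x$n_failed) cat("failed fits (excluded):", x$n_failed, "\n")
  invisible(x)
}

#' Parameter recovery
#'
#' Draws `n_datasets` parameter sets for one model across their generative
#' ranges, simulates one 36-trial dataset each, refits the same model, and
#' correlates generative with recovered parameter values (Pearson for every
#' parameter; Spearman additionally for the generalisation strength `lam`,
#' whose influence on predictions is strongly nonlinear). A generative
#' parameter held constant yields an undefined correlation, reported as `NA`
#' with a warning.
#'
#' @inheritParams model_recovery
#' @param model The model to generate from and refit.
#' @return A `param_recovery`: `correlations` tibble (`term`, `pearson`,
#'   `spearman`), and `draws` with generative and recovered values per
#'   dataset for plotting.
#' @export
parameter_recovery <- function(model, n_datasets = 120,
                               ranges = param_ranges(), v_range = c(0.2, 0.9),
                               n_restarts = 5, p_monotonic = 0.5512, seed = 1,
                               maxeval_global = 200) {
  if (n_datasets < 2) abort("`n_datasets` must be >= 2.")
  model <- match.arg(model, c("perceptual", "value", "hybrid"))
  space <- build_space(0.05)
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, paste("param_recovery", model)))
  draws <- sample_params(model, n = n_datasets, ranges = ranges,
                         p_monotonic = p_monotonic)
  vs <- runif(n_datasets, v_range[1], v_range[2])

  res <- purrr::map_dfr(seq_len(n_datasets), function(i) {
    row <- draws[i, ]
    trials <- simulate_generalisation(
      model, row_to_params(model, row), vs[i], space,
      seed = derive_seed(seed, paste("pr-sim", model, i)))
    fit <- tryCatch(
      fit_gradient(trials, model, v = vs[i], space = space,
                   n_restarts = n_restarts,
                   seed = derive_seed(seed, paste("pr", model, i)),
                   maxeval_global = maxeval_global),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      return(dplyr::bind_cols(tibble(dataset = i, failed = TRUE),
                              stats::setNames(row, paste0("gen_", names(row)))))
    }
    rec <- tidy(fit)
    out <- dplyr::bind_cols(
      tibble(dataset = i, failed = FALSE),
      stats::setNames(row, paste0("gen_", names(row))),
      stats::setNames(as.list(rec$estimate), paste0("rec_", rec$term))
    )
    if (model != "perceptual") out$rec_omega <- fit$params$omega
    out
  })

  ok <- dplyr::filter(res, !.data$failed)
  terms <- model_par_names(model)
  correlations <- purrr::map_dfr(terms, function(p) {
    g <- ok[[paste0("gen_", p)]]
    r <- ok[[paste0("rec_", p)]]
    if (stats::sd(g) == 0 || stats::sd(r) == 0) {
      warn(sprintf("Correlation undefined for `%s` (constant values).", p))
      return(tibble(term = p, pearson = NA_real_, spearman = NA_real_))
    }
    tibble(term = p,
           pearson = cor(g, r),
           spearman = cor(g, r, method = "spearman"))
  })
  structure(
    list(model = model, correlations = correlations, draws = res,
         n_datasets = n_datasets, n_failed = sum(res$failed), seed = seed,
         config = list(ranges = ranges, v_range = v_range,
                       n_restarts = n_restarts, p_monotonic = p_monotonic,
                       maxeval_global = maxeval_global)),
    class = "param_recovery"
  )
}

#' @export
print.param_recovery <- function(x, ...) {
  cat("<param_recovery>", x$model, "model,", x$n_datasets, "datasets\n")
  print(as.data.frame(x$correlations), row.names = FALSE)
  if (x$n_failed) cat("failed fits (excluded):", x$n_failed, "\n")
  invisible(x)
}
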