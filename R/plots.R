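# Diagnostic plots ------------------------------------------------------------

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_text geom_abline facet_wrap labs theme_minimal scale_x_continuous
#' @export
ggplot2::autoplot

# expected rating under the censored-normal observation stage (for display)
expected_rating <- function(mu, sigma) {
  a <- (0 - mu) / sigma
  b <- (1 - mu) / sigma
  mu * (pnorm(b) - pnorm(a)) + sigma * (dnorm(a) - dnorm(b)) +
    (1 - pnorm(b))
}

#' Plot observed versus predicted generalisation gradient
#'
#' Shows the stimulus-mean observed ratings of the fitted trials together
#' with the model-implied expected rating profile (mixture-weighted,
#' censoring-corrected means).
#'
#' @param object A `gen_fit`.
#' @param trials The generalisation trials the model was fitted to.
#' @param space A `stimulus_space`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gen_fit
#' @export
autoplot.gen_fit <- function(object, trials, space = build_space(0.05), ...) {
  comp <- mixture_components(object$model, object$params, object$v, space)
  er <- expected_rating(comp$mean, object$params$sigma)
  pred <- rowSums(comp$weight * er)
  obs <- stimulus_means(trials)
  df <- tibble(
    stimulus = rep(1:9, 2),
    rating = c(obs, pred),
    source = rep(c("observed", "predicted"), each = 9)
  )
  ggplot(df, aes(x = .data$stimulus, y = .data$rating,
                 colour = .data$source)) +
    geom_line() + geom_point() +
    scale_x_continuous(breaks = 1:9) +
    labs(x = "stimulus (CS+ = 5)", y = "expectancy rating",
         title = paste(object$model, "model fit"),
         subtitle = sprintf("BIC = %.1f", object$bic)) +
    theme_minimal()
}

#' Plot a model-recovery confusion matrix
#'
#' @param object A `recovery_report`.
#' @param ... Unused.
#' @return A ggplot tile plot of the generative vs best-fitting confusion
#'   matrix (percentages within generating model).
#' @method autoplot recovery_report
#' @export
autoplot.recovery_report <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  names(df) <- c("generative", "best", "n")
  df <- dplyr::mutate(dplyr::group_by(df, .data$generative),
                      pct = 100 * .data$n / sum(.data$n))
  ggplot(df, aes(x = .data$best, y = .data$generative, fill = .data$pct)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.1f%%", .data$pct))) +
    labs(x = "best-fitting model (BIC)", y = "generating model",
         fill = "%", title = "Model recovery") +
    theme_minimal()
}

#' Plot generative versus recovered parameters
#'
#' @param object A `param_recovery`.
#' @param ... Unused.
#' @return A ggplot scatter, one facet per parameter, with the identity
#'   line.
#' @method autoplot param_recovery
#' @export
autoplot.param_recovery <- function(object, ...) {
  ok <- dplyr::filter(object$draws, !.data$failed)
  terms <- model_par_names(object$model)
  long <- purrr::map_dfr(terms, function(p) {
    tibble(term = p, generative = ok[[paste0("gen_", p)]],
           recovered = ok[[paste0("rec_", p)]])
  })
  ggplot(long, aes(x = .data$generative, y = .data$recovered)) +
    geom_point(alpha = 0.5) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    facet_wrap(~term, scales = "free") +
    labs(title = paste("Parameter recovery:", object$model, "model")) +
    theme_minimal()
}

#' Plot a titration staircase trace
#'
#' @param result A `titration_result`.
#' @return A ggplot of delta-kappa over trials, different-trials marked by
#'   correctness.
#' @export
plot_staircase <- function(result) {
  stopifnot(inherits(result, "titration_result"))
  h <- result$history
  ggplot(h, aes(x = .data$trial, y = .data$delta_kappa)) +
    geom_line(colour = "grey50") +
    geom_point(data = dplyr::filter(h, .data$different),
               aes(colour = .data$correct)) +
    labs(x = "trial", y = expression(Delta * kappa),
         title = sprintf("Weighted up-down staircase (target %.0f%%)",
                         100 * result$target_p)) +
    theme_minimal()
}

#' Plot cohort generalisation gradients by mechanism
#'
#' Mean rating per stimulus for each generative mechanism (and pattern, for
#' value generalisers) of a synthetic cohort.
#'
#' @param cohort A `syn_cohort`.
#' @return A ggplot object.
#' @export
plot_cohort_gradients <- function(cohort) {
  stopifnot(inherits(cohort, "syn_cohort"))
  gen <- dplyr::filter(cohort$trials, .data$phase == "generalisation")
  lab <- dplyr::mutate(
    cohort$truth,
    group = dplyr::if_else(.data$mechanism == "value",
                           paste0("value (", dplyr::if_else(.data$omega == 1,
                                                            "gaussian",
                                                            "monotonic"), ")"),
                           .data$mechanism)
  )[, c("participant", "condition_rr", "condition_disc", "group")]
  df <- dplyr::left_join(gen, lab,
                         by = c("participant", "condition_rr",
                                "condition_disc"))
  agg <- dplyr::summarise(
    dplyr::group_by(df, .data$group, .data$stimulus),
    rating = mean(.data$rating), .groups = "drop"
  )
  ggplot(agg, aes(x = .data$stimulus, y = .data$rating,
                  colour = .data$group)) +
    geom_line() + geom_point() +
    scale_x_continuous(breaks = 1:9) +
    labs(x = "stimulus (CS+ = 5)", y = "mean expectancy rating",
         colour = "generator", title = "Cohort generalisation gradients") +
    theme_minimal()
}
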