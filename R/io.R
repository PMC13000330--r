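# File-format contracts and pipeline orchestration ---------------------------

TRIAL_COLS <- c("participant", "condition_rr", "condition_disc", "phase",
                "trial", "stimulus", "rating", "reinforced")

#' Read and validate a trial table
#'
#' Reads the delimited trial format: header
#' `participant, condition_rr, condition_disc, phase, trial, stimulus,
#' rating, reinforced`. Ratings given on the 0-100 slider scale are rescaled
#' to \[0, 1\] on read (detected when any rating exceeds 1). Malformed rows
#' (bad phase, stimulus outside 1..9, out-of-range ratings) raise an error
#' listing the offending line numbers. Generalisation blocks with a row
#' count other than 36 trigger a warning, and the returned tibble carries an
#' `incomplete_blocks` attribute flagging them.
#'
#' @param path CSV file path.
#' @return A validated trial tibble.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) abort(paste0("Trials file not found: ", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRIAL_COLS, names(raw))
  if (length(missing)) {
    abort(paste0("Trials file is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  raw <- as_tibble(raw)
  bad_phase <- which(!raw$phase %in% c("learning", "generalisation"))
  bad_stim <- which(is.na(raw$stimulus) | raw$stimulus < 1 | raw$stimulus > 9 |
                      raw$stimulus != round(raw$stimulus))
  if (max(raw$rating, na.rm = TRUE) > 1) raw$rating <- raw$rating / 100
  bad_rating <- which(!is.na(raw$rating) & (raw$rating < 0 | raw$rating > 1))
  problems <- list(phase = bad_phase, stimulus = bad_stim, rating = bad_rating)
  problems <- problems[lengths(problems) > 0]
  if (length(problems)) {
    msg <- vapply(names(problems), function(nm) {
      sprintf("invalid %s at line(s) %s", nm,
              paste(utils::head(problems[[nm]] + 1L, 10), collapse = ", "))
    }, character(1))
    abort(paste0("Malformed trial rows in ", path, ": ",
                 paste(msg, collapse = "; ")))
  }
  raw$reinforced <- as.logical(raw$reinforced)
  gen_counts <- dplyr::count(
    dplyr::filter(raw, .data$phase == "generalisation"),
    .data$participant, .data$condition_rr, .data$condition_disc
  )
  incomplete <- dplyr::filter(gen_counts, .data$n != 36)
  if (nrow(incomplete)) {
    warn(sprintf("%d generalisation block(s) do not have 36 rows (9 stimuli x 4 repetitions).",
                 nrow(incomplete)))
  }
  attr(raw, "incomplete_blocks") <- incomplete
  raw
}

#' Write a trial table / fit results / a fit as JSON
#'
#' `write_trials()` writes the trial CSV (ratings on the \[0, 1\] scale, full
#' precision, so write-then-read round-trips). `write_fit_results()` writes
#' the per-fit summary CSV from [fit_models()] (the `fit` list-column is
#' dropped). `write_fit_json()` serialises one `gen_fit`.
#'
#' @param trials,fits_tbl,fit The object to write.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  df <- as.data.frame(trials[, TRIAL_COLS])
  df$rating <- format(df$rating, digits = 15, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
write_fit_results <- function(fits_tbl, path) {
  df <- dplyr::select(fits_tbl, -dplyr::any_of("fit"))
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "gen_fit"))
  out <- list(
    schema = "gengrad_fit/1",
    model = fit$model,
    params = unclass(fit$params),
    bounds = {
      b <- model_box(fit$model)
      stats::setNames(lapply(seq_along(b$names),
                             function(i) c(b$lb[i], b$ub[i])), b$names)
    },
    nll = fit$nll, bic = fit$bic, k = fit$k, n = fit$n,
    n_restarts = fit$n_restarts, best_restart = fit$best_restart,
    v = fit$v, seed = fit$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run configuration
#'
#' @param seed Top-level seed; every stochastic stage derives its own stream
#'   from it.
#' @param out_dir Output directory.
#' @param models Models to fit.
#' @param n_restarts Restarts per fit.
#' @param gen_config A [generative_config()] (its seed is overridden by
#'   `seed`).
#' @param maxeval_global DIRECT-L budget per fit.
#' @param verbose Print stage progress.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("gengrad_run"),
                       models = c("perceptual", "value"), n_restarts = 5,
                       gen_config = generative_config(),
                       maxeval_global = 200, verbose = TRUE) {
  gen_config$seed <- seed
  structure(list(seed = seed, out_dir = out_dir, models = models,
                 n_restarts = n_restarts, gen_config = gen_config,
                 maxeval_global = maxeval_global, verbose = verbose),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Simulate (or read) a cohort, fit the models to every gradient, compare
#' them by BIC, compute the gradient summaries and the anxiety association,
#' and write all reports plus a manifest to `out_dir`. Deterministic stages
#' are bit-identical on rerun with the same config.
#'
#' @param config A [run_config()].
#' @param trials Optional trial table (or CSV path) to analyse instead of a
#'   simulated cohort.
#' @param anxiety Optional tibble `participant`, `anxiety` (taken from the
#'   simulated cohort when available).
#' @return Invisibly, a list with `summary`, `comparison`, `fits`,
#'   `association` and `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), trials = NULL, anxiety = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$verbose) message("[gengrad] ", ...)

  if (is.null(trials)) {
    say("simulating cohort (n = ", config$gen_config$n_participants, ")")
    cohort <- simulate_cohort(config$gen_config)
    trials <- cohort$trials
    anxiety <- anxiety %||%
      cohort$participants[, c("participant", "anxiety")]
    write_trials(trials, file.path(config$out_dir, "trials.csv"))
  } else if (is.character(trials)) {
    say("reading trials from ", trials)
    trials <- read_trials(trials)
  }

  say("fitting models: ", paste(config$models, collapse = ", "))
  fits <- fit_models(trials, models = config$models,
                     n_restarts = config$n_restarts, seed = config$seed,
                     maxeval_global = config$maxeval_global)
  write_fit_results(fits, file.path(config$out_dir, "fits.csv"))

  say("comparing models and summarising gradients")
  summary <- summarise_gradients(trials, fits, anxiety = anxiety)
  utils::write.csv(as.data.frame(summary),
                   file.path(config$out_dir, "summary.csv"), row.names = FALSE)

  association <- NULL
  if (!is.null(anxiety) && all(c("perceptual", "value") %in% config$models)) {
    per_part <- dplyr::summarise(
      dplyr::group_by(summary, .data$participant),
      relative_fit = mean(.data$relative_fit),
      anxiety = .data$anxiety[1], .groups = "drop"
    )
    association <- anxiety_association(per_part$relative_fit, per_part$anxiety,
                                       seed = config$seed)
    utils::write.csv(as.data.frame(association),
                     file.path(config$out_dir, "anxiety_association.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    schema = "gengrad_run/1",
    seed = config$seed,
    models = config$models,
    n_restarts = config$n_restarts,
    package_version = as.character(utils::packageVersion("gengrad")),
    r_version = R.version.string,
    n_participants = dplyr::n_distinct(trials$participant),
    config_hash = config_hash(config)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done: ", config$out_dir)
  invisible(list(summary = summary, fits = fits, association = association,
                 out_dir = config$out_dir))
}

# cheap stable hash of the serialised config (hex of a 32-bit rolling sum);
# output location and verbosity do not affect results, so they are excluded
config_hash <- function(config) {
  core <- unclass(config)
  core$out_dir <- NULL
  core$verbose <- NULL
  bytes <- as.integer(serialize(core, NULL))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
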