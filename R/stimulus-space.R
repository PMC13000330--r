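#' Build a personalised 9-stimulus continuum
#'
#' Constructs the nine-item shape-spikiness continuum used in the
#' generalisation task. The conditioned stimulus (CS+) of medium spikiness
#' (kappa = 0.5) sits at the centre, with four generalisation stimuli on each
#' side separated by the titrated step size `delta_kappa`.
#'
#' A step size above 0.125 would place the endpoint stimuli outside the
#' defined kappa range; such spaces are rejected, mirroring the participant
#' exclusion rule of the titration procedure. The boundary itself
#' (`delta_kappa == 0.125`, giving kappa exactly 0 and 1) is also rejected
#' because all shapes must lie strictly inside (0, 1).
#'
#' @param delta_kappa Titrated step between neighbouring stimuli, in kappa
#'   units. Must satisfy `0 < delta_kappa < 0.125`.
#' @param cs_kappa Spikiness of the CS+; the task always uses 0.5.
#' @param condition_label Optional free-text label (e.g. `"rr50_disc80"`).
#'
#' @return An object of class `stimulus_space`: a list with `kappa_values`
#'   (9 strictly increasing values), `delta_kappa`, `cs_index` (always 5) and
#'   `condition_label`.
#' @examples
#' sp <- build_space(0.05)
#' sp$kappa_values
#' @export
build_space <- function(delta_kappa, cs_kappa = 0.5, condition_label = NA_character_) {
  if (!is.numeric(delta_kappa) || length(delta_kappa) != 1 || is.na(delta_kappa) ||
      delta_kappa <= 0) {
    abort("`delta_kappa` must be a single positive number.")
  }
  if (delta_kappa >= 0.125) {
    abort(paste0(
      "`delta_kappa` = ", format(delta_kappa), " would place the stimulus space ",
      "outside the defined kappa range (0, 1); step sizes of 0.125 or more are ",
      "rejected (exclusion rule: delta_kappa > 0.125, tightened at the boundary ",
      "because endpoints must stay strictly inside (0, 1))."
    ))
  }
  assert_scalar_in(cs_kappa, 0, 1, "cs_kappa", open_lo = TRUE, open_hi = TRUE)
  kappa <- cs_kappa + (-4:4) * delta_kappa
  if (any(kappa <= 0) || any(kappa >= 1)) {
    abort("Stimulus space leaves the open kappa interval (0, 1); reduce `delta_kappa`.")
  }
  structure(
    list(
      kappa_values = kappa,
      delta_kappa = delta_kappa,
      cs_index = 5L,
      condition_label = condition_label
    ),
    class = "stimulus_space"
  )
}

#' @export
print.stimulus_space <- function(x, ...) {
  cat("<stimulus_space> 9 stimuli, CS+ at index", x$cs_index, "\n")
  cat("  kappa:", paste(format(x$kappa_values, digits = 4), collapse = " "), "\n")
  cat("  delta_kappa:", format(x$delta_kappa), "\n")
  if (!is.na(x$condition_label)) cat("  condition:", x$condition_label, "\n")
  invisible(x)
}

#' Distance between two stimuli on the continuum
#'
#' Distances are measured in integer stimulus-index units (not kappa units):
#' the titration procedure equates the perceptual discriminability of
#' neighbouring stimuli, so index distance is the psychologically uniform
#' scale the generalisation models assume.
#'
#' @param space A `stimulus_space`.
#' @param i,j Stimulus indices in 1..9 (vectorised, recycled).
#' @return Non-negative integer distance(s) `|i - j|`.
#' @examples
#' sp <- build_space(0.05)
#' stim_distance(sp, 5, 2)
#' @export
stim_distance <- function(space, i, j) {
  stopifnot(inherits(space, "stimulus_space"))
  n <- length(space$kappa_values)
  if (any(i < 1 | i > n | i != round(i)) || any(j < 1 | j > n | j != round(j))) {
    abort(sprintf("Stimulus indices must be integers in 1..%d.", n))
  }
  as.integer(abs(i - j))
}

#' Validate an experimental condition
#'
#' The task crosses three CS+ reinforcement rates (25/50/75% scream
#' probability) with two discriminability levels (60% and 80% correct
#' identification of neighbours as different).
#'
#' @param reinforcement_rate Probability the CS+ is followed by the scream.
#' @param discriminability Target titration accuracy.
#' @param allow_other Permit values outside the study design levels.
#' @return A tibble row with the validated condition and its label.
#' @export
condition <- function(reinforcement_rate, discriminability, allow_other = FALSE) {
  if (!allow_other) {
    if (!reinforcement_rate %in% c(0.25, 0.50, 0.75)) {
      abort("`reinforcement_rate` must be one of 0.25, 0.50, 0.75 (or set `allow_other`).")
    }
    if (!discriminability %in% c(0.60, 0.80)) {
      abort("`discriminability` must be 0.60 or 0.80 (or set `allow_other`).")
    }
  }
  tibble(
    reinforcement_rate = reinforcement_rate,
    discriminability = discriminability,
    condition = sprintf("rr%02d_disc%02d", round(100 * reinforcement_rate),
                        round(100 * discriminability))
  )
}

#' All six study conditions
#' @return A 6-row tibble of the crossed design.
#' @export
study_conditions <- function() {
  grid <- tidyr::expand_grid(
    reinforcement_rate = c(0.25, 0.50, 0.75),
    discriminability = c(0.60, 0.80)
  )
  dplyr::bind_rows(purrr::pmap(grid, condition))
}

#' Serialise / deserialise a stimulus space as JSON
#' @param space A `stimulus_space`.
#' @param path File path.
#' @return `write_space` returns `path` invisibly; `read_space` the space.
#' @export
write_space <- function(space, path) {
  stopifnot(inherits(space, "stimulus_space"))
  jsonlite::write_json(unclass(space), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_space
#' @export
read_space <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_space(x$delta_kappa,
              cs_kappa = x$kappa_values[x$cs_index],
              condition_label = x$condition_label %||% NA_character_)
}
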