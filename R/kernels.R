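#' Gaussian-like generalisation kernel
#'
#' Similarity kernel of the value model when the shape parameter Omega = 1:
#' `G(d) = 2 / (1 + exp(d^2 / lambda))`. Equals 1 at the CS+ (d = 0) and
#' decays with squared stimulus distance; larger `lam` gives wider
#' generalisation. As `lam -> 0` the kernel collapses to a stick at the CS+
#' (the limit 0 is returned for d > 0 when `lam <= 0`).
#'
#' @param d Non-negative integer stimulus distance(s) from the CS+.
#' @param lam Generalisation-strength parameter, in (0, 10].
#' @return Kernel values in (0, 1].
#' @examples
#' gaussian_kernel(0:4, lam = 3)
#' @export
gaussian_kernel <- function(d, lam) {
  if (any(d < 0)) abort("`d` must be non-negative.")
  if (length(lam) != 1 || is.na(lam)) abort("`lam` must be a single number.")
  if (lam <= 0) {
    # limiting stick kernel: all mass at the CS+
    return(as.numeric(d == 0))
  }
  2 / (1 + exp(d^2 / lam))
}

#' Monotonic generalisation kernel
#'
#' Similarity kernel of the value model when Omega = 0: on the peak side of
#' the CS+ the Gaussian decay is reflected above 1 (`G = 1 + |1 - G_gauss|`),
#' on the other side it is the plain Gaussian decay, producing a strictly
#' monotone profile across the continuum that passes through 1 at the CS+.
#'
#' @param signed_position Integer position(s) relative to the CS+, in -4..4
#'   (negative = left of the CS+).
#' @param lam Generalisation-strength parameter, in (0, 10].
#' @param peak_side Which end of the continuum carries the highest value;
#'   pre-processed gradients are flipped to peak left, so `"left"` is the
#'   canonical orientation.
#' @return Kernel values in (0, 2).
#' @examples
#' monotonic_kernel(-4:4, lam = 3)
#' @export
monotonic_kernel <- function(signed_position, lam, peak_side = c("left", "right")) {
  peak_side <- match.arg(peak_side)
  if (any(abs(signed_position) > 4) || any(signed_position != round(signed_position))) {
    abort("`signed_position` must be integers in -4..4.")
  }
  g <- gaussian_kernel(abs(signed_position), lam)
  on_peak_side <- if (peak_side == "left") signed_position < 0 else signed_position > 0
  ifelse(on_peak_side, 2 - g, g)
}
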