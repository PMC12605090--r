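#' Build a non-uniform saturation-offset grid
#'
#' Constructs the saturation-frequency sampling scheme used for Z-spectrum
#' acquisition: a coarse step in the peripheral ranges
#' `[-outer, -inner]` and `[inner, outer]` and a finer step in the central
#' range `[-inner, inner]`. The default arguments reproduce a 91-point grid
#' from -5 to 5 ppm with 0.2 ppm peripheral and 0.1 ppm central sampling.
#'
#' @param coarse_step Peripheral step size (ppm).
#' @param fine_step Central step size (ppm); must not exceed `coarse_step`.
#' @param outer Half-width of the full acquisition window (ppm).
#' @param inner Half-width of the finely sampled central range (ppm).
#' @return Numeric vector of strictly increasing offsets (ppm) covering
#'   `[-outer, outer]`; the boundary offsets at `-inner` and `inner` appear
#'   exactly once.
#' @examples
#' g <- build_offset_grid()
#' length(g)   # 91
#' range(g)    # -5, 5
#' @export
build_offset_grid <- function(coarse_step = 0.2, fine_step = 0.1,
                              outer = 5, inner = 4) {
  stopifnot(fine_step > 0, coarse_step >= fine_step, inner > 0, outer >= inner)
  .check_divides <- function(len, step, what) {
    k <- len / step
    if (abs(k - round(k)) > 1e-9 / step) {
      stop(sprintf("step %g ppm does not evenly divide the %s range (length %g ppm)",
                   step, what, len), call. = FALSE)
    }
  }
  if (outer > inner) .check_divides(outer - inner, coarse_step, "peripheral")
  .check_divides(2 * inner, fine_step, "central")
  periph_n <- round((outer - inner) / coarse_step)
  fine_n <- round(2 * inner / fine_step)
  left <- -outer + coarse_step * seq(0, periph_n)
  centre <- -inner + fine_step * seq(0, fine_n)
  right <- inner + coarse_step * seq(0, periph_n)
  offs <- c(left[-length(left)], centre, right[-1])
  # snap to exact multiples of the fine step to avoid FP residue
  offs <- round(offs / fine_step) * fine_step
  stopifnot(all(diff(offs) > 0))
  offs
}

#' Default WASSR acquisition grid
#'
#' The WASSR sweep covers a narrow window around the water resonance on a
#' dense uniform grid. The acquisition grid of the direct-water reference
#' scan is configurable; the default spans +/-1 ppm in 0.05 ppm steps.
#'
#' @param half_width Half-width of the sweep (ppm).
#' @param step Step size (ppm).
#' @return Numeric vector of offsets (ppm).
#' @export
wassr_grid <- function(half_width = 1, step = 0.05) {
  stopifnot(half_width > 0, step > 0)
  seq(-half_width, half_width, by = step)
}
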