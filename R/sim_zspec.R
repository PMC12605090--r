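#' Simulate a Z-spectrum from a Lorentzian pool set
#'
#' Generates `S/S0(offset) = 1 - sum_i L_i(offset - b0_shift)` with optional
#' seeded noise. The ground-truth pool table and B0 shift are recorded in
#' the spectrum metadata for recovery tests.
#'
#' @param pools A [pool_table].
#' @param offsets Offset grid (ppm), e.g. from [build_offset_grid].
#' @param b0_shift Apparent water-frequency offset (ppm) applied to all
#'   pools, emulating B0 inhomogeneity.
#' @param noise Optional [noise_spec]; `NULL` for noiseless.
#' @return A [zspectrum] with `meta$truth` (pools, b0_shift).
#' @export
simulate_zspectrum_lorentzian <- function(pools, offsets, b0_shift = 0,
                                          noise = NULL) {
  if (nrow(pools) > 0) {
    ctr <- pools$center + b0_shift
    if (any(ctr < min(offsets) | ctr > max(offsets))) {
      stop("pool center outside the offset grid span after B0 shift",
           call. = FALSE)
    }
  }
  drop <- .pool_drop(pools, offsets - b0_shift)
  if (any(drop > 1 + 1e-12)) {
    stop("pool amplitudes sum above 1 at some offset: signal would go negative",
         call. = FALSE)
  }
  sig <- .apply_noise(1 - drop, noise)
  zspectrum(offsets, pmin(pmax(sig, -0.1), 1.1),
            meta = list(truth = list(pools = pools, b0_shift = b0_shift)))
}

#' Simulate a WASSR spectrum
#'
#' Low-power direct-water reference line: a single Lorentzian of
#' near-complete saturation depth centered at the local B0 offset, sampled
#' on a dense narrow grid around water.
#'
#' @param b0_shift True water-frequency offset (ppm); must lie within half
#'   the grid span.
#' @param offsets WASSR acquisition grid (ppm), default [wassr_grid()].
#' @param width Water line FWHM (ppm).
#' @param depth Saturation depth (peak drop) of the line.
#' @param noise Optional [noise_spec].
#' @return A [zspectrum] with `meta$truth$b0_shift`.
#' @export
generate_wassr_spectrum <- function(b0_shift, offsets = wassr_grid(),
                                    width = 0.3, depth = 0.95, noise = NULL) {
  span <- max(offsets) - min(offsets)
  stopifnot(abs(b0_shift) < span / 2, width > 0, depth > 0, depth <= 1)
  sig <- 1 - lorentzian_value(offsets, depth, b0_shift, width)
  sig <- .apply_noise(sig, noise)
  zspectrum(offsets, pmin(pmax(sig, -0.1), 1.1),
            meta = list(truth = list(b0_shift = b0_shift)))
}
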