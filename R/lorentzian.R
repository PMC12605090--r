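#' Lorentzian line value
#'
#' The Lorentzian used throughout the decomposition is parameterized by its
#' peak amplitude `A` (value at the center), center `c` (ppm) and full width
#' at half maximum `W` (ppm):
#' \deqn{L(\Delta) = A \frac{(W/2)^2}{(W/2)^2 + (\Delta - c)^2}}
#'
#' @param offset Offset(s) at which to evaluate (ppm); vectorized.
#' @param amplitude Peak amplitude `A` (dimensionless signal-drop fraction).
#' @param center Center `c` (ppm).
#' @param fwhm Full width at half maximum `W` (ppm), positive.
#' @return Numeric vector of line values.
#' @examples
#' lorentzian_value(3.5, 0.1, 3.5, 1)  # 0.1 at the center
#' lorentzian_value(4.0, 0.1, 3.5, 1)  # 0.05 at c + W/2
#' @export
lorentzian_value <- function(offset, amplitude, center, fwhm) {
  stopifnot(all(fwhm > 0), all(amplitude >= 0))
  hw2 <- (fwhm / 2)^2
  amplitude * hw2 / (hw2 + (offset - center)^2)
}

#' Pool table constructor
#'
#' A pool set is a data frame with one Lorentzian line per exchanging pool.
#'
#' @param name Character labels.
#' @param amplitude Peak signal-drop fractions in `[0, 1]`.
#' @param center Centers (ppm).
#' @param fwhm Full widths at half maximum (ppm).
#' @return A data frame of class `pool_table`.
#' @export
pool_table <- function(name, amplitude, center, fwhm) {
  stopifnot(all(fwhm > 0), all(amplitude >= 0), all(amplitude <= 1))
  structure(data.frame(name = as.character(name), amplitude = amplitude,
                       center = center, fwhm = fwhm,
                       stringsAsFactors = FALSE),
            class = c("pool_table", "data.frame"))
}

#' Default five-pool baseline
#'
#' Baseline pool set representative of brain tissue at 7 T under 2 uT
#' continuous-wave saturation: direct water saturation at 0 ppm,
#' semi-solid magnetization transfer contrast (MTC) at -1.5 ppm, relayed
#' NOE at -3.5 ppm, creatine at 2 ppm, and the combined amide/amine
#' (mobile proteins/peptides and glutamate) pool at 3.5 ppm.
#'
#' @return A `pool_table` with five rows.
#' @export
default_pools <- function() {
  pool_table(
    name      = c("water", "mtc", "noe", "creatine", "amide"),
    amplitude = c(0.85, 0.10, 0.08, 0.03, 0.05),
    center    = c(0, -1.5, -3.5, 2, 3.5),
    fwhm      = c(1.6, 6, 1.5, 0.8, 1.2)
  )
}

# total signal drop of a pool set at given offsets
.pool_drop <- function(pools, offsets) {
  drop <- numeric(length(offsets))
  for (i in seq_len(nrow(pools))) {
    drop <- drop + lorentzian_value(offsets, pools$amplitude[i],
                                    pools$center[i], pools$fwhm[i])
  }
  drop
}

#' Evaluate a five-pool model as a Z-spectrum
#'
#' Forward model of the decomposition: `S/S0 = 1 - sum_i L_i(offset)`.
#' The drop is linear in the pool amplitudes.
#'
#' @param pools A `pool_table` (any number of rows; the fit uses five).
#' @param offsets Offsets (ppm) at which to evaluate.
#' @return A [zspectrum].
#' @export
five_pool_eval <- function(pools, offsets) {
  zspectrum(offsets, 1 - .pool_drop(pools, offsets))
}

#' Closed-form integral of a Lorentzian pool over a window
#'
#' The fitted integral of a pool's isolated line over `[a, b]`:
#' \deqn{\int_a^b L \, d\Delta = A \frac{W}{2}\left[\arctan\frac{b-c}{W/2}
#'   - \arctan\frac{a-c}{W/2}\right]}
#' Units are ppm times the dimensionless drop.
#'
#' @param amplitude,center,fwhm Pool parameters as in [lorentzian_value]
#'   (vectorized over pools).
#' @param window Length-2 numeric, integration limits in ppm (low, high).
#' @return Numeric integral value(s).
#' @examples
#' pool_integral(0.1, 0, 1, c(-1e6, 1e6))  # ~ pi * A * W / 2
#' @export
pool_integral <- function(amplitude, center, fwhm, window = c(-5, 5)) {
  stopifnot(length(window) == 2, window[1] < window[2])
  hw <- fwhm / 2
  amplitude * hw * (atan((window[2] - center) / hw) -
                      atan((window[1] - center) / hw))
}
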