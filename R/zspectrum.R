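#' Z-spectrum container
#'
#' A Z-spectrum is the normalized water signal S/S0 sampled on a strictly
#' increasing saturation-offset grid (ppm relative to water). Missing
#' samples (e.g. dropped after B0 correction) are stored as `NA` and are
#' excluded from fitting.
#'
#' @param offsets Strictly increasing numeric vector of offsets (ppm).
#' @param signal Numeric vector of S/S0 values, same length as `offsets`.
#'   Values must lie in `[-0.1, 1.1]` (small excursions allowed for noise).
#' @param meta Optional named list of acquisition metadata.
#' @return An object of class `zspectrum`.
#' @export
zspectrum <- function(offsets, signal, meta = list()) {
  offsets <- as.numeric(offsets)
  signal <- as.numeric(signal)
  stopifnot(length(offsets) == length(signal),
            all(is.finite(offsets)), all(diff(offsets) > 0))
  ok <- is.finite(signal)
  if (any(signal[ok] < -0.1 | signal[ok] > 1.1)) {
    stop("normalized signal outside [-0.1, 1.1]", call. = FALSE)
  }
  structure(list(offsets = offsets, signal = signal, meta = meta),
            class = "zspectrum")
}

#' @export
print.zspectrum <- function(x, ...) {
  cat(sprintf("<zspectrum: %d offsets, %.2f to %.2f ppm, %d missing>\n",
              length(x$offsets), min(x$offsets), max(x$offsets),
              sum(!is.finite(x$signal))))
  invisible(x)
}

#' Saturation parameters
#'
#' Continuous-wave saturation settings and the proton resonance frequency
#' used wherever a ppm-to-Hz conversion is needed.
#'
#' @param b1_amplitude Saturation RF amplitude (microtesla).
#' @param duration Saturation duration (seconds).
#' @param field_mhz Proton resonance frequency (MHz); 1 ppm = `field_mhz` Hz.
#' @return A `saturation_spec` list.
#' @export
saturation_spec <- function(b1_amplitude = 2, duration = 1, field_mhz = 300.41) {
  # b1 = 0 is admitted so the no-saturation limit can be simulated
  stopifnot(b1_amplitude >= 0, duration > 0, field_mhz > 0)
  structure(list(b1_amplitude = b1_amplitude, duration = duration,
                 field_mhz = field_mhz), class = "saturation_spec")
}

#' Noise model specification
#'
#' @param model `"gaussian"` (additive on the normalized signal) or
#'   `"rician"` (magnitude of the noisy complex signal; coincides with
#'   gaussian at the SNR of normalized Z-spectra).
#' @param sigma Noise standard deviation on the normalized signal scale.
#' @param seed Integer seed; every stochastic operation is seeded explicitly
#'   and leaves the global RNG state untouched.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(model = c("gaussian", "rician"), sigma = 0, seed = 1L) {
  model <- match.arg(model)
  stopifnot(sigma >= 0, is.finite(seed))
  structure(list(model = model, sigma = sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

# apply a noise_spec to a clean signal vector under its seed
.apply_noise <- function(clean, noise) {
  if (is.null(noise) || noise$sigma == 0) return(clean)
  withr::with_seed(noise$seed, {
    if (noise$model == "gaussian") {
      clean + rnorm(length(clean), 0, noise$sigma)
    } else {
      sqrt((clean + rnorm(length(clean), 0, noise$sigma))^2 +
             rnorm(length(clean), 0, noise$sigma)^2)
    }
  })
}
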