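#' Free induction decay container
#'
#' @param samples Complex vector of time-domain samples.
#' @param spectral_width Sampling bandwidth (Hz); dwell time is its inverse.
#' @param field_mhz Proton resonance frequency (MHz) for ppm conversion.
#' @param meta Optional named list (echo/repetition descriptors are carried
#'   but unused by the preprocessing chain).
#' @return An object of class `fid`.
#' @export
fid <- function(samples, spectral_width = 3005, field_mhz = 300.41,
                meta = list()) {
  stopifnot(length(samples) > 0, spectral_width > 0, field_mhz > 0)
  structure(list(samples = as.complex(samples),
                 n_points = length(samples),
                 spectral_width = spectral_width,
                 field_mhz = field_mhz, meta = meta), class = "fid")
}

#' @export
print.fid <- function(x, ...) {
  cat(sprintf("<fid: %d points, sw = %g Hz, duration = %.4f s>\n",
              x$n_points, x$spectral_width,
              (x$n_points - 1) / x$spectral_width))
  invisible(x)
}

# time axis of an fid (s), starting at 0
fid_times <- function(f) seq(0, f$n_points - 1) / f$spectral_width

#' Generate a synthetic FID
#'
#' Sum of exponentially damped complex sinusoids sampled at the dwell time
#' `1/spectral_width`, with optional seeded complex Gaussian noise. Emulates
#' a water-suppressed metabolite acquisition (default 2048 points, 3005 Hz).
#'
#' @param peaks Data frame with columns `freq_hz`, `amplitude`, `decay`
#'   (1/s) and `phase` (rad); one row per resonance.
#' @param n_points Number of complex samples.
#' @param spectral_width Bandwidth (Hz).
#' @param noise Optional [noise_spec]; `sigma` is the SD of the real and
#'   imaginary noise components.
#' @param field_mhz Proton frequency (MHz).
#' @return An [fid].
#' @export
generate_fid <- function(peaks, n_points = 2048, spectral_width = 3005,
                         noise = NULL, field_mhz = 300.41) {
  stopifnot(n_points > 0, spectral_width > 0,
            all(c("freq_hz", "amplitude", "decay", "phase") %in% names(peaks)))
  t <- seq(0, n_points - 1) / spectral_width
  x <- complex(real = numeric(n_points), imaginary = numeric(n_points))
  for (i in seq_len(nrow(peaks))) {
    x <- x + peaks$amplitude[i] *
      exp(1i * (2 * pi * peaks$freq_hz[i] * t + peaks$phase[i])) *
      exp(-peaks$decay[i] * t)
  }
  if (!is.null(noise) && noise$sigma > 0) {
    x <- x + withr::with_seed(noise$seed,
      complex(real = rnorm(n_points, 0, noise$sigma),
              imaginary = rnorm(n_points, 0, noise$sigma)))
  }
  fid(x, spectral_width, field_mhz)
}
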