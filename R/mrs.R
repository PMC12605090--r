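#' Truncate leading FID points and zero-fill the tail
#'
#' Removes the leading `n_drop` samples (digital-filter dead time of the
#' acquisition electronics) and appends `n_drop` zeros so the series keeps
#' its original length (default 2048 points with the first 68 dropped).
#'
#' @param f An [fid].
#' @param n_drop Number of leading points to remove (and zeros to append).
#' @return An [fid] of unchanged length.
#' @export
truncate_and_zerofill <- function(f, n_drop = 68) {
  stopifnot(inherits(f, "fid"), n_drop >= 0)
  if (n_drop >= f$n_points) stop("n_drop must be smaller than the number of FID points",
                                 call. = FALSE)
  if (n_drop == 0) return(f)
  fid(c(f$samples[-seq_len(n_drop)], complex(real = rep(0, n_drop))),
      f$spectral_width, f$field_mhz, f$meta)
}

#' Exponential apodization
#'
#' Multiplies sample `k` by `exp(-pi * lb * t_k)` with `t_k = k / sw`, the
#' standard convention in which `lb` is the added Lorentzian linewidth in Hz
#' (FWHM). Trades resolution for noise reduction.
#'
#' @param f An [fid].
#' @param line_broadening Line broadening (Hz), non-negative.
#' @return An [fid].
#' @export
apodize <- function(f, line_broadening = 5) {
  stopifnot(inherits(f, "fid"), line_broadening >= 0)
  if (line_broadening == 0) return(f)
  w <- exp(-pi * line_broadening * fid_times(f))
  fid(f$samples * w, f$spectral_width, f$field_mhz, f$meta)
}

#' Fourier transform an FID to a frequency-domain spectrum
#'
#' Forward FFT with centred frequency axis. The ppm axis is referenced by
#' placing the carrier (axis center) at `carrier_ppm`; with the N-acetyl
#' aspartate methyl resonance as the usual reference, a peak at 0 Hz sits at
#' `carrier_ppm`. The stored axis is monotone increasing in ppm (display
#' convention in NMR runs high-to-low left-to-right).
#'
#' @param f An [fid].
#' @param carrier_ppm Chemical shift of the axis center (ppm).
#' @return An object of class `spectrum_mrs` with fields `ppm`, `hz`,
#'   `values` (complex), `field_mhz`.
#' @export
fid_to_spectrum <- function(f, carrier_ppm = 2.5) {
  stopifnot(inherits(f, "fid"))
  n <- f$n_points
  values <- fft(f$samples)
  # reorder to ascending frequency: -sw/2 ... sw/2 - sw/n
  half <- ceiling(n / 2)
  values <- c(values[(half + 1):n], values[1:half])
  hz <- (seq_len(n) - 1 - (n - half)) * f$spectral_width / n
  structure(list(ppm = carrier_ppm + hz / f$field_mhz, hz = hz,
                 values = values, field_mhz = f$field_mhz,
                 spectral_width = f$spectral_width),
            class = "spectrum_mrs")
}

#' Construct a frequency-domain spectrum directly
#'
#' Mainly for building synthetic spectra in tests and examples; acquisition
#' data should arrive through [fid_to_spectrum].
#'
#' @param ppm Monotone increasing chemical-shift axis (ppm).
#' @param values Complex (or numeric) spectral values.
#' @param field_mhz Proton frequency (MHz).
#' @param carrier_ppm Chemical shift at 0 Hz.
#' @return A `spectrum_mrs`.
#' @export
spectrum_mrs <- function(ppm, values, field_mhz = 300.41,
                         carrier_ppm = mean(range(ppm))) {
  stopifnot(length(ppm) == length(values), all(diff(ppm) > 0))
  structure(list(ppm = ppm, hz = (ppm - carrier_ppm) * field_mhz,
                 values = as.complex(values), field_mhz = field_mhz,
                 spectral_width = diff(range(ppm)) * field_mhz),
            class = "spectrum_mrs")
}

#' Zero- and first-order phase correction
#'
#' Multiplies the value at frequency `f` Hz by
#' `exp(-1i * (phi0 + 2 * pi * f * t_fo))`; `t_fo` is the first-order phase
#' expressed as a time (default -0.22 ms).
#'
#' @param spec A `spectrum_mrs`.
#' @param zero_order Zero-order phase (rad).
#' @param first_order_time First-order phase time (s).
#' @return A `spectrum_mrs`.
#' @export
phase_correct <- function(spec, zero_order = 0, first_order_time = -0.22e-3) {
  stopifnot(inherits(spec, "spectrum_mrs"),
            is.finite(zero_order), is.finite(first_order_time))
  spec$values <- spec$values *
    exp(-1i * (zero_order + 2 * pi * spec$hz * first_order_time))
  spec
}

#' Estimate the zero-order phase
#'
#' When no phase is supplied, the zero-order phase is chosen to maximize the
#' integral of the real part over a metabolite window.
#'
#' @param spec A `spectrum_mrs`.
#' @param window ppm window over which to maximize the real integral.
#' @return Zero-order phase (rad).
#' @export
estimate_zero_order_phase <- function(spec, window = c(0.5, 4.2)) {
  sel <- spec$ppm >= window[1] & spec$ppm <= window[2]
  s <- sum(spec$values[sel])
  Arg(s)  # phase_correct multiplies by exp(-i * phi0), so this maximizes Re

}

#' Align spectra on a reference peak
#'
#' Detects the dominant magnitude peak of each spectrum within
#' `search_halfwidth` of `reference_ppm` (parabolic sub-bin interpolation)
#' and resamples the complex values so the peak sits exactly at the
#' reference. Spectra with no detectable peak in the window are flagged and
#' returned unshifted.
#'
#' @param spectra List of `spectrum_mrs` on identical axes.
#' @param reference_ppm Reference position (ppm); default the NAA methyl
#'   resonance at 2.01 ppm.
#' @param search_halfwidth Search window half-width (ppm).
#' @return List with `spectra` (aligned), `shifts_ppm`, and `flagged`
#'   (logical; no peak found).
#' @export
frequency_align <- function(spectra, reference_ppm = 2.01,
                            search_halfwidth = 0.3) {
  stopifnot(length(spectra) >= 1)
  shifts <- numeric(length(spectra))
  flagged <- logical(length(spectra))
  out <- spectra
  for (j in seq_along(spectra)) {
    sp <- spectra[[j]]
    sel <- which(sp$ppm >= reference_ppm - search_halfwidth &
                   sp$ppm <= reference_ppm + search_halfwidth)
    mag <- Mod(sp$values)
    k <- sel[which.max(mag[sel])]
    # a dominant peak must clearly exceed the typical magnitude level
    if (mag[k] < 5 * median(mag)) {
      flagged[j] <- TRUE
      next
    }
    peak_ppm <- sp$ppm[k]
    if (k > 1 && k < length(mag)) {   # parabolic sub-bin refinement
      y1 <- mag[k - 1]; y2 <- mag[k]; y3 <- mag[k + 1]
      den <- y1 - 2 * y2 + y3
      if (den < 0) {
        delta <- 0.5 * (y1 - y3) / den
        peak_ppm <- sp$ppm[k] + delta * (sp$ppm[k + 1] - sp$ppm[k])
      }
    }
    shift <- peak_ppm - reference_ppm
    shifts[j] <- shift
    if (abs(shift) > 0) {
      src <- sp$ppm + shift  # resample so the peak lands on the reference
      re <- approx(sp$ppm, Re(sp$values), xout = src, rule = 2)$y
      im <- approx(sp$ppm, Im(sp$values), xout = src, rule = 2)$y
      sp$values <- complex(real = re, imaginary = im)
      out[[j]] <- sp
    }
  }
  list(spectra = out, shifts_ppm = shifts, flagged = flagged)
}

#' Sum spectra sample-wise
#'
#' Coherent addition of aligned spectra on identical axes.
#'
#' @param spectra List of `spectrum_mrs`.
#' @return A `spectrum_mrs`.
#' @export
sum_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  out <- spectra[[1]]
  for (sp in spectra[-1]) {
    stopifnot(length(sp$values) == length(out$values))
    out$values <- out$values + sp$values
  }
  out
}

#' Spectral quality metrics: SNR and water linewidth
#'
#' SNR is the baseline-subtracted real-part peak height at
#' `signal_peak_ppm` divided by the standard deviation of the real part in
#' the signal-free noise region. The water linewidth is the full width at
#' half maximum of the magnitude water line, measured by linear
#' interpolation of the half-height crossings.
#'
#' @param spec A `spectrum_mrs`.
#' @param water_region ppm window containing the water line.
#' @param noise_region ppm window free of signal.
#' @param signal_peak_ppm Position of the peak used for SNR.
#' @param peak_halfwidth Half-width of the SNR peak search window (ppm).
#' @return List with `snr` and `water_linewidth_ppm`; a noiseless spectrum
#'   reports `snr = Inf`.
#' @export
compute_qc <- function(spec, water_region = c(4.2, 5.2),
                       noise_region = c(6.5, 7.5),
                       signal_peak_ppm = 2.01, peak_halfwidth = 0.15) {
  stopifnot(inherits(spec, "spectrum_mrs"),
            water_region[1] < water_region[2],
            noise_region[1] < noise_region[2])
  if (max(water_region[1], noise_region[1]) <
      min(water_region[2], noise_region[2])) {
    stop("water and noise regions must be disjoint", call. = FALSE)
  }
  in_noise <- spec$ppm >= noise_region[1] & spec$ppm <= noise_region[2]
  in_water <- spec$ppm >= water_region[1] & spec$ppm <= water_region[2]
  in_peak <- abs(spec$ppm - signal_peak_ppm) <= peak_halfwidth
  if (!any(in_noise) || !any(in_water) || !any(in_peak)) {
    stop("empty QC region on this axis", call. = FALSE)
  }
  noise_re <- Re(spec$values[in_noise])
  noise_sd <- sd(noise_re)
  height <- max(Re(spec$values[in_peak])) - mean(noise_re)
  snr <- if (noise_sd == 0) Inf else height / noise_sd

  mag <- Mod(spec$values[in_water])
  x <- spec$ppm[in_water]
  pk <- which.max(mag)
  half <- mag[pk] / 2
  lw <- NA_real_
  lo <- which(mag[seq_len(pk)] <= half)
  hi <- which(mag[pk:length(mag)] <= half)
  if (length(lo) && length(hi)) {
    i <- max(lo)  # last point below half on the left
    xl <- approx(mag[c(i, i + 1)], x[c(i, i + 1)], xout = half)$y
    j <- pk + min(hi) - 1
    xr <- approx(mag[c(j - 1, j)], x[c(j - 1, j)], xout = half)$y
    lw <- xr - xl
  }
  list(snr = snr, water_linewidth_ppm = lw)
}

#' Spectral inclusion gate
#'
#' A spectrum is included when `snr >= snr_min` and
#' `water_linewidth_ppm <= lw_max` (both bounds inclusive).
#'
#' @param metrics Output of [compute_qc].
#' @param snr_min Minimum SNR (default 12).
#' @param lw_max Maximum water linewidth (ppm, default 0.1).
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   violated criteria, empty when passing).
#' @export
qc_gate <- function(metrics, snr_min = 12, lw_max = 0.1) {
  reasons <- character(0)
  if (is.na(metrics$snr)) {
    reasons <- c(reasons, "snr unavailable")
  } else if (metrics$snr < snr_min) {
    reasons <- c(reasons, sprintf("snr %.2f < %g", metrics$snr, snr_min))
  }
  if (is.na(metrics$water_linewidth_ppm)) {
    reasons <- c(reasons, "linewidth unavailable")
  } else if (metrics$water_linewidth_ppm > lw_max) {
    reasons <- c(reasons, sprintf("linewidth %.3f ppm > %g ppm",
                                  metrics$water_linewidth_ppm, lw_max))
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Simplified linear-combination quantitation
#'
#' Non-negative linear least squares of synthetic basis lineshapes on the
#' real part of a spectrum, with Cramer-Rao lower bounds from the linearized
#' covariance at the solution: `crlb_i = sigma * sqrt([(X'X)^-1]_ii)`, with
#' `sigma` the noise SD estimated from a signal-free region, expressed as a
#' percentage of each estimate. This is a deliberately simple stand-in for
#' full basis-set quantitation: basis lines are single Lorentzian or
#' Gaussian peaks, and concentrations are in arbitrary institutional units
#' that are self-consistent within the synthetic world only.
#'
#' @param spec A `spectrum_mrs`.
#' @param basis Data frame with columns `name`, `center_ppm`, `fwhm_ppm`,
#'   and `lineshape` (`"lorentzian"` or `"gaussian"`).
#' @param noise_region ppm window for the noise SD.
#' @return A tibble with `metabolite`, `concentration`, `crlb_percent`
#'   (infinite for zero estimates).
#' @export
lc_quantify <- function(spec, basis, noise_region = c(6.5, 7.5)) {
  stopifnot(inherits(spec, "spectrum_mrs"),
            all(c("name", "center_ppm", "fwhm_ppm", "lineshape") %in%
                  names(basis)))
  if (any(basis$center_ppm < min(spec$ppm) | basis$center_ppm > max(spec$ppm))) {
    stop("basis peak outside the spectral axis", call. = FALSE)
  }
  X <- vapply(seq_len(nrow(basis)), function(i) {
    hw <- basis$fwhm_ppm[i] / 2
    d <- spec$ppm - basis$center_ppm[i]
    if (basis$lineshape[i] == "gaussian") {
      exp(-4 * log(2) * d^2 / basis$fwhm_ppm[i]^2)
    } else {
      hw^2 / (hw^2 + d^2)
    }
  }, numeric(length(spec$ppm)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    cc <- stats::cor(X)
    pairs <- which(abs(cc) > 0.999 & upper.tri(cc), arr.ind = TRUE)
    bad <- apply(pairs, 1, function(p)
      paste(basis$name[p[1]], basis$name[p[2]], sep = "/"))
    stop("rank-deficient basis; collinear pairs: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  y <- Re(spec$values)
  est <- pracma::lsqnonneg(X, y)$x
  in_noise <- spec$ppm >= noise_region[1] & spec$ppm <= noise_region[2]
  sigma <- sd(y[in_noise])
  crlb_abs <- sigma * sqrt(diag(solve(crossprod(X))))
  crlb_pct <- ifelse(est > 0, 100 * crlb_abs / est, Inf)
  tibble::tibble(metabolite = basis$name, concentration = est,
                 crlb_percent = crlb_pct)
}

#' CRLB-based inclusion rules
#'
#' A metabolite enters the group statistics only when its mean CRLB across
#' subjects within a group is at or below `group_mean_max` (default 30%);
#' an individual measurement is flagged reliable when its CRLB is at or
#' below `individual_max` (default 20%). Both bounds inclusive.
#'
#' @param results Data frame with columns `subject`, `group`, `metabolite`,
#'   `concentration`, `crlb_percent`.
#' @param individual_max Individual reliability bound (%).
#' @param group_mean_max Group-mean inclusion bound (%).
#' @return List with `measurements` (input plus `reliable` flag) and
#'   `metabolites` (per group x metabolite: `mean_crlb`, `included`).
#' @export
crlb_filter <- function(results, individual_max = 20, group_mean_max = 30) {
  stopifnot(all(c("subject", "group", "metabolite", "crlb_percent") %in%
                  names(results)))
  res <- tibble::as_tibble(results)
  res$reliable <- res$crlb_percent <= individual_max
  agg <- stats::aggregate(crlb_percent ~ group + metabolite, data = res,
                          FUN = mean)
  names(agg)[names(agg) == "crlb_percent"] <- "mean_crlb"
  agg$included <- agg$mean_crlb <= group_mean_max
  list(measurements = res, metabolites = tibble::as_tibble(agg))
}
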