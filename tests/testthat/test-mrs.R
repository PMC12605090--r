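naa_hz <- (2.01 - 2.5) * 300.41  # NAA offset from the axis carrier

test_that("truncation and zero-filling keep 2048 points with a zero tail", {
  fd <- dead_time_fid(data.frame(freq_hz = naa_hz, amplitude = 1, decay = 8,
                                 phase = 0))
  out <- truncate_and_zerofill(fd, 68)
  expect_equal(out$n_points, 2048)
  expect_true(all(out$samples[(2048 - 67):2048] == 0))
  expect_identical(truncate_and_zerofill(fd, 0), fd)
  expect_error(truncate_and_zerofill(fd, 2048), "smaller")
  # an impulse at index 70 lands at index 2 after dropping 68 points
  imp <- fid(complex(real = c(rep(0, 69), 1, rep(0, 2048 - 70))), 3005)
  expect_equal(which(Mod(truncate_and_zerofill(imp, 68)$samples) > 0), 2)
})

test_that("apodization decays with time and damps noise", {
  fd <- dead_time_fid(data.frame(freq_hz = naa_hz, amplitude = 1, decay = 8,
                                 phase = 0))
  expect_identical(apodize(fd, 0), fd)
  ap <- apodize(fd, 5)
  expect_equal(ap$samples[1], fd$samples[1])  # t = 0 unchanged
  noisy <- generate_fid(data.frame(freq_hz = 0, amplitude = 0, decay = 0,
                                   phase = 0),
                        noise = noise_spec(sigma = 0.05, seed = 2))
  expect_lt(sd(Re(apodize(noisy, 5)$samples)), sd(Re(noisy$samples)))
})

test_that("Fourier transform preserves total power before apodization", {
  fd <- dead_time_fid(data.frame(freq_hz = naa_hz, amplitude = 1, decay = 8,
                                 phase = 0),
                      noise = noise_spec(sigma = 0.01, seed = 9))
  sp <- fid_to_spectrum(fd)
  p_time <- sum(Mod(fd$samples)^2)
  p_freq <- sum(Mod(sp$values)^2) / fd$n_points
  expect_equal(p_freq, p_time, tolerance = 1e-9)
})

test_that("phase correction behaves per its definition", {
  fd <- dead_time_fid(data.frame(freq_hz = naa_hz, amplitude = 1, decay = 8,
                                 phase = 0))
  sp <- fid_to_spectrum(fd)
  expect_equal(phase_correct(sp, 0, 0)$values, sp$values)
  flipped <- phase_correct(sp, pi, 0)
  expect_equal(Re(flipped$values), -Re(sp$values), tolerance = 1e-12)
  # first-order term alone leaves the 0 Hz bin untouched
  fo <- phase_correct(sp, 0, -0.22e-3)
  k0 <- which(sp$hz == 0)
  expect_equal(fo$values[k0], sp$values[k0])
})

test_that("zero-order phase estimation rotates a peak onto the real axis", {
  fd <- dead_time_fid(data.frame(freq_hz = naa_hz, amplitude = 1, decay = 8,
                                 phase = 0.8))
  sp <- fid_to_spectrum(truncate_and_zerofill(fd))  # remove the dead time
  phi <- estimate_zero_order_phase(sp)
  corr <- phase_correct(sp, phi, 0)
  k <- which.max(Mod(corr$values))
  # mostly absorptive; the residual is off-bin dispersion, not phase error
  expect_gt(Re(corr$values[k]) / Mod(corr$values[k]), 0.9)
  uncorr <- which.max(Mod(sp$values))
  expect_gt(Re(corr$values[k]) / Mod(corr$values[k]),
            Re(sp$values[uncorr]) / Mod(sp$values[uncorr]))
})

test_that("frequency alignment centers jittered peaks on the reference", {
  mk <- function(jitter_ppm, seed) {
    fd <- dead_time_fid(data.frame(freq_hz = naa_hz + jitter_ppm * 300.41,
                                   amplitude = 1, decay = 8, phase = 0),
                        noise = noise_spec(sigma = 0.001, seed = seed))
    fid_to_spectrum(apodize(truncate_and_zerofill(fd), 5))
  }
  aligned0 <- frequency_align(list(mk(0, 1), mk(0, 2)))
  expect_lt(max(abs(aligned0$shifts_ppm)), 0.005)
  jit <- c(-0.05, 0.03, 0.05, -0.02)
  al <- frequency_align(lapply(seq_along(jit), function(i) mk(jit[i], i)))
  expect_false(any(al$flagged))
  for (sp in al$spectra) {
    k <- which.max(Mod(sp$values))
    expect_lt(abs(sp$ppm[k] - 2.01), 0.005)
  }
  # coherent sum of N aligned unit peaks has ~N times the height
  ssum <- sum_spectra(al$spectra)
  h1 <- max(Mod(al$spectra[[1]]$values))
  expect_equal(max(Mod(ssum$values)) / h1, 4, tolerance = 0.1)
  # a featureless spectrum is flagged, not shifted
  flat <- fid_to_spectrum(generate_fid(
    data.frame(freq_hz = 0, amplitude = 0, decay = 0, phase = 0),
    noise = noise_spec(sigma = 0.01, seed = 5)))
  alf <- frequency_align(list(flat))
  expect_true(alf$flagged[1])
  expect_equal(alf$shifts_ppm[1], 0)
})

test_that("QC metrics: noiseless SNR is infinite, linewidth is recovered", {
  ppm <- seq(0, 8, length.out = 2048)
  # gaussian lines vanish in the noise window, so the SNR sentinel applies
  water <- 10 * exp(-4 * log(2) * (ppm - 4.7)^2 / 0.08^2)
  naa <- 3 * exp(-4 * log(2) * (ppm - 2.01)^2 / 0.06^2)
  sp <- spectrum_mrs(ppm, water + naa)
  m <- compute_qc(sp)
  expect_true(is.infinite(m$snr))
  expect_true(qc_gate(m)$pass)
  # linewidth of a W = 0.08 ppm water line
  sp2 <- spectrum_mrs(ppm, 10 * (0.04^2) / (0.04^2 + (ppm - 4.7)^2))
  expect_equal(compute_qc(sp2)$water_linewidth_ppm, 0.08, tolerance = 0.005)
  # pure noise in the signal region scores low SNR
  noise_only <- spectrum_mrs(ppm, withr::with_seed(3, rnorm(2048, 0, 1)))
  expect_lt(compute_qc(noise_only)$snr, 3)
  expect_error(compute_qc(sp, water_region = c(6, 7.6),
                          noise_region = c(6.5, 7.5)), "disjoint")
})

test_that("the inclusion gate applies inclusive bounds with reasons", {
  expect_true(qc_gate(list(snr = 12, water_linewidth_ppm = 0.1))$pass)
  g1 <- qc_gate(list(snr = 11.9, water_linewidth_ppm = 0.05))
  expect_false(g1$pass)
  expect_match(g1$reasons, "snr")
  g2 <- qc_gate(list(snr = 50, water_linewidth_ppm = 0.11))
  expect_false(g2$pass)
  expect_match(g2$reasons, "linewidth")
})

test_that("SNR of averaged replicates grows like sqrt(N)", {
  mk <- function(seed) {
    fd <- dead_time_fid(data.frame(freq_hz = naa_hz, amplitude = 1,
                                   decay = 8, phase = 0),
                        noise = noise_spec(sigma = 0.02, seed = seed))
    fid_to_spectrum(apodize(truncate_and_zerofill(fd), 5))
  }
  # a wide signal-free region keeps the noise-SD estimate stable against
  # the bin-to-bin correlation that apodization introduces
  snr <- function(s) compute_qc(s, water_region = c(4.2, 4.95),
                                noise_region = c(5, 8))$snr
  base <- mean(vapply(1:16, function(i) snr(mk(900 + i)), numeric(1)))
  for (n in c(4, 16, 64)) {
    gains <- vapply(1:6, function(r) {
      reps <- lapply(seq_len(n), function(i) mk(1000 * n + 100 * r + i))
      snr(sum_spectra(frequency_align(reps)$spectra)) / base
    }, numeric(1))
    expect_equal(mean(gains), sqrt(n), tolerance = 0.1 * sqrt(n))
  }
})

test_that("quantitation recovers exact linear combinations and scales CRLB", {
  q <- lc_quantify(basis_spectrum(c(3, 1.5), sigma = 0), mrs_test_basis())
  expect_equal(q$concentration, c(3, 1.5), tolerance = 1e-9)
  expect_true(all(q$crlb_percent < 0.01))
  # CRLB% scales inversely with amplitude at fixed design and noise
  qn <- lc_quantify(basis_spectrum(c(1, 10), sigma = 0.02, seed = 8),
                    mrs_test_basis())
  expect_equal(qn$crlb_percent[1] / qn$crlb_percent[2], 10, tolerance = 1)
  # zero-amplitude metabolite reports an infinite CRLB sentinel
  q0 <- lc_quantify(basis_spectrum(c(3, 0), sigma = 0), mrs_test_basis())
  expect_true(is.infinite(q0$crlb_percent[2]))
  # collinear basis names the offending pair
  bad <- rbind(mrs_test_basis(),
               data.frame(name = "naa_copy", center_ppm = 2.01,
                          fwhm_ppm = 0.06, lineshape = "lorentzian"))
  expect_error(lc_quantify(basis_spectrum(c(3, 1.5)), bad), "naa/naa_copy")
})

test_that("quantitation is unbiased and its spread respects the CRLB", {
  truth <- c(3, 1.5)
  sigma <- 0.05
  n <- 500
  est <- matrix(0, n, 2)
  crlb_abs <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    q <- lc_quantify(basis_spectrum(truth, sigma = sigma, seed = 5000 + i),
                     mrs_test_basis())
    est[i, ] <- q$concentration
    crlb_abs[i, ] <- q$crlb_percent / 100 * q$concentration
  }
  for (j in 1:2) {
    se <- sd(est[, j]) / sqrt(n)
    expect_lt(abs(mean(est[, j]) - truth[j]), 2 * se)
    # empirical SD is bounded below by the CRLB (within Monte-Carlo error)
    expect_gte(sd(est[, j]), 0.9 * mean(crlb_abs[, j]))
  }
})

test_that("CRLB filtering applies the group-mean and individual rules", {
  res <- data.frame(
    subject = c("s1", "s2", "s3", "s1", "s2"),
    group = c("a", "a", "a", "b", "b"),
    metabolite = "naa",
    concentration = 1,
    crlb_percent = c(10, 20, 30, 40, 40))
  out <- crlb_filter(res)
  met <- out$metabolites
  expect_true(met$included[met$group == "a"])    # mean 20 <= 30
  expect_false(met$included[met$group == "b"])   # mean 40 > 30
  expect_equal(out$measurements$reliable, c(TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("the full preprocessing chain is bit-reproducible", {
  run <- function() {
    fds <- lapply(1:3, function(i)
      dead_time_fid(data.frame(freq_hz = naa_hz, amplitude = 1, decay = 8,
                               phase = 0.3),
                    noise = noise_spec(sigma = 0.01, seed = i)))
    sps <- lapply(fds, function(f)
      fid_to_spectrum(apodize(truncate_and_zerofill(f), 5)))
    sps <- lapply(sps, function(s)
      phase_correct(s, estimate_zero_order_phase(s), -0.22e-3))
    sum_spectra(frequency_align(sps)$spectra)$values
  }
  expect_identical(run(), run())
})
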