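# shared fixture builders; everything is generated in code under fixed seeds

# random five-pool model strictly inside the default fit bounds, with
# brain-tissue-realistic magnitudes (large water, broad MTC, small solutes)
rand_five_pool <- function(seed) {
  withr::with_seed(seed, pool_table(
    name = c("water", "mtc", "noe", "creatine", "amide"),
    amplitude = c(runif(1, 0.6, 0.9), runif(1, 0.03, 0.15),
                  runif(1, 0.02, 0.12), runif(1, 0.01, 0.06),
                  runif(1, 0.02, 0.10)),
    center = c(runif(1, -0.15, 0.15), -1.5 + runif(1, -0.2, 0.2),
               -3.5 + runif(1, -0.2, 0.2), 2 + runif(1, -0.2, 0.2),
               3.5 + runif(1, -0.2, 0.2)),
    fwhm = c(runif(1, 1, 3), runif(1, 3, 8), runif(1, 0.8, 2.5),
             runif(1, 0.5, 1.5), runif(1, 0.8, 2))))
}

# independent trapezoid oracle for the Lorentzian integral
trapezoid_integral <- function(amplitude, center, fwhm, window, h = 0.001) {
  n <- ceiling((window[2] - window[1]) / h)      # cover the window exactly
  xs <- seq(window[1], window[2], length.out = n + 1)
  ys <- lorentzian_value(xs, amplitude, center, fwhm)
  sum((ys[-1] + ys[-length(ys)]) / 2) * (window[2] - window[1]) / n
}

# FID with the acquisition dead time: n_dead zero samples precede the
# signal, as produced by the digital electronics, so truncation is
# phase-neutral
dead_time_fid <- function(peaks, n_dead = 68, n_points = 2048,
                          spectral_width = 3005, noise = NULL) {
  clean <- generate_fid(peaks, n_points = n_points,
                        spectral_width = spectral_width)
  x <- c(complex(real = rep(0, n_dead)), clean$samples[1:(n_points - n_dead)])
  if (!is.null(noise) && noise$sigma > 0) {
    x <- x + withr::with_seed(noise$seed,
      complex(real = rnorm(n_points, 0, noise$sigma),
              imaginary = rnorm(n_points, 0, noise$sigma)))
  }
  fid(x, spectral_width)
}

# two-line synthetic basis used by the quantitation tests
mrs_test_basis <- function() {
  data.frame(name = c("naa", "cr"), center_ppm = c(2.01, 3.03),
             fwhm_ppm = c(0.06, 0.06), lineshape = "lorentzian",
             stringsAsFactors = FALSE)
}

# spectrum that is an exact linear combination of the test basis plus noise
basis_spectrum <- function(amps = c(3, 1.5), sigma = 0, seed = 1L,
                           n = 1024) {
  ppm <- seq(0, 8, length.out = n)
  b <- mrs_test_basis()
  vals <- numeric(n)
  for (i in seq_len(nrow(b))) {
    hw <- b$fwhm_ppm[i] / 2
    vals <- vals + amps[i] * hw^2 / (hw^2 + (ppm - b$center_ppm[i])^2)
  }
  if (sigma > 0) {
    vals <- vals + withr::with_seed(seed, rnorm(n, 0, sigma))
  }
  spectrum_mrs(ppm, vals)
}

# manual one-way ANOVA F from the sums-of-squares decomposition (oracle)
manual_anova_f <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ss_b <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                     numeric(1)))
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  k <- length(groups); n <- length(all_v)
  f <- (ss_b / (k - 1)) / (ss_w / (n - k))
  list(f = f, p = pf(f, k - 1, n - k, lower.tail = FALSE))
}

# manual Tukey adjusted p-values from the studentized range distribution
manual_tukey_p <- function(groups) {
  k <- length(groups); n <- length(unlist(groups))
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) /
    (n - k)
  nm <- names(groups)
  pairs <- utils::combn(seq_len(k), 2)
  out <- setNames(numeric(ncol(pairs)), apply(pairs, 2, function(p)
    paste(nm[p[2]], nm[p[1]], sep = "-")))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(mse / 2 * (1 / length(groups[[i1]]) + 1 / length(groups[[i2]])))
    q <- abs(mean(groups[[i2]]) - mean(groups[[i1]])) / se
    out[j] <- stats::ptukey(q, k, n - k, lower.tail = FALSE)
  }
  out[order(names(out))]
}
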