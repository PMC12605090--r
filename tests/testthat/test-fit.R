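grid <- build_offset_grid()

test_that("lorentzian_value matches its closed form at key offsets", {
  expect_equal(lorentzian_value(3.5, 0.1, 3.5, 1), 0.1)
  expect_equal(lorentzian_value(4.0, 0.1, 3.5, 1), 0.05)
  expect_equal(lorentzian_value(4.5, 0.1, 3.5, 1), 0.1 * 0.25 / 1.25)
})

test_that("five_pool_eval is the linear-in-amplitude forward model", {
  zeroes <- pool_table(default_pools()$name, rep(0, 5),
                       default_pools()$center, default_pools()$fwhm)
  expect_true(all(five_pool_eval(zeroes, grid)$signal == 1))
  one <- pool_table("amide", 0.1, 3.5, 1)
  expect_equal(1 - five_pool_eval(one, grid)$signal,
               lorentzian_value(grid, 0.1, 3.5, 1))
  p1 <- rand_five_pool(1); p2 <- rand_five_pool(2)
  p1$amplitude <- p1$amplitude / 3   # keep the merged drop below 1
  p2$amplitude <- p2$amplitude / 3
  merged <- rbind(p1, p2)
  drop_sum <- (1 - five_pool_eval(p1, grid)$signal) +
    (1 - five_pool_eval(p2, grid)$signal)
  expect_equal(1 - five_pool_eval(merged, grid)$signal, drop_sum)
})

test_that("noiseless model-generated spectra are recovered exactly", {
  for (s in 1:50) {
    p <- rand_five_pool(s)
    fit <- fit_five_pool(five_pool_eval(p, grid))
    expect_true(fit$converged)
    expect_gte(fit$r_squared, 1 - 1e-10)
    expect_lt(max(abs(fit$pools$amplitude - p$amplitude),
                  abs(fit$pools$center - p$center),
                  abs(fit$pools$fwhm - p$fwhm)), 1e-6)
  }
})

test_that("a flat spectrum yields the all-zero model with R^2 = 0", {
  fit <- fit_five_pool(zspectrum(grid, rep(1, length(grid))))
  expect_true(all(fit$pools$amplitude == 0))
  expect_equal(fit$r_squared, 0)
  expect_true(fit$converged)
})

test_that("a single-pool spectrum leaves the other amplitudes at zero", {
  p <- pool_table(c("water", "amide"), c(0.7, 0.05), c(0, 3.5), c(1.5, 1.2))
  fit <- fit_five_pool(five_pool_eval(p, grid))
  others <- fit$pools$amplitude[fit$pools$name %in% c("mtc", "noe", "creatine")]
  expect_true(all(others < 1e-6))
  expect_equal(fit$pools$amplitude[fit$pools$name == "amide"], 0.05,
               tolerance = 1e-6)
  # brute-force lattice oracle for the amide pool on the water-subtracted drop
  resid_drop <- (1 - five_pool_eval(p, grid)$signal) -
    lorentzian_value(grid, 0.7, 0, 1.5)
  lat <- expand.grid(A = seq(0.01, 0.1, 0.005), c = seq(3.2, 3.8, 0.05),
                     W = seq(0.6, 1.8, 0.1))
  sse <- mapply(function(A, c, W)
    sum((resid_drop - lorentzian_value(grid, A, c, W))^2),
    lat$A, lat$c, lat$W)
  best <- lat[which.min(sse), ]
  expect_equal(best$A, 0.05); expect_equal(best$c, 3.5)
})

test_that("noisy recovery of the amide amplitude improves as noise shrinks", {
  truth <- default_pools()
  med_err <- vapply(c(0.01, 0.005, 0.001), function(sig) {
    errs <- vapply(1:60, function(s) {
      z <- simulate_zspectrum_lorentzian(truth, grid,
                                         noise = noise_spec(sigma = sig,
                                                            seed = s))
      f <- fit_five_pool(z)
      abs(f$pools$amplitude[f$pools$name == "amide"] - 0.05)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_lt(med_err[2], 0.15 * 0.05)       # < 15% of truth at sigma 0.005
  expect_true(all(diff(med_err) < 0))      # monotone improvement
})

test_that("R^2 follows its definition, including negative values", {
  obs <- zspectrum(c(1, 2, 3), c(1, 0.9, 1))
  fit1 <- zspectrum(c(1, 2, 3), c(1, 0.9, 1))
  expect_equal(r_squared(obs, fit1), 1)
  m <- mean(obs$signal)
  fitm <- zspectrum(c(1, 2, 3), rep(m, 3))
  expect_equal(r_squared(obs, fitm), 0)
  fitc <- zspectrum(c(1, 2, 3), c(1, 1, 1))
  expect_equal(r_squared(obs, fitc), -0.5)
  expect_error(r_squared(obs, zspectrum(c(1, 2, 4), c(1, 1, 1))), "grids")
})

test_that("pool integral matches the full-line area and symmetry", {
  expect_equal(pool_integral(0.1, 0, 1, c(-1e6, 1e6)), pi * 0.1 * 0.5,
               tolerance = 1e-5)
  expect_equal(pool_integral(0, 2, 1, c(-5, 5)), 0)
  half <- pool_integral(0.2, 1, 0.8, c(1, 3))
  expect_equal(pool_integral(0.2, 1, 0.8, c(-1, 3)), 2 * half)
})

test_that("closed-form integrals agree with the trapezoid oracle", {
  for (s in 1:100) {
    prm <- withr::with_seed(s, c(A = runif(1, 0.01, 0.9),
                                 c = runif(1, -4, 4),
                                 W = runif(1, 0.3, 10),
                                 a = runif(1, -6, -1), b = runif(1, 1, 6)))
    cf <- pool_integral(prm["A"], prm["c"], prm["W"], c(prm["a"], prm["b"]))
    tr <- trapezoid_integral(prm["A"], prm["c"], prm["W"],
                             c(prm["a"], prm["b"]))
    expect_lt(abs(cf - tr) / cf, 1e-6)
  }
})

test_that("increasing the simulated amide amplitude increases its fitted integral", {
  ints <- vapply(c(0.03, 0.05, 0.07, 0.09), function(a) {
    p <- default_pools()
    p$amplitude[p$name == "amide"] <- a
    f <- fit_five_pool(five_pool_eval(p, grid))
    f$pools$integral[f$pools$name == "amide"]
  }, numeric(1))
  expect_true(all(diff(ints) > 0))
})

test_that("fit results serialize to JSON with per-pool integrals", {
  f <- fit_five_pool(five_pool_eval(default_pools(), grid))
  js <- jsonlite::fromJSON(fit_result_json(f), simplifyVector = FALSE)
  expect_length(js$pools, 5)
  expect_equal(js$r_squared, f$r_squared, tolerance = 1e-12)
  expect_equal(js$pools[[5]]$name, "amide")
})
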