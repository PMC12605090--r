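#' Bloch-McConnell pool specification
#'
#' Physical description of one proton pool for the numerical saturation
#' simulator, which serves as an independent physical oracle for the
#' Lorentzian-sum forward model.
#'
#' @param t1,t2 Longitudinal and transverse relaxation times (s); `t1 >= t2`.
#' @param exchange_rate Exchange rate from this pool to water (1/s).
#' @param proton_fraction Pool size relative to water (water has 1).
#' @param chemical_shift Resonance offset from water (ppm).
#' @return A `bm_pool` list.
#' @export
bm_pool <- function(t1, t2, exchange_rate = 0, proton_fraction = 1,
                    chemical_shift = 0) {
  stopifnot(t2 > 0, t1 >= t2, exchange_rate >= 0, proton_fraction > 0)
  structure(list(t1 = t1, t2 = t2, exchange_rate = exchange_rate,
                 proton_fraction = proton_fraction,
                 chemical_shift = chemical_shift), class = "bm_pool")
}

#' Default water pool for the Bloch-McConnell oracle
#' @return A [bm_pool] with brain-tissue-like relaxation at 7 T.
#' @export
bm_water <- function() bm_pool(t1 = 2, t2 = 0.06, proton_fraction = 1,
                               chemical_shift = 0)

# gyromagnetic ratio of 1H over 2*pi, MHz/T
.GAMMA_HZ_PER_UT <- 42.577478518  # Hz per microtesla

#' Simulate a Z-spectrum with the Bloch-McConnell equations
#'
#' Numerically integrates the coupled Bloch-McConnell equations (3 components
#' per pool, two-site exchange of each solute with water) over the
#' continuous-wave saturation period at every offset and returns the water
#' `Mz/M0`. Deterministic; used as the physical cross-check of the
#' Lorentzian-sum simulator.
#'
#' @param water A [bm_pool] for water (proton fraction 1).
#' @param solutes List of up to 4 solute [bm_pool]s (proton fraction < 1).
#' @param sat A [saturation_spec].
#' @param offsets Saturation offsets (ppm).
#' @param rtol Relative tolerance of the stiff integrator.
#' @return A [zspectrum] of `Mz/M0`.
#' @export
simulate_zspectrum_bm <- function(water = bm_water(), solutes = list(),
                                  sat = saturation_spec(),
                                  offsets, rtol = 1e-8) {
  stopifnot(length(solutes) <= 4)
  for (s in solutes) stopifnot(inherits(s, "bm_pool"),
                               s$proton_fraction < 1)
  pools <- c(list(water), solutes)
  np <- length(pools)
  m0 <- vapply(pools, `[[`, numeric(1), "proton_fraction")
  r1 <- 1 / vapply(pools, `[[`, numeric(1), "t1")
  r2 <- 1 / vapply(pools, `[[`, numeric(1), "t2")
  k_sw <- vapply(pools, `[[`, numeric(1), "exchange_rate")  # solute -> water
  k_ws <- k_sw * m0  # water -> solute (detailed balance, water M0 = 1)
  shift_ppm <- vapply(pools, `[[`, numeric(1), "chemical_shift")
  w1 <- 2 * pi * .GAMMA_HZ_PER_UT * sat$b1_amplitude  # rad/s

  ix <- function(p) 3 * (p - 1) + 1  # Mx index of pool p

  # The Bloch-McConnell system under constant CW irradiation is linear,
  # dy/dt = A y + b, so the (constant) A doubles as the analytic Jacobian
  # for the implicit solver.
  build_A <- function(dw) {
    A <- matrix(0, 3 * np, 3 * np)
    for (p in seq_len(np)) {
      i <- ix(p)
      A[i, i] <- -r2[p];      A[i, i + 1] <- dw[p]
      A[i + 1, i] <- -dw[p];  A[i + 1, i + 1] <- -r2[p]
      A[i + 1, i + 2] <- w1
      A[i + 2, i + 1] <- -w1; A[i + 2, i + 2] <- -r1[p]
    }
    for (p in seq_len(np)[-1]) {  # two-site exchange solute <-> water
      i <- ix(p); iw <- ix(1)
      for (d in 0:2) {
        A[i + d, i + d] <- A[i + d, i + d] - k_sw[p]
        A[i + d, iw + d] <- A[i + d, iw + d] + k_ws[p]
        A[iw + d, iw + d] <- A[iw + d, iw + d] - k_ws[p]
        A[iw + d, i + d] <- A[iw + d, i + d] + k_sw[p]
      }
    }
    A
  }
  b <- as.vector(rbind(0, 0, r1 * m0))

  y0 <- as.vector(rbind(0, 0, m0))
  sig <- vapply(offsets, function(off) {
    dw <- 2 * pi * sat$field_mhz * (shift_ppm - off)
    A <- build_A(dw)
    sol <- try(suppressWarnings(
      deSolve::ode(y = y0, times = c(0, sat$duration),
                   func = function(t, y, parms) list(A %*% y + b),
                   jacfunc = function(t, y, parms) A, jactype = "fullusr",
                   parms = NULL, method = "bdf",
                   rtol = rtol, atol = rtol * 1e-2, maxsteps = 500000)),
      silent = TRUE)
    if (!inherits(sol, "try-error") &&
        abs(sol[nrow(sol), 1] - sat$duration) > 1e-9) {
      sol <- try(stop("early return"), silent = TRUE)
    }
    if (inherits(sol, "try-error") || any(!is.finite(sol[nrow(sol), -1]))) {
      stop(sprintf("stiff integration failed at offset %.3f ppm", off),
           call. = FALSE)
    }
    sol[nrow(sol), 1 + ix(1) + 2]  # water Mz at end of saturation
  }, numeric(1))
  zspectrum(offsets, pmin(pmax(sig, -0.1), 1.1))
}
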