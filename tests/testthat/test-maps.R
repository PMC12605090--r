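# a small phantom keeps the voxel-wise tests quick: 2 ROIs, no-noise variant
small_spec <- function(sigma = 0, seed = 1L, effect = c(amide = 1.3),
                       b0_range = c(0, 0)) {
  shape <- c(12L, 24L)
  mk <- function(r0, c0) {
    r <- matrix(seq_len(shape[1]), shape[1], shape[2])
    cl <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    ((r - r0) / 2.2)^2 + ((cl - c0) / 3.2)^2 <= 1
  }
  b0 <- matrix(seq(b0_range[1], b0_range[2], length.out = shape[2]),
               shape[1], shape[2], byrow = TRUE)
  phantom_spec(shape, list(control_1 = mk(6, 6), exposed_1 = mk(6, 18)),
               c(control_1 = "control", exposed_1 = "exposed"),
               effect = effect, b0_field = b0,
               noise = noise_spec(sigma = sigma, seed = seed))
}

test_that("per-voxel fits recover uniform ground truth without noise or B0", {
  spec <- small_spec()
  img <- generate_phantom(spec)
  wimg <- generate_wassr_image(spec, sigma = 0)
  fits <- fit_image(img, wimg)
  truth <- img$truth$pools
  for (v in seq_len(nrow(fits$coords))) {
    f <- fits$fits[[v]]
    tp <- truth[[fits$coords$roi[v]]]
    expect_lt(max(abs(f$pools$amplitude - tp$amplitude)), 1e-6)
  }
})

test_that("a linear B0 ramp is recovered by the voxel-wise WASSR map", {
  spec <- small_spec(b0_range = c(-0.2, 0.2))
  img <- generate_phantom(spec)
  wimg <- generate_wassr_image(spec, sigma = 0)
  fits <- fit_image(img, wimg)
  fg <- which(img$mask > 0)
  expect_lt(max(abs(fits$b0[fg] - spec$b0_field[fg])), 0.01)
})

test_that("an empty mask produces an empty result without error", {
  spec <- small_spec()
  img <- generate_phantom(spec)
  wimg <- generate_wassr_image(spec, sigma = 0)
  img$mask[] <- 0L
  wimg$mask[] <- 0L
  fits <- fit_image(img, wimg)
  expect_equal(nrow(fits$coords), 0)
})

test_that("contrast maps expose the simulated exposure ratio and QC boundary", {
  spec <- small_spec(sigma = 0.005)
  img <- generate_phantom(spec)
  wimg <- generate_wassr_image(spec)
  fits <- fit_image(img, wimg)
  expect_error(make_contrast_map(fits, "banana"), "valid names")
  map <- make_contrast_map(fits, "amide")
  agg <- roi_aggregate(map)
  ratio <- agg$mean_integral[agg$group == "exposed"] /
    agg$mean_integral[agg$group == "control"]
  expect_equal(ratio, 1.3, tolerance = 0.1)
  # inclusive R^2 threshold: a voxel at exactly the cutoff passes
  r2s <- vapply(fits$fits, function(f) f$r_squared, numeric(1))
  thr <- quantile(r2s, 0.5)
  map_thr <- make_contrast_map(fits, "amide", r2_threshold = thr)
  at_cut <- which(abs(r2s - thr) < 1e-15)
  for (v in at_cut) {
    expect_true(map_thr$qc_mask[fits$coords$row[v], fits$coords$col[v]])
  }
})

test_that("the QC gate catches corrupted voxels and spares clean ones", {
  spec <- default_phantom_spec(sigma = 0.005, seed = 21)
  img <- corrupt_voxels(generate_phantom(spec), n = 10, seed = 77)
  wimg <- generate_wassr_image(spec)
  fits <- fit_image(img, wimg)
  qc <- apply_qc(fits)
  bad <- attr(img, "corrupted")
  bad_keys <- paste(bad[, 1], bad[, 2])
  excl_keys <- paste(qc$excluded$row, qc$excluded$col)
  expect_gte(sum(bad_keys %in% excl_keys), 9)
  expect_lte(sum(!(excl_keys %in% bad_keys)), 2)
  expect_false(qc$dataset_excluded)
})

test_that("raising the R^2 threshold never decreases exclusions", {
  spec <- small_spec(sigma = 0.02, seed = 31)
  img <- generate_phantom(spec)
  wimg <- generate_wassr_image(spec)
  fits <- fit_image(img, wimg)
  counts <- vapply(c(0.2, 0.5, 0.8, 0.95, 0.999),
                   function(t) apply_qc(fits, r2_threshold = t)$n_excluded,
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("ROI aggregation averages only QC-passing voxels", {
  mask <- matrix(0L, 3, 3)
  mask[1, 1:2] <- 1L; mask[2, 1:2] <- 1L
  value <- matrix(NA_real_, 3, 3)
  value[1, 1] <- 1; value[1, 2] <- 2; value[2, 1] <- 3
  qc <- matrix(FALSE, 3, 3)
  qc[1, 1] <- qc[1, 2] <- qc[2, 1] <- TRUE   # the 4th voxel failed QC
  map <- structure(list(pool_name = "amide", value = value, qc_mask = qc,
                        r2 = value, mask = mask, roi_names = "roi_a",
                        groups = c(roi_a = "control")),
                   class = "contrast_map")
  agg <- roi_aggregate(map)
  expect_equal(agg$mean_integral, 2)
  expect_equal(agg$n_voxels_pass, 3)
  expect_equal(agg$n_voxels_total, 4)
  # fully failed ROI reports missing, not zero
  map$qc_mask[] <- FALSE
  map$value[] <- NA_real_
  agg2 <- roi_aggregate(map)
  expect_true(is.na(agg2$mean_integral))
})

test_that("group mean integrals separate in the simulated direction", {
  hits <- vapply(1:20, function(s) {
    tab <- simulate_group_study(effect_amide = 1.3, effect_noe = 1.2,
                                sigma = 0.005, seed = 4000 + s)
    mean(tab$integral_amide[tab$group == "exposed"]) >
      mean(tab$integral_amide[tab$group == "control"])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("contrast maps write to NIfTI + CSV", {
  spec <- small_spec(sigma = 0.005)
  img <- generate_phantom(spec)
  wimg <- generate_wassr_image(spec)
  fits <- fit_image(img, wimg)
  map <- make_contrast_map(fits, "amide")
  dir <- file.path(tempdir(), "map_io")
  write_contrast_map(map, dir)
  csv <- utils::read.csv(file.path(dir, "map_amide.csv"))
  expect_equal(nrow(csv), sum(img$mask > 0))
  expect_true(all(c("x", "y", "pool", "integral", "r2", "qc_pass") %in%
                    names(csv)))
  unlink(dir, recursive = TRUE)
})
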