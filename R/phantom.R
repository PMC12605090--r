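#' Digital phantom specification
#'
#' Describes a 2D phantom: labelled ROI masks (one per embryo brain), a
#' group label per ROI, the baseline pool set, per-pool multiplicative
#' amplitude factors applied to exposed ROIs, a smooth per-voxel B0 offset
#' field, and a noise model. Background voxels carry a 0 label in the mask
#' and `NA` spectra, never zeros, so fits cannot silently run on air.
#'
#' @param shape Integer vector `(rows, cols)`.
#' @param roi_masks Named list of logical matrices of dimension `shape`;
#'   masks must be pairwise disjoint.
#' @param group_labels Named character vector (`"control"` / `"exposed"`),
#'   one per ROI.
#' @param baseline_pools A [pool_table]; default [default_pools()].
#' @param effect Named numeric vector of positive per-pool amplitude factors
#'   applied to exposed ROIs (names matching pool names; unnamed pools get 1).
#' @param b0_field Numeric matrix of per-voxel B0 offsets (ppm), dimension
#'   `shape`, finite.
#' @param noise A [noise_spec].
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape, roi_masks, group_labels,
                         baseline_pools = default_pools(),
                         effect = c(amide = 1.3, noe = 1.2),
                         b0_field = matrix(0, shape[1], shape[2]),
                         noise = noise_spec(sigma = 0.005, seed = 1L)) {
  stopifnot(length(shape) == 2, length(roi_masks) >= 1,
            length(group_labels) == length(roi_masks),
            all(effect > 0), all(is.finite(b0_field)),
            all(dim(b0_field) == shape))
  tot <- Reduce(`+`, lapply(roi_masks, function(m) {
    stopifnot(all(dim(m) == shape)); m + 0
  }))
  if (any(tot > 1)) stop("ROI masks overlap", call. = FALSE)
  stopifnot(all(group_labels %in% c("control", "exposed")))
  structure(list(shape = shape, roi_masks = roi_masks,
                 group_labels = group_labels,
                 baseline_pools = baseline_pools, effect = effect,
                 b0_field = b0_field, noise = noise),
            class = "phantom_spec")
}

#' Default two-group phantom specification
#'
#' Ten elliptical "embryo brain" ROIs (about 50 voxels each, roughly 500
#' foreground voxels in total) on a 40 x 80 slice: five control and five
#' exposed, a left-right linear B0 ramp over `b0_range`, the default
#' five-pool baseline, and Gaussian noise on the normalized signal. The
#' exposure effect mimics drug-induced hyperintensity: amplitude x 1.3 at
#' 3.5 ppm (amide/amine) and x 1.2 at -3.5 ppm (rNOE) unless overridden.
#'
#' @param sigma Noise SD on the normalized signal.
#' @param seed Integer seed.
#' @param effect Named per-pool amplitude factors for exposed ROIs.
#' @param b0_range Range of the linear column-wise B0 ramp (ppm).
#' @return A [phantom_spec].
#' @export
default_phantom_spec <- function(sigma = 0.005, seed = 1L,
                                 effect = c(amide = 1.3, noe = 1.2),
                                 b0_range = c(-0.2, 0.2)) {
  shape <- c(40L, 80L)
  centers <- expand.grid(row = c(11, 29), col = c(8, 24, 40, 56, 72))
  masks <- lapply(seq_len(nrow(centers)), function(i) {
    r <- matrix(seq_len(shape[1]), shape[1], shape[2])
    cl <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    ((r - centers$row[i]) / 3.6)^2 + ((cl - centers$col[i]) / 4.6)^2 <= 1
  })
  names(masks) <- sprintf("%s_%d",
                          rep(c("control", "exposed"), nrow(centers) / 2),
                          rep(seq_len(nrow(centers) / 2), each = 2))
  groups <- setNames(rep(c("control", "exposed"), nrow(centers) / 2),
                     names(masks))
  b0 <- matrix(seq(b0_range[1], b0_range[2], length.out = shape[2]),
               shape[1], shape[2], byrow = TRUE)
  phantom_spec(shape, masks, groups,
               effect = effect, b0_field = b0,
               noise = noise_spec(sigma = sigma, seed = seed))
}

#' Generate a Z-spectrum phantom image
#'
#' Simulates every in-mask voxel's Z-spectrum from the phantom's pool set
#' (exposed ROIs use `amplitude * effect`) shifted by the voxel's B0 offset,
#' with a single seeded noise draw for the whole image so identical
#' specifications produce bit-identical output. Background voxels are `NA`.
#'
#' @param spec A [phantom_spec].
#' @param offsets Offset grid (ppm), e.g. [build_offset_grid()].
#' @return A list of class `zspec_image`: `data` (rows x cols x n_offsets),
#'   `offsets`, `mask` (integer labels, 0 = background), `roi_names`,
#'   `groups`, and `truth` (per-ROI pool tables and the B0 field).
#' @export
generate_phantom <- function(spec, offsets = build_offset_grid()) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  n <- length(offsets)
  data <- array(NA_real_, c(shape, n))
  mask <- matrix(0L, shape[1], shape[2])
  truth_pools <- list()
  for (r in seq_along(spec$roi_masks)) {
    pools <- spec$baseline_pools
    if (spec$group_labels[r] == "exposed") {
      m <- match(names(spec$effect), pools$name)
      if (anyNA(m)) stop("effect names do not match pool names", call. = FALSE)
      pools$amplitude[m] <- pools$amplitude[m] * spec$effect
    }
    truth_pools[[names(spec$roi_masks)[r]]] <- pools
    idx <- which(spec$roi_masks[[r]], arr.ind = TRUE)
    mask[idx] <- r
    for (v in seq_len(nrow(idx))) {
      b0 <- spec$b0_field[idx[v, 1], idx[v, 2]]
      data[idx[v, 1], idx[v, 2], ] <- 1 - .pool_drop(pools, offsets - b0)
    }
  }
  if (spec$noise$sigma > 0) {
    fg <- mask > 0
    nfg <- sum(fg)
    noise_draw <- withr::with_seed(spec$noise$seed,
                                   rnorm(nfg * n, 0, spec$noise$sigma))
    nm <- matrix(noise_draw, nfg, n)
    for (j in seq_len(n)) {
      slab <- data[, , j]
      if (spec$noise$model == "rician") {
        extra <- withr::with_seed(spec$noise$seed + 1L,
                                  rnorm(nfg, 0, spec$noise$sigma))
        slab[fg] <- sqrt((slab[fg] + nm[, j])^2 + extra^2)
      } else {
        slab[fg] <- slab[fg] + nm[, j]
      }
      data[, , j] <- slab
    }
    data <- pmin(pmax(data, -0.1), 1.1)
  }
  structure(list(data = data, offsets = offsets, mask = mask,
                 roi_names = names(spec$roi_masks),
                 groups = spec$group_labels,
                 truth = list(pools = truth_pools, b0_field = spec$b0_field)),
            class = "zspec_image")
}

#' Generate the matching WASSR image for a phantom
#'
#' One WASSR spectrum per foreground voxel, centered at the voxel's true B0
#' offset, with its own seeded noise.
#'
#' @param spec The [phantom_spec] used for the Z-spectrum image.
#' @param offsets WASSR grid (ppm).
#' @param sigma Noise SD (default: the phantom's own sigma).
#' @param width Water line FWHM (ppm).
#' @return A `zspec_image` on the WASSR grid.
#' @export
generate_wassr_image <- function(spec, offsets = wassr_grid(),
                                 sigma = spec$noise$sigma, width = 0.3) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  n <- length(offsets)
  data <- array(NA_real_, c(shape, n))
  mask <- matrix(0L, shape[1], shape[2])
  for (r in seq_along(spec$roi_masks)) {
    idx <- which(spec$roi_masks[[r]], arr.ind = TRUE)
    mask[idx] <- r
    for (v in seq_len(nrow(idx))) {
      b0 <- spec$b0_field[idx[v, 1], idx[v, 2]]
      data[idx[v, 1], idx[v, 2], ] <- 1 - lorentzian_value(offsets, 0.95, b0, width)
    }
  }
  if (sigma > 0) {
    fg <- mask > 0
    noise_draw <- withr::with_seed(spec$noise$seed + 7919L,
                                   rnorm(sum(fg) * n, 0, sigma))
    nm <- matrix(noise_draw, sum(fg), n)
    for (j in seq_len(n)) {
      slab <- data[, , j]
      slab[fg] <- slab[fg] + nm[, j]
      data[, , j] <- slab
    }
    data <- pmin(pmax(data, -0.1), 1.1)
  }
  structure(list(data = data, offsets = offsets, mask = mask,
                 roi_names = names(spec$roi_masks),
                 groups = spec$group_labels,
                 truth = list(b0_field = spec$b0_field)),
            class = "zspec_image")
}

#' Corrupt selected voxels of a phantom image
#'
#' Replaces the Z-spectra of `n` randomly chosen foreground voxels with
#' structureless noise (used to exercise the R-squared quality gate).
#'
#' @param img A `zspec_image`.
#' @param n Number of voxels to corrupt.
#' @param seed Integer seed for the voxel choice and replacement noise.
#' @return The image with a `corrupted` attribute (matrix of voxel indices).
#' @export
corrupt_voxels <- function(img, n = 10, seed = 99L) {
  fg <- which(img$mask > 0, arr.ind = TRUE)
  stopifnot(n <= nrow(fg))
  withr::with_seed(seed, {
    pick <- fg[sample(nrow(fg), n), , drop = FALSE]
    for (v in seq_len(n)) {
      img$data[pick[v, 1], pick[v, 2], ] <-
        pmin(pmax(rnorm(length(img$offsets), 0.5, 0.15), 0), 1)
    }
  })
  attr(img, "corrupted") <- pick
  img
}

#' @export
print.zspec_image <- function(x, ...) {
  cat(sprintf("<zspec_image: %d x %d, %d offsets, %d foreground voxels, %d ROIs>\n",
              dim(x$data)[1], dim(x$data)[2], length(x$offsets),
              sum(x$mask > 0), length(x$roi_names)))
  invisible(x)
}
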