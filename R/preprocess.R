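# Volume preprocessing: resampling to isotropic spacing, HU windowing,
# intensity normalisation, random patch extraction, and the fixed
# multi-scale encoder feature bank used at desk scale.

#' Trilinear (or nearest-neighbour) resampling of a 3D array
#'
#' @param a 3D array.
#' @param spacing source voxel spacing (mm).
#' @param target_spacing output voxel spacing (mm).
#' @param method `"linear"` for images, `"nearest"` for label maps.
#' @return resampled array with attribute `spacing`.
#' @export
resample_volume <- function(a, spacing, target_spacing = c(1, 1, 1),
                            method = c("linear", "nearest")) {
  method <- match.arg(method)
  dm <- dim(a)
  out_dm <- pmax(1L, as.integer(round(dm * spacing / target_spacing)))
  # output voxel centre positions in source voxel coordinates
  pos <- lapply(1:3, function(ax) {
    1 + (seq_len(out_dm[ax]) - 1) * target_spacing[ax] / spacing[ax]
  })
  if (method == "nearest") {
    idx <- lapply(1:3, function(ax) pmin(dm[ax], pmax(1L, round(pos[[ax]]))))
    out <- a[idx[[1]], idx[[2]], idx[[3]]]
    dim(out) <- out_dm
  } else {
    lo <- lapply(1:3, function(ax) pmin(dm[ax] - 1L, pmax(1L, floor(pos[[ax]]))))
    fr <- lapply(1:3, function(ax) clamp(pos[[ax]] - lo[[ax]], 0, 1))
    if (dm[1] == 1) { lo[[1]] <- rep(1L, out_dm[1]); fr[[1]] <- rep(0, out_dm[1]) }
    if (dm[2] == 1) { lo[[2]] <- rep(1L, out_dm[2]); fr[[2]] <- rep(0, out_dm[2]) }
    if (dm[3] == 1) { lo[[3]] <- rep(1L, out_dm[3]); fr[[3]] <- rep(0, out_dm[3]) }
    out <- array(0, out_dm)
    w1 <- list(1 - fr[[1]], fr[[1]])
    w2 <- list(1 - fr[[2]], fr[[2]])
    w3 <- list(1 - fr[[3]], fr[[3]])
    for (d1 in 0:1) for (d2 in 0:1) for (d3 in 0:1) {
      i1 <- pmin(dm[1], lo[[1]] + d1)
      i2 <- pmin(dm[2], lo[[2]] + d2)
      i3 <- pmin(dm[3], lo[[3]] + d3)
      w <- outer(outer(w1[[d1 + 1]], w2[[d2 + 1]], `*`), w3[[d3 + 1]], `*`)
      out <- out + w * a[i1, i2, i3]
    }
  }
  attr(out, "spacing") <- target_spacing
  out
}

#' Preprocess a raw CT volume
#'
#' Resamples to `target_spacing` (trilinear), clips intensities to the HU
#' window and maps them linearly to `[0, 1]`. The default window
#' `[-1200, 600]` covers the lung density range; the default target spacing
#' is 1 mm isotropic.
#'
#' @param raw 3D array of HU values.
#' @param spacing source voxel spacing (mm, positive).
#' @param hu_window clipping window (low, high).
#' @param target_spacing output spacing.
#' @return normalised 3D array in `[0, 1]` with attribute `spacing`.
#' @export
preprocess_volume <- function(raw, spacing, hu_window = c(-1200, 600),
                              target_spacing = c(1, 1, 1)) {
  assert_that(all(spacing > 0), "preprocess_volume: spacing must be positive")
  assert_that(all(is.finite(raw)), "preprocess_volume: non-finite voxel values")
  out <- resample_volume(raw, spacing, target_spacing, method = "linear")
  out <- clamp(out, hu_window[1], hu_window[2])
  out <- (out - hu_window[1]) / (hu_window[2] - hu_window[1])
  attr(out, "spacing") <- target_spacing
  out
}

#' Random spatially aligned patch crop
#'
#' Crops the same region from image and mask; optional Gaussian noise is
#' added to the image only (labels are never perturbed).
#'
#' @param volume 3D array.
#' @param mask 3D label array (same grid).
#' @param patch_size integer triple (default the 128x128x96 training patch).
#' @param seed RNG seed.
#' @param noise_sd intensity noise added to the image patch only.
#' @return list(`patch`, `patch_mask`).
#' @export
random_patch <- function(volume, mask, patch_size = c(128, 128, 96),
                         seed = 1, noise_sd = 0) {
  dm <- dim(volume)
  assert_that(all(patch_size <= dm),
              "random_patch: patch larger than volume")
  set.seed(seed)
  start <- vapply(1:3, function(ax) {
    if (dm[ax] == patch_size[ax]) 1L
    else sample.int(dm[ax] - patch_size[ax] + 1L, 1L)
  }, integer(1))
  ix <- lapply(1:3, function(ax) start[ax]:(start[ax] + patch_size[ax] - 1L))
  patch <- volume[ix[[1]], ix[[2]], ix[[3]]]
  pm <- mask[ix[[1]], ix[[2]], ix[[3]]]
  dim(patch) <- patch_size; dim(pm) <- patch_size
  if (noise_sd > 0) {
    patch <- patch + stats::rnorm(prod(patch_size), sd = noise_sd)
  }
  list(patch = patch, patch_mask = pm)
}

#' Fixed multi-scale encoder feature bank
#'
#' Desk-scale stand-in for a deep image encoder: for every voxel a vector of
#' intensity, Gaussian-smoothed intensities at several scales, gradient
#' magnitudes and a local standard deviation. The bank is deterministic
#' (no trained weights); downstream heads (classification, segmentation)
#' are linear in these channels.
#'
#' @param volume 3D array in `[0, 1]`.
#' @param sigmas smoothing scales in voxels.
#' @return 4D array `[dims, n_channels]`, channel names in attribute
#'   `channels`.
#' @export
encoder_features <- function(volume, sigmas = c(1, 2, 4)) {
  dm <- dim(volume)
  v <- array(as.numeric(volume), dm)
  chans <- list(raw = v)
  blurs <- lapply(sigmas, function(s) gaussian_blur3(v, s))
  names(blurs) <- paste0("blur", sigmas)
  chans <- c(chans, blurs)
  grad_mag <- function(a) {
    # central differences with replicated edges (flat at the boundary)
    k <- c(-0.5, 0, 0.5)
    gx <- convolve_axis(a, k, 1)
    gy <- convolve_axis(a, k, 2)
    gz <- convolve_axis(a, k, 3)
    sqrt(gx^2 + gy^2 + gz^2)
  }
  chans$grad1 <- grad_mag(blurs[[1]])
  chans$grad2 <- grad_mag(blurs[[min(2, length(blurs))]])
  m2 <- gaussian_blur3(v * v, sigmas[1])
  chans$localsd <- sqrt(pmax(0, m2 - blurs[[1]]^2))
  out <- array(0, c(dm, length(chans)))
  for (f in seq_along(chans)) out[, , , f] <- chans[[f]]
  attr(out, "channels") <- names(chans)
  out
}
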