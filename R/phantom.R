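# Synthetic cavity phantoms.
#
# Lung cavities in CT present as dark (air-filled) lumina surrounded by a
# thin bright wall which is often discontinuous. The phantom generator
# reproduces exactly those geometric features — ellipsoidal lumina, a bright
# wall shell of configurable thickness, an optional missing angular sector
# of the wall — on a smoothed-noise background, together with the
# ground-truth mask, the image-level class (cavity count x size rubric) and,
# separately, corrupted CAMs that emulate the partial, blurred, leaky
# localisation a weak classifier produces.

#' Phantom generator configuration
#'
#' @param shape volume dimensions in voxels (all >= 16).
#' @param n_cavities number of cavities to place (>= 0).
#' @param cavity_radius_range min/max mean semi-axis in voxels.
#' @param wall_thickness wall shell thickness in voxels.
#' @param wall_gap_fraction fraction of the wall solid angle removed to
#'   emulate wall discontinuities, in `[0, 1]`.
#' @param noise_sd additive Gaussian intensity noise (image is clamped to
#'   `[0, 1]` afterwards).
#' @param spacing voxel spacing in mm (isotropic 1 mm by default, matching
#'   the preprocessing convention).
#' @param seed RNG seed.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(64, 64, 48), n_cavities = 2,
                           cavity_radius_range = c(4, 12),
                           wall_thickness = 2, wall_gap_fraction = 0.15,
                           noise_sd = 0.05, spacing = c(1, 1, 1), seed = 1) {
  assert_that(length(shape) == 3 && all(shape >= 16),
              "phantom_config: all shape components must be >= 16")
  assert_that(n_cavities >= 0, "phantom_config: n_cavities must be >= 0")
  assert_that(cavity_radius_range[1] <= cavity_radius_range[2],
              "phantom_config: radius range min must be <= max")
  assert_that(noise_sd >= 0, "phantom_config: noise_sd must be >= 0")
  assert_that(wall_gap_fraction >= 0 && wall_gap_fraction <= 1,
              "phantom_config: wall_gap_fraction must lie in [0, 1]")
  structure(list(shape = as.integer(shape), n_cavities = as.integer(n_cavities),
                 cavity_radius_range = cavity_radius_range,
                 wall_thickness = wall_thickness,
                 wall_gap_fraction = wall_gap_fraction,
                 noise_sd = noise_sd, spacing = spacing,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' CAM corruption configuration
#'
#' Emulates the failure modes of weakly supervised localisation: only the
#' most discriminative core of a lesion is activated (`keep_fraction`), the
#' activation is blurred (`blur_sigma`) and spills into the background
#' (`leak_sigma`).
#'
#' @param keep_fraction fraction of lesion voxels kept as the activated
#'   core, in `(0, 1]`.
#' @param blur_sigma Gaussian blur applied to the core indicator (voxels).
#' @param leak_sigma amplitude of smoothed non-negative background noise.
#' @param seed RNG seed.
#' @return object of class `cam_corruption`.
#' @export
cam_corruption <- function(keep_fraction = 0.5, blur_sigma = 1,
                           leak_sigma = 0.05, seed = 1) {
  assert_that(is.finite(keep_fraction) && keep_fraction > 0 && keep_fraction <= 1,
              "cam_corruption: keep_fraction must lie in (0, 1]")
  assert_that(is.finite(blur_sigma) && blur_sigma >= 0,
              "cam_corruption: blur_sigma must be finite and >= 0")
  assert_that(is.finite(leak_sigma) && leak_sigma >= 0,
              "cam_corruption: leak_sigma must be finite and >= 0")
  structure(list(keep_fraction = keep_fraction, blur_sigma = blur_sigma,
                 leak_sigma = leak_sigma, seed = as.integer(seed)),
            class = "cam_corruption")
}

# Image-level class rubric: cavity count x maximum diameter (mm).
#   class 1: no cavities
#   class 2: 1-3 cavities, all < 25 mm
#   class 3: 1-3 cavities, largest > 25 mm
#   class 4: >3 cavities, all < 25 mm
#   class 5: >3 cavities, largest > 25 mm
# Diameter of a component = its largest bounding-box extent in mm.

#' Image-level cavity class of a ground-truth mask
#'
#' @param mask logical or 0/1 3D array.
#' @param spacing mm triple.
#' @param size_threshold_mm diameter cut between "small" and "large" (25 mm).
#' @return integer class in 1..5.
#' @export
cavity_class <- function(mask, spacing = c(1, 1, 1), size_threshold_mm = 25) {
  comp <- components6(array(mask > 0, dim(mask)))
  n <- max(comp)
  if (n == 0) return(1L)
  diam <- vapply(seq_len(n), function(c) {
    ijk <- vox_coords(which(comp == c), dim(mask))
    extents <- (apply(ijk, 2, max) - apply(ijk, 2, min) + 1) * spacing
    max(extents)
  }, numeric(1))
  large <- max(diam) >= size_threshold_mm
  if (n <= 3) (if (large) 3L else 2L) else (if (large) 5L else 4L)
}

# Ellipsoid membership on the voxel grid: returns a logical array.
.ellipsoid_mask <- function(shape, center, semiaxes) {
  i <- seq_len(shape[1]); j <- seq_len(shape[2]); k <- seq_len(shape[3])
  qi <- ((i - center[1]) / semiaxes[1])^2
  qj <- ((j - center[2]) / semiaxes[2])^2
  qk <- ((k - center[3]) / semiaxes[3])^2
  outer(outer(qi, qj, `+`), qk, `+`) <= 1
}

#' Generate a synthetic cavity phantom
#'
#' @param config a [phantom_config()].
#' @return list with components `volume` (3D array in `[0, 1]`, attribute
#'   `spacing`), `mask` (integer 3D array, 1 inside cavities), `class`
#'   (image-level class per the count x size rubric) and `cavities`
#'   (data.frame of centers/semi-axes).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  dm <- config$shape
  rr <- config$cavity_radius_range
  wt <- config$wall_thickness

  # background: smoothed Gaussian noise around mid-grey
  bg <- gaussian_blur3 (array(stats::rnorm(prod(dm)), dm), 2)
  vol <- 0.45 + 0.1 * bg / max(abs(bg), 1e-12)

  mask <- array(0L, dm)
  n <- config$n_cavities
  placed <- list()
  # bounded rejection sampling with a global restart: a greedy sequence can
  # dead-end in crowded shapes, so the whole placement is retried; radius
  # draws anneal towards the lower bound as restarts accumulate
  done <- n == 0
  for (attempt in seq_len(30)) {
    if (done) break
    placed <- list()
    frac <- 1 - (attempt - 1) / 30
    ok_all <- TRUE
    for (c in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(100)) {
        hi <- rr[1] + (rr[2] - rr[1]) * frac
        r0 <- stats::runif(1, rr[1], hi)
        ax <- r0 * stats::runif(3, 0.7, 1.3)
        margin <- ax + wt + 2
        if (any(dm - 2 * margin < 1)) next
        ctr <- vapply(1:3, function(a) {
          stats::runif(1, margin[a], dm[a] - margin[a])
        }, numeric(1))
        clear <- TRUE
        for (p in placed) {
          if (sqrt(sum((ctr - p$ctr)^2)) < max(ax) + max(p$ax) + 2 * wt + 2) {
            clear <- FALSE; break
          }
        }
        if (clear) {
          placed[[length(placed) + 1]] <- list(ctr = ctr, ax = ax)
          ok <- TRUE
          break
        }
      }
      if (!ok) { ok_all <- FALSE; break }
    }
    done <- ok_all && length(placed) == n
  }
  if (!done) {
    stop("generate_phantom: could not place ", n,
         " non-overlapping cavities in the given shape", call. = FALSE)
  }

  for (p in placed) {
    lumen <- .ellipsoid_mask(dm, p$ctr, p$ax)
    shell <- .ellipsoid_mask(dm, p$ctr, p$ax + wt) & !lumen
    if (config$wall_gap_fraction > 0 && any(shell)) {
      # remove a random angular sector of the wall (cos angle to a random
      # direction above a quantile cut)
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      ijk <- vox_coords(which(shell), dm)
      rel <- sweep(ijk, 2, p$ctr)
      cosang <- (rel %*% dir) / pmax(sqrt(rowSums(rel^2)), 1e-9)
      cut <- stats::quantile(cosang, 1 - config$wall_gap_fraction)
      shell[which(shell)[cosang >= cut]] <- FALSE
    }
    vol[lumen] <- 0.08
    vol[shell] <- 0.85
    mask[lumen] <- 1L
  }

  if (config$noise_sd > 0) {
    vol <- vol + stats::rnorm(prod(dm), sd = config$noise_sd)
  }
  vol <- clamp(vol, 0, 1)
  attr(vol, "spacing") <- config$spacing
  cav <- if (length(placed)) {
    data.frame(
      t(vapply(placed, function(p) c(p$ctr, p$ax), numeric(6)))
    )
  } else {
    data.frame(matrix(numeric(0), ncol = 6))
  }
  names(cav) <- c("ci", "cj", "ck", "ai", "aj", "ak")
  list(volume = vol, mask = mask,
       class = cavity_class(mask, config$spacing),
       cavities = cav)
}

#' Corrupt a ground-truth mask into a weak CAM
#'
#' For each foreground class, only the `keep_fraction` most interior lesion
#' voxels (depth ranked by distance to the lesion boundary, with small random
#' tie-breaking) are activated; the indicator is then blurred and smoothed
#' non-negative leak noise is added.
#'
#' @param mask integer 3D array with values in `0..(n_classes - 1)`.
#' @param corruption a [cam_corruption()].
#' @param n_classes total number of semantic classes including background
#'   (>= 2); the CAM has one channel per foreground class.
#' @return 4D array `[dims, n_classes - 1]` in `[0, 1]` of class
#'   `cam_volume`, with attribute `spacing` copied from `mask` if present.
#' @export
corrupt_cam <- function(mask, corruption, n_classes = 2) {
  stopifnot(inherits(corruption, "cam_corruption"))
  assert_that(n_classes >= 2, "corrupt_cam: n_classes must be >= 2")
  assert_that(max(mask) < n_classes, "corrupt_cam: mask classes must be < n_classes")
  set.seed(corruption$seed)
  dm <- dim(mask)
  C <- n_classes - 1L
  cam <- array(0, c(dm, C))
  for (cls in seq_len(C)) {
    ind <- array(mask == cls, dm)
    ch <- array(0, dm)
    nfg <- sum(ind)
    if (nfg > 0) {
      if (corruption$keep_fraction >= 1) {
        ch[ind] <- 1
      } else {
        # depth to lesion boundary; deterministic noise breaks plateaus so
        # cores nest monotonically in keep_fraction for a fixed seed
        depth <- distance_transform(!ind)
        score <- depth[ind] + stats::runif(nfg, 0, 1e-3)
        keep_n <- max(1L, floor(corruption$keep_fraction * nfg))
        core_idx <- which(ind)[order(score, decreasing = TRUE)[seq_len(keep_n)]]
        ch[core_idx] <- 1
      }
      if (corruption$blur_sigma > 0) {
        ch <- gaussian_blur3(ch, corruption$blur_sigma)
        if (max(ch) > 0) ch <- ch / max(ch)
      }
    }
    if (corruption$leak_sigma > 0) {
      leak <- gaussian_blur3(array(abs(stats::rnorm(prod(dm))), dm), 2)
      ch <- ch + corruption$leak_sigma * leak / max(leak)
    }
    cam[, , , cls] <- clamp(ch, 0, 1)
  }
  attr(cam, "spacing") <- attr(mask, "spacing") %||% c(1, 1, 1)
  class(cam) <- "cam_volume"
  cam
}

#' Write a suite of phantom fixtures to disk
#'
#' Generates `n_cases` phantoms (cavity count cycling over 0..4, radii
#' sampled per case), writes volume/mask/CAM NIfTI triplets and a JSON
#' manifest with image-level labels and per-case seeds.
#'
#' @param n_cases number of cases (>= 1).
#' @param out_dir output directory (created if needed).
#' @param seed master seed; per-case seeds are derived from it.
#' @param shape volume shape passed to the generator.
#' @param cavity_radius_range semi-axis range (voxels) for every case.
#' @param corruption a [cam_corruption()] applied to every case (its seed is
#'   re-derived per case).
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
make_fixture_suite <- function(n_cases, out_dir, seed = 1,
                               shape = c(48, 48, 32),
                               cavity_radius_range = c(3, 6),
                               corruption = cam_corruption()) {
  assert_that(n_cases >= 1, "make_fixture_suite: n_cases must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  assert_that(dir.exists(out_dir),
              sprintf("make_fixture_suite: cannot create '%s'", out_dir))
  cases <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    case_seed <- child_seed(seed, i)
    ncav <- (i - 1L) %% 5L
    cfg <- phantom_config(shape = shape, n_cavities = ncav,
                          cavity_radius_range = cavity_radius_range,
                          seed = case_seed)
    ph <- generate_phantom(cfg)
    corr <- corruption
    corr$seed <- child_seed(case_seed, 17L)
    cam <- corrupt_cam(ph$mask, corr, n_classes = 2)
    id <- sprintf("case_%03d", i)
    paths <- list(
      volume = file.path(out_dir, paste0(id, "_vol.nii.gz")),
      mask = file.path(out_dir, paste0(id, "_mask.nii.gz")),
      cam = file.path(out_dir, paste0(id, "_cam.nii.gz"))
    )
    write_nifti(ph$volume, paths$volume, spacing = cfg$spacing)
    write_nifti(ph$mask, paths$mask, spacing = cfg$spacing, datatype = "int16")
    write_nifti(unclass(cam), paths$cam, spacing = cfg$spacing)
    cases[[i]] <- list(case_id = id, paths = paths, class = ph$class,
                       n_cavities = ncav, seed = case_seed,
                       spacing = cfg$spacing)
  }
  manifest <- list(n_cases = n_cases, seed = seed, cases = cases)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
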