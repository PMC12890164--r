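# CAM-driven pseudo-label generation.
#
# A classification head trained on image-level labels yields per-class
# activation maps; dual thresholds (phi_l, phi_h) split voxels into reliable
# background, reliable foreground (argmax class) and an ignored uncertainty
# band; voxel-level cosine affinities in a local 3D window (the Affinity
# Converter) supply the pairwise structure, supervised through the focal
# affinity loss on pairs of reliably labelled voxels.

# sentinel for the uncertainty band; exported label maps use 255
.IGNORE <- -1L
.IGNORE_EXPORT <- 255L

#' Label-smoothing one-vs-rest classification loss
#'
#' Smoothed targets `y~ = (1 - eps) y + eps / K` in a per-class binary
#' cross-entropy, averaged over cases.
#'
#' @param probs n x K matrix of predicted class probabilities (one-vs-rest).
#' @param labels integer class indices (1..K).
#' @param epsilon smoothing weight in `[0, 1)` (default 0.15).
#' @param K number of classes (default `ncol(probs)`).
#' @return scalar loss.
#' @export
classification_loss <- function(probs, labels, epsilon = 0.15, K = ncol(probs)) {
  assert_that(epsilon >= 0 && epsilon < 1,
              "classification_loss: epsilon must lie in [0, 1)")
  n <- nrow(probs)
  y <- matrix(0, n, K)
  y[cbind(seq_len(n), labels)] <- 1
  yt <- (1 - epsilon) * y + epsilon / K
  p <- clamp_prob(probs)
  -mean(rowSums(yt * log(p) + (1 - yt) * log(1 - p)))
}

# global-average-pooled encoder features for one case
.gap_features <- function(volume) {
  fe <- encoder_features(volume)
  apply(fe, 4, mean)
}

#' Train the classification head and extract CAMs
#'
#' Desk-scale classifier: the fixed multi-scale encoder bank
#' ([encoder_features()]) is globally average pooled per channel; a linear
#' one-vs-rest head is trained with the label-smoothing loss by Adam. The
#' CAM of class k is the head-weight-weighted sum of the per-voxel feature
#' maps, min-max normalised to `[0, 1]` per class.
#'
#' @param volumes list of 3D arrays.
#' @param labels integer image-level class per volume (>= 2 distinct).
#' @param config list: `K` (number of classes, default
#'   `max(labels)`), `steps` (200), `lr` (0.1), `epsilon` (0.15), `seed` (1).
#' @return list(`weights` (F x K), `bias` (K), `history` (data.frame step,
#'   loss), `cams` (list of 4D arrays `[dims, K]`), `channels`).
#' @export
train_classifier_and_cam <- function(volumes, labels, config = list()) {
  assert_that(length(unique(labels)) >= 2,
              "train_classifier_and_cam: need >= 2 classes in the manifest")
  cfg <- utils::modifyList(list(K = max(labels), steps = 200, lr = 0.1,
                                epsilon = 0.15, seed = 1), config)
  set.seed(cfg$seed)
  X <- t(vapply(volumes, .gap_features, numeric(length(.gap_features(volumes[[1]])))))
  n <- nrow(X); F_ <- ncol(X); K <- cfg$K
  Xs <- scale(X)
  ctr <- attr(Xs, "scaled:center"); scl <- attr(Xs, "scaled:scale")
  scl[scl == 0 | is.na(scl)] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Wt <- matrix(stats::rnorm(F_ * K, sd = 0.01), F_, K)
  b <- numeric(K)
  y <- matrix(0, n, K); y[cbind(seq_len(n), labels)] <- 1
  yt <- (1 - cfg$epsilon) * y + cfg$epsilon / K
  mW <- vW <- matrix(0, F_, K); mb <- vb <- numeric(K)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  history <- data.frame(step = integer(0), loss = numeric(0))
  for (step in seq_len(cfg$steps)) {
    logits <- sweep(Xs %*% Wt, 2, b, "+")
    p <- sigmoid(logits)
    loss <- classification_loss(p, labels, cfg$epsilon, K)
    history <- rbind(history, data.frame(step = step, loss = loss))
    dlogit <- (p - yt) / n
    gW <- crossprod(Xs, dlogit); gb <- colSums(dlogit)
    mW <- b1 * mW + (1 - b1) * gW; vW <- b2 * vW + (1 - b2) * gW^2
    mb <- b1 * mb + (1 - b1) * gb; vb <- b2 * vb + (1 - b2) * gb^2
    Wt <- Wt - cfg$lr * (mW / (1 - b1^step)) / (sqrt(vW / (1 - b2^step)) + eps)
    b <- b - cfg$lr * (mb / (1 - b1^step)) / (sqrt(vb / (1 - b2^step)) + eps)
  }
  cams <- lapply(volumes, function(v) {
    compute_cam(v, Wt, feature_center = ctr, feature_scale = scl)
  })
  list(weights = Wt, bias = b, history = history, cams = cams,
       feature_center = ctr, feature_scale = scl)
}

#' CAM from head weights on the encoder bank
#'
#' `CAM_k(x) = sum_f w_fk F_f(x)` on standardised feature maps, min-max
#' normalised to `[0, 1]` per class (constant maps stay 0).
#'
#' @param volume 3D array.
#' @param weights F x K head weight matrix.
#' @param feature_center,feature_scale per-channel standardisation applied
#'   before the weighted sum (as used during head training).
#' @return `cam_volume`: 4D array `[dims, K]` in `[0, 1]`.
#' @export
compute_cam <- function(volume, weights, feature_center = NULL,
                        feature_scale = NULL) {
  fe <- encoder_features(volume)
  dm <- dim(fe)[1:3]
  F_ <- dim(fe)[4]; K <- ncol(weights)
  fmat <- matrix(fe, ncol = F_)
  if (!is.null(feature_center)) fmat <- sweep(fmat, 2, feature_center)
  if (!is.null(feature_scale)) fmat <- sweep(fmat, 2, feature_scale, "/")
  raw <- fmat %*% weights
  cam <- array(0, c(dm, K))
  for (k in seq_len(K)) {
    ch <- raw[, k]
    rng <- range(ch)
    if (rng[2] > rng[1]) ch <- (ch - rng[1]) / (rng[2] - rng[1]) else ch <- ch * 0
    cam[, , , k] <- ch
  }
  attr(cam, "spacing") <- attr(volume, "spacing") %||% c(1, 1, 1)
  class(cam) <- "cam_volume"
  cam
}

#' Dual-threshold pseudo-label seeding
#'
#' Per voxel: max activation `>= phi_h` gives the argmax class; `<= phi_l`
#' gives background 0; the band in between is IGNORE (-1).
#'
#' @param cam 4D CAM array `[dims, C]`.
#' @param phi_l,phi_h thresholds with `0 < phi_l < phi_h < 1` (defaults
#'   0.32 / 0.46, the selected configuration).
#' @return `pseudo_label`: 3D integer array with values `-1, 0, 1..C`.
#' @export
dual_threshold <- function(cam, phi_l = 0.32, phi_h = 0.46) {
  assert_that(phi_l > 0 && phi_h < 1 && phi_l < phi_h,
              "dual_threshold: need 0 < phi_l < phi_h < 1")
  dm <- dim(cam)
  C <- dm[4]
  mx <- array(-Inf, dm[1:3]); am <- array(1L, dm[1:3])
  for (c in seq_len(C)) {
    ch <- array(cam[, , , c], dm[1:3])
    upd <- ch > mx
    mx[upd] <- ch[upd]
    am[upd] <- c
  }
  out <- array(.IGNORE, dm[1:3])
  out[mx <= phi_l] <- 0L
  out[mx >= phi_h] <- am[mx >= phi_h]
  storage.mode(out) <- "integer"
  class(out) <- "pseudo_label"
  out
}

# half-space window offsets (first nonzero component positive), excluding 0
.window_offsets <- function(window_radius) {
  g <- as.matrix(expand.grid(-window_radius[1]:window_radius[1],
                             -window_radius[2]:window_radius[2],
                             -window_radius[3]:window_radius[3]))
  colnames(g) <- NULL
  keep <- g[, 1] > 0 |
    (g[, 1] == 0 & g[, 2] > 0) |
    (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
  g[keep, , drop = FALSE]
}

#' Voxel-pair affinities in a local 3D window (Affinity Converter)
#'
#' `A(u, v) = (cos(f(u), f(v)) + 1) / 2` for all voxel pairs within the
#' window; symmetric, self-affinity 1. Zero-norm feature vectors get the
#' uninformative value 0.5 (with a message).
#'
#' @param features 4D per-voxel feature field `[dims, F]`.
#' @param window_radius integer triple (default `c(7, 7, 7)`, the radius at
#'   which performance peaks).
#' @return object of class `sparse_affinity`: list(`window_radius`,
#'   `offsets` (half-space offsets, m x 3), `values` (list of 3D arrays;
#'   entry at voxel v is A(v, v + offset), NA outside the overlap), `dim`,
#'   `logit` flag).
#' @export
voxel_affinity <- function(features, window_radius = c(7, 7, 7)) {
  dm <- dim(features)[1:3]
  F_ <- dim(features)[4]
  fmat <- matrix(features, ncol = F_)
  nrm <- sqrt(rowSums(fmat^2))
  zero <- nrm < 1e-12
  if (any(zero)) message("voxel_affinity: ", sum(zero),
                         " zero-norm feature vectors set to affinity 0.5")
  offs <- .window_offsets(window_radius)
  vals <- vector("list", nrow(offs))
  unit <- fmat / pmax(nrm, 1e-12)
  ua <- array(unit, c(dm, F_))
  for (o in seq_len(nrow(offs))) {
    d <- offs[o, ]
    acc <- array(0, dm)
    valid <- array(TRUE, dm)
    for (f in seq_len(F_)) {
      sh <- shift3(array(ua[, , , f], dm), d, fill = NA)
      acc <- acc + array(ua[, , , f], dm) * sh
      if (f == 1) valid <- !is.na(sh)
    }
    A <- (clamp(acc, -1, 1) + 1) / 2
    zsh <- shift3(array(zero * 1, dm), d, fill = 0)
    zz <- (array(zero, dm) | zsh > 0) & valid
    A[zz] <- 0.5
    A[!valid] <- NA
    vals[[o]] <- A
  }
  structure(list(window_radius = window_radius, offsets = offs,
                 values = vals, dim = dm, logit = FALSE),
            class = "sparse_affinity")
}

#' Convert stored affinities to logits (log-odds)
#'
#' @param affinity a `sparse_affinity` with probabilities.
#' @return the same object with `values` on the logit scale and
#'   `logit = TRUE`.
#' @export
affinity_logits <- function(affinity) {
  assert_that(!affinity$logit, "affinity_logits: already on the logit scale")
  affinity$values <- lapply(affinity$values, function(a) stats::qlogis(clamp_prob(a)))
  affinity$logit <- TRUE
  affinity
}

#' Derive positive/negative affinity supervision pairs
#'
#' For voxel pairs within the window whose pseudo-labels are both reliable
#' (not IGNORE): equal labels form the positive set, different labels the
#' negative set; pairs touching IGNORE are excluded.
#'
#' @param pseudo a `pseudo_label` array.
#' @param window_radius integer triple (shared with the propagation window).
#' @return object of class `affinity_targets`: list(`offsets`, `status`
#'   (list of arrays: 1 positive, -1 negative, 0 excluded/NA), `n_pos`,
#'   `n_neg`).
#' @export
derive_affinity_targets <- function(pseudo, window_radius = c(7, 7, 7)) {
  dm <- dim(pseudo)
  lab <- array(as.integer(pseudo), dm)
  offs <- .window_offsets(window_radius)
  status <- vector("list", nrow(offs))
  n_pos <- 0; n_neg <- 0
  for (o in seq_len(nrow(offs))) {
    nb <- shift3(lab, offs[o, ], fill = NA)
    st <- array(0L, dm)
    ok <- !is.na(nb) & lab != .IGNORE & nb != .IGNORE
    st[ok & lab == nb] <- 1L
    st[ok & lab != nb] <- -1L
    n_pos <- n_pos + sum(st == 1L)
    n_neg <- n_neg + sum(st == -1L)
    status[[o]] <- st
  }
  assert_that(n_pos + n_neg > 0,
              "derive_affinity_targets: no reliable voxel pairs in the window")
  structure(list(offsets = offs, status = status,
                 n_pos = n_pos, n_neg = n_neg),
            class = "affinity_targets")
}

#' Focal affinity loss on logit affinities
#'
#' `L_aff = mean_{K+} log(1 + exp(-W)) + mean_{K-} log(1 + exp(W))`; a term
#' whose pair set is empty is skipped.
#'
#' @param W_aff a `sparse_affinity` on the logit scale (see
#'   [affinity_logits()]), or a plain list of arrays matching
#'   `targets$offsets`.
#' @param targets an `affinity_targets`.
#' @return scalar loss.
#' @export
focal_affinity_loss <- function(W_aff, targets) {
  assert_that(targets$n_pos > 0 || targets$n_neg > 0,
              "focal_affinity_loss: both pair sets empty")
  vals <- if (inherits(W_aff, "sparse_affinity")) {
    assert_that(W_aff$logit,
                "focal_affinity_loss: affinities must be logits (see affinity_logits)")
    W_aff$values
  } else W_aff
  pos_sum <- 0; neg_sum <- 0
  for (o in seq_along(targets$status)) {
    st <- targets$status[[o]]
    Wv <- vals[[o]]
    pidx <- st == 1L
    nidx <- st == -1L
    if (any(pidx)) pos_sum <- pos_sum + sum(softplus(-Wv[pidx]))
    if (any(nidx)) neg_sum <- neg_sum + sum(softplus(Wv[nidx]))
  }
  loss <- 0
  if (targets$n_pos > 0) loss <- loss + pos_sum / targets$n_pos
  if (targets$n_neg > 0) loss <- loss + neg_sum / targets$n_neg
  loss
}

#' Persist / restore a windowed sparse affinity container
#'
#' Compressed container holding the window metadata header (radius,
#' offsets, grid dimension, scale flag) together with the per-offset value
#' arrays.
#'
#' @param affinity a `sparse_affinity`.
#' @param path output path (conventionally `.affz`).
#' @return `path` invisibly; `read_affinity()` returns the restored object.
#' @export
write_affinity <- function(affinity, path) {
  stopifnot(inherits(affinity, "sparse_affinity"))
  saveRDS(list(format = "cavitygraph-affinity", version = 1L,
               container = unclass(affinity)),
          path, compress = "gzip")
  invisible(path)
}

#' @rdname write_affinity
#' @export
read_affinity <- function(path) {
  obj <- readRDS(path)
  assert_that(identical(obj$format, "cavitygraph-affinity"),
              "read_affinity: not an affinity container")
  structure(obj$container, class = "sparse_affinity")
}

#' Export a pseudo-label map as NIfTI
#'
#' The IGNORE sentinel (-1 in memory) is stored as 255; a JSON legend
#' sidecar is written next to the image.
#'
#' @param pseudo a `pseudo_label`.
#' @param path output `.nii`/`.nii.gz` path.
#' @param spacing mm triple.
#' @return `path`, invisibly.
#' @export
export_pseudo_label <- function(pseudo, path, spacing = c(1, 1, 1)) {
  lab <- array(as.integer(pseudo), dim(pseudo))
  lab[lab == .IGNORE] <- .IGNORE_EXPORT
  write_nifti(lab, path, spacing = spacing, datatype = "int16")
  legend <- list(background = 0, ignore = .IGNORE_EXPORT,
                 classes = "1..C foreground class indices")
  jsonlite::write_json(legend, paste0(sub("\\.nii(\\.gz)?$", "", path), "_legend.json"),
                       auto_unbox = TRUE)
  invisible(path)
}
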