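# Pseudo-supervised segmentation training.
#
# The refined pseudo-labels supervise a per-voxel classifier through a
# smoothed cross-entropy (ignored voxels excluded); contour-derived
# scribbles add boundary supervision through a partial cross-entropy on the
# scribbled voxels only; EMA ensembling stabilises the per-case prediction
# fields across training iterations. At desk scale the segmenter is a
# linear softmax decoder over the fixed multi-scale encoder bank (a
# frozen-encoder encoder-decoder); the full deep backbone is out of scope.

#' Smoothed cross-entropy segmentation loss
#'
#' Mean over labelled (non-IGNORE) voxels of
#' `-sum_k ((1 - eps) y_k + eps / K) log p_k`.
#'
#' @param probs n x K matrix of per-voxel class probabilities (rows on the
#'   simplex; K includes background as class 1).
#' @param labels integer vector with values `0..K-1` or the IGNORE
#'   sentinel -1; label m maps to class column m + 1.
#' @param epsilon label-smoothing weight (default 0.15).
#' @param K number of classes.
#' @return scalar loss.
#' @export
seg_loss <- function(probs, labels, epsilon = 0.15, K = ncol(probs)) {
  sup <- which(labels != .IGNORE)
  assert_that(length(sup) > 0, "seg_loss: empty supervision support")
  p <- clamp_prob(probs[sup, , drop = FALSE])
  y <- matrix(0, length(sup), K)
  y[cbind(seq_along(sup), labels[sup] + 1L)] <- 1
  yt <- (1 - epsilon) * y + epsilon / K
  -mean(rowSums(yt * log(p)))
}

#' Initialise an EMA prediction state
#'
#' @param y0 initial prediction field (any numeric array).
#' @param delta smoothing factor in `(0, 1]` (default 0.2); `delta = 1`
#'   reproduces the raw predictions.
#' @param gamma ensembling interval (default 8): the average is refreshed
#'   only on iterations divisible by `gamma`.
#' @return object of class `ema_state`.
#' @export
ema_state <- function(y0, delta = 0.2, gamma = 8) {
  assert_that(delta > 0 && delta <= 1, "ema_state: delta must lie in (0, 1]")
  assert_that(gamma >= 1, "ema_state: gamma must be a positive integer")
  structure(list(y = y0, delta = delta, gamma = as.integer(gamma),
                 update_count = 0L),
            class = "ema_state")
}

#' EMA update rule
#'
#' On iterations with `iteration %% gamma == 0`:
#' `y_n = delta * f + (1 - delta) * y_{n-1}`; otherwise the state is
#' returned unchanged. For constant input `f = c`,
#' `y_n = c + (1 - delta)^n (y_0 - c)`.
#'
#' @param state an `ema_state`.
#' @param prediction current model prediction, same shape as the state.
#' @param iteration training iteration counter.
#' @return updated `ema_state`.
#' @export
ema_update <- function(state, prediction, iteration) {
  stopifnot(inherits(state, "ema_state"))
  assert_that(all(dim(prediction) %||% length(prediction) ==
                    (dim(state$y) %||% length(state$y))),
              "ema_update: prediction shape mismatch")
  if (iteration %% state$gamma != 0) return(state)
  state$y <- state$delta * prediction + (1 - state$delta) * state$y
  state$update_count <- state$update_count + 1L
  state
}

#' Contour-derived scribbles from a pseudo-label map
#'
#' Stand-in for cavity-contour scribbling: foreground scribbles are a
#' subsample of the inner contour (erosion residue of width `band`) of each
#' foreground component; background scribbles are a subsample of the outer
#' shell at distance `band` outside the foreground. Scribbles never cross
#' the pseudo-label boundary.
#'
#' @param pseudo a `pseudo_label` (IGNORE voxels are treated as unlabelled
#'   and never scribbled).
#' @param stride keep every `stride`-th contour voxel (default 4).
#' @param band contour width / background shell distance in voxels.
#' @return object of class `scribble_set`: list(`labels` (3D integer array:
#'   1 foreground, 0 background, -1 unlabelled), `omega` (linear indices of
#'   scribbled voxels), `sparsity`).
#' @export
extract_scribbles <- function(pseudo, stride = 4, band = 1) {
  dm <- dim(pseudo)
  fg <- array(as.integer(pseudo) > 0, dm)
  out <- array(-1L, dm)
  if (!any(fg)) {
    message("extract_scribbles: no foreground component; empty scribble set")
    return(structure(list(labels = out, omega = integer(0), sparsity = 0),
                     class = "scribble_set"))
  }
  er <- fg
  for (b in seq_len(band)) er <- erode6(er)
  inner <- fg & !er
  di <- fg
  for (b in seq_len(band)) di <- dilate6(di)
  prev <- fg
  if (band > 1) for (b in seq_len(band - 1)) prev <- dilate6(prev)
  outer_shell <- di & !prev & array(as.integer(pseudo) == 0L, dm)

  sub <- function(mask) {
    idx <- which(mask)
    idx[seq_along(idx) %% stride == 1L | stride == 1L]
  }
  fg_idx <- sub(inner)
  bg_idx <- sub(outer_shell)
  out[fg_idx] <- 1L
  out[bg_idx] <- 0L
  omega <- c(fg_idx, bg_idx)
  structure(list(labels = out, omega = omega,
                 sparsity = length(omega) / prod(dm)),
            class = "scribble_set")
}

#' Partial cross-entropy on scribbled voxels
#'
#' `-mean_{j in Omega_s} [ Y_s log p + (1 - Y_s) log(1 - p) ]`; voxels
#' outside the scribble set never contribute.
#'
#' @param probs 3D array (or vector) of foreground probabilities.
#' @param scribbles a `scribble_set` with non-empty `omega`.
#' @return scalar loss.
#' @export
partial_ce <- function(probs, scribbles) {
  assert_that(length(scribbles$omega) > 0, "partial_ce: empty scribble set")
  p <- clamp_prob(as.numeric(probs)[scribbles$omega])
  ys <- as.numeric(scribbles$labels)[scribbles$omega]
  -mean(ys * log(p) + (1 - ys) * log(1 - p))
}

#' Weighted total training loss
#'
#' `L = L_cls + l1 L_struct + l2 L_smooth + l3 L_aff + l4 L_pce + l5 L_seg`
#' with the selected weights (0.6, 0.5, 0.5, 0.7, 0.5) as defaults.
#'
#' @param components named numeric vector with elements `cls`, `struct`,
#'   `smooth`, `aff`, `pce`, `seg`.
#' @param weights numeric vector `lambda1..lambda5` (>= 0).
#' @return scalar total loss.
#' @export
total_loss <- function(components,
                       weights = c(0.6, 0.5, 0.5, 0.7, 0.5)) {
  assert_that(all(is.finite(components)), "total_loss: non-finite components")
  assert_that(all(weights >= 0) && length(weights) == 5,
              "total_loss: need 5 non-negative weights")
  unname(components["cls"] +
           weights[1] * components["struct"] +
           weights[2] * components["smooth"] +
           weights[3] * components["aff"] +
           weights[4] * components["pce"] +
           weights[5] * components["seg"])
}

#' Train the pseudo-supervised segmenter
#'
#' Linear softmax decoder over the fixed encoder bank, trained with
#' `lambda5 * L_seg + lambda4 * L_pce` by Adam; per-case prediction fields
#' are ensembled with [ema_update()] every `gamma` iterations.
#'
#' @param volumes list of 3D arrays.
#' @param pseudo_labels list of `pseudo_label` arrays (refined labels).
#' @param scribbles list of `scribble_set`s (or NULL to skip L_pce).
#' @param config list: `steps` (100), `lr` (0.05), `epsilon` (0.15),
#'   `delta` (0.2), `gamma` (8), `lambda4` (0.7), `lambda5` (0.5), `seed`
#'   (1), `truth` (optional list of ground-truth masks for validation DSC).
#' @return list(`weights`, `bias`, `history` (data.frame step, loss_seg,
#'   loss_pce, val_dsc), `predictions` (per-case EMA probability fields),
#'   `raw_predictions`).
#' @export
train_segmenter <- function(volumes, pseudo_labels, scribbles = NULL,
                            config = list()) {
  cfg <- utils::modifyList(list(steps = 100, lr = 0.05, epsilon = 0.15,
                                delta = 0.2, gamma = 8, lambda4 = 0.7,
                                lambda5 = 0.5, seed = 1, truth = NULL),
                           config)
  set.seed(cfg$seed)
  ncase <- length(volumes)
  K <- 2L # background + cavity at desk scale
  feats <- lapply(volumes, function(v) {
    fe <- encoder_features(v)
    matrix(fe, ncol = dim(fe)[4])
  })
  F_ <- ncol(feats[[1]])
  # per-channel standardisation across cases
  allm <- do.call(rbind, feats)
  ctr <- colMeans(allm); scl <- apply(allm, 2, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  feats <- lapply(feats, function(m) sweep(sweep(m, 2, ctr), 2, scl, "/"))
  labs <- lapply(pseudo_labels, function(p) {
    l <- as.integer(p)
    l[l > 0L] <- 1L # collapse to binary cavity foreground
    l
  })
  Wt <- matrix(stats::rnorm(F_ * K, sd = 0.01), F_, K)
  b <- numeric(K)
  mW <- vW <- matrix(0, F_, K); mb <- vb <- numeric(K)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  ema <- vector("list", ncase)
  raw_pred <- vector("list", ncase)
  history <- data.frame(step = integer(0), loss_seg = numeric(0),
                        loss_pce = numeric(0), val_dsc = numeric(0))
  for (step in seq_len(cfg$steps)) {
    gW <- matrix(0, F_, K); gb <- numeric(K)
    ls_tot <- 0; lp_tot <- 0
    for (i in seq_len(ncase)) {
      logits <- sweep(feats[[i]] %*% Wt, 2, b, "+")
      logits <- logits - apply(logits, 1, max)
      ex <- exp(logits)
      p <- ex / rowSums(ex)
      li <- labs[[i]]
      ls <- seg_loss(p, li, cfg$epsilon, K)
      sup <- which(li != .IGNORE)
      y <- matrix(0, length(sup), K)
      y[cbind(seq_along(sup), li[sup] + 1L)] <- 1
      yt <- (1 - cfg$epsilon) * y + cfg$epsilon / K
      dlogit <- matrix(0, nrow(p), K)
      dlogit[sup, ] <- cfg$lambda5 * (p[sup, , drop = FALSE] - yt) /
        (length(sup) * ncase)
      lp <- 0
      if (!is.null(scribbles) && length(scribbles[[i]]$omega) > 0) {
        sc <- scribbles[[i]]
        pf <- p[, 2]
        lp <- partial_ce(pf, sc)
        # d pce / d pf = (pf - ys) / (pf (1 - pf)) / |Omega|
        pfo <- clamp_prob(pf[sc$omega])
        ys <- as.numeric(sc$labels)[sc$omega]
        dpf <- (pfo - ys) / (pfo * (1 - pfo)) / length(sc$omega)
        # softmax: d pf / d logit_k = pf (delta_k2 - p_k)
        dl <- matrix(0, nrow(p), K)
        po <- p[sc$omega, , drop = FALSE]
        dl[sc$omega, 1] <- dpf * (-pfo * po[, 1])
        dl[sc$omega, 2] <- dpf * pfo * (1 - po[, 2])
        dlogit <- dlogit + cfg$lambda4 * dl / ncase
      }
      gW <- gW + crossprod(feats[[i]], dlogit)
      gb <- gb + colSums(dlogit)
      ls_tot <- ls_tot + ls / ncase
      lp_tot <- lp_tot + lp / ncase
      pfield <- array(p[, 2], dim(volumes[[i]]))
      raw_pred[[i]] <- pfield
      if (is.null(ema[[i]])) {
        ema[[i]] <- ema_state(pfield, cfg$delta, cfg$gamma)
      } else {
        ema[[i]] <- ema_update(ema[[i]], pfield, step)
      }
    }
    if (!is.finite(ls_tot + lp_tot)) {
      stop("train_segmenter: non-finite loss at step ", step, call. = FALSE)
    }
    val_dsc <- NA_real_
    if (!is.null(cfg$truth)) {
      d <- vapply(seq_len(ncase), function(i) {
        overlap_metrics(raw_pred[[i]] >= 0.5, cfg$truth[[i]] > 0)["dsc"]
      }, numeric(1))
      val_dsc <- mean(d)
    }
    history <- rbind(history, data.frame(step = step, loss_seg = ls_tot,
                                         loss_pce = lp_tot, val_dsc = val_dsc))
    mW <- b1 * mW + (1 - b1) * gW; vW <- b2 * vW + (1 - b2) * gW^2
    mb <- b1 * mb + (1 - b1) * gb; vb <- b2 * vb + (1 - b2) * gb^2
    Wt <- Wt - cfg$lr * (mW / (1 - b1^step)) / (sqrt(vW / (1 - b2^step)) + eps)
    b <- b - cfg$lr * (mb / (1 - b1^step)) / (sqrt(vb / (1 - b2^step)) + eps)
  }
  list(weights = Wt, bias = b, history = history,
       predictions = lapply(ema, function(s) s$y),
       raw_predictions = raw_pred)
}
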