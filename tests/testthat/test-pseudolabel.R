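test_that("label-smoothing classification loss has the right targets and limits", {
  # smoothed target for the true class at eps = 0.15, K = 5 is 0.88
  eps <- 0.15; K <- 5
  expect_equal((1 - eps) * 1 + eps / K, 0.88)
  # eps = 0 with perfect (clamped) one-hot predictions: loss -> 0
  p <- matrix(1e-7, 2, 3); p[cbind(1:2, c(1, 3))] <- 1 - 1e-7
  expect_lt(classification_loss(p, c(1, 3), epsilon = 0), 1e-5)
  # uniform predictions, any labels: loss = K * ln 2 regardless of eps
  pu <- matrix(0.5, 4, 5)
  expect_equal(classification_loss(pu, c(1, 2, 3, 4), epsilon = 0.15), 5 * log(2))
  expect_error(classification_loss(pu, rep(1, 4), epsilon = 1), "epsilon")
})

test_that("classifier head training reduces the loss and emits normalised CAMs", {
  d <- withr::local_tempdir()
  m <- make_fixture_suite(12, d, seed = 1, shape = c(36, 36, 24),
                          cavity_radius_range = c(2.5, 4))
  vols <- lapply(m$cases, function(cs) read_nifti(cs$paths$volume))
  labs <- vapply(m$cases, function(cs) cs$class, numeric(1))
  cls <- train_classifier_and_cam(vols, labs, list(K = 5, steps = 200, seed = 0))
  h <- cls$history$loss
  expect_lte(utils::tail(h, 1), 0.5 * h[1]) # >= 50% decrease
  cam <- cls$cams[[1]]
  expect_true(all(cam >= 0 & cam <= 1))
  for (k in seq_len(dim(cam)[4])) {
    ch <- cam[, , , k]
    if (max(ch) > min(ch)) {
      expect_equal(min(ch), 0)
      expect_equal(max(ch), 1)
    }
  }
  expect_error(train_classifier_and_cam(vols, rep(2, length(vols))),
               ">= 2 classes")
})

test_that("CAM equals the analytic weighted feature sum before normalisation", {
  # constant feature maps: the raw CAM is the same dot product everywhere,
  # so the normalised CAM is identically zero (constant map convention)
  v <- array(0.5, c(8, 8, 8))
  W <- matrix(c(1, -1, 0.5, 0.2, 0, 1, 2), ncol = 1)
  cam <- compute_cam(v, W)
  expect_true(all(cam == 0))
  # non-constant volume: spot-check one voxel against the explicit dot product
  set.seed(4)
  v2 <- array(runif(8^3), c(8, 8, 8))
  fe <- encoder_features(v2)
  raw <- matrix(fe, ncol = dim(fe)[4]) %*% W
  expected <- (raw - min(raw)) / (max(raw) - min(raw))
  cam2 <- compute_cam(v2, W)
  expect_equal(as.numeric(cam2), as.numeric(expected), tolerance = 1e-12)
})

test_that("dual-threshold partition matches a brute-force scan and is exhaustive", {
  set.seed(9)
  for (rep in 1:5) {
    cam <- random_cam(c(16, 16, 16), C = 3, seed = 100 + rep)
    ps <- dual_threshold(cam, 0.32, 0.46)
    # brute-force per-voxel loop oracle
    counts <- c(fg = 0, bg = 0, ig = 0)
    mism <- 0
    for (i in 1:16) for (j in 1:16) for (k in 1:16) {
      vals <- cam[i, j, k, ]
      expected <- if (max(vals) >= 0.46) which.max(vals)
      else if (max(vals) <= 0.32) 0L else -1L
      if (ps[i, j, k] != expected) mism <- mism + 1
      counts[if (expected > 0) "fg" else if (expected == 0) "bg" else "ig"] <-
        counts[if (expected > 0) "fg" else if (expected == 0) "bg" else "ig"] + 1
    }
    expect_equal(mism, 0)
    expect_equal(sum(counts), 16^3) # exhaustive and exclusive
  }
  # the printed rule at the default thresholds
  cam1 <- array(0, c(1, 1, 1, 2))
  cam1[1, 1, 1, ] <- c(0.50, 0.10)
  expect_equal(as.integer(dual_threshold(cam1)[1, 1, 1]), 1L)
  cam1[1, 1, 1, ] <- c(0.20, 0.10)
  expect_equal(as.integer(dual_threshold(cam1)[1, 1, 1]), 0L)
  cam1[1, 1, 1, ] <- c(0.40, 0.10)
  expect_equal(as.integer(dual_threshold(cam1)[1, 1, 1]), -1L)
  expect_error(dual_threshold(cam1, 0.5, 0.4), "phi")
})

test_that("voxel affinities are cosine-based, symmetric, with unit self-affinity", {
  # identical vectors -> 1; orthogonal -> 0.5; anti-parallel -> 0
  f <- array(0, c(4, 1, 1, 2))
  f[1, 1, 1, ] <- c(1, 0)
  f[2, 1, 1, ] <- c(1, 0)
  f[3, 1, 1, ] <- c(0, 1)
  f[4, 1, 1, ] <- c(-1, 0)
  aff <- voxel_affinity(f, c(3, 0, 0))
  # offsets along axis 1: +1, +2, +3
  o1 <- which(apply(aff$offsets, 1, function(d) all(d == c(1, 0, 0))))
  o3 <- which(apply(aff$offsets, 1, function(d) all(d == c(3, 0, 0))))
  o2 <- which(apply(aff$offsets, 1, function(d) all(d == c(2, 0, 0))))
  expect_equal(aff$values[[o1]][1, 1, 1], 1)    # (1,2) identical
  expect_equal(aff$values[[o2]][1, 1, 1], 0.5)  # (1,3) orthogonal
  expect_equal(aff$values[[o3]][1, 1, 1], 0)    # (1,4) anti-parallel
  # symmetry on a random field: A(u, u+d) stored once covers both directions
  set.seed(5)
  ff <- array(rnorm(6 * 6 * 6 * 3), c(6, 6, 6, 3))
  a2 <- voxel_affinity(ff, c(1, 1, 1))
  for (o in seq_len(nrow(a2$offsets))) {
    d <- a2$offsets[o, ]
    A <- a2$values[[o]]
    idx <- which(!is.na(A), arr.ind = TRUE)
    for (r in sample(nrow(idx), 5)) {
      u <- idx[r, ]; v <- u + d
      cu <- ff[u[1], u[2], u[3], ]; cv <- ff[v[1], v[2], v[3], ]
      expect_equal(A[u[1], u[2], u[3]],
                   (sum(cu * cv) / sqrt(sum(cu^2) * sum(cv^2)) + 1) / 2,
                   tolerance = 1e-12)
    }
  }
  # zero-norm vectors fall back to 0.5
  fz <- array(1, c(3, 1, 1, 2)); fz[2, 1, 1, ] <- 0
  expect_message(az <- voxel_affinity(fz, c(1, 0, 0)), "zero-norm")
  expect_equal(az$values[[1]][1, 1, 1], 0.5)
})

test_that("affinity supervision pairs split by pseudo-label agreement", {
  # two-region half/half cube: brute-force pair enumeration oracle
  lab <- array(0L, c(8, 8, 4)); lab[5:8, , ] <- 1L
  ps <- structure(lab, class = "pseudo_label")
  wr <- c(1, 1, 1)
  tg <- derive_affinity_targets(ps, wr)
  # brute force over all ordered pairs within the window (counted once)
  npos <- 0; nneg <- 0
  offs <- cavitygraph:::.window_offsets(wr)
  for (o in seq_len(nrow(offs))) {
    d <- offs[o, ]
    for (i in 1:8) for (j in 1:8) for (k in 1:4) {
      ii <- i + d[1]; jj <- j + d[2]; kk <- k + d[3]
      if (ii < 1 || ii > 8 || jj < 1 || jj > 8 || kk < 1 || kk > 4) next
      if (lab[i, j, k] == lab[ii, jj, kk]) npos <- npos + 1 else nneg <- nneg + 1
    }
  }
  expect_equal(tg$n_pos, npos)
  expect_equal(tg$n_neg, nneg)

  # all-background labels: every pair positive, negative term skipped
  all_bg <- structure(array(0L, c(6, 6, 6)), class = "pseudo_label")
  tg_bg <- derive_affinity_targets(all_bg, wr)
  expect_equal(tg_bg$n_neg, 0)
  expect_gt(tg_bg$n_pos, 0)
  W0 <- lapply(tg_bg$status, function(s) array(0, dim(s)))
  expect_equal(focal_affinity_loss(W0, tg_bg), log(2)) # positive term only

  # all-IGNORE labels: rejected
  all_ig <- structure(array(-1L, c(6, 6, 6)), class = "pseudo_label")
  expect_error(derive_affinity_targets(all_ig, wr), "no reliable")
})

test_that("focal affinity loss matches softplus arithmetic and its gradients point the right way", {
  lab <- array(0L, c(4, 4, 4)); lab[1:2, , ] <- 1L
  ps <- structure(lab, class = "pseudo_label")
  tg <- derive_affinity_targets(ps, c(1, 1, 1))
  zero_W <- lapply(tg$status, function(s) array(0, dim(s)))
  expect_equal(focal_affinity_loss(zero_W, tg), 2 * log(2), tolerance = 1e-12)
  sat_W <- lapply(tg$status, function(s) array(0, dim(s)) + 20 * s)
  expect_lt(focal_affinity_loss(sat_W, tg), 1e-6)
  # three hand pairs: one positive at 1.2, negatives at -0.3 and 0.4
  hand <- (softplus <- function(x) log1p(exp(x)))(-1.2) / 1 +
    (softplus(-0.3) + softplus(0.4)) / 2
  st <- list(array(c(1L, -1L, -1L, 0L), c(4, 1, 1)))
  Wv <- list(array(c(1.2, -0.3, 0.4, 99), c(4, 1, 1)))
  tg_hand <- structure(list(offsets = matrix(c(1, 0, 0), 1), status = st,
                            n_pos = 1L, n_neg = 2L), class = "affinity_targets")
  expect_equal(focal_affinity_loss(Wv, tg_hand), hand, tolerance = 1e-12)
  # finite-difference monotonicity: dL/dW < 0 on positives, > 0 on negatives
  eps <- 1e-6
  bump <- function(i, delta) {
    W2 <- Wv; W2[[1]][i] <- W2[[1]][i] + delta
    focal_affinity_loss(W2, tg_hand)
  }
  base <- focal_affinity_loss(Wv, tg_hand)
  expect_lt(bump(1, eps), base)  # positive pair
  expect_gt(bump(2, eps), base)  # negative pair
})

test_that("pseudo-label export maps the IGNORE sentinel to 255", {
  lab <- structure(array(c(-1L, 0L, 1L, 2L), c(4, 1, 1)), class = "pseudo_label")
  p <- withr::local_tempfile(fileext = ".nii.gz")
  export_pseudo_label(lab, p)
  r <- read_nifti(p)
  expect_equal(as.integer(r), c(255L, 0L, 1L, 2L))
})
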