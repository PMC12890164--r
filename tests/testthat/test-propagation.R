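test_that("transition matrices are row-stochastic with the element-wise power", {
  Tm <- transition_matrix(matrix(1, 2, 2), eta = 1)
  expect_equal(as.matrix(Tm$values), matrix(0.5, 2, 2))
  T2 <- transition_matrix(matrix(c(2, 1, 1, 2), 2, 2), eta = 2)
  expect_equal(as.matrix(T2$values), matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2))
  set.seed(1)
  W <- matrix(runif(100), 10, 10)
  T3 <- transition_matrix(W, eta = 3)
  expect_true(all(abs(rowSums(as.matrix(T3$values)) - 1) < 1e-9))
  W0 <- W; W0[3, ] <- 0
  expect_error(transition_matrix(W0, 1), "row")
  expect_error(transition_matrix(W, eta = 0), "eta")
})

test_that("propagation is a convex combination matching a dense multiply", {
  set.seed(2)
  n <- 30
  W <- matrix(runif(n * n), n, n)
  Tm <- transition_matrix(W, 1)
  M <- matrix(runif(n * 2), n, 2)
  out <- propagate(Tm, M)
  # independent dense multiply
  Td <- (W^1) / rowSums(W^1)
  expect_equal(out, Td %*% M, tolerance = 1e-12)
  for (c in 1:2) {
    expect_true(all(out[, c] >= min(M[, c]) - 1e-12))
    expect_true(all(out[, c] <= max(M[, c]) + 1e-12))
  }
  # identity and uniform degenerate cases
  Ti <- transition_matrix(diag(n), 1)
  expect_equal(propagate(Ti, M), M)
  Tu <- transition_matrix(matrix(1, n, n), 1)
  expect_equal(propagate(Tu, M[, 1]), rep(mean(M[, 1]), n))
  expect_error(propagate(Tm, M[1:5, ]), "shape")
})

test_that("tilings cover every voxel with the documented stride arithmetic", {
  t1 <- make_tiling(c(8, 8, 8), c(8, 8, 8), 0)
  expect_equal(t1$R, 1)
  t2 <- make_tiling(c(16, 16, 16), c(8, 8, 8), 0.5)
  expect_equal(sort(unique(t2$starts[, 1])), c(1, 5, 9)) # starts {0,4,8} 0-based
  expect_equal(t2$R, 27)
  set.seed(3)
  for (rep in 1:5) {
    gs <- sample(10:30, 3, TRUE)
    bs <- pmin(gs, sample(4:12, 3, TRUE))
    tl <- make_tiling(gs, bs, runif(1, 0, 0.6))
    cov <- array(0L, gs)
    for (r in seq_len(tl$R)) {
      st <- tl$starts[r, ]
      cov[st[1]:(st[1] + tl$block_size[1] - 1),
          st[2]:(st[2] + tl$block_size[2] - 1),
          st[3]:(st[3] + tl$block_size[3] - 1)] <- 1L
    }
    expect_true(all(cov == 1L))
  }
  expect_error(make_tiling(c(8, 8, 8), c(4, 4, 4), 1), "overlap")
})

test_that("distance-weighted merging is idempotent, local, and centre-biased", {
  tl <- make_tiling(c(12, 8, 8), c(8, 8, 8), 0.5)
  C <- 1
  const <- lapply(seq_len(tl$R), function(r) array(0.3, c(tl$block_size, C)))
  merged <- merge_blocks(const, tl)
  expect_equal(as.numeric(merged), rep(0.3, 12 * 8 * 8))
  # two overlapping blocks valued 0 and 1: strictly between, nearer block wins
  tl2 <- make_tiling(c(12, 8, 8), c(8, 8, 8), 0.5)
  expect_equal(tl2$R, 2)
  outs <- list(array(0, c(8, 8, 8, 1)), array(1, c(8, 8, 8, 1)))
  mg <- merge_blocks(outs, tl2)
  overlap_vals <- mg[5:8, 4, 4, 1]
  expect_true(all(overlap_vals > 0 & overlap_vals < 1))
  expect_true(all(diff(overlap_vals) > 0)) # closer to block 2's centre -> higher
  # single-cover voxels keep the covering block's value
  expect_equal(mg[1, 4, 4, 1], 0)
  expect_equal(mg[12, 4, 4, 1], 1)
})

test_that("single-tile refinement equals the dense global random walk", {
  dm <- c(12, 12, 12)
  set.seed(4)
  feats <- array(rnorm(prod(dm) * 3), c(dm, 3))
  aff <- voxel_affinity(feats, c(2, 2, 2))
  cam <- random_cam(dm, C = 2, seed = 5)
  ref <- refine_cam(cam, aff, list(eta = 1, block_size = dm,
                                   overlap_fraction = 0))
  oracle <- dense_walk_oracle(aff, cam, eta = 1)
  expect_lt(max(abs(ref - oracle)), 1e-9)
  # identity affinity (diagonal only) leaves the CAM unchanged
  aff_id <- aff
  aff_id$values <- lapply(aff_id$values, function(A) { A[!is.na(A)] <- 0; A })
  ref_id <- refine_cam(cam, aff_id, list(eta = 1, block_size = dm,
                                         overlap_fraction = 0))
  expect_lt(max(abs(ref_id - cam)), 1e-12)
})

test_that("region-wise propagation on block-diagonal affinities equals global exactly", {
  dm <- c(16, 16, 16)
  set.seed(6)
  feats <- array(rnorm(prod(dm) * 2), c(dm, 2))
  aff <- voxel_affinity(feats, c(2, 2, 2))
  # zero all cross-block affinities (blocks of 8, overlap 0)
  for (o in seq_len(nrow(aff$offsets))) {
    A <- aff$values[[o]]
    idx <- which(!is.na(A))
    co <- arrayInd(idx, dm)
    nb <- sweep(co, 2, aff$offsets[o, ], "+")
    cross <- ((co[, 1] - 1) %/% 8 != (nb[, 1] - 1) %/% 8) |
      ((co[, 2] - 1) %/% 8 != (nb[, 2] - 1) %/% 8) |
      ((co[, 3] - 1) %/% 8 != (nb[, 3] - 1) %/% 8)
    A[idx[cross]] <- 0
    aff$values[[o]] <- A
  }
  cam <- random_cam(dm, C = 1, seed = 7)
  ref_blocks <- refine_cam(cam, aff, list(eta = 1, block_size = c(8, 8, 8),
                                          overlap_fraction = 0))
  ref_global <- refine_cam(cam, aff, list(eta = 1, block_size = dm,
                                          overlap_fraction = 0))
  expect_equal(as.numeric(ref_blocks), as.numeric(ref_global))
})

test_that("eta sharpens transitions: row entropy is non-increasing in eta", {
  set.seed(8)
  for (rep in 1:5) {
    W <- matrix(runif(64, 0.05, 1), 8, 8)
    ent <- vapply(c(0.5, 1, 2, 4), function(eta) {
      Tm <- as.matrix(transition_matrix(W, eta)$values)
      mean(-rowSums(Tm * log(Tm)))
    }, numeric(1))
    expect_true(all(diff(ent) <= 1e-10))
  }
})

test_that("the region-graph stage diffuses region means before the voxel walk", {
  ph <- small_phantom(seed = 15)
  part <- compute_superpixels(ph$volume, n_segments = 40, compactness = 0.1)
  cam <- corrupt_cam(ph$mask, cam_corruption(0.6, 1, 0.05, seed = 1), 2)
  gr <- build_region_graph(part, ph$volume, encoder_features(ph$volume), cam, k = 4)
  tg <- train_ganet(gr, list(hidden_dim = 8, n_layers = 2, steps = 30, seed = 1))
  fe <- array(2 * (ph$mask > 0) - 1, c(dim(ph$mask), 1))
  aff <- voxel_affinity(fe, c(1, 1, 1))
  ref <- refine_cam(cam, aff, list(eta = 1, block_size = c(16, 16, 16),
                                   overlap_fraction = 0.5,
                                   use_region_graph = TRUE,
                                   region_graph = tg$graph))
  expect_true(all(ref >= 0 & ref <= 1))
  expect_equal(dim(ref), dim(cam))
})
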