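test_that("smoothed segmentation CE behaves at its degenerate points", {
  # eps = 0, perfect one-hot predictions: loss ~ 0
  p <- matrix(1e-7, 4, 2); p[cbind(1:4, c(1, 2, 2, 1))] <- 1 - 1e-7
  expect_lt(seg_loss(p, c(0L, 1L, 1L, 0L), epsilon = 0), 1e-5)
  # uniform binary predictions: loss = ln 2 for any smoothing
  pu <- matrix(0.5, 6, 2)
  expect_equal(seg_loss(pu, c(0L, 1L, 0L, 1L, 0L, 1L), epsilon = 0.15), log(2))
  expect_equal(seg_loss(pu, c(0L, 1L, 0L, 1L, 0L, 1L), epsilon = 0), log(2))
  # IGNORE voxels are excluded from the support
  expect_equal(seg_loss(pu, c(0L, -1L, -1L, 1L, -1L, 1L), epsilon = 0.15), log(2))
  expect_error(seg_loss(pu, rep(-1L, 6)), "support")
})

test_that("EMA updates follow the closed form and the interval gating", {
  st <- ema_state(array(0, c(2, 2)), delta = 0.2, gamma = 1)
  st <- ema_update(st, array(1, c(2, 2)), 1)
  expect_equal(unique(as.numeric(st$y)), 0.2)
  st <- ema_update(st, array(1, c(2, 2)), 2)
  expect_equal(unique(as.numeric(st$y)), 0.36)
  # closed form over 50 updates at 1e-12
  y0 <- 0.7; cst <- 0.1; delta <- 0.2
  st2 <- ema_state(y0, delta = delta, gamma = 1)
  for (n in 1:50) {
    st2 <- ema_update(st2, cst, n)
    expect_equal(st2$y, cst + (1 - delta)^n * (y0 - cst), tolerance = 1e-12)
  }
  # gamma gating: off-interval iterations leave the state untouched
  st3 <- ema_state(0.5, delta = 0.5, gamma = 8)
  st3 <- ema_update(st3, 1, 3)
  expect_equal(st3$y, 0.5)
  expect_equal(st3$update_count, 0L)
  st3 <- ema_update(st3, 1, 8)
  expect_equal(st3$y, 0.75)
  # fixed point: f = y0 never moves
  st4 <- ema_state(0.3, delta = 0.2, gamma = 1)
  for (n in 1:5) st4 <- ema_update(st4, 0.3, n)
  expect_equal(st4$y, 0.3)
  # delta = 1 reproduces the raw prediction exactly
  st5 <- ema_state(0.9, delta = 1, gamma = 1)
  st5 <- ema_update(st5, 0.123, 1)
  expect_equal(st5$y, 0.123)
  expect_error(ema_state(0.5, delta = 0), "delta")
})

test_that("scribbles trace the pseudo-label contours sparsely", {
  # empty mask: empty scribble set, flagged
  empty <- structure(array(0L, c(8, 8, 8)), class = "pseudo_label")
  expect_message(sc0 <- extract_scribbles(empty), "no foreground")
  expect_length(sc0$omega, 0)
  # solid 9^3 cube: stride-1 foreground scribbles lie inside the surface shell
  lab <- array(0L, c(13, 13, 13))
  lab[3:11, 3:11, 3:11] <- 1L
  ps <- structure(lab, class = "pseudo_label")
  sc1 <- extract_scribbles(ps, stride = 1, band = 1)
  fg_idx <- which(sc1$labels == 1L)
  # shell enumeration oracle: cube surface voxels
  shell <- array(FALSE, c(13, 13, 13))
  shell[3:11, 3:11, 3:11] <- TRUE
  shell[4:10, 4:10, 4:10] <- FALSE
  expect_true(all(fg_idx %in% which(shell)))
  expect_lte(length(fg_idx), sum(shell))
  # background scribbles sit outside, adjacent to the cube
  bg_idx <- which(sc1$labels == 0L)
  expect_true(all(lab[bg_idx] == 0L))
  # stride-4 reduces the count roughly fourfold
  sc4 <- extract_scribbles(ps, stride = 4, band = 1)
  expect_lt(length(sc4$omega), length(sc1$omega) / 3)
  expect_gt(length(sc4$omega), length(sc1$omega) / 6)
  # scribbles never cross the pseudo-boundary
  expect_true(all(lab[which(sc1$labels == 1L)] == 1L))
})

test_that("partial cross-entropy only sees scribbled voxels", {
  lab <- array(0L, c(6, 6, 6)); lab[2:4, 2:4, 2:4] <- 1L
  ps <- structure(lab, class = "pseudo_label")
  sc <- extract_scribbles(ps, stride = 1, band = 1)
  p <- array(0.5, c(6, 6, 6))
  expect_equal(partial_ce(p, sc), log(2))
  # perfect predictions on the scribbles
  pgood <- array(0.5, c(6, 6, 6))
  pgood[sc$labels == 1L] <- 1 - 1e-9
  pgood[sc$labels == 0L] <- 1e-9
  expect_lt(partial_ce(pgood, sc), 1e-6)
  # perturbing unlabelled voxels changes nothing
  set.seed(1)
  pperturb <- pgood
  unl <- which(sc$labels == -1L)
  pperturb[unl] <- runif(length(unl))
  expect_equal(partial_ce(pperturb, sc), partial_ce(pgood, sc))
  empty <- structure(list(labels = array(-1L, c(2, 2, 2)), omega = integer(0),
                          sparsity = 0), class = "scribble_set")
  expect_error(partial_ce(p, empty), "empty")
})

test_that("total loss is the stated weighted combination and linear in each part", {
  comp <- c(cls = 1, struct = 1, smooth = 1, aff = 1, pce = 1, seg = 1)
  expect_equal(total_loss(comp), 3.8)
  expect_equal(total_loss(comp, weights = rep(0, 5)), 1) # L_cls alone
  # finite-difference slope in each component equals its weight
  w <- c(0.6, 0.5, 0.5, 0.7, 0.5)
  for (i in seq_along(comp)) {
    bump <- comp; bump[i] <- bump[i] + 1
    expect_equal(total_loss(bump, w) - total_loss(comp, w),
                 c(1, w)[i], tolerance = 1e-12)
  }
})

test_that("segmenter training reduces the loss and EMA damps prediction variance", {
  d <- withr::local_tempdir()
  m <- make_fixture_suite(6, d, seed = 2, shape = c(36, 36, 24),
                          cavity_radius_range = c(2.5, 4))
  vols <- lapply(m$cases, function(cs) read_nifti(cs$paths$volume))
  masks <- lapply(m$cases, function(cs) read_nifti(cs$paths$mask))
  pseudos <- lapply(masks, function(mk) {
    structure(array(as.integer(mk > 0), dim(mk)), class = "pseudo_label")
  })
  scribs <- lapply(pseudos, extract_scribbles, stride = 2, band = 1)
  seg <- suppressMessages(train_segmenter(vols, pseudos, scribs,
                                          list(steps = 60, seed = 0,
                                               truth = masks)))
  h <- seg$history
  expect_lte(utils::tail(h$loss_seg, 1), 0.6 * h$loss_seg[1]) # >= 40% decrease
  # EMA-ensembled fields vary less across space than the raw fields on
  # cases with structure
  rawv <- vapply(seg$raw_predictions, function(p) stats::var(as.numeric(p)),
                 numeric(1))
  emav <- vapply(seg$predictions, function(p) stats::var(as.numeric(p)),
                 numeric(1))
  expect_lt(mean(emav), mean(rawv) + 1e-12)
})
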