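# tiny hand-checkable graph: 4-node path 1-2-3-4
path4_graph <- function(seed = 2) {
  set.seed(seed)
  edges <- data.frame(u = c(1, 2, 3), v = c(2, 3, 4), kind = "adjacency",
                      a_init = c(0.4, 0.6, 0.5), w = c(0.9, 0.2, 0.7),
                      a_opt = NA_real_, stringsAsFactors = FALSE)
  structure(list(n_nodes = 4L, edges = edges,
                 node_features = matrix(rnorm(8), 4, 2)),
            class = "region_graph")
}

test_that("attention weights form a proper distribution over each neighbourhood", {
  pp <- make_planted_graph(0)
  params <- ganet_init(ncol(pp$graph$node_features), hidden_dim = 16,
                       n_layers = 4, seed = 1)
  fwd <- ganet_forward(pp$graph, params)
  de <- cavitygraph:::.directed_edges(pp$graph)
  for (l in 1:4) {
    alpha <- fwd$caches[[l]]$alpha
    sums <- rowsum(alpha, de$dst)
    expect_true(all(abs(sums - 1) < 1e-12))
  }
  # a = 0 gives uniform attention 1/|N(i)|
  p0 <- params
  p0$a <- lapply(p0$a, function(a) a * 0)
  fwd0 <- ganet_forward(pp$graph, p0)
  deg <- tabulate(de$dst, pp$graph$n_nodes)
  expect_equal(fwd0$caches[[1]]$alpha, 1 / deg[de$dst], tolerance = 1e-12)
  # singleton neighbourhood gets alpha = 1
  g1 <- path4_graph()
  g1$edges <- g1$edges[1, , drop = FALSE] # nodes 3,4 isolated -> error path
  expect_error(ganet_forward(structure(list(n_nodes = 4L, edges = g1$edges,
                                            node_features = g1$node_features),
                                       class = "region_graph"), params),
               "isolated|dimension")
})

test_that("a hand-parameterised layer matches independent scalar recomputation", {
  gr <- path4_graph(seed = 5)
  H <- matrix(c(0.3, -0.1, 0.5, 0.2, -0.4, 0.6, 0.1, 0.8), 4, 2, byrow = TRUE)
  W <- matrix(c(0.7, -0.2, 0.3, 0.5), 2, 2)
  a <- c(0.4, -0.6, 0.2, 0.1)
  out <- attention_layer_forward(gr, H, list(W = W, a = a))

  # independent scalar recomputation with explicit loops
  nbrs <- list(c(2L), c(1L, 3L), c(2L, 4L), c(3L))
  Z <- matrix(0, 4, 2)
  for (i in 1:4) for (q in 1:2) Z[i, q] <- sum(H[i, ] * W[, q])
  elu <- function(x) if (x > 0) x else exp(x) - 1
  expected <- matrix(0, 4, 2)
  for (i in 1:4) {
    sc <- sapply(nbrs[[i]], function(j) {
      sum(a * c(Z[i, ], Z[j, ]))
    })
    al <- exp(sc - max(sc)); al <- al / sum(al)
    s <- rep(0, 2)
    for (t in seq_along(nbrs[[i]])) s <- s + al[t] * Z[nbrs[[i]][t], ]
    expected[i, ] <- sapply(s, elu)
  }
  expect_lt(max(abs(out - expected)), 1e-10)
})

test_that("edge posteriors are symmetric, bounded, and degenerate correctly", {
  gr <- path4_graph(seed = 6)
  h <- matrix(rnorm(8), 4, 2)
  # U = 0 -> 0.5 everywhere
  expect_equal(edge_posterior(gr, h, rep(0, 4)), rep(0.5, 3))
  # saturation
  hbig <- matrix(10, 4, 2)
  expect_gt(min(edge_posterior(gr, hbig, rep(5, 4))), 1 - 1e-6)
  # symmetry: swapping node order of an edge leaves a_opt unchanged
  U <- rnorm(4)
  a1 <- edge_posterior(gr, h, U)
  gr_sw <- gr
  gr_sw$edges$u <- gr$edges$v; gr_sw$edges$v <- gr$edges$u
  expect_equal(edge_posterior(gr_sw, h, U), a1, tolerance = 1e-12)
  expect_error(edge_posterior(gr, h, rep(0, 6)), "dimension")
})

test_that("structural loss behaves as a soft-label cross-entropy", {
  expect_equal(structural_loss(0.5, 0.5), log(2), tolerance = 1e-12)
  expect_lt(structural_loss(1 - 1e-9, 1), 1e-6)
  # numerical minimiser at a_opt = w (grid of 1000 points)
  grid <- seq(1e-3, 1 - 1e-3, length.out = 1000)
  losses <- vapply(grid, function(a) structural_loss(a, 0.3), numeric(1))
  expect_equal(grid[which.min(losses)], 0.3, tolerance = 2e-3)
  # KL + entropy decomposition on random edges
  set.seed(8)
  w <- runif(50); a <- runif(50, 0.01, 0.99)
  kl <- sum(w * log(w / a) + (1 - w) * log((1 - w) / (1 - a)))
  ent <- -sum(w * log(w) + (1 - w) * log(1 - w))
  expect_equal(structural_loss(a, w), kl + ent, tolerance = 1e-9)
  expect_gte(structural_loss(a, w), ent)
  expect_message(structural_loss(c(0, 0.2), c(0.1, 0.2)), "clamping")
})

test_that("smoothness loss is a masked quadratic anchor", {
  expect_equal(smooth_loss(0.7, 0.5, 1), 0.02)
  expect_equal(smooth_loss(runif(5), runif(5), rep(0, 5)), 0)
  # three hand edges
  expect_equal(smooth_loss(c(0.2, 0.9, 0.5), c(0.1, 0.4, 0.5), c(1, 0.5, 1)),
               0.5 * (0.01 + 0.5 * 0.25 + 0))
  expect_error(smooth_loss(0.5, 0.5, 2), "omega")
})

test_that("analytic gradients agree with finite differences on a small graph", {
  gr <- path4_graph(seed = 3)
  params <- ganet_init(2, hidden_dim = 3, n_layers = 2, seed = 4)
  lam <- 0.5
  omega <- gr$edges$a_init
  lossfun <- function(p) {
    a <- pmin(pmax(ganet_forward(gr, p)$a_opt, 1e-7), 1 - 1e-7)
    structural_loss(a, gr$edges$w) + lam * smooth_loss(a, gr$edges$a_init, omega)
  }
  fwd <- ganet_forward(gr, params)
  a <- fwd$a_opt
  d_a <- (a - gr$edges$w) / (a * (1 - a)) + lam * omega * (a - gr$edges$a_init)
  g <- cavitygraph:::.ganet_backward(gr, params, fwd, d_a)
  g_an <- c(unlist(g$W), unlist(g$a), g$U)
  theta <- cavitygraph:::.gp_flatten(params)
  g_fd <- vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + 1e-6
    tm <- theta; tm[i] <- tm[i] - 1e-6
    (lossfun(cavitygraph:::.gp_unflatten(params, tp)) -
       lossfun(cavitygraph:::.gp_unflatten(params, tm))) / 2e-6
  }, numeric(1))
  expect_lt(max(abs(g_an - g_fd)), 1e-6)
})

test_that("training recovers planted communities and anchors under a strong prior", {
  pp <- make_planted_graph(0)
  tg <- train_ganet(pp$graph, list(hidden_dim = 16, n_layers = 4, steps = 200,
                                   seed = 0))
  a_opt <- tg$graph$edges$a_opt
  expect_gte(rank_auc(a_opt[pp$intra], a_opt[!pp$intra]), 0.9)
  # loss history decreases overall (window-5 smoothed)
  tot <- tg$history$loss_struct + 0.5 * tg$history$loss_smooth
  sm <- stats::filter(tot, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], sm[1])
  # lambda -> infinity pulls the posterior onto the initial affinity
  tg_inf <- train_ganet(pp$graph, list(hidden_dim = 16, n_layers = 4,
                                       steps = 200, seed = 0,
                                       lambda_smooth = 1e6))
  expect_lt(mean(abs(tg_inf$graph$edges$a_opt - pp$graph$edges$a_init)), 0.05)
  # determinism for a fixed seed
  tg2 <- train_ganet(pp$graph, list(hidden_dim = 16, n_layers = 4, steps = 20,
                                    seed = 0))
  tg3 <- train_ganet(pp$graph, list(hidden_dim = 16, n_layers = 4, steps = 20,
                                    seed = 0))
  expect_identical(tg2$graph$edges$a_opt, tg3$graph$edges$a_opt)
})

test_that("deeper message passing contracts node-feature variance (over-smoothing probe)", {
  pp <- make_planted_graph(0)
  params <- ganet_init(ncol(pp$graph$node_features), 16, 4, seed = 1)
  fwd <- ganet_forward(pp$graph, params)
  vs <- vapply(fwd$caches, function(cc) mean(apply(cc$h_out, 2, stats::var)),
               numeric(1))
  expect_true(all(diff(vs) <= 1e-12))
})
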