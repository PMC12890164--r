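# Shared fixtures, built in code.

# Assortative planted-partition region graph: two 30-node communities,
# stochastic-block edges (p_in = 0.25, p_out = 0.05), Gaussian node features
# around +/- mu hypercube community means. Soft targets w = 0.9 within /
# 0.1 between communities.
make_planted_graph <- function(seed = 0, n = 60, p_in = 0.25, p_out = 0.05,
                               d_in = 8, mu = 0.5, noise_sd = 0.5) {
  set.seed(seed)
  comm <- rep(1:2, each = n / 2)
  M <- rbind(rep(mu, d_in), rep(-mu, d_in))
  X <- M[comm, ] + matrix(rnorm(n * d_in, sd = noise_sd), n, d_in)
  pairs <- t(combn(n, 2))
  intra <- comm[pairs[, 1]] == comm[pairs[, 2]]
  keep <- runif(nrow(pairs)) < ifelse(intra, p_in, p_out)
  pairs <- pairs[keep, , drop = FALSE]; intra <- intra[keep]
  deg <- tabulate(c(pairs[, 1], pairs[, 2]), n)
  for (v in which(deg == 0)) {
    u <- which(comm == comm[v] & seq_len(n) != v)[1]
    pairs <- rbind(pairs, c(min(u, v), max(u, v))); intra <- c(intra, TRUE)
  }
  edges <- data.frame(u = pairs[, 1], v = pairs[, 2], kind = "adjacency",
                      a_init = 0.5, w = ifelse(intra, 0.9, 0.1),
                      a_opt = NA_real_, stringsAsFactors = FALSE)
  list(graph = structure(list(n_nodes = n, edges = edges, node_features = X),
                         class = "region_graph"),
       intra = intra, community = comm)
}

# rank-based (Mann-Whitney) AUC
rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# random multi-channel CAM
random_cam <- function(dims, C = 2, seed = 1) {
  set.seed(seed)
  array(runif(prod(dims) * C), c(dims, C))
}

# Independent dense random-walk oracle over a windowed sparse affinity:
# densify W (diagonal 1), row-normalise W^eta, multiply. Uses only its own
# index arithmetic, not the package's block machinery.
dense_walk_oracle <- function(affinity, cam, eta = 1) {
  dm <- affinity$dim
  n <- prod(dm)
  coords <- arrayInd(seq_len(n), dm)
  lin <- function(ijk) (ijk[, 3] - 1) * dm[1] * dm[2] + (ijk[, 2] - 1) * dm[1] + ijk[, 1]
  W <- matrix(0, n, n)
  for (o in seq_len(nrow(affinity$offsets))) {
    A <- affinity$values[[o]]
    idx <- which(!is.na(A))
    nb <- sweep(coords[idx, , drop = FALSE], 2, affinity$offsets[o, ], "+")
    nidx <- lin(nb)
    W[cbind(idx, nidx)] <- A[idx]
    W[cbind(nidx, idx)] <- A[idx]
  }
  diag(W) <- 1
  Wp <- W^eta
  Tm <- Wp / rowSums(Wp)
  C <- dim(cam)[4]
  out <- array(0, c(dm, C))
  for (c in seq_len(C)) out[, , , c] <- array(Tm %*% as.numeric(cam[, , , c]), dm)
  out
}

# small deterministic phantom for module tests
small_phantom <- function(seed = 7, n_cavities = 2, shape = c(32, 32, 24)) {
  generate_phantom(phantom_config(shape = shape, n_cavities = n_cavities,
                                  cavity_radius_range = c(3, 5), seed = seed))
}
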