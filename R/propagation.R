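# Random-walk refinement of CAMs.
#
# A row-stochastic transition matrix T = D^-1 W^eta (element-wise power)
# built from affinities diffuses activation scores: M_aff = T vec(M).
# Propagation runs region-wise in overlapping 3D blocks; block outputs are
# merged with distance weights that taper linearly with distance to the
# block centre. Optionally a region-graph diffusion using the GA-Net edge
# posteriors precedes the voxel-level walk.

#' Row-stochastic transition matrix from an affinity matrix
#'
#' `T = D^-1 W^eta` with the power applied element-wise;
#' `D_ii = sum_j W_ij^eta`.
#'
#' @param W square non-negative affinity matrix (base or `Matrix` sparse).
#' @param eta propagation strength (> 0); larger values sharpen the walk.
#' @return object of class `transition_matrix`: list(`values`
#'   (row-stochastic), `eta`).
#' @export
transition_matrix <- function(W, eta = 1) {
  assert_that(eta > 0, "transition_matrix: eta must be > 0")
  if (inherits(W, "sparseMatrix")) {
    Wp <- W
    Wp@x <- Wp@x^eta
    rs <- Matrix::rowSums(Wp)
  } else {
    assert_that(all(W >= 0), "transition_matrix: W entries must be >= 0")
    Wp <- W^eta
    rs <- rowSums(Wp)
  }
  bad <- which(rs <= 0)
  if (length(bad)) {
    stop("transition_matrix: zero row(s) after exponentiation: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  Tm <- if (inherits(Wp, "sparseMatrix")) {
    Matrix::Diagonal(x = 1 / rs) %*% Wp
  } else {
    Wp / rs
  }
  structure(list(values = Tm, eta = eta), class = "transition_matrix")
}

#' Propagate vectorised activations through a transition matrix
#'
#' `M_aff = T vec(M)`; every output value is a convex combination of input
#' values, so it stays within the input range per class.
#'
#' @param Tm a `transition_matrix`.
#' @param M numeric vector or n x C matrix of activations.
#' @return refined activations with the shape of `M`.
#' @export
propagate <- function(Tm, M) {
  stopifnot(inherits(Tm, "transition_matrix"))
  vec <- is.null(dim(M))
  Mm <- if (vec) matrix(M, ncol = 1) else M
  assert_that(nrow(Mm) == nrow(Tm$values), "propagate: shape mismatch")
  out <- as.matrix(Tm$values %*% Mm)
  if (vec) as.numeric(out) else out
}

#' Overlapping block tiling of a 3D grid
#'
#' Blocks are placed on a regular stride `block_size * (1 -
#' overlap_fraction)`; a final block per axis is snapped to the boundary so
#' that every voxel is covered.
#'
#' @param grid_shape integer triple.
#' @param block_size integer triple, `<= grid_shape` per axis.
#' @param overlap_fraction in `[0, 1)`.
#' @return object of class `region_tiling`: list(`starts` (R x 3),
#'   `block_size`, `centers` (R x 3), `R`, `grid_shape`,
#'   `overlap_fraction`).
#' @export
make_tiling <- function(grid_shape, block_size = c(32, 32, 32),
                        overlap_fraction = 0.5) {
  assert_that(overlap_fraction >= 0 && overlap_fraction < 1,
              "make_tiling: overlap_fraction must lie in [0, 1)")
  block_size <- pmin(as.integer(block_size), as.integer(grid_shape))
  assert_that(all(block_size <= grid_shape),
              "make_tiling: block larger than grid")
  axes <- lapply(1:3, function(ax) {
    n <- grid_shape[ax]; bs <- block_size[ax]
    stride <- max(1L, as.integer(round(bs * (1 - overlap_fraction))))
    st <- seq(1L, max(1L, n - bs + 1L), by = stride)
    if (st[length(st)] != n - bs + 1L) st <- c(st, n - bs + 1L)
    unique(st)
  })
  starts <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]]))
  colnames(starts) <- NULL
  centers <- sweep(starts, 2, (block_size - 1) / 2, "+")
  structure(list(starts = starts, block_size = block_size, centers = centers,
                 R = nrow(starts), grid_shape = as.integer(grid_shape),
                 overlap_fraction = overlap_fraction),
            class = "region_tiling")
}

#' Distance-weighted merging of overlapping block outputs
#'
#' Per voxel, a weighted mean over covering blocks with weight
#' `w_r = max(0, 1 - ||x - c_r|| / r_block)` (`r_block` = half block
#' diagonal, so in-block weights are strictly positive), normalised to sum
#' to one.
#'
#' @param block_outputs list of 4D arrays `[block_size, C]`, one per block.
#' @param tiling a `region_tiling`.
#' @return merged 4D array `[grid_shape, C]`.
#' @export
merge_blocks <- function(block_outputs, tiling) {
  assert_that(length(block_outputs) == tiling$R,
              "merge_blocks: need one output per block")
  bs <- tiling$block_size
  C <- dim(block_outputs[[1]])[4]
  r_block <- sqrt(sum(bs^2)) / 2
  acc <- array(0, c(tiling$grid_shape, C))
  wsum <- array(0, tiling$grid_shape)
  # in-block voxel offsets from the block origin
  rel <- lapply(1:3, function(ax) seq_len(bs[ax]) - 1)
  for (r in seq_len(tiling$R)) {
    st <- tiling$starts[r, ]
    ix <- lapply(1:3, function(ax) st[ax] + rel[[ax]])
    d2 <- outer(outer((ix[[1]] - tiling$centers[r, 1])^2,
                      (ix[[2]] - tiling$centers[r, 2])^2, `+`),
                (ix[[3]] - tiling$centers[r, 3])^2, `+`)
    w <- pmax(0, 1 - sqrt(d2) / r_block)
    wsum[ix[[1]], ix[[2]], ix[[3]]] <- wsum[ix[[1]], ix[[2]], ix[[3]]] + w
    for (c in seq_len(C)) {
      acc[ix[[1]], ix[[2]], ix[[3]], c] <-
        acc[ix[[1]], ix[[2]], ix[[3]], c] + w * block_outputs[[r]][, , , c]
    }
  }
  assert_that(all(wsum > 0), "merge_blocks: voxel with zero total weight")
  for (c in seq_len(C)) acc[, , , c] <- acc[, , , c] / wsum
  acc
}

# sparse affinity matrix restricted to one block: voxels in the block are
# rows/cols; entries come from the windowed offset arrays; diagonal = 1.
.block_affinity_matrix <- function(affinity, start, block_size) {
  dm <- affinity$dim
  bs <- block_size
  nb <- prod(bs)
  # linear voxel index within the block for global coordinates
  in_block <- function(ijk) {
    r <- sweep(ijk, 2, start)
    ok <- r[, 1] >= 0 & r[, 1] < bs[1] & r[, 2] >= 0 & r[, 2] < bs[2] &
      r[, 3] >= 0 & r[, 3] < bs[3]
    list(ok = ok, idx = r[, 1] + r[, 2] * bs[1] + r[, 3] * bs[1] * bs[2] + 1)
  }
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  bi <- seq_len(bs[1]) + start[1] - 1
  bj <- seq_len(bs[2]) + start[2] - 1
  bk <- seq_len(bs[3]) + start[3] - 1
  coords <- as.matrix(expand.grid(bi, bj, bk))
  colnames(coords) <- NULL
  gidx <- vox_index(coords, dm)
  lidx <- seq_len(nb)
  for (o in seq_len(nrow(affinity$offsets))) {
    d <- affinity$offsets[o, ]
    nb_coords <- sweep(coords, 2, d, "+")
    tb <- in_block(nb_coords)
    ok <- tb$ok & nb_coords[, 1] >= 1 & nb_coords[, 1] <= dm[1] &
      nb_coords[, 2] >= 1 & nb_coords[, 2] <= dm[2] &
      nb_coords[, 3] >= 1 & nb_coords[, 3] <= dm[3]
    if (!any(ok)) next
    vals <- affinity$values[[o]][gidx[ok]]
    good <- !is.na(vals)
    if (!any(good)) next
    src <- lidx[ok][good]
    tgt <- tb$idx[ok][good]
    v <- vals[good]
    ii <- c(ii, src, tgt); jj <- c(jj, tgt, src); xx <- c(xx, v, v)
  }
  Matrix::sparseMatrix(i = c(ii, seq_len(nb)), j = c(jj, seq_len(nb)),
                       x = c(xx, rep(1, nb)), dims = c(nb, nb))
}

#' Refine a CAM by random-walk propagation
#'
#' Stage A (optional, `use_region_graph = TRUE`): diffuse region-mean CAM
#' values over the superpixel graph using a transition matrix built from
#' the trained edge posteriors, then broadcast back to voxels. Stage B:
#' region-wise voxel propagation — tile the grid into overlapping blocks,
#' build each block's transition matrix from the windowed voxel affinities,
#' propagate, and merge with distance weights.
#'
#' @param cam 4D CAM array `[dims, C]`.
#' @param affinity a `sparse_affinity` on the same grid (probability scale).
#' @param config list: `eta` (1), `block_size` (c(32, 32, 32)),
#'   `overlap_fraction` (0.5), `n_iterations` (1), `use_region_graph`
#'   (FALSE), `region_graph` (a trained `region_graph` when stage A is on).
#' @return refined 4D CAM array in `[0, 1]`.
#' @export
refine_cam <- function(cam, affinity, config = list()) {
  cfg <- utils::modifyList(list(eta = 1, block_size = c(32, 32, 32),
                                overlap_fraction = 0.5, n_iterations = 1,
                                use_region_graph = FALSE,
                                region_graph = NULL),
                           config)
  dm <- dim(cam)[1:3]
  C <- dim(cam)[4]
  M <- array(as.numeric(cam), c(dm, C))

  if (isTRUE(cfg$use_region_graph)) {
    g <- cfg$region_graph
    assert_that(!is.null(g) && !any(is.na(g$edges$a_opt)),
                "refine_cam: stage A needs a region graph with trained a_opt")
    n <- g$n_nodes
    Wg <- matrix(0, n, n)
    Wg[cbind(g$edges$u, g$edges$v)] <- g$edges$a_opt
    Wg[cbind(g$edges$v, g$edges$u)] <- g$edges$a_opt
    diag(Wg) <- 1
    Tg <- transition_matrix(Wg, cfg$eta)
    part <- g$partition
    pm <- region_cam_means(M, part)
    ref <- propagate(Tg, pm)
    lab <- as.vector(part$labels)
    for (c in seq_len(C)) M[, , , c] <- array(ref[lab, c], dm)
  }

  tiling <- make_tiling(dm, cfg$block_size, cfg$overlap_fraction)
  for (iter in seq_len(cfg$n_iterations)) {
    outs <- vector("list", tiling$R)
    for (r in seq_len(tiling$R)) {
      st <- tiling$starts[r, ]
      bs <- tiling$block_size
      ix <- lapply(1:3, function(ax) st[ax]:(st[ax] + bs[ax] - 1L))
      Wb <- .block_affinity_matrix(affinity, st, bs)
      Tb <- transition_matrix(Wb, cfg$eta)
      sub <- M[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE]
      vecM <- matrix(sub, ncol = C)
      res <- propagate(Tb, vecM)
      outs[[r]] <- array(res, c(bs, C))
    }
    M <- merge_blocks(outs, tiling)
  }
  if (any(M < -1e-6 | M > 1 + 1e-6)) {
    stop("refine_cam: propagated values escape [0, 1]; transition matrix not stochastic",
         call. = FALSE)
  }
  M <- clamp(M, 0, 1)
  attr(M, "spacing") <- attr(cam, "spacing") %||% c(1, 1, 1)
  class(M) <- "cam_volume"
  M
}
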