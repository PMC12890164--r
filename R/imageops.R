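# Low-level 3D array operations: shifts, separable Gaussian smoothing,
# 6-connected morphology, connected components, distance transforms.
# These back the phantom generator, superpixels, affinities and metrics.

#' Shift a 3D array by an integer offset
#'
#' Returns an array `out` with `out[i,j,k] = a[i+d1, j+d2, k+d3]` where the
#' source index is in range, and `fill` elsewhere.
#'
#' @param a 3D array.
#' @param d integer offset triple.
#' @param fill value used outside the source domain.
#' @return array of the same dimension as `a`.
#' @keywords internal
shift3 <- function(a, d, fill = NA) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- lapply(1:3, function(ax) {
    i <- seq_len(dm[ax]) + d[ax]
    i[i >= 1 & i <= dm[ax]]
  })
  dst <- lapply(1:3, function(ax) src[[ax]] - d[ax])
  if (any(vapply(src, length, 1L) == 0)) return(out)
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Apply a 1D kernel along one axis with replicate padding.
#' @keywords internal
convolve_axis <- function(a, kernel, axis) {
  dm <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  n <- dim(ap)[1]
  m <- prod(dim(ap)[-1])
  mat <- matrix(ap, nrow = n, ncol = m)
  r <- (length(kernel) - 1L) %/% 2L
  pad <- rbind(
    mat[rep(1L, r), , drop = FALSE],
    mat,
    mat[rep(n, r), , drop = FALSE]
  )
  out <- matrix(0, n, m)
  for (t in seq_along(kernel)) {
    out <- out + kernel[t] * pad[t:(t + n - 1L), , drop = FALSE]
  }
  res <- array(out, dim(ap))
  aperm(res, order(perm))
}

#' Separable 3D Gaussian smoothing
#'
#' @param a 3D array.
#' @param sigma standard deviation in voxels; 0 returns `a` unchanged.
#' @return smoothed array.
#' @keywords internal
gaussian_blur3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  for (ax in 1:3) a <- convolve_axis(a, k, ax)
  a
}

# 6-connectivity offsets (voxel faces)
.OFFSETS6 <- rbind(
  c(1, 0, 0), c(-1, 0, 0),
  c(0, 1, 0), c(0, -1, 0),
  c(0, 0, 1), c(0, 0, -1)
)

#' @keywords internal
erode6 <- function(mask) {
  out <- mask
  for (r in seq_len(nrow(.OFFSETS6))) {
    out <- out & shift3(mask, .OFFSETS6[r, ], fill = FALSE)
  }
  out
}

#' @keywords internal
dilate6 <- function(mask) {
  out <- mask
  for (r in seq_len(nrow(.OFFSETS6))) {
    out <- out | shift3(mask, .OFFSETS6[r, ], fill = FALSE)
  }
  out
}

#' Label 6-connected components of a binary mask
#'
#' @param mask logical 3D array.
#' @return integer array; 0 outside the mask, components numbered from 1.
#' @keywords internal
components6 <- function(mask) {
  dm <- dim(mask)
  idx <- which(mask)
  out <- array(0L, dm)
  if (length(idx) == 0) return(out)
  # vertex ids: position within idx
  vid <- array(0L, dm)
  vid[idx] <- seq_along(idx)
  edges <- NULL
  for (ax in 1:3) {
    d <- c(0L, 0L, 0L); d[ax] <- 1L
    nb <- shift3(vid, d, fill = 0L)
    both <- which(mask & nb > 0L)
    if (length(both)) edges <- rbind(edges, cbind(vid[both], nb[both]))
  }
  if (is.null(edges) || nrow(edges) == 0) {
    out[idx] <- seq_along(idx)
    return(out)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  out[idx] <- as.integer(comp)
  out
}

# 1D squared distance transform (Felzenszwalb & Huttenlocher lower envelope).
# f: vector of squared distances (may contain Inf); step: grid spacing.
#' @keywords internal
dt1d <- function(f, step) {
  n <- length(f)
  if (all(is.infinite(f))) return(f)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  s2 <- step * step
  for (q in 2:n) {
    if (is.infinite(f[q])) next
    repeat {
      p <- v[k]
      if (is.infinite(f[p])) { # only possible for the very first site
        k <- k - 1L
        if (k == 0L) break
        next
      }
      s <- ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2 * s2 * (q - p))
      if (s <= z[k]) {
        k <- k - 1L
        if (k == 0L) break
      } else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- if (k == 1L) -Inf else s
    z[k + 1L] <- Inf
  }
  out <- numeric(n)
  j <- 1L
  for (q in 1:n) {
    while (z[j + 1L] < q) j <- j + 1L
    p <- v[j]
    out[q] <- f[p] + s2 * (q - p)^2
  }
  out
}

#' Exact Euclidean distance transform of a 3D site mask
#'
#' Squared distances are computed by three separable 1D passes; anisotropic
#' voxel spacing is honoured.
#'
#' @param sites logical 3D array of source voxels.
#' @param spacing mm triple.
#' @return 3D array of Euclidean distances in mm (`Inf` if no site exists).
#' @keywords internal
distance_transform <- function(sites, spacing = c(1, 1, 1)) {
  dm <- dim(sites)
  f <- array(ifelse(sites, 0, Inf), dm)
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    fp <- aperm(f, perm)
    n <- dim(fp)[1]
    mat <- matrix(fp, nrow = n)
    for (col in seq_len(ncol(mat))) {
      if (any(is.finite(mat[, col]))) mat[, col] <- dt1d(mat[, col], spacing[ax])
    }
    f <- aperm(array(mat, dim(fp)), order(perm))
  }
  sqrt(f)
}
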