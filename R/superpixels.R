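# 3D SLIC superpixels.
#
# Simple Linear Iterative Clustering adapted to 3D scalar volumes: cluster
# centres initialised on a regular grid with spacing S, iterative local
# assignment under the combined intensity/space distance
#   D^2 = (v - c_int)^2 + (m / S)^2 * ||x - c_pos||^2
# (m = compactness), centre update, and a final connectivity enforcement
# step that relabels stray fragments into an adjacent region.

#' Partition a volume into superpixels (3D SLIC)
#'
#' @param volume 3D array normalised to `[0, 1]`.
#' @param n_segments requested number of superpixels (>= 2).
#' @param compactness trade-off between intensity similarity and spatial
#'   regularity; larger values give more regular regions.
#' @param max_iter assignment/update sweeps.
#' @return object of class `superpixel_partition`: list(`labels` (3D integer
#'   array, ids 1..n_regions), `n_regions`, `region_sizes`,
#'   `region_centroids` (n x 3, voxel units)).
#' @export
compute_superpixels <- function(volume, n_segments = 200, compactness = 0.1,
                                max_iter = 10) {
  assert_that(n_segments >= 2, "compute_superpixels: n_segments must be >= 2")
  dm <- dim(volume)
  nvox <- prod(dm)
  v <- array(as.numeric(volume), dm)
  S <- max(2, (nvox / n_segments)^(1 / 3))

  # grid-initialised centres (position + intensity); axis counts grown until
  # at least n_segments centres exist
  counts <- pmax(1L, floor(dm / S))
  while (prod(counts) < n_segments) {
    ax <- which.max(dm / counts)
    counts[ax] <- counts[ax] + 1L
  }
  gpos <- lapply(1:3, function(ax) {
    n <- counts[ax]
    (seq_len(n) - 0.5) * dm[ax] / n + 0.5
  })
  ctr <- as.matrix(expand.grid(gpos[[1]], gpos[[2]], gpos[[3]]))
  colnames(ctr) <- NULL
  nc <- nrow(ctr)
  cint <- v[cbind(pmin(dm[1], round(ctr[, 1])),
                  pmin(dm[2], round(ctr[, 2])),
                  pmin(dm[3], round(ctr[, 3])))]

  ratio2 <- (compactness / S)^2
  labels <- array(0L, dm)
  for (it in seq_len(max_iter)) {
    best <- array(Inf, dm)
    labels <- array(0L, dm)
    for (c in seq_len(nc)) {
      w <- lapply(1:3, function(ax) {
        max(1L, floor(ctr[c, ax] - S)):min(dm[ax], ceiling(ctr[c, ax] + S))
      })
      sub <- v[w[[1]], w[[2]], w[[3]], drop = FALSE]
      d2s <- outer(outer((w[[1]] - ctr[c, 1])^2, (w[[2]] - ctr[c, 2])^2, `+`),
                   (w[[3]] - ctr[c, 3])^2, `+`)
      D <- (sub - cint[c])^2 + ratio2 * d2s
      cur <- best[w[[1]], w[[2]], w[[3]], drop = FALSE]
      upd <- D < cur
      cur[upd] <- D[upd]
      best[w[[1]], w[[2]], w[[3]]] <- cur
      lab <- labels[w[[1]], w[[2]], w[[3]], drop = FALSE]
      lab[upd] <- c
      labels[w[[1]], w[[2]], w[[3]]] <- lab
    }
    # any voxel outside every centre window: assign to nearest centre
    un <- which(labels == 0L)
    if (length(un)) {
      ijk <- vox_coords(un, dm)
      for (q in seq_along(un)) {
        d2 <- rowSums(sweep(ctr, 2, ijk[q, ])^2)
        labels[un[q]] <- which.min(d2)
      }
    }
    # centre update
    lab_vec <- as.vector(labels)
    sums <- rowsum(cbind(vox_coords(seq_len(nvox), dm), as.numeric(v)), lab_vec)
    present <- as.integer(rownames(sums))
    cnt <- tabulate(lab_vec, nbins = nc)
    ctr[present, ] <- sums[, 1:3] / cnt[present]
    cint[present] <- sums[, 4] / cnt[present]
  }

  labels <- .enforce_connectivity(labels, v)
  n_regions <- max(labels)
  sizes <- tabulate(labels, nbins = n_regions)
  cents <- rowsum(vox_coords(seq_len(nvox), dm), as.vector(labels)) / sizes
  structure(list(labels = labels, n_regions = n_regions,
                 region_sizes = sizes, region_centroids = cents),
            class = "superpixel_partition")
}

# Relabel connected components; fragments that are not the largest component
# of their SLIC label are merged into the dominant adjacent component.
.enforce_connectivity <- function(labels, v) {
  dm <- dim(labels)
  # components of the "same label" adjacency graph
  comp <- .label_components(labels)
  ncomp <- max(comp)
  sizes <- tabulate(comp, nbins = ncomp)
  # main component per original label = largest
  main <- rep(FALSE, ncomp)
  for (l in sort(unique(as.vector(labels)))) {
    cs <- unique(comp[labels == l])
    main[cs[which.max(sizes[cs])]] <- TRUE
  }
  # adjacency between components (6-connectivity)
  repeat {
    orphan <- which(!main)
    if (!length(orphan)) break
    merged_any <- FALSE
    for (ax in 1:3) {
      d <- c(0L, 0L, 0L); d[ax] <- 1L
      nb <- shift3(comp, d, fill = 0L)
      touch <- which(comp != nb & nb > 0L)
      if (!length(touch)) next
      pairs <- unique(cbind(comp[touch], nb[touch]))
      pairs <- rbind(pairs, pairs[, 2:1, drop = FALSE])
      for (o in orphan) {
        nbrs <- pairs[pairs[, 1] == o, 2]
        nbrs <- nbrs[main[nbrs]]
        if (length(nbrs)) {
          tgt <- nbrs[which.max(sizes[nbrs])]
          comp[comp == o] <- tgt
          sizes[tgt] <- sizes[tgt] + sizes[o]
          main[o] <- TRUE # processed
          merged_any <- TRUE
        }
      }
      if (all(main)) break
    }
    if (!merged_any) { # isolated orphans: promote them to regions
      main[orphan] <- TRUE
    }
  }
  array(as.integer(factor(as.vector(comp))), dm)
}

# connected components where adjacency requires equal label values
.label_components <- function(labels) {
  dm <- dim(labels)
  nvox <- prod(dm)
  edges <- NULL
  for (ax in 1:3) {
    d <- c(0L, 0L, 0L); d[ax] <- 1L
    nb <- shift3(labels, d, fill = -1L)
    same <- which(labels == nb)
    if (length(same)) {
      nb_idx <- same + c(1L, dm[1], dm[1] * dm[2])[ax]
      edges <- rbind(edges, cbind(same, nb_idx))
    }
  }
  if (is.null(edges)) return(array(seq_len(nvox), dm))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nvox - igraph::vcount(g)))
  array(as.integer(igraph::components(g)$membership), dm)
}
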