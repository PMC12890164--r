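# Region graph construction.
#
# Nodes are superpixels; edges are (a) face-adjacency (6-connectivity)
# pairs and (b) kNN long-range edges in appearance feature space, so that
# spatially separated but semantically similar regions (e.g. the two rims
# of a broken cavity wall) exchange messages. Node features concatenate
# [mean encoder feature, intensity statistics, normalised centroid,
# initial-affinity summary]. Initial edge affinities use the cosine
# Affinity Converter form mapped to [0, 1], and soft co-membership targets
# come from the soft Dice overlap of region-mean CAM vectors.

# cosine mapped to [0,1]; rows of X and Y are paired vectors
.cosine01 <- function(X, Y) {
  num <- rowSums(X * Y)
  den <- sqrt(rowSums(X^2)) * sqrt(rowSums(Y^2))
  cosv <- ifelse(den > 1e-12, num / den, 0)
  (clamp(cosv, -1, 1) + 1) / 2
}

#' Mean CAM class vector per region
#'
#' @param cam `cam_volume` (4D array) or 4D array.
#' @param partition a `superpixel_partition`.
#' @return n_regions x C matrix of mean per-class activations.
#' @export
region_cam_means <- function(cam, partition) {
  dm4 <- dim(cam)
  C <- dm4[4]
  lab <- as.vector(partition$labels)
  out <- matrix(0, partition$n_regions, C)
  for (c in seq_len(C)) {
    ch <- as.vector(cam[, , , c])
    out[, c] <- rowsum(ch, lab) / partition$region_sizes
  }
  out
}

#' Soft target affinity between two regions (soft Dice of CAM vectors)
#'
#' `w = 2 <p1, p2> / (||p1||_1 + ||p2||_1 + eps)` where `p_i` is region i's
#' mean CAM class vector. Symmetric; in `[0, 1)`.
#'
#' @param cam 4D CAM array.
#' @param partition a `superpixel_partition`.
#' @param edge integer pair of region ids.
#' @param epsilon stabiliser (> 0).
#' @return scalar soft affinity.
#' @export
soft_target_affinity <- function(cam, partition, edge, epsilon = 1e-6) {
  assert_that(epsilon > 0, "soft_target_affinity: epsilon must be > 0")
  assert_that(all(edge >= 1 & edge <= partition$n_regions),
              "soft_target_affinity: region absent from partition")
  p <- region_cam_means(cam, partition)
  .soft_dice_pair(p[edge[1], , drop = FALSE], p[edge[2], , drop = FALSE], epsilon)
}

# vectorised soft Dice for paired row matrices
.soft_dice_pair <- function(P1, P2, epsilon) {
  as.numeric(2 * rowSums(P1 * P2) / (rowSums(abs(P1)) + rowSums(abs(P2)) + epsilon))
}

#' Build the superpixel region graph
#'
#' @param partition a `superpixel_partition`.
#' @param volume 3D intensity array on the same grid.
#' @param encoder_features 4D per-voxel feature field (same grid), e.g. from
#'   [encoder_features()].
#' @param cam 4D CAM array (same grid) used for the soft targets.
#' @param k number of kNN long-range edges per node (default 10).
#' @param epsilon stabiliser for the soft Dice targets.
#' @return object of class `region_graph`: list(`n_nodes`, `edges`
#'   (data.frame u, v, kind, a_init, w, a_opt), `node_features` (matrix),
#'   `partition`).
#' @export
build_region_graph <- function(partition, volume, encoder_features, cam,
                               k = 10, epsilon = 1e-6) {
  n <- partition$n_regions
  assert_that(n >= 2, "build_region_graph: degenerate single-region partition")
  assert_that(k < n, "build_region_graph: k must be < number of nodes")
  dm <- dim(partition$labels)
  assert_that(all(dim(volume) == dm) && all(dim(encoder_features)[1:3] == dm) &&
                all(dim(cam)[1:3] == dm),
              "build_region_graph: inputs must share the spatial grid")
  lab <- as.vector(partition$labels)
  sizes <- partition$region_sizes

  # f_Enc: region-mean encoder features
  FE <- dim(encoder_features)[4]
  f_enc <- matrix(0, n, FE)
  for (f in seq_len(FE)) {
    f_enc[, f] <- rowsum(as.vector(encoder_features[, , , f]), lab) / sizes
  }
  # f_app: intensity statistics (mean, sd, q10, q90)
  vv <- as.vector(volume)
  mu <- rowsum(vv, lab) / sizes
  m2 <- rowsum(vv^2, lab) / sizes
  sdv <- sqrt(pmax(0, m2 - mu^2))
  qs <- matrix(0, n, 2)
  ord <- order(lab)
  splits <- split(vv[ord], lab[ord])
  for (r in seq_len(n)) {
    qs[r, ] <- stats::quantile(splits[[r]], c(0.1, 0.9), names = FALSE)
  }
  f_app <- cbind(mu, sdv, qs)
  # f_coord: centroid normalised by grid shape
  f_coord <- sweep(partition$region_centroids, 2, dm, "/")

  base <- cbind(f_enc, f_app, f_coord)

  # adjacency edges: region pairs sharing a voxel face
  adj <- NULL
  for (ax in 1:3) {
    d <- c(0L, 0L, 0L); d[ax] <- 1L
    nb <- shift3(partition$labels, d, fill = 0L)
    diffp <- which(nb > 0L & partition$labels != nb)
    if (length(diffp)) {
      adj <- rbind(adj, cbind(partition$labels[diffp], nb[diffp]))
    }
  }
  adj <- unique(cbind(pmin(adj[, 1], adj[, 2]), pmax(adj[, 1], adj[, 2])))

  # kNN long-range edges on (f_app + f_Enc) appearance sub-vector
  app <- cbind(f_app, f_enc)
  app_sc <- scale(app)
  app_sc[is.nan(app_sc)] <- 0
  d2 <- as.matrix(stats::dist(app_sc))^2
  diag(d2) <- Inf
  knn <- NULL
  for (i in seq_len(n)) {
    nbrs <- order(d2[i, ])[seq_len(k)]
    knn <- rbind(knn, cbind(pmin(i, nbrs), pmax(i, nbrs)))
  }
  knn <- unique(knn)
  key <- function(m) paste(m[, 1], m[, 2])
  knn <- knn[!(key(knn) %in% key(adj)), , drop = FALSE]

  edges <- rbind(
    data.frame(u = adj[, 1], v = adj[, 2], kind = "adjacency",
               stringsAsFactors = FALSE),
    if (nrow(knn)) data.frame(u = knn[, 1], v = knn[, 2], kind = "knn",
                              stringsAsFactors = FALSE)
  )

  # a_init per edge: Affinity Converter (normalised cosine) on base features
  base_sc <- scale(base)
  base_sc[is.nan(base_sc)] <- 0
  edges$a_init <- .cosine01(base_sc[edges$u, , drop = FALSE],
                            base_sc[edges$v, , drop = FALSE])

  # soft targets from region CAM vectors
  p <- region_cam_means(cam, partition)
  edges$w <- .soft_dice_pair(p[edges$u, , drop = FALSE],
                             p[edges$v, , drop = FALSE], epsilon)
  edges$a_opt <- NA_real_

  # node a_init summary: mean a_init over incident adjacency edges
  ainit_sum <- rep(0, n); deg <- rep(0, n)
  au <- edges$u[edges$kind == "adjacency"]; av <- edges$v[edges$kind == "adjacency"]
  aa <- edges$a_init[edges$kind == "adjacency"]
  for (t in seq_along(aa)) {
    ainit_sum[au[t]] <- ainit_sum[au[t]] + aa[t]; deg[au[t]] <- deg[au[t]] + 1
    ainit_sum[av[t]] <- ainit_sum[av[t]] + aa[t]; deg[av[t]] <- deg[av[t]] + 1
  }
  a_node <- ifelse(deg > 0, ainit_sum / pmax(deg, 1), 0.5)

  node_features <- cbind(base, a_node)
  colnames(node_features) <- c(
    paste0("enc", seq_len(FE)), "app_mean", "app_sd", "app_q10", "app_q90",
    "coord_i", "coord_j", "coord_k", "a_init_mean"
  )

  structure(list(n_nodes = n, edges = edges, node_features = node_features,
                 partition = partition),
            class = "region_graph")
}

#' Export a superpixel partition as a NIfTI integer label map
#'
#' Region ids are written 0-based (on-disk convention).
#'
#' @param partition a `superpixel_partition`.
#' @param path output `.nii`/`.nii.gz` path.
#' @param spacing mm triple.
#' @return `path`, invisibly.
#' @export
export_partition <- function(partition, path, spacing = c(1, 1, 1)) {
  write_nifti(partition$labels - 1L, path, spacing = spacing,
              datatype = "int16")
  invisible(path)
}

#' Export a region graph edge list as TSV
#'
#' Region ids are written 0-based (on-disk convention).
#'
#' @param graph a `region_graph`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_edges <- function(graph, path) {
  e <- graph$edges
  out <- data.frame(node_u = e$u - 1L, node_v = e$v - 1L, kind = e$kind,
                    a_init = e$a_init, w = e$w, a_opt = e$a_opt)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
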