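# Segmentation and classification metrics plus the paired statistical
# protocol: Dice / IoU, 95th-percentile symmetric Hausdorff surface
# distance (mm, anisotropic spacing respected), exact paired Wilcoxon
# signed-rank tests with Pratt zero handling, macro-averaged classification
# reports with one-vs-rest AUC, and patient-level fold construction.

#' Dice and IoU overlap of two binary masks
#'
#' Convention: two empty masks score `dsc = iou = 1` (logged via message).
#'
#' @param prediction,truth logical/0-1 arrays on the same grid.
#' @return named vector `c(dsc, iou)`.
#' @export
overlap_metrics <- function(prediction, truth) {
  assert_that(all((dim(prediction) %||% length(prediction)) ==
                    (dim(truth) %||% length(truth))),
              "overlap_metrics: shape mismatch")
  p <- prediction > 0; t <- truth > 0
  np <- sum(p); nt <- sum(t); ni <- sum(p & t)
  if (np + nt == 0) {
    message("overlap_metrics: both masks empty; dsc = iou = 1 by convention")
    return(c(dsc = 1, iou = 1))
  }
  dsc <- 2 * ni / (np + nt)
  iou <- ni / (np + nt - ni)
  c(dsc = dsc, iou = iou)
}

# boundary voxels: foreground voxels with at least one 6-neighbour outside
.surface_voxels <- function(mask) {
  m <- array(mask > 0, dim(mask))
  m & !erode6(m)
}

#' 95th-percentile symmetric Hausdorff surface distance (mm)
#'
#' Surfaces are the face-boundary voxels of each mask; distances between
#' boundary voxel centres (anisotropic spacing respected) are pooled in
#' both directions and the 95th percentile taken.
#'
#' @param prediction,truth non-empty binary masks on the same grid.
#' @param spacing mm triple.
#' @param percentile quantile of the pooled surface distances (default
#'   0.95).
#' @return distance in mm.
#' @export
hd95 <- function(prediction, truth, spacing = c(1, 1, 1), percentile = 0.95) {
  assert_that(sum(prediction > 0) > 0 && sum(truth > 0) > 0,
              "hd95: empty mask (no sentinel is substituted; filter such cases upstream)")
  sp <- .surface_voxels(prediction)
  st <- .surface_voxels(truth)
  dt_t <- distance_transform(st, spacing) # distance to truth surface
  dt_p <- distance_transform(sp, spacing)
  d <- c(dt_t[sp], dt_p[st])
  as.numeric(stats::quantile(d, percentile, names = FALSE))
}

# exact distribution of the positive-rank sum W+ over sign assignments of
# the given ranks (each +/- with probability 1/2); ranks may be half-integer
# (midranks), so everything is computed on doubled ranks.
.signed_rank_distribution <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1) # index = value of doubled W+
  f[1] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1):(total + 1)] <- g[(r + 1):(total + 1)] + f[1:(total + 1 - r)]
    f <- g
  }
  f / sum(f)
}

#' Paired Wilcoxon signed-rank test (Pratt zero handling)
#'
#' Zero differences keep their ranks (Pratt) but contribute to neither
#' rank sum. The two-sided p-value is exact (full distribution over sign
#' assignments, tied midranks respected) for up to 25 non-zero differences
#' and uses a normal approximation with tie/zero corrections above.
#'
#' @param scores_a,scores_b equal-length (>= 6) paired per-patient scores.
#' @return list(`statistic` (W+, positive-rank sum), `p` (two-sided),
#'   `n_nonzero`, `method`).
#' @export
paired_wilcoxon <- function(scores_a, scores_b) {
  assert_that(length(scores_a) == length(scores_b) && length(scores_a) >= 6,
              "paired_wilcoxon: need equal lengths >= 6")
  d <- scores_a - scores_b
  nz <- d != 0
  if (!any(nz)) {
    warning("paired_wilcoxon: all differences are zero; p = 1")
    return(list(statistic = 0, p = 1, n_nonzero = 0L, method = "degenerate"))
  }
  ranks <- rank(abs(d)) # Pratt: zeros ranked too
  rnz <- ranks[nz]
  W <- sum(rnz[d[nz] > 0])
  n <- sum(nz)
  if (n <= 25) {
    dist <- .signed_rank_distribution(rnz)
    w2 <- as.integer(round(2 * W))
    p_le <- sum(dist[seq_len(w2 + 1)])
    p_ge <- sum(dist[(w2 + 1):length(dist)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- sum(rnz) / 2
    sig <- sqrt(sum(rnz^2) / 4)
    z <- (W - mu - sign(W - mu) * 0.5) / sig
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = W, p = p, n_nonzero = as.integer(n), method = method)
}

#' Classification metric report
#'
#' Overall accuracy, macro-averaged recall / precision / F1 / FPR over the
#' classes present in the truth, a K x K confusion matrix, and the macro
#' one-vs-rest AUC when per-class scores are supplied.
#'
#' @param predicted integer predicted classes (1..K).
#' @param truth integer true classes (>= 2 distinct).
#' @param scores optional n x K score matrix for AUC.
#' @param K number of classes (default max observed).
#' @return object of class `metric_report`: list(`accuracy`, `recall`,
#'   `precision`, `f1`, `fpr`, `auc`, `confusion`, `per_class`
#'   (data.frame)).
#' @export
classification_report <- function(predicted, truth, scores = NULL,
                                  K = max(c(predicted, truth))) {
  assert_that(length(unique(truth)) >= 2,
              "classification_report: need >= 2 classes in truth")
  n <- length(truth)
  conf <- matrix(0L, K, K, dimnames = list(truth = 1:K, predicted = 1:K))
  for (i in seq_len(n)) conf[truth[i], predicted[i]] <- conf[truth[i], predicted[i]] + 1L
  acc <- sum(diag(conf)) / n
  present <- sort(unique(truth))
  skipped <- setdiff(1:K, present)
  if (length(skipped)) {
    message("classification_report: class(es) absent from truth skipped in macro averages: ",
            paste(skipped, collapse = ", "))
  }
  per <- lapply(present, function(k) {
    tp <- conf[k, k]; fn <- sum(conf[k, ]) - tp
    fp <- sum(conf[, k]) - tp; tn <- n - tp - fn - fp
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    pre <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0
    fpr <- if (fp + tn > 0) fp / (fp + tn) else 0
    auc <- NA_real_
    if (!is.null(scores)) {
      pos <- scores[truth == k, k]; neg <- scores[truth != k, k]
      if (length(pos) && length(neg)) {
        r <- rank(c(pos, neg))
        auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
          (length(pos) * length(neg))
      }
    }
    data.frame(class = k, recall = rec, precision = pre, f1 = f1, fpr = fpr,
               auc = auc)
  })
  per <- do.call(rbind, per)
  structure(list(accuracy = acc,
                 recall = mean(per$recall), precision = mean(per$precision),
                 f1 = mean(per$f1), fpr = mean(per$fpr),
                 auc = if (is.null(scores)) NA_real_ else mean(per$auc, na.rm = TRUE),
                 confusion = conf, per_class = per),
            class = "metric_report")
}

#' Patient-level fold assignment
#'
#' Non-overlapping, exhaustive folds whose sizes differ by at most one;
#' seeded shuffle.
#'
#' @param patient_ids unique patient identifiers.
#' @param n_folds number of folds (default 5), `<=` number of patients.
#' @param seed RNG seed.
#' @return named integer vector mapping patient id to fold (1..n_folds).
#' @export
make_patient_folds <- function(patient_ids, n_folds = 5, seed = 1) {
  assert_that(!anyDuplicated(patient_ids), "make_patient_folds: duplicate patient ids")
  assert_that(n_folds <= length(patient_ids),
              "make_patient_folds: more folds than patients")
  set.seed(seed)
  ord <- sample(seq_along(patient_ids))
  fold <- integer(length(patient_ids))
  fold[ord] <- rep_len(seq_len(n_folds), length(patient_ids))
  names(fold) <- as.character(patient_ids)
  fold
}
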