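# End-to-end pipeline: manifest in, run directory out.
#
# Stages: preprocess -> classifier/CAM -> superpixel graph -> GA-Net
# affinity training -> dual-threshold seeding -> voxel affinity ->
# region-wise random-walk refinement -> refreshed pseudo-labels ->
# contour scribbles -> segmenter training with EMA -> metric reports.
# Every stage is seeded from the run seed and all intermediates are
# persisted with provenance.

#' Pipeline configuration
#'
#' Collects every stage knob with its default. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed below.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    # pseudo-label seeding
    phi_l = 0.32, phi_h = 0.46,
    # propagation
    eta = 1, window_radius = c(2, 2, 2), block_size = c(16, 16, 16),
    overlap_fraction = 0.5, n_iterations = 1, use_region_graph = FALSE,
    # graph + GA-Net
    n_segments = 150, compactness = 0.1, k = 10,
    ganet_layers = 4, ganet_dim = 16, ganet_steps = 100, ganet_lr = 1e-2,
    lambda_smooth = 0.5,
    # classifier
    cls_steps = 200, cls_lr = 0.1, epsilon = 0.15, n_classes = 5,
    # segmenter + EMA
    seg_steps = 100, seg_lr = 0.05, delta = 0.2, gamma = 8,
    # loss weights lambda1..lambda5
    lambda = c(0.6, 0.5, 0.5, 0.7, 0.5),
    # ablation switches (Table-style M-1..M-4 pattern)
    disable_struct = FALSE, disable_aff = FALSE,
    disable_smooth = FALSE, disable_pce = FALSE,
    # scribbles
    scribble_stride = 4, scribble_band = 1,
    # preprocessing
    hu_window = c(-1200, 600), target_spacing = c(1, 1, 1),
    patch_size = c(128, 128, 96),
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  assert_that(length(unknown) == 0,
              paste("pipeline_config: unknown keys:", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, over)
  assert_that(cfg$phi_l > 0 && cfg$phi_l < cfg$phi_h && cfg$phi_h < 1,
              "pipeline_config: need 0 < phi_l < phi_h < 1")
  assert_that(cfg$eta > 0, "pipeline_config: eta must be > 0")
  structure(cfg, class = "pipeline_config")
}

#' Run the full refinement pipeline on a phantom manifest
#'
#' @param manifest manifest list as produced by [make_fixture_suite()] (or
#'   read from its `manifest.json`).
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created).
#' @return list(`out_dir`, `metrics` (per-case data.frame), `loss_components`
#'   (named vector), `total` (weighted total loss)), invisibly.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cases <- manifest$cases
  ncase <- length(cases)
  assert_that(ncase >= 1, "run_pipeline: empty manifest")
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  run_stage <- function(stage, case_id, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("run_pipeline: stage '%s' failed for case '%s': %s",
                   stage, case_id, conditionMessage(e)), call. = FALSE)
    })
  }

  volumes <- list(); masks <- list(); cams <- list(); labels <- integer(ncase)
  for (i in seq_len(ncase)) {
    cs <- cases[[i]]
    volumes[[i]] <- run_stage("load", cs$case_id, read_nifti(cs$paths$volume))
    masks[[i]] <- run_stage("load", cs$case_id, read_nifti(cs$paths$mask))
    cams[[i]] <- run_stage("load", cs$case_id, read_nifti(cs$paths$cam))
    labels[i] <- cs$class
  }
  dm <- dim(volumes[[1]])

  # stage: classification head + CAMs (image-level supervision)
  cls <- run_stage("classifier", "all", train_classifier_and_cam(
    volumes, labels,
    config = list(K = config$n_classes, steps = config$cls_steps,
                  lr = config$cls_lr, epsilon = config$epsilon,
                  seed = child_seed(config$seed, 1))
  ))
  utils::write.csv(cls$history, file.path(out_dir, "loss_classifier.csv"),
                   row.names = FALSE)
  l_cls <- utils::tail(cls$history$loss, 1)

  # the localisation CAM refined downstream is the (corrupted) single-channel
  # cavity CAM shipped with each case; the classifier CAM carries the
  # image-level class evidence
  per_case <- vector("list", ncase)
  l_struct <- l_smooth <- l_aff <- l_pce <- l_seg <- 0
  refined_pseudo <- list(); scribbles <- list()
  for (i in seq_len(ncase)) {
    cs <- cases[[i]]
    vol <- volumes[[i]]
    cam3 <- cams[[i]]
    if (length(dim(cam3)) == 3) dim(cam3) <- c(dim(cam3), 1L)
    seed_i <- child_seed(config$seed, 100 + i)

    # superpixel graph + GA-Net
    part <- run_stage("superpixels", cs$case_id,
                      compute_superpixels(vol, config$n_segments, config$compactness))
    fe <- encoder_features(vol)
    gr <- run_stage("graph", cs$case_id,
                    build_region_graph(part, vol, fe, cam3,
                                       k = min(config$k, part$n_regions - 1L)))
    lam_s <- if (config$disable_smooth) 0 else config$lambda_smooth
    tg <- run_stage("ganet", cs$case_id, train_ganet(gr, list(
      hidden_dim = config$ganet_dim, n_layers = config$ganet_layers,
      steps = config$ganet_steps, lr = config$ganet_lr,
      lambda_smooth = lam_s, seed = seed_i,
      use_struct = !config$disable_struct
    )))
    utils::write.csv(tg$history,
                     file.path(out_dir, paste0(cs$case_id, "_loss_ganet.csv")),
                     row.names = FALSE)
    export_edges(tg$graph, file.path(out_dir, paste0(cs$case_id, "_edges.tsv")))
    if (!config$disable_struct) {
      l_struct <- l_struct +
        structural_loss(tg$graph$edges$a_opt, tg$graph$edges$w) / ncase
    }
    if (!config$disable_smooth) {
      l_smooth <- l_smooth +
        smooth_loss(tg$graph$edges$a_opt, tg$graph$edges$a_init) / ncase
    }

    # dual-threshold seeding + voxel affinity + refinement
    pseudo_raw <- run_stage("dual_threshold", cs$case_id,
                            dual_threshold(cam3, config$phi_l, config$phi_h))
    aff <- run_stage("voxel_affinity", cs$case_id,
                     voxel_affinity(fe, config$window_radius))
    if (!config$disable_aff) {
      tgt <- run_stage("affinity_targets", cs$case_id,
                       derive_affinity_targets(pseudo_raw, config$window_radius))
      l_aff <- l_aff + focal_affinity_loss(affinity_logits(aff), tgt) / ncase
    }
    ref <- run_stage("refine", cs$case_id, refine_cam(cam3, aff, list(
      eta = config$eta, block_size = config$block_size,
      overlap_fraction = config$overlap_fraction,
      n_iterations = config$n_iterations,
      use_region_graph = config$use_region_graph,
      region_graph = tg$graph
    )))
    write_nifti(unclass(ref), file.path(out_dir, paste0(cs$case_id, "_refined_cam.nii.gz")))
    pseudo <- dual_threshold(ref, config$phi_l, config$phi_h)
    export_pseudo_label(pseudo, file.path(out_dir, paste0(cs$case_id, "_pseudo.nii.gz")))
    refined_pseudo[[i]] <- pseudo
    scribbles[[i]] <- if (config$disable_pce) NULL else
      run_stage("scribble", cs$case_id,
                extract_scribbles(pseudo, config$scribble_stride,
                                  config$scribble_band))
  }

  # stage: segmenter with EMA
  seg <- run_stage("segmenter", "all", train_segmenter(
    volumes, refined_pseudo,
    scribbles = if (config$disable_pce) NULL else scribbles,
    config = list(steps = config$seg_steps, lr = config$seg_lr,
                  epsilon = config$epsilon, delta = config$delta,
                  gamma = config$gamma, lambda4 = config$lambda[4],
                  lambda5 = config$lambda[5],
                  seed = child_seed(config$seed, 2), truth = masks)
  ))
  utils::write.csv(seg$history, file.path(out_dir, "loss_segmenter.csv"),
                   row.names = FALSE)
  l_seg <- utils::tail(seg$history$loss_seg, 1)
  if (!config$disable_pce) l_pce <- utils::tail(seg$history$loss_pce, 1)

  # metrics against phantom truth
  rows <- lapply(seq_len(ncase), function(i) {
    pred <- seg$predictions[[i]] >= 0.5
    tr <- masks[[i]] > 0
    om <- overlap_metrics(pred, tr)
    h <- if (sum(pred) > 0 && sum(tr) > 0) {
      hd95(pred, tr, spacing = cases[[i]]$spacing %||% c(1, 1, 1))
    } else NA_real_
    data.frame(case_id = cases[[i]]$case_id, dsc = om["dsc"], iou = om["iou"],
               hd95 = h, row.names = NULL)
  })
  metrics <- do.call(rbind, rows)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)

  lam <- config$lambda
  weights <- c(1,
               if (config$disable_struct) 0 else lam[1],
               if (config$disable_smooth) 0 else lam[2],
               if (config$disable_aff) 0 else lam[3],
               if (config$disable_pce) 0 else lam[4],
               lam[5])
  components <- c(cls = l_cls, struct = l_struct, smooth = l_smooth,
                  aff = l_aff, pce = l_pce, seg = l_seg)
  decomp <- data.frame(component = names(components),
                       value = as.numeric(components),
                       weight = weights,
                       contribution = as.numeric(components) * weights)
  utils::write.csv(decomp, file.path(out_dir, "loss_decomposition.csv"),
                   row.names = FALSE)
  total <- sum(decomp$contribution)
  jsonlite::write_json(list(total_loss = total, mean_dsc = mean(metrics$dsc)),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(out_dir = out_dir, metrics = metrics,
                 loss_components = components, decomposition = decomp,
                 total = total))
}
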