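## End-to-end orchestration of the three stages: (1) simulate or ingest
## particles and estimate per-image parameters by elastic/rigid
## alignment, (2) train the per-parameter-type networks on the labelled
## subset and predict the rest, (3) conformational-space analysis,
## optional group reconstructions, and the evaluation report.
##
## All artifacts are plain files in the run directory (MRC stacks, TSV
## metadata, text logs); a run is fully reproducible from (config,
## seed).

#' Pipeline configuration
#'
#' @param model Reference [coarse_model()].
#' @param modeset `normal_mode_set` for the selected flexible modes.
#' @param trajectory A [trajectory_spec()] for the simulator stage.
#' @param sim A [sim_config()].
#' @param use_ground_truth_labels Train on the simulator's ground
#'   truth instead of the alignment estimates (the alignment stage
#'   dominates runtime at small scale; the reference protocol trains
#'   on alignment output, which remains the default).
#' @param align An [align_config()] (used when
#'   `use_ground_truth_labels` is FALSE).
#' @param mahalanobis_threshold Amplitude outlier threshold (3.2 in
#'   the reference protocol); `NULL` disables filtering.
#' @param split Named fractions for [split_dataset()]; must contain
#'   `train`, `validation` and `test`.
#' @param net_template A [network_config()] whose schedule/depth are
#'   reused for all three parameter heads (target type and output
#'   dimension are overridden per head).
#' @param heads Which parameter types to train.
#' @param pca_d Embedding dimension.
#' @param pc1_bins,min_group_size Group selection along PC1 (NULL
#'   disables grouping).
#' @param do_reconstruct Reconstruct a map per group with the
#'   predicted poses.
#' @param seed Master seed; stage seeds derive from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(model, modeset,
                            trajectory = trajectory_spec(),
                            sim = sim_config(),
                            use_ground_truth_labels = FALSE,
                            align = align_config(),
                            mahalanobis_threshold = 3.2,
                            split = c(train = 0.6, validation = 0.1,
                                      test = 0.3),
                            net_template = network_config(
                              "amplitudes", output_dim = 1L,
                              depth = "tiny"),
                            heads = c("amplitudes", "quaternion",
                                      "shifts"),
                            pca_d = 2L, pc1_bins = NULL,
                            min_group_size = 1L,
                            do_reconstruct = FALSE,
                            seed = 1L) {
  stopifnot(inherits(model, "coarse_model"),
            inherits(modeset, "normal_mode_set"))
  need <- c("train", "validation", "test")
  if (!all(need %in% names(split)))
    stop("split must name train, validation and test fractions")
  structure(list(model = model, modeset = modeset,
                 trajectory = trajectory, sim = sim,
                 use_ground_truth_labels = use_ground_truth_labels,
                 align = align,
                 mahalanobis_threshold = mahalanobis_threshold,
                 split = split, net_template = net_template,
                 heads = heads, pca_d = as.integer(pca_d),
                 pc1_bins = pc1_bins,
                 min_group_size = as.integer(min_group_size),
                 do_reconstruct = do_reconstruct, seed = seed),
            class = "pipeline_config")
}

.head_config <- function(template, target_type, n_modes, seed) {
  network_config(target_type,
                 output_dim = if (target_type == "amplitudes")
                   n_modes else NULL,
                 depth = template$depth,
                 head_widths = template$head_widths,
                 dropout = template$dropout,
                 weight_decay = template$weight_decay,
                 lr0 = template$lr0,
                 lr_decay_every = template$lr_decay_every,
                 epochs = template$epochs,
                 batch_size = template$batch_size,
                 seed = seed)
}

#' Run the full pipeline
#'
#' Simulate -> (align or take ground-truth labels) -> Mahalanobis
#' filter -> split -> train one network per parameter type -> predict
#' the test set -> PCA conformational space (+ optional groups and
#' per-group reconstructions) -> evaluation report against ground
#' truth.  Artifacts land in `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created).
#' @param verbose Log stage progress.
#' @return A list with the trained heads, predicted and ground-truth
#'   records, the conformational space, per-group FSC curves (when
#'   reconstructing) and the `evaluation` report.
#' @export
run_pipeline <- function(config, out_dir = tempfile("nmaflex_run_"),
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) log_msg(...)
  seed <- as.integer(config$seed)
  m <- ncol(config$modeset$vectors)
  if (sum(config$split) > 1 + 1e-9)
    stop("split fractions exceed 1")
  if (config$split["train"] <= 0)
    stop("training stage needs a positive train fraction")

  ## stage 1a: simulate
  say("stage simulate: %d particles, seed %d",
      config$sim$n_particles, seed)
  sim <- config$sim
  sim$seed <- seed
  stack <- simulate_dataset(config$model, config$modeset,
                            config$trajectory, sim)
  truth <- stack$records
  write_metadata(file.path(out_dir, "ground_truth.tsv"), truth)
  L <- dim(stack$images)[1]

  ## phase flip when a CTF was simulated (standard preprocessing)
  if (!is.null(sim$ctf)) {
    say("stage preprocess: phase flip")
    for (k in seq_len(dim(stack$images)[3]))
      stack$images[, , k] <- phase_flip(stack$images[, , k], sim$ctf,
                                        stack$pixel_size)
  }

  ## split
  idx <- split_dataset(nrow(truth), config$split, seed = seed + 1L)

  ## stage 1b: labels for the training subset
  if (config$use_ground_truth_labels) {
    labels_rec <- truth
  } else {
    say("stage align: %d training images",
        length(idx$train) + length(idx$validation))
    lab_idx <- sort(c(idx$train, idx$validation))
    sub <- particle_stack(stack$images[, , lab_idx, drop = FALSE],
                          stack$pixel_size,
                          truth[lab_idx, , drop = FALSE])
    aligned <- align_stack(sub, config$model, config$modeset,
                           config$align, ctf = sim$ctf)
    labels_rec <- truth
    labels_rec[lab_idx, names(aligned)] <- aligned
    write_metadata(file.path(out_dir, "aligned.tsv"), aligned)
  }

  ## Mahalanobis filter on the training labels
  train_idx <- idx$train
  if (!is.null(config$mahalanobis_threshold)) {
    sub <- labels_rec[train_idx, , drop = FALSE]
    class(sub) <- c("particle_records", "data.frame")
    kept <- mahalanobis_filter(sub, config$mahalanobis_threshold)
    say("stage filter: kept %d of %d (threshold %.2f)",
        nrow(kept), length(train_idx), config$mahalanobis_threshold)
    train_idx <- train_idx[attr(kept, "distances") <=
                             config$mahalanobis_threshold]
  }

  ## stage 2: train per-head networks and predict the test set
  test_idx <- idx$test
  trained <- list()
  preds <- list()
  amp_lab <- records_amplitudes(labels_rec)
  quat_lab <- records_quaternion(labels_rec)
  shift_lab <- records_shift(labels_rec)
  lab_for <- function(tt, rows) switch(tt,
    amplitudes = amp_lab[rows, , drop = FALSE],
    quaternion = quat_lab[rows, , drop = FALSE],
    shifts = shift_lab[rows, , drop = FALSE])
  for (tt in config$heads) {
    say("stage train: %s head (%d train / %d val images)", tt,
        length(train_idx), length(idx$validation))
    cfg <- .head_config(config$net_template, tt, m, seed + 2L)
    net <- build_model(cfg, L)
    fit <- train_network(net,
                         stack$images[, , train_idx, drop = FALSE],
                         lab_for(tt, train_idx),
                         stack$images[, , idx$validation,
                                      drop = FALSE],
                         lab_for(tt, idx$validation))
    utils::write.table(fit$training_log,
                       file.path(out_dir,
                                 sprintf("training_log_%s.tsv", tt)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    trained[[tt]] <- fit
    say("stage predict: %s head (%d test images)", tt,
        length(test_idx))
    preds[[tt]] <-
      predict_network(fit, stack$images[, , test_idx, drop = FALSE])
  }

  ## combine per-head predictions into one record table
  k <- length(test_idx)
  pred <- particle_records(
    if ("amplitudes" %in% names(preds))
      records_amplitudes(preds$amplitudes) else matrix(0, k, m),
    if ("quaternion" %in% names(preds))
      records_euler(preds$quaternion) else matrix(0, k, 3),
    if ("shifts" %in% names(preds))
      records_shift(preds$shifts) else matrix(0, k, 2),
    provenance = "inferred")
  write_metadata(file.path(out_dir, "predicted.tsv"), pred)
  truth_test <- truth[test_idx, , drop = FALSE]
  class(truth_test) <- c("particle_records", "data.frame")

  ## stage 3: conformational space and report
  space <- NULL
  selection <- NULL
  fsc_curves <- NULL
  if ("amplitudes" %in% names(preds)) {
    space <- pca_fit(pred, d = min(config$pca_d, m))
    if (!is.null(config$pc1_bins)) {
      selection <- select_groups(space, pc1_bins = config$pc1_bins,
                                 min_group_size = config$min_group_size)
    }
    write_space(file.path(out_dir, "space.tsv"), space, selection)
  }
  if (isTRUE(config$do_reconstruct) && !is.null(selection) &&
      all(c("quaternion", "shifts") %in% names(preds))) {
    say("stage reconstruct: %d groups", length(selection$groups))
    fsc_curves <- list()
    for (g in seq_along(selection$groups)) {
      rows <- selection$groups[[g]]
      grp <- pred[rows, , drop = FALSE]
      class(grp) <- c("particle_records", "data.frame")
      rec_map <- reconstruct(stack$images[, , test_idx[rows],
                                          drop = FALSE],
                             grp, pixel_size = stack$pixel_size)
      ## reference: map rendered from the group-centroid conformation
      centroid_amp <- colMeans(records_amplitudes(grp))
      conf <- apply_amplitudes(config$model, config$modeset,
                               centroid_amp)
      conf$gaussian_sigma <- sim$gaussian_sigma
      ref_map <- render_density(conf, L, stack$pixel_size)
      fsc_curves[[g]] <- fsc(rec_map, ref_map)
      write_map(file.path(out_dir, sprintf("group_%02d.mrc", g)),
                rec_map)
    }
  }

  evaluation <- evaluate_predictions(pred, truth_test, config$model,
                                     config$modeset,
                                     pixel_size = stack$pixel_size)
  rep_path <- file.path(out_dir, "report.txt")
  utils::capture.output(print(evaluation), file = rep_path)
  say("run complete: %s", out_dir)
  invisible(list(out_dir = out_dir, stack = stack, truth = truth,
                 split = idx, trained = trained, predicted = pred,
                 truth_test = truth_test, space = space,
                 selection = selection, fsc = fsc_curves,
                 evaluation = evaluation))
}
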