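#' Scan-level train/validation/test split
#'
#' One scan is held out for external testing; the remaining development scans
#' are split into train/validation at scan granularity as close to 80/20 as
#' integer counts allow (5 scans give a 3/1/1 partition). Splitting at the
#' scan level prevents leakage between highly correlated slices of one
#' acquisition.
#'
#' @param scan_ids character vector of scan identifiers (>= 3)
#' @param seed RNG seed; the split is a pure function of it
#' @return a `split_plan` list with `train_scans`, `val_scans`, `test_scans`
#' @export
make_split <- function(scan_ids, seed = 0L) {
  n <- length(scan_ids)
  if (n < 3) stopf("need at least 3 scans to split")
  perm <- with_seed_(seed, sample(scan_ids))
  test <- perm[1]
  dev <- perm[-1]
  n_val <- max(1L, round(0.2 * length(dev)))
  plan <- structure(list(train_scans = dev[-seq_len(n_val)],
                         val_scans = dev[seq_len(n_val)],
                         test_scans = test),
                    class = "split_plan")
  if (anyDuplicated(unlist(plan))) stopf("split partitions overlap")
  plan
}

#' Per-scan per-bin standardization
#'
#' Standardizes each energy bin of a scan to zero mean and unit variance over
#' all voxels of that scan. Applied to every scan independently before the
#' network sees it.
#'
#' @param volume a `spectral_volume`
#' @return the volume with standardized `values`
#' @export
standardize_volume <- function(volume) {
  v <- volume$values
  nf <- dim(v)[2]
  for (f in seq_len(nf)) {
    x <- v[, f, , ]
    v[, f, , ] <- (x - mean(x)) / (sd(x) + 1e-12)
  }
  volume$values <- v
  volume
}

load_scan_set <- function(data_dir, scan_ids, standardize = TRUE) {
  lapply(scan_ids, function(id) {
    scan <- read_scan(file.path(data_dir, paste0(id, ".rds")))
    if (standardize) scan$volume <- standardize_volume(scan$volume)
    scan$scan_id <- id
    scan
  })
}

# Validation macro Dice: hard-label per-slice per-class Dice under the
# evaluation rules (missing-class omission, background excluded). Inference
# is batched independently of the training batch size (per-sample layers make
# the outputs batch-composition-invariant).
val_macro_dice <- function(net, scans, batch_size = 8L) {
  dices <- c()
  for (scan in scans) {
    pred <- predict_volume(net, scan$volume, batch_size = batch_size,
                           standardize = FALSE)
    tab <- metric_table(pred, scan$labels$labels, net$config$n_classes)
    dices <- c(dices, macro_average(tab)$macro[["dice"]])
  }
  mean(dices)
}

#' Voxel-wise prediction for a whole spectral volume
#'
#' @param net a trained `spff_network`
#' @param volume a `spectral_volume`
#' @param batch_size slices per forward pass
#' @param standardize apply [standardize_volume()] first
#' @return integer Z x H x W array of predicted class ids
#' @export
predict_volume <- function(net, volume, batch_size = 4L, standardize = TRUE) {
  if (standardize) volume <- standardize_volume(volume)
  v <- volume$values
  d <- dim(v) # Z, F, H, W
  out <- array(0L, d[c(1, 3, 4)])
  idx <- seq_len(d[1])
  for (chunk in split(idx, ceiling(idx / batch_size))) {
    nb <- length(chunk)
    x <- array(0, c(nb, 1, d[2], d[3], d[4]))
    for (j in seq_len(nb)) x[j, 1, , , ] <- v[chunk[j], , , ]
    logits <- network_forward(net, x)
    out[chunk, , ] <- predict_labels(logits)
  }
  out
}

#' Train one network under the unified protocol
#'
#' Seeds all RNG streams from `seed`, iterates augmented slices of the
#' training scans, optimizes the composite objective with Adam, evaluates
#' validation macro Dice after each epoch (augmentation off), halves the
#' learning rate on plateau, stops early on the monitor, and restores the
#' best-monitor weights.
#'
#' @param config a [network_config()]
#' @param protocol a [train_protocol()]
#' @param split a [make_split()] plan
#' @param data_dir directory with the native scan containers
#' @param seed integer seed for weight init, shuffling and augmentation
#' @param verbose print per-epoch monitor lines
#' @return list with `checkpoint` (best weights + metadata) and `history`
#'   (per-epoch tibble)
#' @export
train_model <- function(config, protocol, split, data_dir, seed = 0L,
                        verbose = FALSE) {
  if (length(split$train_scans) == 0) stopf("empty training set")
  train_scans <- load_scan_set(data_dir, split$train_scans)
  val_scans <- load_scan_set(data_dir, split$val_scans)
  slices <- do.call(rbind, lapply(seq_along(train_scans), function(i) {
    cbind(scan = i, z = seq_len(dim(train_scans[[i]]$volume$values)[1]))
  }))
  net <- build_network(config, seed = seed)
  state <- adam_init()
  sched <- plateau_scheduler(protocol$lr, protocol$sched_factor,
                             protocol$sched_patience, protocol$min_delta)
  es <- early_stopping(protocol$es_patience, protocol$min_delta)
  aug <- protocol$augment
  aug$train_mode <- TRUE
  best_net <- net
  best_epoch <- 0L
  lr <- protocol$lr
  hist <- list()
  stop_reason <- "max_epochs"
  with_seed_(seed, {
    for (epoch in seq_len(protocol$max_epochs)) {
      t0 <- proc.time()[3]
      ord <- sample(nrow(slices))
      losses <- c()
      for (chunk in split(ord, ceiling(seq_along(ord) / protocol$batch_size))) {
        nb <- length(chunk)
        dsc <- train_scans[[slices[chunk[1], "scan"]]]
        dfhw <- dim(dsc$volume$values)[c(2, 3, 4)]
        x <- array(0, c(nb, 1, dfhw))
        y <- array(0L, c(nb, dfhw[2], dfhw[3]))
        for (j in seq_len(nb)) {
          sc <- train_scans[[slices[chunk[j], "scan"]]]
          z <- slices[chunk[j], "z"]
          a <- augment_sample(sc$volume$values[z, , , ],
                              sc$labels$labels[z, , ], aug)
          x[j, 1, , , ] <- a$image
          y[j, , ] <- a$label
        }
        fwd <- network_forward(net, x, train = TRUE)
        lg <- composite_loss_grad(fwd$logits, y)
        if (!is.finite(lg$loss))
          stopf("non-finite loss at epoch %d (ce=%.4g dice=%.4g)", epoch,
                lg$ce, lg$dice)
        grads <- network_backward(net, lg$dlogits, fwd$cache)
        net <- adam_step(net, grads, state, lr,
                         weight_decay = protocol$weight_decay)
        losses <- c(losses, lg$loss)
      }
      monitor <- val_macro_dice(net, val_scans)
      improved <- es$step(monitor)
      if (improved) {
        best_net <- net
        best_epoch <- epoch
      }
      lr_next <- sched$step(monitor)
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = mean(losses), val_macro_dice = monitor,
        lr = lr, seconds = proc.time()[3] - t0)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val macro Dice %.4f  lr %.2g",
                        epoch, mean(losses), monitor, lr))
      lr <- lr_next
      if (es$should_stop()) { stop_reason <- "early_stopping"; break }
    }
  })
  history <- do.call(rbind, hist)
  checkpoint <- list(net = best_net, config = config, protocol = protocol,
                     split = split, seed = as.integer(seed),
                     best_epoch = best_epoch, best_monitor = es$best(),
                     stop_reason = stop_reason)
  list(checkpoint = checkpoint, history = history)
}

#' Save / load a training checkpoint
#' @param checkpoint checkpoint list from [train_model()]
#' @param path file path
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(c(checkpoint, list(format = "spffunet-ckpt-v1")), path,
          compress = "gzip")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stopf("checkpoint not found: '%s'", path)
  readRDS(path)
}

#' Evaluate a checkpoint on the held-out external test scan
#'
#' Refuses to evaluate on a scan that was part of the training partition
#' (leakage guard). Runs slice-by-slice inference without augmentation,
#' computes the per-slice per-class metric table, macro aggregates, and the
#' slice-wise Dice-error series for the HA and iodine groups; optionally
#' writes tidy CSV/JSON outputs and overlay images.
#'
#' @param checkpoint checkpoint list (or path)
#' @param test_scan scan id to evaluate
#' @param data_dir directory with the scan containers
#' @param out_dir optional output directory for CSV/JSON/overlays
#' @return list with `table` (metric tibble), `macro`, `per_class`,
#'   `error_series`, and `pred` (predicted label volume)
#' @export
evaluate_external <- function(checkpoint, test_scan, data_dir,
                              out_dir = NULL) {
  if (is.character(checkpoint)) checkpoint <- load_checkpoint(checkpoint)
  if (test_scan %in% checkpoint$split$train_scans)
    stopf("scan '%s' was used for training; refusing to evaluate", test_scan)
  scan <- load_scan_set(data_dir, test_scan)[[1]]
  gt <- scan$labels$labels
  pred <- predict_volume(checkpoint$net, scan$volume, standardize = FALSE)
  tab <- metric_table(pred, gt, checkpoint$config$n_classes)
  agg <- macro_average(tab)
  nz <- dim(pred)[1]
  dice_mat <- matrix(NA_real_, nz, 12,
                     dimnames = list(NULL, as.character(1:12)))
  for (cid in 1:12) {
    sub <- tab[tab$class_id == cid, ]
    dice_mat[sub$slice, as.character(cid)] <- sub$dice
  }
  series <- slice_error_series(dice_mat, material_groups())
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(macro = as.list(agg$macro),
           test_scan = test_scan, seed = checkpoint$seed),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    mid <- max(1L, nz %/% 2)
    render_overlay(scan$volume$values[mid, , , ], pred[mid, , ],
                   file.path(out_dir, "overlay_pred.png"))
    render_overlay(scan$volume$values[mid, , , ], gt[mid, , ],
                   file.path(out_dir, "overlay_gt.png"))
  }
  list(table = tab, macro = agg$macro, per_class = agg$per_class,
       error_series = series, pred = pred)
}

#' Train and evaluate a set of ablation variants
#'
#' Trains every (variant, seed) pair under the identical protocol, split and
#' data, evaluates each on the external test scan, and reports macro metrics
#' as mean and SD per variant in the fixed plain-to-full order.
#'
#' @param variants character vector of [network_config()] variants
#' @param protocol a [train_protocol()]
#' @param split a [make_split()] plan
#' @param data_dir scan directory
#' @param seeds integer vector of training seeds
#' @param config_base base [network_config()] whose non-variant fields are
#'   reused for every variant
#' @param verbose print per-epoch lines
#' @return list with `table` (tibble of mean/SD macro metrics per variant)
#'   and `runs` (per variant x seed macro metrics)
#' @export
run_ablation <- function(variants, protocol, split, data_dir,
                         seeds = c(1L, 2L, 3L),
                         config_base = network_config(), verbose = FALSE) {
  order_ref <- c("plain", "sp", "e_sp", "fg_sp", "spff", "blind_control")
  bad <- setdiff(variants, order_ref)
  if (length(bad)) stopf("unknown variant(s): %s", paste(bad, collapse = ", "))
  variants <- order_ref[order_ref %in% variants]
  metrics <- c("dice", "sensitivity", "specificity", "precision", "iou")
  runs <- list()
  for (v in variants) {
    cfg <- config_base
    cfg$variant <- v
    cfg$has_se <- v %in% c("sp", "e_sp", "fg_sp", "spff")
    cfg$has_film <- v %in% c("e_sp", "spff")
    cfg$has_fg <- v %in% c("fg_sp", "spff")
    for (s in seeds) {
      fit <- train_model(cfg, protocol, split, data_dir, seed = s,
                         verbose = verbose)
      ev <- evaluate_external(fit$checkpoint, split$test_scans, data_dir)
      runs[[length(runs) + 1]] <- tibble::tibble(
        variant = v, seed = s,
        dice = ev$macro[["dice"]], sensitivity = ev$macro[["sensitivity"]],
        specificity = ev$macro[["specificity"]],
        precision = ev$macro[["precision"]], iou = ev$macro[["iou"]])
    }
  }
  runs <- do.call(rbind, runs)
  rows <- lapply(variants, function(v) {
    sub <- runs[runs$variant == v, ]
    out <- tibble::tibble(variant = v)
    for (m in metrics) {
      ag <- aggregate_seeds(sub[[m]])
      out[[paste0(m, "_mean")]] <- ag[["mean"]]
      out[[paste0(m, "_sd")]] <- ag[["sd"]]
    }
    out
  })
  list(table = do.call(rbind, rows), runs = runs)
}
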