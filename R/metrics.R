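#' One-vs-rest confusion counts per class for one slice
#'
#' @param pred_labels,gt_labels integer H x W maps with values in
#'   `0..n_classes-1`
#' @param n_classes number of classes (default 13)
#' @return integer matrix `n_classes x 4` with columns TP, FP, FN, TN and one
#'   row per class id 0..n_classes-1
#' @export
confusion_counts <- function(pred_labels, gt_labels, n_classes = 13L) {
  if (!identical(dim(pred_labels), dim(gt_labels)))
    stopf("prediction/ground-truth shape mismatch")
  lev <- 0:(n_classes - 1L)
  tab <- table(factor(pred_labels, levels = lev),
               factor(gt_labels, levels = lev))
  tp <- diag(tab)
  fp <- rowSums(tab) - tp
  fn <- colSums(tab) - tp
  tn <- sum(tab) - tp - fp - fn
  out <- cbind(TP = as.integer(tp), FP = as.integer(fp),
               FN = as.integer(fn), TN = as.integer(tn))
  rownames(out) <- as.character(lev)
  out
}

#' Per-class metrics from confusion counts, with missing-class semantics
#'
#' Dice `= 2TP/(2TP+FP+FN)`, Sensitivity `= TP/(TP+FN)`, Specificity
#' `= TN/(TN+FP)`, Precision `= TP/(TP+FP)`, IoU `= TP/(TP+FP+FN)`. When the
#' slice contains no ground-truth positives for the class (`gt_present =
#' FALSE`), Dice and Sensitivity are recorded as missing (`NA`); Precision and
#' IoU are missing when nothing was predicted either (`TP = 0` and `FP = 0`)
#' and collapse to 0 when `TP = 0` but `FP > 0`. Specificity is missing only
#' in the degenerate case `TN + FP = 0`.
#'
#' @param counts numeric vector with named entries TP, FP, FN, TN (one row of
#'   [confusion_counts()])
#' @param gt_present does the slice contain ground-truth positives for this
#'   class?
#' @return named numeric vector (dice, sensitivity, specificity, precision,
#'   iou), `NA` where undefined
#' @export
per_class_metrics <- function(counts, gt_present) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  fn <- counts[["FN"]]; tn <- counts[["TN"]]
  dice <- if (!gt_present) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  sens <- if (!gt_present) NA_real_ else tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  iou <- if (tp + fp + fn == 0) NA_real_ else tp / (tp + fp + fn)
  c(dice = dice, sensitivity = sens, specificity = spec,
    precision = prec, iou = iou)
}

#' Per-slice per-class metric table for a predicted volume
#'
#' @param pred integer Z x H x W predicted label volume
#' @param gt integer Z x H x W ground-truth label volume
#' @param n_classes number of classes
#' @param materials material table used to name the classes
#' @return a tibble with one row per (slice, class): confusion counts,
#'   `gt_present`, and the five metrics with `NA` for undefined values
#' @export
metric_table <- function(pred, gt, n_classes = 13L,
                         materials = default_materials()) {
  stopifnot(identical(dim(pred), dim(gt)))
  nz <- dim(pred)[1]
  nm <- class_names(materials)
  rows <- vector("list", nz)
  for (z in seq_len(nz)) {
    counts <- confusion_counts(pred[z, , ], gt[z, , ], n_classes)
    present <- (counts[, "TP"] + counts[, "FN"]) > 0
    mets <- t(vapply(seq_len(n_classes),
                     function(i) per_class_metrics(counts[i, ], present[i]),
                     numeric(5)))
    rows[[z]] <- tibble::tibble(
      slice = z, class_id = 0:(n_classes - 1L),
      class = unname(nm[as.character(0:(n_classes - 1L))]),
      gt_present = unname(present),
      TP = counts[, "TP"], FP = counts[, "FP"],
      FN = counts[, "FN"], TN = counts[, "TN"],
      dice = mets[, 1], sensitivity = mets[, 2], specificity = mets[, 3],
      precision = mets[, 4], iou = mets[, 5])
  }
  do.call(rbind, rows)
}

#' Macro averages over foreground classes
#'
#' Per-class means over slices ignore missing entries; the macro score is the
#' unweighted mean over foreground classes that occur anywhere in the test
#' ground truth (background and wholly absent classes are excluded).
#'
#' @param table a [metric_table()]
#' @return list with `per_class` (tibble of slice-averaged metrics per class)
#'   and `macro` (named numeric of the five macro metrics)
#' @export
macro_average <- function(table) {
  metrics <- c("dice", "sensitivity", "specificity", "precision", "iou")
  ids <- sort(unique(table$class_id))
  per_class <- lapply(ids, function(cid) {
    sub <- table[table$class_id == cid, ]
    means <- vapply(metrics, function(m) {
      v <- sub[[m]]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    tibble::tibble(class_id = cid, class = sub$class[1],
                   present_in_gt = any(sub$gt_present),
                   dice = means[["dice"]], sensitivity = means[["sensitivity"]],
                   specificity = means[["specificity"]],
                   precision = means[["precision"]], iou = means[["iou"]])
  })
  per_class <- do.call(rbind, per_class)
  keep <- per_class$class_id != 0 & per_class$present_in_gt
  macro <- vapply(metrics, function(m) mean(per_class[[m]][keep], na.rm = TRUE),
                  numeric(1))
  list(per_class = per_class, macro = macro)
}

#' Per-slice Dice-error series for a class group
#'
#' For each slice, `e = 1 - mean(Dice)` over the group's classes present in
#' that slice; slices where no group class is present yield `NA` and are
#' omitted from the summary. The summary reports the mean and the half-width
#' `1.96 * SD` (sample SD) of the series, the 95% reference band used in
#' slice-wise error plots.
#'
#' @param per_slice_dice numeric matrix, slices x classes, with class ids
#'   (as character) for column names; `NA` where a class is absent
#' @param groups named list mapping group name to a vector of class ids
#' @return named list per group: `series` (tibble slice/e), `mean`, `sd`,
#'   `half_width`
#' @export
slice_error_series <- function(per_slice_dice, groups) {
  lapply(groups, function(cls) {
    if (length(cls) == 0) stopf("empty class group")
    cols <- intersect(as.character(cls), colnames(per_slice_dice))
    if (length(cols) == 0) stopf("group classes not found in dice matrix")
    e <- apply(per_slice_dice[, cols, drop = FALSE], 1, function(v) {
      if (all(is.na(v))) NA_real_ else 1 - mean(v, na.rm = TRUE)
    })
    ok <- !is.na(e)
    s <- if (sum(ok) > 1) sd(e[ok]) else 0
    list(series = tibble::tibble(slice = seq_along(e), e = e),
         mean = mean(e[ok]), sd = s, half_width = 1.96 * s)
  })
}

#' Mean and sample standard deviation across training seeds
#' @param per_seed_values numeric vector of length >= 2
#' @return named numeric `c(mean, sd)`
#' @export
aggregate_seeds <- function(per_seed_values) {
  if (length(per_seed_values) < 2) stopf("need at least 2 seed values")
  c(mean = mean(per_seed_values), sd = sd(per_seed_values))
}

#' Class groups used in the slice-wise error analysis
#' @return named list with `HA` (HA800/400/200/100) and `iodine` (I15/I10/I5)
#'   class ids
#' @export
material_groups <- function() {
  list(HA = c(5L, 4L, 3L, 2L), iodine = c(8L, 7L, 6L))
}
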