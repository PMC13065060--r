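test_that("the pooled foreground soft Dice matches a loop oracle and hand values", {
  set.seed(10)
  for (i in 1:5) {
    rp <- rand_probs_labels(B = 2, C = 4, H = 4, W = 4)
    expect_equal(soft_dice_fg(rp$probs, rp$onehot),
                 loop_soft_dice_fg(rp$probs, rp$onehot), tolerance = 1e-10)
  }
  # two foreground classes, two voxels, hand-evaluated
  probs <- array(0, c(1, 3, 1, 2))
  probs[1, , 1, 1] <- c(0.1, 0.8, 0.1)
  probs[1, , 1, 2] <- c(0.1, 0.2, 0.7)
  onehot <- array(0, c(1, 3, 1, 2))
  onehot[1, 2, 1, 1] <- 1 # class A
  onehot[1, 3, 1, 2] <- 1 # class B
  expect_equal(soft_dice_fg(probs, onehot), 3.0 / (1.8 + 2 + 1e-6),
               tolerance = 1e-9)
  # perfect overlap and zero overlap limits
  expect_equal(soft_dice_fg(onehot, onehot), 2 * 2 / (2 * 2 + 1e-6))
  bg <- array(0, c(1, 3, 1, 2)); bg[1, 1, , ] <- 1
  expect_lt(soft_dice_fg(bg, onehot), 1e-9)
})

test_that("cross-entropy matches its closed forms and a loop oracle", {
  set.seed(11)
  rp <- rand_probs_labels(B = 2, C = 5, H = 4, W = 4)
  expect_equal(cross_entropy_loss(rp$probs, rp$onehot),
               loop_cross_entropy(rp$probs, rp$onehot), tolerance = 1e-10)
  # p at the true class = 0.5 everywhere -> log 2
  C <- 13
  p <- array((1 - 0.5) / (C - 1), c(1, C, 3, 3))
  lab <- array(sample(0:(C - 1), 9, TRUE), c(1, 3, 3))
  oh <- one_hot(lab, C)
  p[oh == 1] <- 0.5
  expect_equal(cross_entropy_loss(p, oh), log(2), tolerance = 1e-12)
  # uniform 1/13 -> log 13
  pu <- array(1 / C, c(1, C, 3, 3))
  expect_equal(cross_entropy_loss(pu, oh), log(13), tolerance = 1e-12)
})

test_that("the composite loss equals CE + (1 - Dice) and bounds hold", {
  set.seed(12)
  rp <- rand_probs_labels(B = 1, C = 4, H = 4, W = 4)
  l <- composite_loss(rp$logits, rp$labels)
  p <- softmax_channels(rp$logits)
  expect_equal(l, loop_cross_entropy(p, rp$onehot) +
                 (1 - loop_soft_dice_fg(p, rp$onehot)), tolerance = 1e-10)
  expect_gte(l, 0)
  # near-perfect prediction drives both terms to ~0
  big <- rp$onehot * 50
  expect_lt(composite_loss(big, rp$labels), 1e-3)
})

test_that("the loss gradient matches finite differences on the logits", {
  set.seed(13)
  logits <- array(rnorm(1 * 4 * 3 * 3), c(1, 4, 3, 3))
  labels <- array(sample(0:3, 9, TRUE), c(1, 3, 3))
  lg <- spffunet:::composite_loss_grad(logits, labels)
  h <- 1e-6
  for (idx in sample(length(logits), 8)) {
    lp <- logits; lp[idx] <- lp[idx] + h
    lm <- logits; lm[idx] <- lm[idx] - h
    num <- (composite_loss(lp, labels) - composite_loss(lm, labels)) / (2 * h)
    expect_equal(lg$dlogits[idx], num, tolerance = 1e-5)
  }
})

test_that("confusion counts match brute force and conserve the voxel count", {
  set.seed(14)
  for (i in 1:5) {
    pred <- matrix(sample(0:12, 100, TRUE), 10, 10)
    gt <- matrix(sample(0:12, 100, TRUE), 10, 10)
    cc <- confusion_counts(pred, gt)
    expect_identical(cc, loop_confusion(pred, gt))
    expect_true(all(rowSums(cc) == 100))
  }
  perfect <- confusion_counts(gt, gt)
  expect_true(all(perfect[, c("FP", "FN")] == 0))
})

test_that("per-class metrics reproduce the worked example and NaN semantics", {
  m <- per_class_metrics(c(TP = 6, FP = 2, FN = 2, TN = 90), gt_present = TRUE)
  expect_equal(unname(m["dice"]), 0.75)
  expect_equal(unname(m["sensitivity"]), 0.75)
  expect_equal(unname(m["specificity"]), 90 / 92)
  expect_equal(unname(m["precision"]), 0.75)
  expect_equal(unname(m["iou"]), 0.6)
  # absent class, nothing predicted: all missing except specificity = 1
  m0 <- per_class_metrics(c(TP = 0, FP = 0, FN = 0, TN = 100), FALSE)
  expect_true(all(is.na(m0[c("dice", "sensitivity", "precision", "iou")])))
  expect_equal(unname(m0["specificity"]), 1)
  # absent class with false positives: precision and IoU collapse to zero
  m1 <- per_class_metrics(c(TP = 0, FP = 3, FN = 0, TN = 97), FALSE)
  expect_equal(unname(m1["precision"]), 0)
  expect_equal(unname(m1["iou"]), 0)
  expect_true(is.na(m1["dice"]))
})

test_that("metric identities hold on random confusion counts", {
  set.seed(15)
  for (i in 1:20) {
    tp <- sample(0:50, 1); fp <- sample(0:20, 1); fn <- sample(1:20, 1)
    m <- per_class_metrics(c(TP = tp, FP = fp, FN = fn,
                             TN = 200 - tp - fp - fn), TRUE)
    if (!is.na(m["dice"]) && !is.na(m["iou"]))
      expect_equal(unname(m["iou"]), unname(m["dice"] / (2 - m["dice"])),
                   tolerance = 1e-12)
    if (fp == fn && tp + fp > 0)
      expect_equal(unname(m["sensitivity"]), unname(m["precision"]))
  }
})

test_that("macro averaging omits missing values, background and absent classes", {
  tab <- tibble::tibble(
    slice = rep(1:3, each = 3),
    class_id = rep(c(0L, 1L, 2L), 3),
    class = rep(c("background", "a", "b"), 3),
    gt_present = rep(c(TRUE, TRUE, TRUE), 3),
    TP = 1, FP = 0, FN = 0, TN = 1,
    dice = c(1, 0.8, 0.4, 1, 0.6, 0.4, 1, NA, 0.4),
    sensitivity = 1, specificity = 1, precision = 1, iou = 1)
  # class with slice dice {0.8, 0.6, NA} averages to 0.7
  agg <- macro_average(tab)
  expect_equal(agg$per_class$dice[agg$per_class$class_id == 1], 0.7)
  # macro = mean(0.7, 0.4), background's 1.0 ignored
  expect_equal(unname(agg$macro["dice"]), mean(c(0.7, 0.4)))
  # a class absent from all slices is excluded entirely
  tab$gt_present[tab$class_id == 2L] <- FALSE
  tab$dice[tab$class_id == 2L] <- NA
  agg2 <- macro_average(tab)
  expect_equal(unname(agg2$macro["dice"]), 0.7)
})

test_that("slice error series and seed aggregation follow direct arithmetic", {
  dice <- matrix(c(0.9, 0.8, 0.7), 3, 2,
                 dimnames = list(NULL, c("2", "3")))
  s <- slice_error_series(dice, list(HA = c(2L, 3L)))
  expect_equal(s$HA$series$e, c(0.1, 0.2, 0.3))
  expect_equal(s$HA$mean, 0.2)
  expect_equal(s$HA$half_width, 1.96 * 0.1, tolerance = 1e-12)
  expect_true(all(s$HA$series$e >= 0 & s$HA$series$e <= 1))
  const <- matrix(0.9, 4, 1, dimnames = list(NULL, "5"))
  sc <- slice_error_series(const, list(g = 5L))
  expect_equal(sc$g$half_width, 0)
  expect_error(slice_error_series(dice, list(bad = integer(0))), "empty")

  ag <- aggregate_seeds(c(0.70, 0.72, 0.74))
  expect_equal(unname(ag["mean"]), 0.72)
  expect_equal(unname(ag["sd"]), 0.02, tolerance = 1e-12)
  expect_equal(aggregate_seeds(c(0.5, 0.5))[["sd"]], 0)
  expect_equal(aggregate_seeds(c(0.74, 0.70, 0.72))[["mean"]], 0.72)
  expect_error(aggregate_seeds(0.7), "at least 2")
})
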