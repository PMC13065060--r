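test_that("the plateau scheduler halves the rate after the patience breach", {
  sch <- plateau_scheduler(1e-4, factor = 0.5, patience = 5, min_delta = 1e-3)
  sch$step(0.700)
  lrs <- vapply(1:6, function(i) sch$step(0.700), numeric(1))
  expect_equal(lrs[1:5], rep(1e-4, 5)) # within patience
  expect_equal(lrs[6], 5e-5)           # sixth bad epoch triggers the halving
  # counter resets after a reduction
  expect_equal(sch$step(0.700), 5e-5)
  # a real improvement resets the counter
  expect_equal(sch$step(0.710), 5e-5)
  expect_equal(sch$lr(), 5e-5)
})

test_that("early stopping waits out exactly the patience window", {
  es <- early_stopping(patience = 12, min_delta = 1e-3)
  expect_true(es$step(0.700))
  # twelve epochs of sub-threshold improvement (0.0005 < 1e-3)
  for (i in 1:11) {
    es$step(0.7005)
    expect_false(es$should_stop())
  }
  es$step(0.7005)
  expect_true(es$should_stop())
  expect_equal(es$best(), 0.700)
  # an above-threshold improvement resets the window
  es2 <- early_stopping(patience = 3, min_delta = 1e-3)
  es2$step(0.5); es2$step(0.5); es2$step(0.5)
  expect_true(es2$step(0.52))
  expect_false(es2$should_stop())
})

test_that("scan-level splits are disjoint, sized (3,1,1), and deterministic", {
  ids <- sprintf("scan_%03d", 1:5)
  sp <- make_split(ids, seed = 4)
  expect_length(sp$train_scans, 3)
  expect_length(sp$val_scans, 1)
  expect_length(sp$test_scans, 1)
  expect_identical(sort(unname(unlist(sp))), sort(ids))
  expect_equal(anyDuplicated(unlist(sp)), 0L)
  expect_identical(sp, make_split(ids, seed = 4))
  expect_false(identical(sp, make_split(ids, seed = 5)))
  expect_error(make_split(ids[1:2]), "at least 3")
})

test_that("evaluation refuses a scan that was part of training", {
  ck <- list(split = list(train_scans = c("a", "b"), val_scans = "c",
                          test_scans = "d"),
             config = network_config(), net = NULL, seed = 1L)
  expect_error(evaluate_external(ck, "a", tempdir()), "refusing")
})

test_that("a short training run honors the protocol contract", {
  dir <- withr::local_tempdir()
  make_tiny_dataset(dir, n_scans = 3, image_size = 32, n_slices = 2, seed = 1)
  split <- make_split(sprintf("scan_%03d", 1:3), seed = 1)
  cfg <- tiny_config("sp", base = 4, levels = 2, F = 5, C = 13)
  proto <- train_protocol(lr = 1e-3, max_epochs = 2, batch_size = 2,
                          augment = augment_params(g_max = 4))
  fit <- train_model(cfg, proto, split, dir, seed = 2)
  h <- fit$history
  expect_equal(nrow(h), 2)
  expect_true(all(is.finite(h$train_loss)))
  expect_true(all(diff(h$lr) <= 0)) # learning rate never increases
  expect_s3_class(fit$checkpoint$net, "spff_network")
  expect_lte(fit$checkpoint$best_epoch, 2)
  # the checkpointed weights reproduce the best monitor value
  val <- spffunet:::load_scan_set(dir, split$val_scans)
  redo <- spffunet:::val_macro_dice(fit$checkpoint$net, val)
  expect_equal(redo, fit$checkpoint$best_monitor, tolerance = 1e-12)
  # determinism: same seed and data reproduce the first-epoch loss
  fit2 <- train_model(cfg, proto, split, dir, seed = 2)
  expect_equal(fit2$history$train_loss[1], h$train_loss[1], tolerance = 1e-10)
  expect_error(train_model(cfg, proto,
                           list(train_scans = character(0),
                                val_scans = "scan_001",
                                test_scans = "scan_002"),
                           dir, seed = 1), "empty training set")
})

test_that("a perfect predictor scores macro Dice 1 and zero error bands", {
  dir <- withr::local_tempdir()
  make_tiny_dataset(dir, n_scans = 1, image_size = 32, n_slices = 3, seed = 9)
  scan <- read_scan(file.path(dir, "scan_001.rds"))
  gt <- scan$labels$labels
  tab <- metric_table(gt, gt)
  agg <- macro_average(tab)
  expect_equal(unname(agg$macro["dice"]), 1)
  expect_equal(unname(agg$macro["iou"]), 1)
  # all-background predictions score zero on present foreground classes
  tab0 <- metric_table(array(0L, dim(gt)), gt)
  agg0 <- macro_average(tab0)
  expect_equal(unname(agg0$macro["dice"]), 0)
  expect_equal(unname(agg0$macro["specificity"]), 1)
})

test_that("the ablation sweep shares one protocol and reports mean and SD", {
  dir <- withr::local_tempdir()
  make_tiny_dataset(dir, n_scans = 3, image_size = 32, n_slices = 1, seed = 3)
  split <- make_split(sprintf("scan_%03d", 1:3), seed = 3)
  proto <- train_protocol(lr = 1e-3, max_epochs = 1, batch_size = 2)
  ab <- run_ablation(c("blind_control", "plain"), proto, split, dir,
                     seeds = 1:2,
                     config_base = tiny_config("plain", base = 4, levels = 2,
                                               F = 5, C = 13))
  expect_equal(ab$table$variant, c("plain", "blind_control")) # fixed order
  expect_equal(nrow(ab$runs), 4)
  expect_true(all(c("dice_mean", "dice_sd", "iou_mean", "iou_sd") %in%
                    names(ab$table)))
  expect_true(all(is.finite(ab$table$dice_mean)))
  expect_error(run_ablation("resunet", proto, split, dir), "unknown")
})
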