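test_that("every variant maps (B,1,F,H,W) to (B,C,H,W) and preserves energy", {
  set.seed(30)
  x <- array(rnorm(1 * 3 * 16 * 16), c(1, 1, 3, 16, 16))
  for (v in c("plain", "sp", "e_sp", "fg_sp", "spff", "blind_control")) {
    cfg <- tiny_config(v, base = 4, levels = 2, F = 3, C = 5)
    net <- build_network(cfg, seed = 1)
    out <- network_forward(net, x, trace = TRUE)
    expect_identical(dim(out$logits), c(1L, 5L, 16L, 16L))
    f_ext <- vapply(out$shapes, function(s) s[3], numeric(1))
    if (v == "blind_control") expect_true(all(f_ext == 1))
    else expect_true(all(f_ext == 3))
    # softmax over classes sums to one per voxel
    p <- softmax_channels(out$logits)
    sums <- apply(p, c(1, 3, 4), sum)
    expect_lt(max(abs(sums - 1)), 1e-6)
  }
  expect_error(network_config("bogus"), "arg")
  expect_error(network_forward(build_network(tiny_config(), 1),
                               array(0, c(1, 1, 3, 15, 15))), "divisible")
})

test_that("variant module sets are respected and parameter counts ordered", {
  cfgs <- lapply(c("plain", "sp", "e_sp", "fg_sp", "spff"), tiny_config)
  nets <- lapply(cfgs, build_network, seed = 0)
  names(nets) <- vapply(cfgs, `[[`, character(1), "variant")
  has <- function(net, suffix) any(grepl(paste0("\\.", suffix, "$"),
                                         names(net$layers)))
  expect_false(has(nets$plain, "se") || has(nets$plain, "film") ||
                 has(nets$plain, "fg"))
  expect_true(has(nets$sp, "se") && !has(nets$sp, "film"))
  expect_true(has(nets$spff, "se") && has(nets$spff, "film") &&
                has(nets$spff, "fg"))
  counts <- vapply(nets, count_parameters, integer(1))
  expect_lt(counts["plain"], counts["sp"])
  expect_lt(counts["sp"], counts["spff"])
  # counts are architecture-determined, not seed-dependent
  expect_identical(count_parameters(build_network(tiny_config("spff"), 7)),
                   counts[["spff"]])
})

test_that("at default size the full model sits in the low millions of parameters", {
  n_spff <- count_parameters(build_network(network_config("spff"), 0))
  n_plain <- count_parameters(build_network(network_config("plain"), 0))
  expect_gt(n_spff, n_plain)
  expect_gt(n_spff, 1e6)
  expect_lt(n_spff, 1e7)
})

test_that("e_sp equals sp at initialization because FiLM starts as identity", {
  set.seed(31)
  x <- array(rnorm(1 * 3 * 16 * 16), c(1, 1, 3, 16, 16))
  y_sp <- network_forward(build_network(tiny_config("sp"), seed = 5), x)
  y_esp <- network_forward(build_network(tiny_config("e_sp"), seed = 5), x)
  expect_lt(max(abs(y_sp - y_esp)), 1e-5)
})

test_that("analytic gradients match finite differences through the whole net", {
  set.seed(32)
  cfg <- tiny_config("spff", base = 4, levels = 2, F = 3, C = 4)
  net <- build_network(cfg, seed = 3)
  x <- array(rnorm(2 * 3 * 8 * 8), c(2, 1, 3, 8, 8))
  y <- array(sample(0:3, 2 * 8 * 8, TRUE), c(2, 8, 8))
  fwd <- network_forward(net, x, train = TRUE)
  lg <- spffunet:::composite_loss_grad(fwd$logits, y)
  grads <- spffunet:::network_backward(net, lg$dlogits, fwd$cache)
  h <- 1e-5
  lossfn <- function(nn) composite_loss(network_forward(nn, x), y)
  check <- list(c("enc1.conv1", "w"), c("enc1.in2", "gamma"),
                c("enc1.se", "w2"), c("bott.film", "w2"), c("bott.fg", "m_raw"),
                c("up1", "w"), c("down1", "w"), c("dec1.conv2", "b"),
                c("fuse", "w"))
  for (spec in check) {
    nm <- spec[1]; f <- spec[2]
    arr <- net$layers[[nm]][[f]]
    for (idx in sample(length(arr), min(2, length(arr)))) {
      n1 <- net; n1$layers[[nm]][[f]][idx] <- arr[idx] + h
      n2 <- net; n2$layers[[nm]][[f]][idx] <- arr[idx] - h
      num <- (lossfn(n1) - lossfn(n2)) / (2 * h)
      expect_lt(abs(grads[[nm]][[f]][idx] - num) / max(1, abs(num)), 2e-4)
    }
  }
})

test_that("the blind control collapses the spectral signature", {
  # two inputs with equal per-voxel band integral but different shape are
  # indistinguishable to the blind control, not to a spectral variant
  set.seed(33)
  net_b <- build_network(tiny_config("blind_control", F = 4), seed = 1)
  net_s <- build_network(tiny_config("spff", F = 4), seed = 1)
  x1 <- array(0, c(1, 1, 4, 16, 16))
  x2 <- x1
  for (f in 1:4) {
    x1[1, 1, f, , ] <- c(4, 3, 2, 1)[f]
    x2[1, 1, f, , ] <- c(1, 2, 3, 4)[f]
  }
  expect_equal(network_forward(net_b, x1), network_forward(net_b, x2),
               tolerance = 1e-10)
  expect_gt(max(abs(network_forward(net_s, x1) - network_forward(net_s, x2))),
            1e-4)
})
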