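# Shared fixtures: everything is generated in code at test time.

tiny_acq <- function(image_size = 64L, n_slices = 2L, voxel = 1.6,
                     noise_sigma0 = 0.01, bias = 0.05, seed = 0L) {
  acquisition_params(image_size = as.integer(image_size),
                     n_slices = as.integer(n_slices),
                     voxel_size_mm = voxel, noise_sigma0 = noise_sigma0,
                     bias_amplitude = bias, seed = as.integer(seed))
}

tiny_config <- function(variant = "spff", base = 4L, levels = 2L, F = 3L,
                        C = 5L) {
  network_config(variant, base_channels = base, levels = levels, n_bins = F,
                 n_classes = C, se_reduction = 4L, film_enc_dim = 8L)
}

rand_feature <- function(B = 2, C = 3, F = 5, H = 4, W = 4) {
  array(rnorm(B * C * F * H * W), c(B, C, F, H, W))
}

# Random softmax-normalized probability tensor plus matching one-hot truth.
rand_probs_labels <- function(B = 2, C = 4, H = 4, W = 4) {
  logits <- array(rnorm(B * C * H * W), c(B, C, H, W))
  labels <- array(sample(0:(C - 1), B * H * W, replace = TRUE), c(B, H, W))
  list(probs = softmax_channels(logits), labels = labels,
       onehot = one_hot(labels, C), logits = logits)
}

# Independent loop-based oracles for the objective terms.
loop_soft_dice_fg <- function(probs, onehot, eps = 1e-6) {
  d <- dim(probs)
  num <- 0; dp <- 0; dg <- 0
  for (b in seq_len(d[1])) for (cc in 2:d[2]) for (h in seq_len(d[3]))
    for (w in seq_len(d[4])) {
      num <- num + probs[b, cc, h, w] * onehot[b, cc, h, w]
      dp <- dp + probs[b, cc, h, w]
      dg <- dg + onehot[b, cc, h, w]
    }
  2 * num / (dp + dg + eps)
}

loop_cross_entropy <- function(probs, onehot) {
  d <- dim(probs)
  acc <- 0
  for (b in seq_len(d[1])) for (cc in seq_len(d[2])) for (h in seq_len(d[3]))
    for (w in seq_len(d[4]))
      acc <- acc - onehot[b, cc, h, w] * log(max(probs[b, cc, h, w], 1e-12))
  acc / (d[1] * d[3] * d[4])
}

loop_confusion <- function(pred, gt, n_classes = 13L) {
  out <- matrix(0L, n_classes, 4,
                dimnames = list(as.character(0:(n_classes - 1)),
                                c("TP", "FP", "FN", "TN")))
  for (cid in 0:(n_classes - 1)) {
    p <- pred == cid; g <- gt == cid
    out[as.character(cid), ] <- c(sum(p & g), sum(p & !g), sum(!p & g),
                                  sum(!p & !g))
  }
  out
}

# Brute-force FourierGate via the full complex DFT matrix, looped.
naive_fourier_gate <- function(u, mask) {
  d <- dim(u)
  B <- d[1]; C <- d[2]; F <- d[3]
  K <- F %/% 2 + 1
  y <- u
  for (b in seq_len(B)) {
    s <- vapply(seq_len(F), function(f) mean(u[b, , f, , ]), numeric(1))
    S <- vapply(0:(F - 1), function(k)
      sum(s * exp(-2i * pi * k * (0:(F - 1)) / F)), complex(1))
    full_mask <- vapply(0:(F - 1), function(k) mask[min(k, F - k) + 1],
                        numeric(1))
    Sm <- S * full_mask
    w <- vapply(0:(F - 1), function(f)
      Re(sum(Sm * exp(2i * pi * f * (0:(F - 1)) / F)) / F), numeric(1))
    for (f in seq_len(F)) y[b, , f, , ] <- u[b, , f, , ] * w[f]
  }
  y
}

# Multiset of (per-voxel spectral vector, label) pairs as sortable strings.
voxel_pair_multiset <- function(image_slice, label_slice) {
  d <- dim(image_slice)
  keys <- character(d[2] * d[3])
  i <- 1
  for (h in seq_len(d[2])) for (w in seq_len(d[3])) {
    keys[i] <- paste(c(sprintf("%.10f", image_slice[, h, w]),
                       label_slice[h, w]), collapse = "|")
    i <- i + 1
  }
  sort(keys)
}

make_tiny_dataset <- function(dir, n_scans = 3L, image_size = 32L,
                              n_slices = 2L, seed = 0L) {
  acq <- tiny_acq(image_size, n_slices, voxel = 100 / image_size * 0.95,
                  seed = seed)
  simulate_dataset(n_scans, acq, dir)
}
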