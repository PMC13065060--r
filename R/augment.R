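#' Augmentation parameters
#'
#' Training-time augmentation settings. The grid-puzzle size `g` is drawn
#' uniformly from `1..g_max` for every sample and acts only when `g > 1`;
#' flips/rotations act in the image plane only (never along the energy axis);
#' brightness is one multiplicative gain shared across all bins and voxels of
#' a slice (a per-bin gain would corrupt the spectral signature the model must
#' learn); additive Gaussian noise is i.i.d. per voxel per bin. All
#' augmentations are applied only when `train_mode` is `TRUE`.
#'
#' @param g_max maximum grid-puzzle size (default 10)
#' @param flip,rot90 enable flags for flips and quarter-turn rotations
#' @param brightness_range multiplicative gain range `(lo, hi)`
#' @param noise_sigma additive Gaussian sigma (intensity units)
#' @param train_mode logical; augmentations are identity when `FALSE`
#' @return an `augment_params` list
#' @export
augment_params <- function(g_max = 10L, flip = TRUE, rot90 = TRUE,
                           brightness_range = c(0.9, 1.1), noise_sigma = 0.01,
                           train_mode = TRUE) {
  if (g_max < 1) stopf("g_max must be >= 1")
  if (brightness_range[1] > brightness_range[2])
    stopf("brightness_range must satisfy lo <= hi")
  structure(list(g_max = as.integer(g_max), flip = flip, rot90 = rot90,
                 brightness_range = as.numeric(brightness_range),
                 noise_sigma = as.numeric(noise_sigma),
                 train_mode = isTRUE(train_mode)),
            class = "augment_params")
}

#' Grid-puzzle tile permutation
#'
#' Partitions the top-left `g*floor(H/g) x g*floor(W/g)` region of a slice
#' into `g^2` equal tiles and applies a single uniformly random permutation of
#' the tiles to all `F` energy bins and to the label map (the same
#' permutation), leaving any remainder border in place. This destroys global
#' geometry (rod contours, ring layout) while preserving local spectral
#' texture and the per-voxel pairing of spectral vector and label. `g = 1` is
#' the identity.
#'
#' @param image_slice F x H x W numeric array
#' @param label_slice H x W integer matrix
#' @param g grid size (>= 1; must not exceed `min(H, W)`)
#' @param perm optional explicit permutation of `1:g^2` (mapping: output tile
#'   `i` receives input tile `perm[i]`); drawn uniformly when `NULL`
#' @return list with `image`, `label`, and `record` (`g`, tile sizes and the
#'   permutation, sufficient for exact inversion via [invert_grid_puzzle()])
#' @export
grid_puzzle <- function(image_slice, label_slice, g, perm = NULL) {
  d <- dim(image_slice)
  H <- d[2]; W <- d[3]
  if (g < 1) stopf("g must be >= 1")
  if (g > min(H, W)) stopf("g = %d exceeds min(H, W) = %d", g, min(H, W))
  g <- as.integer(g)
  if (is.null(perm)) perm <- if (g == 1L) 1L else sample(g^2)
  record <- list(g = g, th = H %/% g, tw = W %/% g, perm = as.integer(perm))
  if (g == 1L)
    return(list(image = image_slice, label = label_slice, record = record))
  out_img <- image_slice
  out_lab <- label_slice
  th <- record$th; tw <- record$tw
  for (i in seq_len(g^2)) {
    src <- record$perm[i]
    ri <- (i - 1) %/% g; ci <- (i - 1) %% g      # destination tile (row, col)
    rs <- (src - 1) %/% g; cs <- (src - 1) %% g  # source tile
    dr <- ri * th + seq_len(th); dc <- ci * tw + seq_len(tw)
    sr <- rs * th + seq_len(th); sc <- cs * tw + seq_len(tw)
    out_img[, dr, dc] <- image_slice[, sr, sc]
    out_lab[dr, dc] <- label_slice[sr, sc]
  }
  list(image = out_img, label = out_lab, record = record)
}

#' Invert a recorded grid-puzzle permutation
#' @param image_slice,label_slice permuted arrays
#' @param record the `record` returned by [grid_puzzle()]
#' @return list with the restored `image` and `label`
#' @export
invert_grid_puzzle <- function(image_slice, label_slice, record) {
  inv <- order(record$perm)
  out <- grid_puzzle(image_slice, label_slice, record$g, perm = inv)
  out[c("image", "label")]
}

#' Random in-plane flips and quarter-turn rotations
#'
#' Flips and 90-degree rotations act in the (H, W) plane only, identically
#' across all energy bins and the label map; the energy axis is never permuted
#' or reflected. Rotations require H == W.
#'
#' @param image_slice F x H x W array
#' @param label_slice H x W matrix
#' @param flip_h,flip_v,k_rot explicit choices; drawn from the RNG when `NULL`
#' @return list with `image` and `label`
#' @export
spatial_flips_rots <- function(image_slice, label_slice, flip_h = NULL,
                               flip_v = NULL, k_rot = NULL) {
  d <- dim(image_slice)
  if (is.null(flip_h)) flip_h <- runif(1) < 0.5
  if (is.null(flip_v)) flip_v <- runif(1) < 0.5
  if (is.null(k_rot)) k_rot <- sample(0:3, 1)
  if (k_rot %% 4 != 0 && d[2] != d[3]) stopf("rotations require H == W")
  img <- image_slice; lab <- label_slice
  if (flip_h) { img <- img[, , rev(seq_len(d[3])), drop = FALSE]; lab <- lab[, rev(seq_len(d[3])), drop = FALSE] }
  if (flip_v) { img <- img[, rev(seq_len(d[2])), , drop = FALSE]; lab <- lab[rev(seq_len(d[2])), , drop = FALSE] }
  for (r in seq_len(k_rot %% 4)) { # counter-clockwise quarter turn
    img <- aperm(img, c(1, 3, 2))[, rev(seq_len(d[3])), , drop = FALSE]
    lab <- t(lab)[rev(seq_len(ncol(lab))), , drop = FALSE]
  }
  list(image = img, label = lab)
}

#' Brightness scaling and additive Gaussian noise
#'
#' `output = a * image + eps` with `a ~ Uniform(brightness_range)` shared
#' across all bins and voxels of the slice and `eps ~ Normal(0, noise_sigma)`
#' i.i.d. per voxel per bin. Labels are untouched.
#'
#' @param image_slice F x H x W array
#' @param params an [augment_params()]
#' @return jittered image array
#' @export
intensity_jitter <- function(image_slice, params) {
  a <- runif(1, params$brightness_range[1], params$brightness_range[2])
  out <- a * image_slice
  if (params$noise_sigma > 0)
    out <- out + array(rnorm(length(out), 0, params$noise_sigma), dim(out))
  out
}

#' Apply the full training-time augmentation chain to one sample
#'
#' When `params$train_mode`: draws `g` uniformly from `1..g_max`, applies the
#' grid puzzle when `g > 1`, then flips/rotations, then intensity jitter.
#' When not in train mode the sample is returned unchanged (augmentation is
#' disabled for validation and test).
#'
#' @param image_slice F x H x W array
#' @param label_slice H x W matrix
#' @param params an [augment_params()]
#' @return list with `image` and `label`
#' @export
augment_sample <- function(image_slice, label_slice, params) {
  if (!params$train_mode)
    return(list(image = image_slice, label = label_slice))
  g <- sample.int(params$g_max, 1)
  if (g > 1L) {
    gp <- grid_puzzle(image_slice, label_slice, g)
    image_slice <- gp$image; label_slice <- gp$label
  }
  if (params$flip || params$rot90) {
    fr <- spatial_flips_rots(image_slice, label_slice,
                             flip_h = if (params$flip) NULL else FALSE,
                             flip_v = if (params$flip) NULL else FALSE,
                             k_rot = if (params$rot90) NULL else 0L)
    image_slice <- fr$image; label_slice <- fr$label
  }
  image_slice <- intensity_jitter(image_slice, params)
  list(image = image_slice, label = label_slice)
}
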