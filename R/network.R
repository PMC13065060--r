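#' Network configuration for the spectral-preserving segmentation model
#'
#' Defines the architecture variant and every hyperparameter fixing the model
#' graph. Variants: `"plain"` (backbone only), `"sp"` (+ spectral
#' squeeze-excitation), `"e_sp"` (spec-SE + EnergyFiLM), `"fg_sp"` (spec-SE +
#' FourierGate), `"spff"` (all three spectral modules), and
#' `"blind_control"` (averages the input over energy bins and runs the same
#' backbone with F = 1; a validation control that destroys spectral shape
#' while keeping band-integrated magnitude).
#'
#' @param variant architecture variant
#' @param base_channels channels at the first level (widths double per level)
#' @param levels number of resolution levels (`levels - 1` down/up steps)
#' @param n_bins energy bins F
#' @param n_classes output classes C (background + 12 materials)
#' @param se_reduction squeeze-excitation bottleneck reduction
#' @param film_enc_dim sinusoidal encoding dimension for EnergyFiLM
#' @param leaky_slope negative slope of the leaky rectifier
#' @return a `network_config` list
#' @export
network_config <- function(variant = c("spff", "plain", "sp", "e_sp", "fg_sp",
                                       "blind_control"),
                           base_channels = 32L, levels = 4L, n_bins = 5L,
                           n_classes = 13L, se_reduction = 8L,
                           film_enc_dim = 16L, leaky_slope = 0.01) {
  variant <- match.arg(variant)
  if (base_channels < 4) stopf("base_channels must be >= 4")
  if (n_bins < 1 || n_classes < 2) stopf("need n_bins >= 1 and n_classes >= 2")
  structure(list(variant = variant,
                 base_channels = as.integer(base_channels),
                 levels = as.integer(levels),
                 n_bins = as.integer(n_bins),
                 n_classes = as.integer(n_classes),
                 se_reduction = as.integer(se_reduction),
                 film_enc_dim = as.integer(film_enc_dim),
                 leaky_slope = leaky_slope,
                 has_se = variant %in% c("sp", "e_sp", "fg_sp", "spff"),
                 has_film = variant %in% c("e_sp", "spff"),
                 has_fg = variant %in% c("fg_sp", "spff")),
            class = "network_config")
}

# Deterministic per-layer seed so that layers shared between variants get
# identical initial weights for the same top-level seed.
layer_seed <- function(seed, name) {
  u <- utf8ToInt(name)
  (as.numeric(seed) * 100003 + sum(u * seq_along(u)) * 131) %% 2147483647
}

#' Build a spectral-preserving encoder-decoder network
#'
#' A 3-D U-Net whose third axis is the energy-bin axis: double-convolution
#' blocks (3x3x3 kernels, instance norm, leaky rectifier), anisotropic
#' down/upsampling with stride 1x2x2 (never along the energy axis; strided
#' convolution down, transposed convolution up), skip connections at matching
#' resolutions, per-variant spectral modules after each double-conv block in
#' encoder, bottleneck and decoder, and a spectral fusion head (a convolution
#' of kernel extent F x 1 x 1) producing per-voxel class logits.
#'
#' @param config a [network_config()]
#' @param seed RNG seed for weight initialization
#' @return a `spff_network` object
#' @export
build_network <- function(config, seed = 0L) {
  stopifnot(inherits(config, "network_config"))
  L <- config$levels
  ch <- config$base_channels * 2^(0:(L - 1))
  f_int <- if (config$variant == "blind_control") 1L else config$n_bins
  layers <- list()
  add_conv <- function(name, cin, cout, k, stride, pad) {
    ly <- conv_init(cout, cin, k, layer_seed(seed, name))
    ly$type <- "conv"; ly$stride <- stride; ly$pad <- pad
    layers[[name]] <<- ly
  }
  add_in <- function(name, c_ch) {
    ly <- instnorm_init(c_ch); ly$type <- "in"
    layers[[name]] <<- ly
  }
  add_dconv <- function(name, cin, cout) {
    add_conv(paste0(name, ".conv1"), cin, cout, c(3, 3, 3), c(1, 1, 1), c(1, 1, 1))
    add_in(paste0(name, ".in1"), cout)
    add_conv(paste0(name, ".conv2"), cout, cout, c(3, 3, 3), c(1, 1, 1), c(1, 1, 1))
    add_in(paste0(name, ".in2"), cout)
    if (config$has_se) {
      ly <- spec_se_init(cout, config$se_reduction,
                         layer_seed(seed, paste0(name, ".se")))
      ly$type <- "se"; layers[[paste0(name, ".se")]] <<- ly
    }
    if (config$has_film) {
      ly <- energy_film_init(cout, f_int, config$film_enc_dim,
                             layer_seed(seed, paste0(name, ".film")))
      ly$type <- "film"; layers[[paste0(name, ".film")]] <<- ly
    }
    if (config$has_fg) {
      ly <- fourier_gate_init(f_int)
      ly$type <- "fg"; layers[[paste0(name, ".fg")]] <<- ly
    }
  }
  for (i in seq_len(L - 1)) {
    add_dconv(paste0("enc", i), if (i == 1) 1L else ch[i - 1], ch[i])
    add_conv(paste0("down", i), ch[i], ch[i], c(1, 2, 2), c(1, 2, 2), c(0, 0, 0))
  }
  add_dconv("bott", ch[L - 1], ch[L])
  for (i in seq_len(L - 1)) {
    cin <- if (i == L - 1) ch[L] else ch[i + 1]
    nm <- paste0("up", i)
    w <- with_seed_(layer_seed(seed, nm), {
      array(rnorm(cin * ch[i] * 4, 0, sqrt(2 / (cin * 4))),
            c(cin, ch[i], 1, 2, 2))
    })
    layers[[nm]] <- list(type = "convt", w = w, b = numeric(ch[i]),
                         stride = c(1, 2, 2))
    add_dconv(paste0("dec", i), 2L * ch[i], ch[i])
  }
  add_conv("fuse", ch[1], config$n_classes, c(f_int, 1, 1), c(1, 1, 1),
           c(0, 0, 0))
  structure(list(config = config, layers = layers, seed = as.integer(seed)),
            class = "spff_network")
}

param_fields <- c("w", "b", "gamma", "beta", "w1", "b1", "w2", "b2", "m_raw")

#' Count trainable parameters of a network
#' @param network a `spff_network`
#' @return total number of trainable scalar parameters
#' @export
count_parameters <- function(network) {
  tot <- 0
  for (ly in network$layers)
    for (f in intersect(names(ly), param_fields))
      tot <- tot + length(ly[[f]])
  as.integer(tot)
}

#' Spectral fusion head
#'
#' A single convolution with kernel extent F x 1 x 1 and no padding along the
#' energy axis collapses the preserved energy axis into per-voxel class
#' logits; the singleton energy axis is then dropped.
#'
#' @param features feature tensor `(B, c, F, H, W)` at full spatial resolution
#' @param layer fusion layer record (fields `w`, `b`; kernel `F x 1 x 1`)
#' @return logits array `(B, C, H, W)`
#' @export
fuse_spectral <- function(features, layer) {
  kf <- dim(layer$w)[3]
  if (dim(features)[3] != kf)
    stopf("fusion head expects energy extent %d, got %d", kf, dim(features)[3])
  y5 <- conv_fwd(layer, features, c(1, 1, 1), c(0, 0, 0))
  array(y5, dim(y5)[c(1, 2, 4, 5)])
}

#' Hard labels from logits
#'
#' Per-voxel argmax over classes; ties are broken toward the lowest class
#' index, so the result is deterministic.
#'
#' @param logits `(B, C, H, W)` array
#' @return `(B, H, W)` integer array of class ids `0..C-1`
#' @export
predict_labels <- function(logits) {
  d <- dim(logits)
  best <- logits[, 1, , ]
  idx <- array(0L, d[c(1, 3, 4)])
  for (cc in seq_len(d[2])[-1]) {
    v <- logits[, cc, , ]
    take <- v > best
    best[take] <- v[take]
    idx[take] <- cc - 1L
  }
  array(idx, d[c(1, 3, 4)])
}

# -- forward ---------------------------------------------------------------

dconv_forward <- function(net, name, x, cache, shapes) {
  ly <- net$layers; cfg <- net$config
  sl <- cfg$leaky_slope
  a1 <- conv_fwd(ly[[paste0(name, ".conv1")]], x, c(1, 1, 1), c(1, 1, 1))
  n1 <- instnorm_fwd(ly[[paste0(name, ".in1")]], a1)
  r1 <- leaky_fwd(n1$y, sl)
  a2 <- conv_fwd(ly[[paste0(name, ".conv2")]], r1, c(1, 1, 1), c(1, 1, 1))
  n2 <- instnorm_fwd(ly[[paste0(name, ".in2")]], a2)
  out <- leaky_fwd(n2$y, sl)
  se_c <- film_c <- fg_c <- NULL
  if (cfg$has_se) {
    se_c <- spec_se(out, ly[[paste0(name, ".se")]], sl, keep_cache = TRUE)
    out <- se_c$y
  }
  if (cfg$has_film) {
    film_c <- energy_film(out, ly[[paste0(name, ".film")]], sl,
                          keep_cache = TRUE)
    out <- film_c$y
  }
  if (cfg$has_fg) {
    fg <- ly[[paste0(name, ".fg")]]
    fg_c <- fourier_gate(out, fg$m_raw^2, basis = fg$A, keep_cache = TRUE)
    out <- fg_c$y
  }
  if (!is.null(cache))
    cache[[name]] <- list(x = x, n1 = n1, n1y = n1$y, r1 = r1, n2 = n2,
                          n2y = n2$y, se = se_c, film = film_c, fg = fg_c)
  if (!is.null(shapes)) shapes[[name]] <- dim(out)
  out
}

#' Forward pass of the network
#'
#' @param net a `spff_network`
#' @param x input tensor `(B, 1, F, H, W)`; H and W must be divisible by
#'   `2^(levels-1)`
#' @param train keep intermediates for the backward pass
#' @param trace record the shape of every intermediate feature tensor
#' @return logits `(B, C, H, W)`; with `train` or `trace`, a list with
#'   `logits` plus `cache` / `shapes`
#' @export
network_forward <- function(net, x, train = FALSE, trace = FALSE) {
  cfg <- net$config; L <- cfg$levels
  d <- dim(x)
  if (length(d) != 5 || d[2] != 1) stopf("input must be (B, 1, F, H, W)")
  div <- 2^(L - 1)
  if (d[4] %% div != 0 || d[5] %% div != 0)
    stopf("H and W must be divisible by %d", div)
  if (cfg$variant == "blind_control" && d[3] > 1) {
    m <- array(x, c(d[1], d[3], d[4] * d[5]))
    s <- m[, 1, , drop = FALSE] * 0
    for (f in seq_len(d[3])) s <- s + m[, f, , drop = FALSE]
    x <- array(s / d[3], c(d[1], 1, 1, d[4], d[5]))
  } else if (cfg$variant != "blind_control" && d[3] != cfg$n_bins) {
    stopf("input has %d bins, network expects %d", d[3], cfg$n_bins)
  }
  cache <- if (train) new.env(parent = emptyenv()) else NULL
  shapes <- if (trace) new.env(parent = emptyenv()) else NULL
  note <- function(nm, s) if (!is.null(shapes)) shapes[[nm]] <- s
  s <- x
  skips <- vector("list", L - 1)
  for (i in seq_len(L - 1)) {
    s <- dconv_forward(net, paste0("enc", i), s, cache, shapes)
    skips[[i]] <- s
    if (train) cache[[paste0("down", i, ".x")]] <- s
    s <- conv_fwd(net$layers[[paste0("down", i)]], s, c(1, 2, 2), c(0, 0, 0))
    note(paste0("down", i), dim(s))
  }
  s <- dconv_forward(net, "bott", s, cache, shapes)
  for (i in rev(seq_len(L - 1))) {
    if (train) cache[[paste0("up", i, ".x")]] <- s
    s <- convT_fwd(net$layers[[paste0("up", i)]], s, c(1, 2, 2))
    note(paste0("up", i), dim(s))
    s <- cat_channels(skips[[i]], s)
    s <- dconv_forward(net, paste0("dec", i), s, cache, shapes)
  }
  if (train) cache[["fuse.x"]] <- s
  logits <- fuse_spectral(s, net$layers[["fuse"]])
  if (!train && !trace) return(logits)
  out <- list(logits = logits)
  if (train) out$cache <- cache
  if (trace) out$shapes <- as.list(shapes)
  out
}

# -- backward --------------------------------------------------------------

dconv_backward <- function(net, name, dy, cache, grads, need_dx = TRUE) {
  ly <- net$layers; cfg <- net$config; sl <- cfg$leaky_slope
  cc <- cache[[name]]
  if (cfg$has_fg) {
    fg <- ly[[paste0(name, ".fg")]]
    bw <- fourier_gate_bwd(fg$m_raw^2, cc$fg, dy)
    grads[[paste0(name, ".fg")]] <- list(m_raw = 2 * fg$m_raw * bw$dmask)
    dy <- bw$dx
  }
  if (cfg$has_film) {
    bw <- energy_film_bwd(ly[[paste0(name, ".film")]], cc$film, dy, sl)
    grads[[paste0(name, ".film")]] <- bw[c("w1", "b1", "w2", "b2")]
    dy <- bw$dx
  }
  if (cfg$has_se) {
    bw <- spec_se_bwd(ly[[paste0(name, ".se")]], cc$se, dy, sl)
    grads[[paste0(name, ".se")]] <- bw[c("w1", "b1", "w2", "b2")]
    dy <- bw$dx
  }
  dy <- leaky_bwd(cc$n2y, dy, sl)
  bw <- instnorm_bwd(ly[[paste0(name, ".in2")]], cc$n2, dy)
  grads[[paste0(name, ".in2")]] <- list(gamma = bw$dgamma, beta = bw$dbeta)
  bw <- conv_bwd(ly[[paste0(name, ".conv2")]], cc$r1, bw$dx, c(1, 1, 1),
                 c(1, 1, 1))
  grads[[paste0(name, ".conv2")]] <- list(w = bw$dw, b = bw$db)
  dy <- leaky_bwd(cc$n1y, bw$dx, sl)
  bw <- instnorm_bwd(ly[[paste0(name, ".in1")]], cc$n1, dy)
  grads[[paste0(name, ".in1")]] <- list(gamma = bw$dgamma, beta = bw$dbeta)
  bw <- conv_bwd(ly[[paste0(name, ".conv1")]], cc$x, bw$dx, c(1, 1, 1),
                 c(1, 1, 1), need_dx = need_dx)
  grads[[paste0(name, ".conv1")]] <- list(w = bw$dw, b = bw$db)
  bw$dx
}

# Returns an environment mapping layer name -> gradient record.
network_backward <- function(net, dlogits, cache) {
  cfg <- net$config; L <- cfg$levels
  grads <- new.env(parent = emptyenv())
  d4 <- dim(dlogits)
  d5 <- array(dlogits, c(d4[1], d4[2], 1, d4[3], d4[4]))
  bw <- conv_bwd(net$layers[["fuse"]], cache[["fuse.x"]], d5, c(1, 1, 1),
                 c(0, 0, 0))
  grads[["fuse"]] <- list(w = bw$dw, b = bw$db)
  ds <- bw$dx
  dskip <- vector("list", L - 1)
  for (i in seq_len(L - 1)) {
    ds <- dconv_backward(net, paste0("dec", i), ds, cache, grads)
    nsk <- dim(ds)[2] / 2
    dskip[[i]] <- ds[, seq_len(nsk), , , , drop = FALSE]
    dup <- ds[, nsk + seq_len(nsk), , , , drop = FALSE]
    bw <- convT_bwd(net$layers[[paste0("up", i)]],
                    cache[[paste0("up", i, ".x")]], dup, c(1, 2, 2))
    grads[[paste0("up", i)]] <- list(w = bw$dw, b = bw$db)
    ds <- bw$dx
  }
  ds <- dconv_backward(net, "bott", ds, cache, grads)
  for (i in rev(seq_len(L - 1))) {
    bw <- conv_bwd(net$layers[[paste0("down", i)]],
                   cache[[paste0("down", i, ".x")]], ds, c(1, 2, 2),
                   c(0, 0, 0))
    grads[[paste0("down", i)]] <- list(w = bw$dw, b = bw$db)
    ds <- bw$dx + dskip[[i]]
    ds <- dconv_backward(net, paste0("enc", i), ds, cache, grads,
                         need_dx = i > 1)
  }
  grads
}

#' @export
print.spff_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<spff_network> variant=%s levels=%d base=%d F=%d C=%d params=%s\n",
              cfg$variant, cfg$levels, cfg$base_channels, cfg$n_bins,
              cfg$n_classes, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}
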