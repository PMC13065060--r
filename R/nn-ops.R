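# Low-level tensor ops for the spectral-preserving network.
#
# All feature tensors are R arrays with dim c(B, C, F, H, W). Convolutions run
# through the compiled im2col+gemm kernels; everything else is vectorized R.
# The leading-dims layout is chosen so that per-(b,c) and per-(b,c,f)
# reductions are plain matrix reshapes.

conv_init <- function(c_out, c_in, k, seed, zero = FALSE) {
  fan_in <- c_in * prod(k)
  w <- if (zero) array(0, c(c_out, c_in, k)) else
    with_seed_(seed, array(rnorm(c_out * c_in * prod(k), 0,
                                 sqrt(2 / fan_in)), c(c_out, c_in, k)))
  list(w = w, b = numeric(c_out))
}

conv_fwd <- function(layer, x, stride, pad) {
  .conv3d_fwd(x, dim(x), layer$w, dim(layer$w), layer$b,
              as.integer(stride), as.integer(pad))
}

conv_bwd <- function(layer, x, dy, stride, pad, need_dx = TRUE) {
  g <- .conv3d_bwd_filter(x, dim(x), dy, dim(dy), dim(layer$w),
                          as.integer(stride), as.integer(pad))
  dx <- if (need_dx)
    .conv3d_bwd_data(dy, dim(dy), layer$w, dim(layer$w), dim(x),
                     as.integer(stride), as.integer(pad)) else NULL
  list(dx = dx, dw = g$dw, db = g$db)
}

# Transposed convolution with kernel == stride (no overlap); weight layout
# (C_in, C_out, kf, kh, kw).
convT_fwd <- function(layer, x, stride) {
  d <- dim(x); k <- dim(layer$w)[3:5]
  ydim <- c(d[1], dim(layer$w)[2],
            (d[3] - 1) * stride[1] + k[1],
            (d[4] - 1) * stride[2] + k[2],
            (d[5] - 1) * stride[3] + k[3])
  y <- .conv3d_bwd_data(x, dim(x), layer$w, dim(layer$w),
                        as.integer(ydim), as.integer(stride),
                        c(0L, 0L, 0L))
  for (cc in seq_len(ydim[2])) y[, cc, , , ] <- y[, cc, , , ] + layer$b[cc]
  y
}

convT_bwd <- function(layer, x, dy, stride) {
  dx <- .conv3d_fwd(dy, dim(dy), layer$w, dim(layer$w),
                    numeric(dim(layer$w)[1]), as.integer(stride),
                    c(0L, 0L, 0L))
  g <- .conv3d_bwd_filter(dy, dim(dy), x, dim(x), dim(layer$w),
                          as.integer(stride), c(0L, 0L, 0L))
  db <- vapply(seq_len(dim(dy)[2]), function(cc) sum(dy[, cc, , , ]),
               numeric(1))
  list(dx = dx, dw = g$dw, db = db)
}

# Instance normalization: per (sample, channel) over the (F, H, W) extent.
instnorm_init <- function(c_ch) list(gamma = rep(1, c_ch), beta = numeric(c_ch))

instnorm_fwd <- function(layer, x, eps = 1e-5) {
  d <- dim(x)
  out <- .instnorm_fwd(x, d[1] * d[2], prod(d[3:5]), layer$gamma,
                       layer$beta, d[1], eps)
  out$x <- x
  out
}

instnorm_bwd <- function(layer, cache, dy) {
  d <- dim(dy)
  bw <- .instnorm_bwd(cache$x, dy, cache$mu, cache$istd, layer$gamma, d[1],
                      prod(d[3:5]))
  list(dx = bw$dx, dgamma = as.numeric(bw$dgamma),
       dbeta = as.numeric(bw$dbeta))
}

leaky_fwd <- function(x, slope) x * (slope + (1 - slope) * (x > 0))

leaky_bwd <- function(x, dy, slope) dy * (slope + (1 - slope) * (x > 0))

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2] + db[2], da[3], da[4], da[5]))
  out[, seq_len(da[2]), , , ] <- a
  out[, da[2] + seq_len(db[2]), , , ] <- b
  out
}

sigmoid_ <- function(x) 1 / (1 + exp(-x))
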