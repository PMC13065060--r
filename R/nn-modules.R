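# The three spectral modules. Each is exposed as a functional op on a feature
# tensor u of dim c(B, C_feat, F, H, W) plus a parameter record, with an
# internal backward used by the training loop.

#' Initialize spectral squeeze-excitation parameters
#' @param c_feat feature channels
#' @param reduction bottleneck reduction ratio (hidden width
#'   `max(1, c_feat / reduction)`)
#' @param seed RNG seed for the initialization
#' @return parameter record (two-layer excitation MLP, shared across energy
#'   indices)
#' @export
spec_se_init <- function(c_feat, reduction = 8L, seed = 0L) {
  hid <- max(1L, c_feat %/% reduction)
  with_seed_(seed, list(
    w1 = matrix(rnorm(hid * c_feat, 0, sqrt(2 / c_feat)), hid, c_feat),
    b1 = numeric(hid),
    w2 = matrix(rnorm(c_feat * hid, 0, sqrt(2 / hid)), c_feat, hid),
    b2 = numeric(c_feat)))
}

#' Spectral squeeze-excitation channel reweighting
#'
#' Squeeze = mean over the spatial extent (H, W) only, yielding a
#' `(B, C_feat, F)` descriptor, so the energy axis survives the squeeze.
#' Excitation = a two-layer bottleneck (leaky activation, then sigmoid)
#' applied per energy index with weights shared across energy indices. The
#' resulting per-(channel, bin) gate in (0, 1) rescales `u`.
#'
#' @param u feature tensor, dim `c(B, C_feat, F, H, W)`
#' @param params record from [spec_se_init()]
#' @param leaky_slope negative slope of the hidden activation
#' @param keep_cache return intermediates for the backward pass
#' @return gated tensor (or list with `y` and cache when `keep_cache`)
#' @export
spec_se <- function(u, params, leaky_slope = 0.01, keep_cache = FALSE) {
  d <- dim(u)
  B <- d[1]; C <- d[2]; F <- d[3]; hw <- d[4] * d[5]
  z <- rowMeans(matrix(u, B * C * F, hw))          # (b,c,f) descriptor
  Z <- matrix(aperm(array(z, c(B, C, F)), c(2, 1, 3)), C, B * F)
  h_pre <- params$w1 %*% Z + params$b1
  h <- leaky_fwd(h_pre, leaky_slope)
  a_pre <- params$w2 %*% h + params$b2
  gate <- sigmoid_(a_pre)                           # C x (B*F)
  gv <- as.vector(aperm(array(gate, c(C, B, F)), c(2, 1, 3)))
  y <- u * gv
  if (!keep_cache) return(y)
  list(y = y, u = u, Z = Z, h_pre = h_pre, h = h, gate = gate, gv = gv)
}

spec_se_bwd <- function(params, cache, dy, leaky_slope = 0.01) {
  d <- dim(dy)
  B <- d[1]; C <- d[2]; F <- d[3]; hw <- d[4] * d[5]
  dgate_bcf <- rowSums(matrix(cache$u * dy, B * C * F, hw))
  dgate <- matrix(aperm(array(dgate_bcf, c(B, C, F)), c(2, 1, 3)), C, B * F)
  da <- dgate * cache$gate * (1 - cache$gate)
  dw2 <- da %*% t(cache$h)
  db2 <- rowSums(da)
  dh <- t(params$w2) %*% da
  dhp <- dh * (leaky_slope + (1 - leaky_slope) * (cache$h_pre > 0))
  dw1 <- dhp %*% t(cache$Z)
  db1 <- rowSums(dhp)
  dZ <- t(params$w1) %*% dhp                        # C x (B*F)
  dz_bcf <- as.vector(aperm(array(dZ, c(C, B, F)), c(2, 1, 3)))
  dx <- dy * cache$gv + dz_bcf / hw
  list(dx = dx, w1 = dw1, b1 = db1, w2 = dw2, b2 = db2)
}

# Sinusoidal positional encoding of the energy index, (F x d).
energy_encoding <- function(n_bins, d) {
  stopifnot(d %% 2 == 0)
  f <- 0:(n_bins - 1)
  k <- 0:(d / 2 - 1)
  freq <- 1 / 10000^(2 * k / d)
  enc <- matrix(0, n_bins, d)
  enc[, 2 * k + 1] <- sin(outer(f, freq))
  enc[, 2 * k + 2] <- cos(outer(f, freq))
  enc
}

#' Initialize EnergyFiLM parameters
#'
#' The final layer is zero-initialized and the scale is produced as
#' `gamma = 1 + delta_gamma`, so the module is exactly the identity at
#' initialization.
#'
#' @param c_feat feature channels
#' @param n_bins energy bins F
#' @param enc_dim sinusoidal encoding dimension (even)
#' @param seed RNG seed
#' @return parameter record (encoding buffer plus two-layer perceptron)
#' @export
energy_film_init <- function(c_feat, n_bins, enc_dim = 16L, seed = 0L) {
  hid <- enc_dim
  with_seed_(seed, list(
    enc = energy_encoding(n_bins, enc_dim),
    w1 = matrix(rnorm(hid * enc_dim, 0, sqrt(2 / enc_dim)), hid, enc_dim),
    b1 = numeric(hid),
    w2 = matrix(0, 2 * c_feat, hid),
    b2 = numeric(2 * c_feat)))
}

#' Per-energy feature-wise affine modulation (FiLM)
#'
#' Each energy index f is embedded with a sinusoidal positional encoding; a
#' two-layer perceptron maps the encoding to `(gamma_f, beta_f)` per feature
#' channel, and the output voxel is `gamma[c,f] * u[b,c,f,h,w] + beta[c,f]`,
#' broadcast across (H, W) and batch.
#'
#' @inheritParams spec_se
#' @param params record from [energy_film_init()]
#' @param gamma_override,beta_override optional fixed `C x F` matrices (or
#'   scalars) replacing the predicted modulation, for controlled probes
#' @return modulated tensor (or list with cache when `keep_cache`)
#' @export
energy_film <- function(u, params, leaky_slope = 0.01, keep_cache = FALSE,
                        gamma_override = NULL, beta_override = NULL) {
  d <- dim(u)
  B <- d[1]; C <- d[2]; F <- d[3]
  p_pre <- params$w1 %*% t(params$enc) + params$b1   # hid x F
  p <- leaky_fwd(p_pre, leaky_slope)
  out2 <- params$w2 %*% p + params$b2                # 2C x F
  gamma <- 1 + out2[seq_len(C), , drop = FALSE]
  beta <- out2[C + seq_len(C), , drop = FALSE]
  if (!is.null(gamma_override)) gamma <- matrix(gamma_override, C, F)
  if (!is.null(beta_override)) beta <- matrix(beta_override, C, F)
  gv <- rep(as.vector(gamma), each = B)
  bv <- rep(as.vector(beta), each = B)
  y <- u * gv + bv
  if (!keep_cache) return(y)
  list(y = y, u = u, p_pre = p_pre, p = p, gv = gv)
}

energy_film_bwd <- function(params, cache, dy, leaky_slope = 0.01) {
  d <- dim(dy)
  B <- d[1]; C <- d[2]; F <- d[3]; hw <- d[4] * d[5]
  s_ud <- rowSums(matrix(cache$u * dy, B * C * F, hw))
  s_d <- rowSums(matrix(dy, B * C * F, hw))
  dgamma <- apply(array(s_ud, c(B, C, F)), c(2, 3), sum)  # C x F
  dbeta <- apply(array(s_d, c(B, C, F)), c(2, 3), sum)
  dout2 <- rbind(dgamma, dbeta)                           # 2C x F
  dw2 <- dout2 %*% t(cache$p)
  db2 <- rowSums(dout2)
  dp <- t(params$w2) %*% dout2
  dpp <- dp * (leaky_slope + (1 - leaky_slope) * (cache$p_pre > 0))
  dw1 <- dpp %*% params$enc
  db1 <- rowSums(dpp)
  dx <- dy * cache$gv
  list(dx = dx, w1 = dw1, b1 = db1, w2 = dw2, b2 = db2)
}

# Real linear transfer basis of the Fourier gate: w = sum_k mask[k] * A_k s,
# where A_k folds the Hermitian-symmetric pair of DFT coefficient k. Built
# once per module from the DFT matrix.
fourier_gate_basis <- function(n_bins) {
  K <- n_bins %/% 2 + 1
  j <- 0:(n_bins - 1)
  Fmat <- exp(-2i * pi * outer(j, j) / n_bins)
  lapply(seq_len(K) - 1L, function(k) {
    mask_full <- as.numeric(pmin(j, n_bins - j) == k)
    Re(Conj(Fmat) %*% diag(mask_full) %*% Fmat) / n_bins
  })
}

#' Initialize FourierGate parameters
#'
#' The learnable magnitude mask is parameterized as `mask = m_raw^2` (kept
#' nonnegative) and initialized to all ones, at which point the
#' rFFT/mask/inverse round trip is the identity on the spectral profile.
#'
#' @param n_bins energy bins F
#' @return parameter record with `m_raw` and the fixed transfer basis
#' @export
fourier_gate_init <- function(n_bins) {
  list(m_raw = rep(1, n_bins %/% 2 + 1), A = fourier_gate_basis(n_bins))
}

#' Fourier-domain spectral gating
#'
#' Computes the global spectral profile `s[b, f]` (mean of `u` over channels
#' and space), takes the real-input discrete Fourier transform along the
#' energy axis, multiplies the `floor(F/2) + 1` coefficients elementwise by a
#' nonnegative mask, inverse-transforms back to length F, and multiplies `u`
#' by the resulting gate `w` broadcast as `(B, 1, F, 1, 1)`.
#'
#' @inheritParams spec_se
#' @param mask nonnegative numeric vector of length `floor(F/2) + 1`
#' @param basis optional precomputed [fourier_gate_basis()]
#' @return gated tensor (or list with cache and the gate `w` when
#'   `keep_cache`)
#' @export
fourier_gate <- function(u, mask, basis = NULL, keep_cache = FALSE) {
  d <- dim(u)
  B <- d[1]; C <- d[2]; F <- d[3]; hw <- d[4] * d[5]
  if (length(mask) != F %/% 2 + 1) stopf("mask must have length floor(F/2)+1")
  if (is.null(basis)) basis <- fourier_gate_basis(F)
  z <- rowMeans(matrix(u, B * C * F, hw))
  s <- apply(array(z, c(B, C, F)), c(1, 3), mean)    # B x F spectral profile
  s <- matrix(s, B, F)
  M <- Reduce(`+`, Map(`*`, as.list(mask), basis))
  w <- s %*% t(M)                                    # B x F gate
  wv <- as.vector(aperm(array(w, c(B, F, C)), c(1, 3, 2)))
  y <- u * wv
  if (!keep_cache) return(y)
  list(y = y, u = u, s = s, w = w, wv = wv, M = M, basis = basis)
}

fourier_gate_bwd <- function(mask, cache, dy) {
  d <- dim(dy)
  B <- d[1]; C <- d[2]; F <- d[3]; hw <- d[4] * d[5]
  t1 <- rowSums(matrix(cache$u * dy, B * C * F, hw))
  dw <- apply(array(t1, c(B, C, F)), c(1, 3), sum)   # B x F
  dw <- matrix(dw, B, F)
  dmask <- vapply(seq_along(mask), function(k) {
    sum(dw * (cache$s %*% t(cache$basis[[k]])))
  }, numeric(1))
  ds <- dw %*% cache$M                               # B x F
  dsv <- as.vector(aperm(array(ds, c(B, F, C)), c(1, 3, 2)))
  dx <- dy * cache$wv + dsv / (C * hw)
  list(dx = dx, dmask = dmask)
}
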