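#' Channel-wise softmax for a logits tensor
#'
#' @param logits B x C x H x W array of per-voxel class scores
#' @return array of the same shape; per-voxel probabilities summing to 1
#' @export
softmax_channels <- function(logits) {
  d <- dim(logits); C <- d[2]
  m <- logits[, 1, , , drop = FALSE]
  for (cc in seq_len(C)[-1]) m <- pmax(m, logits[, cc, , , drop = FALSE])
  out <- logits
  s <- 0 # per-voxel normalizer, kept as a plain vector (B*H*W)
  for (cc in seq_len(C)) {
    e <- as.vector(exp(logits[, cc, , ] - m[, 1, , ]))
    out[, cc, , ] <- e
    s <- s + e
  }
  for (cc in seq_len(C)) out[, cc, , ] <- as.vector(out[, cc, , ]) / s
  out
}

#' One-hot encoding of an integer label map
#' @param labels B x H x W integer array with values in `0..n_classes-1`
#' @param n_classes number of classes (default 13)
#' @return B x n_classes x H x W array
#' @export
one_hot <- function(labels, n_classes = 13L) {
  d <- dim(labels)
  arr <- array(0, c(d[1], n_classes, d[2], d[3]))
  for (cc in 0:(n_classes - 1L)) arr[, cc + 1L, , ] <- (labels == cc) * 1
  arr
}

#' Pooled foreground soft-Dice score
#'
#' The soft Dice used inside the training objective: sums of `p*g`, `p` and
#' `g` are pooled over *all* foreground classes (background excluded) before
#' the ratio, `2 * sum(p*g) / (sum(p) + sum(g) + epsilon)`. A per-class
#' averaged alternative is available behind `per_class = TRUE` but is not used
#' by the default objective.
#'
#' @param probs B x C x H x W probabilities (rows summing to 1 over C)
#' @param onehot B x C x H x W one-hot ground truth
#' @param epsilon stabilizer in the denominator (default 1e-6)
#' @param per_class average per-class Dice over foreground classes instead of
#'   pooling (non-default variant)
#' @return scalar in `[0, 1]`
#' @export
soft_dice_fg <- function(probs, onehot, epsilon = 1e-6, per_class = FALSE) {
  if (!identical(dim(probs), dim(onehot))) stopf("probs/onehot shape mismatch")
  C <- dim(probs)[2]
  fg <- seq_len(C)[-1]
  if (per_class) {
    vals <- vapply(fg, function(cc) {
      i <- sum(probs[, cc, , ] * onehot[, cc, , ])
      (2 * i) / (sum(probs[, cc, , ]) + sum(onehot[, cc, , ]) + epsilon)
    }, numeric(1))
    return(mean(vals))
  }
  i <- sum(probs[, fg, , ] * onehot[, fg, , ])
  (2 * i) / (sum(probs[, fg, , ]) + sum(onehot[, fg, , ]) + epsilon)
}

#' Multiclass cross-entropy over all classes
#'
#' `-(1/N) * sum_i sum_c g[c,i] * log(p[c,i])` with `N = B*H*W` output voxels
#' and the sum running over all classes, background included. Probabilities
#' are clipped at `1e-12` before the logarithm.
#'
#' @inheritParams soft_dice_fg
#' @return nonnegative scalar
#' @export
cross_entropy_loss <- function(probs, onehot) {
  if (!identical(dim(probs), dim(onehot))) stopf("probs/onehot shape mismatch")
  d <- dim(probs)
  n <- d[1] * d[3] * d[4]
  -sum(onehot * log(pmax(probs, 1e-12))) / n
}

#' Composite training objective: cross-entropy plus one-minus-Dice
#'
#' `loss = CE(softmax(logits), g) + (1 - Dice_fg(softmax(logits), g))` where
#' the Dice term pools over foreground classes (see [soft_dice_fg()]) and the
#' cross-entropy runs over all 13 classes.
#'
#' @param logits B x C x H x W logits
#' @param labels B x H x W integer labels in `0..C-1`
#' @param epsilon Dice stabilizer
#' @return scalar loss
#' @export
composite_loss <- function(logits, labels, epsilon = 1e-6) {
  C <- dim(logits)[2]
  p <- softmax_channels(logits)
  g <- one_hot(labels, C)
  cross_entropy_loss(p, g) + (1 - soft_dice_fg(p, g, epsilon))
}

# Loss value plus gradient w.r.t. logits, for the training loop.
composite_loss_grad <- function(logits, labels, epsilon = 1e-6) {
  d <- dim(logits); C <- d[2]
  n <- d[1] * d[3] * d[4]
  p <- softmax_channels(logits)
  g <- one_hot(labels, C)
  ce <- cross_entropy_loss(p, g)
  fg <- seq_len(C)[-1]
  i_fg <- sum(p[, fg, , ] * g[, fg, , ])
  u <- sum(p[, fg, , ]) + sum(g[, fg, , ]) + epsilon
  dice <- 2 * i_fg / u
  # d(1 - Dice)/dp, nonzero on foreground classes only
  dldp <- array(0, d)
  dldp[, fg, , ] <- -(2 * g[, fg, , ] - dice) / u
  # chain through softmax, plus the direct CE-through-softmax term (p - g)/N
  inner <- 0 # per-voxel inner product, plain vector (B*H*W)
  for (cc in seq_len(C))
    inner <- inner + as.vector(dldp[, cc, , ]) * as.vector(p[, cc, , ])
  dlogits <- p * dldp
  for (cc in seq_len(C)) dlogits[, cc, , ] <- as.vector(dlogits[, cc, , ]) -
    as.vector(p[, cc, , ]) * inner
  dlogits <- dlogits + (p - g) / n
  list(loss = ce + (1 - dice), dlogits = dlogits, ce = ce, dice = dice)
}
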