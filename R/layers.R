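# Low-level network primitives.  Activations are stored as (B*H*W) x C
# matrices whose rows are ordered like an R array of dim c(B, H, W): image
# index fastest, then row, then column.  1x1 convolutions are then plain
# matrix products (BLAS); spatial convolutions call the C++ kernels.

#' ReLU6 activation
#'
#' `min(max(0, x), 6)`, applied element-wise.  The upper clamp keeps
#' activations in a range that is robust under low-precision arithmetic.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape.
#' @export
relu6 <- function(x) pmin(pmax(x, 0), 6)

nn_relu6_fwd <- function(X) cpp_relu6_fwd(X)

nn_relu6_bwd <- function(dY, cache) cpp_relu6_bwd(dY, cache$mask)

# Batch normalization over all rows (batch x spatial), per column (channel).
nn_bn_fwd <- function(X, g, b, training, buffers, key, momentum = 0.1, eps = 1e-5) {
  if (training) {
    st <- cpp_bn_stats(X)
    ivar <- 1 / sqrt(st$var + eps)
    ba <- cpp_bn_apply(X, st$mean, ivar, g, b)
    if (!is.null(buffers)) {
      rm0 <- buffers[[key]]$mean; rv0 <- buffers[[key]]$var
      buffers[[key]] <- list(mean = (1 - momentum) * rm0 + momentum * st$mean,
                             var  = (1 - momentum) * rv0 + momentum * st$var)
    }
    list(Y = ba$Y, cache = list(xhat = ba$xhat, ivar = ivar, g = g))
  } else {
    st <- buffers[[key]]
    list(Y = cpp_bn_eval(X, st$mean, 1 / sqrt(st$var + eps), g, b), cache = NULL)
  }
}

nn_bn_bwd <- function(dY, cache) {
  cpp_bn_bwd(dY, cache$xhat, cache$g, cache$ivar)
}

# Fused batch-norm + ReLU6 (the standard block nonlinearity).  In training
# mode the C++ kernel does both in one sweep and returns the batch
# statistics; backprop recomputes xhat from the cached layer input.
nn_bnrelu_fwd <- function(X, g, b, training, buffers, key, momentum = 0.1,
                          eps = 1e-5) {
  if (training) {
    o <- cpp_bnrelu6_fwd(X, g, b, eps)
    if (!is.null(buffers)) {
      rm0 <- buffers[[key]]$mean; rv0 <- buffers[[key]]$var
      buffers[[key]] <- list(mean = (1 - momentum) * rm0 + momentum * o$mean,
                             var  = (1 - momentum) * rv0 + momentum * o$var)
    }
    list(Y = o$Y, cache = list(X = X, mask = o$mask, mean = o$mean,
                               ivar = o$ivar, g = g))
  } else {
    st <- buffers[[key]]
    list(Y = relu6(cpp_bn_eval(X, st$mean, 1 / sqrt(st$var + eps), g, b)),
         cache = NULL)
  }
}

nn_bnrelu_bwd <- function(dR, cache) {
  cpp_bnrelu6_bwd(dR, cache$mask, cache$X, cache$mean, cache$ivar, cache$g)
}

# rows of image b within a (B*H*W) x C activation matrix
image_rows <- function(b, B, HW) seq.int(b, by = B, length.out = HW)

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- squeeze-and-excitation ------------------------------------------------

nn_se_fwd <- function(X, B, HW, w) {
  Z <- cpp_rowblock_means(X, B)                       # B x C squeeze
  H1 <- sweep(Z %*% w$W1, 2L, w$b1, `+`)
  A <- pmax(H1, 0)
  S <- sigmoid(sweep(A %*% w$W2, 2L, w$b2, `+`))      # B x C gates
  Y <- cpp_rowblock_scale(X, S, B)
  list(Y = Y, cache = list(Z = Z, A = A, relu_mask = H1 > 0, S = S,
                           B = B, HW = HW))
}

nn_se_bwd <- function(dY, X, w, cache) {
  B <- cache$B; HW <- cache$HW
  dS <- cpp_rowblock_dots(dY, X, B)
  dlog <- dS * cache$S * (1 - cache$S)
  dW2 <- crossprod(cache$A, dlog)
  db2 <- colSums(dlog)
  dA <- tcrossprod(dlog, w$W2) * cache$relu_mask
  dW1 <- crossprod(cache$Z, dA)
  db1 <- colSums(dA)
  dZ <- tcrossprod(dA, w$W1)
  dX <- cpp_rowblock_scale_add(dY, cache$S, dZ, B)
  list(dX = dX, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

#' Squeeze-and-excitation gating
#'
#' Channel attention on a feature map: global average pooling to a channel
#' vector `z` (the squeeze), a two-layer fully connected gate
#' (FC -> ReLU -> FC -> sigmoid) producing per-channel weights in (0, 1)
#' (the excitation), and channel-wise rescaling of the input.
#'
#' @param F `H x W x C` numeric array.
#' @param cfg List with `reduction` and `floor`; the hidden width is
#'   `max(ceiling(C / reduction), floor)`.  Only used to validate `weights`.
#' @param weights List with `W1` (`C x h`), `b1` (`h`), `W2` (`h x C`),
#'   `b2` (`C`).
#' @return Array of the same shape, each channel scaled by its gate.
#' @export
se_forward <- function(F, cfg = list(reduction = 128L, floor = 4L), weights) {
  F <- as_feature_array(F)
  C <- dim(F)[3]
  if (nrow(weights$W1) != C) stop("SE weight shape does not match ", C, " channels")
  X <- feature_to_mat(F)
  out <- nn_se_fwd(X, 1L, dim(F)[1] * dim(F)[2], weights)
  mat_to_feature(out$Y, dim(F)[1], dim(F)[2])
}

# --- patch attention -------------------------------------------------------

#' Average-pool patch splitting
#'
#' Splits a feature map into non-overlapping `n x n` patches and represents
#' each patch by one position via the per-channel patch mean, giving an
#' `(H/n) x (W/n) x C` map.  `n = 1` is the identity.
#'
#' @param F `H x W x C` numeric array (a matrix is treated as `C = 1`).
#' @param n Patch side; must divide both spatial dimensions.
#' @return `(H/n) x (W/n) x C` array.
#' @export
patch_split <- function(F, n) {
  F <- as_feature_array(F)
  H <- dim(F)[1]; W <- dim(F)[2]; C <- dim(F)[3]
  n <- as.integer(n)
  if (H %% n != 0L || W %% n != 0L) {
    stop("patch size ", n, " does not divide the ", H, "x", W, " feature map")
  }
  if (n == 1L) return(F)
  Hn <- H %/% n; Wn <- W %/% n
  out <- array(0, c(Hn, Wn, C))
  grp <- patch_groups(H, W, n)
  for (cc in seq_len(C)) {
    out[, , cc] <- matrix(rowsum(as.vector(F[, , cc]), grp, reorder = TRUE), Hn, Wn) / (n * n)
  }
  out
}

# patch index (column-major over the (H/n) x (W/n) grid) for each pixel of
# an H x W image flattened column-major
patch_groups <- function(H, W, n) {
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  pi <- (i - 1L) %/% n
  pj <- (j - 1L) %/% n
  pi + (H %/% n) * pj + 1L
}

#' Patch-to-patch attention map
#'
#' Row-stochastic softmax attention between patch descriptors:
#' `S[m, n] = exp(q_m . k_n) / sum_n' exp(q_m . k_n')`, stabilized by
#' subtracting each row's maximum logit.
#'
#' @param q,k `N x C` matrices of query and key vectors.
#' @return `N x N` matrix with rows summing to 1.
#' @export
attention_map <- function(q, k) {
  logits <- q %*% t(k)
  logits <- logits - apply(logits, 1L, max)
  e <- exp(logits)
  e / rowSums(e)
}

# Per-image PAM forward on an (HW x C) feature matrix (rows column-major).
pam_image_fwd <- function(Fm, H, W, n, w) {
  grp <- patch_groups(H, W, n)
  P <- rowsum(Fm, grp, reorder = TRUE) / (n * n)       # N x C pooled patches
  q <- sweep(P %*% w$Wq, 2L, w$bq, `+`)
  k <- sweep(P %*% w$Wk, 2L, w$bk, `+`)
  v <- sweep(P %*% w$Wv, 2L, w$bv, `+`)
  logits <- q %*% t(k)
  mx <- apply(logits, 1L, max)
  e <- exp(logits - mx)
  S <- e / rowSums(e)
  att <- S %*% v
  comb <- w$alpha * att + P
  out <- Fm + comb[grp, , drop = FALSE]                # nearest upsample + add
  list(out = out, cache = list(P = P, q = q, k = k, v = v, S = S, att = att, grp = grp))
}

pam_image_bwd <- function(dOut, Fm, H, W, n, w, cache) {
  grp <- cache$grp
  dF <- dOut
  dcomb <- rowsum(dOut, grp, reorder = TRUE)
  dalpha <- sum(dcomb * cache$att)
  datt <- w$alpha * dcomb
  dP <- dcomb
  dS <- datt %*% t(cache$v)
  dv <- t(cache$S) %*% datt
  dlog <- cache$S * (dS - rowSums(dS * cache$S))
  dq <- dlog %*% cache$k
  dk <- t(dlog) %*% cache$q
  dWq <- t(cache$P) %*% dq; dbq <- colSums(dq)
  dWk <- t(cache$P) %*% dk; dbk <- colSums(dk)
  dWv <- t(cache$P) %*% dv; dbv <- colSums(dv)
  dP <- dP + dq %*% t(w$Wq) + dk %*% t(w$Wk) + dv %*% t(w$Wv)
  dF <- dF + dP[grp, , drop = FALSE] / (n * n)
  list(dF = dF, dWq = dWq, dbq = dbq, dWk = dWk, dbk = dbk,
       dWv = dWv, dbv = dbv, dalpha = dalpha)
}

#' Patch attention module
#'
#' Self-attention over non-overlapping `n x n` patches of a feature map.
#' The map is average-pooled to one position per patch, 1x1 convolutions
#' produce query/key/value maps at full channel width, the row-stochastic
#' attention matrix ([attention_map()]) aggregates the values, the result is
#' scaled by the learnable `alpha`, added to the pooled map, upsampled back
#' (nearest neighbour) and added pixel-wise to the input.  With `n = 1` this
#' is exactly position attention over pixels; the attention matrix holds
#' `1/n^4` as many entries.
#'
#' @param F `H x W x C` numeric array.
#' @param cfg List with `patch_size` (`n`) and `alpha`.
#' @param weights List with `Wq`, `Wk`, `Wv` (`C x C`) and biases `bq`,
#'   `bk`, `bv` (`C`); `alpha` may live here instead of `cfg`.
#' @return Array of the same shape as `F`.
#' @export
pam_forward <- function(F, cfg, weights) {
  F <- as_feature_array(F)
  H <- dim(F)[1]; W <- dim(F)[2]
  n <- as.integer(cfg$patch_size)
  if (H %% n != 0L || W %% n != 0L) {
    stop("patch size ", n, " does not divide the ", H, "x", W, " feature map")
  }
  w <- weights
  if (is.null(w$alpha)) w$alpha <- cfg$alpha
  Fm <- feature_to_mat(F)
  out <- pam_image_fwd(Fm, H, W, n, w)
  mat_to_feature(out$out, H, W)
}

# --- bottleneck residual block --------------------------------------------

# Matrix-level forward for one block.  p holds the parameters, spec the
# (k, kp, s, t, use_se) contract.  Returns output + cache for backprop.
block_fwd <- function(X, B, H, W, p, spec, training, buffers, key) {
  E <- X %*% p$We
  f1 <- nn_bnrelu_fwd(E, p$bn1g, p$bn1b, training, buffers, paste0(key, ".bn1"))
  D <- cpp_dwconv_fwd(f1$Y, B, H, W, p$Kd, spec$s)
  Ho <- (H + 2L - 3L) %/% spec$s + 1L
  Wo <- (W + 2L - 3L) %/% spec$s + 1L
  f2 <- nn_bnrelu_fwd(D, p$bn2g, p$bn2b, training, buffers, paste0(key, ".bn2"))
  A <- f2$Y
  se <- NULL
  if (isTRUE(spec$use_se)) {
    se <- nn_se_fwd(A, B, Ho * Wo, p)
    A <- se$Y
  }
  P <- A %*% p$Wp
  bn3 <- nn_bn_fwd(P, p$bn3g, p$bn3b, training, buffers, paste0(key, ".bn3"))
  Y <- bn3$Y
  residual <- spec$s == 1L && spec$k == spec$kp
  if (residual) Y <- Y + X
  list(Y = Y, H = Ho, W = Wo,
       cache = list(X = X, f1 = f1$cache, r1Y = f1$Y, f2 = f2$cache,
                    A = A, preSE = f2$Y, se = se, bn3 = bn3$cache,
                    residual = residual, B = B, Hin = H, Win = W))
}

block_bwd <- function(dY, p, spec, cache) {
  g <- list()
  bn3 <- nn_bn_bwd(dY, cache$bn3)
  g$bn3g <- bn3$dg; g$bn3b <- bn3$db
  g$Wp <- crossprod(cache$A, bn3$dX)
  dA <- tcrossprod(bn3$dX, p$Wp)
  if (isTRUE(spec$use_se)) {
    seb <- nn_se_bwd(dA, cache$preSE, p, cache$se$cache)
    dA <- seb$dX
    g$W1 <- seb$dW1; g$b1 <- seb$db1; g$W2 <- seb$dW2; g$b2 <- seb$db2
  }
  b2 <- nn_bnrelu_bwd(dA, cache$f2)
  g$bn2g <- b2$dg; g$bn2b <- b2$db
  dw <- cpp_dwconv_bwd(b2$dX, cache$r1Y, cache$B, cache$Hin, cache$Win, p$Kd, spec$s)
  g$Kd <- dw$dK
  b1 <- nn_bnrelu_bwd(dw$dX, cache$f1)
  g$bn1g <- b1$dg; g$bn1b <- b1$db
  g$We <- crossprod(cache$X, b1$dX)
  dX <- tcrossprod(b1$dX, p$We)
  if (cache$residual) dX <- dX + dY
  list(dX = dX, grads = g)
}

#' Bottleneck residual block forward pass
#'
#' The inverted-residual block: 1x1 expansion from `k` to `t*k` channels
#' (batch norm + ReLU6), 3x3 depthwise convolution at stride `s`
#' (batch norm + ReLU6), optional squeeze-and-excitation gate on the
#' expanded representation, and 1x1 linear projection to `kp` channels
#' (batch norm, no nonlinearity).  The input is added to the output iff
#' `s == 1` and `k == kp`.  Batch statistics of the single input map are
#' used for normalization.
#'
#' @param F `H x W x k` numeric array.
#' @param spec List with `k`, `kp`, `s` (1 or 2), `t`, `use_se`.
#' @param weights Parameter list as produced by [build_network()] for one
#'   block (`We`, `bn1g`, `bn1b`, `Kd`, `bn2g`, `bn2b`, optional SE weights
#'   `W1`, `b1`, `W2`, `b2`, then `Wp`, `bn3g`, `bn3b`).
#' @return `(H/s) x (W/s) x kp` array.
#' @export
bottleneck_forward <- function(F, spec, weights) {
  F <- as_feature_array(F)
  H <- dim(F)[1]; W <- dim(F)[2]
  if (dim(F)[3] != spec$k) {
    stop("input has ", dim(F)[3], " channels but spec$k = ", spec$k)
  }
  if (spec$s == 2L && (H %% 2L != 0L || W %% 2L != 0L)) {
    stop("stride-2 block needs even spatial dimensions")
  }
  out <- block_fwd(feature_to_mat(F), 1L, H, W, weights, spec,
                   training = TRUE, buffers = NULL, key = "op")
  mat_to_feature(out$Y, out$H, out$W)
}

# --- array <-> matrix plumbing --------------------------------------------

as_feature_array <- function(F) {
  if (is.matrix(F)) F <- array(F, c(dim(F), 1L))
  if (length(dim(F)) != 3L) stop("expected an H x W x C array")
  F
}

# B = 1 view: (H*W) x C matrix, rows column-major over the image
feature_to_mat <- function(F) {
  d <- dim(F)
  matrix(F, d[1] * d[2], d[3])
}

mat_to_feature <- function(X, H, W) array(X, c(H, W, ncol(X)))
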