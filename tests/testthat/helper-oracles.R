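# Independent brute-force oracles used across the suite.  These are written
# as literal loop implementations, deliberately separate from the package's
# vectorized / compiled code paths.

# --- gray-scale morphology -------------------------------------------------

bf_morph <- function(img, se, op = c("erode", "dilate")) {
  op <- match.arg(op)
  H <- nrow(img); W <- ncol(img)
  r <- (nrow(se) - 1) / 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    vals <- c()
    for (a in seq_len(nrow(se))) for (b in seq_len(ncol(se))) {
      if (!se[a, b]) next
      ii <- i + a - r - 1; jj <- j + b - r - 1
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) vals <- c(vals, img[ii, jj])
    }
    out[i, j] <- if (op == "erode") min(vals) else max(vals)
  }
  out
}

bf_white_tophat <- function(img, se) {
  img - bf_morph(bf_morph(img, se, "erode"), se, "dilate")
}

bf_black_tophat <- function(img, se) {
  bf_morph(bf_morph(img, se, "dilate"), se, "erode") - img
}

# --- patch attention -------------------------------------------------------

# Literal step-by-step patch attention: explicit loops over patches and
# patch pairs, softmax by definition, nearest upsampling by definition.
bf_pam <- function(F, n, w) {
  H <- dim(F)[1]; W <- dim(F)[2]; C <- dim(F)[3]
  Hn <- H / n; Wn <- W / n; N <- Hn * Wn
  P <- matrix(0, N, C)
  for (pi in seq_len(Hn)) for (pj in seq_len(Wn)) {
    idx <- pi + Hn * (pj - 1)
    for (cc in seq_len(C)) {
      s <- 0
      for (a in seq_len(n)) for (b in seq_len(n)) {
        s <- s + F[(pi - 1) * n + a, (pj - 1) * n + b, cc]
      }
      P[idx, cc] <- s / (n * n)
    }
  }
  q <- k <- v <- matrix(0, N, C)
  for (m in seq_len(N)) {
    q[m, ] <- drop(P[m, ] %*% w$Wq) + w$bq
    k[m, ] <- drop(P[m, ] %*% w$Wk) + w$bk
    v[m, ] <- drop(P[m, ] %*% w$Wv) + w$bv
  }
  S <- matrix(0, N, N)
  for (m in seq_len(N)) {
    e <- numeric(N)
    for (nn in seq_len(N)) e[nn] <- exp(sum(q[m, ] * k[nn, ]))
    S[m, ] <- e / sum(e)
  }
  att <- matrix(0, N, C)
  for (m in seq_len(N)) for (nn in seq_len(N)) {
    att[m, ] <- att[m, ] + S[m, nn] * v[nn, ]
  }
  comb <- w$alpha * att + P
  out <- F
  for (i in seq_len(H)) for (j in seq_len(W)) {
    idx <- ((i - 1) %/% n + 1) + Hn * ((j - 1) %/% n)
    out[i, j, ] <- F[i, j, ] + comb[idx, ]
  }
  out
}

# Full position attention over pixels (the n = 1 special case of the above,
# written independently in matrix form over positions).
bf_position_attention <- function(F, w) {
  H <- dim(F)[1]; W <- dim(F)[2]; C <- dim(F)[3]
  N <- H * W
  P <- matrix(F, N, C)
  q <- sweep(P %*% w$Wq, 2, w$bq, `+`)
  k <- sweep(P %*% w$Wk, 2, w$bk, `+`)
  v <- sweep(P %*% w$Wv, 2, w$bv, `+`)
  E <- exp(q %*% t(k))
  S <- E / rowSums(E)
  comb <- w$alpha * (S %*% v) + P
  array(matrix(F, N, C) + comb, c(H, W, C))
}

random_pam_weights <- function(C, alpha = 0.7, seed = 1) {
  set.seed(seed)
  list(Wq = matrix(rnorm(C * C, sd = 0.3), C, C), bq = rnorm(C, sd = 0.1),
       Wk = matrix(rnorm(C * C, sd = 0.3), C, C), bk = rnorm(C, sd = 0.1),
       Wv = matrix(rnorm(C * C, sd = 0.3), C, C), bv = rnorm(C, sd = 0.1),
       alpha = alpha)
}

# --- connectivity ----------------------------------------------------------

# Count 8-connected components of a binary mask (queue-based flood fill).
bf_n_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  ncomp <- 0
  for (i0 in seq_len(H)) for (j0 in seq_len(W)) {
    if (mask[i0, j0] != 1 || seen[i0, j0]) next
    ncomp <- ncomp + 1
    queue <- list(c(i0, j0)); seen[i0, j0] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
            mask[ii, jj] == 1 && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  ncomp
}

# --- shared fixtures -------------------------------------------------------

# The 4-image 96x96 synthetic training fixture used by the end-to-end tests.
make_fixture_pairs <- function(n = 4L, size = 96L, seed = 11L) {
  params <- phantom_params(image_size = c(size, size), seed = seed)
  lapply(seq_len(n), function(i) {
    p <- params
    p$seed <- params$seed + i
    m <- generate_tree_mask(p)
    img <- render_angiogram(m, p)
    attr(m, "vessel_fraction") <- NULL
    list(image = img, mask = m)
  })
}

# Small integer-valued 9x9 rasters for the morphology oracle suite.
make_9x9_rasters <- function() {
  out <- list()
  z <- matrix(0, 9, 9); z[5, 5] <- 1
  out$peak <- z
  o <- matrix(1, 9, 9); o[5, 5] <- 0
  out$pit <- o
  out$constant <- matrix(0.5, 9, 9)
  set.seed(404)
  for (k in 1:4) {
    out[[paste0("random", k)]] <- matrix(sample(0:4, 81, replace = TRUE) / 4, 9, 9)
  }
  out
}

dice_coefficient <- function(y, p, threshold = 0.5) {
  pb <- (p >= threshold) * 1
  2 * sum(y * pb) / (sum(y) + sum(pb))
}
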