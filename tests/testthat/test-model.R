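# Network components: activations, bottleneck blocks, attention modules,
# assembly, parameter accounting, and gradient correctness.

test_that("relu6 clamps at both ends and is identity between", {
  expect_equal(relu6(-3), 0)
  expect_equal(relu6(7), 6)
  expect_equal(relu6(3.5), 3.5)
  x <- array(seq(-8, 8, length.out = 24), c(2, 3, 4))
  expect_equal(relu6(x), pmin(pmax(x, 0), 6))
})

make_block_weights <- function(k, kp, t, seed = 1) {
  m <- t * k
  set.seed(seed)
  list(We = matrix(rnorm(k * m, sd = 0.4), k, m),
       bn1g = rep(1, m), bn1b = rep(0, m),
       Kd = matrix(rnorm(9 * m, sd = 0.3), 9, m),
       bn2g = rep(1, m), bn2b = rep(0, m),
       Wp = matrix(rnorm(m * kp, sd = 0.4), m, kp),
       bn3g = rep(1, kp), bn3b = rep(0, kp))
}

test_that("bottleneck blocks honour their shape contract", {
  F1 <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  spec1 <- list(k = 8L, kp = 8L, s = 1L, t = 2L, use_se = FALSE)
  out1 <- bottleneck_forward(F1, spec1, make_block_weights(8, 8, 2))
  expect_equal(dim(out1), dim(F1))

  F2 <- array(rnorm(32 * 32 * 8), c(32, 32, 8))
  spec2 <- list(k = 8L, kp = 16L, s = 2L, t = 2L, use_se = FALSE)
  out2 <- bottleneck_forward(F2, spec2, make_block_weights(8, 16, 2))
  expect_equal(dim(out2), c(16L, 16L, 16L))

  expect_error(bottleneck_forward(F2, list(k = 4L, kp = 8L, s = 1L, t = 2L,
                                           use_se = FALSE),
                                  make_block_weights(4, 8, 2)),
               "channels")
})

test_that("the residual path passes the input through a zeroed projection", {
  F1 <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  w <- make_block_weights(6, 6, 2)
  w$Wp <- w$Wp * 0
  out <- bottleneck_forward(F1, list(k = 6L, kp = 6L, s = 1L, t = 2L,
                                     use_se = FALSE), w)
  expect_equal(out, F1)
})

test_that("block parameter counts match hand enumeration and are affine in t", {
  expect_equal(block_param_count(list(k = 16, kp = 16, s = 1, t = 2,
                                      use_se = FALSE)), 1472L)
  expect_equal(block_param_count(list(k = 1, kp = 8, s = 1, t = 1,
                                      use_se = FALSE)), 38L)
  cnt <- function(t) block_param_count(list(k = 24, kp = 32, s = 1, t = t,
                                            use_se = FALSE))
  expect_equal(cnt(4) - cnt(2), cnt(6) - cnt(4))
  expect_equal(cnt(6) - cnt(4), cnt(8) - cnt(6))
})

test_that("SE gating squeezes to channel means and scales accordingly", {
  F1 <- array(0, c(2, 2, 2))
  F1[, , 1] <- matrix(c(1, 3, 2, 4), 2, 2)  # mean 2.5
  F1[, , 2] <- 0.7                          # constant channel
  z <- angioseg:::nn_se_fwd(matrix(F1, 4, 2), 1L, 4L,
                            list(W1 = matrix(0, 2, 4), b1 = rep(0, 4),
                                 W2 = matrix(0, 4, 2), b2 = rep(0, 2)))
  expect_equal(drop(z$cache$Z), c(2.5, 0.7))

  # all-zero gate weights: sigmoid(0) = 0.5 scaling everywhere
  w0 <- list(W1 = matrix(0, 2, 4), b1 = rep(0, 4),
             W2 = matrix(0, 4, 2), b2 = rep(0, 2))
  out <- se_forward(F1, list(reduction = 1, floor = 1), w0)
  expect_equal(out, 0.5 * F1)

  # gates always lie strictly inside (0, 1): output is a shrinking rescale
  set.seed(8)
  wr <- list(W1 = matrix(rnorm(8), 2, 4), b1 = rnorm(4),
             W2 = matrix(rnorm(8), 4, 2), b2 = rnorm(2))
  outr <- se_forward(F1, list(reduction = 1, floor = 1), wr)
  ratio <- outr[, , 1] / F1[, , 1]
  expect_true(all(ratio > 0 & ratio < 1))
  expect_equal(diff(range(ratio)), 0, tolerance = 1e-12)  # per-channel scale
})

test_that("patch splitting averages non-overlapping patches", {
  expect_equal(patch_split(array(1, c(4, 4, 1)), 2), array(1, c(2, 2, 1)))
  F1 <- array(c(0, 4, 2, 6), c(2, 2, 1))
  expect_equal(patch_split(F1, 2), array(3, c(1, 1, 1)))
  F2 <- array(rnorm(36), c(6, 6, 1))
  expect_identical(patch_split(F2, 1), F2)
  expect_error(patch_split(F2, 4), "does not divide")
})

test_that("attention maps are row-stochastic softmaxes of q.k", {
  S0 <- attention_map(matrix(0, 4, 3), matrix(0, 4, 3))
  expect_equal(S0, matrix(0.25, 4, 4))
  q <- matrix(c(1, 0), 2, 1)
  S <- attention_map(q, q)
  expect_equal(S[1, ], c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)))
  set.seed(5)
  Sr <- attention_map(matrix(rnorm(12), 4, 3), matrix(rnorm(12), 4, 3))
  expect_equal(rowSums(Sr), rep(1, 4), tolerance = 1e-6)
})

test_that("patch attention matches the literal loop oracle", {
  for (cfg in list(list(H = 4, C = 2, n = 2), list(H = 8, C = 4, n = 2))) {
    set.seed(cfg$H * 10 + cfg$C)
    F1 <- array(rnorm(cfg$H * cfg$H * cfg$C), c(cfg$H, cfg$H, cfg$C))
    w <- random_pam_weights(cfg$C, alpha = 0.7, seed = cfg$C)
    got <- pam_forward(F1, list(patch_size = cfg$n), w)
    want <- bf_pam(F1, cfg$n, w)
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("patch attention with unit patches equals position attention", {
  set.seed(31)
  F1 <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  w <- random_pam_weights(3, alpha = 0.45, seed = 9)
  expect_equal(pam_forward(F1, list(patch_size = 1), w),
               bf_position_attention(F1, w), tolerance = 1e-8)
})

test_that("zero-alpha unit-patch attention with identity maps doubles the input", {
  C <- 2L
  w <- list(Wq = diag(C), bq = rep(0, C), Wk = diag(C), bk = rep(0, C),
            Wv = diag(C), bv = rep(0, C), alpha = 0)
  F1 <- array(rnorm(4 * 4 * C), c(4, 4, C))
  expect_equal(pam_forward(F1, list(patch_size = 1), w), 2 * F1)
})

test_that("patch attention shrinks the attention matrix by n^4", {
  H <- 16L
  w <- random_pam_weights(2, seed = 2)
  for (n in c(1L, 2L, 4L)) {
    Fm <- matrix(rnorm(H * H * 2), H * H, 2)
    o <- angioseg:::pam_image_fwd(Fm, H, H, n, w)
    expect_equal(length(o$cache$S), (H * H)^2 / n^4)
  }
})

test_that("assembled networks map images to same-size probability maps", {
  net <- build_network(net_config(), seed = 3)
  img <- matrix(runif(96 * 96), 96, 96)
  prob <- predict(net, img)
  expect_equal(dim(prob), c(96L, 96L))
  expect_true(all(prob > 0 & prob < 1))

  tiny <- build_network(net_config(stage_widths = c(4L, 4L, 6L, 6L, 8L),
                                   enc_blocks = c(1L, 1L, 1L, 1L),
                                   bridge_blocks = 1L, dec_blocks = 1L), seed = 3)
  prob2 <- predict(tiny, matrix(runif(64 * 64), 64, 64))
  expect_equal(dim(prob2), c(64L, 64L))
  expect_error(predict(net, matrix(0.5, 50, 50)), "divisible by 16")
})

test_that("toggling the attention module changes the count by its own budget", {
  base <- count_parameters(build_network(net_config(use_pam = FALSE,
                                                    use_se = FALSE)))
  with_pam <- count_parameters(build_network(net_config(use_pam = TRUE,
                                                        use_se = FALSE)))
  C <- net_config()$stage_widths[5]
  expect_equal(with_pam - base, 3L * (C * C + C) + 1L)
})

test_that("seeded initialization is reproducible", {
  n1 <- build_network(net_config(), seed = 42)
  n2 <- build_network(net_config(), seed = 42)
  expect_identical(n1$params, n2$params)
  img <- matrix(runif(32 * 32), 32, 32)
  # forward passes are deterministic given weights and input
  expect_identical(predict(n1, resize_image(img, c(96, 96))),
                   predict(n2, resize_image(img, c(96, 96))))
})

test_that("backpropagated gradients match finite differences", {
  set.seed(42)
  cfg <- net_config(stage_widths = c(4L, 4L, 6L, 6L, 8L),
                    enc_blocks = c(1L, 1L, 1L, 1L), bridge_blocks = 1L,
                    dec_blocks = 1L, t = 2L, use_pam = TRUE, patch_size = 1L,
                    use_se = TRUE)
  net <- build_network(cfg, seed = 7)
  B <- 2L; H <- 16L; W <- 16L
  msks <- lapply(1:B, function(i) matrix(rbinom(H * W, 1, 0.15), H, W))
  X <- angioseg:::stack_batch(lapply(1:B, function(i) matrix(runif(H * W), H, W)))
  lp <- loss_params()
  loss_of <- function(nn) {
    fwd <- angioseg:::net_forward(nn, X, B, H, W, training = TRUE)
    sum(vapply(1:B, function(b) {
      rows <- angioseg:::image_rows(b, B, H * W)
      total_loss(as.vector(msks[[b]]), fwd$prob[rows, 1], lp) / B
    }, 0))
  }
  fwd <- angioseg:::net_forward(net, X, B, H, W, training = TRUE)
  dprob <- matrix(0, nrow(fwd$prob), 1)
  for (b in 1:B) {
    rows <- angioseg:::image_rows(b, B, H * W)
    dprob[rows, 1] <- angioseg:::total_loss_grad(as.vector(msks[[b]]),
                                                 fwd$prob[rows, 1], lp) / B
  }
  grads <- angioseg:::net_backward(net, fwd, dprob)
  eps <- 1e-6
  for (nm in names(net$params)) {
    for (pn in names(net$params[[nm]])) {
      expect_false(is.null(grads[[nm]][[pn]]),
                   label = paste("gradient present for", nm, pn))
    }
  }
  set.seed(99)
  picks <- list(c("enc1.b1", "We"), c("bridge.b2", "Kd"), c("pam", "Wq"),
                c("pam", "alpha"), c("dec1.b1", "W2"), c("head", "W"),
                c("stem", "K"), c("dec4.up", "K"), c("enc2.b1", "bn2g"))
  for (pk in picks) {
    nm <- pk[1]; pn <- pk[2]
    k <- sample(length(net$params[[nm]][[pn]]), 1)
    np <- net
    np$params[[nm]][[pn]][k] <- np$params[[nm]][[pn]][k] + eps
    l1 <- loss_of(np)
    np$params[[nm]][[pn]][k] <- np$params[[nm]][[pn]][k] - 2 * eps
    l2 <- loss_of(np)
    num <- (l1 - l2) / (2 * eps)
    ana <- grads[[nm]][[pn]][k]
    expect_equal(ana, num, tolerance = 2e-3,
                 label = paste("gradient of", nm, pn))
  }
})

test_that("checkpoints restore configuration, weights and buffers", {
  cfg <- net_config(stage_widths = c(4L, 4L, 6L, 6L, 8L),
                    enc_blocks = c(1L, 1L, 1L, 1L), bridge_blocks = 1L,
                    dec_blocks = 1L)
  net <- build_network(cfg, seed = 12)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(net, f)
  expect_true(file.exists(paste0(f, ".json")))
  back <- load_checkpoint(f)
  expect_identical(back$params, net$params)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_identical(predict(back, img), predict(net, img))
})
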