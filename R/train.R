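# Training: Adam with additive L2 weight decay, polynomial learning-rate
# decay, seeded mini-batches with paired augmentation.

#' Default training configuration
#'
#' @param base_lr Initial learning rate (default 4e-3).
#' @param power Polynomial decay exponent (default 0.9).
#' @param max_iter Total iterations; if `NULL`, derived as
#'   `epochs * ceiling(n_train / batch_size)` when training starts.
#' @param epochs Epoch count used to derive `max_iter` (default 200).
#' @param batch_size Mini-batch size (default 16).
#' @param weight_decay Additive L2 coefficient (default 1e-4).
#' @param beta1,beta2 Adam moment coefficients (momentum 0.9, 0.999).
#' @param seed Integer seed for batch order, augmentation and initialization.
#' @param augment Apply random paired augmentation to training batches.
#' @param aug_rotate,aug_crop_min Augmentation magnitudes (degrees; fraction).
#' @return A named list.
#' @export
train_config <- function(base_lr = 4e-3, power = 0.9, max_iter = NULL,
                         epochs = 200L, batch_size = 16L, weight_decay = 1e-4,
                         beta1 = 0.9, beta2 = 0.999, seed = 1L,
                         augment = TRUE, aug_rotate = 15, aug_crop_min = 0.9) {
  if (base_lr <= 0) stop("base_lr must be positive")
  if (power <= 0 || power > 1) stop("power must be in (0, 1]")
  if (batch_size < 1) stop("batch_size must be >= 1")
  list(base_lr = base_lr, power = power, max_iter = max_iter, epochs = epochs,
       batch_size = as.integer(batch_size), weight_decay = weight_decay,
       beta1 = beta1, beta2 = beta2, seed = as.integer(seed),
       augment = isTRUE(augment), aug_rotate = aug_rotate,
       aug_crop_min = aug_crop_min)
}

#' Polynomial learning-rate schedule
#'
#' `base_lr * (1 - iter / max_iter)^power`: the rate starts at `base_lr`,
#' decreases strictly on `(0, max_iter)` and reaches 0 at `max_iter`.
#'
#' @param cfg Training configuration (needs `base_lr`, `power`, `max_iter`).
#' @param iter Iteration in `[0, max_iter]`.
#' @return Learning rate.
#' @export
poly_lr <- function(cfg, iter) {
  if (any(iter < 0) || any(iter > cfg$max_iter)) {
    stop("iter must lie in [0, max_iter = ", cfg$max_iter, "]")
  }
  cfg$base_lr * (1 - iter / cfg$max_iter)^cfg$power
}

#' Seeded train/test split
#'
#' Shuffles the sample list with the given seed and partitions it into
#' disjoint, exhaustive train and test sets.
#'
#' @param pairs List of samples (e.g. image/mask pairs).
#' @param train_count,test_count Partition sizes; must sum to
#'   `length(pairs)`.
#' @param seed Integer seed for the shuffle.
#' @return List with elements `train` and `test`.
#' @export
split_dataset <- function(pairs, train_count, test_count, seed = 1L) {
  if (train_count + test_count != length(pairs)) {
    stop("train_count + test_count (", train_count + test_count,
         ") must equal the dataset size (", length(pairs), ")")
  }
  rs <- local_rng(seed)
  perm <- rs$perm(length(pairs))
  list(train = pairs[perm[seq_len(train_count)]],
       test = pairs[perm[train_count + seq_len(test_count)]])
}

# Stack a list of H x W matrices into the (B*H*W) x 1 activation layout.
stack_batch <- function(mats) {
  B <- length(mats)
  H <- nrow(mats[[1]]); W <- ncol(mats[[1]])
  arr <- array(0, c(B, H, W))
  for (b in seq_len(B)) arr[b, , ] <- mats[[b]]
  matrix(as.vector(arr), B * H * W, 1L)
}

#' Train a segmentation network
#'
#' Runs Adam over seeded mini-batches: per iteration, a batch is drawn
#' (with replacement when the training set is smaller than the batch),
#' optionally augmented ([augment_pair()]), passed forward, and the
#' weighted cross-entropy + Dice objective is backpropagated.  The learning
#' rate follows [poly_lr()]; weight decay is added to the gradient.  With
#' identical seeds two runs produce identical loss histories.
#'
#' @param net An `angio_net` from [build_network()].
#' @param pairs Non-empty list of samples, each `list(image, mask)` with
#'   equal-shaped matrices whose sides are divisible by 16.
#' @param cfg Training configuration ([train_config()]).
#' @param lp Loss parameters ([loss_params()]).
#' @param verbose Print progress every 50 iterations.
#' @return The trained `angio_net`, with `history` (data frame of `iter`,
#'   `loss`, `lr`).
#' @export
train_network <- function(net, pairs, cfg = train_config(), lp = loss_params(),
                          verbose = FALSE) {
  if (length(pairs) == 0L) stop("empty training set")
  n <- length(pairs)
  if (is.null(cfg$max_iter)) {
    cfg$max_iter <- cfg$epochs * ceiling(n / cfg$batch_size)
  }
  H <- nrow(pairs[[1]]$image); W <- ncol(pairs[[1]]$image)
  if (H %% 16L != 0L || W %% 16L != 0L) {
    stop("training image sides must be divisible by 16; got ", H, "x", W)
  }

  # Adam state, flat over (node, tensor)
  m <- v <- list()
  for (nm in names(net$params)) {
    m[[nm]] <- lapply(net$params[[nm]], function(x) x * 0)
    v[[nm]] <- lapply(net$params[[nm]], function(x) x * 0)
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(cfg$seed %% .Machine$integer.max)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, globalenv())
  })

  history <- data.frame(iter = integer(cfg$max_iter), loss = numeric(cfg$max_iter),
                        lr = numeric(cfg$max_iter))
  bsz <- min(cfg$batch_size, n)
  npix <- H * W

  for (it in seq_len(cfg$max_iter)) {
    idx <- sample.int(n, bsz)
    batch <- pairs[idx]
    if (cfg$augment) {
      aug_seeds <- sample.int(.Machine$integer.max - 1L, bsz)
      batch <- lapply(seq_len(bsz), function(b) {
        augment_pair(batch[[b]], aug_seeds[b], cfg$aug_rotate, cfg$aug_crop_min)
      })
    }
    X <- stack_batch(lapply(batch, `[[`, "image"))
    fwd <- net_forward(net, X, bsz, H, W, training = TRUE)

    loss <- 0
    dprob <- matrix(0, nrow(fwd$prob), 1L)
    for (b in seq_len(bsz)) {
      rows <- image_rows(b, bsz, npix)
      yb <- as.vector(batch[[b]]$mask)
      pb <- fwd$prob[rows, 1L]
      loss <- loss + total_loss(yb, pb, lp) / bsz
      dprob[rows, 1L] <- total_loss_grad(yb, pb, lp) / bsz
    }
    if (!is.finite(loss)) {
      stop("non-finite training loss at iteration ", it,
           " (lr = ", poly_lr(cfg, it - 1L), "); aborting")
    }
    grads <- net_backward(net, fwd, dprob)

    lr <- poly_lr(cfg, it - 1L)
    b1t <- 1 - cfg$beta1^it
    b2t <- 1 - cfg$beta2^it
    for (nm in names(net$params)) {
      for (pn in names(net$params[[nm]])) {
        g <- grads[[nm]][[pn]]
        if (is.null(g)) next
        g <- g + cfg$weight_decay * net$params[[nm]][[pn]]
        m[[nm]][[pn]] <- cfg$beta1 * m[[nm]][[pn]] + (1 - cfg$beta1) * g
        v[[nm]][[pn]] <- cfg$beta2 * v[[nm]][[pn]] + (1 - cfg$beta2) * g * g
        net$params[[nm]][[pn]] <- net$params[[nm]][[pn]] -
          lr * (m[[nm]][[pn]] / b1t) / (sqrt(v[[nm]][[pn]] / b2t) + 1e-8)
      }
    }
    history$iter[it] <- it - 1L
    history$loss[it] <- loss
    history$lr[it] <- lr
    if (verbose && (it %% 50L == 0L || it == 1L)) {
      message(sprintf("iter %4d  loss %.5f  lr %.6f", it, loss, lr))
    }
  }
  net$history <- history
  net
}

#' Evaluate a network on labelled pairs
#'
#' Runs forward passes in evaluation mode (optionally resizing each image
#' and mask to `eval_size` first: bilinear for images, nearest for masks)
#' and computes the pooled-pixel metrics report.
#'
#' @param net An `angio_net`.
#' @param pairs Non-empty list of `list(image, mask)` samples.
#' @param eval_size Optional `c(h, w)` test-time size.
#' @param threshold Binarization threshold for SE/SP/ACC.
#' @return A `metrics_report` (see [metrics_report()]).
#' @export
evaluate_network <- function(net, pairs, eval_size = NULL, threshold = 0.5) {
  if (length(pairs) == 0L) stop("empty test set")
  ys <- list(); ps <- list()
  for (i in seq_along(pairs)) {
    img <- pairs[[i]]$image; msk <- pairs[[i]]$mask
    if (!is.null(eval_size)) {
      img <- resize_image(img, eval_size, "bilinear")
      msk <- resize_image(msk, eval_size, "nearest")
    }
    ps[[i]] <- predict(net, img)
    ys[[i]] <- msk
  }
  metrics_report(ys, ps, threshold)
}
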