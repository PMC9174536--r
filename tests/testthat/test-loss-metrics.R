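# Training objective and evaluation suite: closed-form hand cases, oracle
# agreement, undefined-metric handling.

test_that("class weight is the background fraction of the mask", {
  expect_equal(class_weight(matrix(c(1, 0, 0, 0), 2, 2)), 0.75)
  expect_equal(class_weight(matrix(0, 3, 3)), 1)
  expect_equal(class_weight(matrix(1, 3, 3)), 0)
  expect_error(class_weight(numeric(0)), "empty")
})

test_that("weighted cross-entropy reproduces the hand-evaluated case", {
  y <- c(1, 0); p <- c(0.5, 0.5)
  # w = 0.5; loss = -(0.2*0.5*log 0.5 + 0.5*log 0.5)/2 = 0.3*log 2
  expect_equal(weighted_ce(y, p), 0.3 * log(2), tolerance = 1e-12)
  yy <- matrix(rbinom(64, 1, 0.2), 8, 8)
  expect_lt(weighted_ce(yy, yy), 1e-6)  # perfect prediction
  set.seed(2)
  pp <- matrix(runif(64), 8, 8)
  expect_gte(weighted_ce(yy, pp), 0)
  expect_error(weighted_ce(c(1, 0), c(0.5)), "shapes differ")
})

test_that("Dice loss hits its closed-form values", {
  sharp <- loss_params(dice_eps = 1e-9)
  y <- c(1, 1, 0, 0)
  expect_equal(dice_loss(y, y, sharp), 0, tolerance = 1e-8)
  expect_equal(dice_loss(y, 1 - y, sharp), 1, tolerance = 1e-8)
  # two vessel pixels, one detected: 1 - 2/3
  expect_equal(dice_loss(c(1, 1, 0, 0), c(1, 0, 0, 0), sharp), 1 / 3,
               tolerance = 1e-8)
})

test_that("the combined loss composes its two terms", {
  y <- c(1, 0); p <- c(0.5, 0.5)
  lp <- loss_params()
  expect_equal(total_loss(y, p, lp),
               weighted_ce(y, p, lp) + 0.01 * dice_loss(y, p, lp))
  lp0 <- loss_params(beta = 0)
  expect_equal(total_loss(y, p, lp0), weighted_ce(y, p, lp0))
  yy <- matrix(rbinom(64, 1, 0.2), 8, 8)
  expect_lt(total_loss(yy, yy), 1e-3)
})

test_that("the loss decreases monotonically toward the ground truth", {
  set.seed(4)
  y <- matrix(rbinom(144, 1, 0.1), 12, 12)
  lambdas <- seq(0, 0.95, by = 0.05)
  losses <- vapply(lambdas, function(l) {
    total_loss(y, 0.5 * (1 - l) + y * l)
  }, 0)
  expect_true(all(diff(losses) < 0))
})

test_that("the analytic loss gradient matches finite differences", {
  set.seed(6)
  y <- rbinom(30, 1, 0.3)
  p <- runif(30, 0.05, 0.95)
  g <- angioseg:::total_loss_grad(y, p)
  eps <- 1e-7
  for (k in c(1, 7, 19, 30)) {
    p1 <- p; p1[k] <- p1[k] + eps
    p2 <- p; p2[k] <- p2[k] - eps
    expect_equal(g[k], (total_loss(y, p1) - total_loss(y, p2)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("confusion counts match direct per-pixel recounts", {
  y <- matrix(c(rep(1, 10), rep(0, 90)), 10, 10)
  p <- y; p[which(y == 1)[1:2]] <- 0  # miss 2 of 10 vessels
  cc <- confusion_counts(y, p, 0.5)
  expect_equal(cc$TP, 8); expect_equal(cc$FN, 2)
  expect_equal(cc$TN, 90); expect_equal(cc$FP, 0)
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 100)

  ccp <- confusion_counts(y, y, 0.4)
  expect_equal(ccp$FP + ccp$FN, 0)
  cc2 <- confusion_counts(matrix(0, 4, 4), matrix(1, 4, 4), 0.5)
  expect_equal(cc2$FP, 16)

  # exhaustive oracle on random rasters
  set.seed(11)
  yy <- matrix(rbinom(64, 1, 0.3), 8, 8)
  pp <- matrix(runif(64), 8, 8)
  cc3 <- confusion_counts(yy, pp, 0.6)
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in 1:8) for (j in 1:8) {
    pos <- pp[i, j] >= 0.6
    if (pos && yy[i, j] == 1) tp <- tp + 1
    if (pos && yy[i, j] == 0) fp <- fp + 1
    if (!pos && yy[i, j] == 1) fn <- fn + 1
    if (!pos && yy[i, j] == 0) tn <- tn + 1
  }
  expect_equal(unclass(cc3), list(TP = tp, TN = tn, FP = fp, FN = fn))
})

test_that("sensitivity/specificity/accuracy follow their definitions", {
  m <- se_sp_acc(list(TP = 8, FN = 2, TN = 90, FP = 10))
  expect_equal(unname(m["sensitivity"]), 0.8)
  expect_equal(unname(m["specificity"]), 0.9)
  m2 <- se_sp_acc(list(TP = 8, FN = 2, TN = 90, FP = 0))
  expect_equal(unname(m2["accuracy"]), 0.98)
  # empty positive class flags, does not crash
  m3 <- se_sp_acc(list(TP = 0, FN = 0, TN = 5, FP = 5))
  expect_true(is.na(m3["sensitivity"]))
  expect_equal(attr(m3, "undefined"), "sensitivity")
})

test_that("AUC matches the exhaustive pairwise rank oracle", {
  # 4-pixel case: pairs (pos, neg): (0.35 vs 0.1 ok), (0.35 vs 0.4 wrong),
  # (0.8 vs 0.1 ok), (0.8 vs 0.4 ok) => 3/4
  ra <- roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
  expect_equal(ra$auc, 0.75)
  expect_equal(ra$roc$fpr[1], 0); expect_equal(ra$roc$tpr[1], 0)
  expect_equal(utils::tail(ra$roc$fpr, 1), 1)
  expect_equal(utils::tail(ra$roc$tpr, 1), 1)
  expect_true(all(diff(ra$roc$fpr) >= 0) && all(diff(ra$roc$tpr) >= 0))

  expect_equal(roc_auc(c(0, 1), c(0.2, 0.9))$auc, 1.0)  # separable
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4))$auc, 0.5)  # constant

  set.seed(13)
  for (k in 1:5) {
    y <- rbinom(200, 1, 0.3)
    p <- round(runif(200), 2)  # many ties
    if (sum(y) == 0 || sum(y) == 200) next
    expect_equal(roc_auc(y, p)$auc, angioseg:::auc_rank(y, p),
                 tolerance = 1e-9)
  }
})

test_that("AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(14)
  y <- rbinom(300, 1, 0.25)
  p <- runif(300)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))))
  expect_equal(roc_auc(y, p)$auc, ref, tolerance = 1e-9)
})

test_that("single-class pools flag AUC as undefined", {
  ra <- roc_auc(rep(1, 10), runif(10))
  expect_true(is.na(ra$auc))
  expect_equal(attr(ra, "undefined"), "auc")
})

test_that("a ground-truth oracle predictor scores perfectly", {
  pairs <- make_fixture_pairs(n = 2, size = 96, seed = 31)
  ys <- lapply(pairs, `[[`, "mask")
  rep1 <- metrics_report(ys, ys)
  expect_equal(rep1$sensitivity, 1)
  expect_equal(rep1$specificity, 1)
  expect_equal(rep1$accuracy, 1)
  expect_equal(rep1$auc, 1)

  # constant-0.5 predictor: chance AUC, threshold convention puts SE at 1
  ps <- lapply(ys, function(y) y * 0 + 0.5)
  rep2 <- metrics_report(ys, ps)
  expect_equal(rep2$auc, 0.5)
  expect_length(rep2$undefined, 0)
  expect_true(rep2$sensitivity %in% c(0, 1))
})
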