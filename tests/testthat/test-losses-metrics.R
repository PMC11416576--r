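test_that("multi-label Dice loss matches a term-by-term oracle and its bounds", {
  # perfect binary prediction: loss ~ 0; disjoint non-empty: loss = 1
  g <- cbind(c(1, 0, 1, 0), c(0, 1, 0, 0))
  expect_equal(multilabel_dice_loss(g, g, c(0.5, 0.5)), 0, tolerance = 1e-6)
  p_disj <- cbind(c(0, 1, 0, 1), c(1, 0, 0, 0))
  expect_equal(multilabel_dice_loss(p_disj, g, c(0.5, 0.5)), 1, tolerance = 1e-6)
  # fixed example evaluated independently
  p <- rbind(c(0.8, 0.2), c(0.4, 0.9))
  g2 <- rbind(c(1, 0), c(0, 1))
  expect_equal(multilabel_dice_loss(p, g2, c(0.5, 0.5)),
               dice_loss_oracle(p, g2, c(0.5, 0.5)), tolerance = 1e-10)
  # random batches stay in [0, 1] and keep matching the oracle
  set.seed(21)
  for (i in 1:20) {
    N <- sample(3:12, 1); K <- sample(1:3, 1)
    p <- matrix(runif(N * K), N, K)
    g <- matrix(rbinom(N * K, 1, 0.4), N, K)
    w <- runif(K); w <- w / sum(w)
    L <- multilabel_dice_loss(p, g, w)
    expect_gte(L, 0); expect_lte(L, 1)
    expect_equal(L, dice_loss_oracle(p, g, w), tolerance = 1e-10)
  }
  expect_error(multilabel_dice_loss(p, g2[, 1, drop = FALSE]), "shapes")
  expect_error(multilabel_dice_loss(matrix(0, 2, 1), matrix(0, 2, 1), eps = 0),
               "0/0")
})

test_that("K = 1 with unit weight reduces to one minus the soft Dice", {
  set.seed(31)
  p <- matrix(runif(50), 50, 1)
  g <- matrix(rbinom(50, 1, 0.5), 50, 1)
  dice_soft <- 2 * sum(p * g) / (sum(p^2) + sum(g^2) + 1e-7)
  expect_equal(multilabel_dice_loss(p, g, weights = 1), 1 - dice_soft,
               tolerance = 1e-12)
})

test_that("analytic Dice gradient agrees with central finite differences", {
  set.seed(13)
  worst <- 0
  for (i in 1:15) {
    N <- sample(3:8, 1); K <- sample(1:3, 1)
    p <- matrix(runif(N * K, 0.05, 0.95), N, K)
    g <- matrix(rbinom(N * K, 1, 0.5), N, K)
    w <- runif(K); w <- w / sum(w)
    an <- multilabel_dice_grad(p, g, w)
    fd <- dice_grad_fd(p, g, w)
    rel <- abs(an - fd) / pmax(abs(fd), 1e-4)
    worst <- max(worst, max(rel))
  }
  expect_lt(worst, 1e-5)
  # on a perfect binary prediction, matched-class coordinates push upward
  g <- cbind(c(1, 0, 1), c(0, 1, 0))
  gr <- multilabel_dice_grad(g, g, c(0.5, 0.5))
  expect_true(all(gr[g == 1] <= 0))
})

test_that("side-output fusion is the exact weighted sum", {
  expect_equal(side_output_loss(c(0, 0, 0)), 0)
  expect_equal(side_output_loss(c(0.2, 0.4, 0.6, 0.8)), 0.5)   # a_m = 0.25
  expect_equal(side_output_loss(0.7, fusion_weights = 1), 0.7)
  expect_error(side_output_loss(c(0.1, 0.2), fusion_weights = c(1, 1, 1)),
               "lengths")
})

test_that("pixel accuracy, IoU and Dice match hand counts", {
  a <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  expect_equal(pixel_accuracy(a, a), 1)
  expect_equal(pixel_accuracy(a, 1L - a), 0)
  b <- a; b[1, 1] <- 0L
  expect_equal(pixel_accuracy(b, a), 0.75)
  # pred covers 2 of 4 gt pixels plus 1 false positive: IoU 2/5
  gt <- matrix(c(1L, 1L, 1L, 1L, 0L, 0L), 2, 3)
  pr <- matrix(c(1L, 1L, 0L, 0L, 1L, 0L), 2, 3)
  expect_equal(iou(pr, gt), 0.4)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, 1L - a), 0)
  # |inter| = 2, |pred| = 3, |gt| = 4 -> Dice 4/7
  gt2 <- matrix(c(1L, 1L, 1L, 1L, 0L, 0L), 2, 3)
  pr2 <- matrix(c(1L, 1L, 0L, 0L, 0L, 1L), 2, 3)
  expect_equal(dice_coefficient(pr2, gt2), 4 / 7)
  expect_equal(dice_coefficient(matrix(0L, 2, 2), matrix(0L, 2, 2)), 1)
  expect_error(iou(a, matrix(0L, 3, 3)), "shapes")
})

test_that("Dice and IoU obey the algebraic identity on random binary pairs", {
  set.seed(17)
  for (i in 1:50) {
    pr <- matrix(rbinom(64, 1, runif(1)), 8, 8)
    gt <- matrix(rbinom(64, 1, runif(1)), 8, 8)
    j <- iou(pr, gt)
    expect_equal(dice_coefficient(pr, gt), 2 * j / (1 + j), tolerance = 1e-12)
  }
})

test_that("metrics are invariant under a common pixel shuffle", {
  set.seed(19)
  pr <- random_label_mask(10, 10); gt <- random_label_mask(10, 10)
  perm <- sample(100)
  prs <- matrix(pr[perm], 10, 10); gts <- matrix(gt[perm], 10, 10)
  expect_equal(pixel_accuracy(pr, gt), pixel_accuracy(prs, gts))
  expect_equal(iou(pr, gt), iou(prs, gts))
  expect_equal(dice_coefficient(pr, gt), dice_coefficient(prs, gts))
  expect_equal(mean_iou(pr, gt, 6), mean_iou(prs, gts, 6))
})

test_that("mean IoU averages per-class IoU with the empty-class convention", {
  pr <- random_label_mask(12, 12, 4)
  expect_equal(mean_iou(pr, pr, 6), 1)   # classes 4,5 absent in both: IoU 1
  # two-class toy with per-class IoUs 0.4 and 0.8 averages to 0.6
  gt <- matrix(0L, 1, 10); gt[1, 1:5] <- 1L
  pr2 <- matrix(0L, 1, 10); pr2[1, 2:5] <- 1L
  # class 1: inter 4, union 5 -> 0.8; class 0: inter 5, union 6 -> 5/6
  expect_equal(mean_iou(pr2, gt, 2), mean(c(5 / 6, 0.8)))
  expect_lte(mean_iou(pr2, gt, 2), max(5 / 6, 0.8))
  expect_error(mean_iou(matrix(7L, 2, 2), matrix(0L, 2, 2), 6), "class id")
})
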