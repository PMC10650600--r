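test_that("BCE matches hand-derived values", {
  expect_lt(bce_loss(c(1, 0, 1), c(1, 0, 1)), 1e-6)
  expect_equal(bce_loss(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  set.seed(1)
  y <- rbinom(20, 1, 0.4); p <- runif(20)
  o <- sample(20)
  expect_equal(bce_loss(y, p), bce_loss(y[o], p[o]))
  expect_error(bce_loss(c(1, 0), c(0.5)), "equal length")
})

test_that("Dice loss matches its closed form and is monotone in overlap", {
  expect_equal(dice_loss(c(1, 1, 0), c(1, 1, 0)), 0, tolerance = 1e-9)
  v <- dice_loss(c(1, 1, 0, 0), c(1, 0, 0, 0), epsilon = 1e-5)
  expect_equal(v, 1 - (2 + 1e-5) / (3 + 1e-5), tolerance = 1e-12)
  expect_error(dice_loss(c(1), c(1), epsilon = 0), "epsilon")
  # enumerate all pairs of binary vectors of length 4: at fixed |y| and |p|
  # the loss is a strictly decreasing function of the overlap
  vecs <- as.matrix(expand.grid(rep(list(0:1), 4)))
  for (yi in seq_len(nrow(vecs))) for (pi in seq_len(nrow(vecs))) {
    yy <- vecs[yi, ]; pp <- vecs[pi, ]
    ov <- sum(yy * pp)
    expected <- 1 - (2 * ov + 1e-5) / (sum(yy) + sum(pp) + 1e-5)
    expect_equal(dice_loss(yy, pp), expected, tolerance = 1e-12)
  }
  # closed form is decreasing in the overlap at fixed sums
  for (tot in 2:6) {
    ls <- sapply(0:min(4, tot), function(ov) 1 - (2 * ov + 1e-5) / (tot + 1e-5))
    expect_true(all(diff(ls) < 0))
  }
})

test_that("joint loss is the exact sum and differentiable", {
  set.seed(2)
  y <- rbinom(50, 1, 0.3); p <- runif(50, 0.05, 0.95)
  expect_equal(joint_loss(y, p), bce_loss(y, p) + dice_loss(y, p),
               tolerance = 1e-12)
  expect_gte(joint_loss(y, p), max(bce_loss(y, p), dice_loss(y, p)))
  g <- stripseg:::joint_loss_grad(y, p)
  for (i in c(1, 17, 42)) {
    e <- 1e-6
    pp <- p; pp[i] <- pp[i] + e
    pm <- p; pm[i] <- pm[i] - e
    fd <- (joint_loss(y, pp) - joint_loss(y, pm)) / (2 * e)
    expect_equal(g[i], fd, tolerance = 1e-4)
  }
})

test_that("confusion counts are FoV-restricted and match a crafted fixture", {
  # 10x10 map: 45 true vessel pixels inside fov, 5 of them missed;
  # 55 background, 5 false alarms -> TP=40 TN=50 FP=5 FN=5
  y <- matrix(0, 10, 10)
  y[1:5, 1:9] <- 1                      # 45 vessel pixels
  p <- y
  p[1, 1:5] <- 0                        # 5 missed
  p[10, 1:5] <- 1                       # 5 false alarms
  fov <- matrix(1, 10, 10)
  cm <- confusion(y, p, fov, 0.5)
  expect_equal(unclass(cm)[c("TP", "TN", "FP", "FN")],
               list(TP = 40L, TN = 50L, FP = 5L, FN = 5L),
               ignore_attr = TRUE)
  # flipping pixels outside the FoV changes nothing
  fov2 <- fov; fov2[, 10] <- 0
  cm_a <- confusion(y, p, fov2)
  p2 <- p; p2[, 10] <- 1 - p2[, 10]
  expect_equal(unclass(confusion(y, p2, fov2)), unclass(cm_a))
  expect_error(confusion(y, p, fov * 0), "empty")
  cm_perfect <- confusion(y, y, fov)
  expect_equal(cm_perfect$FP + cm_perfect$FN, 0)
})

test_that("summary metrics evaluate their formulas", {
  cm <- structure(list(TP = 40, TN = 50, FP = 5, FN = 5), class = "confusion")
  m <- summary_metrics(cm)
  expect_equal(m$ACC, 0.900, tolerance = 1e-12)
  expect_equal(m$SE, 40 / 45, tolerance = 1e-12)   # 0.8889
  expect_equal(m$SP, 50 / 55, tolerance = 1e-12)   # 0.9091
  expect_equal(m$F1, 80 / 90, tolerance = 1e-12)   # 0.8889
  all_right <- structure(list(TP = 10, TN = 20, FP = 0, FN = 0),
                         class = "confusion")
  expect_equal(unlist(summary_metrics(all_right)), c(ACC = 1, SE = 1, SP = 1, F1 = 1))
  # F1 = harmonic mean of precision and recall on random confusions
  set.seed(3)
  for (i in 1:20) {
    cm <- structure(as.list(stats::setNames(sample(1:50, 4, TRUE),
                                            c("TP", "TN", "FP", "FN"))),
                    class = "confusion")
    m <- summary_metrics(cm)
    prec <- cm$TP / (cm$TP + cm$FP)
    expect_equal(m$F1, 2 * prec * m$SE / (prec + m$SE), tolerance = 1e-12)
  }
  none_pos <- structure(list(TP = 0, TN = 5, FP = 0, FN = 0), class = "confusion")
  expect_error(summary_metrics(none_pos), "SE")
})

test_that("ROC/AUC agrees with exhaustive pair counting", {
  y <- matrix(c(0, 0, 1, 1), 2)
  s <- matrix(c(0.1, 0.6, 0.4, 0.9), 2)
  fov <- matrix(1, 2, 2)
  r <- roc_auc(y, s, fov)
  expect_equal(r$auc, 0.75)
  expect_equal(r$curve$FPR[1], 0); expect_equal(r$curve$TPR[1], 0)
  expect_equal(utils::tail(r$curve$FPR, 1), 1)
  expect_equal(utils::tail(r$curve$TPR, 1), 1)
  # perfect separation
  expect_equal(roc_auc(y, y + 0, fov)$auc, 1.0)
  # pooled oracle on random small instances, with ties
  set.seed(4)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    yy <- rbinom(n, 1, 0.4)
    if (sum(yy) == 0 || sum(yy) == n) next
    ss <- round(runif(n), 2)
    got <- roc_auc(matrix(yy, 1), matrix(ss, 1), matrix(1, 1, n))$auc
    expect_equal(got, pair_auc(yy, ss), tolerance = 1e-12)
    # invariant under strictly increasing transforms
    got2 <- roc_auc(matrix(yy, 1), matrix(exp(3 * ss), 1), matrix(1, 1, n))$auc
    expect_equal(got2, got, tolerance = 1e-12)
  }
  expect_error(roc_auc(matrix(1, 1, 4), matrix(runif(4), 1), matrix(1, 1, 4)),
               "single class")
})

test_that("AUC matches the pROC reference on a pooled fixture", {
  skip_if_not_installed("pROC")
  set.seed(5)
  y <- rbinom(300, 1, 0.2)
  s <- y * 0.3 + runif(300, 0, 0.8)
  ours <- roc_auc(matrix(y, 10), matrix(s, 10), matrix(1, 10, 30))$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("evaluation report files are written and coherent", {
  set.seed(6)
  y <- matrix(rbinom(400, 1, 0.2), 20)
  p <- pmin(pmax(y * 0.6 + runif(400, 0, 0.4), 0), 1)
  fov <- matrix(1, 20, 20)
  out <- tempfile("eval")
  met <- evaluate_maps(y, p, fov, out)
  expect_true(file.exists(file.path(out, "metrics.json")))
  expect_true(file.exists(file.path(out, "metrics.txt")))
  expect_true(file.exists(file.path(out, "roc_curve.csv")))
  js <- jsonlite::read_json(file.path(out, "metrics.json"))
  expect_equal(js$ACC, met$ACC, tolerance = 1e-9)
  expect_equal(js$TP + js$TN + js$FP + js$FN, sum(fov))
})
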