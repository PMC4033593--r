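test_that("sensitivity and specificity come straight from the counts", {
  expect_equal(se_sp(tp = 9, fp = 1, tn = 19, fn = 1),
               c(se = 0.90, sp = 0.95))
  expect_equal(se_sp(10, 0, 20, 0), c(se = 1, sp = 1))
  expect_equal(se_sp(0, 0, 20, 10), c(se = 0, sp = 1))
  expect_error(se_sp(0, 1, 2, 0), "positive")
})

test_that("balanced error rate averages the per-class errors", {
  expect_equal(round(ber(0.927, 0.944), 3), 0.064)
  expect_equal(ber(1, 1), 0)
  expect_equal(ber(0.5, 0.5), 0.5)
  # identity with counts-derived rates
  ss <- se_sp(37, 4, 81, 6)
  expect_identical(ber(ss[["se"]], ss[["sp"]]), 1 - (ss[["se"]] + ss[["sp"]]) / 2)
})

test_that("PPV follows the prevalence formula", {
  expect_equal(round(ppv(0.910, 0.966, 0.23), 1), 88.9)
  expect_equal(round(ppv(0.910, 0.966, 0.67), 1), 98.2)
  expect_equal(ppv(0.4, 1, 0.1), 100)
  expect_error(ppv(0, 1, 0.5), "denominator")
})

test_that("PPV is monotone in sensitivity, specificity and prevalence", {
  set.seed(6)
  for (i in 1:100) {
    se <- runif(1, 0.05, 0.95); sp <- runif(1, 0.05, 0.95)
    pv <- runif(1, 0.05, 0.95); eps <- runif(1, 0.01, 0.04)
    expect_gt(ppv(se + eps, sp, pv), ppv(se, sp, pv))
    expect_gt(ppv(se, sp + eps, pv), ppv(se, sp, pv))
    expect_gt(ppv(se, sp, pv + eps), ppv(se, sp, pv))
  }
})

test_that("AUC equals exhaustive pair counting on all small inputs", {
  expect_equal(auc(c(5, 6, 7, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)), 1)
  expect_equal(auc(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  set.seed(14)
  for (n in 2:8) {
    for (rep in 1:20) {
      labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
      scores <- sample(seq_len(n), n, replace = (rep %% 2 == 0))
      expect_equal(auc(scores, labels), oracle_auc(scores, labels))
    }
  }
  expect_error(auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("LEA calibration maximizes asystole detection under the constraint", {
  # separable: all ASY below all shockable in both features
  p <- c(runif(20, 0, 0.1), runif(30, 1, 2))
  l <- c(runif(20, 0.5, 0.6), runif(30, 1, 2))
  asy <- rep(c(TRUE, FALSE), c(20, 30))
  th <- calibrate_lea(p, l, asy, 0.05)
  expect_equal(attr(th, "asy_detected"), 1)
  expect_equal(attr(th, "shock_lost"), 0)

  # zero tolerance with one shockable point inside the ASY cloud
  p2 <- c(0.02, 0.04, 0.06, 0.03, 1.5, 1.8)
  l2 <- c(0.52, 0.55, 0.58, 0.53, 1.5, 1.8)
  asy2 <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  th2 <- calibrate_lea(p2, l2, asy2, 0)
  expect_equal(attr(th2, "shock_lost"), 0)
  expect_lt(attr(th2, "asy_detected"), 1)

  # order invariance
  set.seed(3)
  perm <- sample(length(p))
  th3 <- calibrate_lea(p[perm], l[perm], asy[perm], 0.05)
  expect_equal(th3$p_lea_max, th$p_lea_max)
  expect_equal(th3$l_min_max, th$l_min_max)
})

test_that("LEA calibration always honors the constraint on its own input", {
  set.seed(23)
  for (i in 1:20) {
    n_asy <- sample(10:40, 1); n_sh <- sample(10:40, 1)
    p <- c(rlnorm(n_asy, -3, 1), rlnorm(n_sh, 1, 1.5))
    l <- 0.5 + c(rexp(n_asy, 20), rexp(n_sh, 2))
    asy <- rep(c(TRUE, FALSE), c(n_asy, n_sh))
    th <- calibrate_lea(p, l, asy, 0.05)
    lost <- mean(lea_detect(p[!asy], l[!asy], th))
    expect_lte(lost, 0.05)
    expect_equal(lost, attr(th, "shock_lost"))
    expect_equal(mean(lea_detect(p[asy], l[asy], th)),
                 attr(th, "asy_detected"))
  }
})

test_that("record-level bootstrap intervals behave sanely", {
  ids <- rep(sprintf("r%d", 1:6), each = 4)
  sh <- rep(c(TRUE, FALSE), 12)
  ci <- cluster_ci(rep(TRUE, 24), sh, ids, reps = 500, seed = 2)
  expect_equal(ci$se, 1); expect_equal(ci$sp, 1)
  expect_equal(ci$se_low, 1); expect_equal(ci$sp_low, 1)

  correct <- c(rep(TRUE, 12), rep(FALSE, 12))
  ci2 <- cluster_ci(correct, sh, ids, reps = 500, seed = 2)
  expect_lte(ci2$se_low, ci2$se)
  expect_lte(ci2$sp_low, ci2$sp)
  expect_error(cluster_ci(rep(TRUE, 4), sh[1:4], rep("r1", 4)), "two records")
})

test_that("bootstrap bounds are stable across seeds", {
  set.seed(31)
  ids <- rep(sprintf("r%02d", 1:30), each = 6)
  sh <- rep(rep(c(TRUE, FALSE), 15), each = 6)
  correct <- runif(180) < 0.9
  a <- cluster_ci(correct, sh, ids, reps = 10000, seed = 1)
  b <- cluster_ci(correct, sh, ids, reps = 10000, seed = 2)
  expect_lt(abs(a$se_low - b$se_low), 0.01)
  expect_lt(abs(a$sp_low - b$sp_low), 0.01)
})
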