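test_that("LEA gate fires on either low energy or low curve length", {
  th <- lea_thresholds()           # P_LEA < 0.44 or L_min < 0.63
  expect_true(lea_detect(0.30, 1.00, th))
  expect_true(lea_detect(0.50, 0.62, th))
  expect_false(lea_detect(0.50, 0.70, th))
  # monotone: decreasing either feature never un-detects
  set.seed(8)
  for (i in 1:50) {
    p <- runif(1, 0, 1); l <- runif(1, 0.5, 2)
    if (lea_detect(p, l, th)) {
      expect_true(lea_detect(p * runif(1), l, th) |
                    lea_detect(p, l, th))       # smaller p stays detected
      expect_true(lea_detect(p * runif(1), l * runif(1, 0.5, 1), th))
    }
  }
})

test_that("standardization uses training statistics with population SD", {
  x <- matrix(c(1, 3, 10, 20), ncol = 2)
  st <- standardize_fit(x)
  xs <- standardize_apply(x, st)
  expect_equal(as.numeric(xs[, 1]), c(-1, 1))
  expect_equal(as.numeric(xs[, 2]), c(-1, 1))
  expect_equal(as.numeric(standardize_apply(st$mean, st)), c(0, 0))
  expect_equal(standardize_apply(xs, st, inverse = TRUE), x)
  expect_error(standardize_fit(cbind(a = c(1, 1), b = c(1, 2))), "a")
})

test_that("the discriminant implements the Gaussian-kernel expansion", {
  m1 <- structure(list(sv = matrix(c(0.1, -0.2, 0.3, 0.4), 1), coefs = 1,
                       b = 0, gamma = 0.5, n_sv = 1), class = "saa_svm")
  d <- svm_decide(m1, c(0.1, -0.2, 0.3, 0.4))
  expect_equal(d$f, 1)
  expect_equal(d$decision, "Sh")

  # two symmetric support vectors with opposite labels cancel exactly
  m2 <- structure(list(sv = rbind(c(1, 0, 0, 0), c(-1, 0, 0, 0)),
                       coefs = c(1, -1), b = 0, gamma = 0.3, n_sv = 2),
                  class = "saa_svm")
  d2 <- svm_decide(m2, c(0, 1, 2, -1))
  expect_equal(d2$f, 0)
  expect_equal(d2$decision, "NSh")    # the boundary is nonshockable
  expect_error(svm_decide(m2, c(1, 2)), "dimension")
})

test_that("the discriminant matches a naive double-loop evaluation", {
  set.seed(13)
  for (i in 1:20) {
    ns <- sample(3:15, 1)
    m <- structure(list(sv = matrix(rnorm(ns * 4), ns),
                        coefs = rnorm(ns), b = rnorm(1),
                        gamma = runif(1, 0.01, 2), n_sv = ns),
                   class = "saa_svm")
    x <- rnorm(4)
    expect_equal(svm_decide(m, x)$f,
                 oracle_svm_f(m$sv, m$coefs, m$b, m$gamma, x),
                 tolerance = 1e-12)
  }
})

test_that("grid-search training separates well-separated classes", {
  set.seed(21)
  n <- 100
  x <- rbind(matrix(rnorm(n * 4), ncol = 4) + 10,
             matrix(rnorm(n * 4), ncol = 4))
  colnames(x) <- c("bS", "nP", "P_fib", "P_h")
  y <- rep(c("Sh", "NSh"), each = n)
  cfg <- train_config(cost_grid = 2^seq(-2, 4, 2), gamma_grid = 2^seq(-4, 0, 2),
                      seed = 5)
  m <- svm_train(x, y, cfg)
  expect_lt(m$cv_ber, 0.01)
  expect_true(m$cost %in% cfg$cost_grid)
  expect_true(m$gamma %in% cfg$gamma_grid)
  expect_error(svm_train(x, rep("Sh", 2 * n), cfg), "both classes")
})

test_that("cross-validated BER approaches the Bayes error on overlapping blobs", {
  set.seed(99)
  n <- 1000
  delta <- 2 * qnorm(0.9)          # Bayes error 0.10 for unit-variance blobs
  x <- rbind(cbind(rnorm(n, delta / 2), matrix(rnorm(n * 3), ncol = 3)),
             cbind(rnorm(n, -delta / 2), matrix(rnorm(n * 3), ncol = 3)))
  colnames(x) <- c("bS", "nP", "P_fib", "P_h")
  y <- rep(c("Sh", "NSh"), each = n)
  cfg <- train_config(cost_grid = c(0.25, 1, 4), gamma_grid = c(1 / 16, 1 / 4, 1),
                      seed = 11)
  m <- svm_train(x, y, cfg)
  expect_lt(abs(m$cv_ber - 0.10), 0.03)
})

test_that("window classification gates the SVM behind the LEA detector", {
  model <- cached_small_model()
  asy <- gen_rhythm("ASY", amplitude = 0.05, duration = 3, seed = 3)
  d <- classify_window(asy$samples, model)
  expect_equal(d$decision, "NSh")
  expect_equal(d$stage, "LEA")

  vf <- gen_rhythm("VF", amplitude = 1, rate = 5, duration = 3, seed = 3)
  d2 <- classify_window(vf$samples, model)
  expect_equal(d2$stage, "SVM")

  d3 <- classify_window(numeric(750), model)
  expect_equal(d3$decision, "NSh")
  expect_equal(d3$stage, "LEA")

  # the SVM must never be invoked for a LEA window
  testthat::local_mocked_bindings(
    svm_decide = function(...) stop("SVM evaluated on a LEA window"),
    .package = "cprsaa")
  expect_no_error(classify_window(asy$samples, model))
  expect_error(classify_window(vf$samples, model), "LEA window")
})

test_that("segment majority vote needs two shockable windows", {
  expect_equal(classify_segment(c("Sh", "Sh", "NSh")), "Sh")
  expect_equal(classify_segment(c("NSh", "NSh", "Sh")), "NSh")
  expect_equal(classify_segment(c("NSh", "NSh", "NSh")), "NSh")
  expect_equal(classify_segment(c("Sh", "Sh", "Sh")), "Sh")
  # full truth table: decision is Sh iff >= 2 votes
  for (a in c("Sh", "NSh")) for (b in c("Sh", "NSh")) for (cc in c("Sh", "NSh")) {
    want <- if (sum(c(a, b, cc) == "Sh") >= 2) "Sh" else "NSh"
    expect_equal(classify_segment(c(a, b, cc)), want)
  }
  expect_error(classify_segment(c("Sh", "Sh")), "three")
})

test_that("models survive a JSON round trip", {
  model <- cached_small_model()
  path <- file.path(withr::local_tempdir(), "model.json")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(back$lea$p_lea_max, model$lea$p_lea_max)
  expect_equal(back$svm$sv, model$svm$sv)
  expect_equal(back$svm$coefs, model$svm$coefs)
  expect_equal(back$svm$b, model$svm$b)
  set.seed(1)
  xs <- matrix(rnorm(40), ncol = 4)
  expect_equal(svm_decide(back$svm, xs)$f, svm_decide(model$svm, xs)$f)
  w <- gen_rhythm("VF", amplitude = 0.9, rate = 5.5, duration = 3,
                  seed = 12)$samples
  expect_equal(classify_window(w, back), classify_window(w, model))
})
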