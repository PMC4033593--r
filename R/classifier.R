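#' Low-electrical-activity detection thresholds
#'
#' A window is flagged as low electrical activity (LEA, hence nonshockable)
#' when `P_LEA < p_lea_max` or `L_min < l_min_max`. The defaults are the
#' operating point reported for OHCA data with ECG amplitudes in mV; they
#' can be re-fit on any training corpus with [calibrate_lea()].
#'
#' @param p_lea_max threshold on the high-passed window energy (mV^2 samples).
#' @param l_min_max threshold on the minimum subinterval curve length.
#' @return A list of class `lea_thresholds`.
#' @export
lea_thresholds <- function(p_lea_max = 0.44, l_min_max = 0.63) {
  stopifnot(p_lea_max > 0, l_min_max > 0)
  structure(list(p_lea_max = p_lea_max, l_min_max = l_min_max),
            class = "lea_thresholds")
}

#' LEA detector
#'
#' @param p_lea,l_min the two low-electrical-activity features of a window
#'   (vectorized).
#' @param thresholds a [lea_thresholds()] object.
#' @return Logical: `TRUE` where the window shows low electrical activity.
#' @export
lea_detect <- function(p_lea, l_min, thresholds = lea_thresholds()) {
  stopifnot(inherits(thresholds, "lea_thresholds"))
  p_lea < thresholds$p_lea_max | l_min < thresholds$l_min_max
}

#' Feature standardization statistics
#'
#' Column means and population standard deviations (divide-by-n convention)
#' of a training feature matrix; applied to test vectors unchanged, so the
#' training set itself maps to per-feature mean 0 and SD 1 exactly.
#'
#' @param x numeric matrix (rows = windows, columns = features).
#' @return A list with `mean` and `sd` (named by column).
#' @export
standardize_fit <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd_pop <- sqrt(colMeans(sweep(x, 2, mu)^2))
  if (any(sd_pop <= 0)) {
    bad <- colnames(x)[sd_pop <= 0]
    stop("zero-variance feature(s): ", paste(bad, collapse = ", "))
  }
  list(mean = mu, sd = sd_pop)
}

#' Apply (or invert) standardization
#'
#' @param x numeric matrix or vector of raw (or standardized) features.
#' @param stats a list with `mean` and `sd` from [standardize_fit()].
#' @param inverse map standardized values back to the original scale.
#' @return Matrix of the same shape.
#' @export
standardize_apply <- function(x, stats, inverse = FALSE) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (inverse) sweep(sweep(x, 2, stats$sd, `*`), 2, stats$mean, `+`)
  else sweep(sweep(x, 2, stats$mean), 2, stats$sd, `/`)
}

#' Gaussian-kernel SVM discriminant
#'
#' Evaluates `f(x) = sum_i alpha_i y_i exp(-gamma ||x - x_i||^2) + b` over
#' the support vectors of a trained model and decides shock (`f(x) > 0`)
#' versus no shock (`f(x) <= 0`; the boundary is nonshockable).
#'
#' @param model an `saa_svm` model from [svm_train()].
#' @param x a standardized feature vector, or a matrix with one row per
#'   window.
#' @return A data.frame with columns `decision` (`"Sh"`/`"NSh"`) and `f`
#'   (discriminant value).
#' @export
svm_decide <- function(model, x) {
  stopifnot(inherits(model, "saa_svm"))
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != ncol(model$sv))
    stop(sprintf("feature dimension mismatch: got %d, model has %d",
                 ncol(x), ncol(model$sv)))
  # squared distances via ||x||^2 + ||sv||^2 - 2 x.sv
  d2 <- outer(rowSums(x^2), rowSums(model$sv^2), `+`) - 2 * x %*% t(model$sv)
  d2[d2 < 0] <- 0
  f <- as.numeric(exp(-model$gamma * d2) %*% model$coefs + model$b)
  data.frame(decision = ifelse(f > 0, "Sh", "NSh"), f = f,
             stringsAsFactors = FALSE)
}

#' Training configuration for the shock/no-shock SVM
#'
#' @param cost_grid soft-margin constants C to search (log-spaced by
#'   default, bracketing typical operating points for this problem).
#' @param gamma_grid Gaussian kernel widths to search.
#' @param folds number of cross-validation folds.
#' @param class_weights `"balanced"` (inverse class frequency, normalized to
#'   mean 1) or a named numeric vector `c(Sh = , NSh = )`.
#' @param seed integer seed for fold assignment.
#' @return A list of class `train_config`.
#' @export
train_config <- function(cost_grid = 2^seq(-2, 6), gamma_grid = 2^seq(-6, 2),
                         folds = 5L, class_weights = "balanced", seed = 1L) {
  stopifnot(length(cost_grid) >= 1, length(gamma_grid) >= 1, folds >= 2)
  structure(list(cost_grid = sort(cost_grid), gamma_grid = sort(gamma_grid),
                 folds = as.integer(folds), class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "train_config")
}

# stratified fold assignment; windows of one record never straddle folds
.assign_folds <- function(y, folds, record_id = NULL, seed = 1L) {
  withr_seed(seed, {
    fold <- integer(length(y))
    if (is.null(record_id)) {
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(seq_len(folds), length(idx))
      }
    } else {
      # greedy: assign records (majority-class stratified) to the currently
      # smallest fold for that class
      recs <- split(seq_along(y), record_id)
      rec_cl <- vapply(recs, function(i) names(which.max(table(y[i]))), "")
      rec_n <- lengths(recs)
      load <- matrix(0, folds, length(unique(y)),
                     dimnames = list(NULL, unique(y)))
      ord <- sample(seq_along(recs))
      ord <- ord[order(-rec_n[ord])]
      for (r in ord) {
        f <- which.min(load[, rec_cl[r]])
        fold[recs[[r]]] <- f
        load[f, rec_cl[r]] <- load[f, rec_cl[r]] + rec_n[r]
      }
    }
    fold
  })
}

.resolve_weights <- function(y, class_weights) {
  if (identical(class_weights, "balanced")) {
    tab <- table(y)
    w <- 1 / as.numeric(tab)
    w <- w / mean(w)
    names(w) <- names(tab)
    w
  } else {
    stopifnot(all(c("Sh", "NSh") %in% names(class_weights)))
    class_weights
  }
}

#' Train the shock/no-shock SVM with BER-optimized grid search
#'
#' Standardizes the four features (zero mean, unit population variance on
#' the training set), then grid-searches the soft margin `C` and kernel
#' width `gamma` by stratified k-fold cross-validation, minimizing the
#' balanced error rate `BER = 1 - (TPR + TNR) / 2`. Class weights
#' compensate the shockable/nonshockable imbalance during fitting. Ties are
#' broken toward smaller `C`, then smaller `gamma`; the returned model is
#' refit on the full training set at the winning pair. When record
#' identifiers are supplied, folds are grouped by record so windows of one
#' record never straddle folds.
#'
#' @param x numeric matrix of raw (unstandardized) features, one row per
#'   window, columns `bS`, `nP`, `P_fib`, `P_h`.
#' @param y labels: `"Sh"` / `"NSh"` (character or factor).
#' @param config a [train_config()].
#' @param record_id optional per-row record identifiers for grouped folds.
#' @return An `saa_svm` model: support vectors (standardized), dual
#'   coefficients `alpha_i y_i`, bias `b`, `gamma`, `cost`, the
#'   standardization statistics, and `cv` (a data.frame with the BER of
#'   every grid point).
#' @export
svm_train <- function(x, y, config = train_config(), record_id = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  stopifnot(nrow(x) == length(y), all(y %in% c("Sh", "NSh")))
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (nrow(x) < config$folds) stop("fewer rows than folds")
  stats <- standardize_fit(x)
  xs <- standardize_apply(x, stats)
  w <- .resolve_weights(y, config$class_weights)
  if (!is.null(record_id)) {
    # record-grouped folds need >= 2 records per class, otherwise some class
    # can never appear in a held-out fold; fall back to window stratification
    per_class <- tapply(record_id, y, function(r) length(unique(r)))
    if (any(per_class < 2)) record_id <- NULL
  }
  fold <- .assign_folds(y, config$folds, record_id, config$seed)
  yf <- factor(y, levels = c("Sh", "NSh"))

  grid <- expand.grid(cost = config$cost_grid, gamma = config$gamma_grid)
  grid$ber <- NA_real_
  for (g in seq_len(nrow(grid))) {
    tp <- fp <- tn <- fn <- 0
    for (f in sort(unique(fold))) {
      tr <- fold != f; te <- !tr
      if (length(unique(yf[tr])) < 2 || !any(te)) next
      m <- e1071::svm(xs[tr, , drop = FALSE], yf[tr], kernel = "radial",
                      cost = grid$cost[g], gamma = grid$gamma[g],
                      class.weights = w, scale = FALSE)
      pr <- stats::predict(m, xs[te, , drop = FALSE])
      tp <- tp + sum(pr == "Sh" & yf[te] == "Sh")
      fn <- fn + sum(pr == "NSh" & yf[te] == "Sh")
      tn <- tn + sum(pr == "NSh" & yf[te] == "NSh")
      fp <- fp + sum(pr == "Sh" & yf[te] == "NSh")
    }
    # a grid point is only scored when every class was actually tested
    grid$ber[g] <- if (tp + fn > 0 && tn + fp > 0)
      ber(tp / (tp + fn), tn / (tn + fp)) else NA_real_
  }
  if (all(is.na(grid$ber)))
    stop("cross-validation never tested both classes; ",
         "fewer records than folds in one class? reduce folds")
  best <- grid[order(grid$ber, grid$cost, grid$gamma, na.last = TRUE), ][1, ]
  m <- e1071::svm(xs, yf, kernel = "radial", cost = best$cost,
                  gamma = best$gamma, class.weights = w, scale = FALSE)
  # libsvm orients its decision values by the class that appears first in
  # the training data, not by factor level; normalize so f > 0 means "Sh"
  dv <- attr(stats::predict(m, xs[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  sgn <- if (identical(colnames(dv), "NSh/Sh")) -1 else 1
  structure(list(sv = unname(as.matrix(m$SV)),
                 coefs = sgn * as.numeric(m$coefs),
                 b = sgn * -m$rho,
                 gamma = best$gamma, cost = best$cost,
                 n_sv = nrow(m$SV),
                 class_weights = w,
                 standardization = stats,
                 feature_names = colnames(x),
                 cv = grid,
                 cv_ber = best$ber),
            class = "saa_svm")
}

#' @export
print.saa_svm <- function(x, ...) {
  cat(sprintf("<saa_svm> %d support vectors, C = %g, gamma = %g, CV BER = %.3f\n",
              x$n_sv, x$cost, x$gamma, x$cv_ber))
  invisible(x)
}

#' Shock-advice model: LEA thresholds plus SVM
#'
#' Bundles the two sequential stages of the shock advice algorithm with the
#' feature configuration they were trained under.
#'
#' @param lea a [lea_thresholds()] object.
#' @param svm an `saa_svm` model from [svm_train()].
#' @param feature_config the [feature_config()] used during training.
#' @return A list of class `saa_model`.
#' @export
saa_model <- function(lea, svm, feature_config = cprsaa::feature_config()) {
  stopifnot(inherits(lea, "lea_thresholds"), inherits(svm, "saa_svm"))
  structure(list(lea = lea, svm = svm, feature_config = feature_config),
            class = "saa_model")
}

#' @export
print.saa_model <- function(x, ...) {
  cat(sprintf("<saa_model> LEA: P_LEA < %.3g or L_min < %.3g; ",
              x$lea$p_lea_max, x$lea$l_min_max))
  print(x$svm)
  invisible(x)
}

#' Classify one 3-s window
#'
#' The two sequential stages of the shock advice algorithm: the LEA detector
#' declares low-electrical-activity windows nonshockable outright (the SVM
#' is never evaluated for them); all other windows are decided by the
#' Gaussian-kernel SVM discriminant on the standardized slope and spectral
#' features.
#'
#' @param window numeric vector, one 3-s window of the filtered ECG (mV).
#' @param model an [saa_model()].
#' @return A one-row data.frame (`decision`, `stage`, `f`) where `stage`
#'   records which subalgorithm decided (`"LEA"` or `"SVM"`) and `f` is the
#'   SVM discriminant (`NA` for LEA decisions).
#' @export
classify_window <- function(window, model) {
  stopifnot(inherits(model, "saa_model"))
  cfg <- model$feature_config
  feats <- window_features(window, cfg)
  if (lea_detect(feats["P_LEA"], feats["L_min"], model$lea)) {
    return(data.frame(decision = "NSh", stage = "LEA", f = NA_real_,
                      stringsAsFactors = FALSE))
  }
  xs <- standardize_apply(feats[c("bS", "nP", "P_fib", "P_h")],
                          model$svm$standardization)
  d <- svm_decide(model$svm, xs)
  data.frame(decision = d$decision, stage = "SVM", f = d$f,
             stringsAsFactors = FALSE)
}

#' Majority vote over a 9-s segment
#'
#' @param decisions character vector of exactly three window decisions
#'   (`"Sh"` / `"NSh"`).
#' @return `"Sh"` if at least two windows are shockable, else `"NSh"`.
#' @export
classify_segment <- function(decisions) {
  decisions <- as.character(decisions)
  if (length(decisions) != 3 || !all(decisions %in% c("Sh", "NSh")))
    stop("exactly three Sh/NSh window decisions are required")
  if (sum(decisions == "Sh") >= 2) "Sh" else "NSh"
}
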