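#' Sensitivity and specificity from confusion counts
#'
#' Shockable is the positive class: `Se = TP / (TP + FN)` is the proportion
#' of correctly advised shockable rhythms, `Sp = TN / (TN + FP)` the
#' proportion of correctly advised nonshockable rhythms.
#'
#' @param tp,fp,tn,fn non-negative confusion counts.
#' @return Named numeric vector `c(se = , sp = )`.
#' @export
se_sp <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fn == 0) stop("no positive (shockable) items")
  if (tn + fp == 0) stop("no negative (nonshockable) items")
  c(se = tp / (tp + fn), sp = tn / (tn + fp))
}

#' Balanced error rate
#'
#' `BER = 1 - (TPR + TNR) / 2`: the mean of the per-class error rates,
#' insensitive to class imbalance.
#'
#' @param tpr,tnr true positive and true negative rates in `[0, 1]`.
#' @return Scalar in `[0, 1]`.
#' @export
ber <- function(tpr, tnr) {
  stopifnot(tpr >= 0, tpr <= 1, tnr >= 0, tnr <= 1)
  1 - (tpr + tnr) / 2
}

#' Positive predictive value at a given VF prevalence
#'
#' The confidence in a shock advice depends on the algorithm's sensitivity
#' and specificity and on the prevalence of VF among the analyzed rhythms:
#' `PPV = 100 * Se * Pvf / (Se * Pvf + (1 - Sp) * (1 - Pvf))` (percent).
#' A specificity of 1 gives a PPV of 100 % regardless of prevalence.
#'
#' @param se,sp sensitivity and specificity in `[0, 1]`.
#' @param p_vf VF prevalence in `[0, 1]`.
#' @return PPV as a percentage in `[0, 100]`.
#' @export
ppv <- function(se, sp, p_vf) {
  stopifnot(se >= 0, se <= 1, sp >= 0, sp <= 1, p_vf >= 0, p_vf <= 1)
  den <- se * p_vf + (1 - sp) * (1 - p_vf)
  if (den <= 0) stop("degenerate denominator: no predicted positives")
  100 * se * p_vf / den
}

#' Area under the ROC curve
#'
#' Computed through the Mann-Whitney identity with midrank (half-credit)
#' tie handling: the probability that a random positive scores above a
#' random negative, plus half the probability of a tie. Equals the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric discriminant values (larger = more shockable).
#' @param labels logical or `"Sh"`/`"NSh"`: `TRUE`/`"Sh"` marks positives.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels)) labels <- as.character(labels) == "Sh"
  stopifnot(length(scores) == length(labels), is.logical(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibrate the LEA detection thresholds
#'
#' Exhaustive scan over a two-dimensional grid of candidate thresholds for
#' the rule `P_LEA < a or L_min < b`, jointly maximizing the number of
#' detected asystole windows subject to at most `max_shock_loss` of the
#' shockable windows being misdetected as LEA. Candidates are the unique
#' observed feature values plus midpoints (complete for threshold rules).
#' Ties are broken toward fewer shockable misdetections, then smaller
#' thresholds, so the result does not depend on input order.
#'
#' If even the smallest candidate pair violates the constraint the
#' degenerate all-pass thresholds (smallest candidates) are returned with
#' `attr(, "infeasible") = TRUE` and a warning.
#'
#' @param p_lea,l_min feature vectors, one element per window.
#' @param is_asy logical: `TRUE` for asystole windows, `FALSE` for
#'   shockable windows (the two groups the detector is calibrated on).
#' @param max_shock_loss maximum tolerated fraction of shockable windows
#'   misclassified as LEA (default 0.05).
#' @return A [lea_thresholds()] object with attributes `asy_detected` and
#'   `shock_lost` (achieved fractions on the calibration input).
#' @export
calibrate_lea <- function(p_lea, l_min, is_asy, max_shock_loss = 0.05) {
  stopifnot(length(p_lea) == length(l_min), length(p_lea) == length(is_asy),
            is.logical(is_asy))
  if (!any(is_asy) || !any(!is_asy)) stop("both ASY and shockable windows required")
  cand <- function(v) {
    u <- sort(unique(v))
    mids <- (u[-1] + u[-length(u)]) / 2
    eps <- max(1e-9, 1e-9 * max(abs(u)))
    sort(unique(c(u, mids, max(u) + eps)))
  }
  ca <- cand(p_lea); cb <- cand(l_min)
  n_asy <- sum(is_asy); n_sh <- sum(!is_asy)

  pa <- p_lea[is_asy]; la <- l_min[is_asy]
  ps <- p_lea[!is_asy]; ls <- l_min[!is_asy]
  # detected(a, b) counts points with p < a or l < b
  # = N - #(p >= a & l >= b); the joint count is computed per a by suffix
  # sums over sorted l among the points with p >= a
  best <- NULL
  for (a in ca) {
    la_sub <- sort(la[pa >= a]); ls_sub <- sort(ls[ps >= a])
    det_asy <- n_asy - (length(la_sub) - findInterval(cb - 1e-15, la_sub))
    lost_sh <- n_sh - (length(ls_sub) - findInterval(cb - 1e-15, ls_sub))
    ok <- lost_sh <= max_shock_loss * n_sh
    if (!any(ok)) next
    i <- which(ok)
    i <- i[order(-det_asy[i], lost_sh[i], cb[i])]
    top <- i[1]
    key <- c(det_asy[top], -lost_sh[top], -a, -cb[top])
    if (is.null(best) || .lex_gt(key, best$key)) {
      best <- list(key = key, a = a, b = cb[top],
                   det = det_asy[top], lost = lost_sh[top])
    }
  }
  if (is.null(best)) {
    warning("no feasible threshold pair; returning degenerate all-pass thresholds")
    th <- lea_thresholds(min(ca), min(cb))
    attr(th, "infeasible") <- TRUE
    attr(th, "asy_detected") <- mean(p_lea[is_asy] < min(ca) | l_min[is_asy] < min(cb))
    attr(th, "shock_lost") <- mean(p_lea[!is_asy] < min(ca) | l_min[!is_asy] < min(cb))
    return(th)
  }
  th <- lea_thresholds(best$a, best$b)
  attr(th, "asy_detected") <- best$det / n_asy
  attr(th, "shock_lost") <- best$lost / n_sh
  th
}

.lex_gt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(TRUE)
    if (a[i] < b[i]) return(FALSE)
  }
  FALSE
}

#' Record-level bootstrap confidence intervals for Se and Sp
#'
#' Windows (or segments) of one record are correlated, so item-level
#' intervals would be too tight. This percentile bootstrap resamples whole
#' records with replacement and recomputes sensitivity and specificity on
#' each replicate, reporting the one-sided lower bound at the requested
#' level for each.
#'
#' @param correct logical per item: was the advice correct?
#' @param shockable logical per item: ground-truth shockable?
#' @param record_id per-item record identifier.
#' @param level one-sided confidence level (default 0.90).
#' @param reps bootstrap replicates.
#' @param seed integer seed.
#' @return A list with `se`, `sp` (point estimates) and `se_low`, `sp_low`
#'   (lower bounds), plus `method = "record bootstrap"`.
#' @export
cluster_ci <- function(correct, shockable, record_id, level = 0.90,
                       reps = 2000, seed = 1L) {
  stopifnot(length(correct) == length(shockable),
            length(correct) == length(record_id), is.logical(correct),
            is.logical(shockable))
  recs <- unique(record_id)
  if (length(recs) < 2) stop("at least two records are required")
  by_rec <- split(seq_along(correct), record_id)
  stat <- function(idx_recs) {
    idx <- unlist(by_rec[idx_recs], use.names = FALSE)
    sh <- shockable[idx]
    c(se = if (any(sh)) mean(correct[idx][sh]) else NA_real_,
      sp = if (any(!sh)) mean(correct[idx][!sh]) else NA_real_)
  }
  point <- stat(seq_along(by_rec))
  boot <- withr_seed(seed, {
    vapply(seq_len(reps),
           function(i) stat(sample.int(length(by_rec), replace = TRUE)),
           c(se = 0, sp = 0))
  })
  alpha <- 1 - level
  list(se = unname(point["se"]), sp = unname(point["sp"]),
       se_low = unname(stats::quantile(boot["se", ], alpha, na.rm = TRUE)),
       sp_low = unname(stats::quantile(boot["sp", ], alpha, na.rm = TRUE)),
       level = level, reps = reps, method = "record bootstrap")
}

#' Evaluate a shock-advice model on a corpus of records
#'
#' Runs the full pipeline (preprocess, artifact suppression, window and
#' segment classification) on every record and tabulates window- and
#' segment-level performance with a per-rhythm-class breakdown and
#' record-level bootstrap confidence intervals.
#'
#' @param records list of [signal_record()]s with known rhythm labels.
#' @param model an [saa_model()].
#' @param filter_config a [filter_config()].
#' @param ci_reps,ci_seed,ci_level bootstrap settings for [cluster_ci()].
#' @return A list of class `saa_report`: `windows` and `segments`
#'   (data.frames with truth and advice), `window_metrics`,
#'   `segment_metrics` (each with counts, `se`, `sp`, `ber`, CIs and a
#'   per-class breakdown).
#' @export
evaluate_corpus <- function(records, model, filter_config = cprsaa::filter_config(),
                            ci_reps = 2000, ci_seed = 1L, ci_level = 0.90) {
  res <- lapply(records, function(r) analyze_record(r, model, filter_config))
  win <- do.call(rbind, lapply(res, `[[`, "windows"))
  seg <- do.call(rbind, lapply(res, `[[`, "segments"))
  metrics <- function(d) {
    truth_sh <- d$truth == "Sh"
    adv_sh <- d$decision == "Sh"
    tp <- sum(truth_sh & adv_sh); fn <- sum(truth_sh & !adv_sh)
    tn <- sum(!truth_sh & !adv_sh); fp <- sum(!truth_sh & adv_sh)
    ss <- se_sp(tp, fp, tn, fn)
    ci <- cluster_ci(d$decision == d$truth, truth_sh, d$record_id,
                     level = ci_level, reps = ci_reps, seed = ci_seed)
    by_class <- lapply(split(d, d$class), function(g)
      c(n = nrow(g), correct = mean(g$decision == g$truth)))
    list(counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
         se = unname(ss["se"]), sp = unname(ss["sp"]),
         ber = unname(ber(ss[["se"]], ss[["sp"]])),
         ci = ci, by_class = by_class)
  }
  structure(list(windows = win, segments = seg,
                 window_metrics = metrics(win),
                 segment_metrics = metrics(seg)),
            class = "saa_report")
}

#' @export
print.saa_report <- function(x, ...) {
  w <- x$window_metrics; s <- x$segment_metrics
  cat(sprintf("<saa_report> windows: Se %.1f%% Sp %.1f%% | segments: Se %.1f%% Sp %.1f%%\n",
              100 * w$se, 100 * w$sp, 100 * s$se, 100 * s$sp))
  invisible(x)
}
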