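#' Analyze one record end to end
#'
#' Preprocesses the record (resampling to the analysis rate and 0.5 to
#' 30 Hz band-pass), suppresses the compression artifact with the harmonic
#' LMS filter, splits the filtered ECG into 9-s segments of three 3-s
#' windows, classifies every window (LEA detector then SVM) and every
#' segment (majority vote).
#'
#' @param record a [signal_record()].
#' @param model an [saa_model()].
#' @param filter_config a [filter_config()].
#' @return A list with `windows` and `segments` data.frames (decision,
#'   stage/votes, truth, record and patient ids) and the `filter_result`.
#' @export
analyze_record <- function(record, model, filter_config = cprsaa::filter_config()) {
  stopifnot(inherits(record, "signal_record"), inherits(model, "saa_model"))
  fs <- model$feature_config$fs
  rec <- preprocess_record(record, fs = fs)
  fr <- lms_suppress(rec$ecg, rec$marks, filter_config)
  segs <- extract_segments(signal_trace(fr$s_filt$samples, fs,
                                        rec$ecg$start_time), fs = fs)
  sh <- is_shockable(record$rhythm_label)
  truth <- if (is.na(sh)) NA_character_ else if (sh) "Sh" else "NSh"
  cls <- attr(record, "rhythm_class")
  if (is.null(cls)) {
    cls <- switch(record$rhythm_label, VF = "VF", VT = "VF", ASY = "ASY",
                  PEA = "ORG", PR = "ORG", NA_character_)
  }
  win_rows <- list(); seg_rows <- list()
  for (i in seq_along(segs)) {
    dec <- lapply(seq_len(3), function(j)
      classify_window(segs[[i]]$windows[, j], model))
    dec <- do.call(rbind, dec)
    win_rows[[i]] <- cbind(segment = i, window = seq_len(3), dec)
    seg_rows[[i]] <- data.frame(segment = i,
                                decision = classify_segment(dec$decision),
                                sh_votes = sum(dec$decision == "Sh"),
                                stringsAsFactors = FALSE)
  }
  finish <- function(d) {
    if (is.null(d)) return(NULL)
    d$truth <- truth
    d$class <- cls
    d$record_id <- record$record_id
    d$patient_id <- record$patient_id
    d
  }
  list(windows = finish(do.call(rbind, win_rows)),
       segments = finish(do.call(rbind, seg_rows)),
       filter_result = fr)
}

#' Per-window feature table for a set of records
#'
#' Runs preprocessing and artifact suppression on each record and returns
#' the six features of every 3-s window together with its labels; the
#' training entry point for [train_saa()].
#'
#' @param records list of [signal_record()]s.
#' @param feature_config a [feature_config()].
#' @param filter_config a [filter_config()].
#' @return A data.frame with the six feature columns, `truth`
#'   (`"Sh"`/`"NSh"`), `class` (`"VF"`, `"ORG"`, `"ASY"` when known),
#'   `record_id` and `patient_id`.
#' @export
corpus_features <- function(records, feature_config = cprsaa::feature_config(),
                            filter_config = cprsaa::filter_config()) {
  rows <- lapply(records, function(record) {
    fs <- feature_config$fs
    rec <- preprocess_record(record, fs = fs)
    fr <- lms_suppress(rec$ecg, rec$marks, filter_config)
    segs <- extract_segments(signal_trace(fr$s_filt$samples, fs), fs = fs)
    if (!length(segs)) return(NULL)
    cls <- attr(record, "rhythm_class")
    if (is.null(cls))
      cls <- switch(record$rhythm_label, VF = "VF", VT = "VF", ASY = "ASY",
                    PEA = "ORG", PR = "ORG", NA_character_)
    feats <- do.call(rbind, lapply(segs, function(sg)
      t(apply(sg$windows, 2, window_features, config = feature_config))))
    d <- as.data.frame(feats)
    sh <- is_shockable(record$rhythm_label)
    d$truth <- if (is.na(sh)) NA_character_ else if (sh) "Sh" else "NSh"
    d$class <- cls
    d$record_id <- record$record_id
    d$patient_id <- record$patient_id
    d
  })
  do.call(rbind, rows)
}

#' Train the full shock-advice algorithm
#'
#' Two sequential optimization steps on the training windows, mirroring how
#' the two stages are used at run time:
#'
#' 1. *LEA detector*: thresholds fit by exhaustive scan on the asystole and
#'    shockable windows, maximizing asystole detections subject to at most
#'    `max_shock_loss` of shockable windows lost ([calibrate_lea()]).
#' 2. *Shock/no-shock SVM*: trained on the shockable and organized-rhythm
#'    windows that the fitted LEA detector does not intercept, with
#'    BER-optimized, class-weighted, stratified cross-validated grid search
#'    ([svm_train()]).
#'
#' @param features a feature table from [corpus_features()] (or any
#'   data.frame with the six feature columns, `truth`, `class`, and
#'   `record_id`).
#' @param train_config a [train_config()].
#' @param feature_config the [feature_config()] the features were computed
#'   under (stored in the model).
#' @param max_shock_loss constraint for the LEA calibration.
#' @return An [saa_model()].
#' @export
train_saa <- function(features, train_config = cprsaa::train_config(),
                      feature_config = cprsaa::feature_config(),
                      max_shock_loss = 0.05) {
  needed <- c("P_LEA", "L_min", "bS", "nP", "P_fib", "P_h", "truth", "class")
  stopifnot(all(needed %in% names(features)))
  cal <- features$class %in% c("ASY") | features$truth == "Sh"
  lea <- calibrate_lea(features$P_LEA[cal], features$L_min[cal],
                       features$class[cal] == "ASY", max_shock_loss)
  pass <- !lea_detect(features$P_LEA, features$L_min, lea)
  use <- pass & features$class %in% c("VF", "ORG")
  rid <- if ("record_id" %in% names(features)) features$record_id[use] else NULL
  svm <- svm_train(as.matrix(features[use, c("bS", "nP", "P_fib", "P_h")]),
                   features$truth[use], train_config, record_id = rid)
  saa_model(lea, svm, feature_config)
}

#' Save / load a shock-advice model as JSON
#'
#' Versioned plain-text serialization of the full [saa_model()]: LEA
#' thresholds, support vectors, dual coefficients, bias, kernel width, soft
#' margin, class weights, standardization statistics and the feature
#' configuration.
#'
#' @param model an [saa_model()].
#' @param path output / input file path.
#' @return `save_model`: `path` invisibly. `load_model`: an [saa_model()].
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "saa_model"))
  doc <- list(
    format = "cprsaa-model", version = 1L,
    lea = list(p_lea_max = model$lea$p_lea_max, l_min_max = model$lea$l_min_max),
    svm = list(sv = model$svm$sv, coefs = model$svm$coefs, b = model$svm$b,
               gamma = model$svm$gamma, cost = model$svm$cost,
               class_weights = as.list(model$svm$class_weights),
               mean = as.list(model$svm$standardization$mean),
               sd = as.list(model$svm$standardization$sd),
               feature_names = model$svm$feature_names),
    feature_config = unclass(model$feature_config))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "cprsaa-model"))
    stop("not a cprsaa model file: ", path)
  svm <- structure(list(
    sv = matrix(as.numeric(doc$svm$sv), ncol = length(doc$svm$feature_names)),
    coefs = as.numeric(doc$svm$coefs), b = doc$svm$b,
    gamma = doc$svm$gamma, cost = doc$svm$cost,
    n_sv = length(doc$svm$coefs),
    class_weights = unlist(doc$svm$class_weights),
    standardization = list(mean = unlist(doc$svm$mean), sd = unlist(doc$svm$sd)),
    feature_names = doc$svm$feature_names,
    cv = NULL, cv_ber = NA_real_), class = "saa_svm")
  fc <- do.call(feature_config, doc$feature_config[
    c("lea_highpass_cutoff", "slope_window_ms", "peak_threshold",
      "fib_band", "high_band", "fft_len", "fs")])
  saa_model(lea_thresholds(doc$lea$p_lea_max, doc$lea$l_min_max), svm, fc)
}
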