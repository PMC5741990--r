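#' Contrast-to-noise ratio of a block-design series
#'
#' `CNR = (mean over task frames - mean over rest frames) / SD over rest
#' frames`, with task/rest membership taken from the timeline (half-open
#' block intervals). All rest frames, including the lead-in, enter the rest
#' statistics.
#'
#' @param values Numeric series aligned to the timeline.
#' @param timeline A `timeline` from [build_timeline()].
#' @return Scalar CNR (dimensionless).
#' @export
compute_cnr <- function(values, timeline) {
  stopifnot(inherits(timeline, "timeline"),
            length(values) == length(timeline$task_indicator))
  task <- timeline$task_indicator == 1L
  if (!any(task) || all(task)) stop("timeline must contain task and rest frames")
  s <- sd(values[!task])
  if (!is.finite(s) || s == 0) stop("undefined CNR: rest-period SD is zero")
  (mean(values[task]) - mean(values[!task])) / s
}

#' Correlation with the theoretical activation model
#'
#' Pearson correlation between a series and the boxcar-convolved-HRF
#' regressor of the design.
#'
#' @param values Numeric series aligned to the design timeline.
#' @param design A `block_design`.
#' @param hrf An `hrf_model`.
#' @return Scalar r in \[-1, 1\].
#' @export
compute_model_correlation <- function(values, design, hrf = hrf_model()) {
  reg <- task_regressor(design, hrf)
  stopifnot(length(values) == length(reg))
  if (sd(values) == 0) stop("undefined correlation: series has zero variance")
  cor(values, reg)
}

#' CNR and model-correlation feature vector
#'
#' Optionally runs the signal-conditioning chain first (the same chain must
#' be used in training and application).
#'
#' @param values Numeric series.
#' @param design,hrf Paradigm and HRF.
#' @param preprocess Apply [preprocess_series()] before computing features.
#' @param ... Passed to [preprocess_series()].
#' @return Named numeric vector `c(cnr, r)`.
#' @export
extract_features <- function(values, design, hrf = hrf_model(),
                             preprocess = TRUE, ...) {
  if (sd(values) == 0) stop("zero-variance series: features are undefined")
  if (preprocess) {
    fs <- 1 / design$frame_interval_s
    values <- preprocess_series(values, fs, ...)$values
  }
  tl <- build_timeline(design)
  c(cnr = compute_cnr(values, tl),
    r = compute_model_correlation(values, design, hrf))
}

#' Train the support-vector activation classifier
#'
#' Fits a support-vector machine on the (CNR, r) features of a simulated
#' training corpus. Features are computed after the same signal-conditioning
#' chain used at application time, and standardized inside the SVM. The
#' default kernel is linear with unit cost: on two features that are both
#' monotonically related to activation strength, a linear boundary
#' generalizes to responses far stronger than any training example, whereas
#' a radial-basis decision function decays back to the majority class far
#' from the support vectors and can reject an unambiguous activation.
#' Hyperparameters and per-class training accuracy are recorded in the
#' report.
#'
#' @param corpus A `training_corpus` from [generate_training_corpus()].
#' @param hrf HRF used for the correlation feature.
#' @param kernel,cost,gamma SVM hyperparameters (see [e1071::svm()];
#'   `gamma = NULL` uses the 1/n_features default).
#' @param preprocess Condition each series before feature extraction.
#' @return An `activation_model`: the fitted SVM, the feature table, a
#'   training report (hyperparameters, per-class accuracy) and the corpus
#'   manifest hash.
#' @export
train_activation_classifier <- function(corpus, hrf = hrf_model(),
                                        kernel = "linear", cost = 1,
                                        gamma = NULL, preprocess = TRUE) {
  stopifnot(inherits(corpus, "training_corpus"))
  if (nlevels(droplevels(corpus$labels)) < 2)
    stop("degenerate corpus: both classes must be present")
  design <- corpus$series[[1]]$timeline$design
  feats <- t(vapply(corpus$series, function(s)
    extract_features(s$values, design, hrf, preprocess = preprocess),
    numeric(2)))
  colnames(feats) <- c("cnr", "r")
  args <- list(x = feats, y = corpus$labels, kernel = kernel, cost = cost,
               scale = TRUE, probability = FALSE)
  if (!is.null(gamma)) args$gamma <- gamma
  fit <- do.call(e1071::svm, args)
  pred <- predict(fit, feats)
  acc <- vapply(levels(corpus$labels), function(l)
    mean(pred[corpus$labels == l] == l), numeric(1))
  report <- list(kernel = kernel, cost = cost,
                 gamma = fit$gamma, n_support = fit$tot.nSV,
                 training_accuracy = acc,
                 corpus_hash = config_hash(corpus$manifest))
  structure(list(fit = fit, features = feats, labels = corpus$labels,
                 design = design, hrf = hrf, preprocess = preprocess,
                 report = report),
            class = "activation_model")
}

#' @export
print.activation_model <- function(x, ...) {
  cat(sprintf("Activation classifier: %s-kernel SVM on (CNR, r), %d training sets\n",
              x$report$kernel, nrow(x$features)))
  cat(sprintf("  training accuracy: activation %.0f%%, rest %.0f%%\n",
              100 * x$report$training_accuracy["activation"],
              100 * x$report$training_accuracy["rest"]))
  invisible(x)
}

#' Classify one channel as activated or not
#'
#' Computes the (CNR, r) features of a channel's oxyhemoglobin series and
#' applies the trained classifier. A channel counts as activated only when
#' the classifier assigns the activation class AND its CNR is positive,
#' since the target response is an oxyhemoglobin increase.
#'
#' @param values Oxyhemoglobin series of one channel.
#' @param model An `activation_model`.
#' @param channel Channel identifier.
#' @param preprocess Condition the series first (default: as trained).
#' @return A `channel_decision`: `channel`, `activated`, `features`.
#' @export
classify_channel <- function(values, model, channel = "ch1",
                             preprocess = model$preprocess) {
  stopifnot(inherits(model, "activation_model"))
  f <- extract_features(values, model$design, model$hrf,
                        preprocess = preprocess)
  cls <- as.character(predict(model$fit, matrix(f, nrow = 1,
                                                dimnames = list(NULL, c("cnr", "r")))))
  structure(list(channel = channel,
                 activated = (cls == "activation") && f[["cnr"]] > 0,
                 features = f),
            class = "channel_decision")
}

#' Decode a yes/no answer from per-channel decisions
#'
#' The answer is "yes" iff at least one channel is classified as activated.
#' Summary features are averaged over the activated channels for a "yes"
#' and over all channels for a "no".
#'
#' @param decisions List of `channel_decision` objects (>= 1).
#' @param question_id Identifier of the question.
#' @return An `answer`: `question_id`, `response` ("yes"/"no"),
#'   `n_activated`, `decisions`, `mean_cnr`, `mean_r`.
#' @export
decide_answer <- function(decisions, question_id = "Q1") {
  if (length(decisions) == 0) stop("empty decision set")
  stopifnot(all(vapply(decisions, inherits, logical(1), "channel_decision")))
  act <- vapply(decisions, `[[`, logical(1), "activated")
  feats <- t(vapply(decisions, `[[`, numeric(2), "features"))
  use <- if (any(act)) act else rep(TRUE, length(act))
  structure(list(question_id = question_id,
                 response = if (any(act)) "yes" else "no",
                 n_activated = sum(act),
                 decisions = decisions,
                 mean_cnr = mean(feats[use, 1]),
                 mean_r = mean(feats[use, 2])),
            class = "answer")
}

#' @export
print.answer <- function(x, ...) {
  cat(sprintf("%s: %s (%d/%d channels activated; mean CNR = %.2f, mean r = %.2f)\n",
              x$question_id, toupper(x$response), x$n_activated,
              length(x$decisions), x$mean_cnr, x$mean_r))
  for (d in x$decisions)
    cat(sprintf("  %s: %s  CNR = %.2f, r = %.2f\n", d$channel,
                if (d$activated) "activated" else "not activated",
                d$features[["cnr"]], d$features[["r"]]))
  invisible(x)
}

#' Cycle-averaged time course
#'
#' Folds a series over the task+rest cycle length and returns the mean and
#' standard error per folded frame. By default the lead-in rest is dropped
#' so cycle 1 starts at the first task frame; with
#' `include_lead_in = TRUE` folding starts at t = 0 and any incomplete
#' trailing cycle is dropped with a warning.
#'
#' @param values Numeric series aligned to the design timeline.
#' @param design A `block_design`.
#' @param include_lead_in Fold from t = 0 instead of dropping the lead-in.
#' @return List with `mean`, `sem`, `times` (seconds within the folded
#'   cycle) and `n_cycles`.
#' @export
cycle_average <- function(values, design, include_lead_in = FALSE) {
  dt <- design$frame_interval_s
  cyc <- round((design$task_s + design$cycle_rest_s) / dt)
  start <- if (include_lead_in) 1L else round(design$lead_in_rest_s / dt) + 1L
  x <- values[start:length(values)]
  ncyc <- length(x) %/% cyc
  if (ncyc < 1) stop("need at least one complete cycle")
  if (length(x) %% cyc != 0)
    warning(sprintf("dropping %d frames of an incomplete cycle",
                    length(x) %% cyc))
  M <- matrix(x[seq_len(ncyc * cyc)], nrow = cyc)
  mu <- rowMeans(M)
  sem <- if (ncyc > 1) apply(M, 1, sd) / sqrt(ncyc) else rep(0, cyc)
  list(mean = mu, sem = sem, times = (seq_len(cyc) - 1) * dt,
       n_cycles = ncyc)
}
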