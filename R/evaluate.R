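# ROC/AUC, MCC, sensitivity/specificity under stratified cross-validation.

#' ROC curve and area under it
#'
#' Sweeps all distinct score thresholds; ties are grouped so the curve takes
#' diagonal segments and the trapezoidal area equals the Mann-Whitney
#' statistic with ties counted one half.
#'
#' @param scores Real-valued classifier scores (higher = more positive).
#' @param labels Binary labels in {0, 1}, same length.
#' @return List with `curve` (data frame of fpr, tpr from (0,0) to (1,1))
#'   and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0 || N == 0)
    stop("ROC undefined: both classes must be present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # cumulative counts taken at the last index of each tied-score group
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  tpr <- c(0, cumsum(l)[last] / P)
  fpr <- c(0, cumsum(1 - l)[last] / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Sensitivity, specificity and Matthews correlation from a confusion matrix
#'
#' `sens = 100 * TP / (TP + FN)`, `spec = 100 * TN / (TN + FP)`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with MCC
#' defined as 0 when any factor under the root is zero.
#'
#' @param tp,fp,tn,fn Non-negative integer counts; alternatively pass a list
#'   with those fields as `tp`.
#' @return List with `sensitivity` and `specificity` (percent) and `mcc`.
#' @export
confusion_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.list(tp)) { fp <- tp$fp; tn <- tp$tn; fn <- tp$fn; tp <- tp$tp }
  counts <- c(tp, fp, tn, fn)
  stopifnot(length(counts) == 4, all(counts >= 0))
  if (sum(counts) == 0)
    stop("metrics undefined for all-zero confusion counts", call. = FALSE)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  list(sensitivity = sens, specificity = spec, mcc = mcc)
}

.confusion <- function(scores, labels, threshold) {
  pred <- as.integer(scores > threshold)
  list(tp = sum(pred == 1 & labels == 1), fp = sum(pred == 1 & labels == 0),
       tn = sum(pred == 0 & labels == 0), fn = sum(pred == 0 & labels == 1))
}

#' Seeded stratified fold assignment
#'
#' @param y Binary labels.
#' @param folds Number of folds, >= 2.
#' @param seed Integer seed.
#' @return Integer fold id (1..folds) per example; every fold contains both
#'   classes.
#' @export
stratified_folds <- function(y, folds = 5, seed = 1) {
  stopifnot(folds >= 2)
  y <- as.integer(y)
  if (folds == length(y)) return(seq_along(y)) # leave-one-out
  if (min(table(factor(y, c(0, 1)))) < folds)
    stop(sprintf("each class needs at least %d examples for %d folds",
                 folds, folds), call. = FALSE)
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cls in c(1L, 0L)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Stratified cross-validated evaluation of one hyperparameter setting
#'
#' Splits the data into seeded stratified folds, trains on k-1 folds and
#' scores the held-out fold, then reports per-fold and pooled sensitivity,
#' specificity, MCC and AUC. The pooled ROC is computed from the
#' concatenated held-out scores; the operating threshold is the natural one
#' for the score type (0 for SVM decision values, 0.5 otherwise).
#'
#' @param data A `pl_dataset` (or `list(X, y)`).
#' @param params A `pl_params`.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed (controls fold assignment and training).
#' @param fold_id Optional pre-computed fold assignment (overrides
#'   `folds`/`seed` for the split).
#' @return Object of class `pl_report`.
#' @export
cross_validate <- function(data, params, folds = 5, seed = 1, fold_id = NULL) {
  d <- .as_xy(data)
  if (is.null(fold_id)) fold_id <- stratified_folds(d$y, folds, seed)
  folds <- max(fold_id)
  thr <- score_threshold(params$algorithm)
  pooled_scores <- numeric(length(d$y))
  per_fold <- vector("list", folds)
  for (k in seq_len(folds)) {
    te <- which(fold_id == k)
    tr <- which(fold_id != k)
    model <- train(list(X = d$X[tr, , drop = FALSE], y = d$y[tr]), params,
                   seed = seed)
    sc <- score(model, d$X[te, , drop = FALSE])
    pooled_scores[te] <- sc
    # per-fold metrics are undefined when a fold holds one class only
    # (leave-one-out); the pooled metrics below always exist
    fold_auc <- tryCatch(roc_auc(sc, d$y[te])$auc, error = function(e) NA_real_)
    cm <- confusion_metrics(.confusion(sc, d$y[te], thr))
    per_fold[[k]] <- data.frame(fold = k, auc = fold_auc,
                                sensitivity = cm$sensitivity,
                                specificity = cm$specificity, mcc = cm$mcc)
  }
  roc <- roc_auc(pooled_scores, d$y)
  cmp <- confusion_metrics(.confusion(pooled_scores, d$y, thr))
  structure(
    list(algorithm = params$algorithm, params = params, folds = folds,
         seed = seed, threshold = thr,
         per_fold = do.call(rbind, per_fold),
         pooled = list(auc = roc$auc, sensitivity = cmp$sensitivity,
                       specificity = cmp$specificity, mcc = cmp$mcc),
         roc = roc$curve),
    class = "pl_report"
  )
}

#' Stratified holdout split
#'
#' Randomly samples `test_fraction` of each class into a disjoint test set
#' (the usual 15% holdout), reproducibly by seed.
#'
#' @param data A `pl_dataset` or `list(X, y)`.
#' @param test_fraction Fraction in (0, 1); default 0.15.
#' @param seed Integer seed.
#' @return List with `train` and `test`, both `list(X, y, idx)` where `idx`
#'   are row indices into the input.
#' @export
holdout_split <- function(data, test_fraction = 0.15, seed = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  d <- .as_xy(data)
  set.seed(as.integer(seed))
  # largest-remainder stratified rounding: per-class counts sum to the
  # rounded overall test size (100 examples at 0.15 -> exactly 15)
  classes <- c(1L, 0L)
  n_cls <- vapply(classes, function(cl) sum(d$y == cl), 0L)
  classes <- classes[order(-n_cls)]
  n_cls <- sort(n_cls, decreasing = TRUE)
  total <- round(test_fraction * length(d$y))
  quota <- floor(test_fraction * n_cls)
  rem <- order(-(test_fraction * n_cls - quota))
  k <- total - sum(quota)
  if (k > 0) quota[rem[seq_len(k)]] <- quota[rem[seq_len(k)]] + 1L
  test_idx <- integer(0)
  for (i in seq_along(classes)) {
    idx <- which(d$y == classes[i])
    if (quota[i] == 0 || quota[i] == length(idx))
      stop("test fraction leaves a class empty on one side", call. = FALSE)
    test_idx <- c(test_idx, idx[sample.int(length(idx), quota[i])])
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(d$y), test_idx)
  list(
    train = list(X = d$X[train_idx, , drop = FALSE], y = d$y[train_idx],
                 idx = train_idx),
    test = list(X = d$X[test_idx, , drop = FALSE], y = d$y[test_idx],
                idx = test_idx)
  )
}

#' Serialize an evaluation report to canonical JSON
#'
#' Deterministic text (fixed field order, full precision) so identical runs
#' produce byte-identical reports.
#' @param report A `pl_report`.
#' @param path Optional output path; when given, the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
report_json <- function(report, path = NULL) {
  payload <- list(
    algorithm = report$algorithm, folds = report$folds, seed = report$seed,
    threshold = report$threshold, pooled = report$pooled,
    per_fold = report$per_fold, roc = report$roc
  )
  txt <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                          dataframe = "columns")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Write ROC points as TSV / export the ROC figure
#'
#' @param report A `pl_report`.
#' @param path Output path; for `plot_roc` the extension selects the device
#'   (`.svg` or `.png`).
#' @return `path`, invisibly.
#' @export
write_roc <- function(report, path) {
  utils::write.table(report$roc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_roc
#' @export
plot_roc <- function(report, path = NULL) {
  draw <- function() {
    plot(report$roc$fpr, report$roc$tpr, type = "l",
         xlab = "False positive rate (FPR)",
         ylab = "True positive rate (TPR)",
         main = sprintf("%s, AUC = %.3f", toupper(report$algorithm),
                        report$pooled$auc))
    abline(0, 1, lty = 2, col = "grey")
  }
  if (is.null(path)) {
    draw()
    return(invisible(NULL))
  }
  if (grepl("\\.svg$", path)) grDevices::svg(path)
  else grDevices::png(path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  draw()
  invisible(path)
}

#' @export
print.pl_report <- function(x, ...) {
  cat(sprintf(
    "pl_report: %s, %d-fold CV | AUC %.3f  Sens %.1f%%  Spec %.1f%%  MCC %.3f\n",
    x$algorithm, x$folds, x$pooled$auc, x$pooled$sensitivity,
    x$pooled$specificity, x$pooled$mcc))
  invisible(x)
}
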