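#' Confusion matrix of true vs predicted activity labels
#'
#' @param truth,pred Character or factor vectors of equal length.
#' @param levels Class labels fixing row/column order (default the seven
#'   activity classes).
#' @return A square integer matrix of class `confusion_matrix`; rows are
#'   true classes, columns predicted classes.
#' @export
confusion_matrix <- function(truth, pred, levels = activity_classes()) {
  if (length(truth) != length(pred)) stop("'truth' and 'pred' lengths differ")
  m <- table(factor(truth, levels = levels), factor(pred, levels = levels))
  m <- matrix(as.integer(m), nrow = length(levels),
              dimnames = list(truth = levels, predicted = levels))
  structure(m, class = c("confusion_matrix", class(m)))
}

as_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm))
    stop("confusion matrix must be square")
  if (any(cm < 0)) stop("confusion matrix counts must be non-negative")
  cm
}

#' Multiclass accuracy of a confusion matrix
#'
#' The multiclass generalisation of (TP + TN) / (TP + TN + FP + FN): the
#' share of all samples on the diagonal.
#'
#' @param cm A square count matrix (rows true, columns predicted).
#' @return Accuracy in `[0, 1]`.
#' @export
#' @examples
#' cm_accuracy(matrix(c(40, 20, 10, 30), 2))  # 0.7
cm_accuracy <- function(cm) {
  cm <- as_cm(cm)
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  sum(diag(cm)) / n
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement `k = (po - pe) / (1 - pe)`, with observed
#' agreement `po` the accuracy and expected agreement `pe` the sum over
#' classes of (row total x column total) / total^2. The raw kappa is
#' reported unclamped (it can be negative under worse-than-chance
#' agreement); the agreement band is attached via [agreement_band()].
#'
#' @param cm A square count matrix (rows true, columns predicted).
#' @return An object of class `kappa_result`: list with `kappa`, `po`,
#'   `pe`, `band`.
#' @export
#' @examples
#' cohens_kappa(matrix(c(40, 20, 10, 30), 2))  # kappa 0.4
cohens_kappa <- function(cm) {
  cm <- as_cm(cm)
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-15)
    stop("kappa undefined: expected agreement is 1 (single-class matrix)")
  k <- (po - pe) / (1 - pe)
  structure(list(kappa = k, po = po, pe = pe, band = agreement_band(k)),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa %.4f (po %.4f, pe %.4f): %s agreement\n",
              x$kappa, x$po, x$pe, x$band))
  invisible(x)
}

#' Agreement band of a kappa value
#'
#' Conventional interpretation bands: slight below 0.20, fair in
#' `[0.20, 0.40)`, moderate in `[0.40, 0.60)`, good in `[0.60, 0.80)`,
#' perfect in `[0.80, 1]`. The published band table leaves small gaps at
#' the decade boundaries; half-open intervals are used so every value up
#' to 1 is covered, and negative (worse-than-chance) kappa bands as
#' slight.
#'
#' @param kappa Kappa value (`<= 1`).
#' @return One of "slight", "fair", "moderate", "good", "perfect".
#' @export
#' @examples
#' agreement_band(0.85)  # "perfect"
#' agreement_band(0.50)  # "moderate"
agreement_band <- function(kappa) {
  stopifnot_scalar_num(kappa, "kappa")
  if (kappa > 1 + 1e-12) stop("kappa cannot exceed 1")
  eps <- 1e-9  # keep floating-point kappas at band edges in the upper band
  if (kappa < 0.20 - eps) "slight"
  else if (kappa < 0.40 - eps) "fair"
  else if (kappa < 0.60 - eps) "moderate"
  else if (kappa < 0.80 - eps) "good"
  else "perfect"
}

#' Relative error of an energy-expenditure estimate
#'
#' `RE(%) = |EE_gt - EE_est| / EE_gt * 100`.
#'
#' @param ee_gt Ground-truth energy expenditure in kcal (> 0).
#' @param ee_est Estimated energy expenditure in kcal.
#' @return Relative error in percent.
#' @export
#' @examples
#' relative_error(10, 20)  # 100
relative_error <- function(ee_gt, ee_est) {
  if (any(ee_gt <= 0)) stop("'ee_gt' must be positive")
  abs(ee_gt - ee_est) / ee_gt * 100
}

#' Assemble an evaluation report
#'
#' Bundles a confusion matrix with its accuracy and kappa, optional
#' per-protocol breakdowns and per-subject relative errors.
#'
#' @param cm A [confusion_matrix()].
#' @param per_protocol Optional named list of sub-reports.
#' @param relative_errors Optional named numeric vector (percent).
#' @return An object of class `eval_report`.
#' @export
eval_report <- function(cm, per_protocol = NULL, relative_errors = NULL) {
  structure(list(confusion = cm,
                 accuracy = cm_accuracy(cm),
                 kappa = cohens_kappa(cm),
                 per_protocol = per_protocol,
                 relative_errors = relative_errors),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation: accuracy %.4f, kappa %.4f (%s agreement)\n",
              x$accuracy, x$kappa$kappa, x$kappa$band))
  if (!is.null(x$relative_errors))
    cat(sprintf("EE relative error: max %.2f%%, mean %.2f%%\n",
                max(x$relative_errors), mean(x$relative_errors)))
  invisible(x)
}

#' Serialise an evaluation report
#'
#' `write_eval_report` writes the report as JSON; `write_confusion_csv`
#' exports a confusion matrix as CSV for plotting.
#'
#' @param report An [eval_report()].
#' @param path Output path.
#' @export
write_eval_report <- function(report, path) {
  out <- list(
    accuracy = report$accuracy,
    kappa = report$kappa$kappa,
    po = report$kappa$po,
    pe = report$kappa$pe,
    band = report$kappa$band,
    confusion = as.data.frame.matrix(unclass(report$confusion)),
    relative_errors = as.list(report$relative_errors)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_eval_report
#' @param cm A [confusion_matrix()].
#' @export
write_confusion_csv <- function(cm, path) {
  utils::write.csv(as.data.frame.matrix(unclass(cm)), path, row.names = TRUE)
  invisible(path)
}
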