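# Diagnostic-accuracy statistics: confusion matrix, sensitivity,
# specificity, likelihood ratios, accuracy, exact binomial test against
# chance, ROC curve and AUC.

#' Confusion matrix from true and predicted labels
#'
#' The positive class is DLD (label 1): TP are children with DLD called
#' DLD, FN children with DLD called control, FP controls called DLD, TN
#' controls called control.
#'
#' @param truth,predicted Binary vectors (DLD = 1) of equal length, or a
#'   `selimi` fit's results can be tallied via [summary.selimi()].
#' @return Object of class `confusion_matrix` with integer fields `TP`,
#'   `FN`, `FP`, `TN`.
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) == 0L) stop("no results to tally")
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (!all(truth %in% 0:1) || !all(predicted %in% 0:1))
    stop("labels must be binary 0/1")
  structure(list(TP = sum(truth == 1L & predicted == 1L),
                 FN = sum(truth == 1L & predicted == 0L),
                 FP = sum(truth == 0L & predicted == 1L),
                 TN = sum(truth == 0L & predicted == 0L)),
            class = "confusion_matrix")
}

#' Build a confusion matrix directly from the four counts
#'
#' Convenience constructor for published 2x2 tables.
#'
#' @param TP,FN,FP,TN Nonnegative integer counts.
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(TP, FN, FP, TN) {
  counts <- c(TP = TP, FN = FN, FP = FP, TN = TN)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (sum(counts) == 0) stop("confusion matrix is empty")
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2L, byrow = TRUE,
              dimnames = list(actual = c("DLD", "control"),
                              predicted = c("DLD", "control")))
  print(m)
  invisible(x)
}

#' Exact binomial test of classification success against chance
#'
#' Exact two-sided p-value for observing `successes` correct calls out of
#' `n` under a null success probability `p0`, using the point-mass
#' convention: the two-sided p is the total probability of all outcomes
#' whose binomial mass does not exceed that of the observed count (this is
#' [stats::binom.test()]'s convention). No normal approximation is used.
#'
#' @param successes,n Observed correct calls and trials.
#' @param p0 Null success probability (default chance, 0.5).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return The p-value.
#' @export
binomial_test <- function(successes, n, p0 = 0.5,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (n < 1 || successes < 0 || successes > n)
    stop("invalid counts: need 0 <= successes <= n, n >= 1")
  if (p0 <= 0 || p0 >= 1) stop("p0 must be strictly between 0 and 1")
  stats::binom.test(successes, n, p = p0, alternative = alternative)$p.value
}

# Likelihood-ratio benchmarks: LR+ >= 10 and LR- <= .1 mark large
# confidence in ruling the disorder in / out.
.lr_confidence <- function(lr_pos, lr_neg, eps = 1e-9) {
  c(positive = if (is.infinite(lr_pos) || lr_pos >= 10 - eps) "large"
      else if (lr_pos >= 2 - eps) "slight to moderate" else "minimal",
    negative = if (lr_neg <= 0.1 + eps) "large"
      else if (lr_neg <= 0.5 + eps) "slight to moderate" else "minimal")
}

#' Diagnostic-accuracy report from a confusion matrix
#'
#' Computes sensitivity TP/(TP+FN), specificity TN/(TN+FP), the positive
#' and negative likelihood ratios LR+ = sens/(1-spec) and
#' LR- = (1-sens)/spec, accuracy (TP+TN)/n, and the exact binomial p-value
#' of the accuracy against chance. All values are kept at full precision;
#' rounding happens only in the print method.
#'
#' @param cm A `confusion_matrix`.
#' @param p0 Null success probability for the binomial test.
#' @return Object of class `diagnostic_report` with fields `sensitivity`,
#'   `specificity`, `lr_positive` (may be `Inf` when specificity is 1),
#'   `lr_negative`, `accuracy`, `binomial_p`, `n`, `confusion`,
#'   `lr_confidence` (qualitative benchmark annotations).
#' @export
diagnostic_report <- function(cm, p0 = 0.5) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n_pos <- cm$TP + cm$FN
  n_neg <- cm$TN + cm$FP
  if (n_pos == 0L || n_neg == 0L)
    stop("undefined metrics: both actual classes must be represented")
  sens <- cm$TP / n_pos
  spec <- cm$TN / n_neg
  lr_pos <- if (spec == 1) Inf else sens / (1 - spec)
  lr_neg <- if (spec == 0) Inf else (1 - sens) / spec
  n <- n_pos + n_neg
  acc <- (cm$TP + cm$TN) / n
  structure(list(sensitivity = sens, specificity = spec,
                 lr_positive = lr_pos, lr_negative = lr_neg,
                 accuracy = acc,
                 binomial_p = binomial_test(cm$TP + cm$TN, n, p0),
                 n = n, confusion = cm,
                 lr_confidence = .lr_confidence(lr_pos, lr_neg)),
            class = "diagnostic_report")
}

# Truncate (not round) to d decimals; the convention used for printed
# likelihood ratios, e.g. 4.667 -> "4.6", 0.267 -> "0.26".
.trunc_dec <- function(x, d) {
  if (is.infinite(x)) return("Inf")
  formatC(trunc(x * 10^d) / 10^d, format = "f", digits = d)
}

#' Printed-figure formatting of a diagnostic report
#'
#' Percentages are rounded to whole percent; likelihood ratios are
#' truncated to one (LR+) and two (LR-) decimals.
#'
#' @param report A `diagnostic_report`.
#' @return Named character vector of display strings.
#' @export
format_report <- function(report) {
  c(sensitivity = sprintf("%d%%", round(100 * report$sensitivity)),
    specificity = sprintf("%d%%", round(100 * report$specificity)),
    lr_positive = .trunc_dec(report$lr_positive, 1L),
    lr_negative = .trunc_dec(report$lr_negative, 2L),
    accuracy = sprintf("%d%%", round(100 * report$accuracy)),
    binomial_p = if (report$binomial_p < 0.001) "< 0.001"
      else sprintf("= %.3f", report$binomial_p))
}

#' @export
print.diagnostic_report <- function(x, ...) {
  f <- format_report(x)
  cat(sprintf("sensitivity %s, specificity %s, accuracy %s (n = %d)\n",
              f["sensitivity"], f["specificity"], f["accuracy"], x$n))
  cat(sprintf("LR+ %s (%s confidence), LR- %s (%s confidence)\n",
              f["lr_positive"], x$lr_confidence["positive"],
              f["lr_negative"], x$lr_confidence["negative"]))
  cat(sprintf("binomial test vs chance: p %s\n", f["binomial_p"]))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps the decision cut-off over all distinct score values; tied scores
#' flip together, producing diagonal segments. The AUC is the trapezoid
#' area under the resulting curve, which equals the rank statistic
#' P(score_DLD > score_control) + 0.5 P(equal).
#'
#' @param scores Numeric scores (higher = more DLD-like).
#' @param labels Binary true labels (DLD = 1); both classes required.
#' @return Object of class `roc_curve`: `points` (data frame `fpr`, `tpr`,
#'   ordered from (0,0) to (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to build a ROC curve")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  # descending distinct thresholds; all tied scores flip together
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)[!duplicated(grp, fromLast = TRUE)]
  fp <- cumsum(1 - y)[!duplicated(grp, fromLast = TRUE)]
  pts <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.3f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, add = FALSE, col = "black", ...) {
  if (!add) {
    plot(NA, xlim = c(0, 1), ylim = c(0, 1),
         xlab = "False positive rate (1 - specificity)",
         ylab = "True positive rate (sensitivity)", ...)
    graphics::abline(0, 1, col = "grey")
  }
  graphics::lines(x$points$fpr, x$points$tpr, lwd = 2, col = col)
  invisible(x)
}

#' Write ROC points to TSV
#'
#' @param roc A `roc_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path) {
  utils::write.table(roc$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
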