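# The Semantic Linguistic Impairment Index (SELIMI): leave-one-out
# cross-validated ridge-logistic probability that a narrative was produced
# by a child with DLD.

# Deterministic round-robin fold assignment for the optional inner
# cross-validation; no randomness so results are reproducible.
# Weights that restore a 50% class prevalence: each class is scaled to
# carry half the total weight. Used inside LOOCV training folds, where the
# holdout itself unbalances an otherwise balanced cohort by one child.
.balance_weights <- function(y) {
  n <- length(y)
  w <- ifelse(y == 1, n / (2 * sum(y == 1)), n / (2 * sum(y == 0)))
  as.numeric(w)
}

.inner_cv_lambda <- function(X, y, grid, balance, n_folds = 5L) {
  n <- length(y)
  folds <- rep_len(seq_len(min(n_folds, n)), n)
  dev <- vapply(grid, function(lam) {
    d <- 0
    for (f in unique(folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) return(Inf)
      fit <- tryCatch(
        ridge_logistic(X[tr, , drop = FALSE], y[tr], lambda = lam,
                       weights = if (balance) .balance_weights(y[tr])),
        error = function(e) NULL)
      if (is.null(fit)) return(Inf)
      p <- predict(fit, X[!tr, , drop = FALSE])
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      d <- d - 2 * sum(y[!tr] * log(p) + (1 - y[!tr]) * log(1 - p))
    }
    d
  }, numeric(1))
  grid[which.min(dev)]
}

.loocv_cohort <- function(X, y, lambda, cutoff, select_lambda, standardize,
                          balance) {
  n <- length(y)
  if (n < 3L) stop("cohort has fewer than 3 narratives")
  if (min(table(y)) < 2L)
    stop("degenerate fold: removing one narrative would leave a single-class",
         " training set")
  scores <- numeric(n)
  lambdas <- numeric(n)
  grid <- 10^seq(-3, 3, by = 1)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    xte <- X[i, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(Xtr)
      sdv <- apply(Xtr, 2L, stats::sd)
      sdv[sdv < 1e-12] <- 1
      Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, sdv, `/`)
      xte <- sweep(sweep(xte, 2L, mu), 2L, sdv, `/`)
    }
    lam <- if (select_lambda) .inner_cv_lambda(Xtr, ytr, grid, balance)
           else lambda
    fit <- ridge_logistic(Xtr, ytr, lambda = lam,
                          weights = if (balance) .balance_weights(ytr))
    scores[i] <- predict(fit, xte)
    lambdas[i] <- lam
  }
  list(score = scores, predicted = as.integer(scores > cutoff),
       lambda = lambdas)
}

#' Fit the SELIMI classifier with leave-one-out cross-validation
#'
#' For every narrative, a ridge logistic model is trained on all other
#' narratives of the same cohort and used to score the held-out narrative:
#' the score in \[0, 1\] is the estimated probability that the narrative was
#' produced by a child with DLD (the SELIMI). Cohorts are processed
#' completely independently. A score strictly above `cutoff` yields a DLD
#' call; a score equal to the cutoff is called control.
#'
#' @param x A `narrative_vectors` data frame from [narrative_vectors()], or
#'   a numeric matrix of predictors (then `y` is required).
#' @param y Binary labels (DLD = 1), taken from `x$group_label` when `x` is
#'   a `narrative_vectors` table.
#' @param cohort Factor/character of cohort memberships; taken from `x` when
#'   available. Defaults to a single cohort.
#' @param lambda Ridge penalty applied in every fold (default 1, chosen for
#'   unit-norm inputs).
#' @param cutoff Probability cut-off for the binary call (default 0.5).
#' @param select_lambda If `TRUE`, `lambda` is instead chosen per fold by an
#'   inner 5-fold cross-validation over the grid 10^(-3..3) (deviance
#'   criterion). Default `FALSE`.
#' @param standardize If `TRUE`, predictors are standardized within each
#'   training fold (off by default: narrative vectors are already
#'   unit-norm).
#' @param balance_folds If `TRUE` (default), observations in each training
#'   fold are class-balance weighted so both classes carry equal total
#'   weight. In a balanced cohort the leave-one-out holdout itself tilts
#'   every training fold by one child against the held-out class; without
#'   reweighting, a heavily shrunk model's unpenalized intercept tracks
#'   that tilt and systematically anti-predicts the held-out label.
#' @return An object of class `selimi` with component `results` (one row
#'   per narrative: `child_id`, `cohort`, `true_label`, `score`,
#'   `predicted_label`), per-cohort full-data `models`, and the settings
#'   used. Methods: `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot`.
#' @export
selimi <- function(x, y = NULL, cohort = NULL, lambda = 1, cutoff = 0.5,
                   select_lambda = FALSE, standardize = FALSE,
                   balance_folds = TRUE) {
  cl <- match.call()
  if (inherits(x, "narrative_vectors")) {
    if (is.null(y)) y <- x$group_label
    if (is.null(cohort)) cohort <- as.character(x$cohort)
    child_id <- x$child_id
    X <- .vector_matrix(x)
  } else {
    X <- as.matrix(x)
    if (is.null(y)) stop("y is required when x is a bare matrix")
    child_id <- if (!is.null(rownames(X))) rownames(X) else
      sprintf("obs%03d", seq_len(nrow(X)))
  }
  if (is.null(cohort)) cohort <- rep("A", nrow(X))
  cohort <- as.character(cohort)
  y <- as.integer(y)
  if (!all(y %in% 0:1)) stop("labels must be binary 0/1")

  results <- NULL
  models <- list()
  for (co in unique(cohort)) {
    idx <- which(cohort == co)
    fold <- .loocv_cohort(X[idx, , drop = FALSE], y[idx], lambda, cutoff,
                          select_lambda, standardize, balance_folds)
    results <- rbind(results, data.frame(
      child_id = child_id[idx], cohort = co, true_label = y[idx],
      score = fold$score, predicted_label = fold$predicted,
      stringsAsFactors = FALSE))
    models[[co]] <- ridge_logistic(
      X[idx, , drop = FALSE], y[idx],
      lambda = if (select_lambda) stats::median(fold$lambda) else lambda,
      weights = if (balance_folds) .balance_weights(y[idx]))
  }
  structure(list(results = results, models = models, lambda = lambda,
                 cutoff = cutoff, select_lambda = select_lambda,
                 standardize = standardize, balance_folds = balance_folds,
                 call = cl),
            class = "selimi")
}

#' @export
print.selimi <- function(x, ...) {
  cat("SELIMI leave-one-out classifier\n")
  cat(sprintf("  %d narratives in %d cohort(s); lambda = %s, cutoff = %g\n",
              nrow(x$results), length(x$models),
              if (x$select_lambda) "inner-CV" else format(x$lambda),
              x$cutoff))
  acc <- with(x$results, mean(true_label == predicted_label))
  cat(sprintf("  overall LOOCV accuracy: %.1f%%\n", 100 * acc))
  invisible(x)
}

#' Per-cohort diagnostic summary of a SELIMI fit
#'
#' Builds, for each cohort, the confusion matrix at the fitted cut-off and
#' the full diagnostic report (sensitivity, specificity, likelihood ratios,
#' accuracy, exact binomial test against chance, ROC/AUC).
#'
#' @param object A `selimi` fit.
#' @param ... Unused.
#' @return Object of class `summary.selimi`: named list of per-cohort lists
#'   with `confusion`, `report`, `roc`.
#' @export
summary.selimi <- function(object, ...) {
  out <- lapply(split(object$results, object$results$cohort), function(res) {
    cm <- confusion_matrix(res$true_label, res$predicted_label)
    list(confusion = cm,
         report = diagnostic_report(cm),
         roc = roc_curve(res$score, res$true_label))
  })
  structure(out, class = "summary.selimi")
}

#' @export
print.summary.selimi <- function(x, ...) {
  for (co in names(x)) {
    cat("== Cohort", co, "==\n")
    print(x[[co]]$confusion)
    print(x[[co]]$report)
    cat(sprintf("AUC: %.3f\n\n", x[[co]]$roc$auc))
  }
  invisible(x)
}

#' @export
coef.selimi <- function(object, ...) {
  lapply(object$models, coef)
}

#' @export
fitted.selimi <- function(object, ...) {
  stats::setNames(object$results$score, object$results$child_id)
}

#' @export
residuals.selimi <- function(object, ...) {
  stats::setNames(object$results$true_label - object$results$score,
                  object$results$child_id)
}

#' Score new narrative vectors with the full-cohort SELIMI model
#'
#' Uses the model refitted on all narratives of the requested cohort (not
#' the leave-one-out folds).
#'
#' @param object A `selimi` fit.
#' @param newdata `narrative_vectors` table or numeric matrix.
#' @param cohort Which cohort's model to apply (default the first).
#' @param ... Unused.
#' @return DLD probabilities in (0, 1).
#' @export
predict.selimi <- function(object, newdata, cohort = names(object$models)[1L],
                           ...) {
  if (!cohort %in% names(object$models))
    stop("no model for cohort '", cohort, "'")
  X <- if (inherits(newdata, "narrative_vectors"))
    .vector_matrix(newdata) else as.matrix(newdata)
  predict(object$models[[cohort]], X)
}

#' ROC curves of a SELIMI fit, one per cohort
#'
#' @param x A `selimi` fit.
#' @param ... Passed through to the underlying ROC plotting routine.
#' @return The `summary.selimi` object, invisibly.
#' @export
plot.selimi <- function(x, ...) {
  s <- summary(x)
  first <- TRUE
  cols <- c("black", "firebrick", "steelblue")
  for (i in seq_along(s)) {
    plot(s[[i]]$roc, add = !first, col = cols[(i - 1L) %% 3L + 1L], ...)
    first <- FALSE
  }
  graphics::legend("bottomright",
                   legend = sprintf("cohort %s (AUC %.3f)", names(s),
                                    vapply(s, function(e) e$roc$auc,
                                           numeric(1))),
                   col = cols[seq_along(s)], lwd = 2, bty = "n")
  invisible(s)
}

#' Write SELIMI results as TSV
#'
#' Columns: `child_id`, `cohort`, `true_label`, `score`, `predicted_label`.
#'
#' @param fit A `selimi` fit.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_selimi <- function(fit, path) {
  res <- fit$results
  res$score <- formatC(res$score, format = "g", digits = 17)
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
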