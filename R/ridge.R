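# Ridge-penalized logistic regression by damped iteratively reweighted
# least squares. This is the statistical engine behind the SELIMI score:
# with ~100 predictors and fewer narratives than dimensions, the ridge
# penalty is what makes the maximum-likelihood problem well posed.

# Penalized log-likelihood: sum_i w_i [y_i log p_i + (1-y_i) log(1-p_i)]
# - (lambda/2) ||beta||^2, intercept unpenalized. Unit weights give the
# plain penalized maximum-likelihood objective.
.penalized_loglik <- function(theta, X, y, lambda, w = 1) {
  eta <- theta[1L] + drop(X %*% theta[-1L])
  # log(1+exp(eta)) computed stably
  loglik <- sum(w * (y * eta - ifelse(eta > 30, eta, log1p(exp(eta)))))
  loglik - lambda / 2 * sum(theta[-1L]^2)
}

.penalized_gradient <- function(theta, X, y, lambda, w = 1) {
  p <- stats::plogis(theta[1L] + drop(X %*% theta[-1L]))
  r <- w * (y - p)
  c(sum(r), drop(crossprod(X, r)) - lambda * theta[-1L])
}

#' Fit ridge-penalized logistic regression
#'
#' Maximizes the binomial log-likelihood minus \eqn{(\lambda/2)\|\beta\|^2}
#' (intercept unpenalized) by damped Newton / iteratively reweighted least
#' squares, starting from zero coefficients. Deterministic; convergence is
#' declared when the max-norm of the penalized gradient falls below `tol`.
#'
#' @param X Numeric matrix, one row per observation.
#' @param y Binary labels (0/1), both classes present.
#' @param lambda Nonnegative ridge penalty; must be positive when there are
#'   fewer observations than predictors.
#' @param weights Optional positive observation weights (default all one,
#'   the plain penalized maximum-likelihood fit). The leave-one-out driver
#'   uses class-balancing weights here; see [selimi()].
#' @param tol Gradient max-norm convergence tolerance.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return Object of class `ridge_logistic`: `intercept`, `coefficients`
#'   (length `ncol(X)`), `lambda`, `iterations`, `loglik` (penalized).
#' @export
ridge_logistic <- function(X, y, lambda = 1, tol = 1e-8, max_iter = 200L,
                           weights = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2L)
    stop("degenerate labels: both classes must be present")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (!all(is.finite(X))) stop("X contains non-finite values")
  if (lambda < 0) stop("lambda must be nonnegative")
  if (lambda == 0 && nrow(X) < ncol(X))
    stop("lambda must be positive when n < k")
  w <- if (is.null(weights)) rep.int(1, length(y)) else as.numeric(weights)
  if (length(w) != length(y) || any(!is.finite(w)) || any(w <= 0))
    stop("weights must be positive and match length(y)")

  p <- ncol(X)
  theta <- numeric(p + 1L)
  obj <- .penalized_loglik(theta, X, y, lambda, w)
  penalty_diag <- c(0, rep.int(lambda, p))

  Xa <- cbind(1, X)
  nu <- 0  # Levenberg damping, raised only when a plain Newton step fails
  for (iter in seq_len(max_iter)) {
    g <- .penalized_gradient(theta, X, y, lambda, w)
    if (max(abs(g)) < tol)
      return(structure(list(intercept = theta[1L],
                            coefficients = theta[-1L],
                            lambda = lambda, iterations = iter - 1L,
                            loglik = obj),
                       class = "ridge_logistic"))
    mu <- stats::plogis(theta[1L] + drop(X %*% theta[-1L]))
    hw <- pmax(w * mu * (1 - mu), 1e-10)
    H <- crossprod(Xa, Xa * hw) + diag(penalty_diag, p + 1L)
    # damped Newton: halve the step, then stiffen the Hessian, until the
    # penalized likelihood improves (near-separable folds flatten H)
    improved <- FALSE
    repeat {
      step <- solve(H + diag(nu, p + 1L), g)
      damp <- 1
      while (damp >= 1e-10) {
        cand <- theta + damp * step
        cand_obj <- .penalized_loglik(cand, X, y, lambda, w)
        if (cand_obj > obj) { improved <- TRUE; break }
        damp <- damp / 2
      }
      if (improved || nu > 1e8) break
      nu <- max(nu * 10, 1e-4)
    }
    if (!improved) break  # ascent stalled at numerical precision
    theta <- cand
    obj <- cand_obj
    nu <- nu / 10
  }
  g <- .penalized_gradient(theta, X, y, lambda, w)
  # accept a stall only if the optimum has been located to near precision
  if (max(abs(g)) < sqrt(tol))
    return(structure(list(intercept = theta[1L], coefficients = theta[-1L],
                          lambda = lambda, iterations = max_iter,
                          loglik = obj),
                     class = "ridge_logistic"))
  stop("ridge_logistic did not converge within ", max_iter, " iterations")
}

#' @export
print.ridge_logistic <- function(x, ...) {
  cat(sprintf(
    "Ridge logistic model: %d predictors, lambda = %g, %d IRLS iterations\n",
    length(x$coefficients), x$lambda, x$iterations))
  cat(sprintf("intercept %.4f, ||beta|| %.4f\n",
              x$intercept, sqrt(sum(x$coefficients^2))))
  invisible(x)
}

#' @export
coef.ridge_logistic <- function(object, ...) {
  c("(Intercept)" = object$intercept,
    stats::setNames(object$coefficients,
                    paste0("v", seq_along(object$coefficients))))
}

#' Predicted DLD probability from a fitted ridge logistic model
#'
#' @param object A `ridge_logistic` fit.
#' @param newdata Numeric matrix (or single vector) of predictors with the
#'   model's dimensionality.
#' @param ... Unused.
#' @return Probabilities in (0, 1), one per row of `newdata`.
#' @export
predict.ridge_logistic <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (!all(is.finite(newdata))) stop("newdata contains non-finite values")
  if (ncol(newdata) != length(object$coefficients))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$coefficients))
  stats::plogis(object$intercept + drop(newdata %*% object$coefficients))
}
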