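test_that("an overwhelming penalty shrinks beta to zero and the score to prevalence", {
  set.seed(4)
  X <- matrix(rnorm(40), 10, 4)
  y <- c(1, 1, 1, 0, 0, 0, 1, 0, 0, 0)  # prevalence 0.4
  fit <- ridge_logistic(X, y, lambda = 1e12)
  expect_lt(sqrt(sum(fit$coefficients^2)), 1e-6)
  expect_equal(unname(predict(fit, X[1, ])), mean(y), tolerance = 1e-4)
})

test_that("IRLS coefficients match a generic numeric optimizer to 1e-5", {
  X <- rbind(c(0.2, 1.1), c(-0.4, 0.5), c(1.0, -0.2),
             c(-1.2, -0.8), c(0.7, 0.9), c(-0.1, -1.5))
  y <- c(1, 0, 1, 0, 1, 0)
  fit <- ridge_logistic(X, y, lambda = 1)
  ref <- ref_ridge_logistic(X, y, 1)
  expect_equal(c(fit$intercept, fit$coefficients), ref, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("IRLS matches the numeric oracle across random small problems", {
  set.seed(19)
  for (rep in 1:8) {
    n <- sample(6:20, 1)
    k <- sample(2:5, 1)
    X <- matrix(rnorm(n * k), n, k)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))  # both classes present
    lam <- sample(c(0.1, 1, 10), 1)
    fit <- ridge_logistic(X, y, lambda = lam)
    ref <- ref_ridge_logistic(X, y, lam)
    expect_equal(c(fit$intercept, fit$coefficients), ref, tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("perfectly sign-symmetric data yields a zero intercept", {
  set.seed(6)
  Xp <- matrix(rnorm(12), 4, 3)
  X <- rbind(Xp, -Xp)
  y <- c(rep(1, 4), rep(0, 4))
  fit <- ridge_logistic(X, y, lambda = 2)
  expect_equal(fit$intercept, 0, tolerance = 1e-7)
})

test_that("fit validates inputs", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(ridge_logistic(X, rep(1, 10), lambda = 1), "degenerate")
  expect_error(ridge_logistic(X, c(rep(0:1, 4), 2, 0), lambda = 1), "binary")
  X[1, 1] <- NA
  expect_error(ridge_logistic(X, rep(0:1, 5), lambda = 1), "finite")
  expect_error(ridge_logistic(matrix(rnorm(8), 2, 4), 0:1, lambda = 0),
               "lambda must be positive")
})

test_that("predicted probabilities follow the logistic of the linear score", {
  fit <- structure(list(intercept = 0, coefficients = c(0, 0), lambda = 1),
                   class = "ridge_logistic")
  expect_equal(unname(predict(fit, c(3, -2))), 0.5)
  fit$intercept <- 50
  expect_gt(predict(fit, c(0, 0)), 1 - 1e-9)
  fit2 <- structure(list(intercept = 0.3, coefficients = c(1.2, -0.7),
                         lambda = 1), class = "ridge_logistic")
  x <- c(0.5, 2)
  expect_equal(unname(predict(fit2, x)),
               1 / (1 + exp(-(0.3 + 1.2 * 0.5 - 0.7 * 2))))
  expect_error(predict(fit2, c(1, 2, 3)), "expects")
})

test_that("scores increase monotonically with the intercept", {
  set.seed(3)
  x <- rnorm(4)
  b0s <- seq(-5, 5, length.out = 11)
  scores <- vapply(b0s, function(b0) {
    fit <- structure(list(intercept = b0, coefficients = rnorm(4) * 0 + 0.3,
                          lambda = 1), class = "ridge_logistic")
    unname(predict(fit, x))
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
  expect_true(all(scores > 0 & scores < 1))
})

test_that("class-balancing weights cancel the fold-imbalance intercept", {
  set.seed(14)
  X <- matrix(rnorm(35 * 3, sd = 1e-3), 35, 3)  # essentially uninformative
  y <- c(rep(1, 17), rep(0, 18))
  plain <- ridge_logistic(X, y, lambda = 1e6)
  expect_equal(plain$intercept, qlogis(17 / 35), tolerance = 1e-3)
  w <- ifelse(y == 1, 35 / 34, 35 / 36)
  balanced <- ridge_logistic(X, y, lambda = 1e6, weights = w)
  expect_equal(balanced$intercept, 0, tolerance = 1e-3)
})

test_that("fits agree with glmnet's penalized maximum likelihood", {
  skip_if_not_installed("glmnet")
  # glmnet minimizes -(1/n) loglik + lambda_g ||beta||^2 / 2 for alpha = 0,
  # i.e. our objective with lambda = n * lambda_g
  set.seed(27)
  n <- 30; k <- 4
  X <- matrix(rnorm(n * k), n, k)
  y <- rbinom(n, 1, plogis(X[, 1]))
  for (lam in c(0.5, 2, 10)) {
    fit <- ridge_logistic(X, y, lambda = lam)
    g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = lam / n, standardize = FALSE,
                        thresh = 1e-14)
    expect_equal(c(fit$intercept, fit$coefficients),
                 as.numeric(stats::coef(g)), tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})
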