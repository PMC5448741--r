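sim_xy <- function(n, p = 3, beta = NULL, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  eta <- if (is.null(beta)) rep(0, n) else drop(X %*% beta)
  y <- stats::rbinom(n, 1, stats::plogis(eta - 0.4))
  list(X = X, y = y)
}

test_that("ridge IRLS approaches the maximum-likelihood fit as lambda -> 0", {
  d <- sim_xy(300, beta = c(0.8, -0.5, 0.3), seed = 5)
  fit <- fit_ridge_logistic(d$X, d$y, lambda = 0)
  expect_true(fit$converged)
  ml <- stats::glm(d$y ~ d$X, family = stats::binomial())
  expect_equal(unname(fit$coefficients), unname(stats::coef(ml)), tolerance = 1e-6)
  # score equations of the unpenalized likelihood hold
  p <- predict_prob(fit, d$X)
  score <- drop(crossprod(cbind(1, d$X), p - d$y))
  expect_lt(max(abs(score)), 1e-6)
  # penalized objective never increased across iterations
  expect_true(all(diff(fit$objective_trace) <= 1e-10))
})

test_that("pure-noise predictors give tiny coefficients and an intercept near logit(prevalence)", {
  d <- sim_xy(2000, seed = 6)
  fit <- fit_ridge_logistic(d$X, d$y, lambda = 1e-8)
  expect_lt(max(abs(fit$coefficients[-1])), 0.15)
  expect_equal(unname(fit$coefficients[1]), stats::qlogis(mean(d$y)), tolerance = 0.05)
})

test_that("a huge penalty shrinks coefficients to zero and predictions to the prevalence", {
  d <- sim_xy(200, beta = c(2, 2, 2), seed = 7)
  fit <- fit_ridge_logistic(d$X, d$y, lambda = 1e6)
  expect_lt(sqrt(sum(fit$coefficients[-1]^2)), 1e-3)
  expect_equal(unname(predict_prob(fit, d$X)), rep(mean(d$y), 200), tolerance = 0.01)
})

test_that("separable data with a small ridge attains in-sample AUC 1 without diverging", {
  X <- matrix(c(-(10:1), 1:10), ncol = 1, dimnames = list(NULL, "f1"))
  y <- rep(c(0, 1), each = 10)
  fit <- suppressWarnings(fit_ridge_logistic(X, y, lambda = 1e-8))
  expect_equal(auc(predict_prob(fit, X), y), 1.0)
  expect_error(fit_ridge_logistic(X, rep(1, 20)), "both label classes")
})

test_that("predict_prob follows the logistic form and its invariances", {
  fit0 <- structure(list(coefficients = c(`(Intercept)` = 0, f1 = 0),
                         features = "f1", lambda = 0, converged = TRUE,
                         iterations = 0, penalized_nll = 0),
                    class = "ridge_logit")
  X <- matrix(stats::rnorm(10), dimnames = list(NULL, "f1"))
  expect_equal(predict_prob(fit0, X), rep(0.5, 10))
  fit8 <- fit0; fit8$coefficients[1] <- stats::qlogis(0.8)
  expect_equal(predict_prob(fit8, X), rep(0.8, 10))
  fitb <- fit0; fitb$coefficients["f1"] <- 1.3
  fitm <- fit0; fitm$coefficients["f1"] <- -1.3
  expect_equal(predict_prob(fitb, X), predict_prob(fitm, -X))
  expect_error(predict_prob(fitb, matrix(1, 1, 1, dimnames = list(NULL, "g1"))),
               "f1")
})

test_that("the AUC is the pairwise concordance probability", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(auc(rep(0.3, 6), rep(c(0, 1), 3)), 0.5)
  # exhaustive 4-pair count: 3 concordant of 4
  expect_equal(auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_error(auc(1:3, c(1, 1, 1)), "both label classes")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(51)
  y <- rep(c(0, 1), 15)
  s <- stats::rnorm(30) + y
  a <- auc(s, y)
  expect_equal(auc(exp(s), y), a)
  expect_equal(auc(rank(s), y), a)
})

test_that("bootstrap AUC test: determinism, degenerate certainty and warnings", {
  set.seed(61)
  y <- rep(c(1, 0), c(30, 29))
  s <- stats::rnorm(59) + 2.5 * y
  r1 <- bootstrap_auc_test(s, y, n_boot = 1000, seed = 8)
  r2 <- bootstrap_auc_test(s, y, n_boot = 1000, seed = 8)
  expect_identical(r1, r2)

  sep <- c(stats::runif(30) + 2, stats::runif(29))  # perfectly separated
  r <- bootstrap_auc_test(sep, y, n_boot = 1000, seed = 9)
  expect_equal(r$auc, 1.0)
  expect_lte(r$p_value, 0.001)
  expect_equal(r$ci_high, 1.0, tolerance = 1e-9)
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)

  expect_warning(bootstrap_auc_test(s, y, n_boot = 50, seed = 1), "unstable")
  expect_error(bootstrap_auc_test(s, y, n_boot = 1), "at least 2")
})

test_that("paired AUC comparison: identity, symmetry and power on a perfect model", {
  set.seed(71)
  y <- rep(c(1, 0), c(30, 29))
  a <- stats::rnorm(59) + y
  cmp0 <- bootstrap_auc_compare(a, a, y, n_boot = 500, seed = 3)
  expect_equal(cmp0$delta_auc, 0)
  expect_equal(cmp0$p_value, 1)

  b <- stats::rnorm(59)            # label-independent
  perfect <- 2 * y + stats::runif(59) * 0.1
  cmp <- bootstrap_auc_compare(perfect, b, y, n_boot = 1000, seed = 4)
  expect_gt(cmp$delta_auc, 0.3)
  expect_lte(cmp$p_value, 0.01)

  sw <- bootstrap_auc_compare(b, perfect, y, n_boot = 1000, seed = 4)
  expect_equal(sw$delta_auc, -cmp$delta_auc)
  expect_equal(sw$p_value, cmp$p_value)
  expect_error(bootstrap_auc_compare(a[1:10], a, y), "paired")
})

test_that("ROC curve points are consistent with the trapezoidal AUC", {
  set.seed(81)
  y <- rep(c(0, 1), each = 20)
  s <- stats::rnorm(40) + 0.8 * y
  pts <- roc_points(s, y)
  trap <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  expect_equal(trap, auc(s, y), tolerance = 1e-12)
})
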