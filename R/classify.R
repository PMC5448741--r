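#' Ridge-penalized logistic regression via IRLS
#'
#' Minimizes the penalized negative log-likelihood
#' `-sum(y log p + (1-y) log(1-p)) + lambda * sum(beta_j^2)` with the
#' intercept unpenalized, by Newton iterations (iteratively reweighted
#' least squares) with step-halving whenever a step would increase the
#' objective. Convergence is declared when the maximal score component
#' falls below 1e-8 or the parameter change below 1e-10, within 100
#' iterations; non-convergence yields a flagged model and a warning, not
#' an error.
#'
#' @param x Numeric matrix or data frame of predictors (subjects x
#'   features), no missing values.
#' @param y 0/1 labels, both classes present.
#' @param lambda Ridge penalty, `>= 0`; default `1e-8` (an essentially
#'   maximum-likelihood fit that remains finite under separation).
#' @return A `ridge_logit` object with `coefficients` (intercept first),
#'   `lambda`, `converged`, `iterations` and `penalized_nll`.
#' @export
fit_ridge_logistic <- function(x, y, lambda = 1e-8) {
  x <- as.matrix(x)
  if (anyNA(x)) stop_domain("predictors contain missing values")
  check_binary_labels(y)
  if (nrow(x) != length(y)) stop_domain("x/y dimension mismatch")
  if (lambda < 0) stop_domain("lambda must be non-negative")
  y <- as.numeric(y)
  p_feat <- ncol(x)
  feat_names <- colnames(x) %||% paste0("x", seq_len(p_feat))
  X <- cbind(1, x)
  pen_mask <- c(0, rep(1, p_feat))  # intercept unpenalized

  obj <- function(beta) {
    eta <- drop(X %*% beta)
    # numerically stable -loglik: log(1+exp(eta)) - y*eta
    nll <- sum(ifelse(eta > 30, eta, log1p(exp(eta))) - y * eta)
    nll + lambda * sum((pen_mask * beta)^2)
  }

  beta <- numeric(p_feat + 1)
  beta[1] <- stats::qlogis(mean(y))
  f_old <- obj(beta)
  trace <- f_old
  converged <- FALSE
  iter <- 0
  while (iter < 100) {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    grad <- drop(crossprod(X, p - y)) + 2 * lambda * pen_mask * beta
    if (max(abs(grad)) < 1e-8) { converged <- TRUE; break }
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X * w, X) + diag(2 * lambda * pen_mask, p_feat + 1)
    step <- tryCatch(solve(H, -grad), error = function(e) NULL)
    if (is.null(step)) break
    # step-halving keeps the penalized objective monotone
    alpha <- 1
    repeat {
      cand <- beta + alpha * step
      f_new <- obj(cand)
      if (f_new <= f_old + 1e-12 || alpha < 2^-30) break
      alpha <- alpha / 2
    }
    delta <- alpha * step
    beta <- beta + delta
    f_old <- obj(beta)
    trace <- c(trace, f_old)
    if (max(abs(delta)) < 1e-10) {
      converged <- max(abs(drop(crossprod(X, stats::plogis(drop(X %*% beta)) - y))
                           + 2 * lambda * pen_mask * beta)) < 1e-6 || converged
      break
    }
  }
  if (!converged) warning("ridge logistic IRLS did not converge in ", iter, " iterations")
  structure(list(
    coefficients = stats::setNames(beta, c("(Intercept)", feat_names)),
    features = feat_names, lambda = lambda,
    converged = converged, iterations = iter, penalized_nll = f_old,
    objective_trace = trace
  ), class = "ridge_logit")
}

#' Predicted probability of the trauma-exposed class
#'
#' @param model A `ridge_logit`.
#' @param x New data with the model's feature columns.
#' @return Probabilities in `(0, 1)`.
#' @export
predict_prob <- function(model, x) {
  stopifnot(inherits(model, "ridge_logit"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    if (ncol(x) != length(model$features)) stop_domain("column count mismatch")
    colnames(x) <- model$features
  }
  miss <- setdiff(model$features, colnames(x))
  if (length(miss)) stop_domain("missing feature column(s): ", paste(miss, collapse = ", "))
  eta <- model$coefficients[1] +
    drop(x[, model$features, drop = FALSE] %*% model$coefficients[-1])
  stats::plogis(eta)
}

#' @export
print.ridge_logit <- function(x, ...) {
  cat("Ridge logistic regression (lambda =", format(x$lambda), ")\n")
  cat(" ", length(x$features), "features |",
      if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iterations\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Over all exposed/unexposed subject pairs, the fraction in which the
#' exposed subject's score is higher, with half credit for ties; this
#' equals the trapezoidal area under the ROC curve.
#'
#' @param scores Numeric classification scores (higher = more
#'   exposed-like).
#' @param labels 0/1 labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  check_binary_labels(labels)
  if (length(scores) != length(labels)) stop_domain("scores/labels length mismatch")
  if (anyNA(scores)) stop_domain("scores contain NA")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)  # midranks handle ties with half credit
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap test of an AUC against chance
#'
#' Subjects are resampled with replacement within each group (n_boot
#' stratified resamples); the 95% CI is the 2.5/97.5 percentile interval
#' of the bootstrap AUCs, and the one-sided p-value against AUC = 0.5 is
#' the continuity-corrected fraction of bootstrap AUCs at or below 0.5:
#' `(1 + #\{AUC* <= 0.5\}) / (n_boot + 1)`.
#'
#' @param scores,labels As in [auc()].
#' @param n_boot Bootstrap resamples (study default 1000); fewer than 100
#'   triggers a warning, fewer than 2 an error.
#' @param seed Integer seed; deterministic given the seed.
#' @return A `roc_analysis` with `auc`, `ci_low`, `ci_high`, `p_value`,
#'   `n_boot`, `seed`.
#' @export
bootstrap_auc_test <- function(scores, labels, n_boot = 1000, seed = 1) {
  if (n_boot < 2) stop_domain("n_boot must be at least 2")
  if (n_boot < 100) warning("n_boot < 100 gives unstable bootstrap inference")
  point <- auc(scores, labels)
  i1 <- which(labels == 1)
  i0 <- which(labels == 0)
  y <- c(rep(1, length(i1)), rep(0, length(i0)))
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(i1, length(i1), replace = TRUE),
               sample(i0, length(i0), replace = TRUE))
      auc(scores[idx], y)
    }, numeric(1))
  })
  ci <- unname(stats::quantile(boot, c(0.025, 0.975), type = 7))
  structure(list(
    auc = point, ci_low = ci[1], ci_high = ci[2],
    p_value = (1 + sum(boot <= 0.5)) / (n_boot + 1),
    n_boot = n_boot, seed = seed
  ), class = "roc_analysis")
}

#' @export
print.roc_analysis <- function(x, ...) {
  cat(sprintf("AUC = %.2f, 95%% CI = %.2f to %.2f, P = %.3g (one-sided vs 0.5, %d bootstraps)\n",
              x$auc, x$ci_low, x$ci_high, x$p_value, x$n_boot))
  invisible(x)
}

#' Paired bootstrap comparison of two AUCs
#'
#' Both score vectors come from the same subjects; each stratified
#' resample recomputes both AUCs on the same resampled subjects. The
#' two-sided p-value is the continuity-corrected fraction of centred
#' bootstrap differences at least as extreme as the observed difference.
#'
#' @param scores_a,scores_b Paired score vectors (same subjects).
#' @param labels 0/1 labels.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return A `model_comparison` with `delta_auc` (A minus B), `p_value`,
#'   `n_boot`, `seed`.
#' @export
bootstrap_auc_compare <- function(scores_a, scores_b, labels, n_boot = 1000, seed = 1) {
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(labels)) {
    stop_domain("scores_a, scores_b and labels must be paired (equal length)")
  }
  if (n_boot < 2) stop_domain("n_boot must be at least 2")
  delta <- auc(scores_a, labels) - auc(scores_b, labels)
  i1 <- which(labels == 1)
  i0 <- which(labels == 0)
  y <- c(rep(1, length(i1)), rep(0, length(i0)))
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(i1, length(i1), replace = TRUE),
               sample(i0, length(i0), replace = TRUE))
      auc(scores_a[idx], y) - auc(scores_b[idx], y)
    }, numeric(1))
  })
  centred <- boot - delta
  p <- (1 + sum(abs(centred) >= abs(delta))) / (n_boot + 1)
  structure(list(delta_auc = delta, p_value = min(p, 1),
                 n_boot = n_boot, seed = seed),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Delta AUC = %.3f, two-sided bootstrap P = %.3g (%d bootstraps)\n",
              x$delta_auc, x$p_value, x$n_boot))
  invisible(x)
}

#' ROC curve points
#'
#' False/true positive rates at every distinct score threshold, suitable
#' for plotting or CSV export.
#'
#' @param scores,labels As in [auc()].
#' @return Data frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  check_binary_labels(labels)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  data.frame(
    threshold = th,
    fpr = vapply(th, function(t) sum(scores >= t & labels == 0) / n0, numeric(1)),
    tpr = vapply(th, function(t) sum(scores >= t & labels == 1) / n1, numeric(1))
  )
}
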