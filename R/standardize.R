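#' Fit the covariate-adjustment model on the trauma-unexposed group
#'
#' Each of the 23 features is regressed by ordinary least squares on age
#' and sex (amygdala volume additionally on intracranial volume) using the
#' trauma-unexposed subjects only. The residual standard deviation
#' (denominator n-1) of the reference group defines the Z-scale for
#' [standardize()].
#'
#' Fitting on the unexposed group alone keeps any genuine group difference
#' out of the covariate slopes, so Z-scores are expressed relative to the
#' unexposed reference distribution at the same covariate values.
#'
#' @param table Feature table from [extract_feature_table()]; rows with
#'   `group == 0` are used as the reference sample.
#' @param features Feature columns to adjust; defaults to the canonical 23.
#' @return An `adjustment_model`: per feature, the OLS coefficients and the
#'   reference residual SD.
#' @export
fit_adjustment <- function(table, features = feature_names()) {
  if (!all(c("group", "age", "sex") %in% names(table))) {
    stop_domain("table must contain group, age and sex columns")
  }
  miss <- setdiff(features, names(table))
  if (length(miss)) stop_domain("feature column(s) missing: ", paste(miss, collapse = ", "))
  ref <- table[table$group == 0, , drop = FALSE]
  if (nrow(ref) < 5) stop_domain("need at least 5 unexposed subjects to fit adjustment")
  if (stats::var(ref$age) == 0) stop_domain("degenerate covariate: age is constant")
  terms <- lapply(features, function(f) {
    covs <- c("age", "sex", if (f == "amygdala_volume") "icv")
    if (f == "amygdala_volume" && !"icv" %in% names(table)) {
      stop_domain("icv column required to adjust amygdala_volume")
    }
    X <- cbind(`(Intercept)` = 1, as.matrix(ref[, covs, drop = FALSE]))
    fit <- stats::lm.fit(X, ref[[f]])
    res <- fit$residuals
    s <- stats::sd(res)
    if (!is.finite(s) || s < 1e-12) {
      stop_domain("degenerate feature (zero residual variance): ", f)
    }
    list(coef = stats::setNames(fit$coefficients, colnames(X)),
         covariates = covs, sd = s)
  })
  structure(list(terms = stats::setNames(terms, features),
                 features = features, n_reference = nrow(ref)),
            class = "adjustment_model")
}

#' Z-standardize a feature table against the unexposed reference
#'
#' For every subject (both groups) each feature becomes
#' `Z = (value - prediction from covariates) / reference SD`, where the
#' prediction and SD come from an [fit_adjustment()] model. By construction
#' the unexposed subjects the model was fitted on have per-feature mean 0
#' and SD 1; a negative Z for an exposed subject means their adjusted value
#' lies below the unexposed mean.
#'
#' @param table Feature table (any subjects) sharing the model's columns.
#' @param model An `adjustment_model`.
#' @return The table with feature columns replaced by Z-scores.
#' @export
standardize <- function(table, model) {
  stopifnot(inherits(model, "adjustment_model"))
  miss <- setdiff(model$features, names(table))
  if (length(miss)) stop_domain("unseen/missing feature column(s): ",
                                paste(miss, collapse = ", "))
  out <- table
  for (f in model$features) {
    tm <- model$terms[[f]]
    X <- cbind(1, as.matrix(table[, tm$covariates, drop = FALSE]))
    pred <- drop(X %*% tm$coef)
    out[[f]] <- (table[[f]] - pred) / tm$sd
  }
  out
}

#' Serialize an adjustment model to JSON
#'
#' @param model An `adjustment_model`.
#' @param path File path; the JSON is written there for audit.
#' @return `path`, invisibly.
#' @export
write_adjustment <- function(model, path) {
  stopifnot(inherits(model, "adjustment_model"))
  obj <- list(
    features = model$features,
    n_reference = model$n_reference,
    terms = lapply(model$terms, function(tm)
      list(coef = as.list(tm$coef), covariates = tm$covariates, sd = tm$sd))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.adjustment_model <- function(x, ...) {
  cat("Covariate adjustment model (reference n =", x$n_reference, ")\n")
  cat(" features:", length(x$features),
      "| amygdala_volume additionally adjusted for ICV\n")
  invisible(x)
}
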