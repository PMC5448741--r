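#' Point-biserial correlation with group membership
#'
#' The point-biserial correlation between a continuous feature and a 0/1
#' group indicator is the Pearson correlation computed with the labels as
#' numbers; the classical mean-difference formula is algebraically
#' identical.
#'
#' @param values Numeric feature values.
#' @param labels 0/1 group labels (1 = trauma-exposed).
#' @return Correlation in `[-1, 1]`.
#' @export
point_biserial <- function(values, labels) {
  check_binary_labels(labels)
  if (length(values) != length(labels)) stop_domain("values/labels length mismatch")
  if (anyNA(values)) stop_domain("values contain NA")
  if (stats::var(values) == 0) stop_domain("feature has zero variance")
  stats::cor(values, as.numeric(labels))
}

#' Bootstrap standard error of a point-biserial correlation
#'
#' Subjects are resampled with replacement within each group (stratified,
#' preserving the group sizes); the SE is the SD of the resampled
#' correlations. Resamples in which the feature is constant are redrawn.
#'
#' @param values,labels As in [point_biserial()].
#' @param n_boot Number of bootstrap resamples (study default 5000).
#' @param seed Integer seed; results are deterministic given the seed.
#' @return Bootstrap standard error.
#' @export
bootstrap_se <- function(values, labels, n_boot = 5000, seed = 1) {
  check_binary_labels(labels)
  if (n_boot < 2) stop_domain("n_boot must be at least 2")
  i1 <- which(labels == 1)
  i0 <- which(labels == 0)
  y <- as.numeric(labels)
  with_seed(seed, {
    rs <- vapply(seq_len(n_boot), function(b) {
      for (attempt in 1:1000) {
        idx <- c(sample(i1, length(i1), replace = TRUE),
                 sample(i0, length(i0), replace = TRUE))
        v <- values[idx]
        if (stats::var(v) > 0) return(stats::cor(v, y[idx]))
      }
      stop_domain("could not draw a non-degenerate bootstrap resample")
    }, numeric(1))
    stats::sd(rs)
  })
}

#' Rank the 23 features by absolute point-biserial correlation
#'
#' Features are sorted by decreasing `|r|`; ties are broken by smaller
#' bootstrap SE, then by canonical feature-name order. The top `k`
#' features are flagged as selected (the candidate pool for the model
#' search).
#'
#' @param table Z-scored feature table with a `group` column.
#' @param k Number of features to flag (default 10).
#' @param n_boot Bootstrap resamples for the per-feature SE (default 5000).
#' @param seed Master seed; each feature's bootstrap stream is derived from
#'   it with [derive_seed()].
#' @param features Feature columns to rank; defaults to the canonical 23.
#' @return A `ranking_result` data frame: `feature`, `r`, `se`, `rank`,
#'   `selected`.
#' @export
rank_features <- function(table, k = 10, n_boot = 5000, seed = 1,
                          features = feature_names()) {
  miss <- setdiff(features, names(table))
  if (length(miss)) stop_domain("feature column(s) missing: ", paste(miss, collapse = ", "))
  if (k > length(features)) stop_domain("k cannot exceed the number of features")
  labels <- table$group
  r <- vapply(features, function(f) {
    tryCatch(point_biserial(table[[f]], labels),
             error = function(e) stop_domain("feature ", f, ": ", conditionMessage(e)))
  }, numeric(1))
  se <- vapply(features, function(f) {
    bootstrap_se(table[[f]], labels, n_boot = n_boot,
                 seed = derive_seed(seed, paste0("se_", f)))
  }, numeric(1))
  ord <- order(-abs(r), se, match(features, feature_names()))
  res <- data.frame(feature = features[ord], r = r[ord], se = se[ord],
                    rank = seq_along(features), stringsAsFactors = FALSE)
  res$selected <- res$rank <= k
  rownames(res) <- NULL
  class(res) <- c("ranking_result", "data.frame")
  res
}

#' @export
print.ranking_result <- function(x, ...) {
  cat("Feature ranking by |point-biserial r| (top",
      sum(x$selected), "selected)\n")
  print.data.frame(utils::head(as.data.frame(x), sum(x$selected)), digits = 3)
  invisible(x)
}
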