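#' Nested model search over the top 4-10 ranked features
#'
#' Builds the seven candidate classifiers: for each k in 4..10, a
#' ridge-logistic model on the top-k features of the ranking. Each model's
#' AUC is assessed with [bootstrap_auc_test()]; the best model is the one
#' with the largest point-estimate AUC (ties broken toward fewer
#' features), and it is compared against the second-best with the paired
#' [bootstrap_auc_compare()].
#'
#' @param table Z-scored feature table with a `group` column.
#' @param ranking A `ranking_result` covering all 23 features.
#' @param lambda Ridge penalty (default 1e-8).
#' @param seed Master seed; per-model bootstrap streams are derived from
#'   it.
#' @param n_boot Bootstrap resamples per AUC test (default 1000).
#' @param eval `"apparent"` (in-sample scores, default) or `"loocv"`
#'   (leave-one-out refits of the ridge model on the fixed feature
#'   subsets; note the ranking itself is not re-run per fold — see
#'   [loocv_search()] for a fully honest cross-validated search).
#' @return A `model_search_result`: per-k fits and ROC analyses, `best_k`,
#'   `second_k`, `comparison` and the scores matrix.
#' @export
build_models <- function(table, ranking, lambda = 1e-8, seed = 1,
                         n_boot = 1000, eval = c("apparent", "loocv")) {
  eval <- match.arg(eval)
  stopifnot(inherits(ranking, "ranking_result"))
  if (!all(feature_names() %in% ranking$feature)) {
    stop_domain("ranking must cover all 23 features")
  }
  y <- table$group
  check_binary_labels(y)
  if (nrow(table) <= 10) {
    stop_domain("too few subjects (n <= 10) to fit the largest candidate model")
  }
  ks <- 4:10
  ordered_feats <- ranking$feature[order(ranking$rank)]
  models <- list()
  scores <- matrix(NA_real_, nrow(table), length(ks),
                   dimnames = list(NULL, paste0("k", ks)))
  for (k in ks) {
    feats <- ordered_feats[seq_len(k)]
    X <- as.matrix(table[, feats, drop = FALSE])
    fit <- fit_ridge_logistic(X, y, lambda)
    sc <- if (eval == "apparent") {
      predict_prob(fit, X)
    } else {
      loocv_scores(X, y, lambda)
    }
    roc <- bootstrap_auc_test(sc, y, n_boot = n_boot,
                              seed = derive_seed(seed, paste0("auc_k", k)))
    scores[, paste0("k", k)] <- sc
    models[[paste0("k", k)]] <- list(k = k, features = feats, fit = fit, roc = roc)
  }
  aucs <- vapply(models, function(m) m$roc$auc, numeric(1))
  best_k <- ks[which.max(aucs)]                 # which.max: first max = smaller k
  rest <- setdiff(ks, best_k)
  second_k <- rest[which.max(aucs[paste0("k", rest)])]
  comparison <- bootstrap_auc_compare(
    scores[, paste0("k", best_k)], scores[, paste0("k", second_k)], y,
    n_boot = n_boot, seed = derive_seed(seed, "compare_best_second"))
  structure(list(models = models, aucs = aucs, best_k = best_k,
                 second_k = second_k, comparison = comparison,
                 scores = scores, eval = eval, lambda = lambda,
                 n_boot = n_boot, seed = seed),
            class = "model_search_result")
}

# leave-one-out ridge scores on a fixed feature set
loocv_scores <- function(X, y, lambda) {
  n <- nrow(X)
  vapply(seq_len(n), function(i) {
    fit <- suppressWarnings(fit_ridge_logistic(X[-i, , drop = FALSE], y[-i], lambda))
    predict_prob(fit, X[i, , drop = FALSE])
  }, numeric(1))
}

#' @export
print.model_search_result <- function(x, ...) {
  cat("Model search over nested top-k feature subsets (k = 4..10,",
      x$eval, "evaluation)\n")
  for (m in x$models) {
    tag <- if (m$k == x$best_k) " <- best" else if (m$k == x$second_k) " (second)" else ""
    cat(sprintf("  k=%2d: AUC = %.2f, 95%% CI = %.2f to %.2f, P = %.3g%s\n",
                m$k, m$roc$auc, m$roc$ci_low, m$roc$ci_high, m$roc$p_value, tag))
  }
  cat(sprintf("  best vs second: Delta AUC = %.3f, P = %.3g\n",
              x$comparison$delta_auc, x$comparison$p_value))
  invisible(x)
}

#' Individual-feature classification accuracy
#'
#' For each feature in a subset (typically the best model's features),
#' the AUC of the standardized feature used alone as the classification
#' score, oriented so that AUC >= 0.5 (the orientation is reported), with
#' a stratified-bootstrap standard error.
#'
#' @param table Z-scored feature table with a `group` column.
#' @param features Non-empty character vector of feature names.
#' @param n_boot Bootstrap resamples for the SE (default 1000).
#' @param seed Master seed.
#' @return Data frame with `feature`, `auc`, `se`, `direction` (+1 if
#'   higher values indicate the exposed group, -1 otherwise).
#' @export
individual_feature_auc <- function(table, features, n_boot = 1000, seed = 1) {
  if (length(features) == 0) stop_domain("feature subset must be non-empty")
  miss <- setdiff(features, names(table))
  if (length(miss)) stop_domain("missing feature column(s): ", paste(miss, collapse = ", "))
  y <- table$group
  check_binary_labels(y)
  res <- lapply(features, function(f) {
    v <- table[[f]]
    if (stats::var(v) == 0) stop_domain("constant feature: ", f)
    a <- auc(v, y)
    dir <- if (a >= 0.5) 1 else -1
    sc <- dir * v
    i1 <- which(y == 1); i0 <- which(y == 0)
    yy <- c(rep(1, length(i1)), rep(0, length(i0)))
    boot <- with_seed(derive_seed(seed, paste0("ifa_", f)), {
      vapply(seq_len(n_boot), function(b) {
        idx <- c(sample(i1, length(i1), replace = TRUE),
                 sample(i0, length(i0), replace = TRUE))
        auc(sc[idx], yy)
      }, numeric(1))
    })
    data.frame(feature = f, auc = max(a, 1 - a), se = stats::sd(boot),
               direction = dir, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Honest leave-one-out search (ranking re-run per fold)
#'
#' Unlike `build_models(eval = "loocv")`, the feature ranking itself is
#' recomputed on every training fold, so no information about the held-out
#' subject leaks into feature selection. Under a null cohort the resulting
#' best-model AUC is calibrated around chance. Bootstrap SEs are not used
#' for fold-wise selection (ranking is by |r| alone).
#'
#' @param table Z-scored feature table with a `group` column.
#' @param lambda Ridge penalty.
#' @param ks Candidate subset sizes (default 4:10).
#' @return List with `aucs` (named by k), `best_k`, `best_auc` and the
#'   per-k LOOCV score matrix.
#' @export
loocv_search <- function(table, lambda = 1e-8, ks = 4:10) {
  y <- table$group
  check_binary_labels(y)
  feats <- intersect(feature_names(), names(table))
  n <- nrow(table)
  if (n <= max(ks)) stop_domain("too few subjects for the largest candidate model")
  scores <- matrix(NA_real_, n, length(ks), dimnames = list(NULL, paste0("k", ks)))
  for (i in seq_len(n)) {
    tr <- table[-i, , drop = FALSE]
    ytr <- y[-i]
    r <- vapply(feats, function(f) {
      v <- tr[[f]]
      if (stats::var(v) == 0) return(0)
      abs(stats::cor(v, ytr))
    }, numeric(1))
    ord <- feats[order(-r, match(feats, feature_names()))]
    for (j in seq_along(ks)) {
      sel <- ord[seq_len(ks[j])]
      fit <- suppressWarnings(
        fit_ridge_logistic(as.matrix(tr[, sel, drop = FALSE]), ytr, lambda))
      scores[i, j] <- predict_prob(fit, as.matrix(table[i, sel, drop = FALSE]))
    }
  }
  aucs <- apply(scores, 2, auc, labels = y)
  names(aucs) <- paste0("k", ks)
  best <- which.max(aucs)
  list(aucs = aucs, best_k = ks[best], best_auc = unname(aucs[best]),
       scores = scores)
}

#' Run the full analysis for one timepoint
#'
#' End-to-end pipeline on one wave's subject records: feature extraction,
#' covariate adjustment fitted on the unexposed group, Z-standardization,
#' point-biserial ranking with bootstrap SEs, the nested 4-10-feature
#' model search with bootstrap AUC inference, and the individual-feature
#' AUC listing for the best model. Deterministic given the master seed;
#' identical seeds yield byte-identical written reports.
#'
#' @param records List of `subject_record`s for one timepoint (both
#'   groups present).
#' @param timepoint Label used in output file names (1-3).
#' @param seed Master seed; all stage seeds are derived from it.
#' @param lambda Ridge penalty (default 1e-8).
#' @param n_boot_auc Bootstrap resamples for AUC tests (default 1000).
#' @param n_boot_se Bootstrap resamples for ranking SEs (default 5000).
#' @param eval `"apparent"` or `"loocv"` (passed to [build_models()]).
#' @param out_dir If non-NULL, writes `ranking_t<k>.csv`,
#'   `models_t<k>.json`, `table2_t<k>.csv` and `report_t<k>.md` there.
#' @return A `timepoint_report` with all intermediate results.
#' @export
run_timepoint <- function(records, timepoint = 1, seed = 1, lambda = 1e-8,
                          n_boot_auc = 1000, n_boot_se = 5000,
                          eval = c("apparent", "loocv"), out_dir = NULL) {
  eval <- match.arg(eval)
  stage <- "feature extraction"
  res <- tryCatch({
    tbl <- extract_feature_table(records)
    if (length(unique(tbl$group)) < 2) {
      stop_domain("both groups must be present")
    }
    stage <- "covariate adjustment"
    adj <- fit_adjustment(tbl)
    ztbl <- standardize(tbl, adj)
    stage <- "feature ranking"
    ranking <- rank_features(ztbl, k = 10, n_boot = n_boot_se,
                             seed = derive_seed(seed, "rank"))
    stage <- "model search"
    search <- build_models(ztbl, ranking, lambda = lambda,
                           seed = derive_seed(seed, "search"),
                           n_boot = n_boot_auc, eval = eval)
    stage <- "individual feature AUCs"
    best_feats <- search$models[[paste0("k", search$best_k)]]$features
    tab2 <- individual_feature_auc(ztbl, best_feats, n_boot = n_boot_auc,
                                   seed = derive_seed(seed, "table2"))
    tab2 <- tab2[order(-tab2$auc, tab2$feature), , drop = FALSE]
    rownames(tab2) <- NULL
    list(tbl = tbl, adjustment = adj, ztable = ztbl, ranking = ranking,
         search = search, individual = tab2)
  }, error = function(e) {
    stop("timepoint pipeline failed at stage [", stage, "]: ",
         conditionMessage(e), call. = FALSE)
  })
  report <- structure(c(res, list(timepoint = timepoint, seed = seed,
                                  lambda = lambda, eval = eval)),
                      class = "timepoint_report")
  if (!is.null(out_dir)) write_timepoint_report(report, out_dir)
  report
}

#' @export
print.timepoint_report <- function(x, ...) {
  g <- x$tbl$group
  cat(sprintf("Timepoint %s: %d exposed vs %d unexposed (%s evaluation, seed %d)\n",
              x$timepoint, sum(g == 1), sum(g == 0), x$eval, x$seed))
  best <- x$search$models[[paste0("k", x$search$best_k)]]
  cat(sprintf("Best model: %d features, AUC = %.2f, 95%% CI = %.2f to %.2f, P = %.3g\n",
              best$k, best$roc$auc, best$roc$ci_low, best$roc$ci_high,
              best$roc$p_value))
  cat("Best-model features (by individual AUC):\n")
  print.data.frame(x$individual, digits = 3)
  invisible(x)
}

#' Write the four per-timepoint report files
#'
#' `ranking_t<k>.csv` mirrors the feature-ranking figure (r, bootstrap SE,
#' rank, selected flag); `models_t<k>.json` serializes the seven candidate
#' models with their ROC analyses; `table2_t<k>.csv` lists the best
#' model's individual-feature AUCs with SEs; `report_t<k>.md` is a
#' human-readable summary. Output is deterministic: re-running with the
#' same seed reproduces the files byte for byte.
#'
#' @param report A `timepoint_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_timepoint_report <- function(report, out_dir) {
  stopifnot(inherits(report, "timepoint_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t <- report$timepoint
  paths <- c(
    ranking = file.path(out_dir, sprintf("ranking_t%s.csv", t)),
    models = file.path(out_dir, sprintf("models_t%s.json", t)),
    table2 = file.path(out_dir, sprintf("table2_t%s.csv", t)),
    report = file.path(out_dir, sprintf("report_t%s.md", t))
  )
  rk <- as.data.frame(report$ranking)
  rk$timepoint <- t
  utils::write.csv(format(rk, digits = 10, trim = TRUE, scientific = FALSE),
                   paths["ranking"], row.names = FALSE, quote = FALSE)

  mods <- lapply(report$search$models, function(m) list(
    k = m$k, features = m$features,
    coefficients = as.list(m$fit$coefficients),
    lambda = m$fit$lambda, converged = m$fit$converged,
    iterations = m$fit$iterations,
    auc = m$roc$auc, ci_low = m$roc$ci_low, ci_high = m$roc$ci_high,
    p_value = m$roc$p_value, n_boot = m$roc$n_boot
  ))
  obj <- list(timepoint = t, seed = report$seed, lambda = report$lambda,
              eval = report$eval, models = mods,
              best_k = report$search$best_k,
              second_k = report$search$second_k,
              best_vs_second = list(
                delta_auc = report$search$comparison$delta_auc,
                p_value = report$search$comparison$p_value,
                n_boot = report$search$comparison$n_boot))
  jsonlite::write_json(obj, paths["models"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  utils::write.csv(format(report$individual, digits = 10, trim = TRUE,
                          scientific = FALSE),
                   paths["table2"], row.names = FALSE, quote = FALSE)

  best <- report$search$models[[paste0("k", report$search$best_k)]]
  g <- report$tbl$group
  lines <- c(
    sprintf("# Classification report, timepoint %s", t),
    "",
    sprintf("- Subjects: %d trauma-exposed, %d trauma-unexposed",
            sum(g == 1), sum(g == 0)),
    sprintf("- Evaluation: %s, ridge lambda = %g, master seed = %d",
            report$eval, report$lambda, report$seed),
    "",
    "## Candidate models (top-k features by |point-biserial r|)",
    "",
    "| k | AUC | 95% CI | P vs 0.5 |",
    "|---|-----|--------|----------|",
    vapply(report$search$models, function(m) {
      sprintf("| %d%s | %.2f | %.2f to %.2f | %.3g |",
              m$k, if (m$k == report$search$best_k) " (best)" else "",
              m$roc$auc, m$roc$ci_low, m$roc$ci_high, m$roc$p_value)
    }, character(1)),
    "",
    sprintf("Best (k=%d) vs second-best (k=%d): Delta AUC = %.3f, two-sided P = %.3g",
            report$search$best_k, report$search$second_k,
            report$search$comparison$delta_auc,
            report$search$comparison$p_value),
    "",
    "## Individual features of the best model",
    "",
    "| feature | AUC | SE | direction |",
    "|---------|-----|----|-----------|",
    sprintf("| %s | %.2f | %.2f | %+d |", report$individual$feature,
            report$individual$auc, report$individual$se,
            report$individual$direction),
    ""
  )
  writeLines(lines, paths["report"])
  invisible(paths)
}
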