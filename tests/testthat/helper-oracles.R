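# Independent oracles and small fixture builders used across test files.

# Exhaustive O(n^2) pairwise-concordance AUC: over all exposed/unexposed
# pairs, 1 for a correctly ordered pair, 1/2 for a tie.
auc_oracle <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(s1) * length(s0))
}

# Global efficiency via igraph's Dijkstra shortest paths on 1/density
# edge lengths (independent of the package's Floyd-Warshall).
efficiency_oracle <- function(dm, nodes = rownames(dm)) {
  sub <- dm[nodes, nodes, drop = FALSE]
  n <- nrow(sub)
  edges <- NULL; weights <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sub[i, j] > 0) {
      edges <- c(edges, i, j)
      weights <- c(weights, 1 / sub[i, j])
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, edges)
  d <- igraph::distances(g, weights = weights)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

# point-biserial r from the two-sample t statistic: r = t / sqrt(t^2 + df)
r_from_t <- function(values, labels) {
  tt <- stats::t.test(values[labels == 1], values[labels == 0], var.equal = TRUE)
  t <- unname(tt$statistic)
  df <- unname(tt$parameter)
  sign_ok <- t / sqrt(t^2 + df)
  sign_ok
}

# random symmetric 5x5 density matrix with zero diagonal; sparsity gives
# a mix of connected and disconnected graphs
random_density_matrix <- function(p_edge = 0.7, scale = 2) {
  rois <- fearcircuit::roi_names()
  dm <- matrix(0, 5, 5, dimnames = list(rois, rois))
  for (i in 1:4) for (j in (i + 1):5) {
    if (stats::runif(1) < p_edge) {
      dm[i, j] <- dm[j, i] <- stats::rexp(1, rate = 1 / scale)
    }
  }
  dm
}

# A fully deterministic subject record with hand-set summaries, for
# feature-extraction arithmetic tests. All pairs share `count` and
# `mean_length`; seed tables have 4 voxels per hemisphere.
make_record <- function(count = 40, mean_length = 50, symmetric = TRUE,
                        group = 0, id = "s1") {
  rois <- fearcircuit::roi_names()
  pairs <- fearcircuit::roi_pair_names()
  targets <- fearcircuit::amygdala_targets()
  vols <- c(amygdala = 1.5, OMPFC = 20, hippocampus = 3.5,
            insula = 7, thalamus = 8)
  bump <- if (symmetric) 0 else 0.3
  roi_volume <- rbind(left = vols, right = vols + bump)
  gm <- c(OMPFC = 0.45, hippocampus = 0.5, insula = 0.48, thalamus = 0.44)
  gm_density <- rbind(left = gm, right = gm + if (symmetric) 0 else 0.02)
  cnt <- rbind(left = stats::setNames(rep(count, 10), pairs),
               right = stats::setNames(rep(count, 10), pairs))
  len <- ifelse(cnt > 0, mean_length, NA_real_)
  dimnames(len) <- dimnames(cnt)
  st <- cbind(OMPFC = c(30, 20, 10, 5), hippocampus = c(20, 30, 10, 5),
              insula = c(10, 10, 10, 10), thalamus = c(5, 5, 35, 35),
              any_hits = c(100, 100, 100, 100))
  structure(list(
    subject_id = id, group = group, age = 30, sex = 0, icv = 1450,
    roi_volume = roi_volume, gm_density = gm_density,
    streamline_count = cnt, streamline_mean_length = len,
    seed_table = list(left = st, right = st)
  ), class = "subject_record")
}

# small, fast cohort configuration for structural tests (not the study
# defaults; those are exercised in the acceptance suite)
tiny_config <- function(...) {
  fearcircuit::cohort_config(
    n_exposed = c(8, 6, 4), n_unexposed = c(8, 8, 5),
    diagnosis_counts = c(8, 6, 4, 1),
    seed_voxels = 12, seed_samples = 60, n_calibration = 250, ...)
}
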