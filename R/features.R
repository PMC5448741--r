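#' Connection density between two ROIs
#'
#' Streamline count between two regions divided by the summed volume of the
#' interconnected regions, giving tracts per cubic centimetre.
#'
#' @param count Non-negative streamline count.
#' @param vol_a,vol_b Strictly positive ROI volumes in cm^3.
#' @return Density in tracts/cm^3.
#' @export
connection_density <- function(count, vol_a, vol_b) {
  if (any(vol_a <= 0) || any(vol_b <= 0)) {
    stop_domain("ROI volumes must be strictly positive")
  }
  if (any(count < 0)) stop_domain("streamline count must be non-negative")
  count / (vol_a + vol_b)
}

#' Connection cost between two ROIs
#'
#' Connection density multiplied by the mean streamline length (mm).
#' An absent connection (density 0, no defined length) has cost 0.
#'
#' @param density Connection density, tracts/cm^3.
#' @param mean_length Mean streamline length in mm; may be `NA` when
#'   `density` is 0.
#' @return Connection cost.
#' @export
connection_cost <- function(density, mean_length) {
  if (any(density < 0)) stop_domain("density must be non-negative")
  out <- ifelse(density == 0, 0, density * mean_length)
  if (any(density > 0 & (is.na(mean_length) | mean_length <= 0))) {
    stop_domain("mean_length must be positive wherever density > 0")
  }
  out
}

#' Region-wise aggregation of pair-wise values
#'
#' A region-wise connectivity value is the arithmetic mean of the four
#' pair-wise values of the pairs containing that ROI.
#'
#' @param pair_values Numeric vector of exactly 4 pair-wise values.
#' @return Their mean.
#' @export
regionwise_aggregate <- function(pair_values) {
  if (length(pair_values) != 4 || anyNA(pair_values)) {
    stop_domain("regionwise_aggregate requires exactly 4 non-missing pair values")
  }
  mean(pair_values)
}

#' Relative tract strength from a seed-classification table
#'
#' For each amygdala voxel the ratio of probabilistic samples that reached
#' only the given target ROI to samples that reached any of the four target
#' ROIs is formed; voxels with no sample reaching any target are dropped
#' (the ratio is undefined there), ratios below 0.01 are excluded, and the
#' remaining ratios are averaged. If no voxel survives the 0.01 rule the
#' strength is 0 and a warning is emitted.
#'
#' @param seed_table One hemisphere's seed-classification table: a numeric
#'   matrix with one row per amygdala voxel and columns `OMPFC`,
#'   `hippocampus`, `insula`, `thalamus` (exclusive hit counts) and
#'   `any_hits` (samples reaching any target).
#' @param target One of the four target ROI names.
#' @return Relative tract strength in `[0, 1]`.
#' @export
tract_strength <- function(seed_table, target) {
  if (!is.matrix(seed_table) || nrow(seed_table) < 1) {
    stop_domain("seed_table must be a matrix with at least one voxel row")
  }
  need <- c(amygdala_targets(), "any_hits")
  if (!all(need %in% colnames(seed_table))) {
    stop_domain("seed_table must have columns ", paste(need, collapse = ", "))
  }
  if (!target %in% amygdala_targets()) {
    stop_domain("unknown target ROI: ", target)
  }
  any_hits <- seed_table[, "any_hits"]
  excl <- seed_table[, target]
  if (any(any_hits < 0) || any(excl < 0)) stop_domain("hit counts must be non-negative")
  keep <- any_hits > 0
  if (!any(keep)) stop_domain("no voxel has any_hits > 0")
  ratio <- excl[keep] / any_hits[keep]
  ratio <- ratio[ratio >= 0.01]
  if (length(ratio) == 0) {
    warning("no voxel ratio >= 0.01 for target ", target, "; tract strength set to 0")
    return(0)
  }
  mean(ratio)
}

#' Global efficiency of a density-weighted ROI network
#'
#' Edges carry length 1/density (absent when density is 0); `d_ij` is the
#' shortest-path length within the induced subgraph on `nodes`, and the
#' global efficiency is the average over ordered node pairs of `1/d_ij`,
#' with disconnected pairs contributing 0 (Latora-Marchiori efficiency).
#'
#' @param dm Symmetric non-negative density matrix with zero diagonal and
#'   ROI names as dimnames.
#' @param nodes Character vector (length >= 2) of ROI names to induce the
#'   subnetwork on; defaults to all rows of `dm`.
#' @return Global efficiency (same units as density).
#' @export
network_efficiency <- function(dm, nodes = rownames(dm)) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) stop_domain("dm must be square")
  if (is.null(rownames(dm))) stop_domain("dm must have ROI dimnames")
  if (any(dm < 0)) stop_domain("densities must be non-negative")
  if (max(abs(dm - t(dm))) > 1e-9) stop_domain("dm must be symmetric")
  if (length(nodes) < 2) stop_domain("at least 2 nodes are required")
  if (!all(nodes %in% rownames(dm))) stop_domain("unknown node name(s)")
  sub <- dm[nodes, nodes, drop = FALSE]
  n <- length(nodes)
  len <- ifelse(sub > 0, 1 / sub, Inf)
  diag(len) <- 0
  # Floyd-Warshall on <= 5 nodes
  d <- len
  for (k in seq_len(n)) {
    via <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, via)
  }
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

# validate a subject_record structurally; returns invisibly or errors with
# the missing/invalid field name
validate_record <- function(rec) {
  need <- c("subject_id", "group", "age", "sex", "icv",
            "roi_volume", "gm_density", "streamline_count",
            "streamline_mean_length", "seed_table")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop_domain("incomplete subject record; missing field(s): ",
                                paste(miss, collapse = ", "))
  if (!all(roi_names() %in% colnames(rec$roi_volume))) {
    stop_domain("roi_volume must have one column per ROI")
  }
  if (any(rec$roi_volume <= 0)) stop_domain("ROI volumes must be strictly positive")
  if (rec$icv <= 0) stop_domain("icv must be strictly positive")
  if (!all(roi_pair_names() %in% colnames(rec$streamline_count))) {
    stop_domain("streamline_count must cover all 10 ROI pairs")
  }
  cnt <- rec$streamline_count
  len <- rec$streamline_mean_length
  if (any(cnt > 0 & is.na(len))) stop_domain("mean length missing for a pair with count > 0")
  if (any(cnt == 0 & !is.na(len))) stop_domain("mean length present for a pair with count 0")
  if (!all(c("left", "right") %in% names(rec$seed_table))) {
    stop_domain("seed_table must have left and right hemisphere tables")
  }
  invisible(TRUE)
}

#' Extract the 23 structural features from one subject record
#'
#' Hemisphere combination follows the extensive/intensive rule: the
#' amygdala volume is the left+right sum; grey-matter densities, pair-wise
#' densities/costs and tract strengths are computed per hemisphere and
#' averaged; the efficiency network is built from hemisphere-summed
#' streamline counts and hemisphere-summed volumes. Region-wise connection
#' density and cost are the mean of the four incident pair values.
#'
#' @param subject A `subject_record` as produced by [generate_cohort()] or
#'   [read_cohort()].
#' @param details If `TRUE`, also return the hemisphere-averaged pair-wise
#'   densities and costs and the combined density matrix (used internally
#'   for generator calibration).
#' @return Named numeric vector of length 23 (or a list when
#'   `details = TRUE`).
#' @export
extract_features <- function(subject, details = FALSE) {
  validate_record(subject)
  rois <- roi_names()
  pairs <- roi_pair_names()
  vol <- subject$roi_volume           # 2 x 5, rows left/right
  cnt <- subject$streamline_count     # 2 x 10
  len <- subject$streamline_mean_length

  vol_bilat <- colSums(vol)[rois]

  ends <- vapply(pairs, pair_endpoints, character(2))
  # per-hemisphere pair density and cost, then hemisphere mean
  pd <- matrix(0, 2, length(pairs), dimnames = list(c("left", "right"), pairs))
  pc <- pd
  for (h in 1:2) {
    volsum <- vol[h, ends[1, ]] + vol[h, ends[2, ]]
    pd[h, ] <- connection_density(cnt[h, pairs], vol[h, ends[1, ]], vol[h, ends[2, ]])
    pc[h, ] <- connection_cost(pd[h, ], len[h, pairs])
  }
  pair_density <- colMeans(pd)
  pair_cost <- colMeans(pc)

  conn_density <- vapply(rois, function(r)
    regionwise_aggregate(pair_density[pairs_incident(r)]), numeric(1))
  conn_cost <- vapply(rois, function(r)
    regionwise_aggregate(pair_cost[pairs_incident(r)]), numeric(1))

  ts <- vapply(amygdala_targets(), function(tg) {
    mean(c(tract_strength(subject$seed_table$left, tg),
           tract_strength(subject$seed_table$right, tg)))
  }, numeric(1))

  # hemisphere-combined density matrix: counts summed, volumes summed
  cnt_bilat <- colSums(cnt)[pairs]
  dm <- matrix(0, 5, 5, dimnames = list(rois, rois))
  for (p in pairs) {
    e <- pair_endpoints(p)
    dm[e[1], e[2]] <- dm[e[2], e[1]] <-
      connection_density(cnt_bilat[p], vol_bilat[e[1]], vol_bilat[e[2]])
  }
  eff <- vapply(network_node_sets(), function(nodes)
    network_efficiency(dm, nodes), numeric(1))

  feats <- c(
    amygdala_volume = unname(vol_bilat["amygdala"]),
    stats::setNames(colMeans(subject$gm_density)[amygdala_targets()],
                    paste0("gm_density_", amygdala_targets())),
    stats::setNames(conn_density, paste0("conn_density_", rois)),
    stats::setNames(conn_cost, paste0("conn_cost_", rois)),
    stats::setNames(ts, paste0("tract_strength_amy_", amygdala_targets())),
    stats::setNames(eff, paste0("net_efficiency_", names(eff)))
  )
  feats <- feats[feature_names()]
  if (!details) return(feats)
  list(features = feats, pair_density = pair_density, pair_cost = pair_cost,
       density_matrix = dm)
}

#' Build the cohort feature table
#'
#' Applies [extract_features()] to every record and returns one row per
#' subject with covariates, group label and the 23 features.
#'
#' @param records List of `subject_record`s (one timepoint).
#' @return A `data.frame` with columns `subject_id`, `group`, `age`, `sex`,
#'   `icv` and the 23 canonical feature columns.
#' @export
extract_feature_table <- function(records) {
  if (length(records) == 0) stop_domain("no records supplied")
  fmat <- t(vapply(records, extract_features, numeric(23)))
  meta <- data.frame(
    subject_id = vapply(records, `[[`, character(1), "subject_id"),
    group = vapply(records, `[[`, numeric(1), "group"),
    age = vapply(records, `[[`, numeric(1), "age"),
    sex = vapply(records, `[[`, numeric(1), "sex"),
    icv = vapply(records, `[[`, numeric(1), "icv"),
    stringsAsFactors = FALSE
  )
  cbind(meta, as.data.frame(fmat))
}
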