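# Synthetic longitudinal cohort generator.
#
# The generator emulates the tabular structural summaries the analysis
# consumes (ROI volumes, grey-matter densities, streamline counts and
# lengths, amygdala seed-classification tables) together with covariates
# and longitudinal CAPS/diagnosis records, with configurable group effect
# sizes planted on the *raw-summary* scale so that the full downstream
# pipeline (extraction -> adjustment -> Z-scoring) sees the intended
# standardized shift.

.fc_cache <- new.env(parent = emptyenv())

CALIBRATION_SEED <- 761923L
CAPS_MAX <- 136

#' Synthetic cohort configuration
#'
#' Defaults reproduce the study design: exposed group sizes 30/25/17 and
#' unexposed 29/29/21 across the three imaging waves (nested attrition),
#' CAPS totals declining 87.1, 54.0, 45.6, 35.1 (SD 12.6, 14.1, 11.8,
#' 15.0) over clinical times 0-3, and diagnosis counts 30/30, 23/30,
#' 12/25, 2/17. Baseline generative parameters (volumes, grey-matter
#' densities, streamline counts/lengths, seed-classification weights) are
#' chosen at physiologically realistic scales; streamline counts are
#' negative-binomial (over-dispersed), lengths lognormal, volumes and
#' densities truncated normals, and seed tables Dirichlet-multinomial.
#'
#' @param n_exposed,n_unexposed Group sizes at imaging times 1-3
#'   (non-increasing; dropouts never return).
#' @param effects Named list `t1`/`t2`/`t3`; each element a named numeric
#'   vector of standardized effect sizes (shift of the exposed group in
#'   unexposed-SD units) keyed by [feature_names()]. Empty = null cohort.
#' @param caps_mean,caps_sd CAPS total mean/SD at clinical times 0-3.
#' @param diagnosis_counts Number of exposed subjects meeting PTSD
#'   criteria at clinical times 0-3 (out of `caps_assessed`).
#' @param caps_gap Separation (CAPS points) between diagnosed and
#'   recovered subjects' conditional means; the mixture mean always equals
#'   `caps_mean`.
#' @param age_mean,age_sd,age_range,sex_p_male,icv_mean,icv_sd Covariate
#'   distributions (age truncated to `age_range`; sex 1 = male; ICV cm^3).
#' @param vol_mean,vol_sd Per-hemisphere ROI volume mean/SD (cm^3).
#' @param gm_mean,gm_sd Per-hemisphere grey-matter density mean/SD.
#' @param count_mean Per-hemisphere negative-binomial mean streamline
#'   count per ROI pair; `count_size` is the NB dispersion (size).
#' @param len_mean_mm Mean streamline length per pair (mm); `len_sdlog`
#'   the lognormal sdlog.
#' @param seed_voxels Amygdala voxels per hemisphere in the
#'   seed-classification table.
#' @param seed_samples Mean number of probabilistic samples per voxel
#'   reaching any target (Poisson).
#' @param seed_weights Expected proportions, among samples reaching any
#'   target, of samples reaching exclusively each of the four targets plus
#'   a `shared` category (samples reaching two or more targets, counted in
#'   `any_hits` but in no exclusive count).
#' @param seed_concentration Dirichlet concentration across voxels
#'   (smaller = more voxel-to-voxel heterogeneity for the 0.01 exclusion
#'   rule to act on).
#' @param seed_subject_tau Lognormal SD of subject-level perturbation of
#'   the target weights (between-subject tract-strength variation).
#' @param age_slope_vol,age_slope_gm,age_slope_count,sex_effect_vol,
#'   sex_effect_count,icv_slope_amy Nuisance covariate effects on the raw
#'   summaries (relative slopes per year / male offset; `icv_slope_amy` in
#'   cm^3 amygdala per cm^3 ICV per hemisphere), giving the adjustment
#'   stage something real to remove.
#' @param dropout `"random"` (non-informative, default) or `"caps"`
#'   (subjects with lower CAPS are more likely to drop out).
#' @param n_calibration Subjects used internally to calibrate planted
#'   effect sizes against the reference residual SD of each feature.
#' @param rng_seed Default master seed for the generator functions.
#' @return A validated `cohort_config`.
#' @export
cohort_config <- function(
  n_exposed = c(30, 25, 17),
  n_unexposed = c(29, 29, 21),
  effects = list(t1 = numeric(0), t2 = numeric(0), t3 = numeric(0)),
  caps_mean = c(87.1, 54.0, 45.6, 35.1),
  caps_sd = c(12.6, 14.1, 11.8, 15.0),
  diagnosis_counts = c(30, 23, 12, 2),
  caps_gap = 18,
  age_mean = 27, age_sd = 8, age_range = c(18, 50),
  sex_p_male = 0.37,
  icv_mean = 1450, icv_sd = 130,
  vol_mean = c(amygdala = 1.7, OMPFC = 23, hippocampus = 3.7,
               insula = 7.0, thalamus = 7.8),
  vol_sd = c(amygdala = 0.12, OMPFC = 1.6, hippocampus = 0.26,
             insula = 0.50, thalamus = 0.55),
  gm_mean = c(OMPFC = 0.45, hippocampus = 0.52, insula = 0.48, thalamus = 0.44),
  gm_sd = c(OMPFC = 0.035, hippocampus = 0.035, insula = 0.035, thalamus = 0.035),
  count_mean = c(180, 260, 150, 120, 90, 140, 200, 80, 110, 130),
  count_size = 8,
  len_mean_mm = c(45, 32, 38, 42, 60, 48, 55, 40, 35, 30),
  len_sdlog = 0.15,
  seed_voxels = 200,
  seed_samples = 300,
  seed_weights = c(OMPFC = 0.30, hippocampus = 0.26, insula = 0.14,
                   thalamus = 0.10, shared = 0.20),
  seed_concentration = 24,
  seed_subject_tau = 0.12,
  age_slope_vol = -0.002, age_slope_gm = -0.002, age_slope_count = -0.004,
  sex_effect_vol = 0.04, sex_effect_count = 0.05,
  icv_slope_amy = 0.0008,
  dropout = c("random", "caps"),
  n_calibration = 5000,
  rng_seed = 1
) {
  dropout <- match.arg(dropout)
  pairs <- roi_pair_names()
  if (is.null(names(count_mean))) names(count_mean) <- pairs
  if (is.null(names(len_mean_mm))) names(len_mean_mm) <- pairs
  rm(pairs)
  cfg <- structure(as.list(environment()), class = "cohort_config")
  pairs <- roi_pair_names()

  if (length(n_exposed) != 3 || length(n_unexposed) != 3) {
    stop_domain("n_exposed and n_unexposed must give 3 imaging timepoints")
  }
  if (any(n_exposed < 0) || any(n_unexposed < 0)) stop_domain("group sizes must be non-negative")
  if (any(diff(n_exposed) > 0) || any(diff(n_unexposed) > 0)) {
    stop_domain("attrition must be nested: group sizes cannot increase over time")
  }
  if (length(caps_mean) != 4 || length(caps_sd) != 4 || length(diagnosis_counts) != 4) {
    stop_domain("caps_mean, caps_sd and diagnosis_counts must cover clinical times 0-3")
  }
  assessed <- c(n_exposed[1], n_exposed)
  if (any(diagnosis_counts > assessed)) {
    stop_domain("diagnosis count exceeds number of subjects assessed at a timepoint")
  }
  if (any(diagnosis_counts < 0)) stop_domain("diagnosis counts must be non-negative")
  if (!setequal(names(cfg$seed_weights),
                c(amygdala_targets(), "shared")) || any(cfg$seed_weights <= 0)) {
    stop_domain("seed_weights must be positive and cover the 4 targets plus 'shared'")
  }
  if (!all(pairs %in% names(cfg$count_mean)) || !all(pairs %in% names(cfg$len_mean_mm))) {
    stop_domain("count_mean and len_mean_mm must be named by the 10 ROI pairs")
  }
  if (!is.list(cfg$effects)) stop_domain("effects must be a list")
  for (tn in c("t1", "t2", "t3")) {
    e <- cfg$effects[[tn]] %||% numeric(0)
    if (length(e) && (is.null(names(e)) || !all(names(e) %in% feature_names()))) {
      stop_domain("effects$", tn, " must be named by canonical feature names")
    }
    cfg$effects[[tn]] <- e
  }
  if (cfg$seed_voxels < 1) stop_domain("seed_voxels must be at least 1")
  cfg
}

#' Read a cohort configuration from a YAML or JSON file
#'
#' The file may override any subset of [cohort_config()] arguments;
#' everything else keeps its default.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  raw <- lapply(raw, function(x) if (is.list(x) && !is.null(names(x)) &&
                                     all(vapply(x, is.numeric, logical(1))) &&
                                     !identical(names(x)[1], "t1")) unlist(x) else x)
  if (!is.null(raw$effects)) raw$effects <- lapply(raw$effects, unlist)
  do.call(cohort_config, raw)
}

# identity (null) perturbation of the exposed group's raw summaries
null_perturbation <- function(cfg) {
  pairs <- roi_pair_names()
  list(
    vol_shift_amy_hemi = 0,
    gm_shift = stats::setNames(rep(0, 4), amygdala_targets()),
    count_mult = stats::setNames(rep(1, 10), pairs),
    len_mult = stats::setNames(rep(1, 10), pairs),
    seed_weights = cfg$seed_weights
  )
}

# cache key over everything that shapes the null feature distribution
calibration_key <- function(cfg) {
  keep <- setdiff(names(cfg), c("n_exposed", "n_unexposed", "effects",
                                "caps_mean", "caps_sd", "diagnosis_counts",
                                "caps_gap", "dropout", "rng_seed"))
  paste(vapply(keep, function(k)
    paste0(k, "=", paste(format(unlist(cfg[[k]]), digits = 15), collapse = ",")),
    character(1)), collapse = ";")
}

#' Calibrate the generator's effect-size scale
#'
#' Simulates `n_calibration` null (unexposed-like) subjects with a fixed
#' internal seed, extracts features, fits the covariate adjustment and
#' records each feature's mean and reference residual SD, plus pair-level
#' density/cost means. Planted standardized effects are converted to
#' raw-scale shifts through these constants, so a planted effect of `e`
#' appears downstream as a Z-shift of `e`. The result is cached per
#' generative-parameter set.
#'
#' @param config A `cohort_config`.
#' @return List with `mu_f`, `sigma_f` (named by feature),
#'   `mu_pair_density`, `mu_pair_cost` (named by ROI pair).
#' @export
calibrate_generator <- function(config) {
  key <- calibration_key(config)
  hit <- .fc_cache[[key]]
  if (!is.null(hit)) return(hit)
  recs <- with_seed(CALIBRATION_SEED, {
    simulate_records(config$n_calibration, group = 0, cfg = config,
                     perturb = NULL,
                     ids = sprintf("cal_%05d", seq_len(config$n_calibration)))
  })
  dets <- lapply(recs, extract_features, details = TRUE)
  fmat <- t(vapply(dets, `[[`, numeric(23), "features"))
  tbl <- cbind(
    data.frame(subject_id = vapply(recs, `[[`, character(1), "subject_id"),
               group = 0,
               age = vapply(recs, `[[`, numeric(1), "age"),
               sex = vapply(recs, `[[`, numeric(1), "sex"),
               icv = vapply(recs, `[[`, numeric(1), "icv")),
    as.data.frame(fmat))
  model <- fit_adjustment(tbl)
  calib <- list(
    mu_f = colMeans(fmat),
    sigma_f = vapply(model$terms, `[[`, numeric(1), "sd"),
    mu_pair_density = colMeans(t(vapply(dets, `[[`, numeric(10), "pair_density"))),
    mu_pair_cost = colMeans(t(vapply(dets, `[[`, numeric(10), "pair_cost")))
  )
  assign(key, calib, envir = .fc_cache)
  calib
}

# Translate standardized effect sizes for one timepoint into raw-scale
# perturbations of the exposed group's generative parameters.
#
# Additive features (amygdala volume, gm densities) shift exactly;
# connection densities/costs are planted by multiplicative count/length
# scalings solved by fixed point over the incident pairs (exact in
# expectation, including pairs shared between two planted ROIs); network
# efficiencies use uniform count scalings over their edge sets (exact per
# subject when no overlapping density effect is planted); tract strengths
# re-solve the seed-classification weights so the target mean ratios shift
# by the required amount.
plan_perturbation <- function(cfg, timepoint, calib) {
  pert <- null_perturbation(cfg)
  eff <- cfg$effects[[paste0("t", timepoint)]]
  if (!length(eff)) return(pert)
  eff <- eff[eff != 0]
  if (!length(eff)) return(pert)
  delta <- eff * calib$sigma_f[names(eff)]
  rois <- roi_names()
  pairs <- roi_pair_names()
  mu_f <- calib$mu_f

  clamp_mult <- function(g, what) {
    if (g <= 0.02) {
      warning("planted effect on ", what, " drives its scale near zero; clamped")
      return(0.02)
    }
    g
  }

  if ("amygdala_volume" %in% names(delta)) {
    pert$vol_shift_amy_hemi <- delta[["amygdala_volume"]] / 2
  }
  for (tg in amygdala_targets()) {
    f <- paste0("gm_density_", tg)
    if (f %in% names(delta)) pert$gm_shift[tg] <- delta[[f]]
  }

  # network-efficiency multipliers per pair
  G <- stats::setNames(rep(1, 10), pairs)
  for (nm in names(network_node_sets())) {
    f <- paste0("net_efficiency_", nm)
    if (f %in% names(delta)) {
      nodes <- network_node_sets()[[nm]]
      in_net <- vapply(pairs, function(p) all(pair_endpoints(p) %in% nodes), logical(1))
      g <- clamp_mult(1 + delta[[f]] / mu_f[[f]], f)
      G[in_net] <- G[in_net] * g
    }
  }

  # connection-density count multipliers (fixed point over planted ROIs)
  dens_feats <- intersect(paste0("conn_density_", rois), names(delta))
  planted_d <- sub("conn_density_", "", dens_feats)
  c_r <- stats::setNames(rep(1, 5), rois)
  if (length(planted_d)) {
    for (it in 1:200) {
      c_old <- c_r
      for (r in planted_d) {
        inc <- pairs_incident(r)
        other <- vapply(inc, function(p) setdiff(pair_endpoints(p), r), character(1))
        denom <- mean(G[inc] * c_r[other] * calib$mu_pair_density[inc])
        target <- mu_f[[paste0("conn_density_", r)]] + delta[[paste0("conn_density_", r)]]
        c_r[r] <- clamp_mult(target / denom, paste0("conn_density_", r))
      }
      if (max(abs(c_r - c_old)) < 1e-12) break
    }
  }
  ends <- vapply(pairs, pair_endpoints, character(2))
  pert$count_mult <- G * c_r[ends[1, ]] * c_r[ends[2, ]]
  names(pert$count_mult) <- pairs

  # connection-cost length multipliers, given the count multipliers
  cost_feats <- intersect(paste0("conn_cost_", rois), names(delta))
  planted_c <- sub("conn_cost_", "", cost_feats)
  l_r <- stats::setNames(rep(1, 5), rois)
  if (length(planted_c)) {
    for (it in 1:200) {
      l_old <- l_r
      for (r in planted_c) {
        inc <- pairs_incident(r)
        other <- vapply(inc, function(p) setdiff(pair_endpoints(p), r), character(1))
        denom <- mean(pert$count_mult[inc] * l_r[other] * calib$mu_pair_cost[inc])
        target <- mu_f[[paste0("conn_cost_", r)]] + delta[[paste0("conn_cost_", r)]]
        l_r[r] <- clamp_mult(target / denom, paste0("conn_cost_", r))
      }
      if (max(abs(l_r - l_old)) < 1e-12) break
    }
  }
  pert$len_mult <- l_r[ends[1, ]] * l_r[ends[2, ]]
  names(pert$len_mult) <- pairs

  # tract strengths: joint re-solve of the seed-classification weights
  ts_feats <- intersect(paste0("tract_strength_amy_", amygdala_targets()), names(delta))
  if (length(ts_feats)) {
    planted_t <- sub("tract_strength_amy_", "", ts_feats)
    w <- cfg$seed_weights
    S <- sum(w)
    m_new <- vapply(planted_t, function(tgt) {
      m <- w[[tgt]] / S + delta[[paste0("tract_strength_amy_", tgt)]]
      min(max(m, 0.002), 0.95)
    }, numeric(1))
    if (sum(m_new) >= 0.995) stop_domain("planted tract-strength effects are jointly infeasible")
    U <- S - sum(w[planted_t])
    S_new <- U / (1 - sum(m_new))
    w[planted_t] <- m_new * S_new
    pert$seed_weights <- w
  }
  pert
}

# Vectorized draw of n subject records.
#
# `covariates`, when given, is a data.frame(age, sex, icv) fixing the
# covariates (used by generate_longitudinal to keep them stable within
# subject across waves); otherwise they are drawn from the config.
simulate_records <- function(n, group, cfg, perturb = NULL, ids = NULL,
                             covariates = NULL) {
  if (n == 0) return(list())
  pert <- perturb %||% null_perturbation(cfg)
  rois <- roi_names()
  pairs <- roi_pair_names()
  targets <- amygdala_targets()
  hemis <- c("left", "right")
  if (is.null(ids)) ids <- sprintf("%s_%03d", if (group == 1) "exp" else "unx", seq_len(n))

  if (is.null(covariates)) {
    age <- rnorm_trunc(n, cfg$age_mean, cfg$age_sd, cfg$age_range[1], cfg$age_range[2])
    sex <- stats::rbinom(n, 1, cfg$sex_p_male)
    icv <- stats::rnorm(n, cfg$icv_mean, cfg$icv_sd)
  } else {
    age <- covariates$age; sex <- covariates$sex; icv <- covariates$icv
  }
  age_c <- age - cfg$age_mean
  icv_c <- icv - cfg$icv_mean

  vol <- list()  # per hemi: n x 5
  for (h in hemis) {
    m <- matrix(0, n, 5, dimnames = list(NULL, rois))
    for (r in rois) {
      mu <- cfg$vol_mean[[r]] * (1 + cfg$age_slope_vol * age_c + cfg$sex_effect_vol * sex)
      if (r == "amygdala") {
        mu <- mu + cfg$icv_slope_amy * icv_c + pert$vol_shift_amy_hemi
      }
      m[, r] <- pmax(stats::rnorm(n, mu, cfg$vol_sd[[r]]), 0.05 * cfg$vol_mean[[r]])
    }
    vol[[h]] <- m
  }

  gm <- list()
  for (h in hemis) {
    m <- matrix(0, n, 4, dimnames = list(NULL, targets))
    for (tg in targets) {
      mu <- cfg$gm_mean[[tg]] * (1 + cfg$age_slope_gm * age_c) + pert$gm_shift[[tg]]
      m[, tg] <- pmin(pmax(stats::rnorm(n, mu, cfg$gm_sd[[tg]]), 0.01), 0.99)
    }
    gm[[h]] <- m
  }

  cnt <- list(); len <- list()
  for (h in hemis) {
    cm <- matrix(0L, n, 10, dimnames = list(NULL, pairs))
    lm_ <- matrix(NA_real_, n, 10, dimnames = list(NULL, pairs))
    for (p in pairs) {
      mu <- cfg$count_mean[[p]] * exp(cfg$age_slope_count * age_c) *
        (1 + cfg$sex_effect_count * sex) * pert$count_mult[[p]]
      cm[, p] <- stats::rnbinom(n, size = cfg$count_size, mu = mu)
      ml <- log(cfg$len_mean_mm[[p]] * pert$len_mult[[p]]) - cfg$len_sdlog^2 / 2
      lv <- stats::rlnorm(n, ml, cfg$len_sdlog)
      lm_[, p] <- ifelse(cm[, p] > 0, lv, NA_real_)
    }
    cnt[[h]] <- cm; len[[h]] <- lm_
  }

  # seed-classification tables: Dirichlet-multinomial over 4 exclusive
  # target categories + a shared remainder, with subject-level weight jitter
  V <- cfg$seed_voxels
  w_base <- pert$seed_weights[c(targets, "shared")]
  jitter <- exp(matrix(stats::rnorm(n * 5, 0, cfg$seed_subject_tau), n, 5))
  W <- sweep(jitter, 2, w_base, `*`)
  alpha <- cfg$seed_concentration * W / rowSums(W)   # n x 5

  seed_tabs <- vector("list", n)
  for (i in seq_len(n)) seed_tabs[[i]] <- list()
  chunk <- max(1L, floor(1e6 / V))
  for (h in hemis) {
    start <- 1L
    while (start <= n) {
      idx <- start:min(n, start + chunk - 1L)
      nb <- length(idx)
      N <- nb * V
      a_rep <- alpha[rep(idx, each = V), , drop = FALSE]
      g <- matrix(stats::rgamma(N * 5, shape = a_rep), N, 5)
      q <- g / pmax(rowSums(g), 1e-300)
      any_hits <- stats::rpois(N, cfg$seed_samples)
      excl <- matrix(0L, N, 4, dimnames = list(NULL, targets))
      rem <- any_hits
      cum <- numeric(N)
      for (j in 1:4) {
        pj <- pmin(pmax(q[, j] / pmax(1 - cum, 1e-12), 0), 1)
        excl[, j] <- stats::rbinom(N, rem, pj)
        rem <- rem - excl[, j]
        cum <- cum + q[, j]
      }
      for (k in seq_along(idx)) {
        rows <- ((k - 1L) * V + 1L):(k * V)
        seed_tabs[[idx[k]]][[h]] <-
          cbind(excl[rows, , drop = FALSE],
                any_hits = any_hits[rows])
      }
      start <- start + chunk
    }
  }

  lapply(seq_len(n), function(i) {
    structure(list(
      subject_id = ids[i],
      group = group,
      age = age[i], sex = sex[i], icv = icv[i],
      roi_volume = rbind(left = vol$left[i, ], right = vol$right[i, ]),
      gm_density = rbind(left = gm$left[i, ], right = gm$right[i, ]),
      streamline_count = rbind(left = cnt$left[i, ], right = cnt$right[i, ]),
      streamline_mean_length = rbind(left = len$left[i, ], right = len$right[i, ]),
      seed_table = seed_tabs[[i]]
    ), class = "subject_record")
  })
}

#' Generate one timepoint of a synthetic cohort
#'
#' Draws the configured numbers of exposed and unexposed subject records
#' for one imaging wave. Effects configured for that timepoint are planted
#' on the exposed group's raw summaries (see [calibrate_generator()]), so
#' each planted feature's downstream Z-score shifts by the configured
#' number of unexposed-SD units in expectation. Deterministic given
#' `config` and `seed`.
#'
#' @param config A `cohort_config`.
#' @param timepoint Imaging wave, 1-3.
#' @param seed Master seed (default `config$rng_seed`).
#' @return List of `subject_record`s, exposed first.
#' @export
generate_cohort <- function(config, timepoint = 1, seed = config$rng_seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (!timepoint %in% 1:3) stop_domain("timepoint must be 1, 2 or 3")
  pert <- NULL
  if (length(config$effects[[paste0("t", timepoint)]])) {
    calib <- calibrate_generator(config)
    pert <- plan_perturbation(config, timepoint, calib)
  }
  n1 <- config$n_exposed[timepoint]
  n0 <- config$n_unexposed[timepoint]
  with_seed(derive_seed(seed, paste0("cohort_t", timepoint)), {
    c(simulate_records(n1, 1, config, pert, ids = sprintf("exp_%03d", seq_len(n1))),
      simulate_records(n0, 0, config, NULL, ids = sprintf("unx_%03d", seq_len(n0))))
  })
}

#' Generate a full longitudinal synthetic cohort
#'
#' Produces imaging records for waves 1-3 with nested attrition (subjects
#' present at a wave were present at all earlier waves; covariates are
#' drawn once per subject, with age advancing between waves), plus
#' longitudinal CAPS/diagnosis records for the exposed group at clinical
#' times 0-3. Diagnosis is planted as a label with exactly the configured
#' counts and recovery is permanent; CAPS totals are drawn conditionally
#' on the label from two shifted normals truncated to `[0, 136]` whose
#' mixture mean equals the configured CAPS mean.
#'
#' @param config A `cohort_config`.
#' @param seed Master seed (default `config$rng_seed`).
#' @return A `longitudinal_cohort`: `records` (list `t1`-`t3` of
#'   `subject_record`s), `clinical` (data frame `subject_id`, `timepoint`
#'   0-3, `caps`, `diagnosed` for assessed exposed subjects), `config`,
#'   `seed`.
#' @export
generate_longitudinal <- function(config, seed = config$rng_seed) {
  stopifnot(inherits(config, "cohort_config"))
  n_exp <- config$n_exposed
  n_unx <- config$n_unexposed
  assessed_n <- c(n_exp[1], n_exp)  # clinical times 0..3
  dcount <- config$diagnosis_counts

  exp_ids <- sprintf("exp_%03d", seq_len(n_exp[1]))
  unx_ids <- sprintf("unx_%03d", seq_len(n_unx[1]))

  # covariates fixed per subject; age advances by the inter-wave gaps
  covs <- with_seed(derive_seed(seed, "covariates"), {
    list(
      exposed = data.frame(
        age = rnorm_trunc(n_exp[1], config$age_mean, config$age_sd,
                          config$age_range[1], config$age_range[2]),
        sex = stats::rbinom(n_exp[1], 1, config$sex_p_male),
        icv = stats::rnorm(n_exp[1], config$icv_mean, config$icv_sd),
        row.names = exp_ids),
      unexposed = data.frame(
        age = rnorm_trunc(n_unx[1], config$age_mean, config$age_sd,
                          config$age_range[1], config$age_range[2]),
        sex = stats::rbinom(n_unx[1], 1, config$sex_p_male),
        icv = stats::rnorm(n_unx[1], config$icv_mean, config$icv_sd),
        row.names = unx_ids)
    )
  })
  age_offset <- c(0, 1.25, 2.48)  # years after wave 1, per wave

  # clinical course: rosters, diagnosis labels, CAPS
  clinical <- NULL
  rosters <- vector("list", 4)
  current_dx <- stats::setNames(rep(FALSE, n_exp[1]), exp_ids)
  caps_prev <- stats::setNames(rep(NA_real_, n_exp[1]), exp_ids)
  with_seed(derive_seed(seed, "clinical"), {
    for (t in 0:3) {
      n_t <- assessed_n[t + 1]
      if (t == 0) {
        roster <- exp_ids
      } else {
        prev <- rosters[[t]]
        if (n_t > length(prev)) stop_domain("attrition is not nested")
        w <- if (config$dropout == "caps" && !anyNA(caps_prev[prev])) {
          exp(0.03 * caps_prev[prev])
        } else rep(1, length(prev))
        roster <- if (n_t == 0) character(0) else
          sort(sample(prev, n_t, prob = w))
      }
      rosters[[t + 1]] <- roster
      if (n_t == 0) next
      d_t <- dcount[t + 1]
      if (t == 0) {
        dx_set <- if (d_t == 0) character(0) else sample(roster, d_t)
        current_dx[dx_set] <- TRUE
      } else {
        pool <- roster[current_dx[roster]]
        if (length(pool) < d_t) {
          stop_domain("cannot realize diagnosis counts: only ", length(pool),
                      " still-diagnosed subjects assessed at time ", t,
                      " but ", d_t, " required")
        }
        keep <- if (d_t == 0) character(0) else sample(pool, d_t)
        current_dx[setdiff(pool, keep)] <- FALSE  # recovery is permanent
      }
      dx <- current_dx[roster]
      pi_t <- d_t / n_t
      gap <- config$caps_gap
      mu_t <- config$caps_mean[t + 1]
      sd_t <- config$caps_sd[t + 1]
      sd_w <- sqrt(max(sd_t^2 - gap^2 * pi_t * (1 - pi_t), (0.4 * sd_t)^2))
      mu_i <- ifelse(dx, mu_t + gap * (1 - pi_t), mu_t - gap * pi_t)
      caps <- rnorm_trunc(n_t, mu_i, sd_w, 0, CAPS_MAX)
      caps_prev[roster] <- caps
      clinical <- rbind(clinical, data.frame(
        subject_id = roster, timepoint = t, caps = caps,
        diagnosed = unname(dx), row.names = NULL))
    }
  })

  # control attrition (random; controls carry no CAPS)
  unx_rosters <- with_seed(derive_seed(seed, "attrition_unx"), {
    r <- list(unx_ids)
    for (t in 2:3) r[[t]] <- sort(sample(r[[t - 1]], n_unx[t]))
    r
  })

  calib <- NULL
  records <- list()
  for (t in 1:3) {
    eff <- config$effects[[paste0("t", t)]]
    pert <- NULL
    if (length(eff)) {
      if (is.null(calib)) calib <- calibrate_generator(config)
      pert <- plan_perturbation(config, t, calib)
    }
    e_ids <- rosters[[t + 1]]
    u_ids <- unx_rosters[[t]]
    e_cov <- covs$exposed[e_ids, , drop = FALSE]
    u_cov <- covs$unexposed[u_ids, , drop = FALSE]
    e_cov$age <- e_cov$age + age_offset[t]
    u_cov$age <- u_cov$age + age_offset[t]
    records[[paste0("t", t)]] <- with_seed(derive_seed(seed, paste0("records_t", t)), {
      c(simulate_records(length(e_ids), 1, config, pert, ids = e_ids,
                         covariates = e_cov),
        simulate_records(length(u_ids), 0, config, NULL, ids = u_ids,
                         covariates = u_cov))
    })
  }

  structure(list(records = records, clinical = clinical,
                 config = config, seed = seed),
            class = "longitudinal_cohort")
}

#' @export
print.longitudinal_cohort <- function(x, ...) {
  cat("Synthetic longitudinal cohort\n")
  for (t in 1:3) {
    recs <- x$records[[paste0("t", t)]]
    g <- vapply(recs, `[[`, numeric(1), "group")
    cat(sprintf("  wave %d: %d exposed + %d unexposed\n", t, sum(g == 1), sum(g == 0)))
  }
  if (!is.null(x$clinical)) {
    agg <- stats::aggregate(diagnosed ~ timepoint, x$clinical, function(d) sum(d))
    n <- stats::aggregate(diagnosed ~ timepoint, x$clinical, length)
    cat("  PTSD diagnoses: ",
        paste(sprintf("%d/%d", agg$diagnosed, n$diagnosed), collapse = ", "),
        " (clinical times 0-3)\n", sep = "")
  }
  invisible(x)
}

#' Recovery rates among initially diagnosed subjects
#'
#' For each follow-up timepoint, the fraction of subjects who were
#' diagnosed with PTSD at time 0 and assessed at that timepoint who no
#' longer meet diagnostic criteria.
#'
#' @param x A `longitudinal_cohort`, or a data frame with columns
#'   `timepoint`, `n_assessed`, `n_diagnosed` (counts among
#'   initially-diagnosed subjects).
#' @param ... Unused.
#' @return Data frame with `timepoint`, `n_assessed`, `n_diagnosed`,
#'   `n_recovered`, `rate` (fraction) and `percent`.
#' @export
recovery_rates <- function(x, ...) UseMethod("recovery_rates")

#' @rdname recovery_rates
#' @export
recovery_rates.longitudinal_cohort <- function(x, ...) {
  cl <- x$clinical
  base_dx <- cl$subject_id[cl$timepoint == 0 & cl$diagnosed]
  if (length(base_dx) == 0) stop_domain("no subject diagnosed at time 0")
  counts <- do.call(rbind, lapply(1:3, function(t) {
    at_t <- cl[cl$timepoint == t & cl$subject_id %in% base_dx, , drop = FALSE]
    data.frame(timepoint = t, n_assessed = nrow(at_t),
               n_diagnosed = sum(at_t$diagnosed))
  }))
  recovery_rates.data.frame(counts)
}

#' @rdname recovery_rates
#' @export
recovery_rates.data.frame <- function(x, ...) {
  need <- c("timepoint", "n_assessed", "n_diagnosed")
  if (!all(need %in% names(x))) {
    stop_domain("counts data frame needs columns ", paste(need, collapse = ", "))
  }
  if (any(x$n_assessed == 0)) {
    stop_domain("recovery rate undefined: no subjects assessed at timepoint ",
                paste(x$timepoint[x$n_assessed == 0], collapse = ", "))
  }
  out <- data.frame(
    timepoint = x$timepoint,
    n_assessed = x$n_assessed,
    n_diagnosed = x$n_diagnosed,
    n_recovered = x$n_assessed - x$n_diagnosed
  )
  out$rate <- out$n_recovered / out$n_assessed
  out$percent = 100 * out$rate
  out
}
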