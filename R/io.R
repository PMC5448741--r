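# Plain-CSV interchange (UTF-8, header row, "." decimal).
#
# A cohort is exchanged as four tables: subjects (one row per
# subject-timepoint with covariates, group, CAPS, diagnosis), volumes /
# grey-matter densities (long, per hemisphere and ROI), connectivity
# (long, per hemisphere and ROI pair) and seed classification (long, per
# hemisphere, voxel and target).

#' Write a cohort to four CSV tables
#'
#' @param cohort A `longitudinal_cohort`, or a plain list of
#'   `subject_record`s for a single timepoint.
#' @param dir Output directory (created if needed).
#' @param timepoint Timepoint label used when `cohort` is a plain record
#'   list.
#' @return Invisibly, the four file paths.
#' @export
write_cohort <- function(cohort, dir, timepoint = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(cohort, "longitudinal_cohort")) {
    waves <- lapply(1:3, function(t) cohort$records[[paste0("t", t)]])
    names(waves) <- 1:3
    clinical <- cohort$clinical
  } else {
    waves <- stats::setNames(list(cohort), timepoint)
    clinical <- NULL
  }
  subj <- NULL; vols <- NULL; conn <- NULL; seedcls <- NULL
  for (tn in names(waves)) {
    t <- as.integer(tn)
    for (rec in waves[[tn]]) {
      subj <- rbind(subj, data.frame(
        subject_id = rec$subject_id, timepoint = t, group = rec$group,
        age = rec$age, sex = rec$sex, icv = rec$icv))
      for (h in c("left", "right")) {
        vols <- rbind(vols, data.frame(
          subject_id = rec$subject_id, timepoint = t, hemisphere = h,
          roi = roi_names(),
          volume_cm3 = rec$roi_volume[h, roi_names()],
          gm_density = c(NA, rec$gm_density[h, amygdala_targets()])[
            match(roi_names(), c("amygdala", amygdala_targets()))]))
        pr <- roi_pair_names()
        ends <- vapply(pr, pair_endpoints, character(2))
        conn <- rbind(conn, data.frame(
          subject_id = rec$subject_id, timepoint = t, hemisphere = h,
          roi_a = ends[1, ], roi_b = ends[2, ],
          count = rec$streamline_count[h, pr],
          mean_length_mm = rec$streamline_mean_length[h, pr]))
        st <- rec$seed_table[[h]]
        nv <- nrow(st)
        seedcls <- rbind(seedcls, data.frame(
          subject_id = rec$subject_id, timepoint = t, hemisphere = h,
          voxel_id = rep(seq_len(nv), times = 4),
          target = rep(amygdala_targets(), each = nv),
          exclusive_hits = as.vector(st[, amygdala_targets()]),
          any_hits = rep(st[, "any_hits"], times = 4)))
      }
    }
  }
  if (!is.null(clinical)) {
    cl <- clinical
    names(cl)[names(cl) == "caps"] <- "caps"
    subj <- merge(subj, cl, by = c("subject_id", "timepoint"), all = TRUE)
  } else {
    subj$caps <- NA_real_
    subj$diagnosed <- NA
  }
  subj <- subj[order(subj$timepoint, subj$subject_id), , drop = FALSE]
  paths <- c(
    subjects = file.path(dir, "subjects.csv"),
    volumes = file.path(dir, "volumes.csv"),
    connectivity = file.path(dir, "connectivity.csv"),
    seed_classification = file.path(dir, "seed_classification.csv")
  )
  utils::write.csv(subj, paths["subjects"], row.names = FALSE, quote = FALSE)
  utils::write.csv(vols, paths["volumes"], row.names = FALSE, quote = FALSE)
  utils::write.csv(conn, paths["connectivity"], row.names = FALSE, quote = FALSE)
  utils::write.csv(seedcls, paths["seed_classification"], row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}

#' Read a cohort back from the four CSV tables
#'
#' Inverse of [write_cohort()]. Clinical rows (CAPS/diagnosis) without an
#' imaging record — e.g. clinical time 0 — are kept in the `clinical`
#' element only.
#'
#' @param dir Directory containing `subjects.csv`, `volumes.csv`,
#'   `connectivity.csv`, `seed_classification.csv`.
#' @return A `longitudinal_cohort` (with `config = NULL`); timepoints
#'   absent from the tables are empty lists.
#' @export
read_cohort <- function(dir) {
  subj <- utils::read.csv(file.path(dir, "subjects.csv"))
  vols <- utils::read.csv(file.path(dir, "volumes.csv"))
  conn <- utils::read.csv(file.path(dir, "connectivity.csv"))
  seedcls <- utils::read.csv(file.path(dir, "seed_classification.csv"))
  pairs <- roi_pair_names()
  records <- list(t1 = list(), t2 = list(), t3 = list())
  img <- unique(vols[, c("subject_id", "timepoint")])
  for (i in seq_len(nrow(img))) {
    sid <- img$subject_id[i]; t <- img$timepoint[i]
    srow <- subj[subj$subject_id == sid & subj$timepoint == t, ][1, ]
    v <- vols[vols$subject_id == sid & vols$timepoint == t, ]
    cn <- conn[conn$subject_id == sid & conn$timepoint == t, ]
    sc <- seedcls[seedcls$subject_id == sid & seedcls$timepoint == t, ]
    mk <- function(df, col, keys, keynames) {
      m <- matrix(NA_real_, 2, length(keynames),
                  dimnames = list(c("left", "right"), keynames))
      for (h in c("left", "right")) {
        d <- df[df$hemisphere == h, ]
        m[h, d[[keys]]] <- d[[col]]
      }
      m
    }
    roi_volume <- mk(v, "volume_cm3", "roi", roi_names())
    gm <- mk(v[v$roi != "amygdala", ], "gm_density", "roi", amygdala_targets())
    cn$pair <- paste(cn$roi_a, cn$roi_b, sep = "|")
    cntm <- mk(cn, "count", "pair", pairs)
    lenm <- mk(cn, "mean_length_mm", "pair", pairs)
    seed_table <- lapply(stats::setNames(c("left", "right"), c("left", "right")),
                         function(h) {
      d <- sc[sc$hemisphere == h, ]
      nv <- max(d$voxel_id)
      m <- matrix(0, nv, 5, dimnames = list(NULL, c(amygdala_targets(), "any_hits")))
      for (tg in amygdala_targets()) {
        dd <- d[d$target == tg, ]
        m[dd$voxel_id, tg] <- dd$exclusive_hits
        m[dd$voxel_id, "any_hits"] <- dd$any_hits
      }
      m
    })
    rec <- structure(list(
      subject_id = as.character(sid), group = srow$group,
      age = srow$age, sex = srow$sex, icv = srow$icv,
      roi_volume = roi_volume, gm_density = gm,
      streamline_count = cntm, streamline_mean_length = lenm,
      seed_table = seed_table), class = "subject_record")
    tn <- paste0("t", t)
    records[[tn]] <- c(records[[tn]], list(rec))
  }
  clinical <- subj[!is.na(subj$caps) | !is.na(subj$diagnosed),
                   c("subject_id", "timepoint", "caps", "diagnosed")]
  if (nrow(clinical) == 0) clinical <- NULL else rownames(clinical) <- NULL
  structure(list(records = records, clinical = clinical,
                 config = NULL, seed = NA_integer_),
            class = "longitudinal_cohort")
}

#' Write / read a feature table CSV
#'
#' One row per subject: `subject_id`, `group`, covariates and the 23
#' canonical feature columns.
#'
#' @param table Feature table from [extract_feature_table()] (raw or
#'   Z-scored).
#' @param path CSV file path.
#' @return `path` (write) or the table (read).
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
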