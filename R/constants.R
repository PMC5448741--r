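#' Fear-circuit regions of interest
#'
#' The five bilateral regions of the amygdala-centred fear circuit used
#' throughout the package: amygdala, orbitofrontal and ventromedial
#' prefrontal cortex (OMPFC), hippocampus, insula and thalamus.
#'
#' @return Character vector of the five ROI names, in canonical order.
#' @export
roi_names <- function() {
  c("amygdala", "OMPFC", "hippocampus", "insula", "thalamus")
}

#' Amygdala tractography targets
#'
#' The four ROIs that serve as targets for amygdala seed-based
#' classification (all ROIs except the amygdala itself).
#'
#' @return Character vector of four ROI names.
#' @export
amygdala_targets <- function() {
  c("OMPFC", "hippocampus", "insula", "thalamus")
}

#' Canonical ROI pair labels
#'
#' The ten unordered ROI pairs, labelled `"a|b"` with `a` before `b` in
#' canonical ROI order.
#'
#' @return Character vector of length 10.
#' @export
roi_pair_names <- function() {
  m <- utils::combn(roi_names(), 2)
  paste(m[1, ], m[2, ], sep = "|")
}

# endpoints of pair label "a|b" as a character(2)
pair_endpoints <- function(pair) {
  strsplit(pair, "|", fixed = TRUE)[[1]]
}

# the 4 pair labels incident to an ROI
pairs_incident <- function(roi) {
  pn <- roi_pair_names()
  pn[vapply(pn, function(p) roi %in% pair_endpoints(p), logical(1))]
}

#' Node sets of the efficiency networks
#'
#' The full five-node fear-circuit network and the three three-node
#' subnetworks (OMPFC-amygdala-hippocampus, OMPFC-amygdala-insula,
#' OMPFC-amygdala-thalamus) on which global efficiency is computed.
#'
#' @return Named list of character vectors of ROI names.
#' @export
network_node_sets <- function() {
  list(
    full5            = roi_names(),
    OMPFC_amy_hippo  = c("OMPFC", "amygdala", "hippocampus"),
    OMPFC_amy_insula = c("OMPFC", "amygdala", "insula"),
    OMPFC_amy_thal   = c("OMPFC", "amygdala", "thalamus")
  )
}

#' Canonical names of the 23 structural features
#'
#' The feature set spans four categories: local (amygdala volume, grey-matter
#' densities of the other four ROIs), region-wise connectivity (connection
#' density and connection cost per ROI), pair-wise connectivity (amygdala
#' tract strength to each target) and network (global efficiency of the
#' five-ROI network and of three subnetworks).
#'
#' @return Character vector of length 23, in canonical order.
#' @export
feature_names <- function() {
  c(
    "amygdala_volume",
    paste0("gm_density_", amygdala_targets()),
    paste0("conn_density_", roi_names()),
    paste0("conn_cost_", roi_names()),
    paste0("tract_strength_amy_", amygdala_targets()),
    paste0("net_efficiency_", names(network_node_sets()))
  )
}
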