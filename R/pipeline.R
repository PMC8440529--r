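# ---- End-to-end per-patient analysis ---------------------------------------

#' Analyze one patient end to end
#'
#' Applies the somatic filters and cross-region rescue, estimates CCFs,
#' clusters mutations and derives SNV ITH / TMB / TMB-per-cluster, bins
#' copy number for CNV clonality and Jaccard ITH, computes GII and WGD
#' status (a patient is called WGD when at least half of its regions
#' are), and builds the parsimony tree.
#'
#' @param calls raw [mutation_calls()] for one patient.
#' @param pileups raw per-region read counts at candidate loci (for
#'   rescue); NULL disables rescue.
#' @param segs [segments_cn()] for the patient.
#' @param profiles [region_profiles()] for the patient.
#' @param params [filter_params()].
#' @param coding_mb TMB denominator (default 38).
#' @param k_max,seed clustering controls.
#' @param bin_size CNV binning (default 10 Mb).
#' @param n_sim_wgd permutations for WGD detection (default 1000).
#' @return list: report (one-row data.frame in [write_patient_report()]
#'   order), ccf (table), solution, clonal, tree, wgd (per region),
#'   cnv_events, cnv_clonality, filtered calls.
#' @export
analyze_patient <- function(calls, pileups = NULL, segs, profiles,
                            params = filter_params(), coding_mb = 38,
                            k_max = 6, seed = 1, bin_size = 1e7,
                            n_sim_wgd = 1000) {
  pid <- unique(as.data.frame(calls)$patient_id)
  if (length(pid) != 1) stop("analyze_patient expects a single patient")
  filtered <- apply_somatic_filters(calls, params)
  if (!is.null(pileups) && nrow(filtered)) {
    filtered <- rescue_cross_region(filtered, pileups, params,
                                    regions = profiles$region_id)
  }
  n_regions <- length(profiles$region_id)

  tab <- ccf_table(filtered, segs, profiles)
  cm <- ccf_matrix(tab)
  sol <- cluster_ccf(cm$ccf, depth = cm$depth, k_max = k_max, seed = seed)
  clonal <- assign_clonality(sol)
  ith <- snv_ith(clonal)
  tb <- tmb(filtered, coding_mb = coding_mb)
  tpc <- tmb_per_cluster(tb$tmb, sol$n_clusters)

  events <- lapply(profiles$region_id, function(r) {
    bin_cnv_events(segs[segs$region_id == r, , drop = FALSE],
                   profiles$ploidy[profiles$region_id == r],
                   bin_size = bin_size)
  })
  names(events) <- profiles$region_id
  cnv_clon <- if (n_regions >= 2) classify_cnv_clonality(events) else NULL
  cith <- if (n_regions >= 2) cnv_ith(lapply(events, cnv_event_keys)) else NA
  gii <- gii_patient(segs, profiles)
  wgd <- lapply(profiles$region_id, function(r) {
    detect_wgd(segs[segs$region_id == r, , drop = FALSE],
               n_sim = n_sim_wgd, seed = seed)
  })
  names(wgd) <- profiles$region_id
  wgd_patient <- mean(vapply(wgd, `[[`, logical(1), "is_wgd")) >= 0.5

  pm <- presence_matrix(filtered, segs, regions = profiles$region_id)
  tree <- if (nrow(pm)) build_tree(pm) else NULL

  report <- data.frame(
    patient_id = pid, n_regions = n_regions,
    n_mutations = length(unique(tab$mutation_key)),
    n_nonsilent = tb$n_union, snv_ith = ith, cnv_ith = cith,
    tmb = tb$tmb, tmb_per_cluster = tpc, n_clusters = sol$n_clusters,
    wgd = wgd_patient, gii = gii, stringsAsFactors = FALSE)
  list(report = report, ccf = tab, solution = sol, clonal = clonal,
       tree = tree, wgd = wgd, cnv_events = events,
       cnv_clonality = cnv_clon, filtered = filtered)
}

#' Analyze a whole cohort
#'
#' Runs [analyze_patient()] for every patient and binds the per-patient
#' reports.
#'
#' @param cohort a `sim_cohort` (or a list with calls, pileups, segments,
#'   profiles data.frames covering several patients).
#' @param ... passed to [analyze_patient()].
#' @return list: report (data.frame, one row per patient), details
#'   (per-patient analysis lists).
#' @export
analyze_cohort <- function(cohort, ...) {
  ids <- unique(cohort$profiles$patient_id)
  details <- lapply(ids, function(pid) {
    analyze_patient(
      calls = cohort$calls[cohort$calls$patient_id == pid, , drop = FALSE],
      pileups = if (!is.null(cohort$pileups)) {
        cohort$pileups[cohort$pileups$patient_id == pid, , drop = FALSE]
      },
      segs = cohort$segments[cohort$segments$patient_id == pid, , drop = FALSE],
      profiles = cohort$profiles[cohort$profiles$patient_id == pid, ,
                                 drop = FALSE],
      ...)
  })
  names(details) <- ids
  list(report = do.call(rbind, lapply(details, `[[`, "report")),
       details = details)
}
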