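# ---- Synthetic multi-region cohort generator --------------------------------
# Emulates an FFPE multi-region exome cohort: 40 patients x 3 regions,
# ~252x depth, clonal/subclonal architecture with known clone trees,
# chromosome-scale copy number with optional genome doubling, signature-
# driven trinucleotide contexts, and exponential proportional-hazards
# survival tied to the true heterogeneity metrics.

#' Simulation configuration
#'
#' Defaults reproduce the structure of a surgically resected SCLC
#' multi-region cohort: 40 patients, 3 regions each, mean sequencing depth
#' 252x, purity 0.3-0.9, 0-4 subclones per patient, genome doubling in a
#' substantial minority of patients, and survival hazards increasing with
#' SNV ITH (OS) and decreasing with TMB per cluster (DFS).
#'
#' @param n_patients cohort size (default 40).
#' @param regions_per_patient regions sampled per tumor (default 3).
#' @param mean_depth mean tumor sequencing depth (default 252).
#' @param purity_range tumor purity range (default 0.3-0.9).
#' @param n_clonal_range range of clonal (truncal) mutation counts.
#' @param n_subclone_range range of subclone counts (default 0-4).
#' @param n_submut_range mutations per subclone.
#' @param subclone_ccf_range target CCF range for a subclone in the
#'   regions where it is present (default 0.25-0.8).
#' @param wgd_probability probability of a whole-genome doubling
#'   (default 0.4, reflecting the high WGD prevalence of SCLC).
#' @param signature_mixture named weights over catalog columns.
#' @param coding_mb callable coding footprint (default 38).
#' @param hazard list of log-hazard coefficients: os_snv_ith (per unit
#'   ITH on OS) and dfs_tmb_per_cluster (per mut/Mb/cluster on DFS).
#' @param silent_fraction fraction of silent mutations (default 0.1).
#' @param ffpe_noise_rate expected count of artifactual private low-VAF
#'   C>T calls per region (default 0 = off).
#' @param seed master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 40, regions_per_patient = 3,
                       mean_depth = 252, purity_range = c(0.3, 0.9),
                       n_clonal_range = c(80, 500),
                       n_subclone_range = c(0, 4),
                       n_submut_range = c(15, 120),
                       subclone_ccf_range = c(0.25, 0.8),
                       wgd_probability = 0.4,
                       signature_mixture = c(Signature.1 = 0.4,
                                             Signature.4 = 0.3,
                                             Signature.3 = 0.2,
                                             Signature.24 = 0.1),
                       coding_mb = 38,
                       hazard = list(os_snv_ith = 2.0,
                                     dfs_tmb_per_cluster = -0.25),
                       silent_fraction = 0.1,
                       ffpe_noise_rate = 0,
                       seed = 1L) {
  stopifnot(n_patients >= 1, regions_per_patient >= 1, mean_depth > 0,
            diff(purity_range) >= 0, purity_range[1] > 0,
            purity_range[2] <= 1, diff(n_clonal_range) >= 0,
            diff(n_subclone_range) >= 0, diff(subclone_ccf_range) >= 0,
            wgd_probability >= 0, wgd_probability <= 1, coding_mb > 0,
            all(signature_mixture >= 0))
  signature_mixture <- signature_mixture / sum(signature_mixture)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

patient_seed <- function(master, index) {
  as.integer((as.double(master) %% 2147483647 * 48271 + index * 100003) %%
               2147483647)
}

runif_int <- function(rng) {
  if (rng[1] == rng[2]) return(as.integer(rng[1]))
  sample(seq(rng[1], rng[2]), 1)
}

# clone tree: parent map over clones 1..(1+n_sub) with clone 1 = root;
# linear or branching chosen uniformly
sample_clone_tree <- function(n_sub) {
  parent <- c(0L, rep(1L, n_sub))
  if (n_sub >= 2) {
    if (stats::runif(1) < 0.5) {
      parent[-1] <- c(1L, seq_len(n_sub - 1) + 1L)  # linear chain
    } else {
      for (j in seq(3L, n_sub + 1L)) {
        parent[j] <- sample(seq_len(j - 1L), 1)     # branch anywhere above
      }
    }
  }
  parent
}

# per-clone per-region CCF matrix obeying root=1 and sibling-sum <= parent.
# Subclone prevalence profiles are kept pairwise separated (L-infinity
# >= 0.15): two populations with near-identical prevalence in every region
# are indistinguishable in principle, so the generator does not create them
# and the true clone count stays identifiable.
sample_clone_ccf <- function(parent, n_regions, ccf_range, max_retry = 20,
                             min_sep = 0.15) {
  n_clones <- length(parent)
  draw_clone <- function(ccf, k) {
    par <- parent[k]
    eligible <- ccf[par, ] > 0.05
    present <- (stats::runif(n_regions) < 0.6) & eligible
    if (!any(present) && any(eligible)) {
      present[sample(which(eligible), 1)] <- TRUE
    }
    if (!any(present)) return(NULL)
    row <- rep(0, n_regions)
    for (r in which(present)) {
      sib <- which(parent == par)
      used <- if (length(sib)) sum(ccf[sib, r]) else 0
      avail <- ccf[par, r] - used
      if (avail <= 0.05) next
      target <- stats::runif(1, ccf_range[1], ccf_range[2])
      row[r] <- min(target, avail)
    }
    if (all(row == 0)) return(NULL)
    row
  }
  for (attempt in seq_len(max_retry)) {
    ccf <- matrix(0, n_clones, n_regions)
    ccf[1, ] <- 1
    truncate_at <- 0L
    for (k in seq_len(n_clones)[-1]) {
      placed <- FALSE
      for (inner in seq_len(10)) {
        row <- draw_clone(ccf, k)
        if (is.null(row)) next
        if (k > 2) {
          sep <- min(apply(abs(sweep(ccf[2:(k - 1), , drop = FALSE], 2,
                                     row)), 1, max))
          if (sep < min_sep) next
        }
        ccf[k, ] <- row
        placed <- TRUE
        break
      }
      if (!placed) { truncate_at <- k; break }
    }
    if (truncate_at == 0L) return(ccf)
    if (truncate_at > 2L) {
      # a deep lineage ran out of CCF budget: keep the feasible prefix
      # (parents always precede children, so a suffix cut is consistent)
      return(ccf[seq_len(truncate_at - 1L), , drop = FALSE])
    }
  }
  stop("infeasible CCF configuration after bounded retries")
}

# chromosome-scale allele-specific copy number for all regions of a patient
sample_copy_number <- function(patient_id, regions, wgd) {
  chroms <- names(hg19_contigs(include_sex = FALSE))
  lens <- hg19_contigs(include_sex = FALSE)
  base_major <- rep(1L, length(chroms)); base_minor <- rep(1L, length(chroms))
  gain <- stats::runif(length(chroms)) < 0.15
  loss <- !gain & stats::runif(length(chroms)) < 0.10
  base_major[gain] <- 2L
  base_minor[loss] <- 0L
  rows <- list()
  for (r in regions) {
    maj <- base_major; mnr <- base_minor
    priv <- stats::runif(length(chroms)) < 0.06
    pg <- priv & stats::runif(length(chroms)) < 0.5
    maj[pg] <- maj[pg] + 1L
    mnr[priv & !pg] <- pmax(mnr[priv & !pg] - 1L, 0L)
    if (wgd) {
      maj <- maj * 2L; mnr <- mnr * 2L
      post_loss <- stats::runif(length(chroms)) < 0.08
      mnr[post_loss] <- pmax(mnr[post_loss] - 1L, 0L)
    }
    rows[[r]] <- data.frame(
      patient_id = patient_id, region_id = r, chrom = chroms,
      start = 1L, end = as.integer(lens),
      total_cn = as.numeric(maj + mnr), major_cn = maj, minor_cn = mnr,
      stringsAsFactors = FALSE)
  }
  segments_cn(do.call(rbind, rows))
}

assign_genes <- function(n, clonal) {
  genes <- sprintf("G%04d", sample.int(5000, n, replace = TRUE))
  clonal_drivers <- c(TP53 = 0.88, RB1 = 0.72, CREBBP = 0.30, EGFR = 0.175)
  sub_drivers <- c(LRP1B = 0.22, PCLO = 0.15, KMT2D = 0.15, PTEN = 0.10)
  ci <- which(clonal); si <- which(!clonal)
  for (g in names(clonal_drivers)) {
    if (length(ci) && stats::runif(1) < clonal_drivers[[g]]) {
      i <- sample(ci, 1); genes[i] <- g; ci <- setdiff(ci, i)
    }
  }
  for (g in names(sub_drivers)) {
    if (length(si) && stats::runif(1) < sub_drivers[[g]]) {
      i <- sample(si, 1); genes[i] <- g; si <- setdiff(si, i)
    }
  }
  genes
}

#' Simulate one patient
#'
#' Samples a clone tree and per-clone per-region CCFs (root CCF 1
#' everywhere; sibling CCFs summing at most to their parent per region),
#' assigns mutations to clones with signature-driven contexts, draws read
#' counts as alt ~ Binomial(depth, expected VAF) with depth ~
#' Poisson(mean_depth) and expected VAF = purity * ccf * multiplicity /
#' (purity * total_cn + (1 - purity) * 2), builds chromosome-scale
#' allele-specific segments (doubled under WGD), and draws DFS/OS from an
#' exponential proportional-hazards model on the true metrics.
#'
#' Emitted "calls" mimic a caller's raw candidate list (records with >= 3
#' mutant reads in a region); "pileups" carry the read counts of every
#' simulated locus in every region for cross-region rescue.
#'
#' @param config a [sim_config()].
#' @param patient_index 1-based patient index (seeds are derived per
#'   patient from the master seed, so patients are independent and
#'   reproducible individually).
#' @param catalog signature catalog (default the packaged synthetic one).
#' @return list: calls, pileups, segments, profiles, clinical, truth.
#' @export
simulate_patient <- function(config, patient_index,
                             catalog = read_signature_catalog()) {
  pid <- sprintf("P%03d", patient_index)
  with_seed(patient_seed(config$seed, patient_index), function() {
    regions <- sprintf("R%d", seq_len(config$regions_per_patient))
    purity <- stats::runif(length(regions), config$purity_range[1],
                           config$purity_range[2])
    wgd <- stats::runif(1) < config$wgd_probability
    segs <- sample_copy_number(pid, regions, wgd)

    n_sub <- runif_int(config$n_subclone_range)
    parent <- sample_clone_tree(n_sub)
    clone_ccf <- sample_clone_ccf(parent, length(regions),
                                  config$subclone_ccf_range)
    n_clones <- nrow(clone_ccf)
    parent <- parent[seq_len(n_clones)]
    n_sub <- n_clones - 1L

    n_clonal <- runif_int(config$n_clonal_range)
    n_per_clone <- c(n_clonal,
                     if (n_sub) vapply(seq_len(n_sub), function(i)
                       runif_int(config$n_submut_range), integer(1)))
    clone_of <- rep(seq_len(n_clones), n_per_clone)
    n_mut <- length(clone_of)

    w <- config$signature_mixture[names(config$signature_mixture) %in%
                                    colnames(catalog)]
    ctx <- sample_contexts(n_mut, w / sum(w), catalog[, names(w)])
    # half the records on the purine strand, to exercise the convention
    flip <- stats::runif(n_mut) < 0.5
    ctx$ref[flip] <- chartr("ACGT", "TGCA", ctx$ref[flip])
    ctx$alt[flip] <- chartr("ACGT", "TGCA", ctx$alt[flip])
    ctx$context[flip] <- revcomp(ctx$context[flip])

    chroms <- names(hg19_contigs(include_sex = FALSE))
    lens <- hg19_contigs(include_sex = FALSE)
    chrom <- sample(chroms, n_mut, replace = TRUE,
                    prob = as.double(lens) / sum(as.double(lens)))
    pos <- vapply(chrom, function(ch) sample.int(lens[[ch]] - 2L, 1) + 1L,
                  integer(1))
    effect <- ifelse(stats::runif(n_mut) < config$silent_fraction,
                     "silent", "nonsilent")
    genes <- assign_genes(n_mut, clone_of == 1L)
    # pre-doubling clonal mutations are carried to multiplicity 2 by WGD
    mult <- rep(1L, n_mut)
    if (wgd) mult[clone_of == 1L & stats::runif(n_mut) < 0.8] <- 2L
    paf <- ifelse(stats::runif(n_mut) < 0.02,
                  stats::runif(n_mut, 0, 0.05), 0)

    seg_by_region <- split(seq_len(nrow(segs)), segs$region_id)
    pile <- list()
    for (ri in seq_along(regions)) {
      r <- regions[ri]
      srows <- seg_by_region[[r]]
      seg_idx <- srows[match(chrom, segs$chrom[srows])]
      total_cn <- segs$total_cn[seg_idx]
      major_cn <- segs$major_cn[seg_idx]
      m <- pmin(mult, pmax(major_cn, 1L))
      ccf <- clone_ccf[clone_of, ri]
      vaf_exp <- purity[ri] * ccf * m /
        (purity[ri] * total_cn + (1 - purity[ri]) * 2)
      vaf_exp <- pmin(pmax(vaf_exp, 0), 1)
      depth <- stats::rpois(n_mut, config$mean_depth)
      alt <- stats::rbinom(n_mut, depth, vaf_exp)
      ndepth <- stats::rpois(n_mut, config$mean_depth)
      nalt <- stats::rbinom(n_mut, ndepth, 5e-4)
      pile[[r]] <- data.frame(
        patient_id = pid, region_id = r, chrom = chrom, pos = pos,
        ref = ctx$ref, alt = ctx$alt, gene = genes, effect = effect,
        alt_reads = alt, ref_reads = pmax(depth - alt, 0L),
        normal_alt_reads = nalt, normal_depth = ndepth,
        population_af = paf, context = ctx$context, rescued = FALSE,
        mutation_index = seq_len(n_mut), stringsAsFactors = FALSE)
    }
    pileups <- do.call(rbind, pile)
    if (config$ffpe_noise_rate > 0) {
      pileups <- rbind(pileups, ffpe_noise(pid, regions, config))
    }
    calls <- mutation_calls(
      pileups[pileups$alt_reads >= 3,
              setdiff(names(pileups), "mutation_index"), drop = FALSE])
    profiles <- region_profiles(data.frame(
      patient_id = pid, region_id = regions, purity = purity,
      ploidy = vapply(regions, function(r) {
        s <- segs[segs$region_id == r, ]
        sum(seg_lengths(s) * s$total_cn) / sum(seg_lengths(s))
      }, numeric(1)), stringsAsFactors = FALSE))

    ns <- effect == "nonsilent"
    true_ith <- if (any(ns)) sum(clone_of[ns] != 1L) / sum(ns) else NA_real_
    true_tmb <- sum(ns) / config$coding_mb
    true_tmb_pc <- true_tmb / n_clones
    h_os <- log(2) / 40 * exp(config$hazard$os_snv_ith * true_ith)
    h_dfs <- log(2) / 25 * exp(config$hazard$dfs_tmb_per_cluster * true_tmb_pc)
    t_os <- stats::rexp(1, h_os); c_os <- stats::runif(1, 6, 72)
    t_dfs <- stats::rexp(1, h_dfs); c_dfs <- stats::runif(1, 6, 60)
    clinical <- clinical_records(data.frame(
      patient_id = pid,
      age = round(min(max(stats::rnorm(1, 62, 9), 23), 80)),
      sex = sample(c("Male", "Female"), 1, prob = c(0.875, 0.125)),
      smoking = sample(c("smoker", "non-smoker"), 1, prob = c(0.775, 0.225)),
      stage = sample(c("I", "II", "III"), 1, prob = c(0.375, 0.175, 0.45)),
      tumor_size = round(exp(stats::rnorm(1, log(22.5), 0.6)), 1),
      histology = sample(c("P-SCLC", "C-SCLC"), 1, prob = c(0.85, 0.15)),
      treatment_after_surgery = stats::runif(1) < 0.65,
      dfs_time = round(min(t_dfs, c_dfs), 2), dfs_event = t_dfs <= c_dfs,
      os_time = round(min(t_os, c_os), 2), os_event = t_os <= c_os,
      stringsAsFactors = FALSE))
    clinical$tnb <- stats::rpois(1, 0.05 * sum(ns) *
                                   exp(stats::rnorm(1, 0, 0.4)))
    truth <- list(
      patient_id = pid, parent = parent, clone_ccf = clone_ccf,
      clone_of = clone_of, n_clones = n_clones,
      true_snv_ith = true_ith, true_tmb = true_tmb,
      true_tmb_per_cluster = true_tmb_pc, wgd = wgd,
      signature_weights = w / sum(w),
      cnv_truth = lapply(split(segs, segs$region_id), function(s) {
        p <- sum(seg_lengths(s) * s$total_cn) / sum(seg_lengths(s))
        paste(s$chrom, call_gain_loss(s$total_cn, p), sep = ":")
      }))
    list(calls = calls, pileups = pileups, segments = segs,
         profiles = profiles, clinical = clinical, truth = truth)
  })
}

ffpe_noise <- function(pid, regions, config) {
  rows <- list()
  chroms <- names(hg19_contigs(include_sex = FALSE))
  lens <- hg19_contigs(include_sex = FALSE)
  for (r in regions) {
    k <- stats::rpois(1, config$ffpe_noise_rate)
    if (!k) next
    ch <- sample(chroms, k, replace = TRUE)
    depth <- stats::rpois(k, config$mean_depth)
    alt <- stats::rbinom(k, depth, stats::runif(k, 0.01, 0.025))
    rows[[r]] <- data.frame(
      patient_id = pid, region_id = r, chrom = ch,
      pos = vapply(ch, function(c) sample.int(lens[[c]] - 2L, 1) + 1L,
                   integer(1)),
      ref = "C", alt = "T", gene = "ARTIFACT", effect = "nonsilent",
      alt_reads = alt, ref_reads = pmax(depth - alt, 0L),
      normal_alt_reads = 0L, normal_depth = stats::rpois(k, config$mean_depth),
      population_af = 0, context = "ACA", rescued = FALSE,
      mutation_index = NA_integer_, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Simulate a cohort
#'
#' Per-patient seeds are derived from the master seed, so any patient can
#' be regenerated independently and the cohort is byte-identical for a
#' fixed seed.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; when given, writes
#'   mutations.tsv, pileups.tsv, segments.tsv, profiles.tsv,
#'   clinical.tsv and truth.tsv there via the package writers.
#' @param catalog signature catalog.
#' @return list of class `sim_cohort`: calls, pileups, segments,
#'   profiles, clinical (one data.frame each, all patients), truth
#'   (per-patient list), config.
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL,
                            catalog = read_signature_catalog()) {
  patients <- lapply(seq_len(config$n_patients), function(i) {
    simulate_patient(config, i, catalog = catalog)
  })
  bind <- function(field) do.call(rbind, lapply(patients, `[[`, field))
  cohort <- list(
    calls = mutation_calls(bind("calls")),
    pileups = bind("pileups"),
    segments = segments_cn(bind("segments")),
    profiles = region_profiles(bind("profiles")),
    clinical = clinical_records(bind("clinical")),
    truth = lapply(patients, `[[`, "truth"),
    config = config
  )
  class(cohort) <- "sim_cohort"
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_mutation_table(cohort$calls, file.path(dir, "mutations.tsv"))
    utils::write.table(cohort$pileups, file.path(dir, "pileups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_segments(cohort$segments, file.path(dir, "segments.tsv"))
    utils::write.table(cohort$profiles, file.path(dir, "profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tt <- do.call(rbind, lapply(cohort$truth, function(tr) data.frame(
      patient_id = tr$patient_id, n_clones = tr$n_clones,
      true_snv_ith = tr$true_snv_ith, true_tmb = tr$true_tmb,
      true_tmb_per_cluster = tr$true_tmb_per_cluster, wgd = tr$wgd,
      stringsAsFactors = FALSE)))
    utils::write.table(tt, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cohort
}
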