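test_that("a subclone-free configuration is fully clonal and ubiquitous", {
  cfg <- sim_config(n_subclone_range = c(0, 0), n_clonal_range = c(60, 60),
                    purity_range = c(0.6, 0.9), seed = 101)
  p <- simulate_patient(cfg, 1)
  expect_equal(p$truth$true_snv_ith, 0)
  expect_equal(p$truth$n_clones, 1)
  # every simulated locus has expected VAF > 0 in every region
  by_region <- split(p$pileups, p$pileups$region_id)
  for (d in by_region) expect_equal(nrow(d), 60)
})

test_that("the generator is deterministic for a fixed seed", {
  cfg <- sim_config(n_patients = 2, seed = 202)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$calls, b$calls)
  expect_identical(a$segments, b$segments)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  # and patients are independently reproducible
  p2 <- simulate_patient(cfg, 2)
  expect_identical(p2$truth, a$truth[[2]])
})

test_that("observed VAF matches the binomial expectation at high depth", {
  cfg <- sim_config(mean_depth = 10000, purity_range = c(1, 1),
                    n_subclone_range = c(0, 0),
                    n_clonal_range = c(400, 400),
                    wgd_probability = 0, seed = 303)
  p <- simulate_patient(cfg, 1)
  pil <- p$pileups[p$pileups$region_id == "R1", ]
  seg <- p$segments[p$segments$region_id == "R1", ]
  cn <- seg$total_cn[match(pil$chrom, seg$chrom)]
  # clonal het mutations on diploid chromosomes: expected VAF 1/2
  dip <- cn == 2
  vaf <- pil$alt_reads[dip] / (pil$alt_reads[dip] + pil$ref_reads[dip])
  mc_se <- sd(vaf) / sqrt(sum(dip))
  expect_lt(abs(mean(vaf) - 0.5), 3 * mc_se + 1e-4)
})

test_that("cohorts have the configured shape and truths stay in range", {
  cfg <- sim_config(n_patients = 5, n_clonal_range = c(40, 80),
                    n_submut_range = c(10, 30), seed = 404)
  co <- simulate_cohort(cfg)
  expect_equal(length(unique(co$profiles$patient_id)), 5)
  expect_equal(nrow(co$profiles), 15)  # 3 regions per patient
  ith <- vapply(co$truth, `[[`, numeric(1), "true_snv_ith")
  expect_true(all(ith >= 0 & ith <= 1))
  for (tr in co$truth) {
    expect_equal(tr$clone_ccf[1, ], rep(1, 3))       # root everywhere
    for (k in seq_len(tr$n_clones)[-1]) {            # pigeonhole per region
      kids <- which(tr$parent == k)
      if (length(kids)) {
        expect_true(all(colSums(tr$clone_ccf[kids, , drop = FALSE]) <=
                          tr$clone_ccf[k, ] + 1e-9))
      }
    }
  }
})

test_that("files written by simulate_cohort round-trip through the readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_patients = 2, n_clonal_range = c(30, 50),
                    n_submut_range = c(5, 15), seed = 505)
  co <- simulate_cohort(cfg, dir = dir)
  calls <- read_mutation_table(file.path(dir, "mutations.tsv"), "maf_tsv")
  expect_equal(nrow(calls), nrow(co$calls))
  segs <- read_segments(file.path(dir, "segments.tsv"))
  expect_equal(nrow(segs), nrow(co$segments))
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(truth$patient_id, c("P001", "P002"))
})

test_that("a positive ITH hazard shortens overall survival", {
  cfg <- sim_config(n_patients = 150, n_clonal_range = c(30, 60),
                    n_submut_range = c(10, 30),
                    hazard = list(os_snv_ith = 2.5,
                                  dfs_tmb_per_cluster = 0),
                    seed = 606)
  co <- simulate_cohort(cfg)
  ith <- vapply(co$truth, `[[`, numeric(1), "true_snv_ith")
  rho <- suppressWarnings(
    cor(ith, co$clinical$os_time, method = "spearman"))
  expect_lt(rho, 0)
})

test_that("the simulated spectrum recovers the configured signature mixture", {
  catalog <- read_signature_catalog()
  mix <- c(Signature.1 = 0.4, Signature.4 = 0.3, Signature.3 = 0.2,
           Signature.24 = 0.1)
  cfg <- sim_config(n_clonal_range = c(4000, 4000),
                    n_subclone_range = c(0, 0), signature_mixture = mix,
                    seed = 707)
  p <- simulate_patient(cfg, 1)
  one_region <- p$pileups[p$pileups$region_id == "R1", ]
  spec <- trinucleotide_spectrum(one_region)
  fit <- fit_signatures(spec, catalog)
  l1 <- sum(abs(fit$weights[names(mix)] - mix)) +
    sum(fit$weights[setdiff(names(fit$weights), names(mix))])
  expect_lt(l1, 0.1)
})

test_that("the FFPE artifact knob adds private low-VAF noise when enabled", {
  cfg_off <- sim_config(n_clonal_range = c(50, 50),
                        n_subclone_range = c(0, 0), seed = 808)
  cfg_on <- sim_config(n_clonal_range = c(50, 50),
                       n_subclone_range = c(0, 0), ffpe_noise_rate = 20,
                       seed = 808)
  off <- simulate_patient(cfg_off, 1)
  on <- simulate_patient(cfg_on, 1)
  expect_gt(nrow(on$pileups), nrow(off$pileups))
  noise <- on$pileups[on$pileups$gene == "ARTIFACT", ]
  vaf <- noise$alt_reads / (noise$alt_reads + noise$ref_reads)
  expect_true(all(vaf < 0.1))
})
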