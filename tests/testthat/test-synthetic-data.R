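test_that("generator configuration is validated", {
  expect_error(generator_config(), "seed is mandatory")
  expect_error(generator_config(seed = 1, site_prob = c(promoter = 2, utr5 = 0,
                                                        orf = 0, utr3 = 0)))
  expect_error(generator_config(seed = 1, noise_sd = 0))
  expect_error(generate_survival_cohort(generator_config(seed = 1)), "beta")
  expect_error(generate_expression_response(
    generate_site_truth(generator_config(seed = 1, n_genes = 10)),
    generator_config(seed = 1, n_genes = 10, n_replicates = 1)),
    "2 replicates")
  # a region too short for the requested number of sites
  cfg <- generator_config(seed = 1, n_genes = 5,
                          region_length = list(promoter = c(20, 30),
                                               utr5 = c(20, 30),
                                               orf = c(20, 30),
                                               utr3 = c(10, 12)),
                          max_sites = 3)
  expect_error(generate_transcriptome(cfg, let7a_patterns()), "host")
})

test_that("generators are pure functions of their configuration", {
  p <- let7a_patterns()
  cfg <- generator_config(seed = 77, n_genes = 15)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_region_fasta(generate_transcriptome(cfg, p)$regions, f1)
  write_region_fasta(generate_transcriptome(cfg, p)$regions, f2)
  expect_identical(readLines(f1), readLines(f2))

  t1 <- generate_site_truth(cfg); t2 <- generate_site_truth(cfg)
  expect_identical(t1, t2)

  s1 <- generate_compartment_mirna_profiles(cfg)
  s2 <- generate_compartment_mirna_profiles(cfg)
  expect_identical(s1$values, s2$values)

  cfgS <- generator_config(seed = 77, beta = 1, n_samples = 50)
  expect_identical(generate_survival_cohort(cfgS)$survival,
                   generate_survival_cohort(cfgS)$survival)

  # a different seed gives different data
  expect_false(identical(t1, generate_site_truth(generator_config(seed = 78,
                                                                  n_genes = 15))))
})

test_that("forced site probabilities pin occupancy; zero probability yields zero hits", {
  p <- let7a_patterns()
  cfg1 <- generator_config(seed = 21, n_genes = 30, max_sites = 1,
                           site_prob = c(promoter = 0, utr5 = 0, orf = 0, utr3 = 1))
  tx <- generate_transcriptome(cfg1, p)
  prof <- profile_genes(tx$regions, p)
  expect_true(all(prof$occupancy == "3utr_only"))
  expect_true(all(prof$utr3 == 1L))

  cfg0 <- generator_config(seed = 22, n_genes = 50,
                           site_prob = c(promoter = 0, utr5 = 0, orf = 0, utr3 = 0))
  tx0 <- generate_transcriptome(cfg0, p)
  expect_equal(nrow(scan_regions(tx0$regions, p)), 0L)
})

test_that("the scanner recovers the planted truth exactly (round-trip)", {
  p <- let7a_patterns()
  for (i in 1:10) {
    cfg <- generator_config(seed = 900 + i, n_genes = 12)
    tx <- generate_transcriptome(cfg, p)
    prof <- profile_genes(tx$regions, p)
    for (r in c("promoter", "utr5", "orf", "utr3")) {
      expect_equal(prof[[r]], tx$truth$profile[[r]])
    }
    expect_equal(prof$occupancy, tx$truth$profile$occupancy)
    # typed hits match the recorded planted sites
    hits <- scan_regions(tx$regions, p)
    hits <- hits[order(hits$gene_id, hits$region, hits$start), ]
    want <- tx$truth$sites[order(tx$truth$sites$gene_id, tx$truth$sites$region,
                                 tx$truth$sites$start), ]
    expect_equal(nrow(hits), nrow(want))
    expect_equal(hits$start, want$start)
    expect_equal(hits$site_type, want$site_type)
  }
})

test_that("expression response recovers the planted repression model", {
  # null effect: genome-wide mean log2fc within 3 SE of zero
  cfg0 <- generator_config(seed = 31, n_genes = 2000,
                           delta = c(promoter = 0, utr5 = 0, orf = 0, utr3 = 0))
  de0 <- generate_expression_response(generate_site_truth(cfg0), cfg0)
  se <- sd(de0$log2fc) / sqrt(nrow(de0))
  expect_lt(abs(mean(de0$log2fc)), 3 * se)

  # planted per-gene effect of -1 recovered in the seeded-gene mean
  cfg1 <- generator_config(seed = 32, n_genes = 3000, noise_sd = 0.25)
  truth <- generate_site_truth(cfg1)
  de1 <- generate_expression_response(truth, cfg1)
  seeded <- truth$utr3 > 0
  expect_equal(mean(de1$log2fc[seeded]), -1, tolerance = 0.1)
  expect_equal(mean(de1$log2fc[!seeded & truth$occupancy == "none"]), 0,
               tolerance = 0.05)

  # per-site model: expected difference between 1-site and 2-site genes is delta
  cfg2 <- generator_config(seed = 33, n_genes = 6000, noise_sd = 0.25,
                           effect_model = "per_site")
  truth2 <- generate_site_truth(cfg2)
  de2 <- generate_expression_response(truth2, cfg2)
  d12 <- mean(de2$log2fc[truth2$utr3 == 2]) - mean(de2$log2fc[truth2$utr3 == 1])
  expect_equal(d12, -1, tolerance = 0.12)
  expect_equal(de2$effect[truth2$utr3 == 2][1], -2)
})

test_that("compartment profiles carry the planted ratios and a clean null", {
  # near noise-free: computed fold change approaches the planted ratio
  cfg <- generator_config(seed = 41, n_mirnas = 20, planted_ratio = 10,
                          mirna_noise_sd = 1e-4)
  sim <- generate_compartment_mirna_profiles(cfg)
  fc <- compartment_fold_changes(sim$values, sim$groups, "TEB", "duct")
  expect_equal(fc$fold_change[1:5], rep(10, 5), tolerance = 1e-3)
  expect_equal(fc$fold_change[6:10], rep(0.1, 5), tolerance = 1e-3)
  expect_equal(fc$fold_change[11:20], rep(1, 10), tolerance = 1e-3)

  # flat truth: nothing passes q < 0.05 at the 3/2 design in most replicates
  clean <- 0L
  for (i in 1:20) {
    cfgN <- generator_config(seed = 4100 + i, n_mirnas = 40, planted_ratio = 1)
    simN <- generate_compartment_mirna_profiles(cfgN)
    fcN <- compartment_fold_changes(simN$values, simN$groups, "TEB", "duct")
    if (!any(fcN$q < 0.05, na.rm = TRUE)) clean <- clean + 1L
  }
  expect_gte(clean, 18L)
})

test_that("survival cohorts respect censoring and embed a recoverable score", {
  cfg <- generator_config(seed = 61, beta = 1, n_samples = 300,
                          censoring_fraction = 0)
  co <- generate_survival_cohort(cfg)
  expect_true(all(co$survival$event == 1L))

  cfg2 <- generator_config(seed = 62, beta = 1, n_samples = 2000,
                           censoring_fraction = 0.3)
  co2 <- generate_survival_cohort(cfg2)
  expect_equal(mean(co2$survival$event == 0L), 0.3, tolerance = 0.05)

  # weighted-average scoring of the embedded signature recovers the latent score
  sc <- signature_score(co2$expression, co2$signature_genes)
  expect_gt(cor(sc, co2$truth$score), 0.95)

  # beta = 0: the score carries no hazard information
  sig <- 0L
  for (i in 1:20) {
    cfg0 <- generator_config(seed = 6200 + i, beta = 0, n_samples = 200)
    co0 <- generate_survival_cohort(cfg0)
    grp <- stratify_quantile(co0$truth$score, 0.25)
    if (logrank_test(cbind(co0$survival,
                           group = as.character(grp)))$p.value < 0.05) {
      sig <- sig + 1L
    }
  }
  expect_lte(sig, 4L)
})
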