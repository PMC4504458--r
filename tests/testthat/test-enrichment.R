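test_that("rank-sum p-values match hand-enumerated and reference values", {
  ws <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ws$p.value, 0.10)
  expect_true(ws$exact)

  # identical multisets: no separation
  expect_equal(wilcoxon_rank_sum(c(2, 5, 5), c(2, 5, 5))$p.value, 1.0)

  # group exchange reflects the statistic around its mean, same p
  x <- c(1.2, 3.4, 2.2); y <- c(4.1, 0.3, 5.5, 2.9)
  a <- wilcoxon_rank_sum(x, y); b <- wilcoxon_rank_sum(y, x)
  expect_equal(a$p.value, b$p.value)
  expect_equal(a$statistic + b$statistic, sum(seq_len(7)))

  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")

  # agreement with stats::wilcox.test in the tie-free exact regime
  set.seed(31)
  for (i in 1:15) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    v <- sample(100, m + n) # distinct => no ties
    x <- v[seq_len(m)]; y <- v[-seq_len(m)]
    expect_equal(wilcoxon_rank_sum(x, y)$p.value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("exact enumeration handles ties; large samples use a close approximation", {
  set.seed(32)
  for (i in 1:10) {
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    x <- sample(1:3, m, replace = TRUE); y <- sample(1:3, n, replace = TRUE)
    expect_equal(wilcoxon_rank_sum(x, y)$p.value, oracle_wilcox_p(x, y))
  }
  # normal approximation close to the exhaustive oracle at 8 vs 8
  errs <- vapply(1:20, function(i) {
    x <- rnorm(8); y <- rnorm(8, mean = 0.5)
    ws <- wilcoxon_rank_sum(x, y)
    expect_false(ws$exact)
    abs(ws$p.value - oracle_wilcox_p(x, y))
  }, numeric(1))
  expect_lt(max(errs), 0.02)
  expect_lt(stats::median(errs), 0.01)
})

test_that("BH adjustment matches the hand step-up rule and is order-equivariant", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_qvalues(0.5), 0.5)

  set.seed(33)
  p <- runif(40)
  q <- bh_qvalues(p)
  expect_equal(q, oracle_bh(p))
  expect_true(all(q >= p), all(q <= 1))

  perm <- sample(40)
  expect_equal(bh_qvalues(p[perm]), q[perm])

  # a second adjustment can only move q-values up, never down
  expect_true(all(bh_qvalues(q) >= q - 1e-12))
  # and a flat adjusted vector is a fixed point
  expect_equal(bh_qvalues(rep(0.04, 4)), rep(0.04, 4))

  expect_error(bh_qvalues(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_qvalues(c(0.1, -0.2)), "\\[0, 1\\]")
})

make_cohort <- function(seed, delta = -1, n_genes = 400, noise = 0.5,
                        effect_model = "per_gene", site_prob_utr3 = 0.2) {
  cfg <- generator_config(seed = seed, n_genes = n_genes,
                          delta = c(promoter = 0, utr5 = 0, orf = 0,
                                    utr3 = delta),
                          noise_sd = noise, effect_model = effect_model)
  cfg$site_prob[["utr3"]] <- site_prob_utr3
  profiles <- generate_site_truth(cfg)
  list(profiles = profiles,
       changes = generate_expression_response(profiles, cfg))
}

test_that("regional enrichment flags degenerate regions and finds planted 3'UTR effects", {
  co <- make_cohort(41)
  enr <- regional_enrichment(co$changes, co$profiles, direction = "down")
  expect_equal(enr$region, c("promoter", "utr5", "orf", "utr3"))
  expect_lt(enr$p[enr$region == "utr3"], 0.05)
  expect_equal(enr$n_with + enr$n_without,
               rep(sum(co$changes$log2fc < 0), 4))

  # upregulated direction on a repression cohort: nothing enriched
  up <- regional_enrichment(co$changes, co$profiles, direction = "up")
  expect_true(all(up$p > 0.05, na.rm = TRUE))

  # regions where no gene (promoter) or every gene (utr3) carries a site
  # are degenerate, p reported missing
  cfg0 <- generator_config(seed = 5, n_genes = 50,
                           site_prob = c(promoter = 0, utr5 = 0.5, orf = 0,
                                         utr3 = 1))
  prof0 <- generate_site_truth(cfg0)
  ch0 <- generate_expression_response(prof0, cfg0)
  enr0 <- regional_enrichment(ch0, prof0)
  expect_true(enr0$degenerate[enr0$region == "promoter"])
  expect_true(is.na(enr0$p[enr0$region == "promoter"]))
  expect_true(enr0$degenerate[enr0$region == "utr3"])
  expect_false(enr0$degenerate[enr0$region == "utr5"])

  # the all-unseeded background option changes the contrast population
  enr_bg <- regional_enrichment(co$changes, co$profiles, direction = "down",
                                background = "all_unseeded")
  expect_gt(enr_bg$n_without[enr_bg$region == "utr3"],
            enr$n_without[enr$region == "utr3"])
})

test_that("planted 3'UTR repression is detected and promoter stays null over replicates", {
  hits_utr3 <- 0L; hits_prom <- 0L; n_rep <- 60L
  for (i in seq_len(n_rep)) {
    co <- make_cohort(7000 + i)
    enr <- regional_enrichment(co$changes, co$profiles, direction = "down")
    p3 <- enr$p[enr$region == "utr3"]; pp <- enr$p[enr$region == "promoter"]
    if (!is.na(p3) && p3 < 0.05) hits_utr3 <- hits_utr3 + 1L
    if (!is.na(pp) && pp < 0.05) hits_prom <- hits_prom + 1L
  }
  expect_gte(hits_utr3, ceiling(0.95 * n_rep))
  expect_lte(hits_prom, ceiling(0.12 * n_rep))
})

test_that("seed-count bins summarise per-site trends and omit empty bins with a warning", {
  # per-site additive effect: medians fall with the site count
  co <- make_cohort(42, delta = -0.8, n_genes = 600, effect_model = "per_site")
  scr <- seed_count_response(co$changes, co$profiles, region = "utr3")
  med <- scr$summary$median_log2fc[scr$summary$bin != "0"]
  expect_true(all(diff(med) < 0))
  expect_equal(scr$comparisons$bin_a, c("0", "1", "2"))

  # all genes zero sites: a single bin, no comparisons
  cfg <- generator_config(seed = 6, n_genes = 40,
                          site_prob = c(promoter = 0, utr5 = 0, orf = 0, utr3 = 0))
  prof <- generate_site_truth(cfg)
  ch <- generate_expression_response(prof, cfg)
  expect_warning(scr0 <- seed_count_response(ch, prof), "omitted")
  expect_equal(scr0$summary$bin, "0")
  expect_null(scr0$comparisons)
})

test_that("3'UTR-only genes are more repressed than 5'UTR-only genes when planted so", {
  cfg <- generator_config(seed = 43, n_genes = 600,
                          delta = c(promoter = 0, utr5 = -0.3, orf = 0, utr3 = -1),
                          site_prob = c(promoter = 0.1, utr5 = 0.25, orf = 0.1,
                                        utr3 = 0.25))
  prof <- generate_site_truth(cfg)
  ch <- generate_expression_response(prof, cfg)
  res <- utr_location_contrast(ch, prof)
  expect_lt(res$p, 0.05)
  i3 <- prof$occupancy == "3utr_only"; i5 <- prof$occupancy == "5utr_only"
  expect_lt(median(ch$log2fc[i3]), median(ch$log2fc[i5]))

  # identical distributions: p = 1 exactly (small groups, exact path)
  prof2 <- prof[c(which(i3)[1:3], which(i5)[1:3]), ]
  ch2 <- ch[match(prof2$gene_id, ch$gene_id), ]
  ch2$log2fc <- rep(c(-1, -2, -3), 2)
  expect_equal(utr_location_contrast(ch2, prof2)$p, 1.0)

  # an empty class is an error
  prof3 <- prof[i3, ]
  ch3 <- ch[match(prof3$gene_id, ch$gene_id), ]
  expect_error(utr_location_contrast(ch3, prof3), "5utr_only")
})

test_that("direct-target calls require significance, repression and a 3'UTR site", {
  profiles <- data.frame(
    gene_id = paste0("g", 1:5),
    promoter = 0L, utr5 = 0L, orf = 0L,
    utr3 = c(1L, 0L, 2L, 1L, 0L),
    occupancy = c("3utr_only", "none", "3utr_only", "3utr_only", "none"),
    stringsAsFactors = FALSE)
  changes <- data.frame(
    gene_id = paste0("g", 1:5),
    log2fc = c(-1.5, -1.2, -0.8, 0.4, -1.0),
    q = c(0.001, 0.002, 0.004, 0.003, 0.2),
    stringsAsFactors = FALSE)
  # g1, g3 significantly down with a 3'UTR site; g4 is up, g5 not significant
  tg <- call_direct_targets(changes, profiles, fc_threshold = 1, q_threshold = 0.05)
  expect_equal(tg$gene_id, c("g1", "g3"))  # sorted by repression ratio desc
  expect_equal(tg$repression_ratio, 2^c(1.5, 0.8))

  # fold-change threshold excludes the weaker of the two
  expect_equal(call_direct_targets(changes, profiles, fc_threshold = 2)$gene_id, "g1")

  # set identity: called targets = (3utr_only + both_utrs) among passing genes
  co <- make_cohort(44, delta = -2, noise = 0.2)
  ch <- co$changes
  ch$q <- ifelse(ch$log2fc < 0, 0.01, 0.5) # every downregulated gene passes q
  tg <- call_direct_targets(ch, co$profiles, fc_threshold = 1, q_threshold = 0.05)
  down <- ch$log2fc < 0
  occ <- co$profiles$occupancy
  expect_equal(nrow(tg), sum(down & occ %in% c("3utr_only", "both_utrs")))
})

test_that("change tables convert printed repression ratios and derive q from p", {
  tab <- data.frame(gene_id = c("a", "b"), fold_change = c(2, 0.5),
                    q = c(0.01, 0.01))
  path <- tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  de <- read_de_table(path)
  expect_equal(de$log2fc, c(-1, 1)) # ratio 2 (repressed) -> log2fc -1

  tab2 <- data.frame(gene_id = letters[1:4], log2fc = -1:2,
                     p = c(0.01, 0.02, 0.03, 0.04))
  path2 <- tempfile(fileext = ".tsv")
  utils::write.table(tab2, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_de_table(path2)$q, rep(0.04, 4))

  tab3 <- data.frame(gene_id = "a", fold_change = 2, log2fc = -1, q = 0.1)
  path3 <- tempfile(fileext = ".tsv")
  utils::write.table(tab3, path3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_de_table(path3), "exactly one")
})
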