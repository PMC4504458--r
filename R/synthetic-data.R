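DNA_BASES <- c("A", "C", "G", "T")

#' Configuration for the synthetic-data generators
#'
#' One validated configuration object drives every generator. Defaults
#' mirror the study conditions the analyses assume: a 500-gene
#' transcriptome with ~20% of genes carrying a 3'UTR seed site, a
#' per-gene repression effect of -1 log2 unit with log-scale noise
#' sd 0.5 and 3 replicates per arm, a 3/2/3-replicate compartment design,
#' and a 500-sample survival cohort with hazard proportional to
#' `exp(beta * score)` and 20% censoring.
#'
#' @param seed Integer random seed (mandatory; every generator is a pure
#'   function of its configuration).
#' @param n_genes Number of genes in the synthetic transcriptome.
#' @param region_length Named list of `c(min, max)` length ranges per
#'   region.
#' @param site_prob Named per-region probability that a gene carries at
#'   least one seed site in that region.
#' @param max_sites Maximum planted sites per region per gene; a seeded
#'   region carries `1 + Binomial(max_sites - 1, extra_site_prob)` sites.
#' @param extra_site_prob See `max_sites`.
#' @param effect_model `"per_gene"` (presence of a site triggers the full
#'   regional effect) or `"per_site"` (effect scales with merged site
#'   count).
#' @param delta Named per-region planted log2 fold-change effect.
#' @param noise_sd Log2-scale replicate noise.
#' @param n_replicates Replicates per arm for the expression response.
#' @param baseline_mean,baseline_sd Per-gene baseline log2 intensity.
#' @param n_mirnas,group_sizes,n_enriched,planted_ratio,mirna_noise_sd
#'   Compartment-profile design: number of miRNAs, samples per
#'   compartment, candidates planted as enriched in each of the first two
#'   compartments, their mean ratio, and log2 noise.
#' @param n_samples,beta,baseline_hazard,censoring_fraction Survival
#'   cohort design; `beta` is the log hazard ratio per score unit and
#'   must be set before calling [generate_survival_cohort()].
#' @param n_signature_genes,n_background_genes,expr_noise_sd Survival
#'   cohort expression matrix: genes tracking the latent score, inert
#'   background genes, and their noise.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(seed,
                             n_genes = 500L,
                             region_length = list(promoter = c(300L, 600L),
                                                  utr5 = c(100L, 300L),
                                                  orf = c(300L, 900L),
                                                  utr3 = c(300L, 900L)),
                             site_prob = c(promoter = 0.1, utr5 = 0.1,
                                           orf = 0.1, utr3 = 0.2),
                             max_sites = 3L,
                             extra_site_prob = 0.5,
                             effect_model = c("per_gene", "per_site"),
                             delta = c(promoter = 0, utr5 = 0, orf = 0, utr3 = -1),
                             noise_sd = 0.5,
                             n_replicates = 3L,
                             baseline_mean = 8,
                             baseline_sd = 1,
                             n_mirnas = 50L,
                             group_sizes = c(TEB = 3L, duct = 2L, stroma = 3L),
                             n_enriched = 5L,
                             planted_ratio = 10,
                             mirna_noise_sd = 0.2,
                             n_samples = 500L,
                             beta = NULL,
                             baseline_hazard = 0.1,
                             censoring_fraction = 0.2,
                             n_signature_genes = 18L,
                             n_background_genes = 50L,
                             expr_noise_sd = 0.5) {
  if (missing(seed)) stop("a random seed is mandatory")
  stopifnot(is.numeric(seed), length(seed) == 1L, seed == round(seed))
  effect_model <- match.arg(effect_model)
  stopifnot(all(REGIONS %in% names(region_length)),
            all(REGIONS %in% names(site_prob)),
            all(site_prob >= 0 & site_prob <= 1),
            extra_site_prob >= 0, extra_site_prob <= 1,
            max_sites >= 1, noise_sd > 0, n_replicates >= 1,
            all(REGIONS %in% names(delta)),
            all(unlist(region_length) > 0),
            censoring_fraction >= 0, censoring_fraction < 1,
            baseline_hazard > 0, mirna_noise_sd > 0,
            all(group_sizes >= 1))
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 region_length = region_length, site_prob = site_prob,
                 max_sites = as.integer(max_sites),
                 extra_site_prob = extra_site_prob,
                 effect_model = effect_model, delta = delta,
                 noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 n_mirnas = as.integer(n_mirnas), group_sizes = group_sizes,
                 n_enriched = as.integer(n_enriched),
                 planted_ratio = planted_ratio,
                 mirna_noise_sd = mirna_noise_sd,
                 n_samples = as.integer(n_samples), beta = beta,
                 baseline_hazard = baseline_hazard,
                 censoring_fraction = censoring_fraction,
                 n_signature_genes = as.integer(n_signature_genes),
                 n_background_genes = as.integer(n_background_genes),
                 expr_noise_sd = expr_noise_sd),
            class = "generator_config")
}

gene_ids <- function(n) sprintf("G%04d", seq_len(n))

#' Draw the planted seed-site truth (counts and occupancy) for a cohort
#'
#' Samples, for every gene and region, whether the gene is seeded there
#' (probability `site_prob[region]`) and how many sites it carries. This
#' is the count-level truth behind [generate_transcriptome()]; the
#' sequence generator places exactly these sites, so the table is also a
#' drop-in seed profile for the enrichment analyses.
#'
#' @param config A [generator_config()].
#' @return `data.frame` of class `seed_profile_table` (`gene_id`, merged
#'   counts per region, `occupancy`).
#' @export
generate_site_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_genes
  counts <- sapply(REGIONS, function(r) {
    seeded <- stats::runif(n) < config$site_prob[[r]]
    extra <- if (config$max_sites > 1L)
      stats::rbinom(n, config$max_sites - 1L, config$extra_site_prob) else 0L
    as.integer(seeded) * (1L + extra)
  })
  out <- data.frame(gene_id = gene_ids(n), counts, stringsAsFactors = FALSE)
  out$occupancy <- apply(out[, REGIONS], 1, function(m) occupancy_category(as.list(m)))
  class(out) <- c("seed_profile_table", "data.frame")
  out
}

# background sequence free of both site patterns, as a character vector
random_clean_chars <- function(len, patterns) {
  s <- sample(DNA_BASES, len, replace = TRUE)
  if (len < SITE_WIDTH) return(s)
  repeat {
    str <- paste(s, collapse = "")
    hits <- c(find_pattern_starts(str, patterns$site_7mer_m8),
              find_pattern_starts(str, patterns$site_7mer_1A))
    if (!length(hits)) return(s)
    for (h in unique(hits)) {
      s[(h + 1L):(h + SITE_WIDTH)] <- sample(DNA_BASES, SITE_WIDTH, replace = TRUE)
    }
  }
}

# plant k non-overlapping sites (gap >= 9 so flank fixes stay private)
plant_sites_once <- function(chars, k, patterns) {
  len <- length(chars)
  cand <- sample.int(len - SITE_WIDTH + 1L) - 1L
  chosen <- integer(0)
  for (c0 in cand) {
    if (all(abs(c0 - chosen) >= SITE_WIDTH + 2L)) chosen <- c(chosen, c0)
    if (length(chosen) == k) break
  }
  if (length(chosen) < k) return(NULL)
  chosen <- sort(chosen)
  types <- sample(c("7mer-m8", "7mer-1A"), k, replace = TRUE)
  m8_first <- substr(patterns$site_7mer_m8, 1L, 1L)
  for (i in seq_len(k)) {
    c0 <- chosen[i]
    pat <- if (types[i] == "7mer-m8") patterns$site_7mer_m8 else patterns$site_7mer_1A
    chars[(c0 + 1L):(c0 + SITE_WIDTH)] <- strsplit(pat, "")[[1]]
    if (types[i] == "7mer-m8") {
      # an A after a 7mer-m8 site would create an unplanned 7mer-1A hit
      nxt <- c0 + SITE_WIDTH + 1L
      if (nxt <= len && chars[nxt] == "A") chars[nxt] <- sample(c("C", "G", "T"), 1L)
    } else if (c0 >= 1L && chars[c0] == m8_first) {
      # the m8 first base before a 7mer-1A site would create an m8 hit
      chars[c0] <- sample(setdiff(DNA_BASES, m8_first), 1L)
    }
  }
  list(chars = chars,
       sites = data.frame(start = chosen, site_type = types,
                          stringsAsFactors = FALSE))
}

# build one region sequence containing exactly the planted sites
build_region_sequence <- function(len, k, patterns, max_tries = 25L) {
  if (k > 0L && len < (k - 1L) * (SITE_WIDTH + 2L) + SITE_WIDTH) {
    stop("region of length ", len, " is too short to host ", k, " seed site(s)")
  }
  for (try in seq_len(max_tries)) {
    chars <- random_clean_chars(len, patterns)
    if (k == 0L) {
      return(list(sequence = paste(chars, collapse = ""),
                  sites = data.frame(start = integer(0), site_type = character(0))))
    }
    planted <- plant_sites_once(chars, k, patterns)
    if (is.null(planted)) next
    seqstr <- paste(planted$chars, collapse = "")
    found <- scan_region(seqstr, patterns)
    want <- planted$sites[order(planted$sites$start, planted$sites$site_type), ]
    if (nrow(found) == nrow(want) &&
        all(found$start == want$start) && all(found$site_type == want$site_type)) {
      return(list(sequence = seqstr, sites = planted$sites))
    }
  }
  stop("failed to plant ", k, " site(s) in a region of length ", len,
       " after ", max_tries, " attempts")
}

#' Generate a synthetic transcriptome with planted seed sites
#'
#' Background sequence is uniform over A/C/G/T with every window matching
#' either site pattern rejected and resampled, then sites are planted at
#' recorded positions (non-overlapping, with flanking bases adjusted so
#' no unplanned typed hit arises). The scanner's output on the result
#' equals the planted truth exactly.
#'
#' @param config A [generator_config()].
#' @param patterns A [seed_sequences()] result for the miRNA being
#'   emulated.
#' @return List with `regions` (list of [transcript_regions]), `truth`
#'   (list: `profile` — the [generate_site_truth()] table, `sites` — a
#'   `gene_id`/`region`/`start`/`site_type` table), and `config`.
#' @export
generate_transcriptome <- function(config, patterns) {
  stopifnot(inherits(config, "generator_config"), inherits(patterns, "seed_patterns"))
  profile <- generate_site_truth(config) # seeds the RNG
  for (r in REGIONS) {
    if (config$site_prob[[r]] > 0 &&
        config$region_length[[r]][1] <
          (config$max_sites - 1L) * (SITE_WIDTH + 2L) + SITE_WIDTH) {
      stop("region '", r, "' minimum length cannot host ", config$max_sites,
           " seed site(s)")
    }
  }
  regions <- vector("list", config$n_genes)
  all_sites <- list()
  for (i in seq_len(config$n_genes)) {
    gid <- profile$gene_id[i]
    seqs <- list()
    for (r in REGIONS) {
      rng <- config$region_length[[r]]
      len <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
      built <- build_region_sequence(len, profile[[r]][i], patterns)
      seqs[[r]] <- built$sequence
      if (nrow(built$sites)) {
        all_sites[[length(all_sites) + 1L]] <-
          cbind(data.frame(gene_id = gid, region = r, stringsAsFactors = FALSE),
                built$sites)
      }
    }
    regions[[i]] <- transcript_regions(gid, promoter = seqs$promoter,
                                       utr5 = seqs$utr5, orf = seqs$orf,
                                       utr3 = seqs$utr3)
  }
  names(regions) <- profile$gene_id
  sites <- if (length(all_sites)) do.call(rbind, all_sites) else
    data.frame(gene_id = character(0), region = character(0),
               start = integer(0), site_type = character(0))
  list(regions = regions,
       truth = list(profile = profile, sites = sites),
       config = config)
}

planted_effect <- function(profile, config) {
  counts <- as.matrix(profile[, REGIONS])
  d <- config$delta[REGIONS]
  if (config$effect_model == "per_gene") {
    as.numeric((counts > 0) %*% d)
  } else {
    as.numeric(counts %*% d)
  }
}

#' Generate a differential-expression response to the planted sites
#'
#' Control and treatment replicate intensities are drawn on the log2
#' scale around a per-gene baseline; the treatment mean is shifted by the
#' planted effect (`per_gene`: `delta[region]` once per seeded region;
#' `per_site`: `delta[region]` times the merged site count). Per-gene p
#' comes from a pooled two-sample t-test on log2 intensities, q by
#' Benjamini-Hochberg.
#'
#' @param truth A [generate_transcriptome()] result, its `truth` element,
#'   or a [generate_site_truth()] table.
#' @param config A [generator_config()] (`n_replicates >= 2`).
#' @return `data.frame` with `gene_id`, `log2fc`, `p`, `q` and the planted
#'   `effect`.
#' @export
generate_expression_response <- function(truth, config) {
  stopifnot(inherits(config, "generator_config"))
  profile <- if (inherits(truth, "seed_profile_table")) truth
             else if (!is.null(truth$profile)) truth$profile
             else truth$truth$profile
  stopifnot(inherits(profile, "seed_profile_table"))
  r <- config$n_replicates
  if (r < 2L) stop("need at least 2 replicates per arm for a t-test")
  set.seed(config$seed + 1L)
  n <- nrow(profile)
  effect <- planted_effect(profile, config)
  baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  ctrl <- matrix(stats::rnorm(n * r, 0, config$noise_sd), n, r) + baseline
  trt <- matrix(stats::rnorm(n * r, 0, config$noise_sd), n, r) + baseline + effect
  mc <- rowMeans(ctrl); mt <- rowMeans(trt)
  vc <- rowSums((ctrl - mc)^2) / (r - 1)
  vt <- rowSums((trt - mt)^2) / (r - 1)
  s2 <- (vc + vt) / 2
  tstat <- (mt - mc) / sqrt(s2 * 2 / r)
  p <- 2 * stats::pt(-abs(tstat), df = 2 * r - 2)
  data.frame(gene_id = profile$gene_id, log2fc = mt - mc, p = p,
             q = bh_qvalues(p), effect = effect, stringsAsFactors = FALSE)
}

#' Generate compartment miRNA expression profiles with planted enrichment
#'
#' Lognormal intensities over a replicate-group design (default 3 TEB, 2
#' duct, 3 stroma samples). The first `n_enriched` miRNAs are planted as
#' enriched in the first compartment over the second by
#' `planted_ratio`, the next `n_enriched` as enriched in the second by
#' the same ratio; the rest are flat.
#'
#' @param config A [generator_config()].
#' @return List with `values` (miRNA x sample matrix), `groups` (named
#'   sample -> compartment vector) and `truth` (planted first/second
#'   compartment ratio per miRNA).
#' @export
generate_compartment_mirna_profiles <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (any(config$group_sizes < 1L)) stop("every compartment needs >= 1 sample")
  set.seed(config$seed + 2L)
  gs <- config$group_sizes
  groups <- rep(names(gs), gs)
  samples <- paste0(groups, "_", unlist(lapply(gs, seq_len)))
  n <- config$n_mirnas
  stopifnot(2L * config$n_enriched <= n)
  ids <- sprintf("miR-%03d", seq_len(n))
  ratio <- rep(1, n)
  ratio[seq_len(config$n_enriched)] <- config$planted_ratio
  ratio[config$n_enriched + seq_len(config$n_enriched)] <- 1 / config$planted_ratio
  base <- stats::rnorm(n, 6, 1)
  log2mean <- matrix(base, n, length(samples))
  first <- groups == names(gs)[1]
  log2mean[, first] <- log2mean[, first] + log2(ratio)
  values <- 2^(log2mean + matrix(stats::rnorm(n * length(samples), 0,
                                              config$mirna_noise_sd),
                                 n, length(samples)))
  dimnames(values) <- list(ids, samples)
  list(values = values,
       groups = stats::setNames(groups, samples),
       truth = data.frame(mirna = ids, planted_ratio = ratio,
                          stringsAsFactors = FALSE))
}

#' Generate a survival cohort whose hazard depends on a signature score
#'
#' Each sample carries a latent standard-normal score; event times are
#' exponential with hazard `baseline_hazard * exp(beta * score)`.
#' Censoring times are uniform on `(0, c_max)` with `c_max` calibrated so
#' the expected censored fraction matches `censoring_fraction`. Signature
#' genes in the expression matrix track the latent score (unit slope plus
#' noise), so weighted-average scoring recovers it up to
#' standardisation; background genes are inert.
#'
#' @param config A [generator_config()] with `beta` set.
#' @return List with `expression` (gene x sample matrix; signature genes
#'   named `SIG*`), `survival` (`sample_id`, `time`, `event`),
#'   `signature_genes`, and `truth` (`score`, `hazard` per sample).
#' @export
generate_survival_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(config$beta)) stop("config$beta (log hazard ratio per score unit) must be set")
  set.seed(config$seed + 3L)
  n <- config$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  score <- stats::rnorm(n)
  hazard <- config$baseline_hazard * exp(config$beta * score)
  event_time <- stats::rexp(n, rate = hazard)
  if (config$censoring_fraction > 0) {
    frac_censored <- function(cmax) {
      mean((1 - exp(-hazard * cmax)) / (hazard * cmax)) - config$censoring_fraction
    }
    cmax <- stats::uniroot(frac_censored, lower = 1e-9,
                           upper = 1e3 / config$baseline_hazard,
                           extendInt = "yes")$root
    censor_time <- stats::runif(n, 0, cmax)
    time <- pmin(event_time, censor_time)
    event <- as.integer(event_time <= censor_time)
  } else {
    time <- event_time
    event <- rep(1L, n)
  }
  sig_genes <- sprintf("SIG%02d", seq_len(config$n_signature_genes))
  bg_genes <- sprintf("BG%03d", seq_len(config$n_background_genes))
  expr <- rbind(
    matrix(stats::rnorm(config$n_signature_genes * n, 0, config$expr_noise_sd),
           config$n_signature_genes, n) + rep(score, each = config$n_signature_genes) + 5,
    matrix(stats::rnorm(config$n_background_genes * n, 5, 1),
           config$n_background_genes, n)
  )
  dimnames(expr) <- list(c(sig_genes, bg_genes), ids)
  list(expression = expr,
       survival = data.frame(sample_id = ids, time = time, event = event,
                             stringsAsFactors = FALSE),
       signature_genes = sig_genes,
       truth = data.frame(sample_id = ids, score = score, hazard = hazard,
                          stringsAsFactors = FALSE))
}
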