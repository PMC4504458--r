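#' Load the packaged worked-example tables
#'
#' Two small tables transcribed from the published study travel with the
#' package: the ten compartment-enriched miRNA candidates (ranked fold
#' changes, TEB/duct orientation) and the thirty most repressed genes
#' from the miRNA-overexpression arrays (repression ratio and Q value).
#' A lightweight checksum on row counts and column sums guards against
#' accidental edits.
#'
#' @return List with `compartment_mirnas` (10 rows) and
#'   `repressed_genes` (30 rows).
#' @export
load_fixture_tables <- function() {
  path1 <- system.file("extdata", "table1_compartment_mirnas.tsv",
                       package = "mirseedscape", mustWork = TRUE)
  path2 <- system.file("extdata", "table2_repressed_genes.tsv",
                       package = "mirseedscape", mustWork = TRUE)
  t1 <- utils::read.delim(path1, stringsAsFactors = FALSE)
  t2 <- utils::read.delim(path2, stringsAsFactors = FALSE)
  ok <- nrow(t1) == 10L && nrow(t2) == 30L &&
    isTRUE(all.equal(sum(t1$fold_change), 32.89, tolerance = 1e-6)) &&
    isTRUE(all.equal(sum(t1$q), 0.177, tolerance = 1e-6)) &&
    isTRUE(all.equal(sum(t2$fold_change), 64.04, tolerance = 1e-6)) &&
    isTRUE(all.equal(sum(t2$q), 0.02043236, tolerance = 1e-6))
  if (!ok) stop("packaged fixture tables failed their integrity check")
  list(compartment_mirnas = t1, repressed_genes = t2)
}

#' Default end-to-end pipeline configuration
#'
#' @param seed Integer seed forwarded to [generator_config()].
#' @param ... Overrides for [generator_config()] fields or the pipeline
#'   thresholds `fc_threshold` (2), `q_threshold` (0.05),
#'   `upper_fraction` (0.25), `mirna_sequence` / `mirna_name`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, ...) {
  dots <- list(...)
  pipe_fields <- c("fc_threshold", "q_threshold", "upper_fraction",
                   "mirna_sequence", "mirna_name")
  pipe <- list(fc_threshold = 2, q_threshold = 0.05, upper_fraction = 0.25,
               mirna_sequence = "UGAGGUAGUAGGUUGUAUAGUU",
               mirna_name = "hsa-let-7a-5p")
  pipe[names(dots)[names(dots) %in% pipe_fields]] <-
    dots[names(dots) %in% pipe_fields]
  gen <- do.call(generator_config,
                 c(list(seed = seed), dots[!names(dots) %in% pipe_fields]))
  structure(c(pipe, list(generator = gen, seed = gen$seed)),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic analysis pipeline
#'
#' Stages, in dependency order: simulate a transcriptome with planted
#' sites, scan it, simulate the expression response, test regional
#' enrichment, call direct targets, select a signature from the packaged
#' repressed-gene table, score and stratify a simulated survival cohort,
#' and compare the groups by log-rank. Stage outputs are written to
#' `out_dir` as TSV; a JSON manifest records the configuration, seed and
#' per-stage record counts. A failing stage leaves earlier outputs in
#' place and is marked failed in the manifest.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The run manifest (list of class `run_manifest`), invisibly
#'   containing `stages` (status + record counts), `paths`, `seed` and
#'   the configuration snapshot.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   thresholds = config[c("fc_threshold", "q_threshold",
                                         "upper_fraction")],
                   mirna = config$mirna_name,
                   stages = list(), paths = list())
  state <- new.env(parent = emptyenv())

  stage <- function(name, fun) {
    if (any(vapply(manifest$stages, function(s) identical(s$status, "failed"),
                   logical(1)))) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      warning("stage '", name, "' failed: ", conditionMessage(res))
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
    } else {
      manifest$stages[[name]] <<- c(list(status = "ok"), res)
    }
  }

  patterns <- seed_sequences(mature_mirna(config$mirna_name, config$mirna_sequence))
  gen <- config$generator

  stage("simulate_transcriptome", function() {
    state$tx <- generate_transcriptome(gen, patterns)
    p <- file.path(out_dir, "regions.fa")
    write_region_fasta(state$tx$regions, p)
    manifest$paths$regions <<- p
    list(n_genes = length(state$tx$regions),
         n_planted_sites = nrow(state$tx$truth$sites))
  })
  stage("scan", function() {
    state$profiles <- profile_genes(state$tx$regions, patterns)
    hits <- scan_regions(state$tx$regions, patterns)
    manifest$paths$hits <<- write_tsv(hits, file.path(out_dir, "hits.tsv"))
    manifest$paths$profiles <<- write_tsv(state$profiles,
                                          file.path(out_dir, "profiles.tsv"))
    list(n_hits = nrow(hits),
         n_seeded_genes = sum(state$profiles$occupancy != "none"))
  })
  stage("simulate_expression", function() {
    state$changes <- generate_expression_response(state$tx$truth, gen)
    manifest$paths$de <<- write_tsv(state$changes, file.path(out_dir, "de.tsv"))
    list(n_genes = nrow(state$changes))
  })
  stage("enrich", function() {
    enr <- regional_enrichment(state$changes, state$profiles, direction = "down")
    manifest$paths$enrichment <<- write_tsv(enr,
                                            file.path(out_dir, "enrichment.tsv"))
    list(n_regions = nrow(enr), utr3_p = enr$p[enr$region == "utr3"])
  })
  stage("targets", function() {
    tg <- call_direct_targets(state$changes, state$profiles,
                              fc_threshold = 1,
                              q_threshold = config$q_threshold)
    manifest$paths$targets <<- write_tsv(tg, file.path(out_dir, "targets.tsv"))
    if (nrow(tg) == 0L) warning("no direct targets called under the configured thresholds")
    list(n_targets = nrow(tg))
  })
  stage("signature", function() {
    fixtures <- load_fixture_tables()
    state$sig <- tryCatch(
      select_signature(fixtures$repressed_genes,
                       fc_threshold = config$fc_threshold,
                       q_threshold = config$q_threshold),
      error = function(e) {
        warning("signature selection empty: ", conditionMessage(e))
        NULL
      })
    sig_df <- if (is.null(state$sig)) {
      data.frame(gene_id = character(0), weight = numeric(0))
    } else {
      data.frame(gene_id = state$sig$genes, weight = state$sig$weights)
    }
    manifest$paths$signature <<- write_tsv(sig_df,
                                           file.path(out_dir, "signature.tsv"))
    list(n_genes = nrow(sig_df))
  })
  stage("survive", function() {
    cohort <- generate_survival_cohort(gen)
    scores <- signature_score(cohort$expression, cohort$signature_genes)
    grp <- stratify_quantile(scores, config$upper_fraction)
    rec <- cbind(cohort$survival, group = as.character(grp))
    km <- kaplan_meier(rec)
    lr <- logrank_test(rec)
    manifest$paths$scores <<- write_tsv(
      data.frame(sample_id = names(scores), score = scores,
                 group = as.character(grp)),
      file.path(out_dir, "scores.tsv"))
    manifest$paths$km <<- file.path(out_dir, "km.tsv")
    write_km_curves(km, manifest$paths$km)
    list(n_samples = nrow(rec), n_high = sum(grp == "high"),
         logrank_chisq = lr$statistic, logrank_p = lr$p.value)
  })

  manifest$paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest$paths$manifest,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run (seed", x$seed, ")\n")
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    extras <- st[setdiff(names(st), c("status", "error"))]
    cat(sprintf("  %-22s %s %s\n", s, st$status,
                paste(sprintf("%s=%s", names(extras),
                              vapply(extras, function(v) format(v, digits = 4),
                                     character(1))),
                      collapse = " ")))
  }
  invisible(x)
}

#' Read example miRNAs shipped with the package
#'
#' @return Named list of [mature_mirna] objects parsed from the packaged
#'   example FASTA (let-7a plus a synthetic example).
#' @export
load_example_mirnas <- function() {
  path <- system.file("extdata", "example_mirnas.fa", package = "mirseedscape",
                      mustWork = TRUE)
  seqs <- Biostrings::readRNAStringSet(path)
  nm <- vapply(strsplit(names(seqs), " "), `[`, character(1), 1L)
  stats::setNames(lapply(seq_along(seqs), function(i) {
    mature_mirna(nm[i], as.character(seqs[i]))
  }), nm)
}
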