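#' Construct a mature miRNA record
#'
#' Normalises a mature microRNA sequence (uppercased, DNA-style T converted
#' to U) and validates it for seed-pattern derivation.
#'
#' @param name miRNA identifier (e.g. `"hsa-let-7a-5p"`).
#' @param sequence Mature sequence, 5'->3'. `T` is accepted and converted
#'   to `U`; case is ignored.
#' @return An object of class `mature_mirna` with elements `name` and
#'   `sequence`.
#' @examples
#' mature_mirna("let-7a", "UGAGGUAGUAGGUUGUAUAGUU")
#' @export
mature_mirna <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  seq <- chartr("T", "U", toupper(sequence))
  if (nchar(seq) < 8L) {
    stop("mature miRNA sequence must be at least 8 nt (need positions 2-8 for the seed)")
  }
  bad <- setdiff(strsplit(seq, "")[[1]], c("A", "C", "G", "U"))
  if (length(bad)) {
    stop("non-nucleotide character(s) in miRNA sequence: ",
         paste(unique(bad), collapse = ", "))
  }
  structure(list(name = name, sequence = seq), class = "mature_mirna")
}

#' @export
print.mature_mirna <- function(x, ...) {
  cat("Mature miRNA", x$name, ":", x$sequence, sprintf("(%d nt)\n", nchar(x$sequence)))
  invisible(x)
}

# reverse complement of an RNA/DNA string, returned as DNA
revcomp_dna <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(chartr("U", "T", s))))
}

#' Derive 7mer-m8 and 7mer-1A target-site patterns from a mature miRNA
#'
#' The seed of a miRNA is positions 2-8 of the mature sequence. A
#' *7mer-m8* site is the perfect (DNA, sense-strand) reverse complement of
#' positions 2-8; a *7mer-1A* site is the reverse complement of positions
#' 2-7 followed by an adenosine in the mRNA.
#'
#' @param mirna A [mature_mirna] object, or a character sequence which is
#'   passed through [mature_mirna()] with name `"miRNA"`.
#' @return Object of class `seed_patterns`: list with `mirna_name`,
#'   `site_7mer_m8` and `site_7mer_1A` (both 7-nt DNA strings).
#' @examples
#' seed_sequences(mature_mirna("let-7a", "UGAGGUAGUAGGUUGUAUAGUU"))
#' @export
seed_sequences <- function(mirna) {
  if (is.character(mirna)) mirna <- mature_mirna("miRNA", mirna)
  stopifnot(inherits(mirna, "mature_mirna"))
  m8 <- revcomp_dna(substr(mirna$sequence, 2L, 8L))
  a1 <- paste0(revcomp_dna(substr(mirna$sequence, 2L, 7L)), "A")
  structure(list(mirna_name = mirna$name,
                 site_7mer_m8 = m8,
                 site_7mer_1A = a1),
            class = "seed_patterns")
}

#' @export
print.seed_patterns <- function(x, ...) {
  cat("Seed-site patterns for", x$mirna_name, "\n")
  cat("  7mer-m8:", x$site_7mer_m8, "\n")
  cat("  7mer-1A:", x$site_7mer_1A, "\n")
  invisible(x)
}

REGIONS <- c("promoter", "utr5", "orf", "utr3")
SITE_WIDTH <- 7L

normalize_dna <- function(s, what = "sequence") {
  s <- chartr("U", "T", toupper(s))
  bad <- setdiff(unique(strsplit(s, "")[[1]]), c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop("non-nucleotide character(s) in ", what, ": ", paste(bad, collapse = ", "))
  }
  s
}

#' Bundle per-region transcript sequences for one gene
#'
#' @param gene_id Gene identifier.
#' @param promoter,utr5,orf,utr3 Sense-strand DNA sequences (possibly
#'   empty). `N` is allowed and never matches a site pattern.
#' @return Object of class `transcript_regions`.
#' @export
transcript_regions <- function(gene_id, promoter = "", utr5 = "", orf = "", utr3 = "") {
  regs <- list(promoter = promoter, utr5 = utr5, orf = orf, utr3 = utr3)
  regs <- lapply(regs, normalize_dna)
  structure(c(list(gene_id = gene_id), regs), class = "transcript_regions")
}

# all (overlapping) exact occurrences of a 7-mer pattern; 0-based starts
find_pattern_starts <- function(sequence, pattern) {
  n <- nchar(sequence)
  if (n < SITE_WIDTH) return(integer(0))
  from <- seq_len(n - SITE_WIDTH + 1L)
  which(substring(sequence, from, from + SITE_WIDTH - 1L) == pattern) - 1L
}

#' Scan one sequence for seed-site hits
#'
#' Finds every occurrence of both site patterns; occurrences may overlap
#' (a canonical 8mer site contains a 7mer-m8 and a 7mer-1A hit one base
#' apart, and both are reported).
#'
#' @param sequence DNA string (any case; `U` tolerated).
#' @param patterns A [seed_sequences()] result.
#' @return `data.frame` with columns `start` (0-based offset) and
#'   `site_type` (`"7mer-m8"` or `"7mer-1A"`), sorted by `start`.
#' @export
scan_region <- function(sequence, patterns) {
  stopifnot(inherits(patterns, "seed_patterns"))
  sequence <- normalize_dna(sequence)
  s_m8 <- find_pattern_starts(sequence, patterns$site_7mer_m8)
  s_1a <- find_pattern_starts(sequence, patterns$site_7mer_1A)
  hits <- data.frame(start = c(s_m8, s_1a),
                     site_type = c(rep("7mer-m8", length(s_m8)),
                                   rep("7mer-1A", length(s_1a))),
                     stringsAsFactors = FALSE)
  hits[order(hits$start, hits$site_type), , drop = FALSE]
}

#' Scan a set of gene regions and tabulate all hits
#'
#' @param regions A list of [transcript_regions] objects (or a single one).
#' @param patterns A [seed_sequences()] result.
#' @return `data.frame` with columns `gene_id`, `region`, `start`,
#'   `site_type` — one row per typed hit.
#' @export
scan_regions <- function(regions, patterns) {
  if (inherits(regions, "transcript_regions")) regions <- list(regions)
  out <- lapply(regions, function(tr) {
    per_region <- lapply(REGIONS, function(r) {
      h <- scan_region(tr[[r]], patterns)
      if (nrow(h) == 0L) return(NULL)
      cbind(data.frame(gene_id = tr$gene_id, region = r,
                       stringsAsFactors = FALSE), h)
    })
    do.call(rbind, per_region)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), region = character(0),
                      start = integer(0), site_type = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Merge overlapping typed hits into distinct sites per region
#'
#' Each typed hit spans 7 nt; overlapping hit intervals within a region
#' (e.g. the 7mer-m8 and 7mer-1A halves of an 8mer site) collapse to one
#' counted site.
#'
#' @param hits Hit table from [scan_regions()] restricted to a single gene
#'   (a table from [scan_region()] is accepted and treated as one region).
#' @return Named integer vector of merged site counts over
#'   `promoter`, `utr5`, `orf`, `utr3` (regions absent from `hits` count 0).
#' @export
merge_hits <- function(hits) {
  counts <- stats::setNames(integer(length(REGIONS)), REGIONS)
  if (is.null(hits) || nrow(hits) == 0L) return(counts)
  if ("gene_id" %in% names(hits) && length(unique(hits$gene_id)) > 1L) {
    stop("merge_hits() expects hits from a single gene; got ",
         length(unique(hits$gene_id)))
  }
  region <- if ("region" %in% names(hits)) hits$region else rep("utr3", nrow(hits))
  for (r in unique(region)) {
    starts <- sort(unique(hits$start[region == r]))
    # count connected components of 7-nt intervals [s, s+7)
    counts[[r]] <- sum(diff(c(-SITE_WIDTH - 1L, starts)) >= SITE_WIDTH)
  }
  counts
}

occupancy_category <- function(merged) {
  u3 <- merged[["utr3"]] > 0L
  u5 <- merged[["utr5"]] > 0L
  if (u3 && u5) return("both_utrs")
  if (u3) return("3utr_only")
  if (u5) return("5utr_only")
  if (merged[["promoter"]] > 0L || merged[["orf"]] > 0L) return("non_utr_only")
  "none"
}

#' Seed-site profile of one gene
#'
#' Scans all four regions, records typed hit counts, merges overlapping
#' hits into site counts, and assigns a UTR occupancy category:
#' `3utr_only`, `5utr_only`, `both_utrs`, `non_utr_only` (promoter/ORF
#' sites only) or `none`. UTR occupancy ignores promoter/ORF hits, so a
#' gene with sites in the 3' UTR and the ORF is still `3utr_only`.
#'
#' @param regions A [transcript_regions] object.
#' @param patterns A [seed_sequences()] result.
#' @return Object of class `gene_seed_profile`: list with `gene_id`,
#'   `hits` (typed hit table), `typed_counts` (region x site-type matrix),
#'   `merged_counts` (named vector) and `occupancy`.
#' @export
profile_gene <- function(regions, patterns) {
  stopifnot(inherits(regions, "transcript_regions"))
  hits <- scan_regions(regions, patterns)
  typed <- table(factor(hits$region, levels = REGIONS),
                 factor(hits$site_type, levels = c("7mer-m8", "7mer-1A")))
  merged <- merge_hits(hits)
  structure(list(gene_id = regions$gene_id,
                 hits = hits,
                 typed_counts = unclass(typed),
                 merged_counts = merged,
                 occupancy = occupancy_category(merged)),
            class = "gene_seed_profile")
}

#' @export
print.gene_seed_profile <- function(x, ...) {
  cat("Seed profile for", x$gene_id, "- occupancy:", x$occupancy, "\n")
  cat("  merged sites:",
      paste(sprintf("%s=%d", names(x$merged_counts), x$merged_counts), collapse = " "),
      "\n")
  invisible(x)
}

#' Profile a whole gene set
#'
#' @param regions List of [transcript_regions] objects.
#' @param patterns A [seed_sequences()] result.
#' @return `data.frame` (class `seed_profile_table`) with one row per
#'   gene: `gene_id`, merged site counts `promoter`, `utr5`, `orf`,
#'   `utr3`, and `occupancy`.
#' @export
profile_genes <- function(regions, patterns) {
  rows <- lapply(regions, function(tr) {
    p <- profile_gene(tr, patterns)
    data.frame(gene_id = p$gene_id,
               promoter = p$merged_counts[["promoter"]],
               utr5 = p$merged_counts[["utr5"]],
               orf = p$merged_counts[["orf"]],
               utr3 = p$merged_counts[["utr3"]],
               occupancy = p$occupancy,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("seed_profile_table", "data.frame")
  out
}

#' Read region sequences from a FASTA file
#'
#' Headers follow the dialect `geneID|region` with region one of
#' `promoter`, `utr5`, `orf`, `utr3`; one record per gene-region (missing
#' regions are treated as empty).
#'
#' @param path FASTA file path.
#' @return Named list of [transcript_regions] objects.
#' @export
read_region_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  ok <- lengths(parts) == 2L & vapply(parts, function(p) p[2] %in% REGIONS, logical(1))
  if (!all(ok)) {
    stop("malformed region FASTA header(s): ",
         paste(utils::head(names(seqs)[!ok], 3L), collapse = ", "))
  }
  gene <- vapply(parts, `[`, character(1), 1L)
  region <- vapply(parts, `[`, character(1), 2L)
  out <- lapply(split(seq_along(seqs), gene), function(i) {
    args <- stats::setNames(as.list(as.character(seqs[i])), region[i])
    do.call(transcript_regions, c(list(gene_id = gene[i[1]]), args))
  })
  out[unique(gene)]
}

#' Write region sequences to FASTA
#'
#' @param regions List of [transcript_regions] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_region_fasta <- function(regions, path) {
  if (inherits(regions, "transcript_regions")) regions <- list(regions)
  recs <- unlist(lapply(regions, function(tr) {
    s <- vapply(REGIONS, function(r) tr[[r]], character(1))
    s <- s[nchar(s) > 0L]
    stats::setNames(s, paste(tr$gene_id, names(s), sep = "|"))
  }))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(recs), path)
  invisible(path)
}
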