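#' Two-sample Wilcoxon rank-sum test
#'
#' The rank-sum statistic of the first sample is computed with midranks
#' for ties. For combined sizes `m + n <= 12` the two-sided p-value is
#' exact: every assignment of the observed (mid)ranks to the two groups is
#' enumerated and the tail probabilities of the rank-sum distribution are
#' doubled (capped at 1). For larger samples a tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @return List of class `rank_sum_test`: `statistic` (rank sum of `x`),
#'   `u` (Mann-Whitney U of `x`), `p.value` (two-sided), `exact`
#'   (logical), `n` (`c(m, n)`).
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p.value  # exactly 0.10
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("NA values are not allowed")
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])
  u <- W - m * (m + 1) / 2

  if (N <= 12L) {
    sums <- utils::combn(N, m, FUN = function(idx) sum(r[idx]))
    p <- min(1, 2 * min(mean(sums <= W), mean(sums >= W)))
    exact <- TRUE
  } else {
    mu <- m * (N + 1) / 2
    ties <- table(r)
    sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1 # all values tied
    } else {
      z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    exact <- FALSE
  }
  structure(list(statistic = W, u = u, p.value = p, exact = exact, n = c(m, n)),
            class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: W = %g (U = %g), n = %d vs %d, %s p = %.4g\n",
              x$statistic, x$u, x$n[1], x$n[2],
              if (x$exact) "exact" else "approximate", x$p.value))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a thin validated front over
#' [stats::p.adjust()].
#'
#' @param pvals Numeric vector of raw p-values in `[0, 1]`.
#' @return Vector of q-values, same order as the input.
#' @export
bh_qvalues <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

# canonical per-gene change table: gene_id, log2fc, p (optional), q
as_change_table <- function(changes) {
  stopifnot(is.data.frame(changes), "gene_id" %in% names(changes))
  has_fc <- "fold_change" %in% names(changes)
  has_l2 <- "log2fc" %in% names(changes)
  if (has_fc && has_l2) stop("supply exactly one of fold_change / log2fc, not both")
  if (has_fc) {
    if (any(changes$fold_change <= 0, na.rm = TRUE)) stop("fold_change must be > 0")
    # printed repression ratios are control/treatment: ratio r -> log2fc = -log2(r)
    changes$log2fc <- -log2(changes$fold_change)
  } else if (!has_l2) {
    stop("change table needs a fold_change or log2fc column")
  }
  if (!"q" %in% names(changes)) {
    if (!"p" %in% names(changes)) stop("change table needs q or p to derive q")
    changes$q <- bh_qvalues(changes$p)
  }
  changes
}

#' Read a differential-expression table
#'
#' Tab-separated with columns `gene_id`, exactly one of `fold_change`
#' (repression ratio, control/treatment, > 1 means repressed) or `log2fc`
#' (treatment/control), optional `p` and `q`. `q` is computed by
#' Benjamini-Hochberg from `p` when absent.
#'
#' @param path TSV file path.
#' @return `data.frame` with at least `gene_id`, `log2fc`, `q`.
#' @export
read_de_table <- function(path) {
  as_change_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

match_profiles <- function(changes, profiles) {
  stopifnot(is.data.frame(profiles),
            all(c("gene_id", "utr3", "utr5", "promoter", "orf", "occupancy")
                %in% names(profiles)))
  idx <- match(changes$gene_id, profiles$gene_id)
  if (anyNA(idx)) {
    stop("profiles are missing ", sum(is.na(idx)), " gene(s) present in the change table")
  }
  profiles[idx, , drop = FALSE]
}

#' Regional seed-match enrichment among regulated transcripts
#'
#' For each region, compares the log2 fold-change distribution of genes
#' carrying at least one merged seed site in that region against genes
#' without one, within the chosen regulation direction, using the
#' Wilcoxon rank-sum test. With `background = "all_unseeded"` the
#' comparison is direction-restricted seeded genes versus all unseeded
#' genes irrespective of direction.
#'
#' @param changes Change table (see [read_de_table()]).
#' @param profiles [profile_genes()] table covering the change table's genes.
#' @param direction `"down"` (log2fc < 0) or `"up"` (log2fc > 0).
#' @param background `"direction"` (default) or `"all_unseeded"`.
#' @return `data.frame` of class `enrichment_result`: one row per region
#'   with `region`, `site_class`, `n_with`, `n_without`, `statistic`, `p`,
#'   `degenerate`. Degenerate contrasts (an empty group) carry `p = NA`.
#' @export
regional_enrichment <- function(changes, profiles,
                                direction = c("down", "up"),
                                background = c("direction", "all_unseeded")) {
  direction <- match.arg(direction)
  background <- match.arg(background)
  changes <- as_change_table(changes)
  prof <- match_profiles(changes, profiles)
  in_dir <- if (direction == "down") changes$log2fc < 0 else changes$log2fc > 0

  rows <- lapply(REGIONS, function(r) {
    seeded <- prof[[r]] > 0
    with_i <- in_dir & seeded
    without_i <- if (background == "direction") in_dir & !seeded else !seeded
    n_with <- sum(with_i); n_without <- sum(without_i)
    if (n_with == 0L || n_without == 0L) {
      return(data.frame(region = r, site_class = "any", n_with = n_with,
                        n_without = n_without, statistic = NA_real_,
                        p = NA_real_, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    ws <- wilcoxon_rank_sum(changes$log2fc[with_i], changes$log2fc[without_i])
    data.frame(region = r, site_class = "any", n_with = n_with,
               n_without = n_without, statistic = ws$statistic, p = ws$p.value,
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Repression response by seed-site count
#'
#' Bins genes by merged site count in one region (default bins 0, 1, 2,
#' >=3) and compares adjacent non-empty bins' log2 fold-change
#' distributions by Wilcoxon rank-sum. Reproducing a flat response among
#' seeded bins indicates no additive effect of extra sites.
#'
#' @param changes Change table.
#' @param profiles [profile_genes()] table.
#' @param region Region whose site counts to bin (default `"utr3"`).
#' @param breaks Increasing integer bin lower bounds; the last bin is
#'   open-ended (default `c(0, 1, 2, 3)` giving 0 / 1 / 2 / >=3).
#' @param occupancy Optional occupancy class filter (e.g. `"3utr_only"`)
#'   applied before binning; genes with zero sites are always retained as
#'   the 0 bin.
#' @return List of class `seed_count_response`: `summary` (per-bin n,
#'   median and mean log2fc) and `comparisons` (adjacent-bin Wilcoxon
#'   p-values).
#' @export
seed_count_response <- function(changes, profiles, region = "utr3",
                                breaks = c(0, 1, 2, 3), occupancy = NULL) {
  stopifnot(region %in% REGIONS, length(breaks) >= 1, !is.unsorted(breaks, strictly = TRUE))
  changes <- as_change_table(changes)
  prof <- match_profiles(changes, profiles)
  counts <- prof[[region]]
  keep <- rep(TRUE, nrow(prof))
  if (!is.null(occupancy)) keep <- counts == 0 | prof$occupancy %in% occupancy
  counts <- counts[keep]
  l2 <- changes$log2fc[keep]

  labels <- c(as.character(breaks[-length(breaks)]),
              if (length(breaks) > 1) paste0(">=", breaks[length(breaks)])
              else as.character(breaks))
  bin <- labels[findInterval(counts, breaks)]
  bin <- factor(bin, levels = labels)
  present <- levels(bin)[table(bin) > 0]
  if (length(present) < length(labels)) {
    warning("empty count bin(s) omitted: ",
            paste(setdiff(labels, present), collapse = ", "))
  }
  summ <- do.call(rbind, lapply(present, function(b) {
    v <- l2[bin == b]
    data.frame(bin = b, n = length(v), median_log2fc = stats::median(v),
               mean_log2fc = mean(v), stringsAsFactors = FALSE)
  }))
  comps <- NULL
  if (length(present) >= 2) {
    comps <- do.call(rbind, lapply(seq_len(length(present) - 1), function(i) {
      a <- present[i]; b <- present[i + 1]
      ws <- wilcoxon_rank_sum(l2[bin == a], l2[bin == b])
      data.frame(bin_a = a, bin_b = b, n_a = sum(bin == a), n_b = sum(bin == b),
                 statistic = ws$statistic, p = ws$p.value, stringsAsFactors = FALSE)
    }))
  }
  structure(list(summary = summ, comparisons = comps, region = region),
            class = "seed_count_response")
}

#' @export
print.seed_count_response <- function(x, ...) {
  cat("Seed-count response in", x$region, "\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$comparisons)) {
    cat("Adjacent-bin Wilcoxon comparisons:\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}

#' Contrast repression between 3'UTR-only and 5'UTR-only seeded genes
#'
#' @param changes Change table.
#' @param profiles [profile_genes()] table.
#' @return One-row `enrichment_result` comparing log2fc of `3utr_only`
#'   (counted in `n_with`) versus `5utr_only` genes (`n_without`).
#' @export
utr_location_contrast <- function(changes, profiles) {
  changes <- as_change_table(changes)
  prof <- match_profiles(changes, profiles)
  i3 <- prof$occupancy == "3utr_only"
  i5 <- prof$occupancy == "5utr_only"
  if (!any(i3) || !any(i5)) {
    stop("need at least one gene in each of the 3utr_only and 5utr_only classes")
  }
  ws <- wilcoxon_rank_sum(changes$log2fc[i3], changes$log2fc[i5])
  out <- data.frame(region = "utr", site_class = "3utr_only vs 5utr_only",
                    n_with = sum(i3), n_without = sum(i5),
                    statistic = ws$statistic, p = ws$p.value, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Call direct targets: significantly repressed genes with a 3'UTR seed site
#'
#' @param changes Change table.
#' @param profiles [profile_genes()] table.
#' @param fc_threshold Repression-ratio threshold (`2^-log2fc >
#'   fc_threshold`); the default 1 keeps any repressed gene.
#' @param q_threshold Significance threshold on the adjusted p-value.
#' @return `data.frame` with `gene_id`, `repression_ratio`, `log2fc`, `q`
#'   and `utr3` merged site count, sorted by repression ratio descending.
#' @export
call_direct_targets <- function(changes, profiles, fc_threshold = 1,
                                q_threshold = 0.05) {
  stopifnot(fc_threshold > 0, q_threshold >= 0)
  changes <- as_change_table(changes)
  prof <- match_profiles(changes, profiles)
  ratio <- 2^(-changes$log2fc)
  sel <- changes$q < q_threshold & ratio > fc_threshold & prof$utr3 > 0
  out <- data.frame(gene_id = changes$gene_id[sel],
                    repression_ratio = ratio[sel],
                    log2fc = changes$log2fc[sel],
                    q = changes$q[sel],
                    utr3 = prof$utr3[sel],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$repression_ratio, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
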