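#' Read a miRNA (or gene) expression matrix from TSV
#'
#' First column holds feature identifiers, remaining columns one sample
#' each.
#'
#' @param path TSV file path.
#' @return Numeric matrix, features in rows.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix to TSV
#' @param values Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_column Header for the identifier column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(values, path, id_column = "feature_id") {
  df <- data.frame(rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample -> compartment mapping from TSV
#' @param path TSV with columns `sample` and `group`.
#' @return Named character vector, sample -> group.
#' @export
read_sample_groups <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "group") %in% names(df)))
  stats::setNames(df$group, df$sample)
}

#' Per-miRNA fold changes between two compartments
#'
#' Fold change is the ratio of group means of normalised intensities
#' (orientation `group_a / group_b`). The p-value comes from a two-sample
#' pooled t-test on log2 intensities when both groups have at least two
#' samples; q is Benjamini-Hochberg across all testable miRNAs.
#'
#' @param values miRNA x sample intensity matrix (non-negative).
#' @param groups Named vector mapping every column of `values` to a
#'   compartment label.
#' @param group_a,group_b Labels to contrast (fold change `a / b`).
#' @return `data.frame` with `mirna`, `fold_change`, `p`, `q`, `flagged`
#'   (`TRUE` where a zero group mean makes the ratio undefined).
#' @export
compartment_fold_changes <- function(values, groups, group_a, group_b) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  if (!all(colnames(values) %in% names(groups))) {
    stop("every sample column needs a group label")
  }
  g <- groups[colnames(values)]
  a <- values[, g == group_a, drop = FALSE]
  b <- values[, g == group_b, drop = FALSE]
  if (ncol(a) < 1L || ncol(b) < 1L) stop("both groups need at least one sample")
  ma <- rowMeans(a); mb <- rowMeans(b)
  flagged <- mb == 0 | ma == 0
  fc <- ifelse(flagged, NA_real_, ma / mb)
  p <- rep(NA_real_, nrow(values))
  if (ncol(a) >= 2L && ncol(b) >= 2L) {
    la <- log2(pmax(a, .Machine$double.xmin))
    lb <- log2(pmax(b, .Machine$double.xmin))
    for (i in seq_len(nrow(values))) {
      if (flagged[i]) next
      tt <- try(stats::t.test(la[i, ], lb[i, ], var.equal = TRUE), silent = TRUE)
      if (!inherits(tt, "try-error")) p[i] <- tt$p.value
    }
  }
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- bh_qvalues(p[!is.na(p)])
  data.frame(mirna = rownames(values), fold_change = fc, p = p, q = q,
             flagged = flagged, stringsAsFactors = FALSE)
}

#' Rank compartment-enriched candidates by fold change
#'
#' Direction `"a"` ranks candidates enriched in the numerator compartment
#' (fold change descending, largest first); `"b"` ranks candidates
#' enriched in the denominator (fold change ascending, smallest ratio
#' first). Ties break by q ascending, then identifier.
#'
#' @param rows Output of [compartment_fold_changes()] or any data frame
#'   with `mirna` (or `gene_id`), `fold_change` and optionally `q`.
#' @param direction `"a"` or `"b"`.
#' @param top_n Number of candidates to keep (default all).
#' @return The ranked sublist with a `rank` column prepended.
#' @export
rank_enriched <- function(rows, direction = c("a", "b"), top_n = Inf) {
  direction <- match.arg(direction)
  if (!is.infinite(top_n) && (!is.numeric(top_n) || top_n <= 0)) {
    stop("top_n must be a positive number")
  }
  stopifnot("fold_change" %in% names(rows))
  rows <- rows[!is.na(rows$fold_change), , drop = FALSE]
  id <- if ("mirna" %in% names(rows)) rows$mirna else rows$gene_id
  q <- if ("q" %in% names(rows)) rows$q else rep(NA_real_, nrow(rows))
  key <- if (direction == "a") -rows$fold_change else rows$fold_change
  ord <- order(key, q, id)
  rows <- rows[ord, , drop = FALSE]
  rows <- utils::head(rows, top_n)
  rownames(rows) <- NULL
  cbind(rank = seq_len(nrow(rows)), rows)
}

#' qPCR relative quantification against a reference gene
#'
#' Standard `2^-dCt` relative expression: `2^-(ct_target - ct_reference)`.
#'
#' @param ct_target,ct_reference Cycle-threshold values (vectorised).
#' @return Relative expression ratio(s).
#' @examples
#' relative_expression(25, 20) # 1/32
#' @export
relative_expression <- function(ct_target, ct_reference) {
  stopifnot(is.numeric(ct_target), is.numeric(ct_reference),
            all(is.finite(ct_target)), all(is.finite(ct_reference)))
  2^(-(ct_target - ct_reference))
}

#' Hierarchical clustering of miRNA expression profiles
#'
#' Agglomerative clustering with distance `1 - Pearson correlation`
#' across samples and (by default) average linkage — the common default
#' for expression-profile heatmaps. Constant rows have undefined
#' correlation and are dropped with a warning. Rows are pre-sorted by
#' identifier so the dendrogram is invariant to input row order.
#'
#' @param values miRNA x sample matrix (>= 2 non-constant rows, >= 2
#'   samples).
#' @param method Linkage passed to [stats::hclust()].
#' @return An `hclust` object.
#' @export
cluster_mirnas <- function(values, method = "average") {
  stopifnot(is.matrix(values), ncol(values) >= 2L)
  constant <- apply(values, 1, function(v) stats::sd(v) == 0)
  if (any(constant)) {
    warning("dropping ", sum(constant), " constant row(s): ",
            paste(utils::head(rownames(values)[constant], 3L), collapse = ", "))
    values <- values[!constant, , drop = FALSE]
  }
  if (nrow(values) < 2L) stop("need at least 2 non-constant rows to cluster")
  values <- values[order(rownames(values)), , drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(t(values)))
  stats::hclust(d, method = method)
}
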