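#' Select a repressed-gene signature from a differential-expression table
#'
#' Keeps genes with repression ratio above `fc_threshold` and adjusted
#' p-value below `q_threshold`, ordered by repression ratio descending.
#' All signature genes are repressed by the same miRNA, so default
#' weights are uniform (+1); `weights = "log2_ratio"` weights each gene
#' by the log2 of its repression ratio instead.
#'
#' @param changes Change table with `gene_id`, `fold_change` (repression
#'   ratio) or `log2fc`, and `q` (or `p`).
#' @param fc_threshold Repression-ratio cutoff (default 2).
#' @param q_threshold Adjusted-p cutoff (default 0.05).
#' @param weights `"equal"`, `"log2_ratio"`, or a numeric vector named by
#'   gene.
#' @return Object of class `signature_geneset`: list with `genes`,
#'   `weights` (named numeric) and the thresholds used.
#' @export
select_signature <- function(changes, fc_threshold = 2, q_threshold = 0.05,
                             weights = c("equal", "log2_ratio")) {
  stopifnot(fc_threshold >= 0, q_threshold > 0)
  changes <- as_change_table(changes)
  ratio <- 2^(-changes$log2fc)
  sel <- ratio > fc_threshold & changes$q < q_threshold
  if (!any(sel)) {
    stop("no gene passes fold-change > ", fc_threshold, " and q < ", q_threshold,
         "; signature is empty")
  }
  genes <- changes$gene_id[sel][order(-ratio[sel])]
  if (is.numeric(weights)) {
    if (is.null(names(weights)) || !all(genes %in% names(weights))) {
      stop("numeric weights must be named and cover every signature gene")
    }
    w <- weights[genes]
  } else {
    weights <- match.arg(weights)
    w <- if (weights == "equal") stats::setNames(rep(1, length(genes)), genes)
         else stats::setNames(sort(log2(ratio[sel]), decreasing = TRUE), genes)
  }
  if (all(w == 0)) stop("signature weights must not all be zero")
  structure(list(genes = genes, weights = w,
                 fc_threshold = fc_threshold, q_threshold = q_threshold),
            class = "signature_geneset")
}

#' @export
print.signature_geneset <- function(x, ...) {
  cat(sprintf("Gene signature: %d genes (repression ratio > %g, q < %g)\n",
              length(x$genes), x$fc_threshold, x$q_threshold))
  cat("  ", paste(utils::head(x$genes, 8), collapse = ", "),
      if (length(x$genes) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Weighted-average signature score per sample
#'
#' Each signature gene's expression is standardised across samples (mean
#' 0, sample standard deviation with the n-1 denominator); the score of
#' sample s is `sum_g w_g z_gs / sum_g |w_g|`. Signature genes absent
#' from the matrix, or with zero variance, are excluded with a warning.
#'
#' @param expr Gene x sample numeric matrix.
#' @param signature A [select_signature()] object (or a character vector
#'   of genes, weighted equally).
#' @return Named numeric vector of per-sample scores.
#' @export
signature_score <- function(expr, signature) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (is.character(signature)) {
    signature <- structure(list(genes = signature,
                                weights = stats::setNames(rep(1, length(signature)),
                                                          signature)),
                           class = "signature_geneset")
  }
  stopifnot(inherits(signature, "signature_geneset"))
  present <- signature$genes[signature$genes %in% rownames(expr)]
  if (length(present) < length(signature$genes)) {
    warning(length(signature$genes) - length(present),
            " signature gene(s) absent from the expression matrix")
  }
  if (length(present) == 0L) stop("no signature gene present in the expression matrix")
  sub <- expr[present, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    warning("excluding ", sum(sds == 0), " zero-variance signature gene(s)")
    sub <- sub[sds > 0, , drop = FALSE]
    if (nrow(sub) == 0L) stop("all present signature genes have zero variance")
  }
  z <- t(scale(t(sub)))
  w <- signature$weights[rownames(sub)]
  stats::setNames(as.numeric(colSums(w * z) / sum(abs(w))), colnames(expr))
}

#' Stratify samples into high/low score groups at a quantile
#'
#' Samples at or above the `1 - upper_fraction` quantile (type-7 linear
#' interpolation) are labelled `high`; threshold ties all go high.
#'
#' @param scores Named numeric vector of per-sample scores (>= 2 samples).
#' @param upper_fraction Fraction targeted for the high group (default
#'   0.25, i.e. top quartile vs bottom three quartiles).
#' @return Factor with levels `high`, `low`, named by sample.
#' @export
stratify_quantile <- function(scores, upper_fraction = 0.25) {
  stopifnot(is.numeric(scores), length(scores) >= 2L,
            upper_fraction > 0, upper_fraction < 1)
  if (stats::sd(scores) == 0) {
    stop("scores are constant; quantile stratification is meaningless")
  }
  thr <- stats::quantile(scores, probs = 1 - upper_fraction, type = 7, names = FALSE)
  factor(ifelse(scores >= thr, "high", "low"), levels = c("high", "low"))
}

as_survival_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("time", "event", "group") %in% names(records)))
  if (any(records$time < 0)) stop("survival times must be non-negative")
  if (!all(records$event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (event)")
  records
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimates via [survival::survfit()]; censored
#' observations reduce the at-risk count without a step.
#'
#' @param records `data.frame` with columns `time`, `event` (1 = event,
#'   0 = censored) and `group` (and optionally `sample_id`).
#' @return Object of class `km_curves`: a named list of per-group curves,
#'   each with `time`, `survival`, `at_risk` and `n_event` at every
#'   observed time (steps occur where `n_event > 0`).
#' @export
kaplan_meier <- function(records) {
  records <- as_survival_records(records)
  curves <- lapply(split(records, records$group), function(sub) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = sub)
    list(time = fit$time, survival = fit$surv, at_risk = fit$n.risk,
         n_event = fit$n.event)
  })
  structure(curves, class = "km_curves")
}

#' @export
print.km_curves <- function(x, ...) {
  for (g in names(x)) {
    ev <- x[[g]]$n_event > 0
    cat(sprintf("Group %s: %d times, %d events, final S = %.3f\n",
                g, length(x[[g]]$time), sum(x[[g]]$n_event),
                utils::tail(x[[g]]$survival, 1)))
  }
  invisible(x)
}

#' Median survival time from a KM curve
#'
#' Smallest observed time at which the survival estimate drops to 0.5 or
#' below; `Inf` when the curve never reaches 0.5.
#'
#' @param curve One element of a [kaplan_meier()] result.
#' @return Median survival time.
#' @export
km_median <- function(curve) {
  i <- which(curve$survival <= 0.5)
  if (length(i) == 0L) return(Inf)
  curve$time[min(i)]
}

#' Survival probability at given times from a KM curve
#' @param curve One element of a [kaplan_meier()] result.
#' @param times Times at which to evaluate the step function.
#' @return Survival probabilities (1 before the first observed time).
#' @export
km_survival_at <- function(curve, times) {
  vapply(times, function(t) {
    i <- which(curve$time <= t)
    if (length(i) == 0L) 1 else curve$survival[max(i)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' @param records As in [kaplan_meier()]; exactly two groups with at
#'   least one event in total.
#' @return List with `statistic` (chi-square, 1 df) and `p.value`.
#' @export
logrank_test <- function(records) {
  records <- as_survival_records(records)
  groups <- unique(records$group)
  if (length(groups) != 2L) stop("log-rank test needs exactly 2 groups, got ",
                                 length(groups))
  if (sum(records$event) < 1L) stop("log-rank test needs at least one event")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = records)
  list(statistic = fit$chisq,
       p.value = stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE))
}

#' Read a survival table from TSV
#' @param path TSV with columns `sample_id`, `time`, `event`.
#' @return `data.frame`.
#' @export
read_survival_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "time", "event") %in% names(df)))
  df
}

#' Export KM curves to a tidy TSV
#' @param curves A [kaplan_meier()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_km_curves <- function(curves, path) {
  rows <- do.call(rbind, lapply(names(curves), function(g) {
    data.frame(group = g, time = curves[[g]]$time,
               survival = curves[[g]]$survival, at_risk = curves[[g]]$at_risk,
               n_event = curves[[g]]$n_event, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
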