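#' Normalize an expression study
#'
#' Removes sample-level intensity offsets before testing. `median` shifts
#' each sample's log2 intensities so that every sample median equals the
#' global median; `quantile` equalizes the empirical intensity distributions
#' across samples (via limma's quantile normalization on the log2 scale);
#' `none` returns the study unchanged. The input study is not modified.
#'
#' @param study An [expression_study()] with strictly positive intensities.
#' @param method One of `"median"`, `"quantile"`, `"none"`.
#' @return A new `expression_study` with normalized intensities.
#' @export
normalize_study <- function(study, method = c("median", "quantile", "none")) {
  method <- match.arg(method)
  stopifnot(inherits(study, "expression_study"))
  if (method == "none") return(study)
  m <- study$intensities
  nonpos <- which(m <= 0, arr.ind = TRUE)
  if (nrow(nonpos))
    stop("domain error: non-positive intensity at probe ",
         rownames(m)[nonpos[1, 1]], ", sample ",
         colnames(m)[nonpos[1, 2]])
  l <- log2(m)
  l <- switch(method,
    median = {
      meds <- apply(l, 2, stats::median)
      sweep(l, 2, meds - stats::median(l))
    },
    quantile = {
      q <- limma::normalizeQuantiles(l)
      dimnames(q) <- dimnames(l)
      q
    })
  out <- study
  out$intensities <- 2^l
  out
}

#' Per-probe differential-expression statistics
#'
#' For every probe: log2 fold change = mean(log2 treated) - mean(log2
#' control), and a two-sided unequal-variance (Welch) t-test P-value on the
#' log2 intensities. Degenerate probes with zero variance in both groups get
#' P = 1 when the group means are equal and P = 0 otherwise.
#'
#' @param study An [expression_study()] with >= 2 replicates per group and
#'   strictly positive intensities.
#' @return An unfiltered [signature_table()] (one row per probe) with
#'   `background_size` set to the probe count.
#' @export
probe_statistics <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  tr <- study$group_labels == "treated"
  ct <- study$group_labels == "control"
  n1 <- sum(tr); n2 <- sum(ct)
  if (n1 < 2L || n2 < 2L)
    stop("need >= 2 replicates per group for a variance estimate")
  m <- study$intensities
  if (any(m <= 0))
    stop("domain error: non-positive intensity; normalize/filter first")
  l <- log2(m)
  x1 <- l[, tr, drop = FALSE]; x2 <- l[, ct, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  lfc <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  tstat <- lfc / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(lfc[degenerate] == 0, 1, 0)
  # t-test can return exact 0 only in the degenerate case; clamp for the
  # (0, 1] p-value contract of signature tables
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  map <- stats::setNames(study$probe_gene_map$gene_id,
                         study$probe_gene_map$probe_id)
  signature_table(rownames(m), unname(map[rownames(m)]), lfc, p,
                  background_size = nrow(m))
}

#' Filter probe statistics into a significance signature
#'
#' Keeps exactly the probes with P-value below `alpha` and sorts the result
#' by ascending P-value, ties broken by descending absolute fold change,
#' then probe id. No multiple-testing correction is applied by default (the
#' signature is defined by raw P < alpha); Benjamini-Hochberg adjustment is
#' available as an opt-in.
#'
#' @param stats A [signature_table()] of per-probe statistics (e.g. from
#'   [probe_statistics()]).
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param background_size Probes surveyed; defaults to the table's own
#'   background size, or its row count if unset.
#' @param adjust `"none"` (default) or `"BH"`: filter on BH-adjusted
#'   P-values instead of raw ones.
#' @return A filtered `signature_table` with `alpha` and `background_size`
#'   recorded.
#' @export
build_signature <- function(stats, alpha = 0.05, background_size = NULL,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(stats, "signature_table"))
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (is.null(background_size)) {
    background_size <- attr(stats, "background_size")
    if (is.na(background_size)) background_size <- nrow(stats)
  }
  crit <- if (adjust == "BH") stats::p.adjust(stats$p_value, "BH")
          else stats$p_value
  keep <- crit < alpha
  out <- stats[keep, , drop = FALSE]
  ord <- order(out$p_value, -abs(out$log2fc), out$probe_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "background_size") <- as.integer(background_size)
  attr(out, "alpha") <- alpha
  class(out) <- c("signature_table", "data.frame")
  out
}

#' Collapse a probe-level signature to gene level
#'
#' Keeps one entry per gene: among multiple probes of the same gene the one
#' with the smallest P-value wins (ties: largest absolute fold change, then
#' probe id). Idempotent.
#'
#' @param sig A [signature_table()] with gene ids on every row.
#' @return A gene-level `signature_table` (one row per distinct gene).
#' @export
collapse_to_genes <- function(sig) {
  stopifnot(inherits(sig, "signature_table"))
  if (any(is.na(sig$gene_id) | !nzchar(sig$gene_id)))
    stop("gene_id must be present on every entry")
  if (!nrow(sig)) return(sig)
  # pick the winning probe per gene, then keep the table's original row order
  ord <- order(sig$p_value, -abs(sig$log2fc), sig$probe_id, method = "radix")
  winner_rows <- ord[!duplicated(sig$gene_id[ord])]
  out <- sig[sort(winner_rows), , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("background_size", "alpha")) attr(out, a) <- attr(sig, a)
  class(out) <- c("signature_table", "data.frame")
  out
}

#' Summarize the regulation direction of a signature
#'
#' Counts up- and down-regulated entries (by sign of the log2 fold change)
#' and reports percentages to one decimal.
#'
#' @param sig A non-empty [signature_table()].
#' @return A list of class `direction_summary` with `n_up`, `n_down`,
#'   `pct_up`, `pct_down`.
#' @export
summarize_direction <- function(sig) {
  stopifnot(inherits(sig, "signature_table"))
  if (!nrow(sig)) stop("empty signature: direction percentages undefined")
  n_up <- sum(sig$log2fc > 0)
  n_down <- sum(sig$log2fc < 0)
  structure(list(n_up = n_up, n_down = n_down,
                 pct_up = round(100 * n_up / (n_up + n_down), 1),
                 pct_down = round(100 * n_down / (n_up + n_down), 1)),
            class = "direction_summary")
}

#' @export
print.direction_summary <- function(x, ...) {
  cat(sprintf("direction: %d up (%.1f%%), %d down (%.1f%%)\n",
              x$n_up, x$pct_up, x$n_down, x$pct_down))
  invisible(x)
}
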