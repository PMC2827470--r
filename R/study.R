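#' Two-condition replicate expression study
#'
#' Container for a probes-by-samples intensity matrix with treated/control
#' group labels, a probe-to-gene map, and — when the study is synthetic —
#' the planted truth needed to score recovery.
#'
#' @param intensities Non-negative numeric matrix, probes in rows (unique
#'   rownames), samples in columns.
#' @param group_labels Character vector, one of `"treated"`/`"control"` per
#'   sample; both groups must be non-empty.
#' @param probe_gene_map A [probe_map()] covering every probe.
#' @param truth Optional list with elements `signature_probes`,
#'   `true_log2fc` (named by probe), `enriched_pathways`,
#'   `concordance_labels`.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(intensities, group_labels, probe_gene_map,
                             truth = NULL) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)) || anyDuplicated(rownames(intensities)))
    stop("intensity matrix needs unique probe rownames")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  group_labels <- as.character(group_labels)
  if (length(group_labels) != ncol(intensities))
    stop("every sample needs a group label")
  if (!all(group_labels %in% c("treated", "control")))
    stop("group labels must be 'treated' or 'control'")
  if (!all(c("treated", "control") %in% group_labels))
    stop("both groups must be non-empty")
  stopifnot(inherits(probe_gene_map, "probe_map"))
  missing <- setdiff(rownames(intensities), probe_gene_map$probe_id)
  if (length(missing))
    stop("probe map misses ", length(missing), " probe(s), e.g. ", missing[1])
  structure(list(intensities = intensities,
                 group_labels = group_labels,
                 probe_gene_map = probe_gene_map,
                 truth = truth),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d probes x %d samples (%d treated, %d control)%s\n",
              nrow(x$intensities), ncol(x$intensities),
              sum(x$group_labels == "treated"),
              sum(x$group_labels == "control"),
              if (!is.null(x$truth)) ", with planted truth" else ""))
  invisible(x)
}
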