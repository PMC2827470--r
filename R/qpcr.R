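#' qPCR panel container
#'
#' Long-format Ct table: one row per gene, condition and replicate, with
#' threshold cycles for the target gene and the internal-control reference
#' gene measured in the same reaction plate.
#'
#' @param gene,condition Character vectors; condition in
#'   `"treated"`/`"control"`.
#' @param replicate Integer replicate index.
#' @param ct_target,ct_reference Finite threshold-cycle values.
#' @return A data.frame of class `qpcr_panel`.
#' @export
qpcr_panel <- function(gene, condition, replicate, ct_target, ct_reference) {
  condition <- as.character(condition)
  if (!all(condition %in% c("treated", "control")))
    stop("condition must be 'treated' or 'control'")
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("Ct values must be finite")
  structure(data.frame(gene = as.character(gene), condition = condition,
                       replicate = as.integer(replicate),
                       ct_target = as.numeric(ct_target),
                       ct_reference = as.numeric(ct_reference),
                       stringsAsFactors = FALSE),
            class = c("qpcr_panel", "data.frame"))
}

#' Read / write a qPCR Ct table (CSV)
#'
#' Columns: `gene`, `condition`, `replicate`, `ct_target`, `ct_reference`.
#'
#' @param path Path to a CSV file.
#' @return A [qpcr_panel()].
#' @export
read_qpcr_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  req <- c("gene", "condition", "replicate", "ct_target", "ct_reference")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("format error: missing required column '", miss[1], "' in ", path)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v)))
      stop("parse error: non-numeric ", col, " at line ",
           which(is.na(v))[1] + 1L, " of ", path)
    v
  }
  qpcr_panel(df$gene, df$condition, num("replicate"), num("ct_target"),
             num("ct_reference"))
}

#' @rdname read_qpcr_csv
#' @param panel A [qpcr_panel()].
#' @export
write_qpcr_csv <- function(panel, path) {
  stopifnot(inherits(panel, "qpcr_panel"))
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Delta-delta-Ct log2 fold changes
#'
#' For each gene: delta-Ct = mean(Ct_target) - mean(Ct_reference) within each
#' condition (replicate Cts averaged before differencing); the log2 fold
#' change is -(delta-Ct_treated - delta-Ct_control), i.e. fold = 2^(-ddCt)
#' under the standard 100%-amplification-efficiency assumption.
#'
#' @param panel A [qpcr_panel()] with both conditions present for every
#'   gene.
#' @return data.frame with columns `gene`, `qpcr_log2fc`.
#' @examples
#' p <- qpcr_panel("g1", c("treated", "control"), c(1L, 1L),
#'                 c(20, 22), c(15, 15))
#' ddct(p)  # log2fc = 2 (4-fold up)
#' @export
ddct <- function(panel) {
  stopifnot(inherits(panel, "qpcr_panel"))
  genes <- unique(panel$gene)
  lfc <- vapply(genes, function(g) {
    sub <- panel[panel$gene == g, , drop = FALSE]
    for (cond in c("treated", "control"))
      if (!any(sub$condition == cond))
        stop("missing condition '", cond, "' for gene ", g)
    dct <- vapply(c("treated", "control"), function(cond) {
      s <- sub[sub$condition == cond, , drop = FALSE]
      mean(s$ct_target) - mean(s$ct_reference)
    }, numeric(1))
    -(dct[["treated"]] - dct[["control"]])
  }, numeric(1))
  data.frame(gene = genes, qpcr_log2fc = unname(lfc),
             stringsAsFactors = FALSE)
}

#' Validate an array signature against a qPCR panel
#'
#' Pairs each shared gene's array log2 fold change with its delta-delta-Ct
#' log2 fold change and quantifies agreement by the Pearson product-moment
#' correlation (reported as r and R^2).
#'
#' @param array_sig A [signature_table()]; collapsed to gene level if
#'   needed.
#' @param panel A [qpcr_panel()] sharing at least 3 genes with the
#'   signature.
#' @return A list of class `validation_report` with `per_gene` (data.frame
#'   `gene`, `array_log2fc`, `qpcr_log2fc`), `pearson_r`, `r_squared`.
#' @export
validate_panel <- function(array_sig, panel) {
  stopifnot(inherits(array_sig, "signature_table"))
  q <- ddct(panel)
  sig <- collapse_to_genes(array_sig)
  shared <- intersect(sig$gene_id, q$gene)
  if (length(shared) < 3L)
    stop("need >= 3 genes shared between panel and signature, got ",
         length(shared))
  a <- stats::setNames(sig$log2fc, sig$gene_id)[shared]
  b <- stats::setNames(q$qpcr_log2fc, q$gene)[shared]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: zero variance in a fold-change vector")
  r <- stats::cor(a, b)
  structure(list(per_gene = data.frame(gene = shared,
                                       array_log2fc = unname(a),
                                       qpcr_log2fc = unname(b),
                                       stringsAsFactors = FALSE),
                 pearson_r = r, r_squared = r^2),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("qPCR validation: %d genes, Pearson r = %.3f, R^2 = %.3f\n",
              nrow(x$per_gene), x$pearson_r, x$r_squared))
  invisible(x)
}
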