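#' Synthetic signature fixture with a prescribed marginal structure
#'
#' Constructs a synthetic probe-level signature table with exact marginal
#' counts: total probes, distinct genes (the excess probes become second
#' probes of the first genes), and upregulated probes. Fold-change
#' magnitudes and P-values are drawn reproducibly from the seed; the
#' structure (counts, signs, probe/gene multiplicity) is deterministic.
#' Defaults mirror the scale of a whole-genome induction signature: 961
#' probes over 955 genes on a 27,868-probe array, 870 up / 91 down (90.5%
#' up). Useful for validating the parse / collapse / direction / partition
#' operations against a known tabular structure.
#'
#' @param n_probes Total signature rows.
#' @param n_genes Distinct genes (<= `n_probes`).
#' @param n_up Upregulated rows (<= `n_probes`).
#' @param background_size Probes surveyed on the array.
#' @param alpha Significance level all rows satisfy.
#' @param seed Integer seed.
#' @return A [signature_table()].
#' @export
synthetic_signature_fixture <- function(n_probes = 961L, n_genes = 955L,
                                        n_up = 870L,
                                        background_size = 27868L,
                                        alpha = 0.05, seed = 1L) {
  stopifnot(n_genes <= n_probes, n_up <= n_probes,
            n_probes - n_genes <= n_genes)
  set.seed(seed)
  gene_ids <- sprintf("G%06d", seq_len(n_genes))
  # duplicate probes attach to the last genes so gene collapse is exercised;
  # they keep their gene's sign so probe- and gene-level directions agree
  extra <- n_probes - n_genes
  dup_idx <- if (extra > 0) n_genes - seq_len(extra) + 1L else integer()
  genes <- c(gene_ids, gene_ids[dup_idx])
  probes <- sprintf("P%06d", seq_len(n_probes))
  sgn <- rep(c(1, -1), c(n_up, n_probes - n_up))
  if (extra > 0) sgn[n_genes + seq_len(extra)] <- sgn[dup_idx]
  mag <- pmax(abs(stats::rnorm(n_probes, 2, 0.5)), 1e-6)
  p <- stats::runif(n_probes, 1e-8, alpha * 0.999)
  build_signature(
    signature_table(probes, genes, sgn * mag, p,
                    background_size = background_size),
    alpha = alpha, background_size = background_size)
}

#' Synthetic co-regulation fixture for cross-condition partitions
#'
#' Given a gene-level signature, selects two overlapping subsets of its
#' genes with exact partition counts (`n_both` in both subsets, `n_only_a`
#' / `n_only_b` exclusive) and returns them as gene-level signature tables
#' restricted to those genes — the structure produced when a signature is
#' co-filtered against two other conditions' regulated-gene lists.
#'
#' @param gene_sig A gene-level [signature_table()].
#' @param n_both,n_only_a,n_only_b Exact partition counts; their sum must
#'   not exceed the signature's gene count.
#' @param seed Integer seed for which genes land in which class.
#' @return A list with gene-level `sig_a`, `sig_b` ([signature_table()]s)
#'   and the `genes_both`, `genes_only_a`, `genes_only_b` id vectors.
#' @export
synthetic_coregulation_fixture <- function(gene_sig, n_both = 50L,
                                           n_only_a = 90L, n_only_b = 64L,
                                           seed = 1L) {
  stopifnot(inherits(gene_sig, "signature_table"))
  if (anyDuplicated(gene_sig$gene_id)) stop("gene-level signature required")
  total <- n_both + n_only_a + n_only_b
  if (total > nrow(gene_sig))
    stop("partition counts exceed the signature's gene count")
  set.seed(seed)
  chosen <- sample(gene_sig$gene_id, total)
  genes_both <- chosen[seq_len(n_both)]
  genes_only_a <- chosen[n_both + seq_len(n_only_a)]
  genes_only_b <- chosen[n_both + n_only_a + seq_len(n_only_b)]
  subset_sig <- function(genes) {
    out <- gene_sig[gene_sig$gene_id %in% genes, , drop = FALSE]
    rownames(out) <- NULL
    for (a in c("background_size", "alpha"))
      attr(out, a) <- attr(gene_sig, a)
    class(out) <- c("signature_table", "data.frame")
    out
  }
  list(sig_a = subset_sig(c(genes_both, genes_only_a)),
       sig_b = subset_sig(c(genes_both, genes_only_b)),
       genes_both = genes_both,
       genes_only_a = genes_only_a,
       genes_only_b = genes_only_b)
}
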