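#' Map a signature onto a shared gene namespace
#'
#' Translates probe-level entries to gene ids through a platform probe map
#' and retains entries whose gene is present in the target universe (the set
#' of genes representable on the other platform). When several probes map to
#' one gene the smallest P-value wins. Idempotent on already-mapped tables.
#'
#' @param sig A [signature_table()].
#' @param source_map A [probe_map()] for the signature's platform. Probes
#'   absent from the map are counted as unmapped, not an error.
#' @param target_universe Non-empty character vector of gene ids.
#' @return A list with `table` (the mapped, gene-collapsed
#'   `signature_table`, probe ids replaced by gene ids) and
#'   `mapped_fraction` (retained / total entries).
#' @export
map_signature <- function(sig, source_map, target_universe) {
  stopifnot(inherits(sig, "signature_table"), inherits(source_map, "probe_map"))
  target_universe <- unique(as.character(target_universe))
  if (!length(target_universe)) stop("empty target_universe")
  n_total <- nrow(sig)
  lookup <- stats::setNames(source_map$gene_id, source_map$probe_id)
  gene <- unname(lookup[sig$probe_id])
  keep <- !is.na(gene) & gene %in% target_universe
  mapped <- sig[keep, , drop = FALSE]
  mapped$gene_id <- gene[keep]
  mapped$probe_id <- mapped$gene_id
  mapped <- collapse_to_genes(mapped)
  list(table = mapped,
       mapped_fraction = if (n_total) nrow(sig[keep, ]) / n_total else NA_real_)
}

#' Disjoint Venn partition of 2 or 3 labeled gene sets
#'
#' Decomposes the union of the input sets into the standard disjoint Venn
#' regions with stable labels `A`, `B` (`C`), `AB` (`AC`, `BC`, `ABC`),
#' where a single letter means "in that set only".
#'
#' @param sets Named list of 2 or 3 character vectors; names must be unique.
#' @return A list of class `venn_partition` with `regions` (label -> gene
#'   vector), `counts` (named integer) and `set_labels`.
#' @examples
#' venn_partition(list(TAF9 = c("g1", "g3"), TAF9b = c("g2", "g3")))$counts
#' @export
venn_partition <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L)
    stop("need 2 or 3 labeled sets")
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(!nzchar(names(sets))))
    stop("sets must carry unique non-empty labels")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  letters_used <- LETTERS[seq_along(sets)]
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  region_of <- apply(membership, 1L, function(row)
    paste(letters_used[row], collapse = ""))
  all_regions <- unlist(lapply(seq_along(sets), function(k)
    utils::combn(letters_used, k, paste, collapse = "")))
  regions <- lapply(all_regions, function(r) universe[region_of == r])
  names(regions) <- all_regions
  structure(list(regions = regions,
                 counts = vapply(regions, length, integer(1)),
                 set_labels = stats::setNames(names(sets), letters_used)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition of", paste(x$set_labels, collapse = ", "), "\n")
  print(x$counts)
  invisible(x)
}

#' Direction concordance between two gene-level signatures
#'
#' Over the genes significant in both signatures, classifies each gene as
#' same-direction (equal fold-change signs) or opposite-direction, and
#' reports the same-direction fraction. When one signature comes from a
#' depletion experiment compared against an induction, `orientation_b =
#' "inverted"` flips the second signature's signs before comparison.
#'
#' @param sig_a,sig_b Gene-level [signature_table()]s.
#' @param orientation_b `"as-is"` (default) or `"inverted"`.
#' @return A list of class `concordance_report` with `fraction_same`,
#'   `same` and `opposite` gene vectors, and `n_shared`.
#' @export
concordance <- function(sig_a, sig_b, orientation_b = c("as-is", "inverted")) {
  orientation_b <- match.arg(orientation_b)
  stopifnot(inherits(sig_a, "signature_table"),
            inherits(sig_b, "signature_table"))
  if (anyDuplicated(sig_a$gene_id) || anyDuplicated(sig_b$gene_id))
    stop("gene-level tables required: collapse_to_genes() first")
  shared <- intersect(sig_a$gene_id, sig_b$gene_id)
  if (!length(shared)) stop("zero shared genes: fraction undefined")
  fa <- stats::setNames(sig_a$log2fc, sig_a$gene_id)[shared]
  fb <- stats::setNames(sig_b$log2fc, sig_b$gene_id)[shared]
  if (orientation_b == "inverted") fb <- -fb
  same <- sign(fa) == sign(fb)
  structure(list(fraction_same = mean(same),
                 same = shared[same],
                 opposite = shared[!same],
                 n_shared = length(shared)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance: %d shared genes, %.1f%% same-direction\n",
              x$n_shared, 100 * x$fraction_same))
  invisible(x)
}

#' Condition-crosstalk partition of two signatures
#'
#' Classifies genes by which condition(s) they are significantly regulated
#' in: only the first, only the second, or both, with percentages relative
#' to a chosen reference set (the union, or the first signature alone —
#' useful when asking what fraction of one condition's targets depend on
#' the other condition).
#'
#' @param sig_1,sig_2 Gene-level [signature_table()]s, at least one
#'   non-empty.
#' @param reference `"union"` (default) or `"condition1"`.
#' @return A list of class `crosstalk_partition` with `classes` (gene
#'   vectors `only_1`, `only_2`, `both`) and `percentages` relative to the
#'   reference.
#' @export
crosstalk_partition <- function(sig_1, sig_2,
                                reference = c("union", "condition1")) {
  reference <- match.arg(reference)
  stopifnot(inherits(sig_1, "signature_table"),
            inherits(sig_2, "signature_table"))
  g1 <- unique(sig_1$gene_id); g2 <- unique(sig_2$gene_id)
  if (!length(g1) && !length(g2)) stop("both signatures empty")
  classes <- list(only_1 = setdiff(g1, g2),
                  only_2 = setdiff(g2, g1),
                  both = intersect(g1, g2))
  ref_n <- switch(reference,
                  union = length(union(g1, g2)),
                  condition1 = length(g1))
  if (ref_n == 0L) stop("reference set is empty")
  structure(list(classes = classes,
                 percentages = vapply(classes, function(s)
                   100 * length(s) / ref_n, numeric(1)),
                 reference = reference),
            class = "crosstalk_partition")
}

#' @export
print.crosstalk_partition <- function(x, ...) {
  cat(sprintf("crosstalk (reference = %s): only_1 %.1f%%, only_2 %.1f%%, both %.1f%%\n",
              x$reference, x$percentages[["only_1"]],
              x$percentages[["only_2"]], x$percentages[["both"]]))
  invisible(x)
}

#' Gene-by-signature fold-change matrix for heat-map export
#'
#' Rows are the union of genes across the signatures, ordered by the first
#' signature's log2 fold change (descending; genes absent from the first
#' signature follow, ordered by id). Cells where a gene is absent from a
#' signature hold 0 and are flagged in a logical missingness mask — they are
#' masked, never imputed.
#'
#' @param signatures Ordered named list of gene-level [signature_table()]s.
#' @return A list of class `foldchange_matrix` with `log2fc` (numeric
#'   matrix) and `missing` (logical matrix of the same shape).
#' @export
foldchange_matrix <- function(signatures) {
  if (!is.list(signatures) || !length(signatures))
    stop("need a non-empty list of signatures")
  if (is.null(names(signatures)))
    names(signatures) <- paste0("S", seq_along(signatures))
  for (s in signatures) {
    stopifnot(inherits(s, "signature_table"))
    if (anyDuplicated(s$gene_id)) stop("gene-level tables required")
  }
  first <- signatures[[1]]
  rest <- sort(setdiff(unique(unlist(lapply(signatures, `[[`, "gene_id"))),
                       first$gene_id), method = "radix")
  genes <- c(first$gene_id[order(-first$log2fc, first$gene_id,
                                 method = "radix")], rest)
  fc <- sapply(signatures, function(s) {
    v <- stats::setNames(s$log2fc, s$gene_id)[genes]
    ifelse(is.na(v), 0, v)
  })
  miss <- sapply(signatures, function(s) !(genes %in% s$gene_id))
  fc <- matrix(fc, nrow = length(genes),
               dimnames = list(genes, names(signatures)))
  miss <- matrix(miss, nrow = length(genes),
                 dimnames = list(genes, names(signatures)))
  structure(list(log2fc = fc, missing = miss), class = "foldchange_matrix")
}
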