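#' Pathway annotation with inverse-membership gene weights
#'
#' A pathway annotation maps pathway ids to gene-id sets. Because one gene can
#' be assigned to several pathways, counting genes per pathway overstates the
#' evidence for genes with broad annotations. Each annotated gene g is
#' therefore weighted by 1/k(g), where k(g) is the number of pathways
#' containing g, so that every gene contributes exactly one unit of count in
#' total across all pathways ("weighted counts" can then be non-integer).
#'
#' @param sets Named list of character vectors (pathway id -> gene ids).
#'   Members are deduplicated; empty sets are rejected.
#' @param descriptions Optional character vector of pathway descriptions,
#'   recycled or named by pathway id.
#' @return An object of class `pathway_annotation`: a list with `sets`
#'   (named list of unique gene-id vectors), `membership_count` (named
#'   integer: gene -> k) and `weight` (named numeric: gene -> 1/k).
#' @examples
#' ann <- pathway_annotation(list(P1 = c("g1", "g2"), P2 = c("g2", "g3")))
#' ann$weight[["g2"]]  # 0.5: g2 sits in two pathways
#' @export
pathway_annotation <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a named list of gene-id vectors")
  if (anyDuplicated(names(sets)))
    stop("duplicate pathway ids: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  empty <- lengths(sets) == 0L
  if (any(empty))
    stop("empty pathway set(s): ", paste(names(sets)[empty], collapse = ", "))
  k <- table(unlist(sets, use.names = FALSE))
  membership <- stats::setNames(as.integer(k), names(k))
  weight <- 1 / membership
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(sets), names(sets))
  } else {
    if (is.null(names(descriptions)))
      descriptions <- stats::setNames(rep_len(descriptions, length(sets)),
                                      names(sets))
    descriptions <- descriptions[names(sets)]
  }
  structure(list(sets = sets,
                 membership_count = membership,
                 weight = weight,
                 descriptions = descriptions),
            class = "pathway_annotation")
}

#' Genes annotated to at least one pathway
#' @param ann A `pathway_annotation`.
#' @return Character vector of annotated gene ids.
#' @export
annotated_genes <- function(ann) {
  stopifnot(inherits(ann, "pathway_annotation"))
  names(ann$membership_count)
}

#' @export
print.pathway_annotation <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("pathway_annotation: %d pathways, %d annotated genes\n",
              length(x$sets), length(x$membership_count)))
  cat(sprintf("  set sizes: %d-%d (median %g); genes in >1 pathway: %d\n",
              min(sz), max(sz), stats::median(sz),
              sum(x$membership_count > 1L)))
  invisible(x)
}
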