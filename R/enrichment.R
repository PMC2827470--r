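#' Upper tail of a binomial distribution with a continuous extension
#'
#' Returns Pr(X >= w) for X ~ Binomial(n, p). Inverse-membership weighting
#' makes observed pathway counts non-integer, so the tail is evaluated through
#' the regularized incomplete beta function, I_p(w, n - w + 1), which
#' coincides with the exact binomial sum at every integer w and interpolates
#' monotonically in between. `w <= 0` returns 1 exactly.
#'
#' @param n Number of trials (>= 1).
#' @param p Success probability in \[0, 1\].
#' @param w Observed count, possibly non-integer, in \[0, n\].
#' @return Pr(X >= w), a probability. Vectorized over `w` and `p`.
#' @examples
#' binomial_tail(10, 0.5, 10)        # 0.5^10
#' binomial_tail(4, 0.25, 3)         # 0.05078125
#' binomial_tail(20, 0.2, 2.5)       # continuous interpolation
#' @export
binomial_tail <- function(n, p, w) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  if (any(w > n)) stop("domain error: observed count w exceeds n")
  out <- numeric(length(w))
  len <- max(length(w), length(p))
  w <- rep_len(w, len); p <- rep_len(p, len); n <- rep_len(n, len)
  out <- ifelse(w <= 0, 1, stats::pbeta(p, pmax(w, .Machine$double.xmin),
                                        n - w + 1))
  as.numeric(out)
}

#' Pathway overrepresentation with weighted counts and a binomial null
#'
#' For each pathway P, the observed count is the sum of inverse-membership
#' weights of signature genes in P; the expected count is the signature size
#' times the weighted fraction of the background annotated to P; the P-value
#' is the upper binomial tail Pr(X >= count) with X ~ Binomial(|signature|,
#' S_P / |background|) where S_P is the weighted background count of P. The
#' null model is a random gene set of identical size drawn from the array
#' background.
#'
#' @param sig_genes Character vector: the regulated (signature) gene set.
#' @param background Character vector: the array universe of genes. Must be a
#'   superset of `sig_genes`.
#' @param ann A [pathway_annotation()].
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param adjust Multiple-testing adjustment for the `p_adjusted` column:
#'   `"none"` (default; significance filtering uses raw P) or `"BH"`.
#' @return A data.frame of class `enrichment_result`, one row per pathway,
#'   with columns `pathway`, `count` (weighted, possibly non-integer),
#'   `expect`, `p_value`, `p_adjusted`, `significant`, sorted by ascending
#'   `p_value` with ties broken by pathway id.
#' @export
overrepresentation <- function(sig_genes, background, ann, alpha = 0.05,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(ann, "pathway_annotation"))
  sig_genes <- unique(as.character(sig_genes))
  background <- unique(as.character(background))
  if (!length(background)) stop("background must be non-empty")
  missing_bg <- setdiff(sig_genes, background)
  if (length(missing_bg))
    stop("null model ill-defined: ", length(missing_bg),
         " signature gene(s) absent from background, e.g. ", missing_bg[1])
  n_sig <- length(sig_genes)
  n_bg <- length(background)
  w <- ann$weight
  count <- vapply(ann$sets, function(members) {
    hit <- intersect(members, sig_genes)
    if (length(hit)) sum(w[hit]) else 0
  }, numeric(1))
  s_p <- vapply(ann$sets, function(members) {
    hit <- intersect(members, background)
    if (length(hit)) sum(w[hit]) else 0
  }, numeric(1))
  p_null <- s_p / n_bg
  expect <- n_sig * p_null
  # weighted counts can exceed n*p_null's support ceiling only by fp error
  p_value <- binomial_tail(n_sig, p_null, pmin(count, n_sig))
  res <- data.frame(pathway = names(ann$sets),
                    count = count,
                    expect = expect,
                    p_value = p_value,
                    stringsAsFactors = FALSE, row.names = NULL)
  res$p_adjusted <- if (adjust == "BH") stats::p.adjust(res$p_value, "BH") else res$p_value
  crit <- if (adjust == "BH") res$p_adjusted else res$p_value
  res$significant <- crit < alpha
  res <- res[order(res$p_value, res$pathway, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  attr(res, "n_signature") <- n_sig
  attr(res, "n_background") <- n_bg
  attr(res, "alpha") <- alpha
  res
}

#' Pathway-pair interconnectivity
#'
#' Tests, for every unordered pair of selected pathways, whether the genes
#' shared by the two pathways are overrepresented among the regulated genes.
#' The shared background is the set of array genes annotated to both
#' pathways; the observed statistic is the number of regulated genes among
#' them; the P-value is the same binomial upper tail used for single-pathway
#' overrepresentation. Links are tiered: `high` (P < 0.05), `significant`
#' (P < 0.10), `low` otherwise. Pairs sharing fewer than 2 regulated genes
#' are reported with tier `low` and flagged unassessed.
#'
#' @param selected Character vector of pathway ids to test pairwise.
#' @param sig_genes,background,ann As in [overrepresentation()].
#' @param weighted If `TRUE`, shared counts are inverse-membership weighted
#'   like single-pathway counts; the default `FALSE` uses plain gene counts
#'   for the shared sets.
#' @param tiers Numeric `c(high, significant)` P-value thresholds.
#' @return A data.frame of class `pair_links`: columns `pathway_a`,
#'   `pathway_b`, `shared_regulated`, `shared_background`, `p_value`, `tier`,
#'   `assessed`, sorted by ascending `p_value`.
#' @export
interconnectivity <- function(selected, sig_genes, background, ann,
                              weighted = FALSE, tiers = c(0.05, 0.10)) {
  stopifnot(inherits(ann, "pathway_annotation"))
  selected <- unique(as.character(selected))
  missing <- setdiff(selected, names(ann$sets))
  if (length(missing))
    stop("selected pathway(s) not in annotation: ",
         paste(missing, collapse = ", "))
  sig_genes <- unique(as.character(sig_genes))
  background <- unique(as.character(background))
  n_sig <- length(sig_genes)
  n_bg <- length(background)
  empty <- data.frame(pathway_a = character(), pathway_b = character(),
                      shared_regulated = numeric(),
                      shared_background = numeric(),
                      p_value = numeric(), tier = character(),
                      assessed = logical(), stringsAsFactors = FALSE)
  if (length(selected) < 2L) {
    class(empty) <- c("pair_links", "data.frame")
    return(empty)
  }
  pairs <- utils::combn(sort(selected), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    shared <- intersect(ann$sets[[a]], ann$sets[[b]])
    shared_bg_genes <- intersect(shared, background)
    shared_reg_genes <- intersect(shared, sig_genes)
    n_reg_genes <- length(shared_reg_genes)
    if (weighted) {
      shared_bg <- if (length(shared_bg_genes)) sum(ann$weight[shared_bg_genes]) else 0
      shared_reg <- if (n_reg_genes) sum(ann$weight[shared_reg_genes]) else 0
    } else {
      shared_bg <- as.numeric(length(shared_bg_genes))
      shared_reg <- as.numeric(n_reg_genes)
    }
    if (shared_bg == 0 && shared_reg > 0)
      stop("consistency error: pair (", a, ", ", b,
           ") has regulated shared genes outside the shared background")
    p <- if (n_sig == 0L) 1 else
      binomial_tail(n_sig, shared_bg / n_bg, pmin(shared_reg, n_sig))
    data.frame(pathway_a = a, pathway_b = b,
               shared_regulated = shared_reg, shared_background = shared_bg,
               p_value = p, n_shared_regulated_genes = n_reg_genes,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$assessed <- res$n_shared_regulated_genes >= 2L
  res$tier <- ifelse(!res$assessed, "low",
                     ifelse(res$p_value < tiers[1], "high",
                            ifelse(res$p_value < tiers[2], "significant",
                                   "low")))
  res$n_shared_regulated_genes <- NULL
  res <- res[order(res$p_value, res$pathway_a, res$pathway_b,
                   method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res <- res[, c("pathway_a", "pathway_b", "shared_regulated",
                 "shared_background", "p_value", "tier", "assessed")]
  class(res) <- c("pair_links", "data.frame")
  res
}

#' Build a Pajek network of overrepresented pathways
#'
#' Vertices are the significant pathways of an enrichment result, colored by
#' the tier of their strongest (smallest-P) incident link; edges are the
#' interconnectivity links with at least 2 shared regulated genes, weighted
#' by the shared regulated-gene count.
#'
#' @param results An `enrichment_result` from [overrepresentation()].
#' @param links A `pair_links` table from [interconnectivity()].
#' @param colors Named character vector mapping tiers (and `"none"` for
#'   unlinked vertices) to Pajek color tokens.
#' @return A [pajek_network()].
#' @export
pathway_network <- function(results, links,
                            colors = c(high = "Red", significant = "Orange",
                                       low = "Gray", none = "Gray")) {
  stopifnot(inherits(results, "enrichment_result"))
  vertices <- results$pathway[results$significant]
  dangling <- setdiff(unique(c(links$pathway_a, links$pathway_b)),
                      results$pathway)
  if (length(dangling))
    stop("validation error: link endpoint(s) not in enrichment results: ",
         paste(dangling, collapse = ", "))
  keep <- links$shared_regulated >= 2 &
    links$pathway_a %in% vertices & links$pathway_b %in% vertices
  el <- links[keep, , drop = FALSE]
  vcol <- vapply(vertices, function(v) {
    inc <- el[el$pathway_a == v | el$pathway_b == v, , drop = FALSE]
    if (!nrow(inc)) return(colors[["none"]])
    colors[[inc$tier[which.min(inc$p_value)]]]
  }, character(1))
  idx <- stats::setNames(seq_along(vertices), vertices)
  pajek_network(
    vertices = data.frame(id = seq_along(vertices), label = vertices,
                          color = unname(vcol), stringsAsFactors = FALSE),
    edges = data.frame(from = unname(idx[el$pathway_a]),
                       to = unname(idx[el$pathway_b]),
                       weight = el$shared_regulated)
  )
}
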