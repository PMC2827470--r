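#' Generate a synthetic two-condition expression study with planted truth
#'
#' Emulates a treated-vs-control array experiment in biological replicate:
#' per-probe baseline log2 intensities are drawn from N(8, 1.5) (a plausible
#' microarray scale), i.i.d. Gaussian noise of `noise_sd` is added per probe
#' and sample on the log2 scale, and a random set of `signature_size` probes
#' receives a planted signed log2 fold-change shift in the treated group.
#' Effect signs follow `frac_up` by exact quota; magnitudes are
#' |N(effect_log2fc_mean, effect_log2fc_sd)|. A configurable subset of genes
#' carries two probes (controlled by `n_genes`). Identical config + seed
#' reproduces the study bit-for-bit; random draws are made in a fixed order
#' (baseline, signature membership, effect magnitudes, noise).
#'
#' @param config A [simulation_config()].
#' @return An [expression_study()] whose `truth` holds `signature_probes`,
#'   `true_log2fc` (named by probe id) and `enriched_pathways` (the planted
#'   pathway ids with multiplier > 1).
#' @export
generate_study <- function(config) {
  validate_simulation_config(config)
  np <- config$n_probes; ng <- config$n_genes
  r <- config$replicates_per_group
  if (np - ng > ng)
    stop("configuration error: n_probes - n_genes extra probes exceed gene count")
  set.seed(config$seed)
  probe_ids <- sprintf("P%06d", seq_len(np))
  gene_ids <- sprintf("G%06d", seq_len(ng))
  # probes beyond the gene count become second probes of a random gene subset
  extra <- np - ng
  map_gene <- c(gene_ids,
                if (extra > 0) gene_ids[sample.int(ng, extra)] else character())
  pmap <- probe_map(probe_ids, map_gene, platform = "synthetic")
  baseline <- stats::rnorm(np, mean = 8, sd = 1.5)
  sig_idx <- sample.int(np, config$signature_size)
  n_up <- round(config$frac_up * config$signature_size)
  mag <- abs(stats::rnorm(config$signature_size, config$effect_log2fc_mean,
                          config$effect_log2fc_sd))
  mag <- pmax(mag, 1e-6)  # signature members must have nonzero fold change
  sgn <- rep(c(1, -1), c(n_up, config$signature_size - n_up))
  lfc <- numeric(np)
  lfc[sig_idx] <- sgn * mag
  n_samp <- 2L * r
  noise <- matrix(stats::rnorm(np * n_samp, 0, config$noise_sd), np, n_samp)
  logm <- baseline + noise
  logm[, seq_len(r)] <- logm[, seq_len(r)] + lfc
  intensities <- 2^logm
  dimnames(intensities) <- list(probe_ids,
                                c(paste0("treated_", seq_len(r)),
                                  paste0("control_", seq_len(r))))
  planted <- config$planted_enriched_pathways
  truth <- list(
    signature_probes = probe_ids[sig_idx],
    true_log2fc = stats::setNames(lfc[sig_idx], probe_ids[sig_idx]),
    enriched_pathways = names(planted)[planted > 1],
    concordance_labels = NULL)
  expression_study(intensities,
                   rep(c("treated", "control"), each = r),
                   pmap, truth = truth)
}

#' Generate an overlapping synthetic pathway annotation
#'
#' Draws `n_pathways` gene sets with sizes uniform in `pathway_size_range`
#' over the supplied gene universe. A `multi_membership_rate` fraction of the
#' annotated genes is assigned to two or more pathways (multi-membership
#' genes average ~2.5 memberships); assignment spreads genes across pathways
#' proportionally to remaining capacity. Pathways listed in
#' `planted_enriched_pathways` with multiplier m > 1 are then re-seeded so
#' that their signature-gene fraction is m times the background signature
#' rate (multiplier 1 leaves a pathway as sampled, i.e. uniform).
#'
#' @param config A [simulation_config()].
#' @param genes Character vector: the gene universe to annotate from.
#' @param signature_genes Optional character vector of planted signature
#'   genes. When omitted, planted multipliers are ignored and the annotation
#'   is plain uniform sampling.
#' @return A [pathway_annotation()] with pathway ids `PW001`, `PW002`, ...
#' @export
generate_pathways <- function(config, genes, signature_genes = NULL) {
  validate_simulation_config(config)
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("gene universe must be non-empty")
  rng <- config$pathway_size_range
  if (rng[2] > length(genes))
    stop("configuration error: pathway_size_range max exceeds gene universe")
  set.seed(config$seed + 1L)
  npw <- config$n_pathways
  ids <- sprintf("PW%03d", seq_len(npw))
  sizes <- sample(seq(rng[1], rng[2]), npw, replace = TRUE)
  total <- sum(sizes)
  rate <- config$multi_membership_rate
  n_ann <- min(length(genes),
               if (rate == 0) total else ceiling(total / (1 + 1.5 * rate)))
  if (rate == 0 && total > length(genes))
    stop("configuration error: pathway sizes need ", total,
         " distinct genes but universe has ", length(genes),
         " (raise multi_membership_rate)")
  ann <- sample(genes, n_ann)
  extras <- total - n_ann
  n_multi <- min(round(rate * n_ann), extras)
  k <- rep(1L, n_ann)
  if (n_multi > 0) {
    k[seq_len(n_multi)] <- 2L
    spare <- extras - n_multi
    if (spare > 0) {
      add <- tabulate(sample.int(n_multi, spare, replace = TRUE), n_multi)
      k[seq_len(n_multi)] <- pmin(k[seq_len(n_multi)] + add, npw)
    }
  } else if (extras > 0) {
    # degenerate small universe: absorb leftover slots as extra memberships
    add <- tabulate(sample.int(n_ann, extras, replace = TRUE), n_ann)
    k <- pmin(k + add, npw)
  }
  # deal memberships: genes with the most memberships first, pathways chosen
  # without replacement with probability proportional to remaining capacity
  capacity <- sizes
  members <- vector("list", npw)
  for (i in order(k, decreasing = TRUE)) {
    avail <- which(capacity > 0)
    ki <- min(k[i], length(avail))
    if (ki == 0L) break
    pick <- if (length(avail) == 1L) avail
            else sample(avail, ki, prob = capacity[avail])
    for (p in pick) members[[p]] <- c(members[[p]], ann[i])
    capacity[pick] <- capacity[pick] - 1L
  }
  names(members) <- ids
  planted <- config$planted_enriched_pathways
  planted <- planted[planted > 1 & names(planted) %in% ids]
  # without a signature there is nothing to seed: plain uniform annotation
  if (length(planted) && !is.null(signature_genes)) {
    signature_genes <- intersect(unique(as.character(signature_genes)), genes)
    base_rate <- length(signature_genes) / length(genes)
    for (id in names(planted)) {
      set_g <- members[[id]]
      target <- min(length(set_g),
                    round(planted[[id]] * base_rate * length(set_g)),
                    length(signature_genes))
      cur <- intersect(set_g, signature_genes)
      need <- target - length(cur)
      if (need > 0) {
        incoming <- sample(setdiff(signature_genes, set_g), need)
        outgoing <- sample(setdiff(set_g, signature_genes), need)
        members[[id]] <- c(setdiff(set_g, outgoing), incoming)
      }
    }
  }
  pathway_annotation(members,
                     descriptions = stats::setNames(
                       sprintf("synthetic pathway %d", seq_len(npw)), ids))
}

#' Generate a pair of cross-platform signatures with planted concordance
#'
#' Builds two gene-level signature tables on distinct probe namespaces (`A_`
#' and `B_` prefixes) that share a `mapping_coverage` fraction of genes.
#' Among the shared significant genes, an exact quota of
#' `concordant_fraction` (assigned deterministically after a seeded shuffle,
#' not sampled) carries a same-signed fold change on both platforms; the
#' rest are opposite-signed.
#'
#' @param config A [simulation_config()]; `signature_size` sets the
#'   gene-level size of the first signature.
#' @return A list with `sig_a`, `sig_b` ([signature_table()]s), `map_a`,
#'   `map_b` ([probe_map()]s), `universe_b` (genes representable on
#'   platform B) and `truth` (with `concordance_labels`: gene ->
#'   "same"/"opposite").
#' @export
generate_paired_signatures <- function(config) {
  validate_simulation_config(config)
  if (config$mapping_coverage == 0)
    stop("configuration error: mapping_coverage = 0 leaves no shared genes")
  set.seed(config$seed + 2L)
  s <- config$signature_size
  genes <- sprintf("G%06d", seq_len(s))
  n_up <- round(config$frac_up * s)
  mag_a <- pmax(abs(stats::rnorm(s, config$effect_log2fc_mean,
                                 config$effect_log2fc_sd)), 1e-6)
  sgn_a <- rep(c(1, -1), c(n_up, s - n_up))
  p_a <- stats::runif(s, 1e-8, 0.05)
  sig_a <- signature_table(paste0("A_", genes), genes, sgn_a * mag_a, p_a,
                           background_size = config$n_probes, alpha = 0.05)
  n_map <- round(config$mapping_coverage * s)
  mapped <- sample(genes, n_map)
  shuffled <- sample(mapped)
  n_same <- round(config$concordant_fraction * n_map)
  labels <- stats::setNames(rep(c("same", "opposite"),
                                c(n_same, n_map - n_same)), shuffled)
  sgn_b <- ifelse(labels[mapped] == "same", 1, -1) *
    sgn_a[match(mapped, genes)]
  mag_b <- pmax(abs(stats::rnorm(n_map, config$effect_log2fc_mean,
                                 config$effect_log2fc_sd)), 1e-6)
  p_b <- stats::runif(n_map, 1e-8, 0.05)
  sig_b <- signature_table(paste0("B_", mapped), mapped, sgn_b * mag_b, p_b,
                           background_size = config$n_probes, alpha = 0.05)
  list(sig_a = sig_a,
       sig_b = sig_b,
       map_a = probe_map(paste0("A_", genes), genes, platform = "A"),
       map_b = probe_map(paste0("B_", mapped), mapped, platform = "B"),
       universe_b = mapped,
       truth = list(concordance_labels = labels,
                    concordant_fraction = n_same / n_map,
                    mapped_genes = mapped))
}

#' Generate a qPCR panel consistent with a study's planted truth
#'
#' For each requested gene, builds replicate Ct values for the target and
#' the internal-control reference gene in both conditions such that the
#' delta-delta-Ct log2 fold change equals the gene's planted array log2 fold
#' change plus Gaussian Ct-level noise of `ct_noise_sd` per replicate
#' measurement. Reference Cts are fixed at 18 cycles and the target control
#' baseline at 25 cycles (typical TaqMan scale).
#'
#' @param study A synthetic [expression_study()] with planted truth.
#' @param genes Character vector of gene ids present in the study.
#' @param ct_noise_sd Ct-level noise SD in cycles.
#' @param seed Integer seed.
#' @return A [qpcr_panel()].
#' @export
generate_qpcr <- function(study, genes, ct_noise_sd = 0.25, seed = 1L) {
  stopifnot(inherits(study, "expression_study"))
  if (is.null(study$truth))
    stop("study carries no planted truth; cannot anchor qPCR fold changes")
  genes <- as.character(genes)
  known <- unique(study$probe_gene_map$gene_id)
  bad <- setdiff(genes, known)
  if (length(bad)) stop("lookup error: unknown gene id ", bad[1])
  # gene-level planted fold change: the gene's largest-|effect| probe, 0 if null
  tr <- study$truth$true_log2fc
  gene_lfc <- vapply(genes, function(g) {
    probes <- study$probe_gene_map$probe_id[study$probe_gene_map$gene_id == g]
    eff <- tr[intersect(probes, names(tr))]
    if (!length(eff)) 0 else eff[which.max(abs(eff))]
  }, numeric(1))
  r <- sum(study$group_labels == "treated")
  set.seed(seed)
  rows <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene = g,
               condition = rep(c("treated", "control"), each = r),
               replicate = rep(seq_len(r), 2L),
               ct_target = c(25 - gene_lfc[[g]] +
                               stats::rnorm(r, 0, ct_noise_sd),
                             25 + stats::rnorm(r, 0, ct_noise_sd)),
               ct_reference = 18,
               stringsAsFactors = FALSE)
  }))
  qpcr_panel(rows$gene, rows$condition, rows$replicate, rows$ct_target,
             rows$ct_reference)
}
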