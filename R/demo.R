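#' Run the full pipeline end-to-end on synthetic data
#'
#' Generates a synthetic study, pathway annotation, paired cross-platform
#' signatures and a qPCR panel from one configuration, then runs every
#' analysis stage: median normalization, per-probe Welch statistics,
#' significance filtering, gene collapse and direction summary; weighted
#' pathway overrepresentation and pathway-pair interconnectivity with Pajek
#' network export; cross-platform mapping, Venn partitioning and direction
#' concordance; and delta-delta-Ct validation of a 14-gene panel. All
#' artifacts are written as plain-text files; identical seeds give
#' byte-identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [simulation_config()]; by default a 5000-probe study with
#'   a 500-probe planted signature (90.5% up), 131 pathways with one planted
#'   at 5x enrichment, triplicates and 0.25 log2 noise — large enough to
#'   exercise every stage, small enough to run in seconds.
#' @param seed Integer seed used when `config` is not supplied.
#' @param alpha Significance level of the filter.
#' @param n_qpcr_genes Number of signature genes in the qPCR panel.
#' @return Invisibly, a list with the artifact `paths` and a `summary` list
#'   (signature size, direction split, top pathways, link tiers, qPCR R^2).
#' @export
run_demo <- function(out_dir, config = NULL, seed = 1L, alpha = 0.05,
                     n_qpcr_genes = 14L) {
  if (is.null(config))
    config <- simulation_config(n_probes = 5000L, signature_size = 500L,
                                seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- generate_study(config)
  study <- normalize_study(study, "median")
  stats <- probe_statistics(study)
  sig <- build_signature(stats, alpha = alpha)
  gene_sig <- collapse_to_genes(sig)
  direction <- summarize_direction(sig)

  background <- unique(study$probe_gene_map$gene_id)
  ann <- generate_pathways(config, background,
                           signature_genes = unique(
                             study$probe_gene_map$gene_id[
                               study$probe_gene_map$probe_id %in%
                                 study$truth$signature_probes]))
  enr <- overrepresentation(gene_sig$gene_id, background, ann, alpha = alpha)
  selected <- enr$pathway[enr$significant]
  if (length(selected) < 2L) selected <- utils::head(enr$pathway, 5L)
  links <- interconnectivity(selected, gene_sig$gene_id, background, ann)
  net <- pathway_network(enr, links)

  pair <- generate_paired_signatures(config)
  mapped_a <- map_signature(pair$sig_a, pair$map_a, pair$universe_b)
  conc <- concordance(mapped_a$table, collapse_to_genes(pair$sig_b))
  venn <- venn_partition(list(A = pair$sig_a$gene_id,
                              B = pair$sig_b$gene_id))

  sig_genes_truth <- unique(study$probe_gene_map$gene_id[
    study$probe_gene_map$probe_id %in% study$truth$signature_probes])
  set.seed(config$seed + 3L)
  panel_genes <- sample(sort(sig_genes_truth), n_qpcr_genes)
  panel <- generate_qpcr(study, panel_genes, ct_noise_sd = 0.25,
                         seed = config$seed + 4L)
  validation <- validate_panel(gene_sig, panel)

  paths <- c(signature = file.path(out_dir, "signature.csv"),
             gene_signature = file.path(out_dir, "signature_genes.csv"),
             enrichment = file.path(out_dir, "enrichment.csv"),
             links = file.path(out_dir, "links.csv"),
             network = file.path(out_dir, "network.net"),
             venn = file.path(out_dir, "venn.csv"),
             concordance = file.path(out_dir, "concordance.csv"),
             qpcr = file.path(out_dir, "qpcr_validation.csv"),
             summary = file.path(out_dir, "summary.txt"))
  write_signature_csv(sig, paths[["signature"]])
  write_signature_csv(gene_sig, paths[["gene_signature"]])
  utils::write.csv(as.data.frame(enr), paths[["enrichment"]],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(links), paths[["links"]],
                   row.names = FALSE, quote = FALSE)
  write_pajek(net, paths[["network"]])
  utils::write.csv(
    data.frame(region = names(venn$regions),
               count = unname(venn$counts),
               genes = vapply(venn$regions, paste, character(1),
                              collapse = ";")),
    paths[["venn"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(gene = c(conc$same, conc$opposite),
               class = rep(c("same-direction", "opposite-direction"),
                           c(length(conc$same), length(conc$opposite)))),
    paths[["concordance"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(validation$per_gene, paths[["qpcr"]], row.names = FALSE,
                   quote = FALSE)

  summary <- list(
    n_probes = nrow(study$intensities),
    signature_probes = nrow(sig),
    signature_genes = nrow(gene_sig),
    pct_up = direction$pct_up,
    pct_down = direction$pct_down,
    top_pathways = utils::head(enr$pathway, 5L),
    top_pathway_p = utils::head(enr$p_value, 5L),
    n_links_high = sum(links$tier == "high"),
    n_links_significant = sum(links$tier == "significant"),
    concordant_fraction = conc$fraction_same,
    qpcr_r_squared = validation$r_squared)
  writeLines(c(
    sprintf("n_probes=%d", summary$n_probes),
    sprintf("signature_probes=%d", summary$signature_probes),
    sprintf("signature_genes=%d", summary$signature_genes),
    sprintf("pct_up=%.1f", summary$pct_up),
    sprintf("pct_down=%.1f", summary$pct_down),
    sprintf("top_pathways=%s", paste(summary$top_pathways, collapse = ";")),
    sprintf("links_high=%d", summary$n_links_high),
    sprintf("links_significant=%d", summary$n_links_significant),
    sprintf("concordant_fraction=%.4f", summary$concordant_fraction),
    sprintf("qpcr_r_squared=%.4f", summary$qpcr_r_squared)),
    paths[["summary"]])
  invisible(list(paths = paths, summary = summary))
}
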