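test_that("planted direction quota and determinism hold for generated studies", {
  cfg <- small_config(seed = 7L, frac_up = 0.9)
  st1 <- generate_study(cfg)
  st2 <- generate_study(cfg)
  expect_identical(st1$intensities, st2$intensities)
  expect_identical(st1$truth, st2$truth)

  lfc <- st1$truth$true_log2fc
  expect_length(lfc, 100L)
  expect_identical(sum(lfc > 0), 90L)
  expect_identical(sum(lfc < 0), 10L)
  expect_setequal(st1$truth$signature_probes, names(lfc))
  expect_true(all(st1$truth$signature_probes %in%
                    rownames(st1$intensities)))
  expect_identical(dim(st1$intensities), c(1000L, 6L))
})

test_that("zero-noise studies carry the planted fold change exactly", {
  cfg <- small_config(seed = 3L, noise_sd = 0, effect_log2fc_mean = 2)
  st <- generate_study(cfg)
  l <- log2(st$intensities)
  diff <- rowMeans(l[, st$group_labels == "treated"]) -
    rowMeans(l[, st$group_labels == "control"])
  expected <- numeric(nrow(l))
  names(expected) <- rownames(l)
  expected[names(st$truth$true_log2fc)] <- st$truth$true_log2fc
  expect_equal(unname(diff), unname(expected), tolerance = 1e-12)
})

test_that("invalid study configurations are rejected", {
  expect_error(small_config(signature_size = 2000L), "signature_size")
  expect_error(small_config(replicates_per_group = 1L), "replicates")
  expect_error(small_config(frac_up = 1.2), "frac_up")
  expect_error(small_config(pathway_size_range = c(0L, 5L)),
               "pathway_size_range")
})

test_that("pathway generation honors count, sizes and membership structure", {
  cfg <- small_config(seed = 11L, n_pathways = 131L,
                      pathway_size_range = c(5L, 15L),
                      multi_membership_rate = 0.3)
  genes <- sprintf("G%06d", 1:990)
  ann <- generate_pathways(cfg, genes)
  expect_length(ann$sets, 131L)
  expect_true(all(lengths(ann$sets) >= 5 & lengths(ann$sets) <= 15))
  expect_true(all(vapply(ann$sets, anyDuplicated, integer(1)) == 0L))

  # zero multi-membership: every annotated gene belongs to exactly one set
  cfg0 <- small_config(seed = 11L, multi_membership_rate = 0)
  ann0 <- generate_pathways(cfg0, genes)
  expect_true(all(ann0$membership_count == 1L))
  expect_true(all(ann0$weight == 1))

  expect_error(generate_pathways(small_config(pathway_size_range = c(5L, 40L)),
                                 genes[1:30]),
               "exceeds gene universe")
})

test_that("unplanted pathways draw signature genes uniformly", {
  cfg <- small_config(seed = 5L, n_probes = 2000L, n_genes = 2000L,
                      signature_size = 400L, n_pathways = 40L,
                      pathway_size_range = c(20L, 60L),
                      planted_enriched_pathways = numeric())
  st <- generate_study(cfg)
  genes <- unique(st$probe_gene_map$gene_id)
  sig <- unique(st$probe_gene_map$gene_id[
    st$probe_gene_map$probe_id %in% st$truth$signature_probes])
  ann <- generate_pathways(cfg, genes, signature_genes = sig)
  p0 <- length(sig) / length(genes)
  z <- vapply(ann$sets, function(s) {
    phat <- mean(s %in% sig)
    (phat - p0) / sqrt(p0 * (1 - p0) / length(s))
  }, numeric(1))
  expect_lt(mean(abs(z) > 3), 0.05)
  expect_true(all(abs(z) < 5))
})

test_that("planted enrichment seeds signature genes at the requested multiplier", {
  cfg <- small_config(seed = 9L, n_probes = 2000L, n_genes = 2000L,
                      signature_size = 200L, n_pathways = 30L,
                      pathway_size_range = c(30L, 50L),
                      planted_enriched_pathways = c(PW001 = 5))
  st <- generate_study(cfg)
  genes <- unique(st$probe_gene_map$gene_id)
  sig <- unique(st$probe_gene_map$gene_id[
    st$probe_gene_map$probe_id %in% st$truth$signature_probes])
  ann <- generate_pathways(cfg, genes, signature_genes = sig)
  size <- length(ann$sets$PW001)
  hits <- sum(ann$sets$PW001 %in% sig)
  expect_equal(hits, min(size, round(5 * length(sig) / length(genes) * size)))
})

test_that("paired signatures plant exact concordance and coverage quotas", {
  cfg <- small_config(seed = 13L, signature_size = 500L,
                      mapping_coverage = 0.9, concordant_fraction = 0.8)
  pair <- generate_paired_signatures(cfg)
  expect_identical(nrow(pair$sig_a), 500L)
  expect_identical(nrow(pair$sig_b), 450L)
  labels <- pair$truth$concordance_labels
  expect_equal(sum(labels == "same"), round(0.8 * 450))

  # labels match the actual fold-change signs on the two platforms
  fa <- setNames(pair$sig_a$log2fc, pair$sig_a$gene_id)
  fb <- setNames(pair$sig_b$log2fc, pair$sig_b$gene_id)
  shared <- names(fb)
  expect_identical(unname(labels[shared] == "same"),
                   unname(sign(fa[shared]) == sign(fb[shared])))

  all_same <- generate_paired_signatures(
    small_config(seed = 13L, concordant_fraction = 1))
  lab <- all_same$truth$concordance_labels
  expect_true(all(lab == "same"))
  expect_error(generate_paired_signatures(
    small_config(mapping_coverage = 0)), "mapping_coverage")
})

test_that("qPCR panels encode the planted fold change through delta-delta-Ct", {
  cfg <- small_config(seed = 17L, noise_sd = 0.25)
  st <- generate_study(cfg)
  sig_genes <- unique(st$probe_gene_map$gene_id[
    st$probe_gene_map$probe_id %in% st$truth$signature_probes])
  genes <- sort(sig_genes)[1:14]
  panel <- generate_qpcr(st, genes, ct_noise_sd = 0, seed = 2L)
  lfc <- ddct(panel)
  truth <- vapply(lfc$gene, function(g) {
    pr <- st$probe_gene_map$probe_id[st$probe_gene_map$gene_id == g]
    eff <- st$truth$true_log2fc[intersect(pr, names(st$truth$true_log2fc))]
    eff[which.max(abs(eff))]
  }, numeric(1))
  expect_equal(lfc$qpcr_log2fc, unname(truth), tolerance = 1e-12)

  # single gene, planted log2fc 2, no noise: the raw Ct arithmetic gives -2
  one <- st
  one$truth$true_log2fc[] <- 0
  one$truth$true_log2fc[1] <- 2
  g1 <- st$probe_gene_map$gene_id[
    st$probe_gene_map$probe_id == names(one$truth$true_log2fc)[1]]
  p1 <- generate_qpcr(one, g1, ct_noise_sd = 0, seed = 2L)
  dct <- tapply(p1$ct_target - p1$ct_reference, p1$condition, mean)
  expect_equal(unname(dct[["treated"]] - dct[["control"]]), -2,
               tolerance = 1e-12)

  expect_error(generate_qpcr(st, "NOT_A_GENE", seed = 1L), "unknown gene")
})
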