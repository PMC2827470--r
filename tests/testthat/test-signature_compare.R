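test_that("signature mapping translates, filters and collapses correctly", {
  tab <- toy_signature()
  id_map <- probe_map(tab$probe_id, tab$gene_id)
  res <- map_signature(tab, id_map, unique(tab$gene_id))
  expect_equal(res$mapped_fraction, 1)
  expect_setequal(res$table$gene_id, tab$gene_id)
  expect_equal(sort(res$table$log2fc), sort(tab$log2fc))

  # universe missing half the genes on a balanced toy
  half <- map_signature(tab, id_map, c("g1", "g2"))
  expect_equal(half$mapped_fraction, 2 / 3)

  # two probes to one gene: smaller p wins
  two <- signature_table(c("pX", "pY"), c("gX", "gY"), c(1, 2), c(0.04, 0.01))
  merge_map <- probe_map(c("pX", "pY"), c("gZ", "gZ"))
  merged <- map_signature(two, merge_map, "gZ")
  expect_identical(nrow(merged$table), 1L)
  expect_equal(merged$table$log2fc, 2)

  # idempotent on already-mapped tables
  again <- map_signature(res$table, probe_map(res$table$probe_id,
                                              res$table$gene_id),
                         unique(tab$gene_id))
  expect_equal(again$mapped_fraction, 1)
  expect_identical(again$table$gene_id, res$table$gene_id)

  # planted mapping coverage is recovered
  cfg <- small_config(seed = 23L, signature_size = 500L,
                      mapping_coverage = 0.9)
  pair <- generate_paired_signatures(cfg)
  m <- map_signature(pair$sig_a, pair$map_a, pair$universe_b)
  expect_equal(m$mapped_fraction, 0.9, tolerance = 1 / 500)

  expect_error(map_signature(tab, id_map, character()), "empty")
})

test_that("venn partitions are exact on toys and disjoint-exhaustive in general", {
  p <- venn_partition(list(X = c("1", "2", "3"), Y = c("3", "4")))
  expect_setequal(p$regions$A, c("1", "2"))
  expect_setequal(p$regions$AB, "3")
  expect_setequal(p$regions$B, "4")

  same <- venn_partition(list(X = c("a", "b"), Y = c("a", "b")))
  expect_identical(unname(same$counts[c("A", "B", "AB")]), c(0L, 0L, 2L))

  expect_error(venn_partition(list(X = "a", X = "b")), "unique")
  expect_error(venn_partition(list(X = "a")), "2 or 3")

  set.seed(77)
  for (trial in 1:200) {
    k <- sample(2:3, 1)
    sets <- stats::setNames(
      lapply(seq_len(k), function(i)
        sample(as.character(1:40), sample(0:25, 1))),
      LETTERS[24:26][seq_len(k)])
    part <- venn_partition(sets)
    genes <- unlist(part$regions, use.names = FALSE)
    expect_identical(anyDuplicated(genes), 0L)
    expect_setequal(genes, unique(unlist(sets)))
    expect_identical(sum(part$counts), length(unique(unlist(sets))))
  }
})

test_that("concordance classifies directions and recovers planted fractions", {
  sig <- collapse_to_genes(toy_signature())
  expect_equal(concordance(sig, sig)$fraction_same, 1)
  flipped <- sig
  flipped$log2fc <- -flipped$log2fc
  expect_equal(concordance(sig, flipped)$fraction_same, 0)
  expect_equal(concordance(sig, flipped, orientation_b = "inverted")$fraction_same, 1)

  cfg <- small_config(seed = 29L, signature_size = 500L,
                      concordant_fraction = 0.8, mapping_coverage = 0.9)
  pair <- generate_paired_signatures(cfg)
  m <- map_signature(pair$sig_a, pair$map_a, pair$universe_b)
  rep <- concordance(m$table, collapse_to_genes(pair$sig_b))
  expect_equal(rep$fraction_same, pair$truth$concordant_fraction)
  expect_equal(rep$fraction_same, round(0.8 * 450) / 450)

  other <- signature_table("pz", "zz", 1, 0.01)
  expect_error(concordance(sig, other), "zero shared genes")
})

test_that("crosstalk partitions count exclusive and shared regulation", {
  s1 <- signature_table(paste0("p", 1:4), c("a", "b", "c", "d"),
                        rep(1, 4), rep(0.01, 4))
  s2 <- signature_table(paste0("q", 1:3), c("c", "d", "e"),
                        rep(1, 3), rep(0.01, 3))
  ct <- crosstalk_partition(s1, s2, reference = "union")
  expect_equal(unname(ct$percentages),
               c(only_1 = 40, only_2 = 20, both = 40),
               ignore_attr = TRUE)
  expect_setequal(ct$classes$both, c("c", "d"))
  expect_equal(sum(ct$percentages), 100, tolerance = 0.1)

  # identical signatures: everything is shared
  expect_equal(crosstalk_partition(s1, s1)$percentages[["both"]], 100)

  # disjoint signatures under the union reference
  s3 <- signature_table("r1", "z", 1, 0.01)
  dj <- crosstalk_partition(s1, s3)
  expect_equal(dj$percentages[["only_1"]] + dj$percentages[["only_2"]], 100)
  expect_equal(dj$percentages[["both"]], 0)

  # condition1 reference rescales to the first signature
  c1 <- crosstalk_partition(s1, s2, reference = "condition1")
  expect_equal(c1$percentages[["both"]], 50)

  empty <- build_signature(signature_table("p1", "g1", 1, 1))
  expect_error(crosstalk_partition(empty, empty), "both signatures empty")
})

test_that("fold-change matrices align genes with masked missing cells", {
  s1 <- signature_table(paste0("p", 1:3), c("a", "b", "c"),
                        c(3, -1, 2), rep(0.01, 3))
  s2 <- signature_table(paste0("q", 1:2), c("b", "d"),
                        c(0.5, -2), rep(0.01, 2))
  fm <- foldchange_matrix(list(first = s1, second = s2))
  expect_identical(dim(fm$log2fc), c(4L, 2L))
  expect_identical(rownames(fm$log2fc), c("a", "c", "b", "d"))
  expect_true(fm$missing["d", "first"])
  expect_identical(fm$log2fc["d", "first"], 0)
  expect_false(fm$missing["d", "second"])
  expect_equal(fm$log2fc["b", "second"], 0.5)

  one <- foldchange_matrix(list(s1))
  expect_identical(rownames(one$log2fc), c("a", "c", "b"))

  cfg <- small_config(seed = 33L, signature_size = 200L)
  pair <- generate_paired_signatures(cfg)
  third <- collapse_to_genes(toy_signature())
  fm3 <- foldchange_matrix(list(A = collapse_to_genes(pair$sig_a),
                                B = collapse_to_genes(pair$sig_b),
                                C = third))
  expect_identical(nrow(fm3$log2fc),
                   length(unique(c(pair$sig_a$gene_id, pair$sig_b$gene_id,
                                   third$gene_id))))
  expect_identical(ncol(fm3$log2fc), 3L)
})
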