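test_that("binomial upper tail matches closed forms and the summation oracle", {
  expect_identical(binomial_tail(10, 0.5, 0), 1)
  expect_equal(binomial_tail(10, 0.5, 10), 0.5^10, tolerance = 1e-15)
  expect_equal(binomial_tail(4, 0.25, 3), 0.05078125, tolerance = 1e-12)
  expect_equal(binomial_tail(20, 0.2, 7), binom_tail_oracle(20, 0.2, 7),
               tolerance = 1e-12)
  expect_error(binomial_tail(5, 0.5, 6), "domain error")

  # continuous extension coincides with the summation at every integer w
  set.seed(5)
  for (i in 1:200) {
    n <- sample(1:60, 1); p <- runif(1); w <- sample(0:n, 1)
    expect_equal(binomial_tail(n, p, w), binom_tail_oracle(n, p, w),
                 tolerance = 1e-12)
  }

  # monotone non-increasing in w, non-decreasing in p
  w <- seq(0, 20, by = 0.25)
  expect_true(all(diff(binomial_tail(20, 0.3, w)) <= 1e-15))
  p <- seq(0, 1, by = 0.01)
  expect_true(all(diff(binomial_tail(20, p, 6.5)) >= -1e-15))
})

test_that("overrepresentation reproduces the hand-computed toy example", {
  background <- paste0("g", 1:20)
  ann <- pathway_annotation(list(PW = paste0("g", 1:5)))
  sig <- c("g1", "g2", "g3", "g15")
  res <- overrepresentation(sig, background, ann)
  expect_equal(res$count, 3)
  expect_equal(res$expect, 4 * (5 / 20))
  expect_equal(res$p_value, 0.05078125, tolerance = 1e-12)
  expect_false(res$significant)

  # disjoint pathway: count 0, p 1
  ann2 <- pathway_annotation(list(PW = paste0("g", 1:5),
                                  FAR = paste0("g", 16:20)))
  res2 <- overrepresentation(c("g1", "g2"), background, ann2)
  far <- res2[res2$pathway == "FAR", ]
  expect_equal(far$count, 0)
  expect_equal(far$p_value, 1)

  # single-membership weights reduce to plain intersection counts
  expect_equal(res$count, length(intersect(sig, ann$sets$PW)))

  expect_error(overrepresentation(c("g1", "zzz"), background, ann),
               "ill-defined")
})

test_that("weighted counts conserve one unit per annotated gene", {
  cfg <- small_config(seed = 6L, n_pathways = 25L,
                      pathway_size_range = c(5L, 40L),
                      multi_membership_rate = 0.4)
  genes <- sprintf("G%04d", 1:500)
  ann <- generate_pathways(cfg, genes)
  for (trial in 1:20) {
    g_set <- sample(genes, sample(20:200, 1))
    total <- sum(vapply(ann$sets, function(s) {
      hit <- intersect(s, g_set)
      if (length(hit)) sum(ann$weight[hit]) else 0
    }, numeric(1)))
    expect_equal(total, sum(g_set %in% annotated_genes(ann)),
                 tolerance = 1e-9)
  }
})

test_that("the binomial null is approximately calibrated against random sets", {
  set.seed(14)
  cfg <- small_config(seed = 14L, n_pathways = 10L,
                      pathway_size_range = c(20L, 60L))
  genes <- sprintf("G%04d", 1:600)
  ann <- generate_pathways(cfg, genes)
  hits <- matrix(0L, 2000, 3)
  for (i in 1:2000) {
    draw <- sample(genes, 50)
    res <- overrepresentation(draw, genes, ann)
    hits[i, ] <- res$p_value[match(c("PW001", "PW002", "PW003"),
                                   res$pathway)] <= 0.05
  }
  rates <- colMeans(hits)
  # binomial null vs hypergeometric truth: deliberately loose band
  expect_true(all(rates >= 0.01 & rates <= 0.08))
})

test_that("interconnectivity tiers and P-values follow the shared-gene null", {
  bg <- paste0("g", 1:100)
  # A and B share g1..g10; 4 of them regulated
  ann <- pathway_annotation(list(A = paste0("g", 1:20),
                                 B = paste0("g", c(1:10, 30:40)),
                                 C = paste0("g", 60:70)))
  sig <- paste0("g", c(1:4, 50:55))
  links <- interconnectivity(c("A", "B", "C"), sig, bg, ann)
  ab <- links[links$pathway_a == "A" & links$pathway_b == "B", ]
  expect_identical(ab$shared_regulated, 4)
  expect_identical(ab$shared_background, 10)
  expect_equal(ab$p_value, binom_tail_oracle(10, 0.1, 4), tolerance = 1e-12)
  expect_equal(ab$p_value, 0.0127952, tolerance = 1e-6)
  expect_identical(ab$tier, "high")

  # disjoint pair: nothing shared, tier low and unassessed
  ac <- links[links$pathway_a == "A" & links$pathway_b == "C", ]
  expect_identical(ac$shared_regulated, 0)
  expect_identical(ac$tier, "low")
  expect_false(ac$assessed)

  # a P-value between 0.05 and 0.10 lands in the 'significant' tier:
  # 16 shared background genes, 4 regulated, |sig| = 10 -> P = 0.0614
  ann2 <- pathway_annotation(list(A = paste0("g", 1:20),
                                  B = paste0("g", c(1:16, 30:35))))
  sig2 <- paste0("g", c(1:4, 50:55))
  l2 <- interconnectivity(c("A", "B"), sig2, bg, ann2)
  expect_equal(l2$p_value, binom_tail_oracle(10, 0.16, 4), tolerance = 1e-12)
  expect_gt(l2$p_value, 0.05)
  expect_lt(l2$p_value, 0.10)
  expect_identical(l2$tier, "significant")

  # regulated shared gene outside the shared background is inconsistent
  ann3 <- pathway_annotation(list(A = c("x", "g1"), B = c("x", "g2")))
  expect_error(interconnectivity(c("A", "B"), c("x"), bg, ann3),
               "consistency error")

  expect_error(interconnectivity(c("A", "NOPE"), sig, bg, ann),
               "not in annotation")
})

test_that("weighted interconnectivity uses inverse-membership shared counts", {
  bg <- paste0("g", 1:50)
  ann <- pathway_annotation(list(A = paste0("g", 1:10),
                                 B = paste0("g", 5:14),
                                 C = paste0("g", 5:8)))
  sig <- paste0("g", 5:9)
  lw <- interconnectivity(c("A", "B"), sig, bg, ann, weighted = TRUE)
  # shared A-B genes g5..g10: g5..g8 have k=3, g9..g10 k=2
  expect_equal(lw$shared_background, 4 / 3 + 2 / 2, tolerance = 1e-12)
  expect_equal(lw$shared_regulated, 4 / 3 + 1 / 2, tolerance = 1e-12)
})

test_that("pathway networks carry significant vertices and filtered edges", {
  res <- structure(
    data.frame(pathway = c("A", "B", "C"),
               count = c(5, 4, 1), expect = c(1, 1, 1),
               p_value = c(0.001, 0.01, 0.9),
               p_adjusted = c(0.001, 0.01, 0.9),
               significant = c(TRUE, TRUE, FALSE)),
    class = c("enrichment_result", "data.frame"))
  links <- structure(
    data.frame(pathway_a = c("A", "A"), pathway_b = c("B", "C"),
               shared_regulated = c(3, 1), shared_background = c(5, 4),
               p_value = c(0.01, 0.5), tier = c("high", "low"),
               assessed = c(TRUE, FALSE)),
    class = c("pair_links", "data.frame"))
  net <- pathway_network(res, links)
  expect_identical(net$vertices$label, c("A", "B"))
  expect_identical(net$vertices$color, c("Red", "Red"))
  expect_identical(nrow(net$edges), 1L)  # A-C dropped: < 2 shared regulated
  expect_equal(net$edges$weight, 3)

  # no significant pathways -> empty network
  res0 <- res; res0$significant <- FALSE
  empty <- pathway_network(res0, links[0, ])
  expect_identical(nrow(empty$vertices), 0L)
  expect_identical(nrow(empty$edges), 0L)

  bad <- links; bad$pathway_b[1] <- "GHOST"
  expect_error(pathway_network(res, bad), "validation error")
})
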