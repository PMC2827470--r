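# Shared fixture builders: small, fast configurations used across test files.

small_config <- function(seed = 1L, ...) {
  defaults <- list(n_probes = 1000L, n_genes = 990L, signature_size = 100L,
                   n_pathways = 20L, pathway_size_range = c(5L, 30L),
                   seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# a tiny deterministic signature table
toy_signature <- function(lfc = c(1.5, -0.8, 2.1),
                          p = c(0.01, 0.03, 0.001),
                          genes = paste0("g", seq_along(lfc)),
                          probes = paste0("p", seq_along(lfc)),
                          background = 1000L) {
  signature_table(probes, genes, lfc, p, background_size = background,
                  alpha = 0.05)
}

# independent Welch t-test oracle: statistic assembled by hand, t CDF by
# numeric integration of the density (lgamma form), never via pt()
welch_p_oracle <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  v1 <- sum((x1 - mean(x1))^2) / (n1 - 1)
  v2 <- sum((x2 - mean(x2))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x1) - mean(x2)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  dens <- function(u) exp(lgamma((df + 1) / 2) - lgamma(df / 2) -
                            0.5 * log(df * pi) -
                            (df + 1) / 2 * log1p(u^2 / df))
  upper <- 0.5 - stats::integrate(dens, 0, abs(t), rel.tol = 1e-13,
                                  abs.tol = 1e-14)$value
  2 * upper
}

# brute-force binomial upper tail at integer w: explicit pmf summation
binom_tail_oracle <- function(n, p, w) {
  if (w <= 0) return(1)
  k <- seq(ceiling(w), n)
  sum(choose(n, k) * p^k * (1 - p)^(n - k))
}
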