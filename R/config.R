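#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators into one validated
#' object. The defaults emulate the scale of a whole-genome expression study on
#' a ~27,868-probe array run in biological triplicate, with a planted
#' treatment signature that is predominantly upregulated (90.5% up / 9.5%
#' down), an overlapping annotation of 131 pathways, a paired cross-platform
#' signature sharing ~88% of genes with ~80% same-direction changes, and
#' log2-scale Gaussian measurement noise.
#'
#' @param n_probes Number of probes on the array.
#' @param n_genes Number of distinct genes the probes map to (<= `n_probes`).
#'   The default leaves ~1% of genes with two probes, mirroring the small
#'   probe/gene excess of real arrays.
#' @param replicates_per_group Biological replicates per condition (>= 2).
#' @param signature_size Number of probes with a planted treatment effect.
#' @param frac_up Fraction of signature probes that are upregulated.
#' @param effect_log2fc_mean,effect_log2fc_sd Mean and SD of the absolute
#'   planted log2 fold change.
#' @param noise_sd SD of i.i.d. Gaussian noise on the log2 intensity scale,
#'   per probe and sample.
#' @param n_pathways Number of pathway annotation sets to generate.
#' @param pathway_size_range Integer vector `c(min, max)` of pathway sizes.
#' @param multi_membership_rate Fraction of annotated genes that belong to two
#'   or more pathways.
#' @param planted_enriched_pathways Named numeric vector: pathway id ->
#'   enrichment multiplier. A multiplier m > 1 seeds the pathway with
#'   signature genes at m times the background rate; m = 1 leaves the pathway
#'   as sampled.
#' @param mapping_coverage Fraction of signature genes mappable to the second
#'   platform in paired-signature generation.
#' @param concordant_fraction Fraction of shared significant genes with
#'   same-signed fold change across the paired signatures.
#' @param seed Integer seed; identical config + seed reproduces every
#'   generator output bit-for-bit.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @examples
#' cfg <- simulation_config(n_probes = 1000, signature_size = 100, seed = 1)
#' cfg$frac_up
#' @export
simulation_config <- function(n_probes = 27868L,
                              n_genes = round(n_probes / 1.01),
                              replicates_per_group = 3L,
                              signature_size = 961L,
                              frac_up = 0.905,
                              effect_log2fc_mean = 2,
                              effect_log2fc_sd = 0.5,
                              noise_sd = 0.25,
                              n_pathways = 131L,
                              pathway_size_range = c(10L, 80L),
                              multi_membership_rate = 0.3,
                              planted_enriched_pathways = c(PW001 = 5),
                              mapping_coverage = 0.88,
                              concordant_fraction = 0.8,
                              seed = 1L) {
  cfg <- list(
    n_probes = as.integer(n_probes),
    n_genes = as.integer(n_genes),
    replicates_per_group = as.integer(replicates_per_group),
    signature_size = as.integer(signature_size),
    frac_up = as.numeric(frac_up),
    effect_log2fc_mean = as.numeric(effect_log2fc_mean),
    effect_log2fc_sd = as.numeric(effect_log2fc_sd),
    noise_sd = as.numeric(noise_sd),
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    multi_membership_rate = as.numeric(multi_membership_rate),
    planted_enriched_pathways = planted_enriched_pathways,
    mapping_coverage = as.numeric(mapping_coverage),
    concordant_fraction = as.numeric(concordant_fraction),
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$n_probes < 1L) stop("configuration error: n_probes must be >= 1")
  if (cfg$n_genes < 1L || cfg$n_genes > cfg$n_probes)
    stop("configuration error: n_genes must be in [1, n_probes]")
  if (cfg$signature_size > cfg$n_probes)
    stop("configuration error: signature_size exceeds n_probes")
  if (cfg$replicates_per_group < 2L)
    stop("configuration error: replicates_per_group must be >= 2 (variance undefined)")
  for (f in c("frac_up", "multi_membership_rate", "mapping_coverage",
              "concordant_fraction")) {
    v <- cfg[[f]]
    if (!is.finite(v) || v < 0 || v > 1)
      stop(sprintf("configuration error: %s must be in [0, 1]", f))
  }
  if (length(cfg$pathway_size_range) != 2L || cfg$pathway_size_range[1] < 1L ||
      cfg$pathway_size_range[1] > cfg$pathway_size_range[2])
    stop("configuration error: pathway_size_range must be c(min, max) with 1 <= min <= max")
  if (cfg$noise_sd < 0 || cfg$effect_log2fc_sd < 0)
    stop("configuration error: standard deviations must be non-negative")
  pm <- cfg$planted_enriched_pathways
  if (length(pm) && (is.null(names(pm)) || any(!nzchar(names(pm)))))
    stop("configuration error: planted_enriched_pathways must be a named vector")
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' All fields of [simulation_config()] are recognized as top-level YAML keys;
#' `planted_enriched_pathways` is a mapping of pathway id to multiplier.
#' Missing keys fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$planted_enriched_pathways))
    raw$planted_enriched_pathways <- unlist(raw$planted_enriched_pathways)
  if (!is.null(raw$pathway_size_range))
    raw$pathway_size_range <- as.integer(unlist(raw$pathway_size_range))
  do.call(simulation_config, raw)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:",
      sprintf("%d probes / %d genes, %d+%d replicates",
              x$n_probes, x$n_genes, x$replicates_per_group,
              x$replicates_per_group),
      "\n")
  cat(sprintf("  signature: %d probes, %.1f%% up, effect %.2g +/- %.2g log2, noise sd %.2g\n",
              x$signature_size, 100 * x$frac_up, x$effect_log2fc_mean,
              x$effect_log2fc_sd, x$noise_sd))
  cat(sprintf("  pathways: %d, sizes [%d, %d], multi-membership %.0f%%\n",
              x$n_pathways, x$pathway_size_range[1], x$pathway_size_range[2],
              100 * x$multi_membership_rate))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
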