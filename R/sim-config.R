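#' Simulation configuration for the synthetic-data generator
#'
#' Bundles every tunable of the planted-truth simulator: gene set size and
#' length range, sequencing depth and background stop rates for the probing
#' libraries, the couplings that tie folding to R-loop intensity and to the
#' per-site mutation rate, and the phylogeny size. A single `seed` fixes every
#' stochastic draw end-to-end; each generator derives its own sub-seed from it
#' so the generators are individually reproducible.
#'
#' @param n_genes Number of genes to simulate.
#' @param gene_length_range Integer length-2 vector; gene lengths are drawn
#'   uniformly (in nt) from this closed range.
#' @param depth_per_nt Expected sequenced read pairs per nucleotide per
#'   treatment; the per-gene read count is `round(depth_per_nt * length)`.
#' @param dmso_background Relative RT-stop weight per nucleotide independent of
#'   chemical modification (the DMSO control samples only this background).
#' @param nai_multiplier Added RT-stop weight per unit unpairedness in the
#'   NAI-N3 library, on the same relative scale as `dmso_background`.
#' @param footprint Number of 3'-terminal nucleotides hidden inside the
#'   transcription elongation complex (default 18).
#' @param n_transitions Planted cotranscriptional structural transitions per
#'   gene (step changes in unpairedness at one nucleotide).
#' @param transition_effect Absolute step size in unpairedness at a planted
#'   transition (probability units, so at most 1).
#' @param contaminant_frac Fraction of reads emitted with mapping quality
#'   below 30 (removed by the quality filter).
#' @param mismatch_frac Fraction of reads flagged with a first-base mismatch.
#' @param rloop_coupling Slope (log2 DRIP intensity per unit site foldedness)
#'   linking folding to R-loop propensity; negative means folded sites form
#'   fewer R-loops.
#' @param drip_depth Expected DRIP reads per site at average foldedness.
#' @param input_depth Expected input-chromatin reads per site (uniform).
#' @param mu_fold_coupling Slope (log2 mutation rate per unit foldedness);
#'   negative plants the antimutator effect of folding.
#' @param mu_rloop_coupling Slope (log2 mutation rate per unit planted R-loop
#'   log2-enrichment); positive plants R-loop-driven mutagenesis.
#' @param k_base Expected mutation count per site on the whole tree at
#'   average foldedness (the Poisson budget spread over branches).
#' @param n_tips Number of tips of the simulated phylogeny.
#' @param branch_rate Rate of the exponential branch-length distribution.
#' @param seed Integer seed fixing all draws.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 2, seed = 7)
#' truths <- simulate_genes(cfg)
sim_config <- function(n_genes = 50,
                       gene_length_range = c(120L, 240L),
                       depth_per_nt = 30,
                       dmso_background = 1,
                       nai_multiplier = 8,
                       footprint = 18L,
                       n_transitions = 1L,
                       transition_effect = 0.8,
                       contaminant_frac = 0.02,
                       mismatch_frac = 0.01,
                       rloop_coupling = -3,
                       drip_depth = 20,
                       input_depth = 20,
                       mu_fold_coupling = -2,
                       mu_rloop_coupling = 1,
                       k_base = 3,
                       n_tips = 190L,
                       branch_rate = 1,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    depth_per_nt = depth_per_nt,
    dmso_background = dmso_background,
    nai_multiplier = nai_multiplier,
    footprint = as.integer(footprint),
    n_transitions = as.integer(n_transitions),
    transition_effect = transition_effect,
    contaminant_frac = contaminant_frac,
    mismatch_frac = mismatch_frac,
    rloop_coupling = rloop_coupling,
    drip_depth = drip_depth,
    input_depth = input_depth,
    mu_fold_coupling = mu_fold_coupling,
    mu_rloop_coupling = mu_rloop_coupling,
    k_base = k_base,
    n_tips = as.integer(n_tips),
    branch_rate = branch_rate,
    seed = as.integer(seed)
  )
  if (cfg$n_genes < 0L) stop("n_genes must be non-negative")
  if (any(cfg$gene_length_range <= 0L)) {
    stop("gene lengths must be positive")
  }
  if (cfg$gene_length_range[1] > cfg$gene_length_range[2]) {
    stop("gene_length_range must be non-decreasing")
  }
  rates <- c(cfg$depth_per_nt, cfg$dmso_background, cfg$nai_multiplier,
             cfg$drip_depth, cfg$input_depth, cfg$k_base, cfg$branch_rate)
  if (any(rates < 0)) stop("all rates must be non-negative")
  if (cfg$transition_effect < 0 || cfg$transition_effect > 1) {
    stop("transition_effect must lie in [0, 1]")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Sub-seed for stage `offset`; kept within 32-bit integer range.
sim_seed <- function(config, offset) {
  as.integer((as.numeric(config$seed) * 101 + offset) %% .Machine$integer.max)
}
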