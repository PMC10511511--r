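#' Run the full analysis pipeline on a synthetic bundle
#'
#' Generates planted-truth inputs with the synthetic-data module, then runs
#' every analysis stage in order: read filtering and deduplication, RT-stop
#' assignment, single-stranded scoring and gene summaries, per-intermediate
#' matrices and transition detection (for the first `n_transition_genes`
#' genes), R-loop scoring, per-site mutation rates on the simulated
#' phylogeny, the correspondence statistics (among-gene correlations,
#' MH-combined within-gene odds ratios, within-gene permutation test) and
#' the per-gene fold-reduction / selection-coefficient model. When
#' `out_dir` is given, the canonical tables plus a manifest (package
#' version, seeds, input checksums) are written there.
#'
#' @param config A [sim_config()].
#' @param n_perm Permutations for the within-gene null.
#' @param n_boot Bootstrap resamples for the combined-OR s.d.
#' @param n_transition_genes Genes scanned for structural transitions
#'   (the scan is the most expensive stage; default 10).
#' @param min_mean_stops Gene filter: minimum mean NAI RT stops per
#'   nucleotide for gene-level summaries (default 1).
#' @param out_dir Optional output directory.
#' @return A list bundle with elements `truths`, `reads`, `stops`, `scored`,
#'   `genes` (per-gene joined table), `site_table`, `transitions`, `rloop`,
#'   `rates`, `correlations`, `ors`, `permutation`, `fold_reductions`,
#'   `selection`.
#' @export
run_pipeline <- function(config = sim_config(), n_perm = 200L,
                         n_boot = 200L, n_transition_genes = 10L,
                         min_mean_stops = 1, out_dir = NULL) {
  truths <- simulate_genes(config)
  if (length(truths) == 0L) stop("configuration produced no genes")
  reads <- simulate_espet_reads(truths, config)
  if (nrow(reads) == 0L) stop("simulated read table is empty")
  coverage <- simulate_rloop_counts(truths, config)
  phylo <- simulate_phylogeny_and_mutations(truths, config)

  gene_lengths <- stats::setNames(
    vapply(truths, `[[`, integer(1), "length"),
    vapply(truths, `[[`, character(1), "gene_id"))

  filtered <- filter_and_dedup(reads)
  stops <- assign_rt_stops(filtered, gene_lengths)
  scored <- single_stranded_score(stops)
  summaries <- gene_summary(scored)

  trans <- lapply(truths[seq_len(min(n_transition_genes, length(truths)))],
                  function(truth) {
    recs <- filtered[filtered$gene_id == truth$gene_id, , drop = FALSE]
    imat <- build_intermediate_matrix(recs, truth$length,
                                      footprint = truth$footprint)
    tf <- transition_fraction(imat)
    data.frame(gene_id = truth$gene_id, fraction = tf$fraction,
               informative = tf$informative, flagged = tf$flagged,
               stringsAsFactors = FALSE)
  })
  trans <- do.call(rbind, trans)

  rl <- rloop_score(coverage)
  rates <- site_rates(phylo$tree, phylo$genotypes)

  site_table <- scored[, c("gene_id", "pos", "theta")]
  key <- paste0(site_table$gene_id, ":", site_table$pos)
  site_table$rloop <- rl$sites$score[match(key, paste0(rl$sites$gene_id, ":",
                                                       rl$sites$pos))]
  site_table$mu <- rates$rate[match(key, rates$site)]

  keep_genes <- summaries$gene_id[summaries$mean_stops_nai >= min_mean_stops]
  mu_gene <- tapply(site_table$mu, site_table$gene_id,
                    function(v) mean(v, na.rm = TRUE))
  genes <- summaries
  genes$rloop <- rl$genes$rloop_score[match(genes$gene_id,
                                            rl$genes$gene_id)]
  genes$mu <- as.numeric(mu_gene[genes$gene_id])
  genes <- genes[genes$gene_id %in% keep_genes, , drop = FALSE]

  gene_table <- data.frame(gene_id = genes$gene_id,
                           structure = -genes$mean_theta,
                           rloop = genes$rloop, mu = genes$mu,
                           stringsAsFactors = FALSE)
  correlations <- gene_level_correlations(gene_table)
  ors <- correspondence_ors(site_table, n_boot = n_boot,
                            seed = sim_seed(config, 10L))
  permutation <- permutation_null(site_table, n_perm = n_perm,
                                  seed = sim_seed(config, 11L))

  fold <- lapply(truths, function(truth) {
    g <- site_table[site_table$gene_id == truth$gene_id, , drop = FALSE]
    rate <- g$mu
    rate[is.na(rate)] <- NA_real_
    fr <- fold_reduction(g$theta, rate)
    if (length(fr) == 0L) return(NULL)
    data.frame(gene_id = truth$gene_id, x = fr$x, capped = fr$capped,
               stringsAsFactors = FALSE)
  })
  fold <- do.call(rbind, fold[!vapply(fold, is.null, logical(1))])
  params <- selection_params()
  selection <- NULL
  if (!is.null(fold) && nrow(fold) > 0L) {
    selection <- fold
    selection$s <- suppressWarnings(
      selection_coefficient(selection$x, params))
    selection$above_drift <- selection$s > 1 / params$Ne
  }

  bundle <- list(truths = truths, reads = reads, stops = stops,
                 scored = scored, genes = genes, site_table = site_table,
                 transitions = trans, rloop = rl, rates = rates,
                 correlations = correlations, ors = ors,
                 permutation = permutation, fold_reductions = fold,
                 selection = selection, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p_reads <- file.path(out_dir, "pair_table.tsv")
    write_pair_table(reads, p_reads)
    p_cov <- file.path(out_dir, "rloop_coverage.tsv")
    write_coverage_table(coverage, p_cov)
    p_tree <- file.path(out_dir, "tree.nwk")
    ape::write.tree(phylo$tree, p_tree)
    p_geno <- file.path(out_dir, "genotypes.tsv")
    write_genotype_matrix(phylo$genotypes, p_geno)
    write_score_track(scored[, c("gene_id", "pos", "theta", "low_coverage")],
                      file.path(out_dir, "theta_track.tsv"))
    write_score_track(site_table, file.path(out_dir, "site_table.tsv"))
    manifest <- list(
      package = "nascentfold",
      version = as.character(utils::packageVersion("nascentfold")),
      seed = config$seed,
      perm_seed = permutation$seed,
      inputs = lapply(stats::setNames(
        c(p_reads, p_cov, p_tree, p_geno),
        c("pair_table", "rloop_coverage", "tree", "genotypes")),
        function(p) unname(tools::md5sum(p)))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  bundle
}
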