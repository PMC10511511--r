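#' Per-site and per-gene R-loop scores from DRIP-style coverage
#'
#' For each site, with `n` the number of reads whose 5'-most nucleotide maps
#' to the site and `m` the genome-wide sum of `n`, the log-abundance is
#' `x = log2((n + 1) / m)`; the R-loop score of a site is `x` from the
#' DRIP/wild-type track minus `x` from the input-chromatin track. Sites with
#' no coverage in either track keep the formula's value rather than being
#' dropped. Per-gene scores aggregate site scores by the mean (or median).
#'
#' @param coverage Data frame with columns `gene_id`, `pos`, `drip`, `input`
#'   (per-site counts; the site universe, typically gene bodies).
#' @param aggregate Per-gene aggregator, `"mean"` (default) or `"median"`.
#' @return List with `sites` (the input plus a `score` column) and `genes`
#'   (data frame `gene_id`, `rloop_score`, `n_sites`).
#' @export
rloop_score <- function(coverage, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  stopifnot(all(c("gene_id", "pos", "drip", "input") %in% names(coverage)))
  m_wt <- sum(coverage$drip)
  m_in <- sum(coverage$input)
  if (m_wt == 0 || m_in == 0) stop("zero total coverage in a track")
  coverage$score <- log2((coverage$drip + 1) / m_wt) -
    log2((coverage$input + 1) / m_in)
  agg <- if (aggregate == "mean") mean else stats::median
  sc <- tapply(coverage$score, coverage$gene_id, agg)
  genes <- data.frame(gene_id = names(sc), rloop_score = as.numeric(sc),
                      n_sites = as.integer(table(coverage$gene_id)[names(sc)]),
                      stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  list(sites = coverage, genes = genes)
}
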