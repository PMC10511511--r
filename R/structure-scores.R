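#' Depth-normalization constants for the two probing libraries
#'
#' With library totals `S_DMSO` and `S_NAI` (total mapped reads per sample),
#' the constants `k_DMSO = (S_DMSO + S_NAI) / (2 S_DMSO)` and
#' `k_NAI = (S_DMSO + S_NAI) / (2 S_NAI)` rescale raw stop counts so both
#' libraries contribute at the average depth.
#'
#' @param S_dmso,S_nai Positive library totals.
#' @return Named numeric vector `c(k_dmso =, k_nai =)`.
#' @export
normalization_constants <- function(S_dmso, S_nai) {
  if (S_dmso <= 0 || S_nai <= 0) {
    stop("library totals must be positive")
  }
  tot <- S_dmso + S_nai
  c(k_dmso = tot / (2 * S_dmso), k_nai = tot / (2 * S_nai))
}

#' Per-nucleotide single-stranded score
#'
#' For every nucleotide the raw NAI-N3 and DMSO RT-stop counts are depth
#' normalized (`N_t(i) = k_t * n_t(i)`) and combined as
#' `theta(i) = log2((N_NAI(i) + 1) / (N_DMSO(i) + 1) + 1)`, with pseudocounts
#' of 1 keeping the score strictly positive; raw scores above `cap` are capped
#' (default 7). Higher theta means a more flexible, likely unpaired
#' nucleotide. Positions with zero coverage in both libraries take the
#' formula's value of 1 but are flagged `low_coverage`.
#'
#' @param stops Stop-count table from [assign_rt_stops()] (columns `gene_id`,
#'   `pos`, `n_nai`, `n_dmso`; attribute `S` with library totals), or any
#'   data frame with those columns if `S` is given.
#' @param S Optional named vector `c(NAI =, DMSO =)` of library totals,
#'   overriding the attribute.
#' @param cap Score ceiling (default 7).
#' @return The input with columns `theta` and `low_coverage` added.
#' @export
single_stranded_score <- function(stops, S = attr(stops, "S"), cap = 7) {
  stopifnot(all(c("gene_id", "pos", "n_nai", "n_dmso") %in% names(stops)))
  if (is.null(S)) stop("library totals S are required")
  k <- normalization_constants(S[["DMSO"]], S[["NAI"]])
  theta <- theta_score(stops$n_nai, stops$n_dmso,
                       k_nai = k[["k_nai"]], k_dmso = k[["k_dmso"]], cap = cap)
  stops$theta <- theta
  stops$low_coverage <- stops$n_nai == 0L & stops$n_dmso == 0L
  stops
}

#' @rdname single_stranded_score
#' @param n_nai,n_dmso Raw stop counts.
#' @param k_nai,k_dmso Normalization constants.
#' @export
theta_score <- function(n_nai, n_dmso, k_nai = 1, k_dmso = 1, cap = 7) {
  raw <- log2((k_nai * n_nai + 1) / (k_dmso * n_dmso + 1) + 1)
  pmin(raw, cap)
}

#' Gene-level structure summaries
#'
#' The gene score is the arithmetic mean of its nucleotides' single-stranded
#' scores; the Gini index of the same scores summarizes how unevenly
#' flexibility is distributed (a higher Gini marks a more structured gene,
#' since folded regions concentrate the signal in few unpaired sites).
#' Low-coverage positions are excluded by default, and genes are annotated
#' with their mean NAI RT-stop coverage so the standard ">= 1 average stop
#' per nucleotide" gene filter can be applied downstream.
#'
#' @param scored Output of [single_stranded_score()].
#' @param exclude_low_coverage Drop flagged positions from the summaries.
#' @return Data frame per gene: `gene_id`, `n_sites`, `mean_stops_nai`,
#'   `mean_theta`, `gini_theta`.
#' @export
gene_summary <- function(scored, exclude_low_coverage = TRUE) {
  stopifnot(all(c("gene_id", "theta") %in% names(scored)))
  use <- scored
  if (exclude_low_coverage && "low_coverage" %in% names(use)) {
    use <- use[!use$low_coverage, , drop = FALSE]
  }
  genes <- unique(scored$gene_id)
  res <- do.call(rbind, lapply(genes, function(g) {
    th <- use$theta[use$gene_id == g]
    all_g <- scored[scored$gene_id == g, , drop = FALSE]
    if (length(th) < 2L) {
      stop("gene ", g, " has fewer than 2 scored nucleotides")
    }
    data.frame(gene_id = g, n_sites = length(th),
               mean_stops_nai = mean(all_g$n_nai),
               mean_theta = mean(th), gini_theta = gini(th),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Gini index of a non-negative vector
#'
#' Standard mean-absolute-difference definition,
#' `G = sum_i sum_j |x_i - x_j| / (2 n^2 mean(x))`, computed via the sorted
#' form in O(n log n).
#'
#' @param x Non-negative numeric vector.
#' @return Gini index in `[0, 1)`.
#' @export
gini <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L || mean(x) == 0) return(NA_real_)
  xs <- sort(x)
  (2 * sum(seq_len(n) * xs) / (n * sum(xs))) - (n + 1) / n
}

#' Structural similarity between two score profiles
#'
#' Pearson correlation of two single-stranded score profiles of the same gene
#' over shared scored positions (e.g. nascent vs mature RNA).
#'
#' @param theta_a,theta_b Numeric score vectors aligned by position (`NA`
#'   marks unscored positions).
#' @return Pearson `r`, or `NA` with a warning when either profile has zero
#'   variance over the shared positions.
#' @export
structural_similarity <- function(theta_a, theta_b) {
  stopifnot(length(theta_a) == length(theta_b))
  ok <- !is.na(theta_a) & !is.na(theta_b)
  if (sum(ok) < 3L) stop("need at least 3 shared scored positions")
  if (stats::sd(theta_a[ok]) == 0 || stats::sd(theta_b[ok]) == 0) {
    warning("zero-variance profile; similarity undefined")
    return(NA_real_)
  }
  stats::cor(theta_a[ok], theta_b[ok])
}
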