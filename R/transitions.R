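#' Longitudinal RT-stop profile of one nucleotide
#'
#' Extracts, from a per-intermediate density matrix, the trajectory of a
#' nucleotide's winsorized RT-stop density across the transcriptional
#' intermediates in which it is exposed (intermediate length at least
#' `pos + footprint`).
#'
#' @param imat An `intermediate_matrix` from [build_intermediate_matrix()].
#' @param pos Nucleotide position within the gene.
#' @return List with `gene_id`, `pos`, `lengths` (increasing intermediate
#'   lengths), `density` (winsorized densities) and `reads` (raw counts).
#' @export
longitudinal_profile <- function(imat, pos) {
  stopifnot(inherits(imat, "intermediate_matrix"))
  rows <- which(imat$lengths >= pos + imat$footprint)
  list(gene_id = imat$gene_id, pos = pos,
       lengths = imat$lengths[rows],
       density = imat$density[rows, pos],
       reads = imat$raw[rows, pos])
}

#' Detect cotranscriptional structural transitions at one nucleotide
#'
#' Scans the longitudinal density profile with a sliding window of `window`
#' consecutive intermediate lengths (step 1). Within each window the first
#' and last `window/2` lengths form two halves; windows are evaluable only if
#' each half contains at least one raw read. Evaluable halves are compared
#' with a two-sided Wilcoxon rank-sum test on the density values (exact p for
#' small tie-free samples, normal approximation with tie correction
#' otherwise), and windows with `p < alpha` are called transitions.
#'
#' @param profile Output of [longitudinal_profile()] (or any list with
#'   `density` and `reads` vectors over increasing lengths).
#' @param window Window size in intermediate lengths (default 50).
#' @param alpha Per-window significance threshold (default 0.05).
#' @param adjust Optional multiple-testing correction applied to the window
#'   p-values before thresholding (`"none"`, default, or `"BH"`).
#' @return Data frame with one row per evaluated window: `start` (index),
#'   `L_start` (intermediate length at the window start, if lengths known),
#'   `p`, `significant`. Attribute `n_evaluable` counts evaluable windows.
#'   Profiles shorter than `window` return an empty frame with attribute
#'   `too_short = TRUE`.
#' @export
detect_transitions <- function(profile, window = 50L, alpha = 0.05,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  d <- profile$density
  r <- profile$reads
  n <- length(d)
  half <- window %/% 2L
  empty <- data.frame(start = integer(), L_start = integer(),
                      p = numeric(), significant = logical())
  if (n < window) {
    attr(empty, "too_short") <- TRUE
    attr(empty, "n_evaluable") <- 0L
    return(empty)
  }
  starts <- seq_len(n - window + 1L)
  # cumulative read sums make the >=1-read-per-half rule O(1) per window
  cr <- cumsum(ifelse(is.na(r), 0, r))
  half_sum <- function(from, to) cr[to] - if (from > 1L) cr[from - 1L] else 0
  pvals <- rep(NA_real_, length(starts))
  for (s in starts) {
    if (half_sum(s, s + half - 1L) < 1 ||
        half_sum(s + half, s + window - 1L) < 1) {
      next                               # not evaluable
    }
    pvals[s] <- ranksum_p(d[s:(s + half - 1L)],
                          d[(s + half):(s + window - 1L)])
  }
  keep <- !is.na(pvals)
  if (!any(keep)) {
    attr(empty, "n_evaluable") <- 0L
    return(empty)
  }
  res <- data.frame(
    start = starts[keep],
    L_start = if (!is.null(profile$lengths))
      profile$lengths[starts[keep]] else NA_integer_,
    p = pvals[keep])
  if (adjust == "BH") res$p_adj <- stats::p.adjust(res$p, "BH")
  res$significant <- (if (adjust == "BH") res$p_adj else res$p) < alpha
  attr(res, "n_evaluable") <- nrow(res)
  res
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact p for tie-free samples with fewer than 50 values on each side,
#' normal approximation with tie correction and continuity correction
#' otherwise (the same switch [stats::wilcox.test()] uses); all-tied samples
#' return 1.
#'
#' @param x,y Numeric samples.
#' @return Two-sided p-value.
#' @export
ranksum_p <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0L || n2 == 0L) return(NA_real_)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0L
  if (!has_ties && n1 < 50L && n2 < 50L) {
    p <- if (W > n1 * n2 / 2) {
      2 * stats::pwilcox(W - 1, n1, n2, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(W, n1, n2)
    }
    return(min(p, 1))
  }
  nties <- table(r)
  n <- n1 + n2
  sigma2 <- (n1 * n2 / 12) *
    ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- W - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
  2 * stats::pnorm(-abs(z))
}

#' Fraction of nucleotides with a significant structural transition
#'
#' A nucleotide is informative when it has at least one evaluable window
#' (see [detect_transitions()]); it is flagged when any of its windows is
#' significant. The transition fraction of a gene is flagged/informative,
#' `NA` when no nucleotide is informative.
#'
#' @param imat An `intermediate_matrix`.
#' @inheritParams detect_transitions
#' @return List with `fraction`, `informative`, `flagged`, and `calls` (data
#'   frame per informative nucleotide: `pos`, `best_L`, `min_p`,
#'   `significant`).
#' @export
transition_fraction <- function(imat, window = 50L, alpha = 0.05,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  n_pos <- ncol(imat$raw)
  calls <- lapply(seq_len(n_pos), function(i) {
    prof <- longitudinal_profile(imat, i)
    det <- detect_transitions(prof, window = window, alpha = alpha,
                              adjust = adjust)
    if (attr(det, "n_evaluable") == 0L) return(NULL)
    best <- which.min(det$p)
    data.frame(pos = i, best_L = det$L_start[best], min_p = det$p[best],
               significant = any(det$significant))
  })
  calls <- do.call(rbind, calls)
  if (is.null(calls)) {
    return(list(fraction = NA_real_, informative = 0L, flagged = 0L,
                calls = data.frame(pos = integer(), best_L = integer(),
                                   min_p = numeric(), significant = logical())))
  }
  list(fraction = mean(calls$significant),
       informative = nrow(calls),
       flagged = sum(calls$significant),
       calls = calls)
}
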