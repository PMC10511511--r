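#' Parameters of the mutation-rate-modifier selection model
#'
#' Defaults follow the standard yeast figures: 70% of mutations at a target
#' site deleterious, a folding-altering mutation influencing a 10-nt target,
#' a genomic average per-generation per-nucleotide mutation rate of
#' 3.3e-10, and an effective population size of 1e7.
#'
#' @param f_del Fraction of target-site mutations that are deleterious.
#' @param target_size Nucleotides whose mutation rate one folding-altering
#'   mutation affects.
#' @param y Per-generation per-nucleotide mutation rate.
#' @param Ne Effective population size.
#' @return List of class `selection_params`.
#' @export
selection_params <- function(f_del = 0.7, target_size = 10, y = 3.3e-10,
                             Ne = 1e7) {
  stopifnot(f_del > 0, f_del <= 1, target_size > 0, y > 0, Ne > 0)
  structure(list(f_del = f_del, target_size = target_size, y = y, Ne = Ne),
            class = "selection_params")
}

#' Per-gene fold reduction of mutation rate across structure extremes
#'
#' Within one gene, slides 50-bp windows (step 1) over the single-stranded
#' score profile, picks the window with the highest and the window with the
#' lowest mean score (each required to contain at least one site with
#' mutation-rate data; the two windows may not overlap), and returns the
#' ratio of mean mutation rates, most-unstructured over most-structured.
#' Division by zero (a structured window with no observed mutations) is
#' capped.
#'
#' @param theta Per-nucleotide single-stranded scores (`NA` = unscored).
#' @param rate Per-nucleotide relative mutation rates (`NA` = no data).
#' @param window Window size in nt (default 50).
#' @param min_frac Minimum fraction of sites with rate data (default 0.05);
#'   genes below it are excluded.
#' @param cap Value assigned to infinite ratios (default 50).
#' @return List with `x` (the fold reduction), `max_window` and `min_window`
#'   (start positions), `capped`; genes failing the filters return an empty
#'   list whose `"reason"` attribute names the exclusion.
#' @export
fold_reduction <- function(theta, rate, window = 50L, min_frac = 0.05,
                           cap = 50) {
  n <- length(theta)
  stopifnot(length(rate) == n)
  if (n < 2L * window) {
    return(structure(list(), reason = "gene shorter than two windows"))
  }
  if (mean(!is.na(rate)) < min_frac) {
    return(structure(list(), reason = "insufficient mutation rate data"))
  }
  starts <- seq_len(n - window + 1L)
  win_stat <- function(v, fun) {
    vapply(starts, function(s) fun(v[s:(s + window - 1L)]), numeric(1))
  }
  mean_theta <- win_stat(theta, function(v) mean(v, na.rm = TRUE))
  n_rate <- win_stat(rate, function(v) sum(!is.na(v)))
  mean_rate <- win_stat(rate, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  eligible <- n_rate >= 1L & is.finite(mean_theta)
  if (!any(eligible)) {
    return(structure(list(), reason = "no eligible window"))
  }
  i_max <- starts[eligible][which.max(mean_theta[eligible])]
  non_overlap <- eligible & abs(starts - i_max) >= window
  if (!any(non_overlap)) {
    return(structure(list(), reason = "no non-overlapping low-score window"))
  }
  i_min <- starts[non_overlap][which.min(mean_theta[non_overlap])]
  num <- mean_rate[starts == i_max]
  den <- mean_rate[starts == i_min]
  capped <- FALSE
  if (den == 0) {
    x <- cap
    capped <- TRUE
  } else {
    x <- num / den
    if (!is.finite(x) || x > cap) {
      x <- min(x, cap, na.rm = TRUE)
      capped <- TRUE
    }
  }
  list(x = x, max_window = i_max, min_window = i_min, capped = capped)
}

#' Selection coefficient of a folding-strengthening mutation
#'
#' A mutation that strengthens nascent RNA folding and thereby reduces the
#' mutation rate of its target by `x`-fold gains a fitness advantage equal to
#' the reduction of the deleterious mutation rate:
#' `s = f_del * target_size * (x - 1) * y`.
#'
#' @param x Fold reduction in mutation rate (values below 1, the
#'   folding-weakening direction, yield a negative `s` with a warning).
#' @param params A [selection_params()].
#' @return The selection coefficient `s` (vectorized over `x`).
#' @export
selection_coefficient <- function(x, params = selection_params()) {
  if (any(x < 1)) warning("x < 1: folding-weakening direction, s < 0")
  params$f_del * params$target_size * (x - 1) * params$y
}

#' Phase diagram of the selection coefficient with the drift boundary
#'
#' Evaluates `s` on a grid of fold reductions `x` and mutation rates `y` and
#' returns the `s = 1/Ne` contour, above which the advantage is large enough
#' to be seen by selection. The contour satisfies
#' `(x - 1) y = 1 / (Ne f_del target_size)` exactly.
#'
#' @param x_grid,y_grid Positive numeric grids.
#' @param params A [selection_params()] (its `y` is ignored; the grid
#'   supplies it).
#' @return List with `grid` (data frame `x`, `y`, `s`) and `contour` (data
#'   frame `x`, `y` with `s = 1/Ne`).
#' @export
phase_boundary <- function(x_grid, y_grid, params = selection_params()) {
  stopifnot(all(x_grid > 0), all(y_grid > 0))
  grid <- expand.grid(x = x_grid, y = y_grid)
  grid$s <- params$f_del * params$target_size * (grid$x - 1) * grid$y
  crit <- 1 / (params$Ne * params$f_del * params$target_size)
  contour <- data.frame(y = y_grid, x = 1 + crit / y_grid)
  list(grid = grid, contour = contour, s_crit = 1 / params$Ne)
}
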