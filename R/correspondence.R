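# Statistics linking nascent RNA folding, R-loops and mutation rate.
#
# Conventions: "structure prevalence" enters as the negative single-stranded
# score (or its Gini index), so under the competitive-inhibition model the
# expected signs are: structure vs R-loop negative, R-loop vs mutation rate
# positive, structure vs mutation rate negative.

#' Among-gene rank correlations between folding, R-loop and mutation rate
#'
#' @param gene_table Data frame with one row per gene and columns
#'   `structure` (prevalence of nascent RNA structure, e.g. negative mean
#'   single-stranded score or Gini index), `rloop` and `mu`.
#' @return Data frame with `pair`, Spearman `rho`, and two-sided `p`.
#' @export
gene_level_correlations <- function(gene_table) {
  stopifnot(all(c("structure", "rloop", "mu") %in% names(gene_table)))
  if (nrow(gene_table) < 10L) stop("need at least 10 genes")
  pairs <- list(`structure-rloop` = c("structure", "rloop"),
                `rloop-mu` = c("rloop", "mu"),
                `structure-mu` = c("structure", "mu"))
  res <- lapply(names(pairs), function(nm) {
    x <- gene_table[[pairs[[nm]][1]]]
    y <- gene_table[[pairs[[nm]][2]]]
    ok <- !is.na(x) & !is.na(y)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(data.frame(pair = nm, rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    data.frame(pair = nm, rho = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, res)
}

#' First-order partial Spearman correlation
#'
#' `(rho_xy - rho_xz rho_yz) / sqrt((1 - rho_xz^2)(1 - rho_yz^2))` computed
#' on the Spearman correlations of the three variables over complete triples.
#'
#' @param x,y Variables of interest.
#' @param z Controlled variable.
#' @return Partial rank correlation; `NA` with a warning when `|rho_xz|` or
#'   `|rho_yz|` is 1 (degenerate control).
#' @export
partial_spearman <- function(x, y, z) {
  ok <- stats::complete.cases(x, y, z)
  if (sum(ok) < 10L) stop("need at least 10 complete triples")
  r_xy <- stats::cor(x[ok], y[ok], method = "spearman")
  r_xz <- stats::cor(x[ok], z[ok], method = "spearman")
  r_yz <- stats::cor(y[ok], z[ok], method = "spearman")
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12) {
    warning("controlled variable collinear with x or y; partial undefined")
    return(NA_real_)
  }
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

#' Fraction of an association mediated by a controlled variable
#'
#' Contrasts a correlation with the corresponding partial correlation:
#' `1 - rho_partial^2 / rho^2`. When the partial correlation shrinks toward
#' zero after controlling a mediator, the fraction approaches 1.
#'
#' @param rho Marginal correlation.
#' @param rho_partial Partial correlation controlling the mediator.
#' @return The mediated fraction (negative values, returned with a warning,
#'   indicate `|rho_partial| > |rho|` and no meaningful mediation).
#' @export
mediated_fraction <- function(rho, rho_partial) {
  if (rho == 0) stop("marginal correlation is zero; fraction undefined")
  frac <- 1 - rho_partial^2 / rho^2
  if (frac < 0) warning("partial exceeds marginal correlation in magnitude")
  frac
}

#' Within-gene fourfold table and odds ratio
#'
#' Dichotomizes two per-nucleotide variables at their within-gene means
#' (strictly above the mean counts as high; ties go low), adds a pseudocount
#' of 1 to each of the four cells, and returns the odds ratio `ad / bc`
#' where `a` counts nucleotides high in both variables.
#'
#' @param x,y Per-nucleotide values of one gene (pairs with `NA` dropped).
#' @return List with `table` (named cells `a`, `b`, `c`, `d`, pseudocounted)
#'   and `or`.
#' @export
within_gene_or <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 complete sites")
  hx <- x > mean(x)
  hy <- y > mean(y)
  cells <- c(a = sum(hx & hy), b = sum(hx & !hy),
             c = sum(!hx & hy), d = sum(!hx & !hy)) + 1
  list(table = cells, or = (cells["a"] * cells["d"]) /
         (cells["b"] * cells["c"]))
}

#' Combine per-gene fourfold tables by the Mantel-Haenszel procedure
#'
#' The common odds ratio is `sum_g(a_g d_g / n_g) / sum_g(b_g c_g / n_g)`
#' over the (pseudocounted) gene tables; significance is the
#' Cochran-Mantel-Haenszel chi-squared test without continuity correction.
#' The standard deviation of the combined OR is estimated by resampling
#' genes with replacement.
#'
#' @param tables List of fourfold tables (named `a`, `b`, `c`, `d` cells, as
#'   produced by [within_gene_or()]`$table`).
#' @param n_boot Bootstrap resamples for the s.d. (default 1000; 0 skips).
#' @param seed Seed for the bootstrap.
#' @return List with `or`, `chisq`, `p`, `boot_sd`, `n_genes`, `seed`.
#' @export
mh_combine <- function(tables, n_boot = 1000L, seed = 1L) {
  if (length(tables) < 1L) stop("need at least one table")
  m <- do.call(rbind, lapply(tables, function(t) t[c("a", "b", "c", "d")]))
  combined_or <- function(m) {
    n <- rowSums(m)
    sum(m[, "a"] * m[, "d"] / n) / sum(m[, "b"] * m[, "c"] / n)
  }
  or <- combined_or(m)
  n <- rowSums(m)
  r1 <- m[, "a"] + m[, "b"]
  r2 <- m[, "c"] + m[, "d"]
  c1 <- m[, "a"] + m[, "c"]
  c2 <- m[, "b"] + m[, "d"]
  e_a <- r1 * c1 / n
  v_a <- r1 * r2 * c1 * c2 / (n^2 * (n - 1))
  chisq <- (sum(m[, "a"]) - sum(e_a))^2 / sum(v_a)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  boot_sd <- NA_real_
  if (n_boot > 0L && nrow(m) > 1L) {
    set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(i) {
      combined_or(m[sample.int(nrow(m), replace = TRUE), , drop = FALSE])
    }, numeric(1))
    boot_sd <- stats::sd(boots)
  }
  list(or = unname(or), chisq = unname(chisq), p = unname(p),
       boot_sd = boot_sd, n_genes = nrow(m), seed = seed)
}

#' Within-gene odds ratios for the three variable pairs, MH-combined
#'
#' Builds per-gene fourfold tables for single-stranded score vs R-loop
#' score (S-R), R-loop score vs mutation rate (R-M) and single-stranded
#' score vs mutation rate (S-M), then combines each set across genes with
#' [mh_combine()]. Under the competitive-inhibition model all three combined
#' ORs exceed 1.
#'
#' @param site_table Data frame with columns `gene_id`, `theta`, `rloop`,
#'   `mu` (per-nucleotide values).
#' @param min_sites Minimum complete sites for a gene to contribute a table.
#' @inheritParams mh_combine
#' @return Named list (`S-R`, `R-M`, `S-M`) of [mh_combine()] results.
#' @export
correspondence_ors <- function(site_table, min_sites = 10L, n_boot = 1000L,
                               seed = 1L) {
  stopifnot(all(c("gene_id", "theta", "rloop", "mu") %in% names(site_table)))
  pairs <- list(`S-R` = c("theta", "rloop"),
                `R-M` = c("rloop", "mu"),
                `S-M` = c("theta", "mu"))
  by_gene <- split(site_table, site_table$gene_id)
  lapply(pairs, function(pr) {
    tabs <- lapply(by_gene, function(g) {
      x <- g[[pr[1]]]
      y <- g[[pr[2]]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < min_sites) return(NULL)
      within_gene_or(x, y)$table
    })
    tabs <- tabs[!vapply(tabs, is.null, logical(1))]
    mh_combine(tabs, n_boot = n_boot, seed = seed)
  })
}

# Mean within-gene Spearman correlations of (-theta, rloop), (rloop, mu) and
# (-theta, mu); operates on pre-split per-gene data for speed.
mean_within_gene_cors <- function(by_gene, min_sites) {
  sums <- c(sr = 0, rm = 0, sm = 0)
  counts <- c(sr = 0L, rm = 0L, sm = 0L)
  for (g in by_gene) {
    s <- -g$theta
    r <- g$rloop
    m <- g$mu
    add <- function(key, x, y) {
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < min_sites) return()
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return()
      sums[key] <<- sums[key] + stats::cor(x[ok], y[ok], method = "spearman")
      counts[key] <<- counts[key] + 1L
    }
    add("sr", s, r)
    add("rm", r, m)
    add("sm", s, m)
  }
  sums / pmax(counts, 1L)
}

#' Permutation null for the mean within-gene correlations
#'
#' The observed statistic is the average, across genes, of the within-gene
#' Spearman correlations between negative single-stranded score, R-loop
#' score and mutation rate (three pairs). The null distribution is built by
#' independently shuffling each of the three per-nucleotide vectors within
#' each gene `n_perm` times. Empirical p-values use the add-one correction
#' `(1 + #{null at least as extreme}) / (n_perm + 1)`, one-sided in the
#' direction the model predicts (negative for the two structure pairs,
#' positive for R-loop vs mutation rate).
#'
#' @inheritParams correspondence_ors
#' @param n_perm Number of permutations (must be positive).
#' @param seed Seed for the shuffles.
#' @param min_sites Minimum complete sites per gene per pair (default 5).
#' @return List with `observed` (named vector `sr`, `rm`, `sm`), `null`
#'   (matrix `n_perm` x 3), `p` (named vector), `seed`.
#' @export
permutation_null <- function(site_table, n_perm = 1000L, seed = 1L,
                             min_sites = 5L) {
  if (n_perm <= 0L) stop("n_perm must be positive")
  stopifnot(all(c("gene_id", "theta", "rloop", "mu") %in% names(site_table)))
  by_gene <- split(site_table[, c("theta", "rloop", "mu")],
                   site_table$gene_id)
  observed <- mean_within_gene_cors(by_gene, min_sites)
  set.seed(seed)
  null <- matrix(NA_real_, nrow = n_perm, ncol = 3,
                 dimnames = list(NULL, c("sr", "rm", "sm")))
  for (b in seq_len(n_perm)) {
    perm <- lapply(by_gene, function(g) {
      n <- length(g$theta)
      list(theta = g$theta[sample.int(n)],
           rloop = g$rloop[sample.int(n)],
           mu = g$mu[sample.int(n)])
    })
    null[b, ] <- mean_within_gene_cors(perm, min_sites)
  }
  side <- c(sr = -1, rm = 1, sm = -1)
  p <- vapply(colnames(null), function(k) {
    if (side[k] > 0) {
      (1 + sum(null[, k] >= observed[k])) / (n_perm + 1)
    } else {
      (1 + sum(null[, k] <= observed[k])) / (n_perm + 1)
    }
  }, numeric(1))
  list(observed = observed, null = null, p = p, seed = seed)
}
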