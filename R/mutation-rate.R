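# Per-site relative mutation rates on a fixed phylogeny.
#
# The estimator conditions on the tree: with total branch length B and k the
# expected number of mutations at a site over the whole tree, the mutation
# count on branch i of length b_i is Poisson(k b_i / B), so a branch changes
# genotype with probability 1 - exp(-k b_i / B). Branches are partitioned by
# an ancestral reconstruction into changed (G1) and unchanged (G0) sets, and
# k is the positive root of d log L / d k = 0. Because B is shared by all
# sites, k / B values are comparable across sites whatever B's actual scale.

BASES <- c("A", "C", "G", "T")
BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

#' Ancestral states at one site by Fitch parsimony
#'
#' Downpass/uppass Fitch reconstruction on a rooted tree (multifurcations
#' handled by sequential pairwise combination). Ambiguities are resolved
#' deterministically: a non-root node keeps its parent's state when that
#' state is in its candidate set; remaining ties (and root ties) are broken
#' toward the state most frequent among the site's tips, then
#' alphabetically.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @param tip_states Character vector of tip genotypes (A/C/G/T), named by
#'   tip label or ordered as `tree$tip.label`.
#' @return Character vector of states for all nodes (tips then internals,
#'   standard `phylo` numbering).
#' @export
infer_ancestral_states <- function(tree, tip_states) {
  if (!is.null(names(tip_states))) tip_states <- tip_states[tree$tip.label]
  geno <- matrix(tip_states, nrow = 1L)
  st <- fitch_states(tree, geno)
  BASES[st[1L, ]]
}

# Vectorized Fitch over many sites: geno is a sites x tips character matrix.
# Returns an integer matrix sites x nodes of state indices into BASES.
fitch_states <- function(tree, geno) {
  n_tip <- length(tree$tip.label)
  n_site <- nrow(geno)
  edge <- tree$edge
  n_node <- max(edge)
  root <- setdiff(unique(edge[, 1]), edge[, 2])

  bit <- matrix(BASE_BITS[geno], nrow = n_site)
  if (anyNA(bit)) stop("tip genotypes must be A/C/G/T")
  masks <- matrix(0L, nrow = n_site, ncol = n_node)
  masks[, seq_len(n_tip)] <- bit

  freq <- vapply(BASES, function(b) rowSums(geno == b), numeric(n_site))
  if (n_site == 1L) freq <- matrix(freq, nrow = 1L)

  po <- ape::reorder.phylo(tree, "postorder")
  parents_po <- unique(po$edge[, 1])
  children_of <- split(edge[, 2], edge[, 1])
  for (p in parents_po) {
    kids <- children_of[[as.character(p)]]
    m <- masks[, kids[1]]
    for (k in kids[-1]) {
      inter <- bitwAnd(m, masks[, k])
      m <- ifelse(inter > 0L, inter, bitwOr(m, masks[, k]))
    }
    masks[, p] <- m
  }

  # choose a state from `mask`, preferring `pref` (bit) when allowed, else
  # by tip-majority then alphabetical order
  pick <- function(mask, pref = NULL) {
    if (!is.null(pref)) {
      ok <- bitwAnd(mask, pref) > 0L
    } else {
      ok <- rep(FALSE, length(mask))
    }
    score <- vapply(1:4, function(b) {
      ifelse(bitwAnd(mask, BASE_BITS[b]) > 0L, freq[, b] * 8 + (4 - b), -1)
    }, numeric(length(mask)))
    if (length(mask) == 1L) score <- matrix(score, nrow = 1L)
    chosen <- max.col(score, ties.method = "first")
    ifelse(ok, as.integer(log2(pref)) + 1L, chosen)
  }

  states <- matrix(0L, nrow = n_site, ncol = n_node)
  states[, root] <- pick(masks[, root])
  cl <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(cl$edge))) {
    p <- cl$edge[e, 1]
    ch <- cl$edge[e, 2]
    pref_bit <- BASE_BITS[states[, p]]
    states[, ch] <- pick(masks[, ch], pref = pref_bit)
  }
  states
}

#' Partition branches into unchanged (G0) and changed (G1) sets
#'
#' A branch belongs to G1 when the reconstructed states of its parent and
#' child differ. `|G1|` equals the parsimony score of the site.
#'
#' @param tree A rooted `phylo`.
#' @param states Node states from [infer_ancestral_states()].
#' @return List with integer edge-index vectors `G0` and `G1`.
#' @export
partition_branches <- function(tree, states) {
  edge <- tree$edge
  changed <- states[edge[, 1]] != states[edge[, 2]]
  list(G0 = which(!changed), G1 = which(changed))
}

#' Maximum-likelihood mutation count at one site
#'
#' Maximizes `L = prod_{i in G1}(1 - exp(-k b_i / B)) prod_{j in G0}
#' exp(-k b_j / B)` in `k`. With G1 empty the likelihood is maximized at the
#' boundary `k = 0`; with G0 empty the log-likelihood increases without bound
#' and the site is flagged (`NA`). Otherwise the unique positive root of the
#' stationarity equation `sum_{G1} (b_i/B) exp(-k b_i/B)/(1 - exp(-k b_i/B))
#' = sum_{G0} b_j/B` is found by bracketing (upper bound doubled until the
#' sign changes) and bisection to relative tolerance 1e-9.
#'
#' @param G0,G1 Integer indices of unchanged/changed branches into `b`.
#' @param b Positive branch lengths of all branches.
#' @param B Total branch length (defaults to `sum(b)`).
#' @return The estimate `k_hat` (0 for invariant sites, `NA` when G0 is
#'   empty).
#' @export
estimate_k <- function(G0, G1, b, B = sum(b)) {
  if (any(b <= 0)) stop("branch lengths must be positive")
  if (length(G1) == 0L) return(0)
  if (length(G0) == 0L) return(NA_real_)
  w1 <- b[G1] / B
  rhs <- sum(b[G0] / B)
  f <- function(k) sum(w1 * exp(-k * w1) / (-expm1(-k * w1))) - rhs
  lo <- 1e-12
  hi <- 1
  while (f(hi) > 0) {
    hi <- hi * 2
    if (hi > 1e12) return(NA_real_)
  }
  while ((hi - lo) > 1e-9 * hi) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Per-site relative mutation rates from a genotype matrix
#'
#' Runs the ancestral reconstruction, branch partition and maximum-likelihood
#' count estimate for every site and divides by the total branch length.
#' Non-segregating sites are assigned a zero (negligible) rate; sites whose
#' reconstruction leaves no unchanged branch are flagged and get `NA`.
#'
#' @param tree A rooted `phylo` with positive branch lengths.
#' @param genotypes Character matrix, sites x tips (colnames matched against
#'   `tree$tip.label`), entries A/C/G/T. Sites with missing entries are
#'   flagged and excluded from estimation.
#' @return Data frame with `site` (rownames of `genotypes`), `segregating`,
#'   `flagged`, `n_changes` (`|G1|`), `k_hat`, `rate` (`k_hat / B`).
#' @export
site_rates <- function(tree, genotypes) {
  if (any(tree$edge.length <= 0)) stop("branch lengths must be positive")
  stopifnot(ncol(genotypes) == length(tree$tip.label))
  if (!is.null(colnames(genotypes))) {
    genotypes <- genotypes[, tree$tip.label, drop = FALSE]
  }
  n_site <- nrow(genotypes)
  B <- sum(tree$edge.length)
  site <- rownames(genotypes)
  if (is.null(site)) site <- as.character(seq_len(n_site))
  out <- data.frame(site = site, segregating = FALSE, flagged = FALSE,
                    n_changes = 0L, k_hat = 0, rate = 0,
                    stringsAsFactors = FALSE)

  ok_base <- matrix(genotypes %in% BASES, nrow = n_site)
  complete <- rowSums(ok_base) == ncol(genotypes)
  out$flagged[!complete] <- TRUE
  out$k_hat[!complete] <- NA_real_
  out$rate[!complete] <- NA_real_

  same_as_first <- rowSums(genotypes == genotypes[, 1]) == ncol(genotypes)
  seg <- complete & !same_as_first
  out$segregating <- seg
  idx <- which(seg)
  if (length(idx) == 0L) return(out)

  states <- fitch_states(tree, genotypes[idx, , drop = FALSE])
  edge <- tree$edge
  b <- tree$edge.length
  changed <- states[, edge[, 1], drop = FALSE] !=
    states[, edge[, 2], drop = FALSE]
  out$n_changes[idx] <- rowSums(changed)
  for (j in seq_along(idx)) {
    g1 <- which(changed[j, ])
    g0 <- which(!changed[j, ])
    kh <- estimate_k(g0, g1, b, B)
    out$k_hat[idx[j]] <- kh
    out$rate[idx[j]] <- kh / B
    if (is.na(kh)) out$flagged[idx[j]] <- TRUE
  }
  out
}

#' Strand assignment of C-to-T mutations
#'
#' Assuming hydrolytic deamination of cytosine dominates C/G-to-T/A events,
#' C-to-T mutations (reference coordinates, Watson strand) happened on the
#' Watson strand and G-to-A mutations are C-to-T events on the Crick strand.
#' The event's role is `coding` when its assigned strand equals the gene's
#' sense strand and `template` otherwise. Other substitution types are
#' excluded (counted in attribute `n_excluded`).
#'
#' @param mutations Data frame with `gene_id`, `pos`, `ref`, `alt` (Watson
#'   strand alleles).
#' @param genes Data frame with `gene_id`, `strand` (`"+"`/`"-"`), and
#'   optionally `c_watson`, `c_crick` (cytosine counts per strand, used to
#'   normalize rates).
#' @return Data frame per gene: `gene_id`, `coding_count`, `template_count`,
#'   plus `coding_rate`, `template_rate` when cytosine counts are supplied.
#' @export
strand_classify <- function(mutations, genes) {
  stopifnot(all(c("gene_id", "pos", "ref", "alt") %in% names(mutations)),
            all(c("gene_id", "strand") %in% names(genes)))
  is_ct <- mutations$ref == "C" & mutations$alt == "T"
  is_ga <- mutations$ref == "G" & mutations$alt == "A"
  n_excluded <- sum(!(is_ct | is_ga))
  mut <- mutations[is_ct | is_ga, , drop = FALSE]
  mut$strand_hit <- ifelse(mut$ref == "C", "+", "-")  # Watson / Crick
  gene_strand <- genes$strand[match(mut$gene_id, genes$gene_id)]
  if (anyNA(gene_strand)) stop("mutation in unannotated gene")
  mut$role <- ifelse(mut$strand_hit == gene_strand, "coding", "template")

  res <- genes[, "gene_id", drop = FALSE]
  tab <- table(factor(mut$gene_id, levels = genes$gene_id), mut$role)
  res$coding_count <- if ("coding" %in% colnames(tab))
    as.integer(tab[, "coding"]) else 0L
  res$template_count <- if ("template" %in% colnames(tab))
    as.integer(tab[, "template"]) else 0L
  if (all(c("c_watson", "c_crick") %in% names(genes))) {
    coding_c <- ifelse(genes$strand == "+", genes$c_watson, genes$c_crick)
    template_c <- ifelse(genes$strand == "+", genes$c_crick, genes$c_watson)
    res$coding_rate <- res$coding_count / coding_c
    res$template_rate <- res$template_count / template_c
  }
  attr(res, "n_excluded") <- n_excluded
  res
}
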