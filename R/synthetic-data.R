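#' Simulate per-gene folding ground truth
#'
#' Draws, for each gene, a per-nucleotide baseline unpairedness (probability a
#' nucleotide is flexible/unpaired) and plants step-change structural
#' transitions: at a transition `(i, L*)` the unpairedness of nucleotide `i`
#' jumps by `transition_effect` once the transcriptional intermediate reaches
#' length `L*`. All other nucleotides keep a constant unpairedness across
#' intermediate lengths (instant folding).
#'
#' @param config A [sim_config()].
#' @return A list of `folding_truth` objects, each a list with `gene_id`,
#'   `length`, `footprint`, `u0` (baseline unpairedness per nucleotide) and
#'   `transitions` (data frame with `pos`, `L_star`, `before`, `after`).
#' @export
simulate_genes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sim_seed(config, 0L))
  if (config$n_genes == 0L) return(list())
  len_choices <- seq(config$gene_length_range[1], config$gene_length_range[2])
  lens <- len_choices[sample.int(length(len_choices), config$n_genes,
                                 replace = TRUE)]
  lapply(seq_len(config$n_genes), function(g) {
    len <- lens[g]
    # gene-level fraction of unpaired (loop) nucleotides varies across genes;
    # per-site unpairedness is bimodal, emulating the near-binary pairing
    # state of stems (low flexibility) versus loops (high flexibility)
    p_g <- 0.2 + 0.6 * stats::rbeta(1, 2, 2)
    loop <- stats::runif(len) < p_g
    u0 <- ifelse(loop, stats::rbeta(len, 8, 2), stats::rbeta(len, 2, 8))
    eff <- config$transition_effect
    fp <- config$footprint
    trans <- data.frame(pos = integer(), L_star = integer(),
                        before = numeric(), after = numeric())
    n_tr <- config$n_transitions
    # a transition is only observable while the site is exposed for a span of
    # lengths on both sides of L*; require some room
    max_pos <- len - fp - 55L
    if (n_tr > 0L && max_pos >= 1L) {
      pos <- sample.int(max_pos, min(n_tr, max_pos))
      trans <- do.call(rbind, lapply(pos, function(i) {
        lo <- i + fp + 25L
        hi <- len - 25L
        L_star <- if (hi > lo) sample(seq(lo, hi), 1L) else lo
        before <- stats::runif(1, 0.02, 1 - eff - 0.02)
        data.frame(pos = i, L_star = as.integer(L_star),
                   before = before, after = before + eff)
      }))
      u0[trans$pos] <- trans$before
    }
    structure(list(gene_id = sprintf("gene%03d", g), length = len,
                   footprint = fp, u0 = u0, transitions = trans),
              class = "folding_truth")
  })
}

#' Unpairedness of every exposed nucleotide at intermediate length L
#'
#' Nucleotides within `footprint` of the 3' end are hidden inside the
#' elongation complex and return no value.
#'
#' @param truth A `folding_truth`.
#' @param L Intermediate length (nt).
#' @return Numeric vector over positions `1..(L - footprint)` (length 0 when
#'   nothing is exposed).
#' @export
unpairedness_at <- function(truth, L) {
  n_exp <- L - truth$footprint
  if (n_exp < 1L) return(numeric(0))
  u <- truth$u0[seq_len(n_exp)]
  tr <- truth$transitions
  if (nrow(tr) > 0L) {
    idx <- tr$pos <= n_exp
    u[tr$pos[idx]] <- ifelse(L < tr$L_star[idx], tr$before[idx], tr$after[idx])
  }
  u
}

# Site foldedness used by the R-loop and mutation-rate couplings: one minus
# the baseline unpairedness (the full-length behaviour after any transition).
site_foldedness <- function(truth) {
  u <- truth$u0
  tr <- truth$transitions
  if (nrow(tr) > 0L) u[tr$pos] <- tr$after
  1 - u
}

#' Simulate eSPET-seq-style read pairs for both treatments
#'
#' Each read pair carries a transcription site (the reverse read's position,
#' drawn uniformly over intermediate lengths with at least one exposed
#' nucleotide) and one RT stop. In the NAI-N3 library the stop position is
#' drawn over exposed nucleotides with weight
#' `dmso_background + nai_multiplier * unpairedness`; the DMSO control samples
#' the background weight only. The forward read's 5' end is one base 3' of the
#' stop (`fwd5 = stop + 1`). UMIs are random 3-mers; a configured fraction of
#' reads carries mapping quality below 30 or a first-base mismatch.
#'
#' @param truths List of `folding_truth` from [simulate_genes()].
#' @param config A [sim_config()].
#' @return Data frame with columns `gene_id`, `treatment` ("NAI"/"DMSO"),
#'   `fwd5`, `txn_site`, `umi`, `mapq`, `first_base_mismatch`.
#' @export
simulate_espet_reads <- function(truths, config) {
  stopifnot(inherits(config, "sim_config"), length(truths) > 0L)
  set.seed(sim_seed(config, 1L))
  umis <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            c("A", "C", "G", "T")), 1, paste0, collapse = "")
  out <- vector("list", 2L * length(truths))
  k <- 0L
  for (truth in truths) {
    len <- truth$length
    fp <- truth$footprint
    n_reads <- as.integer(round(config$depth_per_nt * len))
    for (trt in c("NAI", "DMSO")) {
      k <- k + 1L
      if (n_reads == 0L || len <= fp) next
      L_choices <- seq(fp + 1L, len)
      L <- L_choices[sample.int(length(L_choices), n_reads, replace = TRUE)]
      stop_pos <- integer(n_reads)
      keep <- rep(TRUE, n_reads)
      for (Lv in sort(unique(L))) {
        idx <- which(L == Lv)
        w <- rep(config$dmso_background, Lv - fp)
        if (trt == "NAI") {
          w <- w + config$nai_multiplier * unpairedness_at(truth, Lv)
        }
        if (sum(w) <= 0) {            # no stop can occur: read never made
          keep[idx] <- FALSE
          next
        }
        stop_pos[idx] <- sample.int(Lv - fp, length(idx), replace = TRUE,
                                    prob = w)
      }
      n_kept <- sum(keep)
      if (n_kept == 0L) next
      mapq <- ifelse(stats::runif(n_kept) < config$contaminant_frac,
                     sample(0:29, n_kept, replace = TRUE), 42L)
      out[[k]] <- data.frame(
        gene_id = truth$gene_id,
        treatment = trt,
        fwd5 = stop_pos[keep] + 1L,
        txn_site = L[keep],
        umi = sample(umis, n_kept, replace = TRUE),
        mapq = as.integer(mapq),
        first_base_mismatch = stats::runif(n_kept) < config$mismatch_frac,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(), treatment = character(),
                      fwd5 = integer(), txn_site = integer(),
                      umi = character(), mapq = integer(),
                      first_base_mismatch = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate DRIP-style and input coverage counts
#'
#' Per-site DRIP intensity is `drip_depth * 2^(rloop_coupling * (foldedness -
#' 0.5))`, so with a negative coupling more-folded sites accumulate fewer
#' DRIP reads; input coverage is uniform. Counts are Poisson.
#'
#' @inheritParams simulate_espet_reads
#' @return Data frame with `gene_id`, `pos`, `drip`, `input` and an attribute
#'   `true_log2_enrichment` (the planted per-site log2 DRIP intensity offset).
#' @export
simulate_rloop_counts <- function(truths, config) {
  stopifnot(inherits(config, "sim_config"), length(truths) > 0L)
  set.seed(sim_seed(config, 2L))
  out <- lapply(truths, function(truth) {
    fold <- site_foldedness(truth)
    e <- config$rloop_coupling * (fold - 0.5)
    data.frame(gene_id = truth$gene_id, pos = seq_len(truth$length),
               drip = stats::rpois(truth$length, config$drip_depth * 2^e),
               input = stats::rpois(truth$length, config$input_depth),
               true_e = e, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  truth_e <- res$true_e
  res$true_e <- NULL
  attr(res, "true_log2_enrichment") <- truth_e
  res
}

#' Simulate a phylogeny and per-site mutations on it
#'
#' Builds a random bifurcating tree with exponential branch lengths, then for
#' every site of every gene sets a true mutation budget
#' `k_true = k_base * 2^(mu_fold_coupling*(fold-0.5) +
#' mu_rloop_coupling*e_rloop)` and drops a Poisson(`k_true * b_i / B`) number
#' of mutations on each branch `i`, propagating genotypes from a random root
#' base (each mutation moves to one of the other three bases).
#'
#' @inheritParams simulate_espet_reads
#' @param rloop_enrichment Optional numeric vector of planted per-site log2
#'   R-loop enrichment (as produced by [simulate_rloop_counts()]); defaults to
#'   recomputing it from the truths.
#' @return List with `tree` (an [ape::read.tree()]-style `phylo`), `genotypes`
#'   (character matrix, sites x tips, rownames `gene:pos`), and `sites` (data
#'   frame with `gene_id`, `pos`, `k_true`, `n_mutations`).
#' @export
simulate_phylogeny_and_mutations <- function(truths, config,
                                             rloop_enrichment = NULL) {
  stopifnot(inherits(config, "sim_config"), length(truths) > 0L)
  if (config$n_tips < 3L) stop("need at least 3 tips")
  set.seed(sim_seed(config, 3L))
  tree <- ape::rtree(config$n_tips, br = function(n) stats::rexp(n, config$branch_rate))
  tree$edge.length <- pmax(tree$edge.length, 1e-6)

  fold <- unlist(lapply(truths, site_foldedness))
  if (is.null(rloop_enrichment)) {
    rloop_enrichment <- unlist(lapply(truths, function(t)
      config$rloop_coupling * (site_foldedness(t) - 0.5)))
  }
  gene_id <- rep(vapply(truths, `[[`, character(1), "gene_id"),
                 vapply(truths, `[[`, integer(1), "length"))
  pos <- unlist(lapply(truths, function(t) seq_len(t$length)))
  k_true <- config$k_base *
    2^(config$mu_fold_coupling * (fold - 0.5) +
       config$mu_rloop_coupling * rloop_enrichment)

  n_sites <- length(k_true)
  bases <- c("A", "C", "G", "T")
  edge <- tree$edge
  b <- tree$edge.length
  B <- sum(b)
  n_nodes <- max(edge)
  root <- setdiff(edge[, 1], edge[, 2])
  # preorder over edges so parent states exist before children are visited
  ord <- ape::reorder.phylo(tree, "cladewise")
  states <- matrix(0L, nrow = n_sites, ncol = n_nodes)
  states[, root] <- sample.int(4L, n_sites, replace = TRUE)
  n_mut_total <- integer(n_sites)
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]
    chi <- ord$edge[e, 2]
    be <- ord$edge.length[e]
    n_mut <- stats::rpois(n_sites, k_true * be / B)
    n_mut_total <- n_mut_total + n_mut
    st <- states[, par]
    hit <- which(n_mut > 0L)
    for (s in hit) {
      for (m in seq_len(n_mut[s])) {
        st[s] <- sample(setdiff(1:4, st[s]), 1L)
      }
    }
    states[, chi] <- st
  }
  tips <- seq_len(config$n_tips)
  geno <- matrix(bases[states[, tips]], nrow = n_sites, ncol = length(tips),
                 dimnames = list(paste0(gene_id, ":", pos), tree$tip.label))
  list(tree = tree,
       genotypes = geno,
       sites = data.frame(gene_id = gene_id, pos = pos, k_true = k_true,
                          n_mutations = n_mut_total,
                          stringsAsFactors = FALSE))
}
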