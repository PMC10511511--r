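# Shared fixtures: tiny configurations and hand-built tables.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_genes = 3L, gene_length_range = c(120L, 160L),
                   depth_per_nt = 10, n_tips = 12L, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# A pair-table row builder with sensible defaults.
pair_row <- function(gene_id = "g1", treatment = "NAI", fwd5 = 10L,
                     txn_site = 60L, umi = "ACG", mapq = 42L,
                     first_base_mismatch = FALSE) {
  data.frame(gene_id = gene_id, treatment = treatment, fwd5 = fwd5,
             txn_site = txn_site, umi = umi, mapq = mapq,
             first_base_mismatch = first_base_mismatch,
             stringsAsFactors = FALSE)
}

pair_rows <- function(...) do.call(rbind, list(...))

# Newick helpers for small reconstruction cases.
star_tree <- function(n, brlen = 1) {
  tips <- paste0("t", seq_len(n))
  txt <- paste0("(", paste0(tips, ":", brlen, collapse = ","), ");")
  ape::read.tree(text = txt)
}

# Log-likelihood of the branch-change data at mutation count k (independent
# oracle used against the stationarity-equation root).
loglik_k <- function(k, G0, G1, b, B = sum(b)) {
  w <- b / B
  sum(log1p(-exp(-k * w[G1]))) - k * sum(w[G0])
}

# Iteratively refined grid argmax of loglik_k: a brute-force maximizer kept
# independent of the root-finding path.
grid_argmax_k <- function(G0, G1, b, B = sum(b), lo = 1e-8, hi = 200,
                          n_grid = 2000, passes = 4) {
  for (i in seq_len(passes)) {
    ks <- seq(lo, hi, length.out = n_grid)
    ll <- vapply(ks, loglik_k, numeric(1), G0 = G0, G1 = G1, b = b, B = B)
    j <- which.max(ll)
    step <- ks[2] - ks[1]
    lo <- max(ks[j] - step, 1e-10)
    hi <- ks[j] + step
  }
  ks[j]
}
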