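test_that("gene simulation respects configuration and is deterministic", {
  expect_length(simulate_genes(tiny_config(n_genes = 0L)), 0L)

  cfg <- tiny_config()
  a <- simulate_genes(cfg)
  b <- simulate_genes(cfg)
  expect_identical(a, b)

  lens <- vapply(a, `[[`, integer(1), "length")
  expect_true(all(lens >= 120L & lens <= 160L))
  for (t in a) {
    expect_true(all(t$u0 >= 0 & t$u0 <= 1))
    expect_equal(nrow(t$transitions), 1L)
    expect_equal(t$transitions$after - t$transitions$before,
                 cfg$transition_effect)
  }
  expect_error(sim_config(gene_length_range = c(0L, 10L)), "positive")
})

test_that("exposure honours the elongation-complex footprint", {
  cfg <- tiny_config()
  t <- simulate_genes(cfg)[[1]]
  expect_length(unpairedness_at(t, cfg$footprint), 0L)
  expect_length(unpairedness_at(t, cfg$footprint + 5L), 5L)
  # transition flips the planted site's unpairedness exactly at L*
  tr <- t$transitions
  expect_equal(unpairedness_at(t, tr$L_star - 1L)[tr$pos], tr$before)
  expect_equal(unpairedness_at(t, tr$L_star)[tr$pos], tr$after)
})

test_that("read simulation conserves depth and tracks the planted truth", {
  cfg <- tiny_config(contaminant_frac = 0, mismatch_frac = 0)
  truths <- simulate_genes(cfg)
  reads <- simulate_espet_reads(truths, cfg)
  expect_identical(reads, simulate_espet_reads(truths, cfg))

  for (t in truths) {
    n_nai <- sum(reads$gene_id == t$gene_id & reads$treatment == "NAI")
    expect_identical(n_nai, as.integer(round(cfg$depth_per_nt * t$length)))
  }
  expect_true(all(reads$fwd5 >= 1L & reads$fwd5 <= reads$txn_site))
  expect_true(all(nchar(reads$umi) == 3L))

  empty <- simulate_espet_reads(truths, tiny_config(depth_per_nt = 0))
  expect_equal(nrow(empty), 0L)
})

test_that("with no modification signal the two libraries are exchangeable", {
  # unpairedness forced to zero: NAI weight reduces to the DMSO background,
  # so the per-position stop-count distributions must agree
  cfg <- tiny_config(n_genes = 1L, nai_multiplier = 0, depth_per_nt = 30,
                     n_transitions = 0L, contaminant_frac = 0,
                     mismatch_frac = 0)
  truths <- simulate_genes(cfg)
  reads <- simulate_espet_reads(truths, cfg)
  stops_of <- function(trt) {
    r <- reads[reads$treatment == trt & reads$fwd5 > 1L, ]
    tabulate(r$fwd5 - 1L, nbins = truths[[1]]$length)
  }
  tab <- rbind(stops_of("NAI"), stops_of("DMSO"))
  keep <- colSums(tab) > 0
  p <- suppressWarnings(stats::chisq.test(tab[, keep])$p.value)
  expect_gt(p, 0.01)
})

test_that("a single fully unpaired nucleotide attracts every NAI stop", {
  cfg <- tiny_config(n_genes = 1L, dmso_background = 0, n_transitions = 0L,
                     contaminant_frac = 0, mismatch_frac = 0)
  truths <- simulate_genes(cfg)
  truths[[1]]$u0[] <- 0
  truths[[1]]$u0[5L] <- 1
  reads <- simulate_espet_reads(truths, cfg)
  nai <- reads[reads$treatment == "NAI", ]
  expect_true(all(nai$fwd5 - 1L == 5L))
  # DMSO has zero sampling weight everywhere: no control reads survive
  expect_equal(sum(reads$treatment == "DMSO"), 0L)
})

test_that("R-loop counts respond to the folding coupling", {
  cfg <- tiny_config(n_genes = 200L, seed = 33L)
  truths <- simulate_genes(cfg)
  cov <- simulate_rloop_counts(truths, cfg)
  rl <- rloop_score(cov)
  fold <- vapply(truths, function(t) mean(1 - t$u0), numeric(1))
  rho <- stats::cor(rl$genes$rloop_score, fold, method = "spearman")
  expect_lt(rho, -0.5)

  # a zero coupling leaves gene scores unrelated to foldedness
  cfg0 <- tiny_config(n_genes = 200L, seed = 33L, rloop_coupling = 0)
  cov0 <- simulate_rloop_counts(simulate_genes(cfg0), cfg0)
  rl0 <- rloop_score(cov0)
  rho0 <- stats::cor(rl0$genes$rloop_score, fold, method = "spearman")
  expect_lt(abs(rho0), 0.2)

  czero <- simulate_rloop_counts(truths, tiny_config(drip_depth = 0,
                                                     input_depth = 0))
  expect_true(all(czero$drip == 0L & czero$input == 0L))
})

test_that("phylogeny simulation plants Poisson mutation budgets", {
  cfg <- tiny_config(n_genes = 2L, n_tips = 10L)
  truths <- simulate_genes(cfg)
  sim <- simulate_phylogeny_and_mutations(truths, cfg)
  sim2 <- simulate_phylogeny_and_mutations(truths, cfg)
  expect_identical(ape::write.tree(sim$tree), ape::write.tree(sim2$tree))
  expect_identical(sim$genotypes, sim2$genotypes)

  # zero budget: every site invariant
  cfg0 <- tiny_config(n_genes = 2L, n_tips = 10L, k_base = 0)
  sim0 <- simulate_phylogeny_and_mutations(simulate_genes(cfg0), cfg0)
  expect_true(all(apply(sim0$genotypes, 1,
                        function(r) length(unique(r)) == 1L)))

  # law of total expectation: realized mutations match the planted budget
  tot <- sum(sim$sites$n_mutations)
  expected <- sum(sim$sites$k_true)
  expect_lt(abs(tot - expected), 5 * sqrt(expected))

  expect_error(simulate_phylogeny_and_mutations(
    truths, tiny_config(n_tips = 2L)), "3 tips")
})

test_that("null couplings leave downstream correlations centred on zero", {
  # planted-null property: with every coupling off, the gene-level
  # correlation between foldedness and R-loop score is noise around 0
  rhos <- vapply(seq_len(100L), function(s) {
    cfg <- sim_config(n_genes = 15L, gene_length_range = c(60L, 80L),
                      rloop_coupling = 0, mu_fold_coupling = 0,
                      mu_rloop_coupling = 0, n_transitions = 0L, seed = s)
    truths <- simulate_genes(cfg)
    rl <- rloop_score(simulate_rloop_counts(truths, cfg))
    fold <- vapply(truths, function(t) mean(1 - t$u0), numeric(1))
    stats::cor(rl$genes$rloop_score[match(
      vapply(truths, `[[`, character(1), "gene_id"), rl$genes$gene_id)],
      fold, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 2 * stats::sd(rhos) / sqrt(length(rhos)) + 0.02)
  expect_gt(stats::t.test(rhos)$p.value, 0.01)
})
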