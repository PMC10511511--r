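test_that("ancestral reconstruction matches small parsimony instances", {
  # invariant site: everything takes the tip state, no branch changes
  tr <- star_tree(5)
  st <- infer_ancestral_states(tr, rep("A", 5))
  expect_true(all(st == "A"))
  expect_length(partition_branches(tr, match(st, c("A", "C", "G", "T")))$G1,
                0L)

  # one T among five A on a star: root A, change on the T terminal branch
  tr6 <- star_tree(6)
  tips <- c(rep("A", 5), "T")
  st6 <- infer_ancestral_states(tr6, tips)
  root <- length(tr6$tip.label) + 1L
  expect_equal(st6[root], "A")
  part <- partition_branches(tr6, match(st6, c("A", "C", "G", "T")))
  expect_equal(part$G1, which(tr6$edge[, 2] == 6L))

  # a T-T cherry sister to three A tips: cherry ancestor T, one stem change
  tree <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,(t4:1,t5:1):1):1);")
  tips2 <- c(t1 = "T", t2 = "T", t3 = "A", t4 = "A", t5 = "A")
  st2 <- infer_ancestral_states(tree, tips2)
  cherry_mrca <- ape::getMRCA(tree, c("t1", "t2"))
  expect_equal(st2[cherry_mrca], "T")
  part2 <- partition_branches(tree, match(st2, c("A", "C", "G", "T")))
  expect_length(part2$G1, 1L)
  expect_equal(tree$edge[part2$G1, 2], cherry_mrca)
})

test_that("branch changes equal the parsimony score on random trees", {
  skip_if_not_installed("phangorn")
  set.seed(5)
  for (i in 1:20) {
    n <- sample(4:15, 1)
    tree <- ape::rtree(n)
    tips <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
                   prob = c(0.5, 0.2, 0.2, 0.1))
    st <- infer_ancestral_states(tree, stats::setNames(tips, tree$tip.label))
    part <- partition_branches(tree, match(st, c("A", "C", "G", "T")))
    dat <- phangorn::phyDat(matrix(tips, ncol = 1,
                                   dimnames = list(tree$tip.label, NULL)))
    expect_equal(length(part$G1), phangorn::parsimony(tree, dat))
    expect_equal(length(part$G0) + length(part$G1), nrow(tree$edge))
  }
})

test_that("the ML mutation count solves the stationarity equation", {
  expect_equal(estimate_k(G0 = 1:4, G1 = integer(0), b = rep(1, 4)), 0)
  expect_true(is.na(estimate_k(G0 = integer(0), G1 = 1:4, b = rep(1, 4))))
  expect_error(estimate_k(1:2, 3, b = c(1, -1, 2)), "positive")

  # star with 4 equal branches, one changed: k = 4 log(4/3) in closed form
  k_star <- estimate_k(G0 = 2:4, G1 = 1L, b = rep(1, 4))
  expect_equal(k_star, 4 * log(4 / 3), tolerance = 1e-8)

  # the root is a local maximum of the log-likelihood
  set.seed(8)
  for (i in 1:10) {
    b <- stats::rexp(12) + 0.05
    G1 <- sample(12, sample(1:10, 1))
    G0 <- setdiff(1:12, G1)
    if (length(G0) == 0) next
    kh <- estimate_k(G0, G1, b)
    ll <- loglik_k(kh, G0, G1, b)
    expect_gte(ll, loglik_k(kh * 1.01, G0, G1, b))
    expect_gte(ll, loglik_k(kh * 0.99, G0, G1, b))
    # scale invariance: only b_i / B enters
    expect_equal(estimate_k(G0, G1, b * 7.3), kh, tolerance = 1e-6)
  }

  # moving a branch from G0 to G1 never decreases the estimate
  b <- c(0.5, 1, 1.5, 2, 0.8)
  k1 <- estimate_k(G0 = 2:5, G1 = 1L, b = b)
  k2 <- estimate_k(G0 = 3:5, G1 = 1:2, b = b)
  expect_gt(k2, k1)
})

test_that("per-site rates zero out invariant sites and flag saturated ones", {
  tree <- ape::rtree(6)
  geno <- matrix("A", nrow = 3, ncol = 6,
                 dimnames = list(paste0("s", 1:3), tree$tip.label))
  rt <- site_rates(tree, geno)
  expect_true(all(rt$rate == 0))
  expect_false(any(rt$segregating))

  # every tip different from every other at a site on a star-ish tree
  # makes all terminal branches changed; internal unchanged branches remain,
  # so the site is estimable; missing genotypes are flagged
  geno2 <- geno
  geno2[2, ] <- c("A", "C", "G", "T", "A", "C")
  geno2[3, 1] <- "N"
  rt2 <- site_rates(tree, geno2)
  expect_true(rt2$segregating[2])
  expect_gt(rt2$k_hat[2], 0)
  expect_true(rt2$flagged[3])
  expect_true(is.na(rt2$rate[3]))
})

test_that("planted per-site budgets are recovered on a deep phylogeny", {
  cfg <- sim_config(n_genes = 5L, gene_length_range = c(200L, 200L),
                    n_tips = 190L, seed = 17L)
  truths <- simulate_genes(cfg)
  sim <- simulate_phylogeny_and_mutations(truths, cfg)
  expect_equal(nrow(sim$genotypes), 1000L)
  rt <- site_rates(sim$tree, sim$genotypes)
  ok <- !rt$flagged
  rho <- stats::cor(rt$k_hat[ok], sim$sites$k_true[ok], method = "spearman")
  expect_gt(rho, 0.6)
})

test_that("C-to-T strand assignment composes with gene orientation", {
  genes <- data.frame(gene_id = c("gp", "gm"), strand = c("+", "-"),
                      c_watson = c(100L, 80L), c_crick = c(50L, 40L))
  mut <- data.frame(gene_id = c("gp", "gp", "gm", "gp"),
                    pos = c(10L, 20L, 5L, 30L),
                    ref = c("C", "G", "C", "A"),
                    alt = c("T", "A", "T", "G"))
  res <- strand_classify(mut, genes)
  # C>T in a plus gene: Watson hit, coding strand
  expect_equal(res$coding_count[res$gene_id == "gp"], 1L)
  # G>A in a plus gene: Crick hit, template strand
  expect_equal(res$template_count[res$gene_id == "gp"], 1L)
  # C>T in a minus gene: Watson hit, template strand
  expect_equal(res$template_count[res$gene_id == "gm"], 1L)
  expect_equal(attr(res, "n_excluded"), 1L)   # the A>G event
  expect_equal(res$coding_rate[1], 1 / 100)
  expect_equal(res$template_rate[1], 1 / 50)
})
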