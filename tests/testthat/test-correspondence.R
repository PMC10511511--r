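test_that("gene-level rank correlations hit the deterministic extremes", {
  x <- stats::rnorm(30)
  tab <- data.frame(structure = x, rloop = x, mu = -x)
  res <- gene_level_correlations(tab)
  expect_equal(res$rho[res$pair == "structure-rloop"], 1)
  expect_equal(res$rho[res$pair == "structure-mu"], -1)
  expect_equal(res$rho[res$pair == "rloop-mu"], -1)
  expect_error(gene_level_correlations(tab[1:5, ]), "at least 10")
  const <- data.frame(structure = rep(1, 20), rloop = stats::rnorm(20),
                      mu = stats::rnorm(20))
  expect_true(is.na(
    gene_level_correlations(const)$rho[1]))
})

test_that("mediated fractions contrast partial and marginal correlations", {
  expect_equal(round(100 * mediated_fraction(-0.219, -0.177), 1), 34.7)
  expect_equal(round(100 * mediated_fraction(-0.156, -0.086), 1), 69.6)
  expect_equal(mediated_fraction(-0.4, -0.4), 0)
  expect_warning(f <- mediated_fraction(0.1, 0.3), "exceeds")
  expect_lt(f, 0)
  expect_error(mediated_fraction(0, 0.1), "undefined")
})

test_that("partial Spearman reduces and degenerates as the formula says", {
  set.seed(12)
  x <- stats::rnorm(4000)
  y <- 0.5 * x + stats::rnorm(4000)
  z <- stats::rnorm(4000)
  # z unrelated to x and y: the partial matches the marginal correlation
  expect_equal(partial_spearman(x, y, z),
               stats::cor(x, y, method = "spearman"), tolerance = 0.05)
  expect_warning(r <- partial_spearman(x, y, x), "collinear")
  expect_true(is.na(r))

  # a mediator carrying the whole association drives the partial to zero
  for (noise in c(0.3, 0.1, 0.03)) {
    z2 <- stats::rnorm(4000)
    x2 <- z2 + noise * stats::rnorm(4000)
    y2 <- z2 + stats::rnorm(4000)
    p <- partial_spearman(x2, y2, z2)
    expect_lt(abs(p), abs(stats::cor(x2, y2, method = "spearman")))
  }
  p_small <- partial_spearman(z2 + 0.01 * stats::rnorm(4000), y2, z2)
  expect_lt(abs(p_small), 0.05)
})

test_that("within-gene fourfold tables are pseudocounted and directional", {
  # perfectly concordant split: n/2 high-high, n/2 low-low
  n <- 40
  x <- c(rep(1, n / 2), rep(0, n / 2))
  y <- c(rep(5, n / 2), rep(2, n / 2))
  res <- within_gene_or(x, y)
  expect_equal(unname(res$or), (n / 2 + 1)^2)
  expect_true(all(res$table >= 1))

  # affine transforms preserve the mean split, hence the OR
  res2 <- within_gene_or(3 * x - 1, 0.5 * y + 2)
  expect_equal(res2$or, res$or)

  # independent variables: OR concentrates near 1
  ors <- vapply(1:100, function(s) {
    set.seed(s)
    within_gene_or(stats::runif(1000), stats::runif(1000))$or
  }, numeric(1))
  expect_gte(mean(ors >= 0.8 & ors <= 1.25), 0.95)
})

test_that("MH combining matches the stratified reference implementation", {
  one <- list(c(a = 12, b = 5, c = 4, d = 9))
  expect_equal(mh_combine(one, n_boot = 0)$or,
               unname((12 * 9) / (5 * 4)))

  balanced <- replicate(4, c(a = 6, b = 6, c = 6, d = 6), simplify = FALSE)
  mb <- mh_combine(balanced, n_boot = 0)
  expect_equal(mb$or, 1)
  expect_gt(mb$p, 0.9)

  set.seed(31)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    tabs <- lapply(seq_len(k), function(j) {
      c(a = sample(1:40, 1), b = sample(1:40, 1),
        c = sample(1:40, 1), d = sample(1:40, 1))
    })
    arr <- array(unlist(lapply(tabs, function(t)
      matrix(c(t["a"], t["c"], t["b"], t["d"]), 2))), dim = c(2, 2, k))
    ref <- stats::mantelhaen.test(arr, correct = FALSE)
    ours <- mh_combine(tabs, n_boot = 0)
    expect_equal(ours$or, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(ours$chisq, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    # the combined OR lies within the range of the stratum ORs
    strat <- vapply(tabs, function(t)
      unname(t["a"] * t["d"] / (t["b"] * t["c"])), numeric(1))
    expect_gte(ours$or, min(strat) - 1e-12)
    expect_lte(ours$or, max(strat) + 1e-12)
  }
})

test_that("the permutation null is consistent and roughly calibrated", {
  expect_error(permutation_null(
    data.frame(gene_id = "g", theta = 1:9, rloop = 1:9, mu = 1:9),
    n_perm = 0L), "positive")

  set.seed(14)
  make_null_table <- function() {
    do.call(rbind, lapply(1:6, function(g) {
      data.frame(gene_id = paste0("g", g), theta = stats::rnorm(30),
                 rloop = stats::rnorm(30), mu = stats::rnorm(30))
    }))
  }
  tab <- make_null_table()
  pn <- permutation_null(tab, n_perm = 99L, seed = 3L)
  # observed statistic agrees with a direct per-gene computation
  direct <- mean(vapply(split(tab, tab$gene_id), function(g)
    stats::cor(-g$theta, g$rloop, method = "spearman"), numeric(1)))
  expect_equal(unname(pn$observed["sr"]), direct)

  # under the null the empirical p is near-uniform: check bin occupancy
  ps <- vapply(1:80, function(i) {
    permutation_null(make_null_table(), n_perm = 49L, seed = i)$p["sr"]
  }, numeric(1))
  bins <- table(cut(ps, breaks = c(0, 0.25, 0.5, 0.75, 1)))
  expect_gt(stats::chisq.test(bins)$p.value, 0.01)
})
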