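# nascentfold

Quantifying cotranscriptional RNA folding and its antimutagenic effect.

`nascentfold` is an R package for analysing structural probing of
elongating transcripts — paired-end libraries in which the forward read's
5' end marks a reverse-transcription stop at a chemically modified
(single-stranded) base and the reverse read marks the transcription site —
together with DRIP-style R-loop coverage and population-genomic mutation
data. It is aimed at researchers asking whether the folding of nascent RNA
near the transcription site competes with R-loop formation and thereby
suppresses transcription-associated mutagenesis.

## What it computes

* **Read processing** — quality/duplicate filtering of read pairs
  (mapq ≥ 30, first-base-mismatch removal, UMI-aware deduplication),
  RT-stop assignment (the base preceding the forward read's 5' end), and
  per-intermediate stop matrices with an 18-nt elongation-complex footprint
  mask and 90% winsorization per intermediate.
* **Single-stranded score** — per nucleotide, with library normalization
  constants `k_t = (S_DMSO + S_NAI) / (2 S_t)`:

  `theta(i) = log2((N_NAI(i) + 1) / (N_DMSO(i) + 1) + 1)`, capped at 7;

  gene-level mean and Gini index summarize structure prevalence, and
  Pearson correlation of profiles measures nascent/mature structural
  similarity.
* **Structural transitions** — a 50-length sliding window over each
  nucleotide's longitudinal stop-density profile, two-sided Wilcoxon
  rank-sum test between window halves (each half must contain a read),
  per-gene transition fractions.
* **R-loop score** — per site `x = log2((n + 1) / m)`, DRIP track minus
  input track; per-gene means.
* **Per-site mutation rate** — maximum likelihood on a fixed phylogeny:
  branch changes (from Fitch reconstruction) partition branches into
  changed/unchanged sets `G1`/`G0`, and `k` maximizes
  `L = prod_{G1}(1 - e^(-k b_i / B)) prod_{G0} e^(-k b_j / B)`;
  `k/B` is the relative rate. C→T / G→A events can be assigned to coding
  vs template strands.
* **Correspondence statistics** — among-gene Spearman and partial rank
  correlations with mediation fractions `1 - rho_partial^2 / rho^2`;
  within-gene mean-dichotomized fourfold tables with +1 pseudocounts,
  odds ratios `ad/bc` combined by the Cochran–Mantel–Haenszel procedure
  with gene-bootstrap standard deviations; within-gene permutation nulls.
* **Selection model** — per-gene fold reduction `x` of mutation rate
  between the most- and least-structured 50-bp windows, and the
  selection coefficient `s = 0.7 × 10 (x − 1) y` of a folding-strengthening
  mutation-rate modifier, with the `s = 1/Ne` phase boundary.

A synthetic-data generator (`sim_config()`, `simulate_genes()`,
`simulate_espet_reads()`, `simulate_rloop_counts()`,
`simulate_phylogeny_and_mutations()`) plants ground truth — bimodal
paired/unpaired states, step transitions, folding→R-loop and
folding/R-loop→mutation couplings on a simulated phylogeny — so every
stage has a parameter-recovery test without external data.

## Worked example

```r
library(nascentfold)
cfg <- sim_config(n_genes = 30, gene_length_range = c(120L, 180L),
                  depth_per_nt = 20, n_tips = 60, seed = 7)
res <- run_pipeline(cfg, n_perm = 199, n_boot = 200, n_transition_genes = 2)
res$correlations
#>              pair    rho        p
#> 1 structure-rloop -0.467 9.36e-03
#> 2        rloop-mu  0.965 7.28e-18
#> 3    structure-mu -0.469 8.91e-03
```

The three among-gene rank correlations recover the planted model: genes
with more prevalent nascent structure (higher `-mean(theta)`) have lower
R-loop scores and lower mutation rates, while R-loop score and mutation
rate correlate positively.

```r
for (nm in names(res$ors))
  cat(sprintf("  %-3s OR = %.2f (boot sd %.2f), MH p = %.3g\n",
      nm, res$ors[[nm]]$or, res$ors[[nm]]$boot_sd, res$ors[[nm]]$p))
#>   S-R OR = 9.50 (boot sd 0.87), MH p = 3.49e-255
#>   R-M OR = 39.26 (boot sd 6.30), MH p = 0
#>   S-M OR = 9.12 (boot sd 1.08), MH p = 2.46e-244
res$permutation$p
#>    sr    rm    sm
#> 0.005 0.005 0.005
```

Within genes, nucleotides above the gene mean in single-strandedness are
enriched for above-mean R-loop scores and mutation rates (all three
MH-combined odds ratios > 1), and the mean within-gene correlations are
far outside their per-gene shuffled nulls (one-sided permutation p at the
resolution floor of 199 permutations).

```r
selection_coefficient(40, selection_params())
#> [1] 9.009e-08
```

A 40-fold mutation-rate reduction across structure extremes confers a
fitness advantage below the drift barrier `1/Ne = 1e-7`: even strong
antimutator folding is effectively neutral in yeast-sized populations.

## Package layout

* `R/` — simulation (`sim-config.R`, `synthetic-data.R`), read processing,
  structure scores, transitions, R-loop, mutation rate, correspondence
  statistics, selection model, I/O, and the `run_pipeline()` driver.
* `vignettes/nascentfold-methods.Rmd` — the models, assumptions, parameter
  choices and limitations in detail.
* `tests/testthat/` — unit, property and acceptance tests (fixtures are
  generated in code; no binary data).
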