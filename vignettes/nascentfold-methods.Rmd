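---
title: "Models and methods behind nascentfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nascentfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nascentfold)
```

# The measurement model

`nascentfold` analyses structural probing of elongating transcripts. The
assay produces paired reads: the reverse read's 5' position marks the
transcription site, i.e. the length `L` of the transcriptional intermediate,
while the forward read's 5' end sits one base 3' of a reverse-transcription
(RT) stop at a chemically acylated nucleotide. NAI-N3 modifies flexible
(unpaired) bases of all four nucleotides; a DMSO-treated control captures
modification-independent stops. Two facts shape every downstream
computation:

* the RT stop site is the base *preceding* the forward read's 5' position,
  so a read with `fwd5 = 1` is a mapped read without an interpretable stop
  (it still counts toward the library total);
* the 18 nucleotides at the 3' end of an intermediate are buried in the
  transcription elongation complex and can never be probed. All
  per-intermediate computations mask this footprint.

## Single-stranded score

With library totals $S_{\mathrm{DMSO}}$ and $S_{\mathrm{NAI}}$, counts are
depth-normalized by $k_t = (S_{\mathrm{DMSO}}+S_{\mathrm{NAI}})/(2 S_t)$,
and each nucleotide receives

$$\theta(i) = \log_2\!\left(\frac{N_{\mathrm{NAI}}(i)+1}
{N_{\mathrm{DMSO}}(i)+1} + 1\right),$$

with pseudocounts of 1 keeping $\theta$ strictly positive and raw values
above 7 capped at 7. Sites uncovered in both libraries take the formula's
value of 1 but carry a `low_coverage` flag; gene summaries (arithmetic mean
and Gini index of $\theta$) exclude them by default, and genes are annotated
with their mean stop coverage so the usual "at least one average RT stop per
nucleotide" gene filter can be applied. Library-wide totals are used for
$S$; per-gene totals can be substituted by passing `S` explicitly.

A high mean $\theta$ marks a flexible, unstructured gene; a high Gini index
marks a structured one, because folded regions concentrate the probing
signal into few unpaired sites. Structure prevalence therefore enters the
correlation machinery as $-\bar\theta$ (or the Gini index).

## Intermediate matrices and the transition scan

Read pairs sharing a transcription site derive from the same intermediate.
Stops are counted per `(L, i)`, the footprint is masked, and each row is
normalized by 90% winsorization: clipping at the row's 5th and 95th
percentiles, then scaling the row maximum to 1. We winsorize the raw counts
and then scale; whether one clips counts or count densities first is an
open reading of the phrase "90% winsorization", and the winsor fraction is
exposed as a parameter. Winsorization is order-preserving, so a constant
row stays constant and rank-based downstream tests are unaffected by the
scaling choice.

A cotranscriptional structural transition at nucleotide `i` is a change in
its RT-stop density as `L` grows. The scan slides a 50-length window (step
1) along the longitudinal profile of `i`, splits it into halves of 25,
requires at least one raw read in each half, and compares the halves'
densities with a two-sided Wilcoxon rank-sum test (exact when tie-free and
small, normal approximation with tie and continuity correction otherwise —
the same switch `stats::wilcox.test` uses; the implementation is its own
lean rank-sum and is tested for exact agreement with `wilcox.test`).
Windows with $p < \alpha = 0.05$ are transition calls; no multiple-testing
correction is applied by default (a Benjamini–Hochberg option exists), and
a nucleotide is "transitioning" if any of its windows is significant. The
DMSO control plays no role here: modification-independent stop propensity
is a property of the nucleotide and cancels in longitudinal comparisons of
the same nucleotide.

At sparse per-intermediate depth (a handful of reads per intermediate) the
winsorized densities are dominated by 0/1 counts and the scan becomes
anticonservative — declining per-position sampling rates with growing `L`
masquerade as transitions. Transition fractions are therefore only
meaningful for deeply covered genes, which is why `run_pipeline()` scans a
configurable subset and why the sensitivity/calibration checks in the test
suite use saturating depth and resampled nulls respectively.

## R-loop score

For each site, with `n` reads whose 5'-most base maps to the site and `m`
the genome-wide total, $x = \log_2((n+1)/m)$; the R-loop score is $x$ from
the DRIP-style track minus $x$ from the input-chromatin track. Sites with
no coverage keep the formula's (finite) value. Per-gene scores are the mean
of site scores (median available); the score is antisymmetric under
swapping the tracks and stable under depth changes up to the pseudocount.

## Per-site mutation rates on a fixed phylogeny

Conditioned on a tree with total branch length $B$, the mutation count on
branch $i$ of length $b_i$ is Poisson with mean $k b_i / B$. An ancestral
reconstruction partitions branches into changed ($G_1$) and unchanged
($G_0$) sets, giving

$$L(k) = \prod_{i \in G_1}\left(1 - e^{-k b_i / B}\right)
\prod_{j \in G_0} e^{-k b_j / B}.$$

$\hat k$ solves $\partial \ln L / \partial k = 0$, which we bracket (upper
bound doubled until the stationarity function changes sign) and bisect to
relative tolerance $10^{-9}$; the derivative is monotone, so the positive
root is unique. Invariant sites get $k = 0$; sites whose reconstruction
leaves $G_0$ empty have no finite maximizer and are flagged. Because $B$ is
shared, $\hat k / B$ is comparable across sites whatever the tree's absolute
time scale.

The literature description of the reconstruction step ("highest posterior
probability by a distance-based method") under-determines the algorithm, so
we use Fitch parsimony with deterministic tie-breaking: a node keeps its
parent's state when allowed, remaining ties go to the tip-majority state and
then alphabetically. The estimator only consumes the $G_0/G_1$ partition,
so any reconstruction with the same parsimony assignment is equivalent; the
test suite cross-checks $|G_1|$ against an independent parsimony-score
implementation.

C/G$\to$T/A mutation events can additionally be assigned strands: assuming
cytosine deamination dominates, C$\to$T events happened on the Watson
strand and G$\to$A events are C$\to$T on the Crick strand; composing with
gene orientation yields coding- versus template-strand counts (and rates,
when per-strand cytosine counts are supplied).

## Linking folding, R-loops and mutation rate

Among genes, the three pairwise Spearman correlations are computed on
structure prevalence ($-\bar\theta$ or Gini), gene R-loop score and gene
mean mutation rate; under the competitive-inhibition model the expected
signs are negative, positive (R-loop vs rate) and negative. The fraction of
the folding–mutation association mediated by the R-loop contrasts the
marginal and the first-order partial rank correlation,
$1 - \rho_{\mathrm{partial}}^2/\rho^2$.

Within genes, nucleotides are dichotomized at the within-gene mean of each
variable (strictly above = high; ties low), the four cells get +1
pseudocounts, and the odds ratio is $ad/bc$ with `a` the both-high cell.
Gene tables are combined by the Mantel–Haenszel common OR
$\sum_g a_g d_g/n_g \big/ \sum_g b_g c_g/n_g$ with the MH chi-squared test
(no continuity correction); the implementation follows the standard
formulas and is verified against `stats::mantelhaen.test` to $10^{-10}$.
Pseudocounted cells are used both for the per-gene ORs and inside the MH
combination, for consistency; raw cells are a trivial variation. The
combined OR's spread is estimated by resampling genes with replacement
(1000 draws by default; the seed is recorded in the result).

The permutation null for the mean within-gene correlations shuffles each of
the three per-nucleotide vectors independently within each gene, recomputes
the three averaged within-gene Spearman correlations per shuffle, and
reports add-one-corrected empirical p-values, one-sided in the model's
predicted direction.

## Fold reduction and the selection model

Per gene, 50-bp windows slide by 1 bp over the $\theta$ profile; among
windows containing at least one site with rate data, the highest-mean-
$\theta$ window and the lowest-mean-$\theta$ window (required not to
overlap each other, since identical windows would force a degenerate ratio
of 1) give $x$ = mean rate in the most-unstructured window over mean rate
in the most-structured window. Genes need at least 5% of sites with rate
data and a length of at least two windows; infinite ratios (structured
window without observed mutations) are capped at 50. A mutation that
strengthens folding and reduces its 10-site target's rate $x$-fold gains

$$s = f_{\mathrm{del}} \cdot \mathrm{target} \cdot (x - 1) \cdot y
    = 0.7 \times 10 (x-1) y,$$

with $y = 3.3\times10^{-10}$ per generation per nucleotide. Against a
drift barrier $1/N_e = 10^{-7}$, $s$ exceeds drift only for
$x \gtrsim 44$; `phase_boundary()` returns the exact contour
$(x-1)y = 1/(N_e f_{\mathrm{del}}\,\mathrm{target})$.

```{r}
selection_coefficient(40, selection_params())
```

# The synthetic-data generator

Every stage is exercised against planted ground truth, generated by
`simulate_genes()` and friends from a single `sim_config()` seed:

* **Folding truth.** Per-site unpairedness is a bimodal mixture — loops
  drawn from Beta(8, 2), stems from Beta(2, 8), with a gene-level loop
  fraction between 0.2 and 0.8 — emulating the near-binary pairing state of
  real secondary structure. Each gene plants one step transition
  `(i, L*)` of effect 0.8 in unpairedness.
* **Reads.** Transcription sites are uniform over intermediate lengths with
  at least one exposed nucleotide (the empirical distribution is
  data-dependent and configurable); each read carries one RT stop drawn
  multinomially over exposed positions with weight
  `background + multiplier * unpairedness` (NAI) or `background` (DMSO).
  Defaults: 30 read pairs per nucleotide per treatment, background weight 1,
  multiplier 8 — i.e. a fully unpaired base stops RT nine times as often as
  background, a contrast typical of SHAPE-style probing. UMIs are random
  3-mers; 2% of reads carry sub-threshold mapping quality and 1% a
  first-base mismatch, so the filters have work to do.
* **R-loops.** Site DRIP intensity is
  `drip_depth * 2^(rloop_coupling * (foldedness - 0.5))` with
  `rloop_coupling = -3` (folded sites form fewer R-loops); input coverage
  is uniform; counts are Poisson.
* **Phylogeny.** A random bifurcating topology with Exp(1) branch lengths
  (the estimator conditions on the tree, so the topology model is
  immaterial); per-site budgets
  `k_true = k_base * 2^(-2 (fold - 0.5) + 1 * e_rloop)` plant the
  antimutator couplings; mutations drop on branches as Poisson
  `k_true b_i / B` and genotypes propagate from a random root base.

What the generator does *not* emulate: sequence-level biases (GC, ligation),
R-loop thermodynamics, selection on the simulated lineages, linkage between
sites, or the long-tailed empirical intermediate-length distribution. A
green recovery suite therefore demonstrates the estimators' correctness and
power under idealized sampling, not robustness to those real-data artifacts.

# Numerical choices and degenerate inputs

* Winsorization quantiles use R's default (type 7) empirical quantiles; a
  row whose clipped maximum is 0 is left at 0 rather than divided by 0.
* Duplicate removal keeps the first record in a stable sort by the
  duplicate key — observationally irrelevant, since duplicates agree in all
  used fields, but it makes the output order-independent.
* A DMSO background weight of 0 leaves the control sampler with zero total
  weight; such reads cannot exist and are simply not emitted, while NAI
  depth conservation is exact by construction.
* `estimate_k` flags sites with every branch changed (no finite maximizer)
  and returns 0 at the boundary for invariant sites; ties in the
  reconstruction are broken deterministically so the whole pipeline is a
  pure function of its seed.
* Empirical permutation p-values use the add-one correction, avoiding
  p = 0 at any permutation count.
* Problem sizes in the test suite are chosen for desk-scale runs: the full
  recovery experiment uses 200 genes of 120–240 nt, 190 tips and 30 read
  pairs per nucleotide, with 499 permutations and 200 bootstrap draws;
  calibration and sensitivity checks use 100 replicate profiles each.

# Limitations

The transition scan inherits the anticonservative behaviour described
above at sparse depth. The mutation-rate estimator treats the tree and its
branch lengths as known and assumes sites evolve independently. Gene-level
R-loop aggregation uses the mean (the aggregation of site scores is not
uniquely dictated by the score's definition); the median option is provided
for sensitivity analyses. The score cap at 7 interacts with neither the
winsorized matrices (the cap applies only to pooled stop profiles) nor the
rank-based statistics.
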