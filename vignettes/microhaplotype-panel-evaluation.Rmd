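---
title: "Evaluating microhaplotype panels for forensic work: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating microhaplotype panels for forensic work: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhpanel)
```

## The marker system

A microhaplotype is a genomic window shorter than 200 bp containing two or
more SNPs. Because a single sequencing read covers the whole window, the
jointly *phased* alleles — one base per SNP, read as a string such as
`"ACT"` — behave as a single multi-allelic marker. Panels built around
tri-allelic SNPs push the allele count per locus higher still, which is what
makes them useful for individual identification, kinship testing and
two-person mixture detection. `mhpanel` implements the statistics a forensic
laboratory computes when constructing and validating such a panel, together
with fully seeded simulators for every input, so each estimator can be
exercised against known ground truth.

The package ships a 20-locus reference panel (`mh_reference_panel()`):
locus definitions (1-based GRCh37 coordinates, rsIDs, one tri-allelic member
per locus except mh22zha008) plus the per-locus forensic parameters
estimated from a Chinese Han sample of 50 unrelated individuals.

## Per-locus forensic parameters

For a locus with allele frequencies $p_i$:

* **Effective number of alleles** $A_e = 1/\sum_i p_i^2$, the number of
  equally frequent alleles giving the same homozygosity. Equivalently the
  expected heterozygosity is $H_e = 1 - 1/A_e$.
* **Observed heterozygosity** $H_o$: the fraction of genotyped individuals
  whose two alleles differ. Missing genotypes (`"./."`) are excluded
  pairwise, per locus — the data model is silent about missingness, so no
  imputation is attempted.
* **Matching probability** $MP = \sum_G (n_G/n)^2$ over *observed* genotype
  counts, and **power of discrimination** $PD = 1 - MP$. Using observed
  counts rather than Hardy–Weinberg expectations is the forensic convention;
  the two agree in expectation under random mating.
* **Power of exclusion** as a function of observed heterozygosity,
  $PE = H_o^2\,(1 - 2H_o(1-H_o)^2)$. Published microhaplotype tables are
  produced by forensic parameter calculators whose internals are not
  printed; this classic exclusion-power form reproduces 19 of the 20
  reference-panel rows to 3 decimal places (the remaining row, mh17zha001,
  prints PE 0.562 against Ho 0.64, which corresponds to Ho 0.78 under the
  same formula — we flag it as anomalous rather than "correcting" it).

Panel-level quantities combine per-locus values by complement products,
$CPD = 1-\prod_i(1-PD_i)$, $CPE = 1-\prod_i(1-PE_i)$, $CMP = \prod_i MP_i$,
accumulated in log space because a 20-locus panel drives $1-CPD$ down to the
$10^{-18}$ scale where naive products lose precision.

`bn_match_probability()` adds the Balding–Nichols coancestry correction: the
match probability for two members of a subpopulation with coancestry
$\theta$, using the standard conditional genotype probabilities. $\theta$
defaults to 0 (the panmictic reduction $\sum_G P(G)^2$) and is a parameter,
since published panel evaluations rarely state the $\theta$ they used.

## Two-person mixture detection

A two-contributor mixture is detectable at a locus when the union of the two
genotypes shows at least three distinct alleles. Under Hardy–Weinberg the
four allele draws are independent, so by inclusion–exclusion

$$p = 1 - \Big[\sum_a p_a^4 + \sum_{a<b}\big((p_a+p_b)^4-p_a^4-p_b^4\big)\Big],$$

which is maximised at equal frequencies: $4/9 \approx 0.4444$ for three
alleles, $21/32 = 0.65625$ for four. The panel-level probability follows the
*floor rule* used in published panel evaluations: each locus contributes the
equal-frequency probability at $k=\lfloor A_e\rfloor$ (loci flooring below 3
contribute nothing), combined as $1-\prod_i(1-p_i)$. This is deliberately an
operational definition — no dropout, stutter or analytical-threshold
modelling, and no three-contributor mixtures. An independent enumeration
oracle (`mixture_probability_oracle()`, exact sum over all ordered allele
4-tuples) guards the closed form in the test suite.

## Equilibrium testing

`hwe_exact_test()` is a Monte-Carlo exact test in the Guo–Thompson style:
the $2n$ alleles are reshuffled into pairs and each table is ranked by its
conditional probability given the allele counts. The p-value uses the
add-one estimator $(\#\{T \le T_{obs}\}+1)/(B+1)$, so it is bounded below by
$1/(B+1)$; $B$ defaults to $10^5$ (the shuffling kernel is compiled).
Monomorphic loci are untestable and return $p=1$ with a warning.

`ld_permutation_test()` approximates the classic two-locus disequilibrium
test: the statistic is a $\chi^2$ over the joint haplotype table, with
haplotype frequencies estimated by EM when phase is unavailable, and the
null distribution obtained by permuting one locus across samples (preserving
both marginal genotype distributions). $B$ defaults to $10^4$. The
multi-allelic $r^2$ summary is the frequency-weighted average
$\sum_{ij} p_i q_j\, r^2_{ij}$ — conventions differ between tools, so this
choice is stated prominently; allele pairs with a fixed allele are skipped
with weight renormalisation.

## Kinship: duo paternity indices

The package covers single-parent duos only. Per locus the paternity index is
the likelihood ratio of the child's genotype given the alleged parent's
(transmission probability $1/2$ per parental allele, untransmitted allele
from the population) versus an unrelated individual under Hardy–Weinberg.
Under the default *no-mutation policy* an allele-sharing violation gives
$PI = 0$ and hence $CPI = 0$; an optional mutation-tolerant mode scales the
transmission probability by a single-step uniform replacement model at a
user-set rate, because microhaplotype mutation models are not standardised
and the default should match the strict Mendelian reading. Observed alleles
absent from the frequency database get the minimum-allele-count floor
$5/(2n+2)$, logged when applied. $CPI = \prod_i PI_i$ is accumulated in
log10 space and classified against the conventional confirmation threshold
of 10 000. Every PI formula is verified in the tests against an exhaustive
transmission-enumeration oracle over all genotype configurations.

## Population structure

* **Haplotype frequencies from unphased data.** `em_haplotype_freqs()` is
  the standard haplotype EM (E-step distributes each phase-ambiguous
  genotype over consistent haplotype pairs proportionally to current
  frequency products). It is this package's desk-scale substitute for
  Bayesian phasing tools, labelled `method = "haplotype-EM"` in its output;
  the haplotype space is capped at 6 SNPs per locus. The log-likelihood is
  asserted nondecreasing, and multi-restart selection is deterministic under
  a fixed seed.
* **Fst.** `pairwise_fst()` uses a Hudson-style estimator on haplotype
  frequencies with a $2n/(2n-1)$ within-population sample-size correction
  when genotype tables are supplied, combining loci as a ratio of averages.
  Negative estimates are truncated to 0 only in the returned distance
  matrix (tree input); raw values are preserved in the `"raw"` attribute.
  The estimator name travels in the output metadata because AMOVA-based
  tools compute related but not identical quantities.
* **Trees.** `nj_tree()` delegates Saitou–Nei neighbour joining and Newick
  serialisation to the `ape` package (the de-facto standard), after
  validating symmetry, nonnegativity and the zero diagonal; a 2-taxon
  matrix is handled as the trivial split.

The simulation side provides the matching generative model:
`bn_population_freqs()` draws subpopulation spectra from the
Balding–Nichols Dirichlet with parameters $p_i(1-\theta)/\theta$, whose
expected pairwise Fst is $\theta$ — the test suite checks that the estimator
recovers the generating $\theta$ and that two drifted clusters
($\theta_{within}=0.01 \ll \theta_{between}=0.2$) are separated by an NJ
bipartition.

## Marker screening

`screen_candidates()` reproduces the published candidate-selection chain on
a variant table: maximal windows of MAF-passing SNPs with span under 200 bp
(1-based inclusive) and at least 3 SNPs; per-SNP MAF above 0.10; removal of
window members with identical frequency spectra (identical spectra imply
complete LD, so such SNPs are redundant — the alternative "reject the whole
candidate" reading is available via `dedup_action`); a tri-allelic member
required; haplotype $A_e$ above 3.0; a heterozygosity criterion at 0.6; and
greedy-by-$A_e$ spacing above 2.0 Mb on the same chromosome. Failures
accumulate rather than short-circuit, so every rejected candidate reports
all its named reasons. Three choices deserve explicit mention:

* **MAF of a tri-allelic SNP** is taken as the *minimum* allele frequency,
  the strictest reading of "minor allele frequency".
* **Heterozygosity direction.** The published criterion reads "at most
  0.6", yet every reported locus has heterozygosity above 0.6; the default
  is therefore `>= 0.6`, with the literal `<=` available via
  `screening_params(het_direction = "le")`. The contradiction is surfaced,
  not silently resolved.
* **Candidate spectra** are the product of per-SNP spectra (so candidate
  $A_e$ is the product of per-SNP $A_e$), a linkage-equilibrium
  approximation appropriate before haplotype data exist; observed haplotype
  frequencies can be supplied to `apply_filters()` instead.

Sequencing-depth quality control, primer design and homology checks are
wet-lab steps outside this package's scope.

## Synthetic data: what it emulates, and what it does not

All generators (`sample_allele_freqs()`, `hwe_genotypes()`,
`simulate_duos()`, `bn_population_freqs()`, `simulate_mixture_profiles()`,
`simulate_screening_variants()`) are deterministic under a fixed seed, with
one base seed expanded into per-locus substreams so adding loci never
perturbs earlier draws. `default_panel_freqs()` builds a 20-locus frequency
database whose $A_e$ profile mirrors the reference panel (one locus below 3,
fifteen in $[3,4)$, four at 4 or above) using `spectrum_with_ae()` — a
one-major-allele spectrum solved to hit each target $A_e$ exactly — so
panel-level code paths (including the mixture floor rule) are exercised
under the same conditions as the reference panel.

The generators emulate: Hardy–Weinberg sampling at user-specified spectra,
Mendelian transmission with an optional single-step uniform mutation model,
Balding–Nichols drift, and two-person mixtures without dropout. They do
*not* emulate: sequencing error, allele dropout or imbalance, within-locus
recombination (negligible over < 200 bp), linked loci, or admixed
individuals. Passing tests therefore validate the estimators under their
own model assumptions; they do not certify performance on degraded or
low-template casework samples.

## Numerical and design choices

* Cumulative panel quantities use `log1p`/`expm1` accumulation; CPI uses
  log10 sums; both are exact to the reported digits at the $10^{-18}$
  scale.
* Frequency vectors must sum to 1 within $10^{-6}$ and are renormalised
  exactly; genotype strings are stored with alleles sorted so unordered
  pairs compare equal.
* Permutation p-values are add-one estimators, never exactly 0.
* EM convergence: absolute log-likelihood change below $10^{-8}$ (two-locus
  LD EM) or a configurable `tol` (haplotype EM), with iteration caps.
* Coordinates are 1-based inclusive throughout; `span = end - start + 1`,
  validated against the reference panel's printed lengths (20/20 agree).
* The reference panel's cumulative PD, recomputed from its rounded 3-d.p.
  PD column, lands near $1-2.4\times10^{-18}$; recovering a headline value
  quoted to two significant digits requires the unrounded per-locus inputs,
  which a printed table cannot provide, so tests assert order of magnitude
  only. The cumulative PE column, by contrast, reproduces its headline
  value within 1%.

## Problem sizes used in the test suite

Statistical properties are checked at sizes chosen to keep each check's
Monte-Carlo error well inside its assertion band: genotype-frequency
convergence at $n = 2\times10^4$–$5\times10^4$; mixture-fraction
convergence at $n = 5\times10^4$; HWE null calibration over 80 datasets at
$B = 1999$; LD type-I error over 100 replicates at $B = 10^3$; EM recovery
at $n = 500$ (3 standard errors); Fst–$\theta$ consistency over 10
replicates of 100 loci; duo simulations at 500 true and 500 unrelated
pairs; NJ cluster separation over 10 replicates. Tolerances are derived
from binomial/KS sampling theory at those sizes, not tuned.

## Limitations

Duos only (no trios or sibship indices); two-contributor mixtures only; no
mixture deconvolution; no admixture/ancestry-component modelling; the EM
estimator, unlike Bayesian phasing, returns point frequencies without
uncertainty; Fst values from different estimators (AMOVA-based tools in
particular) are comparable in pattern but not numerically identical.
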