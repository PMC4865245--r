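---
title: "Models and methods behind snppop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind snppop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`snppop` implements the standard population-genetic characterisation of a
few livestock populations genotyped on a medium-density SNP chip. This
vignette records the models each stage assumes, the defaults and why they
were chosen, the numerical decisions that are easy to get subtly wrong,
and what the simulation-based validation does and does not establish.

## The genotype model

Everything operates on a diploid biallelic dosage matrix (samples x SNPs,
codes 0/1/2 counting copies of the per-SNP `allele_b`, `NA` for missing
calls) with a physical map. Coding is canonical (major, minor) by observed
frequency with lexicographic tie-breaks, so `MAF = mean(dosage)/2` in the
coding population and a PED/MAP round trip is the identity for canonically
coded data. Merging anchors allele assignment to the first dataset and
flips dosages (`x -> 2 - x`) where a later cohort coded the same two
alleles the other way. No strand flipping is attempted: cohorts genotyped
on the same chip should agree up to an a/b swap, and an A/T or C/G
mismatch is more likely a data problem than a strand problem, so it is an
error rather than a silent repair. Physical positions drive all distance
computations; the genetic-position MAP column is read and ignored.

## Quality control

The cascade removes samples with call rate below 95%, then (on the
surviving matrix) SNPs failing call rate (< 95%), minor allele frequency
(< 0.05; a MAF of exactly 0.05 is kept, since the rule removes
strictly-below), and the Hardy–Weinberg exact test (p < 0.001). Each SNP
is attributed to the first criterion it fails, which makes the report's
per-criterion counts disjoint and lets them tile the panel exactly — a
convention the report header documents, since published QC tables do not
always state whether their columns overlap.

The HWE test is the exact conditional test: given the allele counts, the
heterozygote count follows the distribution
`P(h) proportional to 2^h n! / (n_AA! h! n_BB!)`, and the two-sided
p-value sums the probabilities of all outcomes no more probable than the
observed one (no mid-p). The implementation works in log space; the test
suite checks it against a plain factorial-weight enumeration for every
genotype table with up to 50 individuals.

## Two-locus LD by EM

With unphased genotypes, only double heterozygotes are phase-ambiguous.
The EM iterates the expected split of double heterozygotes between the
cis and trans configurations, starting from linkage equilibrium, until
the largest frequency change is below 1e-10 (at most 1000 iterations).
Phase-known tables are solved by direct counting. Because the allele
margins are fixed by the observed dosages, the likelihood profiles over a
single free haplotype frequency; the tests compare the EM against a
three-stage grid search of that profile and against direct counts on
tables without double heterozygotes. From the haplotype frequencies:
`D = p_ab - p_a p_b`, `r2 = D^2 / (p_a(1-p_a) p_b(1-p_b))`, and
`D' = |D| / D_max` with `D_max = min(p_a p_b, (1-p_a)(1-p_b))` for
negative `D` and `min(p_a(1-p_b), (1-p_a)p_b)` otherwise.

Missing data are handled pairwise-complete (samples missing either
genotype are dropped for that pair) rather than imputed — at chip
missingness rates the efficiency loss is negligible and the estimator
stays unbiased. Pairs whose pairwise-complete subset leaves a locus
monomorphic, or fewer than two samples, are reported as `NA` and excluded
from averages.

Pruning follows the windowed greedy rule (window 50 SNPs, step 5,
threshold r2 > 0.2). The removal rule had to be pinned down to make the
result deterministic: within a window the highest-r2 offending pair is
found and its lower-MAF member dropped, ties going to the later map
position. Dropping the lower-MAF SNP preserves the more informative
marker.

Decay tables bin same-chromosome pairs below 1 Mb into the conventional
intervals (0–10, 10–20, 20–40, 40–60, 60–100, 100–200, 200–500,
500–1000 kb). Interval labels overlap at their printed edges, so the
bins are half-open `[lo, hi)` — a pair at exactly 10 kb falls in
10–20 kb. The pooled column is computed on the merged genotypes, not by
averaging population means, because pair counts differ wildly between
populations. Per-chromosome summaries average adjacent-in-map pairs
only: on a 50k chip adjacent spacing (~50 kb) is what such tables
conventionally describe.

## Diversity and kinship

Expected heterozygosity uses the plug-in `2p(1-p)` (the `2n/(2n-1)`
small-sample correction is available but off by default, matching how
chip-QC tools report "expected heterozygosity"). Individual inbreeding is
the method-of-moments excess homozygosity
`f = (O_hom - E_hom) / (L - E_hom)`. Both use within-population allele
frequencies when reported per population; the merged-set `f` deliberately
conflates structure with inbreeding (the Wahlund effect) because that is
what the computation, as defined, measures on a pooled sample.

`PI_HAT` inverts the expected IBS-state counts given allele frequencies
into `P(IBD = 0/1/2)` per pair, truncates negative solutions to `[0, 1]`
and renormalises. The truncation is the standard repair and biases
`pi_hat` upward near its boundary: for truly third-degree pairs
(expected 12.5%) the recovered mean sits near 13%, which the validation
tolerances anticipate. Pairs with fewer than 100 overlapping SNPs are
flagged low-confidence rather than dropped.

## Structure

**AMOVA.** The three-level decomposition treats each individual as two
allele copies: among populations / among individuals within populations /
within individuals, with degrees of freedom `(r-1, N-r, N)` and the usual
unequal-sample-size coefficient `n_c`. Squared-Euclidean distance on
dosage vectors is equivalent, up to scale, to allele-mismatch distance
for biallelic loci, and the scale cancels in percentages and FST.
Negative component estimates are retained, as variance-component
estimators allow. The permutation test shuffles individuals among
populations and recomputes the among-population component, with the
`(b+1)/(m+1)` p-value estimator so p is never zero; under a true null the
suite checks the rejection rate at 0.05 stays in `[0.02, 0.10]` across
200 simulations. Missing dosages are imputed with their locus's
population mean before the sums of squares — at simulation scale inputs
are complete, so this only matters for real data with missingness.

**FST.** Weir–Cockerham variance components per SNP, with the global
value as the ratio of summed components. On Balding–Nichols simulations
both the W-C and the AMOVA-derived estimators recover the generative FST
within ±0.02 and agree with each other closely, which is the reason both
are offered: they answer the same question through different estimators
and serve as mutual checks.

**PCA.** The GRM is the allele-frequency-standardised cross-product with
per-pair adjustment of the SNP count under missingness; eigenvectors of
the GRM equal the left singular vectors of the standardised genotype
matrix (asserted in the tests via principal angles). Variance fractions
are reported over the retained components so the printed fractions sum
to 100%. The sign of each eigenvector is fixed by making its
largest-magnitude loading positive.

**Admixture.** The binomial likelihood
`x_ik ~ Binomial(2, sum_c q_ic p_ck)` is maximised by EM (the classic
frappe updates) from random Dirichlet/uniform starts, best of 5 restarts
by log-likelihood; monotonicity of the log-likelihood is asserted every
iteration, and frequencies are clamped to `[1e-6, 1 - 1e-6]` to keep the
likelihood finite. EM is slower than quasi-Newton block relaxation but
transparent and entirely adequate at this scale (up to ~15k SNPs, ~150
samples). K is chosen by cell-holdout cross-validation: non-missing
genotype cells are split into 5 folds, each fold masked in turn, and the
mean held-out binomial deviance per cell scored; masks that would empty a
sample or SNP are redrawn. Cell-holdout was preferred over
individual-holdout because held-out individuals have no ancestry
estimates without an extra projection step, whereas held-out cells are
scored directly by the fitted `Q %*% P`.

## Effective population size

Binned LD decay is inverted through
`N_T(t) = (1 / 4 f(c)) (1 / E[r2_adj | c] - alpha)` with `t = 1/(2c)`.
Defaults: 20 bins of 50 kb tiling 0–1 Mb; physical distance mapped to
recombination fraction at 1 cM/Mb (a typical genome-wide average for
livestock genomes; configurable because every Ne estimate scales with
it); Sved's mapping `f(c) = c(1 - c/2)/(1 - c)^2` with the identity
mapping available; `alpha = 1`, the drift-only constant, with 2.2 (the
mutation-adjusted value) selectable; sampling-bias adjustment
`r2 - 1/(beta n)` with `beta = 1` for genotype-based r2 and 2 for phased
haplotypes. Bins whose mean adjusted r2 implies a non-positive Ne are
skipped with a warning. Composing the drift expectation
`E[r2] = 1/(alpha + 4Nc)` with the inversion under the identity mapping
returns N exactly — the suite asserts this to machine precision on 1000
random draws.

## What the simulators emulate — and what they do not

The simulators generate exactly the structures the estimators assume:
Balding–Nichols drift differentiation (population frequencies Beta around
uniform ancestral frequencies at a target FST), admixed dosages from
`Q %*% P`, pedigree gene-dropping through minimal pedigrees at
independent loci, and a forward Wright–Fisher population (random mating
with selfing permitted, Poisson recombination on a linear map, no
mutation, chip-like initial frequencies uniform on `[0.05, 0.5]`). Each
returns its generative parameters so tests are parameter-recovery
checks, and each is a pure function of its seed.

They deliberately omit several features of real chip data: SNP
ascertainment is approximated by the bounded initial MAF spectrum rather
than by modelling discovery panels; there is no genotyping error, no
linked selection, no overlapping generations, and no realistic goat
demography. Passing recovery tests therefore establishes that the
estimators are correctly implemented for their assumed models — not that
those models capture every property of a particular real cohort.

Validation scales were chosen to keep the full suite within a desk-scale
run: Wright–Fisher recovery uses 20 chromosomes x 5 Mb with a 15,000-SNP
initial panel, 4N generations of drift (so roughly 2,000–2,500 SNPs
survive QC, giving >1000 pairs per 50 kb bin) and three replicate
populations per census size, averaging the three largest-`c` ("most
recent") bins. Replicate averaging matters: at N = 50 the genome-wide
mean r2 of a single population varies substantially between replicates
because all loci share one pedigree, and single-population estimates
scatter roughly ±40% around the truth. The MAF >= 0.05 filter — part of
the workflow being modelled — measurably inflates mean r2 and pulls Ne
estimates downward of the no-floor estimates; the recovery bands absorb
both effects.

The admixture-CV validation uses three clusters of 30 at FST 0.2 with
800 SNPs: sample sizes mirror a three-population chip study, and the
differentiation sits between a within-breed value (0.12) and the
strongly separated two-cluster recovery scenario (0.3).

## Known limitations

- LD-based Ne is reported without confidence intervals; a block jackknife
  over chromosomes would be the natural extension.
- The AMOVA's missing-data imputation slightly shrinks within-individual
  variance when missingness is high.
- `PI_HAT` assumes the supplied (or estimated) allele frequencies are the
  founder frequencies of the pairs being tested; cross-population pairs
  need merged-set frequencies, and small reference samples bias the
  inversion.
- The admixture EM can need many iterations near flat likelihood regions
  (weak structure, large K); restarts mitigate but do not eliminate local
  optima.
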