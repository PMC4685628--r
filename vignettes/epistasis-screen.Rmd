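---
title: "Screening case-control cohorts for epistasis with cross-validated MDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening case-control cohorts for epistasis with cross-validated MDR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdrscan)
```

## The problem

Conventional single-SNP GWAS tests marginal effects one locus at a time.
In small or rare-disease cohorts — a few dozen cases against a hundred-odd
controls — almost nothing survives multiple-testing correction, yet pairs
of loci can jointly carry risk that neither shows alone (epistasis). This
package implements the standard screen for such pairs: quality control,
reduction to linkage-disequilibrium tag SNPs, a conventional single-SNP
association pass, and an exhaustive pairwise multifactor-dimensionality
reduction (MDR) scan scored by cross-validation. A synthetic cohort
generator with *planted* two-locus penetrance models provides ground
truth, so every stage is testable without any external genotype data.

## The MDR model

For a SNP pair with minor-allele dosages $g_1, g_2 \in \{0,1,2\}$, the
nine joint-genotype cells of the training data are labelled

$$\text{high-risk} \iff \frac{\#\text{cases in cell}}{\#\text{controls in cell}} \ge T,$$

with $T$ the case:control ratio of the training split (a cell with cases
but no controls is high-risk; a cell with neither is *empty*). The pair
then acts as a one-dimensional classifier: high-risk cell → predict case,
low-risk → predict control. Under stratified 10-fold cross-validation the
**CVV** of a pair is defined here as the mean *held-out balanced accuracy*

$$\mathrm{CVV} = \frac{1}{10}\sum_{f=1}^{10}
  \frac{\text{sensitivity}_f + \text{specificity}_f}{2}.$$

Two choices deserve flagging, because "CVV" is used loosely in the
applied literature:

* **Balanced rather than raw accuracy.** The cohorts this screen targets
  are unbalanced (49:109, 38:111). Raw accuracy rewards always-predict-
  control; balanced accuracy is 0.5 for any chance classifier regardless
  of imbalance, which makes the conventional "CVV > 0.5" significance
  cut meaningful. Reported interaction CVVs in the 0.5–0.75 range are
  consistent with held-out accuracies and not with fold-consistency
  counts (which take values $k/10$), supporting this reading.
* **Empty cells and missing genotypes** in a held-out sample default to
  a *low-risk* prediction (`empty_cell_policy = "low_risk"`):
  deterministic and conservative. The alternative,
  `"unknown_misclassified"`, counts such samples as errors; both are
  implemented and covered by the same brute-force oracle tests.

The ratio threshold is compared by integer cross-multiplication
(`cases * train_controls >= controls * train_cases`), so grid labelling
involves no floating-point division and the compiled scan, the R
reference implementation and the naive test oracle agree exactly.

### Significance: CVV > 0.5, and what it cannot do

The screen's published convention flags a pair significant when
CVV > 0.5 (strict). Under the null, however, each pair's CVV is centred
at 0.5 — the flag is a per-pair coin flip — and the *top* of an
exhaustive ranking over $\binom{m}{2}$ pairs sits several null standard
deviations above 0.5 by selection alone. Two permutation tools are
therefore provided:

* `permutation_null()` — the per-pair label-permutation p-value,
  $p = (1 + \#\{\mathrm{CVV}^{perm} \ge \mathrm{CVV}^{obs}\})/(B+1)$.
  Valid only for a *pre-specified* pair; applied to a pair picked for
  topping the ranking it is anti-conservative by construction.
* `scan_permutation_null()` — the familywise max-statistic test: labels
  are permuted, the whole scan is re-run, and the maximum CVV is
  recorded each time. Comparing a top pair's CVV against this null
  distribution of maxima gives a selection-valid empirical p, and it is
  what the package's own calibration checks use for ranked pairs.

## Quality control

Filter order is fixed as samples-then-variants, because variant
statistics (MAF, HWE) must describe the final sample set:

1. sample missingness > 7%;
2. heterozygosity outside mean ± 2 SD, the mean and SD computed on the
   samples surviving step 1 (whether the reference pipeline computed
   them before or after the missingness exclusion is not documented
   anywhere we could find; computing them after is the defensible
   choice and is fixed here);
3. duplicate pairs at mean IBS ≥ 0.95 (later-indexed member removed) —
   full IBD $\hat\pi$ estimation is deliberately out of scope;
4. genotype-PCA ancestry outliers: > 6 SD on any of the top 10
   components, the EIGENSTRAT-style convention. The PCA uses
   $(g - 2f)/\sqrt{2f(1-f)}$ scaling and **only common variants**
   (folded MAF ≥ 1%): under that scaling a near-private variant loads a
   whole component onto its one or two carriers and the "outlier" it
   flags is a rare-allele carrier, not divergent ancestry;
5. variant missingness > 5%; 6. MAF < 1%; 7. Hardy-Weinberg exact
   p < 10⁻⁵ *in controls only* (a case-only departure may be signal, a
   control departure is genotyping error).

Each removal carries exactly the first reason that fired, so
`retained + removed = input` holds by construction on both axes. The
heterozygosity rule is the one filter that is *not* idempotent: removing
tail samples changes the mean and SD, so a rerun can trim further —
this is a property of the published rule itself, not of the
implementation.

The HWE test is the exact conditional test (no mid-p): all heterozygote
counts compatible with the observed allele counts are enumerated via the
stable two-sided recurrence from the modal count, and the p-value sums
the probabilities of tables no more probable than the observed one
(ties included with a $1+10^{-12}$ relative guard, so knife-edge equal
tables are treated identically by the recurrence and by the independent
enumeration oracle the tests compare against).

## Tag-SNP selection

Variant `i` covers variant `j` when the squared Pearson correlation of
dosages (composite LD — no phasing, deterministic, oracle-checkable;
EM haplotype-frequency r² is a non-goal) is at least `r2_threshold`
within `window_bp`. Selection is greedy most-coverage-first set cover
per chromosome with ties broken by position then id, the pairwise-mode
analogue of conventional tagging tools; defaults r² ≥ 0.8 within 250 kb
are those tools' conventions, since the reference analysis does not
state its settings. Coverage (every variant has a tag at r² ≥ threshold
in-window) is asserted directly in the tests, and greedy solutions are
compared against an exhaustive minimum-cover oracle on small instances.

## The synthetic cohort generator

The generator emulates what this screen's study design sees:

* two unbalanced cohort shapes as defaults (49 cases / 109 controls;
  the second preset 38 / 111), desk-scale SNP counts (~1,000) standing
  in for the hundreds of thousands of a real array;
* HWE genotypes with per-block MAFs uniform on [0.05, 0.5];
* LD blocks by copy-with-mutation: each allele of variant $j$ copies
  variant $j-1$ and is replaced by a fresh HWE draw with probability
  $1-\sqrt{r^2_{target}}$, giving adjacent genotype correlation
  $\sqrt{r^2_{target}}$ and monotonically decaying LD within a block;
* MCAR missingness only (informative missingness out of scope);
* sex/age covariates drawn independently of status (so covariate
  adjustment is exercised but must not change conclusions);
* 0–2 planted pairs with explicit 3×3 penetrance tables (`xor`,
  `threshold`, `multiplicative`, `marginal_additive`, `null`); multiple
  pairs combine by noisy-OR, $P(\text{case}) = 1 - \prod_k(1 - p_k)$,
  which is order-independent. Case/control quotas are met by rejection
  sampling from a latent population capped at 10⁶ draws, failing loudly
  rather than undershooting. Planted loci are simulated as independent
  single-SNP blocks at the model's MAFs so the planted signal is not
  diluted or aliased by block neighbours.

What the generator does **not** emulate: population structure/admixture
(the PCA stage is exercised with explicitly shifted-MAF subpopulations
in the tests instead), genotyping-batch artefacts, informative
missingness, sex chromosomes, and realistic LD beyond the block model.
Passing tests therefore demonstrate correctness of the machinery and
calibration under clean conditions, not robustness to every real-data
pathology.

## Numerical and design choices

* Genotype codes count minor-allele copies, with "minor" fixed on the
  full pre-QC dataset: MAF is `mean(code)/2` and odds ratios keep a
  stable orientation; an allele swap maps codes $g \to 2-g$ and OR to
  1/OR (property-tested).
* Positions are 1-based internally; BED annotation intervals are parsed
  as 0-based half-open, so a variant at position $p$ is inside
  $[start,end)$ iff $start < p \le end$ — stated to keep the gene
  filter off-by-one-free.
* Odds-ratio CIs are Woolf (log-scale) intervals; with a zero cell the
  CI is undefined unless Haldane-Anscombe +0.5 correction is requested.
* The allelic test is the 1-df Pearson chi-square without continuity
  correction; a zero margin returns p = 1 by convention.
* Logistic association fits `status ~ dosage + sex + age` by IRLS
  (tolerance 10⁻⁸, ≤ 50 iterations); non-convergence and
  separation-scale estimates (|β| > 10 or SE > 10) are flagged with
  missing p rather than reported.
* Fold assignment is cyclic within each class after a seeded shuffle,
  so per-class fold sizes differ by at most one and the leave-one-out
  limit degrades gracefully.
* Ranking ties are broken lexicographically by ids; the scan is a pure
  map over pairs, so results are identical for any worker count.

## Problem sizes used by the checks

The packaged verification suite runs at desk scale, chosen so the full
chain is exercised meaningfully: HWE oracle equivalence over all
genotype tables with $n \le 60$; MDR oracle equivalence on 50
micro-cohorts (≤ 20 samples); null calibration on 20 cohorts of 260
samples × 200 SNPs (~19,900 pairs each) with 59-permutation familywise
tests of the top 5 pairs; planted-pair recovery on 20 cohorts of 400
samples × 202 SNPs with one xor pair (baseline 0.05, effect 0.45,
MAFs 0.3), requiring the planted pair to rank first in ≥ 80% of seeds —
in practice it ranks first in essentially all of them at these effect
sizes. `scripts/acceptance.R` re-runs the same computations at slightly
reduced seed counts and also a reference cohort at the 49/109 shape.

## Known limitations

* Only order-2 interactions; no GMDR/MB-MDR model-based variants.
* Composite-LD tagging can differ from haplotype-based tagging around
  recombination hotspots.
* The CVV > 0.5 flag is reported for fidelity to the screen's
  convention but should never be read as calibrated significance; use
  the familywise permutation p.
* The duplicate filter catches duplicates and near-duplicates only;
  cryptic relatedness below IBS 0.95 passes through.
* PLINK *text* formats only; binary `.bed` is out of scope at desk
  scale.
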