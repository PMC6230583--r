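---
title: "Methods: selection scans, haplotype association and temporal trajectories in inbred breeding panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection scans, haplotype association and temporal trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`breedscan` analyses biallelic SNP-array genotypes of inbred crop breeding
lines for footprints of artificial selection, and relates the selected
genomic regions to quantitative traits. This vignette documents the models,
the tunable parameters, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## Data model and assumptions

Genotypes are alt-allele dosages in {0, 1, 2}, with `NA` for missing calls.
Breeding lines are assumed near-fully inbred, so every estimator in the
package treats a line as a single haploid allele draw (dose/2): Fst has no
within-individual component, LD r² is the haploid-equivalent squared
correlation of dosages, and haplotype "alleles" are multi-marker genotype
words read directly off the homozygous calls. Residual heterozygotes
(code 1) are tolerated arithmetically but not modelled.

REF/ALT orientation is fixed when a panel is loaded and never re-polarised;
"major/minor" and "reference trajectory allele" labels are computed per
analysis from the data, so a global allele flip of any marker leaves every
result invariant (this is asserted by tests).

## Genotype curation

* **Duplicate removal** collapses marker groups whose non-missing calls are
  identical, directly or after a global 0↔2 flip (array strand reporting
  can flip alleles without changing information). The first marker in map
  order is retained.
* **Imputation** defaults to k-nearest-neighbour (k = 10) by allele-sharing
  distance with majority vote, falling back to the per-marker mode. A mode
  strategy is also provided. kNN was chosen over a random-forest regression
  because it is deterministic, dependency-light and behaviourally close for
  array data; the imputer is pluggable.
* **MAF filter** removes markers with minor-allele frequency below 0.05
  (computed on non-missing calls as `min(p, 1 − p)`, `p = mean(calls)/2`).
* **Informative subset**: clustering and the selection scans run on a
  high-informativeness subset. Biallelic PIC
  (`1 − p² − q² − 2p²q²`) is bounded by 0.375, so the default window is
  PIC ∈ [0.30, 0.375]; published windows quoted up to 0.45 can only refer
  to gene diversity (He, bounded by 0.5), so an He-thresholding mode is
  provided and both statistics are always reported. No intent is guessed:
  the measure and window are configurable.

## Population structure and diversity

* **DAPC-style clustering**: the centred genotype matrix is reduced by PCA
  (retaining the smallest PC count explaining ≥ 90% of variance, capped at
  n/3); k-means with ≥ 20 restarts is scored by
  `BIC(K) = n·ln(WSS_K/n) + K·ln(n)` and the K minimising BIC wins (ties to
  the smaller K); linear discriminant axes are then computed on the
  retained PCs. The BIC form is the standard k-means convention; the
  literature this mirrors names BIC without stating a formula.
* **Weir–Cockerham θ** for haploid samples: per locus,
  `a = (MSP − MSG)/nc`, `b = MSG`, `θ = a/(a+b)`; the multilocus estimate
  is the ratio of summed components, never a mean of ratios. Negative
  per-locus estimates are legitimate and kept.
* **AMOVA** partitions squared-Euclidean genotype distances into
  among-subpopulation and among-line strata with the standard
  variance-component coefficients, and permutes line labels for the
  among-component p-value (10,000 permutations at the full profile). A
  third "within-individual" stratum seen in diploid-coded published tables
  is structurally zero for inbred haploid coding and is not reconstructed;
  the two-stratum table is reported.
* **Gene diversity by decade**: cohorts are decade bins of the year each
  line entered the registration trial; per cohort,
  `π = mean over markers of (n/(n−1))·2pq` with a bootstrap CI over
  markers.

## The three selection scans

All three scans consume the same per-locus Weir–Cockerham θ, so their
cut-offs are comparable; outlier declaration always requires both the
method-specific evidence and a θ cut-off (0.20 for the two
frequentist scans, 0.15 for the Bayesian scan, both configurable — the
combination is applied conjunctively because published descriptions are
ambiguous about whether the cut-off replaced or accompanied the quantile
rule).

* **FDIST-style envelope.** The neutral mean is the trimmed (5%)
  multilocus θ. A Balding–Nichols island-model simulation with matching
  deme count and sample sizes is calibrated to that target by bisection on
  F (tolerance 0.005), the drift-equilibrium Beta approximation standing in
  for an explicit coalescent: it matches the first two moments of
  island-model Fst, is orders of magnitude faster, and the envelope
  conditions on He exactly as the original method does. Simulated (He, θ)
  pairs are binned into ≥ 20 He bins; the per-bin 99% quantile, smoothed by
  a running median over 3 bins, is the envelope.
* **Hierarchical island-model null.** Groups of demes absorb
  structure-induced Fst inflation: group frequencies are BN(p, F_CT) and
  deme frequencies BN(group, F_SC), with both calibrated by bisection
  against the trimmed among-group and within-group θ. The default grouping
  cuts the UPGMA tree of pairwise subpopulation Fst into two groups
  (overridable); published analyses rarely state their grouping, so the
  default is declared rather than inferred. The per-locus p-value is the
  share of same-He-bin simulated loci with θ at least as large.
* **Bayesian genome scan.** A Dirichlet-multinomial (beta-binomial)
  likelihood for per-deme allele counts with concentration `1/Fst_ij − 1`
  and `logit(Fst_ij) = α_i + β_j`. A reversible jump includes/excludes each
  locus effect α_i with prior odds 10 for the neutral model; priors are
  `β ~ N(−1, 1.8²)`, `α ~ N(0, 1)`, `p_i ~ U(0,1)` updated on the logit
  scale. Pilot runs adapt random-walk scales to acceptance in [0.25, 0.45]
  (runs aborting with a diagnostic if adaptation fails). The q-value of a
  locus is the mean posterior error probability over all loci with at least
  its inclusion probability; flags require q < 0.05, positive posterior
  mean α (divergent selection) and the θ cut-off. The MCMC core is
  compiled (Rcpp) with the full-condition likelihood cached per locus ×
  deme; the default run lengths are 20 pilots × 50,000 iterations then
  100,000 iterations retaining 5,000 samples at thinning 10, and the
  reduced "ci" profile uses 10 × 500 + 20,000 (2,000 samples) for
  integration testing.

## Haplotype loci and kinship mixed-model association

Selected markers are chained per chromosome, left to right in map order: a
marker joins the current block iff its LD r² to **every** member is
≥ `r2_min` (default 0.7) and the gap to the previous member is
≤ `max_gap_cM` (default 5 cM); otherwise a new block starts. Singletons are
allowed; ids are `hap_<chrom>_<index>`. A line's locus allele is its
concatenated genotype word; alleles rarer than `pool_freq` (default 0.05)
pool into `"RARE"`, and lines missing any member call are dropped for that
locus (haplotype words are categorical; imputing them would fabricate
alleles).

Association uses `y = μ + locus + u + e`, `cov(u) = σ_g²K`,
`cov(e) = σ_e²I`, with `K = ZZ'/(2Σp(1−p))` on centred dosages over the
full post-QC marker set plus a 10⁻⁶ ridge. The variance ratio is profiled
by exact REML per locus after one eigendecomposition of K (the panel is
small enough that re-estimating per locus costs nothing and avoids the
approximate once-per-trait shortcut), and the locus is tested with an
F-test whose numerator df is the number of allele classes minus one. With
K = I the procedure reduces exactly to the OLS F-test, which the tests
assert to 10⁻⁶. Reported per trait: p, Benjamini–Hochberg q (significance
is flagged on q ≤ 0.05 by default, with the raw-p mode available through
the `fdr_level` and downstream filtering, since published practice states
both an FDR and a raw-p rule), locus R² (reduction in whitened residual
variance), λ_GC (median χ² ratio), and carrier-vs-population allelic
effects for each common allele — all common alleles are reported because
which allele published tables print is not stated. Structure covariates
can be added (MLM-QK) to reproduce the kinship-vs-kinship+structure
comparison; kinship-only is the default since it controls inflation
without overcorrection in this setting.

## Temporal trajectories

Per marker, cohort frequencies are computed for decade bins with at least
`min_n` lines; the reference allele is the major allele of the earliest
eligible cohort (ties to alt). A **complete reversal of allelic state** is
formalised as: earliest frequency ≥ 0.5 + margin and final frequency
≤ 0.5 − margin, with margin 0.10 by default — a symmetric majority flip
that preserves fixation (terminal frequency within `1/(2n)` of 0 or 1) as
a subset, matching how published work reports fixation among reversals.
The switch cohort is the earliest cohort after which the reference allele
stays minor through the end, matching the narrative of single dated
switches per SNP. The margin and `min_n` are exposed because the published
criterion is verbal, not quantitative.

## The synthetic-panel generator

The generator emulates the study conditions end to end: 192 lines in 4
subpopulations (Balding–Nichols F = 0.10, inside the "moderate" 0.05–0.15
band), mapped biallelic markers on 14 chromosomes (2,000 by default — a
desk-scale stand-in for a full array panel, chosen so the calibration
invariants hold within ±0.02 while a full run stays in CPU-minutes), 5% of
loci under divergent selection at locus-F 0.6, seven decade cohorts
(1950s–2010s), and traits with haplotype QTL, kinship-structured polygenic
background and designated trait pairs correlated ≈ 0.8.

Choices worth calling out:

* Ancestral frequencies are Uniform(0.05, 0.95): polymorphism is
  guaranteed and the He range the envelope conditions on is covered.
* **Divergence conditioning.** Loci under divergent selection draw their
  deme frequencies from the Balding–Nichols Beta conditioned on a
  divergent configuration (at least one deme on each side of 0.5;
  rejection sampling). Unconditional draws at F = 0.6 land all demes on
  one side ≈ 20% of the time, leaving those "selected" loci with realized
  θ below any defensible cut-off — a locus that drifted to common fixation
  is not under divergent selection in any meaningful sense. Conditioning
  matches the biology (divergent optima push subpopulations apart) and
  makes planted power well-defined (≈ 97% for the envelope scan at the
  default cut-offs).
* **Cohorts are orthogonal to subpopulations** (round-robin within each
  subpopulation). An era-correlated design was considered — it reproduces
  the real-data phenomenon that temporal-reversal loci are also Fst
  outliers — but it converts neutral drift between subpopulations into
  apparent temporal trends, inflating false reversal flags to 5–8%, so it
  was rejected in favour of the orthogonal design (false flags ≈ 1%).
* Reversal loci follow `p_t = plogis(s(t − t0) + δ_j)` with slope 2 per
  cohort and per-subpopulation switch-time offsets δ_j ~ N(0, 3.5²)
  truncated to ±5: every subpopulation completes the flip inside the
  sampled decades (recovery ≈ 100%), while the offset spread leaves
  reversal loci moderately differentiated (θ ≈ 0.16 vs 0.09 neutral).
* Trait noise is scaled to the empirical genetic variance so realized
  broad-sense h² matches the target; pair correlations are achieved by
  solving the mixing coefficient of the shared polygenic/noise components
  against the realized QTL covariance, then clamping to [−1, 1].

What the generator does **not** emulate: pedigree descent (cohorts are
independent cross-sections, so there is no drift autocorrelation along the
breeding timeline), realistic LD decay with recombination distance
(markers are exchangeable given their locus class — LD-based block
building is exercised through planted duplicated/correlated markers in
tests rather than background LD), multi-allelic markers, genotyping error,
and ascertainment bias of array content. Passing tests therefore
demonstrate correctness of the estimators and calibration of the decision
rules under the stated stochastic model, not robustness to those
real-data features.

## Numerical choices and degenerate inputs

* Bisection calibrations reuse one frozen random stream per evaluation, so
  the objective is monotone in F and the loop terminates at tolerance
  0.005 in ≤ 25 iterations.
* Envelope He bins: 25 equal-width bins on [0, 0.5]; empty bins are
  interpolated from neighbours before the running-median smoothing.
* Monomorphic markers are excluded from scans (with a log entry), never
  silently scored; all-missing markers abort imputation by name.
* The logit-Fst linear predictor is clamped to ±18 in the MCMC likelihood
  to avoid overflow of the beta-binomial concentration.
* k-means/BIC degeneracy: K exceeding the number of distinct lines is
  dropped from the candidate set; a panel of identical lines selects K = 1.
* All randomness descends from one global seed through a deterministic
  substream derivation (`derive_seed`), so pipeline reruns are
  byte-identical; seeds stay below 2³¹.

## Problem sizes used by the test-suite

The packaged tests run the calibration checks at 2,000 markers × 200 lines
(20 replicates), the scan error/power checks at 500–2,020 markers with the
reduced MCMC profile, association recovery at n = 192 over 20 seeds, and
the end-to-end pipeline twice at 800 markers for the determinism check —
sizes chosen so the whole suite completes in CPU-minutes while every
tolerance is still binding.

## Known limitations

Fst-outlier scans inherit their usual caveats: demographic events
(bottlenecks, admixture) masquerade as selection, and the hierarchical
null only absorbs the structure it models. The Bayesian scan's q-values
are posterior quantities under the prior odds chosen, not frequentist FDR
guarantees. The association model tests one locus at a time; linked QTL
are attributed to whichever haplotype locus tags them best. BLUPs are
consumed as given — trial-design uncertainty in the phenotypes is not
propagated.
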