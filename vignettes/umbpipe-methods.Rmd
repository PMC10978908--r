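---
title: "Models and methods behind umbpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind umbpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`umbpipe` re-implements, as one coherent package, the computational chain
used to study lineage differentiation and flowering-time clines in a selfing
wild wheat relative genotyped by 3′-tag RNA-seq. This vignette explains the
models, their assumptions, the tunable parameters, what the synthetic-data
generators do and do not emulate, and the design decisions taken where the
design was genuinely open.

## The biological setting and its consequences

The species is a heavily selfing diploid: individual accessions from a
germplasm bank are near-fully homozygous. Two modelling consequences run
through the whole package:

* **Haploid coding.** Each accession carries one effective haplotype, so
  genotypes are coded 0 (reference allele) / 1 (alternative) / NA, with no
  heterozygous state. The admixture model, F_ST estimator, and distance
  computations all use one allele copy per accession per locus.
* **Homozygous-only calling.** SNP callers keep a site only when a single
  non-reference base dominates the pileup (≥ 95% during reference polishing,
  > 80% for population genotyping), which in a selfer is exactly the signal
  of a true homozygous difference rather than noise or paralogy.

## Reference polishing

Reads from the focal species are aligned to a related species' transcript
set; confident substitutions (depth ≥ 10, alternative fraction ≥ 0.95) are
written into the reference, and the loop repeats. Counts of newly detected
SNPs shrink every round because each substitution removes its own evidence;
the loop stops at a SNP count of zero, at an exact plateau
(`stop_tolerance = 0`, configurable to a relative change), or at the
iteration cap (default 16). On error-free synthetic data the trajectory is
m → 0: every fully covered divergent site is called in round one and none
remain in round two. Real data plateaus above zero (sequencing error,
paralogy, coverage gaps); the plateau rule, not a hard-coded round count, is
the exposed decision.

Thresholds read literally from their defining sentences: "less than 95% …
discarded" becomes *keep iff fraction ≥ 0.95*; "over 80%" is a strict
*> 0.80*. Both are parameters of `call_regime()`.

## Alignment model

The aligner is deliberately minimal: k-mer seeds (default k = 21) taken
every k bases, ungapped extension over the full read, mismatch budget 4% of
read length. Non-overlapping seeds give a pigeonhole guarantee: 7 seeds on a
150 bp read tolerate the full 6-mismatch budget without losing the true
placement. A read is reported only when its best placement is strictly
better than the runner-up — a conservative stand-in for discarding
multi-mapped reads, whose handling the original protocol leaves unstated.
Ungapped alignment is adequate because 3′-tag reads meet transcript
references at ≤ 2% divergence and the downstream substitution model is
SNP-only; reads over indels simply drop out. Reverse-strand search is off
for synthetic (forward-simulated) reads and is a flag for real libraries.

Quality trimming follows the published trimmer's sliding-window semantics:
scanning 4-base windows from the 5′ end, the read is cut at the first
window whose mean quality falls below the threshold, *retaining any leading
bases of that window that individually meet the threshold* — this is the
tool's documented behaviour and is what the worked examples require; plain
truncation at the window start would shorten such reads by one base.

## Admixture model and cluster-number choice

The structure model is the classic independent-allele-frequency admixture
model: for accession *i* and locus *l*, the allele copy's cluster of origin
z
follows the membership vector q_i (Dirichlet(α) prior, α = 1 by default),
and cluster allele frequencies have Beta(1,1) priors. All three blocks have
conjugate Gibbs updates; missing cells are skipped. Memberships are
posterior means of q after burn-in; the model evidence is estimated from the
log-likelihood trace as mean(lnL) − var(lnL)/2, the estimator the original
tool documents. The published budget (110,000 sweeps, 10,000 burn-in, 10
runs per K) is a configuration value; desk-scale tests use a few thousand
sweeps, which this conjugate sampler mixes well within.

A practical bound of the model worth knowing: with α = 1 the posterior mean
membership can never exceed (L + 1)/(L + K) for L observed loci, so
"memberships > 0.99" statements require on the order of 100+ loci regardless
of how clean the data are.

Cluster number uses Evanno's ΔK = mean(|L″(K)|)/sd(L(K)) over runs, with
runs paired by index across K; endpoints have no ΔK. Run label-switching is
resolved by exhaustively permuting each run's columns (K! for K ≤ 6) to
minimize Frobenius distance to run 1, then averaging. Accessions are
assigned to their argmax cluster only when that membership strictly exceeds
0.8; everything else is reported "intermediate", which is how admixed
individuals surface.

ΔK famously prefers the deepest level of a hierarchy. The default synthetic
lineage tree therefore keeps the two sublineages' split comparable in depth
to the deep split (short shared internal branch) — matching the
near-equidistant pairwise F_ST pattern reported for the real lineages —
so that a three-lineage world is detected as K = 3 rather than K = 2.

## F_ST and phylogeny

Weir–Cockerham variance components, specialized to haploid samples: per
locus, among-population (MSP) and within-population (MSG) mean squares from
allele frequencies and sample sizes give components a = (MSP − MSG)/n_c and
b = MSG; the multi-locus estimate is Σa / Σ(a+b) (ratio of sums, not mean of
ratios). Fixed differences give exactly 1; finite samples may dip slightly
below 0.

Distances concatenate each pair's shared genotyped loci into a
pseudo-sequence and apply the Kimura two-parameter formula
d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q) (P transitions, Q transversions).
Pairs whose log arguments are non-positive are *saturated* and reported
absent rather than fabricated. Because the loci are ascertained variable
sites, P and Q are far larger than genome-wide divergence; at desk scale a
handful of accessions can saturate easily. This is also why the
"non-redundant SNPs" option (`dedupe`) defaults to off in the pipeline:
with few accessions, deduplicating identical genotype columns collapses all
of an accession's private variants to one locus and the diagnostic loci to a
handful of patterns, concentrating differences and saturating the distance;
at the real study's scale (87 accessions) the option is harmless.

Trees are neighbor-joining on that distance matrix (canonical Q-criterion),
with support from resampling loci with replacement, rebuilding distance and
tree, and counting each original internal bipartition — the point-estimate
topology's splits labelled with their replicate percentage. The original
study searched a maximum-likelihood topology under the same substitution
model; ML search is out of scope here, and the deviation is recorded in the
tree's `method` attribute ("NJ/K2P").

## Phenotype models

**Scaling and imputation.** Traits are unit-variance scaled. Missing cells
are imputed by EM for probabilistic PCA with the latent scores *and* the
missing entries as hidden variables; an automatic-relevance prior on each
loading column shrinks superfluous components (100 steps by default, after
the published protocol). Observed cells are never altered. The monotonicity
property tested in the suite tracks the observed-data log-likelihood with
the relevance update disabled, because the type-II update of the relevance
precisions is not itself an EM step and need not increase the likelihood.

**PCA.** Eigendecomposition of the covariance of the scaled matrix;
contributions are eigenvalue shares in percent; the sign convention makes
each component's largest-magnitude loading positive. Trait dendrograms use
Euclidean distances between loading vectors with Ward linkage.

**The lineage × season mixed model.** For one trait,
y = β₀ + β₁·lineage + β₂·season + β₃·lineage:season + γ_accession + ε with
γ ~ N(0, σ_γ²) and ε ~ N(0, σ_ε²). The source equations write one symbol for
both variances; two separate variances are almost surely intended (it is
what the named fitting software does) and are used here, with a shared-
variance reading available by fixing them equal in the generator. Priors are
β ~ N(0, 10⁶) and Inverse-Gamma(0.01, 0.01) on both variances — the original
work used its tool's defaults without listing them; conjugate choices give
exact Gibbs updates and effectively flat information. Treatment coding with
the alphabetically first lineage and season as references (coding was
unstated). Replicates enter as repeated records sharing the accession's
random intercept. The published budget — 4 chains × 5000 iterations, 1000
burn-in, 16,000 retained draws, split-chain R̂ < 1.1 — is the default of
`fit_glmm()`; non-convergence flags the result rather than suppressing it.

**Flowering dendrogram.** Days to flowering are z-normalized within each
season; Euclidean distances over season vectors (missing seasons pairwise-
excluded with rescaling, as `stats::dist` defines) feed Ward clustering.

## Geo-climate clines

Winter is November–February and summer March–June; July–October enters
neither season. The climate PCA normalizes the 5 variables × 2 seasons plus
elevation (11 rows of loadings) and shares the PCA implementation above.
Cline tests are ordinary least squares plus the Pearson correlation with a
two-sided t-test on n − 2 degrees of freedom; zero predictor variance gives
an absent result, not an error. Raster retrieval is out of scope — the
module consumes a flat CSV whose column convention (`{var}_{01..12}`)
matches standard monthly climatology extracts.

## The synthetic world — and what a green test does not establish

The generators state one world and stay there:

* **Sequences.** An ancestral transcriptome (default 600 bp transcripts,
  uniform random bases) diverges along a lineage tree by per-site, per-branch
  substitution probabilities; accessions add private substitutions; admixed
  accessions are per-transcript mosaics of two parent lineages with the
  realized fraction recorded. Truth records every divergent site by
  exhaustive comparison against the ancestor.
* **Reads.** Single-end 150 bp (the genotyping-usable half of the real
  paired-end libraries), Poisson reads per transcript, start positions
  uniform or with a truncated-geometric 3′ bias, independent per-base
  substitution errors, clipped-normal Phred qualities. The real instrument's
  error and bias profiles are not published; these defaults are conventions,
  not estimates.
* **Genotype matrices.** For structure/F_ST testing, an island model with
  Balding–Nichols lineage frequencies around uniform ancestral frequencies,
  so a target F_ST is a generator parameter rather than an emergent
  accident.
* **Phenotypes.** Drawn from exactly the mixed model that is later fitted,
  including the 10-day flowering contrast between the two sublineages used
  as the recovery benchmark.
* **Climate.** Monthly values are a seasonal baseline plus a linear-in-
  latitude term plus Gaussian noise; elevation uniform per lineage range.

None of this emulates paralogy, mapping bias, indels, linkage, coalescent
noise, genotype-by-environment interaction, or measurement batch effects. A
green suite establishes that the estimators recover the stated generative
structure at desk scale — not that the pipeline is robust to everything real
data contains.

## Numerical choices and degenerate inputs

* Polishing stop: exact plateau by default; `stop_tolerance` exposes looser
  plateaus. Substitution with a stale reference base is a hard error.
* Call fractions exclude N bases from denominators; depth gates use total
  read depth.
* VCF output is minimal v4.2, haploid GT 0/1/., 1-based positions
  (0-based internally; boundary shifts covered by tests).
* Saturated K2P pairs and zero-variance cline predictors are reported
  absent; zero within-chain variance defines R̂ = 1 with a warning; zero
  between-run sd makes ΔK infinite with a warning.
* Ties in the aligner (equal best placements) are unaligned by design.
* The label-alignment search is exhaustive and bounded at K ≤ 6; larger K
  raises an error asking for a heuristic rather than silently approximating.
* Single master seed; each stage derives an independent substream by
  hashing a stage label, so toggling one stage never shifts another's
  randomness.

## Known limitations

* No gapped or spliced alignment, no paired-end mates, no adapter clipping
  (synthetic reads carry no adapters; real data should be pre-clipped).
* No linkage or correlated-allele-frequency structure model; no ML/Bayesian
  tree search; no migration inference.
* The GLMM handles Gaussian responses only.
* K2P on ascertained SNP loci overstates absolute divergence; distances are
  comparative, not clock-calibrated.
* The coverage-stratified SNP sets depend on the "confirmed nucleotide"
  reading: a non-called cell counts as reference only with at least one
  aligned non-N read, and set membership needs ≥ 3 supporting reads.
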