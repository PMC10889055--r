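---
title: "Context-aware in silico mutagenesis: model, design and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-aware in silico mutagenesis: model, design and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`caism` scores the predicted chromatin-level consequences of single-
nucleotide variants by in silico mutagenesis and asks two questions that LD
pruning silently assumes away: do tightly linked variants share a predicted
function, and does a variant's effect depend on the alleles of its
neighbours? This vignette is the package's own account of the model, the
choices behind it, and what the synthetic ground truth does and does not
establish.

## The scoring model

For a candidate SNP at position p, the scoring window spans the 1-based
interval [p − 999, p + 1000] (length L = 2000, the center at window offset
1000). The *reference* window carries the major allele at the center and at
every neighbouring SNP inside the window; the *alternate* window differs
only at the center, which takes the minor allele. Declared alleles always
win over the assembly base: if the genome base at a variant position matches
neither declared allele, the substitution proceeds and the window is
flagged, because silent divergence between the declared alleles and the
sequence actually scored would corrupt the ref/alt contrast. Indels and
multiallelic sites are rejected at load time — the procedure is defined only
for single-nucleotide substitutions in a fixed-length window.

An annotator maps a window to one probability per chromatin feature. With
P_ref and P_alt the predictions for a feature,

* log-odds change: Δ = logit(P_ref) − logit(P_alt), natural log. Positive Δ
  means the minor allele lowers the predicted probability (loss of
  function).
* E statistic: E = Δ · (P_ref − P_alt). Because the logit is strictly
  increasing, both factors share a sign, so E ≥ 0 with equality iff
  P_ref = P_alt. E folds direction in; direction is reported separately as
  the sign of Δ.

*Genetic context.* The k neighbouring SNPs inside the window define 2^k
major/minor combinations. All of them are enumerated (deterministically:
neighbours ordered by position, major before minor, all-major first) and the
ref/alt contrast is recomputed within each context — the context modifies
the sequence background in *both* windows, the contrast is always the center
allele. Enumeration refuses beyond `max_neighbors` (default 12, i.e. 4096
contexts) with an explicit error rather than truncating silently;
exponential blowup should be the caller's conscious decision. Restricted to
the all-major context the machinery reduces exactly to the no-context
analysis, a regression identity the test suite asserts bit-for-bit. An
optional haplotype-restricted enumeration was considered and deliberately
left out of the default path: enumerating all combinations, including
haplotypes that may not segregate in any population, matches the method
being studied.

## Empirical calibration

Raw Δ values have no universal scale, so significance is empirical: n
background variants are sampled uniformly over the genome (alternate allele
uniform over the three non-reference bases, positions at least L/2 from
contig edges), scored identically without context, and each feature keeps
its own sorted null of E values — per-feature nulls, because chromatin
features differ wildly in their baseline sensitivity. A candidate's e-value
is the add-one rank (r + 1)/(n + 1) with ties counted on the ≥ side: no
e-value is exactly zero, the smallest achievable is 1/(n + 1), and ties are
resolved conservatively. No multiple-testing correction is applied across
features or variants in the primary output; that matches the operating
convention of reporting |Δ| ≥ 1 together with e ≤ 0.05.

At desk scale the background defaults to n = 999 (so the minimum e-value is
exactly 0.001), against 10 features on a 60 kb genome — sizes chosen so the
full suite re-scores everything from scratch in about a minute while keeping
the add-one arithmetic exact. In the default scenario the sampler also
excludes the candidate windows: on a 60 kb genome a non-trivial fraction of
uniform draws would otherwise land inside the planted motifs, an artifact of
the miniature genome with no analogue at genome scale, where random
background SNPs essentially never coincide with the loci under study.

## The synthetic annotator

The pluggable annotator contract is a pure function: sequence in, one
probability per declared feature out, deterministic, with probabilities
clamped to [1e-6, 1 − 1e-6] so logits are always finite (a deep model never
emits exact 0/1, but a synthetic scorer could). The shipped implementation
is motif-based with known ground truth:

* Each feature carries one or more motifs (consensus strings or real-valued
  4 × m position weight matrices). Every window position gets the summed
  per-base score; positions whose score relative to the best achievable
  clears a cutoff contribute exp(score − best) to that motif's occupancy R,
  so an exact consensus match contributes 1. N bases have zero affinity.
* The feature's logit is intercept + Σ wᵢ Rᵢ + c · Π Rᵢ. Linearity in R is
  the point: planted effect sizes are exact logit arithmetic. Destroying a
  planted instance moves the logit by exactly its weight, and the
  cooperative product term makes the center's effect depend on the
  neighbour's allele by exactly c — genuine, closed-form context dependence.
* Strand symmetry (on by default) adds the reverse-complement scan into the
  same occupancy. Contributions are summed after sorting, which makes the
  score of a sequence and its reverse complement *bit-identical*, not just
  close: the forward-and-reverse contribution multisets coincide, and sorted
  summation removes the order dependence of floating-point addition. The
  reversed-sequence consistency pass is therefore exactly zero under this
  annotator, the idealised version of the observation that reversed profiles
  are nearly identical for trained models.

Two cutoff regimes serve different purposes. The default finite cutoff
(mismatch −30, cutoff −15) keeps only near-consensus sites: substitutions
away from any planted instance change nothing, effects are exactly their
planted sizes, and null candidates score E = 0. For calibration studies that
regime is useless — a null of zeros cannot rank anything — so
`calibration_annotator()` builds smooth-occupancy features (cutoff −∞) from
random real-valued PWMs, where every substitution shifts E continuously.
Real-valued matrices matter here: with integer-scored consensus motifs a
substitution frequently just permutes the multiset of position scores,
producing exact ties at a surprising rate. The constructor probes occupancy
on genome windows and centres the logit automatically, because the occupancy
scale varies by orders of magnitude across random PWM draws and a fixed
intercept would saturate the clamp.

## The synthetic scenario

`default_scenario()` fixes the study conditions; everything downstream is a
deterministic function of one seed. A 60 kb uniform-random genome carries
planted 10-bp motif instances, scrubbed of chance occurrences of any motif
on either strand so occupancies are exactly the planted counts. Ten
candidate SNPs each have three in-window neighbours (8 contexts each; 800
records over 10 features):

* `rs001` — dominant loss of function, Δ = 2.5 in every context;
* `rs002` — cooperative pair with neighbour `rs002.n2`: Δ = 1.2 alone,
  2.2 when the neighbour is minor (margin = cooperative weight 1.0);
* `rs003`/`rs004` — high-LD pair (target r² = 0.96) where only the anchor
  carries an effect (a gain, Δ = −2.0);
* `rs005`/`rs006` — protective epistatic pair in the cohort model;
* the rest are nulls.

Haplotype LD is induced by a copy mixture: the partner copies the anchor's
allele with probability sqrt(r²_target), else draws independently, which
makes the expected indicator correlation sqrt(r²_target) and hence the
expected r² equal to the target (both members must share a minor-allele
frequency; the generator enforces this). This gives exact control of
pairwise r² with no external simulator, at the cost of population-genetic
realism: no recombination maps, no demography, no allele-frequency spectrum.
Realized r² at 2000 haplotypes is within ±0.05 of target.

The cohort model draws dosages Binomial(2, maf) and case status from a
logistic model with main-effect and interaction odds ratios. The default
scenario plants a protective interaction (OR_int = 0.5, main ORs 0.75/0.8,
MAF 0.3 at both loci, baseline case rate 0.35, n = 2000). MAF and baseline
were fixed once by a design-stage power computation — at these values the
interaction test has ~95% power for p < 1e-4 at |ln OR_int| = ln 2 and
n = 2000 — and reflect a typical memory-clinic cohort composition; they are
study conditions, not tuning knobs.

## The epistasis test

Within cases and controls separately, the pair's 2 × 2 allele table is
formed from dosage cross-products — each sample contributes the expected
allele pairings (g_a g_b, g_a(2−g_b), …)/2 — and the statistic is the
difference of the two log odds ratios over its standard error, two-sided
normal. The variance is where this implementation departs from the textbook
allele-counting formula Σ 1/N: on unphased genotypes the expected-count
table is a *smoothed* functional of n individuals, not a multinomial sample
of 2n gametes, and Σ 1/N overstates the variance so badly that the measured
type-I error was 0/400 at α = 0.05. The delta method over the empirical
per-sample contribution vectors gives the correct asymptotic variance and
restores nominal size (measured 0.035–0.05 across seeds at n = 5000); a
calibrated test is a prerequisite for the power claim to mean anything. A
logistic-regression interaction test (Wald z on the dosage product) ships as
a labelled alternative; zero cells receive the Haldane–Anscombe 0.5
correction and are flagged. Carrier-group proportions use the 0/1
carrier dichotomization (any minor allele vs none) with per-pair
complete-case handling, missing counts reported.

## Numerical and reporting decisions

* Probability clamp 1e-6; logits are finite everywhere.
* E-value ties count ≥ (conservative); add-one keeps e-values in (0, 1].
* Context-stability label: a flagged variant/feature is "context_stable"
  when its across-context range of Δ is below 25% of its median |Δ|. The
  25% fraction is this package's explicit operationalisation of a
  qualitative notion ("the effect does not depend on the context") and is
  configurable; it is reported alongside the raw range so users can apply
  their own rule.
* LD groups are anchor-centred threshold sets (r² ≥ 0.8 by default), not
  haplotype blocks; monomorphic variants are excluded with a warning rather
  than given r² = 0. "Divergence" is the max–min spread of member effects
  per feature, and members in r² ≥ 0.9 with the anchor that fail the effect
  threshold the anchor passes are flagged individually.
* Enumeration, windows and the annotator are deterministic; every sampling
  site takes an explicit seed which is recorded in the output metadata, and
  pipeline reruns are byte-identical.

## What the tests do and do not show

Against the planted truth the suite verifies: exact recovery of all planted
effects at the |Δ| ≥ 1, e ≤ 0.05 operating point with no false positives;
the minimum-achievable e-value 0.001 for the top planted effect against the
n = 999 null; the closed-form context margin to 1e-9; realized r² ≥ 0.95
with a partner effect of exactly 0; uniform null e-values (Kolmogorov–
Smirnov) with ~5% rejection at e ≤ 0.05; and the interaction test's size and
power. These are checks of the *machinery* under an annotator whose truth is
known by construction. They do not certify any pretrained deep model's
predictions, the biological reality of any specific variant, or behaviour
under model misspecification; with a real annotator the reversed-sequence
pass is a diagnostic, not an identity, and e-values inherit whatever biases
the background variant sample carries. Sample sizes here (60 kb genome,
n = 999 background, 2000 haplotypes, 2000-sample cohort) are the package's
deliberate desk-scale defaults; all of them scale up by configuration.
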