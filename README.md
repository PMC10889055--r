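# caism — context-aware in silico mutagenesis

GWAS hits arrive in clusters: a lead SNP sits inside a linkage-disequilibrium
(LD) block of tightly correlated neighbours that are conventionally pruned
away as redundant. At the level of *predicted regulatory function* that
convention is questionable — two variants with r² close to 1 can have
completely different effects on chromatin marks, and a variant's effect can
depend on which alleles its neighbours carry. `caism` is an analysis package
for interrogating exactly this, by in silico mutagenesis: substitute alleles
into fixed-length sequence windows, score each window with a
sequence → chromatin-feature annotator, and compare.

It is written for statistical geneticists and regulatory genomicists who
want a tested, deterministic desk-scale pipeline for the method itself. A
synthetic annotator with *planted, closed-form ground truth* stands in for a
pretrained deep chromatin model, so every stage is verifiable end to end.

## The statistics

For a candidate SNP, a window of L = 2000 bp is built around it (999 bp
upstream, 1000 bp downstream), with every SNP in the reference window set to
its major allele; the alternate window carries the center minor allele. An
annotator maps each window to per-feature probabilities. For each chromatin
feature with predicted probabilities P_ref and P_alt:

* **log-odds change**  Δ = logit(P_ref) − logit(P_alt) — the per-feature
  effect of the minor allele (Δ > 0: loss of function, Δ < 0: gain);
* **E statistic**  E = Δ · (P_ref − P_alt) ≥ 0 — the product of the
  relative and absolute change;
* **e-value** — the add-one empirical p-value (r + 1)/(n + 1) of E against
  a per-feature background null built from n randomly sampled variants
  scored the same way;
* **genetic context** — all 2^k major/minor combinations of the k
  neighbouring SNPs inside the window are enumerated; the ref/alt contrast
  is always the center allele, the context modifies the sequence background;
* **LD contrast** — r² from phased haplotypes groups variants
  (anchor-centred, r² ≥ 0.8) whose no-context effects are then compared;
* **epistasis validation** — candidate pairs are tested in case/control
  genotypes via the difference of allelic log odds ratios between cases and
  controls (delta-method variance), plus carrier-group case proportions.

Variant/feature records passing |Δ| ≥ 1 and e ≤ 0.05 are flagged, and each
flagged effect is labelled context-stable or context-dependent from its
across-context range.

## Worked example

The analysis is organised as numbered drivers over the package functions:

```sh
Rscript analysis/01_simulate.R      # synthetic genome, variants, haplotypes, cohort
Rscript analysis/02_effects.R      # context-aware scoring vs n = 999 background
Rscript analysis/03_ld_contrast.R  # effects across the high-LD pair
Rscript analysis/04_epistasis.R    # carrier proportions + interaction test
```

`02_effects.R` scores 10 candidates × 8 contexts × 10 features and prints:

```
Variant/feature pairs passing |log-odds change| >= 1 and e <= 0.05:
 variant_id            feature min_loc max_loc range             label
      rs001 DNase_glioblastoma     2.5     2.5     0    context_stable
      rs002  CTCF_glioblastoma     1.2     2.2     1 context_dependent
      rs003        H3K18ac_NPC    -2.0    -2.0     0    context_stable
      rs005          DNase_NHA     2.0     2.0     0    context_stable

All planted effects recovered, no false positives.
```

rs001 loses a DNase site with the same Δ = 2.5 in every context
(context-stable); rs002's CTCF loss deepens from 1.2 to 2.2 exactly when its
cooperative neighbour carries the minor allele (context-dependent — the
margin equals the planted cooperative logit weight, 1.0); rs003 is a gain of
function (Δ = −2). `03_ld_contrast.R` then shows the LD phenomenon made
literal:

```
Realized r2(rs003, rs004) = 0.9644 (target 0.96) over 2000 haplotypes
 variant_id     feature log_odds_change r2_to_anchor
      rs003 H3K18ac_NPC              -2    1.0000000
      rs004 H3K18ac_NPC               0    0.9643986
```

— a variant in near-perfect LD with the anchor carries none of its predicted
effect. `04_epistasis.R` validates the planted protective pair in the
simulated cohort (case proportion 0.377 in non-carriers falling to 0.116 in
double carriers; allele-based interaction Z = −3.61, p = 3.1e-4).

## Layout

* `R/` — package code: windows, context enumeration, annotator contract +
  synthetic annotator, effect statistics and background null, LD, epistasis,
  generators, orchestration.
* `analysis/` — the numbered narrative drivers shown above.
* `tests/testthat/` — unit, property and end-to-end acceptance tests.
* `vignettes/context-mutagenesis.Rmd` — the methods vignette: model,
  assumptions, parameter choices, numerical decisions, limitations.
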