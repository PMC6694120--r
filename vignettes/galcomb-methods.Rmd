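---
title: "Methods: from cytometry events to rewired GAL switches"
author: "galcomb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from cytometry events to rewired GAL switches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`galcomb` analyses combinatorially complete mutant libraries of the three
regulators of the yeast galactose switch — *GAL4* (activator), *GAL80*
(repressor) and *GAL3* (sensor) — measured by flow cytometry in a repressing
(glucose-saturated, "time 0") and an inducing (12 h galactose) condition.
The pipeline has five stages:

1. **simulate** — a seeded synthetic emulation of the study design
   (libraries of 46/39/43 alleles combined pairwise, ~5,400 double mutants,
   two conditions, two replicates, ~5,000 events per sample);
2. **preprocess** — gating, saturation correction, pseudo-log expression
   summaries, event-rate cell densities, Malthusian growth rates;
3. **classify** — HDBSCAN* clustering of paired expression distributions
   into phenotypic classes (Inducible, Constitutive, Uninducible, Leaky,
   Weak expression), with deterministic curation and a rescue step;
4. **predict** — double-mutant growth under a multiplicative null and under
   expression-class-mean models, with variance partitioning and downsampled
   cross-validation;
5. **sensors** — dependency of each GAL4–GAL80 background on the two
   galactose sensors (*GAL3* deletion; *GAL1* sensing removed by replacing
   it with a heterologous galactokinase, `GAL1::GALK`), with a logistic
   "leakiness" null for sensorless growth.

All tunables live in one nested configuration, `galcomb_config()`; each is
discussed below with its default and rationale.

# Cytometry preprocessing

**Gating.** Events are first restricted to the central 95% *per axis* of
FSC and SSC (2.5% trimmed from each tail of each axis). "A rectangle
including 95% of observations" is ambiguous between a joint and a marginal
reading; the marginal reading is deterministic and order-free, so it is
used. A density centroid is then located as the mode of a 64×64 2-D
histogram on standardized axes, and the 40% of rectangle-gated events
farthest from it are excluded (the midpoint of the 30–50% range used in
practice). Boundary ties are kept, so a degenerate all-identical cloud
survives intact. The two-stage gate keeps ≈ 0.95² × 0.60 ≈ 54% of events.
Note one limitation: a quantile-based rectangle is *not* idempotent — each
application trims a further 5% — so re-gating gated data is a user error
the package does not mask.

**Saturation.** Digital cytometers clip FITC-A at a ceiling (default
2¹⁸ − 1 A.U.). Because PE-A is spectrally correlated with FITC-A, an OLS
fit of `log(FITC) ~ log(PE)` over non-saturated events (per sample; ≥ 30
usable events required) predicts replacement values for clipped events
only. A degenerate fit (zero PE variance) flags the sample and leaves
values at the ceiling.

**Pseudo-log.** Dim cells yield negative raw A.U., so summaries use
`log10(raw + 1000) − 3`: raw 0 maps to 0, raw 99,000 to 2. The transform
is strictly increasing and exactly invertible on raw > −1000.

**Summaries.** Per sample: the fraction of cells above the ON cutoff; mean
pseudo-log and raw signal; and a 60-bin density histogram over pseudo-log
[−0.5, 3.5] (raw 0 to ≈ 3×10⁶ A.U.; the bin count is fixed by the method,
the range is a package choice recorded in the config). Out-of-range events
are counted in the edge bins so densities always integrate to one. The ON
cutoff is the 99.9th percentile of pooled autofluorescent-control signal
("empirically determined" is made concrete this way; fallback default
0.25 pseudo-log).

**Density and growth.** Cell density is the OLS slope of cumulative event
count against acquisition time (events/ms), scaled by the sampling rate
(µl/s) to cells/µl. The galactose culture is inoculated at 9/150 of the
glucose culture's density, so after 12 h
µ = ln(density_gal / (density_glu × 9/150)) / 12 per hour, and
generations = log2 of the same ratio. Gating removes the same fraction of
events in both conditions, so the gate factor cancels exactly in µ; on
synthetic data the estimated µ recovers the planted value with
|bias| < 10⁻⁴/h.

# Expression classification

**Features.** Per genotype, replicate-mean 60-bin densities in glucose and
galactose are concatenated (120 units), transformed by
`V = log10(round(v, 3) + 0.001)` to exaggerate low-density structure, and
z-scaled per column (constant columns are set to zero). R's `round()`
rounds half to even; the 0.0005 boundary is covered by a unit test.

**Clustering.** HDBSCAN* is implemented in the package (no density-based
clustering package ships with the supported environment): core distances as
the minPts-th nearest-neighbour distance, mutual-reachability
single-linkage hierarchy, condensation at minimum cluster size = minPts,
stability in λ = 1/distance, excess-of-mass selection. Labelings are
computed for minPts ∈ {5, 10, 15, 25} and scored by the variance of five
per-genotype phenotypes (fraction ON and mean signal in both conditions,
and µ; each z-scaled) explained by the saturated
`value ~ cluster × phenotype` model. Noise points enter as singleton
labels so the score is always defined; the fitted values of that model are
exactly the (cluster, phenotype) cell means, which is how the quantity is
computed (asserted equal to `lm()` in the tests). The chosen labeling
maximizes explained variance with a parsimony tie-break within 0.5
percentage points; parsimony counts *all* labels the model used — clusters
plus noise singletons — because singleton labels fit their cells exactly
and would otherwise let a labeling "win" by shedding points as noise.

**Curation.** Each cluster is mapped to the nearest of five reference
archetype profiles (deterministic large-sample simulations from the
nominal class parameters, standing in for the archetypal deletion-experiment
samples). Per-genotype overrides then use the induction ratio (raw mean
galactose / raw mean glucose signal): a Constitutive call with ratio ≥ 3
becomes Leaky (detectable but partial glucose ON fraction) or Inducible; an
Inducible call with ratio ≤ 1.5 becomes Uninducible; an Uninducible call
with > 40% of cells ON in galactose at an ON mode above pseudo-log 1.0
becomes Inducible. Only the 40% figure is printed in the source material;
the other thresholds are package defaults, all config-exposed.

**Rescue.** Unclustered genotypes are re-clustered together with anchor
exemplars — first the Weak-expression exemplars alone, then the three
archetypal classes — inheriting the majority anchor class of their cluster;
any residue is assigned to the nearest anchor. Every genotype therefore
ends with a class, and `provenance` records how it got one.

The broad three-class scheme coarsens Leaky to Inducible (a flavour of an
inducible switch) and Weak expression to Inducible (those alleles behave
WT-like apart from a low expression ceiling).

# Growth prediction

**Multiplicative null.** With all rates background-subtracted (background =
growth with no functional GAL regulator; recomputed as the mean µ of the
triple deletion when the 2³ design is present),
µ_MUT = µ_mut1 × µ_mut2 / µ_WT. Three standard-error modes are shipped
because the printed propagation formula cannot be reconciled with
first-order theory: `as_printed` reproduces it verbatim (including the
(N−1) factor and a repeated µ_mut1 denominator), `typo_fixed` reads the
last denominator as µ_mut2, and `delta` (default) is standard first-order
propagation, |µ_MUT|·sqrt((se_WT/µ_WT)² + (se₁/µ₁)² + (se₂/µ₂)²), which is
the mode validated against Monte-Carlo simulation (within 15%).

**Class-mean models.** Each double mutant is keyed by the expression
classes of its two single mutants; the model's parameters are the per-key
mean observed growth rates. Locus-aware keys are class triples over
(GAL3, GAL80, GAL4) with the unmutated locus carrying Inducible — 23 keys
under the five-class scheme and 14 under the three-class scheme in the
pairwise design (32 − 9 and 18 − 4 after removing the never-constructed
triple-mutant classes with Uninducible GAL3 and two non-Inducible
partners). Locus-blinded keys are unordered class pairs — 6 (three-class)
and 13 (five-class). Predictions for unseen keys fall back to the training
grand mean and are flagged. Variance explained is 1 − SSR/SST about the
grand mean of within-genotype mean growth rates, overall and per locus
pair. Downsampled cross-validation refits the model on the doubles of k
randomly chosen alleles per (locus, class) group and scores the held-out
remainder (default 1000 iterations; tests use 200, a stated scale-down).

# Sensor dependency

Per GAL4–GAL80 pair, replicate growth rates in the ∆GAL3 and GAL1::GALK
arms are compared with the intact arm by Welch two-sample t-tests
(the unequal-variance form is chosen where only "t-test" is stated),
BH-adjusted within one family per contrast type; significance additionally
requires |effect| ≥ 0.03 µ/h. For backgrounds with both sensors removed,
growth from an uninduced state is modelled by a three-parameter logistic of
µ on mean glucose expression (pseudo-log), fitted per GALK ortholog with
`SSlogis` self-start and grid-initialized restarts; pairs above that null
are detected by one-tailed one-sample t-tests, BH-adjusted. Verdicts:
*essential* (significant loss and the arm falls below background +
0.02/h while the intact arm grows), *contributing* (significant loss,
still growing), *deleterious* (significant gain, or the arm reverts a
Constitutive class to Inducible/Leaky — sensing was driving glucose
expression), *dispensable* (no significant change), *indeterminate*
(missing arm). A pair is *harmonious* when both singles are non-Inducible
(broad scheme), the double is Inducible or Leaky, and its galactose growth
reaches 75% of the WT rate. The growth floor and the 75% fraction encode
what the source figures show visually; both are config values.

# The synthetic world

The generator's defaults are the stated experimental design: 46/39/43
alleles, 2% dropout of pairwise constructions ("98% of possible pairs"),
N = 2 replicates (the median replication), 5,000 events/sample, a 2¹⁸ − 1
A.U. ceiling, and the 9/150 galactose inoculum dilution. Choices the study
does not state, made once:

* **Component shapes.** OFF events are normal on the raw scale (mean 50,
  SD 200 A.U., clipped at −999 as instruments do), putting the OFF mode at
  pseudo-log ≈ 0; ON events are normal on the pseudo-log scale around a
  class-specific location (2.0 for full induction ≈ raw 10⁵, 1.2 for leaky
  glucose expression, 1.0 for weak expression; SD 0.2–0.25). PE-A follows
  `log(FITC) = 1.1·log(PE) + 0.2` plus noise, so saturation correction has
  a planted relation to recover. ~5% of fully-ON events exceed the ceiling.
* **Per-class allele counts** (not reported per locus): GAL3 26 I / 20 U;
  GAL80 12 I / 9 C / 10 U / 8 L; GAL4 18 I / 10 C / 12 U / 3 W — the three
  weak-expression GAL4 alleles match the narrative.
* **Growth model.** µ_true = 0.05 + 0.30·fracON_gal + 0.02·fracON_glu +
  N(0, 0.01), truncated at zero: WT ≈ 0.35/h, regulator-free background ≈
  0.05/h, a constitutive head start worth ≈ 0.02/h. These reproduce the
  qualitative fraction-ON → growth relationship.
* **Planted epistasis.** Double-mutant classes follow the stereotyped
  rules the study reports (e.g. Uninducible GAL3 × Leaky GAL80 → Leaky in
  96% of pairings; Constitutive GAL80 × Uninducible GAL4 → Uninducible);
  the one empirically diverse pairing, Uninducible GAL80 × Constitutive
  GAL4, draws from {C 56%, U 20%, I 12%, L 6%, W 6%} under a seeded
  substream. These rules are the *planted truth* that round-trip tests
  recover; they are not claims about new biology.
* **Sensor panel.** Six pair archetypes (WT-like, leaky repressor,
  constitutive activator, flipped, constitutive, dead) with four arms each;
  the sensorless arm grows according to the logistic leakiness null
  (Asym 0.30, xmid 1.5, scal 0.30, noise SD 0.01).

Every randomized operation draws from a named substream of one master seed
(FNV-1a hashed), so adding genotypes never perturbs others and identical
seeds give byte-identical outputs.

**What a green test does and does not establish.** The generator plants
exactly the structure the analysis assumes: log-normal-ish mixtures, class
determinism up to two stochastic pairings, growth linear in fraction ON.
Green round-trip tests therefore establish that the pipeline recovers
planted structure at realistic noise — not that real libraries obey these
forms. Real data add instrument drift, doublets, day effects and
transformation artifacts that are out of scope here (no spectral
compensation, no doublet discrimination beyond the two-stage gate).

# Numerical choices and degenerate inputs

* Distances for HDBSCAN* reuse one precomputed matrix across the minPts
  grid; λ uses a denormal-guarded reciprocal, and an all-identical input is
  special-cased to a single cluster.
* The deletion-experiment clustering fixture uses N = 4 replicates (the
  deletion experiment's replication) and 10,000 events/sample: at N = 2 ×
  5,000 events, single stray events in near-empty bins survive the
  V-transform's rounding and become genuine HDBSCAN noise points — the same
  effect that makes a rescue step necessary at all.
* Zero gated events, zero-variance t-test inputs, empty class-combination
  keys, non-positive densities and non-converged logistic fits all flag or
  fall back explicitly rather than erroring mid-pipeline.
* Tests and the acceptance script scale simulations down where the science
  allows (smaller libraries, 200 CV iterations); the full-scale run
  (≈ 21,800 samples) executes once in the acceptance suite and completes in
  ≈ 6–7 minutes on one CPU.

# Known limitations

* The narrow (nine-category) labeling is exposed only as raw cluster
  labels; no curated naming is attempted for it.
* The goodness-of-fit construction behind the study's enrichment p-value
  for the most diverse pairing is unspecified and is not reproduced.
* "Manual curation" is replaced by deterministic archetype mapping plus
  override rules; provenance fields keep every such decision auditable,
  but borderline real-data profiles may be curated differently than a
  human would.
* The multiplicative null scores far below the class-mean models on the
  synthetic world (as it does, less extremely, on the real data), because
  the planted epistasis is class-driven by construction.
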