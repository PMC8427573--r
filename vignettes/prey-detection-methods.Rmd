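---
title: "Diagnostic marker design and k-of-n prey detection: methods and design notes"
author: "preydetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic marker design and k-of-n prey detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preydetect)
```

`preydetect` implements the computational pipeline behind multi-marker
molecular diet analysis: designing species-diagnostic cytochrome *b*
assays, quantifying their specificity on endpoint-PCR intensity plates,
and calling prey species in predator scats. This vignette explains the
models and procedures, the parameters that matter, what the synthetic
data generator does and does not emulate, and the design decisions taken
where the problem admitted several reasonable answers.

## 1. The screening model for diagnostic loci

The inputs are pre-aligned cyt *b* sequences grouped by species (the
package does not run multiple sequence alignment; that step is commodity
and any aligner's FASTA output is accepted). One species is the *target*;
every other species in the set — other prey, the predator, close domestic
relatives — is *background*.

A column is emitted as a diagnostic locus when two conditions hold:

* **Conspecific fixation.** Every target sequence carries the same plain
  `A`/`C`/`G`/`T` at the column. A gap or IUPAC ambiguity code anywhere in
  the target disqualifies the column outright: an ambiguous target base
  could mask intraspecific variation, and the entire point of the locus is
  that it never varies within the target species.
* **Diagnosticity.** The fraction of background *species* whose alleles
  exclude the target base must reach `min_diagnosticity` (default 1). A
  background species counts as sharing the base when *any* of its
  sequences can carry it, and background ambiguity codes expand to every
  base they denote. Both choices are deliberately conservative: they can
  only lower diagnosticity, never inflate it, so a fully diagnostic call
  is robust to what the background sample happened to contain.

Diagnosticity is a per-species (not per-sequence) fraction because
specificity failures happen at the species level: one matching individual
in a background species is enough for that species to amplify.

The default `min_diagnosticity = 1` demands full diagnosticity; the
parameter exists because screening real faunas occasionally forces
tolerating a background species that shares the base (the classic case is
a pair of wild ungulates sharing a 3′ nucleotide), and a cutoff of, say,
0.9 makes that tolerance explicit rather than ad hoc.

Coordinates are 1-based alignment columns; each locus also carries its
ungapped position in the first target sequence, which is what a primer
order form needs.

## 2. Primer windows and the 3′ preference

`score_assay_windows()` models the two locus-specific primers as windows
of `window_length` columns (default 15, a typical annealing-region
length) that **end** at the locus (forward primer) or **start** at it
(reverse primer). Under this placement the diagnostic base is the
terminal, amplicon-facing base of each primer — its 3′ end on the
respective strand — which is where a mismatch blocks extension and buys
the most specificity. Windows are scored for:

* **conservation**: fraction of window columns fixed on a single
  unambiguous base within the target (primers must anneal in all
  conspecifics);
* **differentiation**: mean per-column fraction of background species
  excluding the target's consensus base (mismatches against non-targets
  further suppress nonspecific amplification).

`three_prime_diagnostic` is true when the locus is fully diagnostic *and*
at least one window fits inside the alignment untruncated. A locus too
close to the alignment edge gets truncated windows with flags rather than
an error, because edge loci can still be usable with a shorter primer.
Whether the historical screens placed their tolerated shared-3′ cases at
the locus column or within the windows is not decidable from the record;
tying the flag to the locus column is the stricter reading and the one
implemented.

`design_panel()` ranks candidates (fully diagnostic, then 3′-diagnostic,
then conservation, then differentiation, ties broken by lower position
for determinism), keeps one assay per locus, and reports — never pads —
species that fall short of `min_markers_per_species` (default 4). Four
markers per species is the floor because multiple markers insure against
low DNA quantity, unsampled intraspecific variation, and residual
non-diagnosticity. The numeric cut to a final panel happens later, in
`rank_and_select()`, once plate data exist: designing wide and selecting
on measured specificity mirrors how such panels are actually built.
A species indistinguishable from a background species (the wolf/dog
situation) simply yields zero candidates plus a shortfall entry.

## 3. Specificity statistics from intensity plates

Endpoint fluorescence is read on two dyes per marker (FAM and HEX,
intensities `I_F`, `I_H`) relative to the passive ROX dye.

**Frequency of overlap.** For a marker, the proportion of nonspecific
reference samples with intensity ≥ the minimum specific-sample intensity.
It is a detection-oriented statistic, so missing wells count as intensity
0 there (a missing nonspecific well cannot overlap; a missing specific
well drags the specific minimum to 0, flagging the marker loudly — which
is the right failure mode).

**Dye selection.** Overlap is computed on both dyes; the dye with lower
overlap is used for everything downstream. Both zero → seeded random
pick (the R RNG, so `set.seed()` before evaluation makes runs
reproducible); exactly one zero → that dye; both positive and equal →
FAM, an arbitrary but fixed tie-break.

**t-tests.** Specific vs. nonspecific intensities on the chosen dye are
compared with a two-sided Welch *t*-test (unequal variances). Welch
rather than pooled: group sizes are tiny and unbalanced (2–5 specific vs.
dozens of nonspecific tissues) and variances demonstrably differ between
amplifying and non-amplifying wells; it is also the R default a field
analyst would have used. With a single specific tissue the two-sample
test is undefined and a one-sample test of the nonspecific intensities
against the lone specific value is substituted (negative *t* = good
separation). Zero nonspecific variance makes that statistic infinite; it
is reported as ±Inf with p = 0 and a `zero_variance` flag rather than an
error, since constant-zero nonspecific wells are a real (and excellent)
outcome. Missing wells are excluded from t-tests — the test is about
measured intensities, unlike the overlap statistic.

**Multiple testing.** p-values are adjusted with Benjamini–Yekutieli,
which controls FDR under the arbitrary dependence structure a shared
plate induces. The adjustment family is *all markers evaluated in the
run*, never per species: the decision "keep this marker" is made once
across the whole panel.

**ROX outliers.** Wells with near-absent ROX make the ROX-relative dye
intensities meaningless. Each sample's ROX is summarized by its median
over wells and screened low-side only against median − `k_mad`·MAD
(default `k_mad = 3`, `stats::mad` with its usual consistency constant).
Median/MAD rather than mean/SD so one dead sample cannot mask another.
Excluded samples disappear from every statistic and every denominator.

**Nonspecific set.** For a marker, the nonspecific samples are all
reference tissues — whatever their nominal role — whose species differs
from the marker's target; every tissue on the plate is evidence about
every marker. Negative controls are never mixed into the nonspecific
set; they get their own QC check, because a contaminated water control
means something different from a cross-amplifying tissue.

**Final selection.** Within species, markers are ordered by overlap
(ascending) then separation `min(specific) − max(nonspecific)`
(descending), with a stable sort so exact ties preserve input order.

## 4. Baselines and the minimum-k calling rule

Per marker, the detection baseline is `max(floor, highest nonspecific
reference intensity in the run)` with `floor = 0.2`, the intensity level
that separates genuine amplification from background drift. Baselines
are computed per run and never pooled across plates — plate-to-plate
intensity shifts are the norm. A marker with no nonspecific reference in
the run falls back to the floor, flagged.

A marker amplifies iff its chosen-dye intensity is **strictly** above
baseline. Only "below baseline" is defined as non-amplifying by the
procedure being formalized; the boundary case is resolved toward
non-amplification, the specific direction, so equality never creates a
detection.

A species is present at threshold *k* when some combination of *k* of
its markers all amplify. That subset formulation is equivalent to
`n_amplifying ≥ k`; both are implemented (`detect_species(method =
"combinations")` enumerates subsets) and asserted equal in the tests,
because the equivalence is the correctness argument for the fast path.
Presence at *k* implies presence at *k* − 1 by construction; detection
percentages are therefore nonincreasing in *k*, which the test suite
checks on simulated cohorts. `k` defaults to 1..4; the trade-off is
sensitivity (low *k*) against protection from cross-amplification noise
(high *k*), and `benchmark_thresholds()` quantifies exactly that.

Summaries report, per *k*, the percentage of samples with ≥ 1 detected
species and the mean/range of species per detected sample, plus
per-species frequencies of occurrence over all analyzed samples (these
may sum past 100%: scats can contain several prey). Samples excluded by
the ROX screen are excluded from all denominators. Species detected via
mitochondrial markers are maternal lineages; hybrid individuals carry
one parent's mitochondria, so the two hare lineages, for example, are
always reported separately and never merged.

## 5. The synthetic-data generator

`simulation_config()` fixes the simulated study at realistic defaults:
18 target species plus 2 background species, 5 aligned sequences per
species over 1140 columns (the cyt *b* gene length), 6 planted
diagnostic sites per target, intraspecific substitution rate 0.002 per
column, 3 reference tissues per species, one water control, 4 markers
per species, and 80 field scats.

*Alignments* start from one shared ancestral sequence; each target gets
fixed species-specific substitutions planted at distinct columns, and
intraspecific variation is added only away from planted columns, so the
planted truth is exactly recoverable at mutation rate 0 — the
parameter-recovery oracle the tests use.

*Intensities* follow a truncated-at-zero normal model: mean 0.93 (SD
0.1) when the marker's target DNA is present in the well, mean 0.08 (SD
0.05) otherwise — the observed scale of specific and nonspecific
endpoint intensities on this chemistry. The two dyes share one latent
amplification level plus independent channel noise (SD 0.02), the
simplest model that makes dye choice non-trivial without inventing an
unmeasured dye bias. Three failure processes are injected i.i.d. per
well or sample: cross-amplification (a nonspecific well drawing a
specific-level intensity, probability 0.005), dropout (a specific well
zeroed, probability 0.02), and per-sample ROX collapse (ROX × 0.01,
probability 0.0125 ≈ 1 sample in 80). The cross-amplification and
dropout defaults were calibrated so that a simulated reference plate
reproduces the overlap statistics observed on real reference plates of
this size — a large majority of markers with zero frequency of overlap
and a mean overlap near 0.05, with specific tissues essentially always
amplifying; scat DNA degradation can be emulated by raising
`dropout_prob`. Scat content is 1 + Poisson(0.7) prey species drawn
uniformly among targets, matching the observed ~1.7 species per scat at
the most permissive threshold.

What the generator deliberately does **not** emulate: phylogenetic
structure among species (all interspecific differences are independent
plants), correlated cross-amplification within related species (real
cross-amplification follows sequence similarity; simulated events are
i.i.d., so simulated false positives are *easier* to suppress with the
k rule than real ones), PCR kinetics, and plate-position effects.
Passing tests on simulated data therefore demonstrate the pipeline's
logic and calibration, not field performance on degraded scats.

Determinism: every simulation function seeds the R generator from
`config$seed` (with small fixed offsets per stage), so a config implies
its outputs bit-for-bit.

## 6. Numerical choices and degenerate inputs

* Equality at the baseline → not amplifying (see above); equality at the
  specific minimum → counted as overlap (the statistic's "≥").
* `detect_rox_outliers(k_mad = Inf)` disables the screen cleanly; MAD 0
  (all-equal ROX) excludes nothing unless a sample lies strictly below
  the median.
* Zero-length alignments yield empty locus sets, not errors; empty
  species files, unequal sequence lengths and non-IUPAC residues are
  errors naming the offender.
* BY adjustment is `stats::p.adjust(method = "BY")`; the test suite pins
  it to hand-evaluated values so the procedure, not the library call, is
  the contract.
* Panel ranking ties fall back to alignment position; marker ranking
  uses a stable sort. All output tables are tab-separated with `.`
  decimals, locale-independent, and carry schema version, seed and input
  checksums in comment headers so reruns are byte-identical.

## 7. Problem sizes in the shipped checks

The test suite validates the screen against an exhaustive per-column
brute force on 100+ random alignments (≤ 4 species, ≤ 50 columns), the
k-of-n rule against subset enumeration for all counts 0..8 and k 1..8,
and the Monte-Carlo benchmark against the closed-form binomial tail
P(Bin(m, p_cross) ≥ k) on cohorts of 1,000 simulated scats — sizes
chosen to give the oracles full coverage while keeping a complete run in
well under a minute per property. `scripts/acceptance.R` runs the
default 18-species, 80-scat study plus a 5-replicate benchmark from one
seed.

## 8. Known limitations

* The design stage screens single columns; multi-SNP haplotype assays
  are out of scope.
* Primer thermodynamics (Tm, GC, dimers) are not evaluated — candidates
  still need a thermodynamic check before ordering.
* The one-sample t-test route cannot detect variance inflation in the
  lone specific tissue; a rerun with more tissue is the real fix.
* Baselines assume the run's nonspecific references bracket the run's
  cross-amplification behaviour; a marker whose nonspecific intensity is
  systematically higher in scat matrix than in tissue would need
  matrix-matched references.
* Quantification (biomass, relative read abundance) is explicitly not
  attempted: outputs are presence/absence per threshold k.
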