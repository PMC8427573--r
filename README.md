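# preydetect

Molecular diet analysis of carnivores from scat DNA. Predators such as
wolves leave faecal samples whose prey-DNA content can be read with panels
of species-specific PCR markers: short mitochondrial cytochrome *b* loci
where a target prey species carries a fixed nucleotide that other species
in the fauna (and the predator itself) do not. `preydetect` implements the
full computational side of that workflow for ecologists and wildlife
geneticists:

1. **Marker design** — screen multi-species cyt *b* alignments for
   diagnostic loci and score flanking primer windows;
2. **Specificity evaluation** — turn dual-dye (FAM/HEX) endpoint-PCR
   intensity plates with a passive ROX reference into per-marker
   specificity statistics;
3. **Species calling** — convert field-sample intensities into binary
   prey detections with per-marker baselines and a minimum-*k*
   amplifying-marker rule;
4. **Simulation** — generate alignments and plates with known ground
   truth, so the whole pipeline can be validated and benchmarked without
   any laboratory data.

## The method

**Diagnostic loci.** For a target species *t* and alignment column *j*,
the column is a candidate locus when all conspecific sequences share one
unambiguous base *a* (no gaps, no IUPAC ambiguity), and its
*diagnosticity* is

> d(j) = (number of background species whose observed alleles at *j*
> exclude *a*) / (number of background species),

where a background species counts as carrying *a* if **any** of its
sequences can carry it (ambiguity codes expand to every base they denote —
the worst case for specificity). `find_diagnostic_sites()` returns the
columns with d(j) ≥ `min_diagnosticity` (default 1, i.e. fully
diagnostic). Primer windows flanking the locus are scored for conservation
within the target and differentiation against the background, with a
preference for assays whose diagnostic base sits at the 3′ terminus of a
primer.

**Specificity.** Each marker is read on two dyes relative to ROX
(intensities I_F, I_H). For reference tissues, the *frequency of overlap*
per dye is the proportion of nonspecific samples with intensity ≥ the
minimum specific-sample intensity. The scoring dye is the one with the
lower overlap (random seeded pick when both are 0), specific vs.
nonspecific intensities are compared with a two-sided Welch *t*-test (a
one-sample test when only one specific tissue exists), and p-values are
adjusted once across all markers with the Benjamini–Yekutieli procedure.
Samples with near-absent ROX (below median − 3·MAD) are excluded.

**Calling.** Each marker's baseline is max(0.2, highest nonspecific
reference intensity in the run); a marker amplifies in a sample iff its
chosen-dye intensity is strictly above baseline. A prey species is deemed
present at threshold *k* when at least one combination of *k* of its
markers amplifies — provably equivalent to counting `n_amplifying ≥ k`,
and both routes are implemented and cross-checked.

## Worked example

Simulate a small study — 4 target species, 2 background species, 40 scats
— then design, evaluate and call:

```r
library(preydetect)

cfg <- simulation_config(n_species = 6, n_targets = 4,
                         alignment_length = 400, n_scats = 40, seed = 7)

## design: screen the alignment for diagnostic loci
sim  <- simulate_alignments(cfg)
loci <- find_diagnostic_sites(sim$alignment, "target_01")
head(loci, 3)
#>   target_species position ungapped_position target_allele diagnosticity
#> 1      target_01        1                 1             A             1
#> 2      target_01       73                73             T             1
#> 3      target_01      126               126             T             1

## evaluate: specificity statistics from a reference/scat plate
panel <- synthetic_panel(cfg)
plate <- simulate_plate(panel, simulate_scat_truth(cfg), cfg)
set.seed(7)
ev  <- evaluate_markers(plate, panel)
sel <- rank_and_select(ev, min_markers_per_species = 4)
head(as.data.frame(sel)[c("marker_id", "chosen_dye", "freq_overlap",
                          "separation", "p_adjusted")], 4)
#>       marker_id chosen_dye freq_overlap separation  p_adjusted
#> 1 target_01_mk3        FAM    0.0000000  0.7863548 0.018026036
#> 2 target_01_mk1        HEX    0.0000000  0.7121392 0.002522393
#> 3 target_01_mk4        FAM    0.0000000  0.6727494 0.017868969
#> 4 target_01_mk2        FAM    0.9333333 -0.1550031 0.759858072

## call: baselines, k-of-n detection, summary
bl    <- compute_baselines(plate, sel)
calls <- call_species(plate, bl, k = 1:4)
summarize_detections(calls)
#> Detection summary over 38 sample(s) (2 ROX outlier(s) excluded)
#>   k >= 1: 38 sample(s) (100%) with >= 1 species; mean 1.7 species/sample (range 1-3)
#>   k >= 2: 38 sample(s) (100%) with >= 1 species; mean 1.5 species/sample (range 1-3)
#>   k >= 3: 38 sample(s) (100%) with >= 1 species; mean 1.5 species/sample (range 1-3)
#>   k >= 4: 37 sample(s) (97%) with >= 1 species; mean 1.4 species/sample (range 1-3)

verify_negative_controls(plate, bl)
#> Negative-control QC: PASS (no amplification)
```

Reading the output: `freq_overlap` 0 with a large positive `separation`
means clean discrimination between specific and nonspecific tissues;
marker `target_01_mk2` drew a simulated cross-amplification in a reference
well (overlap 0.93, negative separation) and ranks last for its species.
Detection percentages fall as the required number of amplifying markers
*k* rises — the sensitivity/specificity trade-off the threshold controls.
Two samples were dropped by the ROX screen before any denominator was
formed.

A command-line interface wraps the same functions
(`inst/cli/preydetect`): subcommands `simulate`, `design`, `evaluate`,
`select`, `call`, `benchmark`.

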