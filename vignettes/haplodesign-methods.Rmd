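---
title: "Models and methods behind haplodesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind haplodesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplodesign)
```

## The inference problem

A *MiMe* (mitosis-instead-of-meiosis) hybrid produces clonal gametes:
unreduced gametes carrying the parent's full diploid genotype with no
recombination and no segregation. Crossing two such hybrids yields a
tetraploid whose four chromosome sets are the four grandparental haplotypes,
intact. Sequencing-based validation of such a plant must answer four
questions, and each has a clean expectation under the clonal model:

* **Did recombination occur?** At markers that distinguish the two
  haplotypes of one parent, a clonal offspring is heterozygous everywhere:
  the B-allele frequency (AF) holds a genome-wide 0.5 plateau, exactly like
  the F1 hybrid itself. A meiotic (F2-like) offspring shows segments at AF
  0 and 1 with transitions at crossover positions.
* **Are all four genomes present?** Each haplotype's unique markers should
  be recovered at ~100% in a true 4-haplotype plant and at ~0% in a control
  that does not carry the haplotype.
* **Is the karyotype intact?** Loss of one chromosome copy (whole or
  partial) in a balanced tetraploid moves local coverage to 3/4 and local
  AF from 1/2 to 1/3 or 2/3, depending on which haplotype was lost.
* **What gene dosage was transmitted?** Under clonal transmission every
  grandparental haplotype contributes exactly one copy, so locus dosage is
  the carrier count over the four haplotypes, checkable as pooled read AF
  at the locus, which sits on the grid {0, 1/4, 1/2, 3/4, 1}.

The package implements each answer as a tested operation, and a forward
simulator of the whole crossing scheme supplies ground truth for all of
them.

## The forward simulator

`simulate_founders()` draws founder-private SNPs as a homogeneous point
process along each chromosome. All coordinates are relative to the
*reference founder*'s genome: a site private to a non-reference founder
carries its alt allele in that founder only, while a site private to the
reference founder (a variant of the reference assembly itself) surfaces as
an alt allele in *every other* genome aligned against it. This mirrors how
real call sets against a single reference behave, and it is what makes
reference-haplotype markers (diagnostic *ref* allele) possible.

Defaults are the study conditions the package is built around:

| parameter | default | meaning |
| --- | --- | --- |
| layout | 12 chromosomes, ~770 Mb | tomato-like nuclear genome |
| `snp_density` | 100 SNPs/Mb | founder-private marker density |
| introgression | chr9, 5–58 Mb, ×10 in the reference founder | a wild-relative introgression block with elevated divergence |
| `crossover_rate` | 1 per chromosome, obligate | meiotic model, `max(1, Poisson(1))` |
| `mean_depth` | 30× | sequencing depth at full copy number |
| `error_rate` | 0.01 | per-read allele miscall probability |
| `evidence_dropout` | 0.05 | per-site recall loss of one evidence replicate |
| `evidence_fp_per_mb` | 1 | false-positive calls per Mb per replicate |

Clonal gametes copy both parental haplotypes verbatim; meiotic gametes
return one recombinant chromatid per chromosome with uniformly placed
breakpoints. Offspring are unions of gamete chromatids; an optional
truncation deletes a terminal interval from one copy, recorded in the truth
record. Read counts at a site follow
`depth ~ Poisson(mean_depth × cn/ploidy)` and
`alt ~ Binomial(depth, p(1−e) + (1−p)e)` with `p` the local alt-copy
fraction — so copy-number changes move AF and coverage jointly, exactly the
signature the aneuploidy detector looks for.

**What the simulator does not model.** Crossover positions are uniform with
no interference and no centromere suppression; real recombination
landscapes are strongly structured, so breakpoint-accuracy results here
speak to the window machinery, not to landscape effects. There is no
sequence-level read simulation (no mapping bias, no GC effects), coverage
is observed at marker sites only (no BAM-level tracks), evidence noise is a
site-level thinning rather than technology-specific error profiles, and
founder SNPs are biallelic private SNPs only (no indels or structural
variants). Passing tests therefore demonstrate correctness of the set
algebra, windowing, segmentation and dosage arithmetic under a clean
generative model — not robustness to alignment artifacts.

One master seed drives everything; stage seeds are derived from it with a
deterministic string hash (`child_seed`), so identical configurations are
bit-reproducible while stages stay independently perturbable.

## Marker set algebra

Two design choices deserve note beyond the derivation rules themselves
(README):

* **Exclusion is position-level, not allele-level.** Any position seen in
  any blocking call set removes the candidate, regardless of allele — the
  conservative reading of "no ambiguous markers".
* **Sister-haplotype subtraction.** When deriving one hybrid haplotype's
  markers, the sister haplotype's assembly positions are subtracted
  explicitly: the two haplotype assemblies can call the same variant at
  shared positions, and such sites would otherwise be assigned to both
  lists. Positions claimed by more than one haplotype after all steps are
  dropped everywhere.
* **Evidence intersection.** `intersect_evidence()` (for two replicate
  call sets of the *same* genome) requires the same position, the same alt
  allele and the same genotype class; conflicting classes are dropped and
  counted. Matching assembly calls to *heterozygous* read calls of a hybrid
  is a different operation — there the genotype classes necessarily differ,
  so the match is by position and allele only.
* The chromosome-9 introgression mask is applied to all four lists by
  default (`exclude_haplotypes` overrides per haplotype); the region is
  divergent in more than one cultivar, so a global mask is the safe
  default.

`verify_marker_uniqueness()` is deliberately independent of the derivation:
it recounts carriers of each diagnostic allele directly from the simulator's
carrier matrix.

## Windowed profiles

Windows of width `W = 1` Mb advance by `s = 50` kb; a chromosome shorter
than `W` gets one whole-chromosome window, and for longer chromosomes the
count is `floor((L − W)/s) + 1` (the trailing partial window is dropped).
The window mean is the *unweighted* mean of site AFs (a depth-weighted mode
exists behind `build_profile`'s site frequencies if needed); windows with
fewer than `min_markers = 10` informative sites are *missing*, never zero —
a zero would masquerade as a homozygous-reference state in marker deserts.
Coverage is the mean marker-site depth per window divided by the
genome-wide median of window means, so the genome-wide median is 1 by
construction. Degenerate inputs (all-zero depth) are an error rather than a
division by zero.

## Offspring classification

The study this package formalizes judged AF plateaus visually; the
contribution of the classification module is to make that judgement
explicit and configurable. Defaults, calibrated on the simulator at 30×
depth:

| threshold | default | role |
| --- | --- | --- |
| `t_het`, `t_low` | 0.15 | diploid heterozygous/homozygous AF bands |
| `t_dose` | 0.08 | half-width around tetraploid dosage grid points |
| `t_af` | 0.10 | minimum AF deviation for aneuploidy |
| `t_cov` | 0.15 | minimum coverage deviation for aneuploidy |
| `min_run` | 5 windows | minimum run for segments and aneuploidy events |
| `f_tol` | 0.02 | tolerated off-balance fraction for a clonal call |

Segmentation collapses window states by run length: runs shorter than
`min_run` are absorbed into the larger neighbour, ambiguous windows never
break a run. Crossovers are reported as an interval (last confident window
of the left segment to first confident window of the right) plus its
midpoint — with symmetric bands the windows straddling a true breakpoint go
ambiguous on both sides, making the midpoint unbiased up to window
granularity. Positions are *approximations* by construction; uncertainty is
a property of the window geometry and is reported, not hidden.

Aneuploidy uses the AND rule — both AF and coverage must deviate — so
allelic bias alone (e.g. mapping artifacts at one locus) cannot create an
event; an OR mode exists for sensitivity analysis only. Two robustness
details matter numerically: gaps shorter than `min_run` between qualifying
windows are closed before run formation (one noisy window must not split an
event), and after boundary refinement overlapping same-direction segments
merge (near-threshold fragmentation of one event would otherwise inflate
counts, which would also break the expectation that raising thresholds can
only remove events). Boundaries are refined to the centre of the first/last
window whose AF deviation exceeds half the plateau deviation: across a true
copy-number breakpoint, the windowed deviation ramps linearly and crosses
half-plateau in the window centred on the breakpoint, so the estimate is
accurate to about one window step; runs touching a chromosome end are
clamped to it. A 2/3-AF plateau is an off-grid state for a euploid
tetraploid, so windows inside detected aneuploidy segments are masked
before state segmentation — a dosage anomaly must not be misread as a
crossover.

`classify_sample()` then labels a sample clonal (no crossovers, ≥
`1 − f_tol` of classified windows balanced), recombinant (≥ 1 crossover) or
anomalous, with `+anomalous` appended when aneuploidy co-occurs — clonal
offspring with a chromosome truncation are a real and expected category.

## Presence scoring and dosage

A marker is "found" when at least `min_supporting_reads = 1` reads carry
its diagnostic allele **and** the diagnostic fraction is at least
`min_supporting_frac = 0.05`. The fraction guard is the package's answer to
an underspecified point: with 30× depth and a 1% miscall rate, a pure
1-read rule would mark `1 − 0.99^30 ≈ 26%` of an *absent* haplotype's
markers as present — visibly filled control circles where near-empty ones
are expected — while a carried haplotype (diagnostic fraction ≥ 0.25 in a
tetraploid) loses almost nothing: the probability of fewer than
`0.05 × depth` diagnostic reads at 30× is about 0.2%. Markers without
coverage are excluded from the denominator and reported (a strict mode
would count them absent); the four-haplotype decision applies a presence
floor of 90%, far below carried-haplotype recovery (~99.7%) and far above
absent-haplotype leakage (<1%), both measured in the test suite.

Expected dosage is the carrier sum over the four design haplotypes —
clonal transmission contributes each haplotype exactly once — and is
invariant to their order. Observed dosage pools diagnostic reads over the
locus's covered markers; `af × ploidy` snaps to the nearest integer with
exact halves rounded *down*, conservative against overcalling resistance
copies. With ≥ 10 pooled markers at 30×, exact recovery exceeds 99% for
every true dosage 0–4, and accuracy is monotone in depth (tested).

## Problem sizes and determinism

The unit suites run on 2–4 chromosome layouts of 2–20 Mb, where every
operation's truth is enumerable; the end-to-end checks use the full default
layout with 6–12 samples per design, 100 random panels for the uniqueness
oracle, and 200–500 replicates for distributional properties — sizes chosen
so the whole suite completes in a few minutes while keeping binomial
standard errors well inside the asserted tolerances. All randomness flows
from fixed seeds; shuffling input row order changes no profile, and
re-running any stage with the same configuration is bit-identical.

## Known limitations

* The uniform, interference-free crossover model is a stand-in; no claim is
  made about the real recombination landscape.
* Coverage is computed at marker sites, not from alignments; GC and
  mappability structure are invisible here.
* Segmentation is run-length based by design (transparent, few knobs); an
  HMM or changepoint model would be the natural extension for noisier data.
* Allele-specific copy number beyond the balanced 2+2 design is out of
  scope: when markers cannot distinguish which grandparental copy was lost,
  the lost haplotype is reported missing rather than guessed.
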