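# haplodesign

Validation toolkit for **polyploid genome design** crosses — breeding schemes
in which hybrid plants carrying a mitosis-instead-of-meiosis (*MiMe*) mutant
background produce **clonal gametes**: unreduced, nonrecombined gametes
genetically identical to the parent. Crossing two such hybrids yields
tetraploid "4-haplotype" plants that carry the complete, intact genomes of
their four inbred grandparents. `haplodesign` implements the sequencing-based
computational validation of such designs, developed around the tomato model
system (a Moneyberg-TMV × Micro-Tom model hybrid crossed to commercial
hybrids), and ships a forward simulator of the entire crossing scheme so that
every inference step can be tested against known truth.

## What the package computes

Let a marker site carry reads supporting the reference-founder allele
(`ref_count`) and the alternate-founder allele (`alt_count`). The pipeline is
built on the per-site B-allele frequency

```
AF = alt_count / (ref_count + alt_count)
```

oriented so 0 is the reference founder and 1 the alternate founder, averaged
in sliding windows (width *W* = 1 Mb, step *s* = 50 kb).

1. **Haplotype-unique marker derivation** (`derive_two_way_markers`,
   `derive_four_way_markers`): set algebra over variant call sets.
   Two-haplotype case: homozygous dual-evidence SNPs of the partner genome
   minus every position called in the reference genome's own alignment.
   Four-haplotype case adds the hybrid parent's haplotypes (assembly calls
   confirmed heterozygous in hybrid reads, minus all other genomes' and the
   sister haplotype's positions) and reference-haplotype markers (positions
   homozygous-alt in *every* other genome; the reference allele is
   diagnostic). A shared wild-introgression region (chromosome 9, 5–58 Mb)
   is masked. `verify_marker_uniqueness` is a brute-force oracle against
   simulator truth.
2. **Windowed profiles** (`window_af`, `window_coverage`,
   `window_snp_density`, `build_profile`): mean window AF, normalized
   coverage (genome-wide median = 1), and SNP density (flags introgressions).
3. **Offspring inference** (`classify_sample`): window states (diploid bands
   or the tetraploid dosage grid {0, ¼, ½, ¾, 1}), run-based segmentation,
   crossover calls at segment junctions (interval + midpoint), and
   aneuploidy segments where **both** |AF − ½| ≥ 0.10 **and**
   |coverage − 1| ≥ 0.15 over ≥ 5 windows. A one-copy loss in a balanced
   tetraploid is expected at coverage ¾ and AF ⅓ or ⅔; the AF direction
   names the lost haplotype. Clonal offspring: zero crossovers and ≥ 98% of
   classified windows balanced.
4. **Presence & dosage** (`marker_presence`, `validate_four_hap`,
   `expected_dosage`, `estimate_dosage`): percentage of each haplotype's
   markers recovered in a sample; expected locus dosage under clonal
   transmission (carrier sum over the four haplotypes); observed dosage as
   the pooled diagnostic-allele frequency snapped to the nearest of
   {0, …, ploidy} copies.
5. **Forward simulator** (`simulate_founders`, `make_hybrid`,
   `simulate_gamete`, `simulate_offspring`, `simulate_reads`): founder
   panels with private SNPs and introgression blocks, clonal or meiotic
   (Poisson, obligate-crossover) gametes, tetraploid unions, optional
   terminal chromosome truncation, and Poisson/binomial read sampling —
   all with complete truth records.

## Worked example

```r
library(haplodesign)

cfg <- sim_config(layout = genome_layout(paste0("chr", 1:3), c(3e7, 2.5e7, 2e7)),
                  founder_ids = c("REF", "ALT"), introgression = NULL, seed = 7)
panel   <- simulate_founders(cfg)
markers <- sim_two_way_markers(panel)
hyb     <- make_hybrid(panel, "REF", "ALT")

mime <- make_clonal_tetraploid(hyb, hyb, cfg, seed = 1, sample_id = "MiMe_1")
pr   <- profile_offspring(mime, markers, seed = 2)
classify_sample(pr$profile, ploidy = 4)
#> sample MiMe_1: clonal (0 crossover(s), 0 aneuploid segment(s), 100.0% balanced windows)

f2  <- make_f2(hyb, cfg, seed = 3, sample_id = "F2_1")
pr2 <- profile_offspring(f2, markers, seed = 4)
cl2 <- classify_sample(pr2$profile, ploidy = 2)
cl2
#> sample F2_1: recombinant (7 crossover(s), 0 aneuploid segment(s), 23.7% balanced windows)
head(cl2$crossovers[, c("chrom", "midpoint")], 3)
#>   chrom midpoint
#> 1  chr1 14625000
#> 2  chr1 15125000
#> 3  chr2  5775000
true_breakpoints(f2)[1:2, ]
#>   chrom      pos
#> 1  chr1 15021566
#> 2  chr2  5785069
```

The clonal tetraploid keeps the genome-wide 0.5 AF plateau with no crossover
calls, while the recombinant F2 resolves into homozygous and heterozygous
segments whose junction midpoints sit within half a window of the true
breakpoints recorded by the simulator.

## Analysis workflow

The `analysis/` directory holds the numbered study drivers, each a thin
script over the package that writes its tables under `results/`:

| script | output |
| --- | --- |
| `01_simulate_crosses.R` | study configs, layout, founder VCFs, cohort + truth |
| `02_derive_markers.R` | two-/four-way marker tables, density, uniqueness audit |
| `03_window_profiles.R` | per-sample AF/coverage profiles, SNP-density track |
| `04_classify_offspring.R` | classifications, crossover/aneuploidy BED, truth comparison |
| `05_presence_dosage.R` | presence report, 4-haplotype validation, dosage calls |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate_crosses.R`.

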