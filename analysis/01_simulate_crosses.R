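#!/usr/bin/env Rscript
# Step 1 — forward-simulate the crossing scheme with full ground truth.
#
# Two studies are set up: a two-founder cross (reference genome x inbred
# partner, the model hybrid used for crossover and aneuploidy analysis) and
# a four-founder double-cross design (two hybrids contributing clonal
# gametes to a 4-haplotype tetraploid). Configuration, layout, founder call
# sets and the offspring cohort definition are written under
# results/simulation/.

source("analysis/_common.R")
out <- "results/simulation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg2 <- study_cfg2()
cfg4 <- study_cfg4()
write_sim_config(cfg2, file.path(out, "config_two_founder.yaml"))
write_sim_config(cfg4, file.path(out, "config_four_founder.yaml"))
write_layout(cfg2$layout, file.path(out, "layout.tsv"))

panel2 <- get_panel2()
panel4 <- get_panel4()
message("two-founder panel: ", nrow(panel2$sites), " SNP sites")
message("four-founder panel: ", nrow(panel4$sites), " SNP sites")

# founder truth and evidence-replicate call sets (VCF) for the model cross
for (f in panel2$founder_ids) {
  write_vcf(founder_variants(panel2, f),
            file.path(out, paste0("founder_", f, "_truth.vcf")),
            sample_name = f, layout = panel2$layout)
  for (r in 1:2) {
    write_vcf(panel2$evidence[[f]][[r]],
              file.path(out, paste0("founder_", f, "_evidence", r, ".vcf")),
              sample_name = f, layout = panel2$layout)
  }
}

# introgression truth as BED
write_bed(panel_introgression_regions(panel2),
          file.path(out, "introgression_truth.bed"))

# cohort definition and per-sample simulation truth
cohort <- cohort_table()
utils::write.table(cohort, file.path(out, "cohort.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
truth <- lapply(seq_len(nrow(cohort)), function(i) {
  off <- make_cohort_sample(panel2, cohort[i, ])
  n_bp <- sum(lengths(off$truth$breakpoints$maternal)) +
    sum(lengths(off$truth$breakpoints$paternal))
  list(sample_id = off$sample_id, ploidy = off$ploidy,
       gamete_modes = off$truth$gamete_modes,
       n_true_breakpoints = n_bp,
       truncations = off$truncations,
       total_chromosome_copies = sum(copy_number_segments(off)$cn))
})
jsonlite::write_json(truth, file.path(out, "cohort_truth.json"),
                     auto_unbox = TRUE, digits = NA, dataframe = "rows")

tet <- make_cohort_sample(panel2, cohort[cohort$type == "mime", ][1, ])
message("clonal tetraploid chromosome copies: ",
        sum(copy_number_segments(tet)$cn), " (expected 48)")
message("wrote ", out)
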