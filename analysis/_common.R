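# Shared study definition for the analysis scripts (01..05).
# Every script can be run standalone; heavyweight objects are cached under
# scratch/ so later scripts reuse earlier results.

suppressPackageStartupMessages(library(haplodesign))

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

STUDY_SEED <- 101

# the model two-way cross (reference founder x inbred partner)
study_cfg2 <- function() sim_config(founder_ids = c("fREF", "fB"),
                                    seed = STUDY_SEED)
# the four-founder double-cross design
study_cfg4 <- function() sim_config(founder_ids = c("fREF", "fB", "fC", "fD"),
                                    seed = STUDY_SEED + 100)

cached <- function(name, expr) {
  path <- file.path("scratch", paste0("cache_", name, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  val <- expr
  saveRDS(val, path)
  val
}

get_panel2 <- function() cached("panel2", simulate_founders(study_cfg2()))
get_panel4 <- function() cached("panel4", simulate_founders(study_cfg4()))
get_markers2 <- function() cached("markers2", sim_two_way_markers(get_panel2()))
get_markers4 <- function() cached("markers4", sim_four_way_markers(get_panel4()))

# the offspring cohort: controls and MiMe-derived samples of the two-way
# study, plus one truncated sample carrying a terminal chromosome-9 loss
cohort_table <- function() {
  data.frame(
    sample_id = c(paste0("F1_", 1:2), paste0("MiMe_", 1:6),
                  paste0("F2_", 1:6), "MiMe_trunc"),
    type = c(rep("f1", 2), rep("mime", 6), rep("f2", 6), "mime_trunc"),
    seed = STUDY_SEED + c(1:2, 11:16, 21:26, 31),
    stringsAsFactors = FALSE)
}

make_cohort_sample <- function(panel, row) {
  hyb <- make_hybrid(panel, "fREF", "fB")
  cfg <- panel$config
  if (row$type == "f1") {
    make_f1(hyb, cfg, seed = row$seed, sample_id = row$sample_id)
  } else if (row$type == "f2") {
    make_f2(hyb, cfg, seed = row$seed, sample_id = row$sample_id)
  } else if (row$type == "mime") {
    make_clonal_tetraploid(hyb, hyb, cfg, seed = row$seed,
                           sample_id = row$sample_id)
  } else {
    L9 <- chrom_length_of(panel, "chr9")
    tr <- data.frame(copy = 1, chrom = "chr9", start = L9 - 1e7, end = L9)
    make_clonal_tetraploid(hyb, hyb, cfg, seed = row$seed,
                           sample_id = row$sample_id, truncation = tr)
  }
}

chrom_length_of <- function(panel, chrom) {
  panel$layout$length_bp[panel$layout$chrom == chrom]
}
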