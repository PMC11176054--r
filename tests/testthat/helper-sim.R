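# Small layouts and configs used across the suite; fixtures are always
# generated in code.

small_layout <- function(n = 2, len = 5e6) {
  genome_layout(paste0("c", seq_len(n)), rep(len, n))
}

two_founder_config <- function(seed = 1, layout = small_layout(), ...) {
  sim_config(layout = layout, founder_ids = c("R", "B"),
             introgression = NULL, seed = seed, ...)
}

four_founder_config <- function(seed = 1, layout = small_layout(3, 8e6), ...) {
  sim_config(layout = layout, founder_ids = c("R", "B", "C", "D"),
             introgression = NULL, seed = seed, ...)
}

# toy variant set builder: positions on one chromosome, all hom_alt "A">"T"
toy_vs <- function(pos, chrom = "c1", genotype = "hom_alt", alt = "T",
                   source = "toy") {
  variant_set(rep(chrom, length(pos)), pos, "A", alt, genotype,
              source = source)
}
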