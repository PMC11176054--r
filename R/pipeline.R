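#' Union of variant sets
#'
#' Position-level union; the first occurrence of a (chrom, pos) wins.
#' Used to pool evidence replicates into a conservative blocker set.
#'
#' @param ... [variant_set()]s.
#' @export
vs_union <- function(...) {
  all <- do.call(rbind, lapply(list(...), as.data.frame))
  validate_variant_set(all[!duplicated(paste(all$chrom, all$pos)), ,
                           drop = FALSE])
}

#' Two-way marker derivation over a simulated panel
#'
#' Runs the two-haplotype marker pipeline on a two-founder panel's emitted
#' evidence: the non-reference founder's two evidence replicates are
#' dual-evidence intersected, homozygous calls are kept, and every position
#' seen in the reference genome's own read alignment (both replicates,
#' pooled) is subtracted.
#'
#' @param panel A [simulate_founders()] panel (2+ founders; the second
#'   founder is the target by default).
#' @param target Target founder id (default: the first non-reference
#'   founder).
#' @param exclusion Optional [region_set()] applied to the result.
#' @return A [marker_set()] for the target haplotype (alt diagnostic).
#' @export
sim_two_way_markers <- function(panel, target = NULL, exclusion = NULL) {
  if (is.null(target)) {
    target <- setdiff(panel$founder_ids, panel$reference)[1]
  }
  dual <- intersect_evidence(panel$evidence[[target]][[1]],
                             panel$evidence[[target]][[2]])
  ref_snps <- vs_union(panel$evidence[[panel$reference]][[1]],
                       panel$evidence[[panel$reference]][[2]])
  ms <- derive_two_way_markers(dual, ref_snps, haplotype = target,
                               layout = panel$layout)
  if (!is.null(exclusion)) ms <- apply_exclusion(ms, exclusion)
  ms
}

#' Four-way marker derivation over a simulated panel
#'
#' Assembles the inputs of [derive_four_way_markers()] from a four-founder
#' panel: per-haplotype assembly SNP sets are the founders' true variant
#' sets (a haplotype-resolved assembly aligned to the reference), read-based
#' calls of the inbred and of the hybrid parent are dual-evidence
#' intersections of two noisy observations, and the reference genome's own
#' pooled call set is the global blocker.
#'
#' @param panel A four-founder [simulate_founders()] panel.
#' @param inbred_id The non-reference inbred founder (default second
#'   founder).
#' @param hybrid_hap_ids The two founders forming the hybrid parent
#'   (default third and fourth).
#' @param exclusion Optional [region_set()] applied last (default: the
#'   panel's introgression blocks, the standard mask for a shared wild
#'   introgression).
#' @return A [marker_set()] over the four haplotypes.
#' @export
sim_four_way_markers <- function(panel,
                                 inbred_id = panel$founder_ids[2],
                                 hybrid_hap_ids = panel$founder_ids[3:4],
                                 exclusion = panel_introgression_regions(panel)) {
  cfg <- panel$config
  assembly <- stats::setNames(
    lapply(c(inbred_id, hybrid_hap_ids), function(h)
      founder_variants(panel, h)),
    c(inbred_id, hybrid_hap_ids))
  reads_inbred <- intersect_evidence(panel$evidence[[inbred_id]][[1]],
                                     panel$evidence[[inbred_id]][[2]])
  hyb_obs <- lapply(1:2, function(r) {
    observe_genome(panel, hybrid_hap_ids,
                   source = paste0("hybrid_rep", r),
                   seed = child_seed(cfg$seed, paste0("ev_hyb_", r)))
  })
  reads_hybrid <- intersect_evidence(hyb_obs[[1]], hyb_obs[[2]])
  reads_reference <- vs_union(panel$evidence[[panel$reference]][[1]],
                              panel$evidence[[panel$reference]][[2]])
  derive_four_way_markers(
    reference_id = panel$reference, inbred_id = inbred_id,
    hybrid_hap_ids = hybrid_hap_ids, assembly_snps = assembly,
    reads_inbred = reads_inbred, reads_hybrid = reads_hybrid,
    reads_reference = reads_reference, exclusion = exclusion,
    layout = panel$layout)
}

#' Introgression truth blocks of a panel as a region set
#'
#' @param panel A founder panel.
#' @return A [region_set()] (empty when the panel has no blocks).
#' @export
panel_introgression_regions <- function(panel) {
  b <- panel$introgression
  if (is.null(b) || !nrow(b)) return(region_set())
  region_set(b$chrom, b$start, b$end, layout = panel$layout)
}

#' Convenience constructors for study offspring
#'
#' `make_clonal_tetraploid` fuses one clonal gamete from each of two hybrids
#' (the double-cross design); `make_f2` fuses two meiotic gametes from the
#' same hybrid (a selfed-F1 recombinant control).
#'
#' @param hybrid1,hybrid2,hybrid [make_hybrid()] genomes.
#' @param config A [sim_config()].
#' @param seed Integer seed (stage seeds derived from it).
#' @param sample_id Sample label.
#' @param truncation Optional explicit truncation (see
#'   [simulate_offspring()]).
#' @return An `offspring_genome`.
#' @export
make_clonal_tetraploid <- function(hybrid1, hybrid2,
                                   config = hybrid1$panel$config, seed,
                                   sample_id = "tetraploid",
                                   truncation = NULL) {
  gm <- simulate_gamete(hybrid1, "clonal", config,
                        seed = child_seed(seed, "gm"))
  gp <- simulate_gamete(hybrid2, "clonal", config,
                        seed = child_seed(seed, "gp"))
  simulate_offspring(gm, gp, config, seed = child_seed(seed, "off"),
                     sample_id = sample_id, truncation = truncation)
}

#' @rdname make_clonal_tetraploid
#' @export
make_f1 <- function(hybrid, config = hybrid$panel$config, seed = 0L,
                    sample_id = "f1") {
  layout <- hybrid$panel$layout
  whole <- function(src) {
    stats::setNames(lapply(seq_len(nrow(layout)), function(i) {
      data.frame(start = 0, end = layout$length_bp[i], source = src,
                 stringsAsFactors = FALSE)
    }), layout$chrom)
  }
  empty_bp <- stats::setNames(lapply(layout$chrom, function(x) numeric()),
                              layout$chrom)
  haploid <- function(src) {
    # a gamete of an inbred founder: one non-recombinant chromatid per
    # chromosome (the parent is homozygous, so crossovers are invisible)
    structure(list(parent_id = src, parents = c(src, src), mode = "meiotic",
                   chromatids = list(whole(src)), breakpoints = empty_bp,
                   panel = hybrid$panel), class = "gamete")
  }
  simulate_offspring(haploid(hybrid$parents[1]), haploid(hybrid$parents[2]),
                     config, seed = child_seed(seed, "f1"),
                     sample_id = sample_id)
}

#' @rdname make_clonal_tetraploid
#' @export
make_f2 <- function(hybrid, config = hybrid$panel$config, seed,
                    sample_id = "f2") {
  gm <- simulate_gamete(hybrid, "meiotic", config,
                        seed = child_seed(seed, "gm"))
  gp <- simulate_gamete(hybrid, "meiotic", config,
                        seed = child_seed(seed, "gp"))
  simulate_offspring(gm, gp, config, seed = child_seed(seed, "off"),
                     sample_id = sample_id)
}

#' Sequence an offspring at marker sites and profile it
#'
#' Samples read counts at the marker positions and computes the joint
#' windowed AF/coverage profile.
#'
#' @param offspring An `offspring_genome`.
#' @param markers A [marker_set()].
#' @param seed Integer seed for read sampling.
#' @param mean_depth,error_rate Read model (defaults from the panel config).
#' @param W,s,min_markers,min_depth Windowing parameters (see
#'   [build_profile()]).
#' @return List: `counts` (the [count_table()]) and `profile` (the
#'   `window_profile`).
#' @export
profile_offspring <- function(offspring, markers, seed,
                              mean_depth = offspring$panel$config$mean_depth,
                              error_rate = offspring$panel$config$error_rate,
                              W = 1e6, s = 5e4, min_markers = 10,
                              min_depth = 1) {
  counts <- simulate_reads(offspring, markers, mean_depth = mean_depth,
                           error_rate = error_rate, seed = seed)
  prof <- build_profile(counts, offspring$layout, W = W, s = s,
                        min_markers = min_markers, min_depth = min_depth)
  list(counts = counts, profile = prof)
}

#' All true crossover breakpoints of an offspring
#'
#' @param offspring An `offspring_genome`.
#' @return data.frame `chrom`, `pos` — union of both gametes' breakpoints.
#' @export
true_breakpoints <- function(offspring) {
  out <- list()
  for (side in c("maternal", "paternal")) {
    bps <- offspring$truth$breakpoints[[side]]
    for (chr in names(bps)) {
      if (length(bps[[chr]])) {
        out[[length(out) + 1]] <- data.frame(chrom = chr, pos = bps[[chr]],
                                             stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), pos = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
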