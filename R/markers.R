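#' Intersect two evidence replicates of a variant call set
#'
#' Keeps records supported by both call sets — same (chrom, pos, alt) and the
#' same genotype class. Sites present in both but with conflicting genotype
#' classes are dropped (and counted in attribute `n_class_conflict`); sites
#' with a different alt allele at the same position do not match. This is the
#' dual-evidence step that removes technology-specific false calls before
#' marker derivation.
#'
#' @param a,b Two [variant_set()]s on the same coordinates.
#' @return A [variant_set()] (fields from `a`, source tags combined).
#' @export
intersect_evidence <- function(a, b) {
  ka <- paste(a$chrom, a$pos, a$alt)
  kb <- paste(b$chrom, b$pos, b$alt)
  i <- match(ka, kb)
  both <- !is.na(i)
  agree <- both & a$genotype_class == b$genotype_class[ifelse(both, i, 1)]
  out <- a[which(agree), , drop = FALSE]
  if (nrow(out)) {
    out$source <- paste(out$source, b$source[i[which(agree)]], sep = "+")
  }
  out <- validate_variant_set(as.data.frame(out))
  attr(out, "n_class_conflict") <- sum(both & !agree)
  out
}

#' Remove target records overlapping any blocker position
#'
#' Position-level (not allele-level) exclusion: a target record is removed if
#' its (chrom, pos) occurs in any blocker set, regardless of allele or
#' genotype — the conservative rule that leaves no ambiguous markers.
#'
#' @param target A [variant_set()].
#' @param blockers A list of [variant_set()]s (or a single one).
#' @return The filtered [variant_set()].
#' @export
subtract_overlaps <- function(target, blockers) {
  if (inherits(blockers, "variant_set")) blockers <- list(blockers)
  blocked <- unique(unlist(lapply(blockers, vs_key)))
  keep <- !vs_key(target) %in% blocked
  validate_variant_set(as.data.frame(target[keep, , drop = FALSE]))
}

#' Derive haplotype-unique markers for a two-haplotype cross
#'
#' For a cross between a reference genome and one other inbred genome:
#' markers of the non-reference genome are its homozygous dual-evidence SNPs
#' at positions showing no SNP in the reference genome's own read alignment;
#' the alt allele is diagnostic.
#'
#' @param target_dual_evidence [variant_set()] of the non-reference genome,
#'   already intersected across evidence sources ([intersect_evidence()]).
#' @param reference_genome_snps [variant_set()] of SNPs seen when the
#'   reference genome's own reads are aligned to its assembly (residual
#'   heterozygosity and caller artifacts).
#' @param haplotype Label for the marker list.
#' @param layout Optional [genome_layout()].
#' @return A [marker_set()] with one haplotype, diagnostic allele `alt`.
#' @export
derive_two_way_markers <- function(target_dual_evidence,
                                   reference_genome_snps,
                                   haplotype = "target", layout = NULL) {
  hom <- target_dual_evidence[
    target_dual_evidence$genotype_class == "hom_alt", , drop = FALSE]
  kept <- subtract_overlaps(validate_variant_set(as.data.frame(hom)),
                            reference_genome_snps)
  marker_set(rep(haplotype, nrow(kept)), kept$chrom, kept$pos,
             rep("alt", nrow(kept)), layout = layout)
}

#' Derive haplotype-unique markers for a four-haplotype design
#'
#' Implements the set algebra for a double-cross design whose four haplotypes
#' are: the reference inbred genome, a second inbred genome (the reference's
#' hybrid partner), and the two haplotypes of a second, hybrid parent:
#'
#' 1. **Hybrid-parent haplotypes** — assembly-vs-reference SNPs of that
#'    haplotype that match heterozygous SNPs in the hybrid's read calls,
#'    minus all SNP positions of the reference and inbred genomes, minus the
#'    sister haplotype's SNP positions.
#' 2. **Non-reference inbred** — its homozygous dual-evidence SNPs minus all
#'    other genomes' and haplotypes' SNP positions.
#' 3. **Reference haplotype** — positions homozygous-alt in *all*
#'    non-reference genomes (the inbred and the hybrid): only the reference
#'    carries the ref allele there, so the ref allele is diagnostic.
#'
#' Exclusion regions (e.g. a shared wild introgression) are applied last.
#'
#' @param reference_id,inbred_id Haplotype labels of the reference and the
#'   non-reference inbred genome.
#' @param hybrid_hap_ids Length-2 character: labels of the hybrid parent's
#'   two haplotypes.
#' @param assembly_snps Named list of [variant_set()]s, assembly-vs-reference
#'   calls for `inbred_id` and both `hybrid_hap_ids`.
#' @param reads_inbred,reads_hybrid Read-based [variant_set()]s (with
#'   genotype classes) for the inbred genome and the hybrid genome,
#'   each already dual-evidence intersected.
#' @param reads_reference Read-based calls of the reference genome against
#'   its own assembly (may be empty).
#' @param exclusion A [region_set()] of masked regions, or `NULL`.
#' @param exclude_haplotypes Haplotypes the exclusion applies to
#'   (default all four).
#' @param layout Optional [genome_layout()].
#' @return A [marker_set()] over the four haplotypes; pairwise
#'   position-disjoint by construction (asserted).
#' @export
derive_four_way_markers <- function(reference_id, inbred_id, hybrid_hap_ids,
                                    assembly_snps, reads_inbred, reads_hybrid,
                                    reads_reference = variant_set(),
                                    exclusion = NULL,
                                    exclude_haplotypes = NULL,
                                    layout = NULL) {
  stopifnot(length(hybrid_hap_ids) == 2)
  need <- c(inbred_id, hybrid_hap_ids)
  miss <- setdiff(need, names(assembly_snps))
  if (length(miss)) {
    stop("missing assembly SNP set for haplotype(s): ",
         paste(miss, collapse = ", "))
  }
  het_hyb <- reads_hybrid[reads_hybrid$genotype_class == "het", , drop = FALSE]
  hom_hyb <- reads_hybrid[reads_hybrid$genotype_class == "hom_alt", , drop = FALSE]
  hom_inb <- reads_inbred[reads_inbred$genotype_class == "hom_alt", , drop = FALSE]

  out <- list()
  # (1) hybrid-parent haplotypes: assembly SNPs confirmed heterozygous in the
  # hybrid's reads — matched by (chrom, pos, alt); the genotype classes
  # necessarily differ (assembly calls are haploid/homozygous, read calls het)
  for (h in hybrid_hap_ids) {
    sister <- setdiff(hybrid_hap_ids, h)
    asm <- assembly_snps[[h]]
    m <- asm[paste(asm$chrom, asm$pos, asm$alt) %in%
               paste(het_hyb$chrom, het_hyb$pos, het_hyb$alt), , drop = FALSE]
    m <- subtract_overlaps(validate_variant_set(as.data.frame(m)),
                           list(reads_reference, reads_inbred,
                                assembly_snps[[inbred_id]],
                                assembly_snps[[sister]]))
    out[[h]] <- data.frame(haplotype = rep(h, nrow(m)), chrom = m$chrom,
                           pos = m$pos, allele = rep("alt", nrow(m)),
                           stringsAsFactors = FALSE)
  }
  # (2) non-reference inbred
  m <- subtract_overlaps(validate_variant_set(as.data.frame(hom_inb)),
                         list(reads_reference, reads_hybrid,
                              assembly_snps[[hybrid_hap_ids[1]]],
                              assembly_snps[[hybrid_hap_ids[2]]]))
  out[[inbred_id]] <- data.frame(haplotype = rep(inbred_id, nrow(m)),
                                 chrom = m$chrom, pos = m$pos,
                                 allele = rep("alt", nrow(m)),
                                 stringsAsFactors = FALSE)
  # (3) reference haplotype: hom-alt in every non-reference genome
  k_inb <- vs_key(hom_inb)
  k_hyb <- vs_key(hom_hyb)
  common <- intersect(k_inb, k_hyb)
  m <- hom_inb[k_inb %in% common, , drop = FALSE]
  out[[reference_id]] <- data.frame(haplotype = rep(reference_id, nrow(m)),
                                    chrom = m$chrom, pos = m$pos,
                                    allele = rep("ref", nrow(m)),
                                    stringsAsFactors = FALSE)
  df <- do.call(rbind, out)
  # a position claimed by more than one haplotype is ambiguous: drop everywhere
  key <- paste(df$chrom, df$pos)
  dup <- key %in% key[duplicated(key)]
  df <- df[!dup, , drop = FALSE]
  ms <- marker_set(df$haplotype, df$chrom, df$pos, df$allele, layout = layout)
  if (!is.null(exclusion)) {
    ms <- apply_exclusion(ms, exclusion, haplotypes = exclude_haplotypes)
  }
  stopifnot(!anyDuplicated(paste(ms$chrom, ms$pos)))
  ms
}

#' Mask markers inside exclusion regions
#'
#' Removes markers whose position falls inside any region (0-based half-open:
#' a 1-based position `p` is inside iff `start < p <= end`). Removal counts
#' per haplotype are attached as attribute `n_removed`.
#'
#' @param markers A [marker_set()].
#' @param regions A [region_set()].
#' @param haplotypes If non-`NULL`, apply the mask only to these haplotypes'
#'   marker lists.
#' @return The filtered [marker_set()].
#' @export
apply_exclusion <- function(markers, regions, haplotypes = NULL) {
  hit <- in_regions(markers$chrom, markers$pos, regions)
  if (!is.null(haplotypes)) hit <- hit & markers$haplotype %in% haplotypes
  removed <- table(factor(markers$haplotype[hit],
                          levels = unique(markers$haplotype)))
  out <- markers[!hit, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("marker_set", "data.frame")
  attr(out, "n_removed") <- removed
  out
}

#' Verify marker uniqueness against simulator truth
#'
#' Brute-force oracle: for every marker, counts the founders that truly carry
#' the diagnostic allele in the panel. An alt-diagnostic marker must be
#' carried by exactly the claimed haplotype; a ref-diagnostic marker must
#' have the ref allele carried only by the reference founder. Marker
#' positions absent from the panel (false-positive calls that survived
#' filtering) are violations.
#'
#' @param markers A [marker_set()].
#' @param panel A [simulate_founders()] panel.
#' @return data.frame of violations (`haplotype`, `chrom`, `pos`, `reason`);
#'   zero rows on a clean marker set.
#' @export
verify_marker_uniqueness <- function(markers, panel) {
  if (!nrow(markers)) {
    return(data.frame(haplotype = character(), chrom = character(),
                      pos = numeric(), reason = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- match(paste(markers$chrom, markers$pos),
               paste(panel$sites$chrom, panel$sites$pos))
  nf <- length(panel$founder_ids)
  n_alt_carriers <- rowSums(panel$carriers)[pmax(idx, 1)]
  claim_col <- match(markers$haplotype, panel$founder_ids)
  claim_carries <- panel$carriers[cbind(pmax(idx, 1), pmax(claim_col, 1))]
  is_alt <- markers$allele == "alt"
  ok <- !is.na(idx) & !is.na(claim_col) &
    ifelse(is_alt,
           n_alt_carriers == 1 & claim_carries,
           # ref diagnostic: only the reference founder lacks the alt allele
           n_alt_carriers == nf - 1 & !claim_carries &
             markers$haplotype == panel$reference)
  reason <- rep(NA_character_, nrow(markers))
  reason[is.na(idx)] <- "position absent from panel truth"
  reason[!ok & is.na(reason) & is_alt] <-
    "alt allele not unique to claimed haplotype"
  reason[!ok & is.na(reason) & !is_alt] <-
    "ref allele not unique to reference haplotype"
  bad <- which(!ok)
  data.frame(haplotype = markers$haplotype[bad], chrom = markers$chrom[bad],
             pos = markers$pos[bad], reason = reason[bad],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Marker density per haplotype
#'
#' @param markers A [marker_set()].
#' @param layout A [genome_layout()].
#' @return data.frame `haplotype`, `n_markers`, `per_mb` (genome-wide mean
#'   density).
#' @export
marker_density <- function(markers, layout) {
  tot_mb <- sum(layout$length_bp) / 1e6
  tab <- table(markers$haplotype)
  data.frame(haplotype = names(tab), n_markers = as.integer(tab),
             per_mb = as.numeric(tab) / tot_mb,
             row.names = NULL, stringsAsFactors = FALSE)
}
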