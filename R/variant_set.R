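#' Variant set
#'
#' A genome's biallelic SNP records relative to a reference coordinate system:
#' chromosome, 1-based position, single-base ref and alt alleles, a genotype
#' class (`hom_alt` or `het`) and a free-text evidence source tag.
#'
#' @param chrom,pos,ref,alt,genotype_class Record fields (recycled scalars
#'   allowed for `ref`, `alt`, `genotype_class`, `source`).
#' @param source Evidence tag (e.g. which technology produced the call).
#' @param layout Optional [genome_layout()] used for sorting and bounds
#'   checks; without it rows sort by chromosome name.
#' @return Object of class `variant_set`: a data.frame with columns `chrom`,
#'   `pos`, `ref`, `alt`, `genotype_class`, `source`, sorted, unique by
#'   (chrom, pos).
#' @export
variant_set <- function(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        genotype_class = character(),
                        source = "truth", layout = NULL) {
  n <- length(pos)
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   ref = rep_len(as.character(ref), n),
                   alt = rep_len(as.character(alt), n),
                   genotype_class = rep_len(as.character(genotype_class), n),
                   source = rep_len(as.character(source), n),
                   stringsAsFactors = FALSE)
  validate_variant_set(df, layout)
}

validate_variant_set <- function(df, layout = NULL) {
  if (nrow(df)) {
    if (any(nchar(df$ref) != 1) || any(nchar(df$alt) != 1)) {
      stop("variant_set holds biallelic SNPs only (single-base ref/alt)")
    }
    bad <- !df$genotype_class %in% c("hom_alt", "het")
    if (any(bad)) stop("genotype_class must be 'hom_alt' or 'het'")
    if (any(df$pos < 1)) stop("positions are 1-based (>= 1)")
    if (!is.null(layout)) {
      L <- chrom_length(layout, df$chrom)
      if (any(df$pos > L)) stop("variant position beyond chromosome length")
      df <- order_by_layout(df, layout)
    } else {
      df <- df[order(df$chrom, df$pos), , drop = FALSE]
    }
    if (anyDuplicated(paste(df$chrom, df$pos))) {
      stop("duplicate (chrom, pos) in variant_set")
    }
  }
  rownames(df) <- NULL
  class(df) <- c("variant_set", "data.frame")
  df
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d SNPs (%d hom_alt, %d het)\n", nrow(x),
              sum(x$genotype_class == "hom_alt"),
              sum(x$genotype_class == "het")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

vs_key <- function(x) paste(x$chrom, x$pos, sep = ":")

#' Genomic region set
#'
#' Intervals in 0-based half-open coordinates (BED convention).
#'
#' @param chrom,start,end Interval fields; `start < end` required.
#' @param layout Optional [genome_layout()] for bounds checks.
#' @return Object of class `region_set`.
#' @export
region_set <- function(chrom = character(), start = numeric(),
                       end = numeric(), layout = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$start < 0)) stop("region start must be >= 0")
    if (any(df$start >= df$end)) stop("region start must be < end")
    if (!is.null(layout)) {
      L <- chrom_length(layout, df$chrom)
      if (any(df$end > L)) stop("region extends beyond chromosome length")
    }
    df <- df[order(df$chrom, df$start), , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("region_set", "data.frame")
  df
}

# TRUE for each (chrom, pos[1-based]) falling inside any region
# (half-open: pos is inside iff start < pos <= end, i.e. pos-1 in [start,end)).
in_regions <- function(chrom, pos, regions) {
  hit <- rep(FALSE, length(pos))
  if (!nrow(regions)) return(hit)
  p0 <- pos - 1
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (chrom == regions$chrom[i] &
                    p0 >= regions$start[i] & p0 < regions$end[i])
  }
  hit
}

#' Allele count table
#'
#' Per-sample, per-site read observations: counts of reads supporting the
#' reference and the alternate allele.
#'
#' @param sample_id,chrom,pos,ref_count,alt_count Column vectors.
#' @return Object of class `count_table`, unique by (sample, chrom, pos).
#' @export
count_table <- function(sample_id = character(), chrom = character(),
                        pos = integer(), ref_count = integer(),
                        alt_count = integer()) {
  df <- data.frame(sample_id = as.character(sample_id),
                   chrom = as.character(chrom), pos = as.numeric(pos),
                   ref_count = as.numeric(ref_count),
                   alt_count = as.numeric(alt_count),
                   stringsAsFactors = FALSE)
  validate_count_table(df)
}

validate_count_table <- function(df) {
  if (nrow(df)) {
    if (any(df$ref_count < 0) || any(df$alt_count < 0)) {
      stop("read counts must be >= 0")
    }
    key <- paste(df$sample_id, df$chrom, df$pos)
    dup <- duplicated(key)
    if (any(dup)) {
      stop("duplicate count rows for key: ", key[which(dup)[1]])
    }
    df <- df[order(df$sample_id, df$chrom, df$pos), , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("count_table", "data.frame")
  df
}

#' Marker set
#'
#' Haplotype-unique SNP markers: for each haplotype, the sites whose
#' diagnostic allele (ref or alt, in reference coordinates) is carried by
#' that haplotype and no other in the design. The ref allele is diagnostic
#' only for the reference haplotype.
#'
#' @param haplotype,chrom,pos,allele Column vectors; `allele` in
#'   `{"ref","alt"}`.
#' @param layout Optional [genome_layout()] for sorting.
#' @return Object of class `marker_set`; a (chrom, pos) appears under at most
#'   one haplotype.
#' @export
marker_set <- function(haplotype = character(), chrom = character(),
                       pos = integer(), allele = character(),
                       layout = NULL) {
  df <- data.frame(haplotype = as.character(haplotype),
                   chrom = as.character(chrom), pos = as.numeric(pos),
                   allele = as.character(allele), stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(!df$allele %in% c("ref", "alt"))) {
      stop("diagnostic allele must be 'ref' or 'alt'")
    }
    key <- paste(df$chrom, df$pos)
    if (anyDuplicated(key)) {
      stop("a (chrom, pos) may be a marker for at most one haplotype")
    }
    if (!is.null(layout)) {
      df <- order_by_layout(df, layout)
    } else {
      df <- df[order(df$chrom, df$pos), , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  class(df) <- c("marker_set", "data.frame")
  df
}

#' @export
print.marker_set <- function(x, ...) {
  cat("marker_set:\n")
  if (nrow(x)) print(table(x$haplotype)) else cat("  (empty)\n")
  invisible(x)
}
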