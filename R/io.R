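#' Read a variant set from a VCF file
#'
#' Consumes the output of a standard small-variant caller. Only biallelic SNP
#' records are kept: multiallelic records, indels and records with symbolic
#' alleles are skipped and counted. The genotype class is taken from the
#' first sample's GT field (`1/1` or `1|1` -> `hom_alt`; `0/1`, `1/0`, `0|1`,
#' `1|0` -> `het`); `0/0` and missing genotypes carry no alt evidence and are
#' skipped. An evidence tag is read from the `SRC` INFO key when present.
#'
#' @param path Path to an uncompressed VCF 4.x file.
#' @param require_gt If `TRUE` (default), error when the file has no GT
#'   field; if `FALSE`, records without GT are classed `hom_alt` (suitable
#'   for assembly-vs-assembly call sets that carry no genotypes).
#' @param layout Optional [genome_layout()] for sorting and bounds checks.
#' @return A [variant_set()] with attribute `n_skipped` (records dropped as
#'   non-SNP/multiallelic/no-alt-evidence).
#' @export
read_vcf <- function(path, require_gt = TRUE, layout = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (n == 0) {
    out <- variant_set(layout = layout)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  has_gt <- ncol(v@gt) >= 2
  if (!has_gt && require_gt) {
    stop("VCF has no genotype (GT) column; set require_gt = FALSE for ",
         "genotype-free call sets")
  }
  snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (has_gt) {
    gt <- vcfR::extract.gt(v, element = "GT")[, 1]
    gt <- gsub("\\|", "/", gt)
    class <- ifelse(gt == "1/1", "hom_alt",
                    ifelse(gt %in% c("0/1", "1/0"), "het", NA))
  } else {
    class <- rep("hom_alt", n)
  }
  keep <- snp & !is.na(class)
  src <- rep("vcf", n)
  m <- regmatches(fix$INFO, regexpr("SRC=[^;]+", fix$INFO))
  if (length(m)) {
    hasrc <- grepl("SRC=", fix$INFO)
    src[hasrc] <- sub("SRC=", "", m)
  }
  out <- variant_set(fix$CHROM[keep], as.numeric(fix$POS[keep]),
                     fix$REF[keep], fix$ALT[keep], class[keep],
                     source = src[keep], layout = layout)
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Write a variant set as a minimal VCF 4.2 file
#'
#' One sample column carrying GT; the evidence tag goes into the `SRC` INFO
#' key. Output is sorted and deterministic.
#'
#' @param x A [variant_set()].
#' @param path Output path.
#' @param sample_name Sample column header.
#' @param layout Optional [genome_layout()]; adds contig header lines.
#' @export
write_vcf <- function(x, path, sample_name = "sample", layout = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SRC,Number=1,Type=String,Description=\"Evidence source tag\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (!is.null(layout)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", layout$chrom,
                          as.integer(layout$length_bp)))
  }
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_name, sep = "\t"))
  gt <- ifelse(x$genotype_class == "hom_alt", "1/1", "0/1")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tSRC=%s\tGT\t%s",
                  x$chrom, as.integer(x$pos), x$ref, x$alt, x$source, gt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write BED3 region files
#'
#' Three-column BED (chrom, start, end), 0-based half-open. Readers reject
#' malformed rows (`start >= end`, negative coordinates) rather than coerce.
#'
#' @param path File path.
#' @param layout Optional [genome_layout()] for bounds checks.
#' @return `read_bed` returns a [region_set()].
#' @export
read_bed <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (length(readLines(path, n = 1)) == 0) return(region_set(layout = layout))
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric", "numeric"),
                          col.names = c("chrom", "start", "end"))
  region_set(df$chrom, df$start, df$end, layout = layout)
}

#' @rdname read_bed
#' @param x A [region_set()].
#' @export
write_bed <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(x)) {
    writeLines(sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start),
                       as.integer(x$end)), con)
  }
  invisible(path)
}

#' Read / write allele count tables as TSV
#'
#' Tab-separated with header `sample_id, chrom, pos, ref_count, alt_count`.
#' Duplicate (sample, chrom, pos) keys and negative counts are rejected.
#'
#' @param path File path.
#' @return `read_counts` returns a [count_table()].
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "chrom", "pos", "ref_count", "alt_count")
  if (!all(req %in% names(df))) {
    stop("count table must have columns: ", paste(req, collapse = ", "))
  }
  count_table(df$sample_id, df$chrom, df$pos, df$ref_count, df$alt_count)
}

#' @rdname read_counts
#' @param x A [count_table()].
#' @export
write_counts <- function(x, path) {
  df <- as.data.frame(x)
  df$pos <- as.integer(df$pos)
  df$ref_count <- as.integer(df$ref_count)
  df$alt_count <- as.integer(df$alt_count)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write marker sets as TSV
#'
#' Tab-separated with header `haplotype, chrom, pos, allele`.
#'
#' @param path File path.
#' @param layout Optional [genome_layout()] for sorting.
#' @return `read_markers` returns a [marker_set()].
#' @export
read_markers <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("haplotype", "chrom", "pos", "allele")
  if (!all(req %in% names(df))) {
    stop("marker table must have columns: ", paste(req, collapse = ", "))
  }
  marker_set(df$haplotype, df$chrom, df$pos, df$allele, layout = layout)
}

#' @rdname read_markers
#' @param x A [marker_set()].
#' @export
write_markers <- function(x, path) {
  df <- as.data.frame(x)
  df$pos <- as.integer(df$pos)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
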