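#' Score haplotype presence by marker recovery
#'
#' For each sample and each haplotype's marker list, counts the markers whose
#' diagnostic allele is supported by reads: at least `min_supporting_reads`
#' reads carrying it *and* a supporting-read fraction of at least
#' `min_supporting_frac` (the fraction guard keeps isolated miscalled reads
#' at high depth from faking presence). Alt-diagnostic markers count alt
#' reads; ref-diagnostic markers (the reference haplotype's) count ref
#' reads. Markers without any coverage are excluded from the denominator and
#' reported separately.
#'
#' @param counts A [count_table()] (any number of samples).
#' @param markers A [marker_set()].
#' @param min_supporting_reads Minimum diagnostic reads (default 1).
#' @param min_supporting_frac Minimum diagnostic read fraction (default
#'   0.05).
#' @return data.frame of class `presence_report`: `sample_id`, `haplotype`,
#'   `n_markers_total` (covered), `n_markers_observed`, `n_uncovered`,
#'   `percent_found` (`NA` for a haplotype with no covered markers).
#' @export
marker_presence <- function(counts, markers, min_supporting_reads = 1,
                            min_supporting_frac = 0.05) {
  key_m <- paste(markers$chrom, markers$pos)
  out <- list()
  for (sid in unique(counts$sample_id)) {
    x <- counts[counts$sample_id == sid, , drop = FALSE]
    i <- match(key_m, paste(x$chrom, x$pos))
    depth <- x$ref_count[i] + x$alt_count[i]
    diag_reads <- ifelse(markers$allele == "alt", x$alt_count[i],
                         x$ref_count[i])
    covered <- !is.na(depth) & depth > 0
    observed <- covered & diag_reads >= min_supporting_reads &
      diag_reads / pmax(depth, 1) >= min_supporting_frac
    for (h in unique(markers$haplotype)) {
      sel <- markers$haplotype == h
      n_cov <- sum(covered & sel)
      out[[length(out) + 1]] <- data.frame(
        sample_id = sid, haplotype = h,
        n_markers_total = n_cov,
        n_markers_observed = sum(observed & sel),
        n_uncovered = sum(sel) - n_cov,
        percent_found = if (n_cov > 0) 100 * sum(observed & sel) / n_cov else
          NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("presence_report", "data.frame")
  res
}

#' Validate a four-haplotype design from a presence report
#'
#' Accepts a sample as a true four-haplotype plant iff all four haplotypes'
#' marker-recovery percentages reach the presence floor.
#'
#' @param report A [marker_presence()] report for one sample covering four
#'   haplotypes.
#' @param presence_floor Minimum percent found (default 90).
#' @return List: `accept` (logical), `failing` (character vector of
#'   haplotypes below the floor), `percents` (named numeric).
#' @export
validate_four_hap <- function(report, presence_floor = 90) {
  if (length(unique(report$sample_id)) != 1) {
    stop("validate_four_hap expects a single sample's report")
  }
  if (nrow(report) != 4) stop("expected exactly four haplotypes in report")
  p <- stats::setNames(report$percent_found, report$haplotype)
  failing <- names(p)[is.na(p) | p < presence_floor]
  list(accept = length(failing) == 0, failing = failing, percents = p)
}

#' Locus table for dosage genotyping
#'
#' Defines the loci to genotype: an id, location, and per-haplotype carrier
#' status (1 = that founder haplotype carries the allele of interest,
#' e.g. a resistance haplotype; 0 = it does not).
#'
#' @param locus_id,chrom,start,end Locus identity and interval (0-based
#'   half-open).
#' @param carriers Named list (one element per locus) of named 0/1 integer
#'   vectors over the design's haplotype ids.
#' @return data.frame of class `locus_table` with a `carriers` list-column.
#' @export
locus_table <- function(locus_id, chrom, start, end, carriers) {
  stopifnot(length(carriers) == length(locus_id))
  df <- data.frame(locus_id = locus_id, chrom = chrom, start = start,
                   end = end, stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("locus start must be < end")
  df$carriers <- carriers
  class(df) <- c("locus_table", "data.frame")
  df
}

#' Expected gene dosage under clonal gamete transmission
#'
#' With clonal gametes every grandparental haplotype contributes exactly one
#' copy to the tetraploid, so the expected dosage is the sum of carrier
#' status over the four haplotypes of the design (order-invariant).
#'
#' @param locus One row of a [locus_table()] (or a list with `carriers`).
#' @param design Character vector of the four haplotype ids forming the
#'   tetraploid (with multiplicity, if a haplotype enters twice).
#' @return Integer expected copy number, 0..length(design).
#' @export
expected_dosage <- function(locus, design) {
  carr <- if (is.data.frame(locus)) locus$carriers[[1]] else locus$carriers
  miss <- setdiff(design, names(carr))
  if (length(miss)) {
    stop("carrier status undefined for haplotype(s): ",
         paste(miss, collapse = ", "))
  }
  as.integer(sum(carr[design]))
}

#' Estimate gene dosage from pooled read counts at a locus's markers
#'
#' Pools diagnostic-allele reads and depth over the covered markers of the
#' locus, takes the pooled allele frequency, and snaps `af * ploidy` to the
#' nearest integer copy number (exact halves round *down* — conservative
#' against overcalling), clipped to `[0, ploidy]`.
#'
#' @param counts A [count_table()] for one sample.
#' @param locus_markers data.frame with `chrom`, `pos`, `allele` — the
#'   diagnostic markers of the locus (e.g. the relevant rows of a
#'   [marker_set()] restricted to the locus interval).
#' @param ploidy Total copy number of the design.
#' @return List of class `dosage_call`: `observed_af`, `estimated_copies`,
#'   `n_markers_used`; `estimated_copies` is `NA` when no marker is covered.
#' @export
estimate_dosage <- function(counts, locus_markers, ploidy) {
  i <- match(paste(locus_markers$chrom, locus_markers$pos),
             paste(counts$chrom, counts$pos))
  depth <- counts$ref_count[i] + counts$alt_count[i]
  diag_reads <- ifelse(locus_markers$allele == "alt",
                       counts$alt_count[i], counts$ref_count[i])
  use <- !is.na(depth) & depth > 0
  if (!any(use)) {
    return(structure(list(observed_af = NA_real_,
                          estimated_copies = NA_integer_,
                          n_markers_used = 0L), class = "dosage_call"))
  }
  af <- sum(diag_reads[use]) / sum(depth[use])
  k <- ceiling(af * ploidy - 0.5)          # ties round down
  structure(list(observed_af = af,
                 estimated_copies = as.integer(min(max(k, 0), ploidy)),
                 n_markers_used = sum(use)),
            class = "dosage_call")
}

#' Read / write locus tables as TSV
#'
#' Columns `locus_id`, `chrom`, `start`, `end` plus one `carrier_<hap>`
#' 0/1 column per haplotype. An example file ships under
#' `system.file("extdata", "example_loci.tsv", package = "haplodesign")`.
#'
#' @param path File path.
#' @return `read_locus_table` returns a [locus_table()].
#' @export
read_locus_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("locus_id", "chrom", "start", "end")
  if (!all(req %in% names(df))) {
    stop("locus table must have columns: ", paste(req, collapse = ", "))
  }
  cc <- grep("^carrier_", names(df), value = TRUE)
  if (!length(cc)) stop("locus table needs carrier_<haplotype> columns")
  haps <- sub("^carrier_", "", cc)
  carriers <- lapply(seq_len(nrow(df)), function(i) {
    stats::setNames(as.integer(df[i, cc]), haps)
  })
  locus_table(df$locus_id, df$chrom, df$start, df$end, carriers)
}

#' @rdname read_locus_table
#' @param x A [locus_table()].
#' @export
write_locus_table <- function(x, path) {
  haps <- names(x$carriers[[1]])
  mat <- do.call(rbind, lapply(x$carriers, function(v) v[haps]))
  colnames(mat) <- paste0("carrier_", haps)
  df <- cbind(data.frame(locus_id = x$locus_id, chrom = x$chrom,
                         start = as.integer(x$start), end = as.integer(x$end),
                         stringsAsFactors = FALSE), mat)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Example locus table: five agronomic tomato loci
#'
#' The five classic loci genotyped in tomato polyploid designs — tobacco
#' mosaic virus resistance (Tm-2^2, Solyc09g018220), root-knot nematode
#' resistance (Mi, Solyc06g008720), self-pruning (SP, Solyc06g074350),
#' dwarfism (D, Solyc02g089160) and Fusarium wilt resistance (I,
#' Solyc11g011180) — with synthetic coordinates and an illustrative carrier
#' assignment over a four-haplotype design; intended for simulated designs
#' and as a template for real ones.
#'
#' @param hap_ids Character vector of four haplotype ids.
#' @return A [locus_table()].
#' @export
example_locus_table <- function(hap_ids = c("fREF", "fB", "fC", "fD")) {
  stopifnot(length(hap_ids) == 4)
  mk <- function(v) stats::setNames(as.integer(v), hap_ids)
  locus_table(
    locus_id = c("Solyc09g018220", "Solyc06g008720", "Solyc06g074350",
                 "Solyc02g089160", "Solyc11g011180"),
    chrom = c("chr9", "chr6", "chr6", "chr2", "chr11"),
    start = c(2.0e6, 1.0e6, 44.0e6, 45.0e6, 4.5e6),
    end   = c(2.1e6, 1.1e6, 44.1e6, 45.1e6, 4.6e6),
    carriers = list(mk(c(1, 0, 0, 0)), mk(c(0, 0, 1, 0)),
                    mk(c(0, 1, 0, 0)), mk(c(0, 1, 0, 0)),
                    mk(c(0, 0, 0, 1)))
  )
}
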