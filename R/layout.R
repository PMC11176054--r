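#' Genome layout
#'
#' A genome layout is the ordered set of chromosomes the whole pipeline works
#' over: names and lengths in base pairs. Chromosome order is fixed at
#' construction and every sorted object (variant sets, marker sets, window
#' profiles) follows it.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length_bp Integer vector of chromosome lengths (>= 1), same length
#'   as `chrom`.
#' @return An object of class `genome_layout`: a data.frame with columns
#'   `chrom` and `length_bp`, row order defining chromosome order.
#' @export
genome_layout <- function(chrom, length_bp) {
  chrom <- as.character(chrom)
  length_bp <- as.numeric(length_bp)
  if (length(chrom) != length(length_bp)) {
    stop("chrom and length_bp must have equal length")
  }
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(length_bp)) || any(length_bp < 1)) {
    stop("chromosome lengths must be >= 1")
  }
  out <- data.frame(chrom = chrom, length_bp = length_bp,
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Default 12-chromosome tomato-like layout
#'
#' Chromosome lengths approximate the cultivated tomato nuclear genome
#' (12 chromosomes, ~770 Mb total); sizes are rounded to 0.1 Mb.
#'
#' @return A [genome_layout()].
#' @export
default_layout <- function() {
  genome_layout(
    chrom = paste0("chr", 1:12),
    length_bp = c(90.9, 53.5, 65.3, 64.9, 65.5, 47.8,
                  68.2, 63.0, 68.5, 64.8, 54.9, 66.7) * 1e6
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosomes, %.1f Mb total\n",
              nrow(x), sum(x$length_bp) / 1e6))
  print.data.frame(x, ...)
  invisible(x)
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) stop("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "))
  layout$length_bp[i]
}

#' Order rows by layout chromosome order, then position
#'
#' @param df data.frame with `chrom` and `pos` columns.
#' @param layout A [genome_layout()].
#' @keywords internal
order_by_layout <- function(df, layout) {
  i <- match(df$chrom, layout$chrom)
  if (anyNA(i)) stop("rows on chromosomes absent from layout: ",
                     paste(unique(df$chrom[is.na(i)]), collapse = ", "))
  df[order(i, df$pos), , drop = FALSE]
}

#' Read / write a genome layout as TSV
#'
#' Two-column tab-separated file with header `chrom` and `length_bp`.
#'
#' @param path File path.
#' @return `read_layout` returns a [genome_layout()]; `write_layout`
#'   invisibly returns `path`.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "length_bp") %in% names(df))) {
    stop("layout file must have columns 'chrom' and 'length_bp'")
  }
  genome_layout(df$chrom, df$length_bp)
}

#' @rdname read_layout
#' @param layout A [genome_layout()].
#' @export
write_layout <- function(layout, path) {
  utils::write.table(as.data.frame(layout), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
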