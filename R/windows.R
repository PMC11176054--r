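#' Per-site allele frequency
#'
#' `alt / (ref + alt)` oriented so that 0 is the reference-founder allele and
#' 1 the alternate-founder allele. Sites with depth below `min_depth` are
#' missing (`NA`).
#'
#' @param ref_count,alt_count Non-negative read counts.
#' @param min_depth Minimum depth for a defined frequency (default 1).
#' @return Numeric vector of frequencies in `[0, 1]` with `NA` for
#'   low-coverage sites.
#' @export
site_af <- function(ref_count, alt_count, min_depth = 1) {
  if (any(ref_count < 0, na.rm = TRUE) || any(alt_count < 0, na.rm = TRUE)) {
    stop("read counts must be >= 0")
  }
  depth <- ref_count + alt_count
  ifelse(depth >= min_depth, alt_count / depth, NA_real_)
}

# Window start coordinates (0-based) for one chromosome:
# floor((L - W) / s) + 1 windows for L >= W, else one whole-chromosome window.
window_starts <- function(L, W, s) {
  if (W <= 0 || s <= 0) stop("window width and step must be > 0")
  if (L >= W) seq(0, (floor((L - W) / s)) * s, by = s) else 0
}

# Windowed sums of a per-site value via cumulative sums.
# pos is 1-based; a site is in window [a, a+W) iff a < pos <= a+W.
# Returns list(n = sites per window, sum = value sum per window,
#              n_inf = non-NA sites, sum_inf = non-NA value sum).
window_accumulate <- function(pos, value, starts, W) {
  o <- order(pos)
  p0 <- pos[o] - 1
  v <- value[o]
  ends <- pmin(starts + W, max(p0, starts + W) + 1)
  lo <- findInterval(starts - 0.5, p0)
  hi <- findInterval(starts + W - 0.5, p0)
  n <- hi - lo
  inf <- !is.na(v)
  cs_n <- cumsum(inf)
  cs_v <- cumsum(ifelse(inf, v, 0))
  at <- function(cs, i) ifelse(i > 0, cs[pmax(i, 1)], 0)
  list(n = n,
       n_inf = at(cs_n, hi) - at(cs_n, lo),
       sum_inf = at(cs_v, hi) - at(cs_v, lo))
}

#' Sliding-window mean allele frequency
#'
#' Windows of width `W` advance by step `s` along each chromosome (the last
#' partial window is dropped; chromosomes shorter than `W` get one
#' whole-chromosome window). The window mean is the unweighted mean of the
#' defined site frequencies inside it; windows with fewer than `min_markers`
#' informative sites are missing rather than zero, so marker deserts cannot
#' produce artifactual states.
#'
#' @param sites data.frame with `chrom`, `pos` (1-based) and `af` (from
#'   [site_af()]; may contain `NA`).
#' @param layout A [genome_layout()].
#' @param W Window width in bp (default 1 Mb).
#' @param s Step in bp (default 50 kb).
#' @param min_markers Minimum informative sites per window (default 10).
#' @return A `window_profile`: data.frame `chrom`, `win_start`, `win_end`
#'   (0-based half-open), `n_markers`, `mean_af`, with attributes `W`, `s`.
#' @export
window_af <- function(sites, layout, W = 1e6, s = 5e4, min_markers = 10) {
  out <- lapply(seq_len(nrow(layout)), function(ci) {
    chr <- layout$chrom[ci]
    L <- layout$length_bp[ci]
    starts <- window_starts(L, W, s)
    sel <- sites$chrom == chr
    acc <- window_accumulate(sites$pos[sel], sites$af[sel], starts, W)
    mean_af <- ifelse(acc$n_inf >= min_markers, acc$sum_inf / acc$n_inf,
                      NA_real_)
    data.frame(chrom = chr, win_start = starts,
               win_end = pmin(starts + W, L), n_markers = acc$n_inf,
               mean_af = mean_af, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, W = W, s = s, class = c("window_profile", "data.frame"))
}

#' Sliding-window normalized coverage
#'
#' Mean read depth at marker sites per window, divided by the genome-wide
#' median of window mean depths, so the genome-wide median of the output is 1
#' and a region present at 3 of 4 copies sits near 0.75. Empty windows are
#' missing.
#'
#' @param sites data.frame with `chrom`, `pos`, `depth`.
#' @inheritParams window_af
#' @return A `window_profile` data.frame with `mean_norm_cov`.
#' @export
window_coverage <- function(sites, layout, W = 1e6, s = 5e4) {
  if (!nrow(sites) || all(sites$depth == 0)) {
    stop("cannot normalize coverage: no nonzero depths")
  }
  out <- lapply(seq_len(nrow(layout)), function(ci) {
    chr <- layout$chrom[ci]
    L <- layout$length_bp[ci]
    starts <- window_starts(L, W, s)
    sel <- sites$chrom == chr
    acc <- window_accumulate(sites$pos[sel], sites$depth[sel], starts, W)
    data.frame(chrom = chr, win_start = starts,
               win_end = pmin(starts + W, L),
               mean_depth = ifelse(acc$n_inf > 0, acc$sum_inf / acc$n_inf,
                                   NA_real_),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  med <- stats::median(res$mean_depth, na.rm = TRUE)
  if (!is.finite(med) || med <= 0) {
    stop("cannot normalize coverage: zero median window depth")
  }
  res$mean_norm_cov <- res$mean_depth / med
  rownames(res) <- NULL
  structure(res, W = W, s = s, class = c("window_profile", "data.frame"))
}

#' Sliding-window SNP density
#'
#' SNP count per window scaled to SNPs/Mb; windows at or above
#' `flag_threshold` are flagged as candidate wild-introgression regions.
#'
#' @param variants A [variant_set()] (or any data.frame with `chrom`, `pos`).
#' @inheritParams window_af
#' @param flag_threshold Density (SNPs/Mb) at or above which a window is
#'   flagged (default 4x the genome-wide median, which is robust to the
#'   block itself inflating the genome-wide level).
#' @return A `window_profile` data.frame with `snp_density` and `flagged`.
#' @export
window_snp_density <- function(variants, layout, W = 1e6, s = 5e4,
                               flag_threshold = NULL) {
  out <- lapply(seq_len(nrow(layout)), function(ci) {
    chr <- layout$chrom[ci]
    L <- layout$length_bp[ci]
    starts <- window_starts(L, W, s)
    sel <- variants$chrom == chr
    acc <- window_accumulate(variants$pos[sel],
                             rep(1, sum(sel)), starts, W)
    width <- pmin(starts + W, L) - starts
    data.frame(chrom = chr, win_start = starts,
               win_end = pmin(starts + W, L),
               snp_density = acc$n_inf * (1e6 / width),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(flag_threshold)) {
    flag_threshold <- 4 * stats::median(res$snp_density)
  }
  res$flagged <- res$snp_density >= flag_threshold
  rownames(res) <- NULL
  structure(res, W = W, s = s, flag_threshold = flag_threshold,
            class = c("window_profile", "data.frame"))
}

#' Joint windowed profile of one sample
#'
#' Combines [window_af()] and [window_coverage()] over one sample's allele
#' counts at marker positions: the standard input to offspring
#' classification. Site frequencies are oriented by the marker's diagnostic
#' allele convention (alt fraction; 0 = reference founder).
#'
#' @param counts A [count_table()] for a single sample (or one sample of a
#'   multi-sample table, chosen by `sample_id`).
#' @param layout A [genome_layout()].
#' @param sample_id Which sample to profile (default: the only one present).
#' @param W,s,min_markers,min_depth See [window_af()] and [site_af()].
#' @return A `window_profile` data.frame with `n_markers`, `mean_af` and
#'   `mean_norm_cov` columns.
#' @export
build_profile <- function(counts, layout, sample_id = NULL,
                          W = 1e6, s = 5e4, min_markers = 10, min_depth = 1) {
  if (is.null(sample_id)) {
    ids <- unique(counts$sample_id)
    if (length(ids) != 1) stop("multiple samples present; give sample_id")
    sample_id <- ids
  }
  x <- counts[counts$sample_id == sample_id, , drop = FALSE]
  if (!nrow(x)) stop("no rows for sample ", sample_id)
  sites <- data.frame(chrom = x$chrom, pos = x$pos,
                      af = site_af(x$ref_count, x$alt_count, min_depth),
                      depth = x$ref_count + x$alt_count,
                      stringsAsFactors = FALSE)
  af <- window_af(sites, layout, W = W, s = s, min_markers = min_markers)
  cov <- window_coverage(sites, layout, W = W, s = s)
  af$mean_norm_cov <- cov$mean_norm_cov
  attr(af, "sample_id") <- sample_id
  af
}
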