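#' Simulation configuration
#'
#' Collects every tunable of the forward cross simulator. Defaults emulate the
#' study conditions of a tomato polyploid-design experiment: a 12-chromosome
#' genome, 100 founder-private SNPs per Mb, one high-density wild-introgression
#' block on chromosome 9 (5-58 Mb) in the reference founder, an obligate
#' crossover per chromosome in meiotic gametes, 30x sequencing depth and a 1%
#' allele-miscall rate.
#'
#' @param layout A [genome_layout()].
#' @param founder_ids Character vector of 2 or 4 founder labels; the first is
#'   the reference founder (carries no alt alleles of its own — its private
#'   variants surface as alt alleles in every other genome when calls are made
#'   against its assembly).
#' @param snp_density Founder-private SNPs per Mb (single value or one per
#'   founder).
#' @param introgression data.frame with columns `founder`, `chrom`, `start`,
#'   `end` (0-based half-open) and `multiplier`: blocks where that founder's
#'   private-SNP density is multiplied. `NULL` for none.
#' @param share_frac Fraction of each non-reference founder's sites also
#'   carried by one other random non-reference founder (stress-tests marker
#'   uniqueness filters). Default 0.
#' @param crossover_rate Expected crossovers per chromosome per meiosis
#'   (Poisson mean).
#' @param obligate_co If `TRUE`, at least one crossover per chromosome
#'   (count is `max(1, Poisson(rate))`).
#' @param truncation_prob Probability that an offspring loses a terminal
#'   segment of one chromosome copy.
#' @param truncation_frac Length-2 numeric: min and max lost fraction of the
#'   chromosome (uniform draw).
#' @param mean_depth Mean sequencing depth at full copy number.
#' @param error_rate Per-read allele miscall probability, in [0, 0.5).
#' @param evidence_dropout Per-site probability that a true SNP is missing
#'   from one evidence replicate (models imperfect recall of a single
#'   sequencing technology).
#' @param evidence_fp_per_mb False-positive SNP calls per Mb in one evidence
#'   replicate.
#' @param seed Master seed; all stage seeds are derived deterministically
#'   from it.
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(layout = default_layout(),
                       founder_ids = c("fREF", "fB", "fC", "fD"),
                       snp_density = 100,
                       introgression = default_introgression(layout, founder_ids[1]),
                       share_frac = 0,
                       crossover_rate = 1,
                       obligate_co = TRUE,
                       truncation_prob = 0,
                       truncation_frac = c(0.05, 0.5),
                       mean_depth = 30,
                       error_rate = 0.01,
                       evidence_dropout = 0.05,
                       evidence_fp_per_mb = 1,
                       seed = 1L) {
  stopifnot(inherits(layout, "genome_layout"))
  founder_ids <- as.character(founder_ids)
  if (!length(founder_ids) %in% c(2L, 4L)) {
    stop("founder_ids must name 2 or 4 founders")
  }
  if (anyDuplicated(founder_ids)) stop("founder ids must be unique")
  if (length(snp_density) == 1) {
    snp_density <- rep(snp_density, length(founder_ids))
  }
  if (length(snp_density) != length(founder_ids)) {
    stop("snp_density must be scalar or one value per founder")
  }
  if (any(snp_density < 0)) stop("snp_density must be >= 0")
  if (!is.null(introgression)) {
    req <- c("founder", "chrom", "start", "end", "multiplier")
    if (!all(req %in% names(introgression))) {
      stop("introgression needs columns: ", paste(req, collapse = ", "))
    }
    if (!all(introgression$founder %in% founder_ids)) {
      stop("introgression block for unknown founder")
    }
    L <- chrom_length(layout, introgression$chrom)
    if (any(introgression$start < 0) || any(introgression$end > L) ||
        any(introgression$start >= introgression$end)) {
      stop("introgression blocks must lie within chromosome bounds")
    }
    if (any(introgression$multiplier < 1)) stop("multiplier must be >= 1")
  }
  if (share_frac < 0 || share_frac >= 1) stop("share_frac must be in [0, 1)")
  if (crossover_rate < 0) stop("crossover_rate must be >= 0")
  if (truncation_prob < 0 || truncation_prob > 1) {
    stop("truncation_prob must be in [0, 1]")
  }
  stopifnot(length(truncation_frac) == 2, truncation_frac[1] > 0,
            truncation_frac[2] <= 1, truncation_frac[1] <= truncation_frac[2])
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (error_rate < 0 || error_rate >= 0.5) stop("error_rate must be in [0, 0.5)")
  if (evidence_dropout < 0 || evidence_dropout >= 1) {
    stop("evidence_dropout must be in [0, 1)")
  }
  if (evidence_fp_per_mb < 0) stop("evidence_fp_per_mb must be >= 0")
  seed <- as.integer(seed)

  structure(list(
    layout = layout, founder_ids = founder_ids,
    reference = founder_ids[1], snp_density = snp_density,
    introgression = introgression, share_frac = share_frac,
    crossover_rate = crossover_rate, obligate_co = obligate_co,
    truncation_prob = truncation_prob, truncation_frac = truncation_frac,
    mean_depth = mean_depth, error_rate = error_rate,
    evidence_dropout = evidence_dropout,
    evidence_fp_per_mb = evidence_fp_per_mb, seed = seed
  ), class = "sim_config")
}

#' Default wild-introgression block
#'
#' One block on chromosome 9 between 5 Mb and 58 Mb in the given founder, with
#' a 10x SNP density multiplier — emulating a wild-relative introgression in a
#' cultivated reference genome. Returns `NULL` when the layout has no
#' chromosome 9 or it is shorter than 58 Mb (small test layouts).
#'
#' @param layout A [genome_layout()].
#' @param founder Founder id carrying the block.
#' @export
default_introgression <- function(layout, founder) {
  if (!"chr9" %in% layout$chrom) return(NULL)
  if (chrom_length(layout, "chr9") < 58e6) return(NULL)
  data.frame(founder = founder, chrom = "chr9",
             start = 5e6, end = 58e6, multiplier = 10,
             stringsAsFactors = FALSE)
}

#' Read / write a simulation configuration as YAML
#'
#' The scalar fields of [sim_config()] map to top-level keys; the layout and
#' introgression tables map to lists of records.
#'
#' @param path File path.
#' @return `read_sim_config` returns a `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  layout <- genome_layout(vapply(y$layout, `[[`, "", "chrom"),
                          vapply(y$layout, `[[`, 0, "length_bp"))
  intro <- NULL
  if (length(y$introgression)) {
    intro <- do.call(rbind, lapply(y$introgression, as.data.frame))
  }
  sim_config(layout = layout,
             founder_ids = unlist(y$founder_ids),
             snp_density = unlist(y$snp_density),
             introgression = intro,
             share_frac = y$share_frac,
             crossover_rate = y$crossover_rate,
             obligate_co = y$obligate_co,
             truncation_prob = y$truncation_prob,
             truncation_frac = unlist(y$truncation_frac),
             mean_depth = y$mean_depth,
             error_rate = y$error_rate,
             evidence_dropout = y$evidence_dropout,
             evidence_fp_per_mb = y$evidence_fp_per_mb,
             seed = y$seed)
}

#' @rdname read_sim_config
#' @param config A [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  y <- list(
    layout = lapply(seq_len(nrow(config$layout)), function(i) {
      list(chrom = config$layout$chrom[i],
           length_bp = config$layout$length_bp[i])
    }),
    founder_ids = config$founder_ids,
    snp_density = config$snp_density,
    introgression = if (is.null(config$introgression)) list() else
      lapply(seq_len(nrow(config$introgression)), function(i)
        as.list(config$introgression[i, ])),
    share_frac = config$share_frac,
    crossover_rate = config$crossover_rate,
    obligate_co = config$obligate_co,
    truncation_prob = config$truncation_prob,
    truncation_frac = config$truncation_frac,
    mean_depth = config$mean_depth,
    error_rate = config$error_rate,
    evidence_dropout = config$evidence_dropout,
    evidence_fp_per_mb = config$evidence_fp_per_mb,
    seed = config$seed
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

# Deterministic child seed from a master seed and a stage tag.
# Polynomial string hash folded into [1, 2^31 - 2]; R integers are 32-bit.
child_seed <- function(master, tag) {
  h <- as.numeric(master) %% 2147483647
  for (b in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

# Evaluate expr under a temporary RNG state seeded with `seed`;
# the caller's RNG state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
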