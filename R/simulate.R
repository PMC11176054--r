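#' Simulate a panel of inbred founder genomes
#'
#' Draws founder-private SNPs along each chromosome as a homogeneous point
#' process at the configured density (multiplied inside introgression blocks),
#' with all positions distinct across founders. Alleles are expressed relative
#' to the reference founder's genome: a site "owned" by a non-reference
#' founder carries its alt allele in that founder only, while a site owned by
#' the reference founder (a variant private to the reference assembly)
#' surfaces as an alt allele in every *other* genome when reads are aligned to
#' the reference. A configurable sharing fraction copies some sites into a
#' second non-reference founder to stress-test marker-uniqueness filters.
#'
#' Each founder additionally gets two evidence-replicate variant sets —
#' independent thinnings of its true read-level SNP set plus a configurable
#' false-positive rate — emulating SNP calls from two sequencing technologies
#' whose intersection the marker pipeline consumes.
#'
#' @param config A [sim_config()].
#' @return Object of class `founder_panel`: list with `layout`, `founder_ids`,
#'   `reference`, `sites` (data.frame `chrom`, `pos`, `ref`, `alt`, `owner`),
#'   `carriers` (site x founder logical matrix of alt-allele carriage),
#'   `introgression`, `evidence` (per founder, two `variant_set` replicates)
#'   and the `config`.
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- config$layout
  founders <- config$founder_ids
  nf <- length(founders)
  with_seed(child_seed(config$seed, "founders"), {
    chroms <- list()
    for (ci in seq_len(nrow(layout))) {
      chr <- layout$chrom[ci]
      L <- layout$length_bp[ci]
      n_base <- stats::rpois(nf, config$snp_density * L / 1e6)
      blocks <- config$introgression
      if (is.null(blocks)) {
        blocks <- data.frame(founder = character(), chrom = character(),
                             start = numeric(), end = numeric(),
                             multiplier = numeric(), stringsAsFactors = FALSE)
      }
      blocks <- blocks[blocks$chrom == chr, , drop = FALSE]
      n_block <- if (nrow(blocks)) {
        vapply(seq_len(nrow(blocks)), function(i) {
          f <- match(blocks$founder[i], founders)
          stats::rpois(1, config$snp_density[f] * (blocks$multiplier[i] - 1) *
                         (blocks$end[i] - blocks$start[i]) / 1e6)
        }, 0L)
      } else integer()
      if (sum(n_base) + sum(n_block) > L) {
        stop("SNP density too high: sites exceed length of ", chr)
      }
      # block sites first, then genome-wide base sites avoiding them
      pos <- integer(); owner <- character()
      for (i in seq_along(n_block)) {
        bl <- blocks$end[i] - blocks$start[i]
        p <- sample.int(bl, n_block[i]) + blocks$start[i]
        pos <- c(pos, p)
        owner <- c(owner, rep(blocks$founder[i], n_block[i]))
      }
      need <- sum(n_base)
      base <- sample.int(L, need)
      while (any(base %in% pos) || anyDuplicated(base)) {
        bad <- duplicated(base) | base %in% pos
        base[bad] <- sample.int(L, sum(bad))
      }
      pos <- c(pos, base)
      owner <- c(owner, rep(founders, n_base))
      o <- order(pos)
      pos <- pos[o]; owner <- owner[o]
      n <- length(pos)
      ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
      alt <- sample(c("A", "C", "G"), n, replace = TRUE)
      alt[alt == ref] <- "T"
      chroms[[chr]] <- data.frame(chrom = rep(chr, n), pos = pos, ref = ref,
                                  alt = alt, owner = owner,
                                  stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, chroms)
    rownames(sites) <- NULL

    carriers <- matrix(FALSE, nrow(sites), nf, dimnames = list(NULL, founders))
    ref_owned <- sites$owner == config$reference
    carriers[ref_owned, setdiff(founders, config$reference)] <- TRUE
    for (f in setdiff(founders, config$reference)) {
      carriers[sites$owner == f, f] <- TRUE
    }
    if (config$share_frac > 0 && nf > 2) {
      nonref <- setdiff(founders, config$reference)
      for (f in nonref) {
        idx <- which(sites$owner == f)
        k <- floor(config$share_frac * length(idx))
        if (k > 0) {
          pick <- sample(idx, k)
          other <- sample(setdiff(nonref, f), k, replace = TRUE)
          carriers[cbind(pick, match(other, founders))] <- TRUE
        }
      }
    }
    panel <- structure(list(layout = layout, founder_ids = founders,
                            reference = config$reference, sites = sites,
                            carriers = carriers,
                            introgression = config$introgression,
                            evidence = NULL, config = config),
                       class = "founder_panel")
    panel$evidence <- lapply(stats::setNames(founders, founders), function(f) {
      lapply(1:2, function(r) {
        observe_genome(panel, f, source = paste0(f, "_rep", r),
                       seed = child_seed(config$seed, paste0("ev_", f, "_", r)))
      })
    })
    panel
  })
}

#' @export
print.founder_panel <- function(x, ...) {
  cat(sprintf("founder_panel: %d founders (reference %s), %d SNP sites, %d chromosomes\n",
              length(x$founder_ids), x$reference, nrow(x$sites),
              nrow(x$layout)))
  print(table(owner = x$sites$owner))
  invisible(x)
}

#' True variant set of one founder genome
#'
#' All sites where the founder carries the alt allele (relative to the
#' reference founder's assembly); an inbred founder is homozygous at each.
#'
#' @param panel A [simulate_founders()] panel.
#' @param founder Founder id.
#' @export
founder_variants <- function(panel, founder) {
  genome_variants(panel, c(founder, founder), source = paste0(founder, "_truth"))
}

#' True read-level variant set of a genome built from haplotypes
#'
#' `hap_ids` lists the founder haplotypes the genome is made of (with
#' multiplicity: an inbred is `c(f, f)`, an F1 hybrid `c(a, b)`). Genotype
#' class is `hom_alt` where every haplotype carries the alt allele and `het`
#' where only some do.
#'
#' @param panel A founder panel.
#' @param hap_ids Character vector of founder ids with multiplicity.
#' @param source Evidence tag.
#' @export
genome_variants <- function(panel, hap_ids, source = "truth") {
  stopifnot(all(hap_ids %in% panel$founder_ids))
  nalt <- rowSums(panel$carriers[, hap_ids, drop = FALSE])
  keep <- nalt > 0
  variant_set(panel$sites$chrom[keep], panel$sites$pos[keep],
              panel$sites$ref[keep], panel$sites$alt[keep],
              ifelse(nalt[keep] == length(hap_ids), "hom_alt", "het"),
              source = source, layout = panel$layout)
}

#' Noisy observation of a genome's SNP calls (one evidence replicate)
#'
#' Thins the true read-level variant set at the configured dropout rate and
#' adds false-positive calls at random positions, emulating one sequencing
#' technology's imperfect call set.
#'
#' @inheritParams genome_variants
#' @param seed Integer seed.
#' @param dropout,fp_per_mb Override the panel config's evidence noise.
#' @export
observe_genome <- function(panel, hap_ids, source = "obs", seed,
                           dropout = panel$config$evidence_dropout,
                           fp_per_mb = panel$config$evidence_fp_per_mb) {
  truth <- genome_variants(panel, if (length(hap_ids) == 1)
    c(hap_ids, hap_ids) else hap_ids, source = source)
  with_seed(seed, {
    keep <- stats::runif(nrow(truth)) >= dropout
    obs <- truth[keep, , drop = FALSE]
    tot_mb <- sum(panel$layout$length_bp) / 1e6
    n_fp <- stats::rpois(1, fp_per_mb * tot_mb)
    if (n_fp > 0) {
      ci <- sample.int(nrow(panel$layout), n_fp, replace = TRUE,
                       prob = panel$layout$length_bp)
      fpos <- floor(stats::runif(n_fp) * panel$layout$length_bp[ci]) + 1
      ref <- sample(c("A", "C", "G", "T"), n_fp, replace = TRUE)
      alt <- sample(c("A", "C", "G"), n_fp, replace = TRUE)
      alt[alt == ref] <- "T"
      fp <- data.frame(chrom = panel$layout$chrom[ci], pos = fpos,
                       ref = ref, alt = alt,
                       genotype_class = sample(c("het", "hom_alt"), n_fp,
                                               replace = TRUE),
                       source = source, stringsAsFactors = FALSE)
      fp <- fp[!paste(fp$chrom, fp$pos) %in% paste(obs$chrom, obs$pos) &
                 !duplicated(paste(fp$chrom, fp$pos)), , drop = FALSE]
      obs <- rbind(as.data.frame(obs), fp)
    }
    validate_variant_set(obs, panel$layout)
  })
}

#' Cross two founders into an F1 hybrid genome
#'
#' @param panel A founder panel.
#' @param founder_a,founder_b Distinct founder ids in the panel.
#' @param id Sample label (default `"a x b"` collapsed).
#' @return Object of class `hybrid_genome` holding the two haplotype ids.
#' @export
make_hybrid <- function(panel, founder_a, founder_b,
                        id = paste(founder_a, founder_b, sep = "x")) {
  if (!founder_a %in% panel$founder_ids) stop("unknown founder: ", founder_a)
  if (!founder_b %in% panel$founder_ids) stop("unknown founder: ", founder_b)
  if (founder_a == founder_b) {
    stop("a hybrid requires two distinct founders (got ", founder_a, " twice)")
  }
  structure(list(id = id, parents = c(founder_a, founder_b), panel = panel),
            class = "hybrid_genome")
}

#' Genotypes of a hybrid at the panel's SNP sites
#'
#' @param hybrid A [make_hybrid()] genome.
#' @return data.frame `chrom`, `pos`, `n_alt` (0, 1 or 2 alt copies).
#' @export
hybrid_genotypes <- function(hybrid) {
  p <- hybrid$panel
  data.frame(chrom = p$sites$chrom, pos = p$sites$pos,
             n_alt = rowSums(p$carriers[, hybrid$parents, drop = FALSE]),
             stringsAsFactors = FALSE)
}

#' Draw a gamete from a hybrid
#'
#' Clonal mode returns an unreduced gamete genetically identical to the
#' parent: two chromatids per chromosome, one per parental haplotype, no
#' crossovers. Meiotic mode returns one recombinant chromatid per chromosome:
#' the crossover count is Poisson with the configured rate (with an optional
#' obligate-crossover floor of one), breakpoint positions are uniform, and
#' segments alternate between the two parental haplotypes.
#'
#' @param hybrid A [make_hybrid()] genome.
#' @param mode `"clonal"` or `"meiotic"`.
#' @param config A [sim_config()] (crossover model parameters).
#' @param seed Integer seed.
#' @return Object of class `gamete`: `chromatids` is a list of chromatid
#'   mosaics (each a per-chromosome data.frame `start`, `end`, `source` in
#'   0-based half-open coordinates), `breakpoints` a per-chromosome vector of
#'   crossover positions (truth).
#' @export
simulate_gamete <- function(hybrid, mode = c("clonal", "meiotic"),
                            config = hybrid$panel$config, seed) {
  mode <- match.arg(mode)
  layout <- hybrid$panel$layout
  a <- hybrid$parents[1]; b <- hybrid$parents[2]
  whole <- function(src) {
    stats::setNames(lapply(seq_len(nrow(layout)), function(i) {
      data.frame(start = 0, end = layout$length_bp[i], source = src,
                 stringsAsFactors = FALSE)
    }), layout$chrom)
  }
  empty_bp <- stats::setNames(lapply(seq_len(nrow(layout)), function(i)
    numeric()), layout$chrom)
  if (mode == "clonal") {
    chromatids <- list(whole(a), whole(b))
    breakpoints <- empty_bp
  } else {
    with_seed(seed, {
      chromatid <- list(); breakpoints <- list()
      for (i in seq_len(nrow(layout))) {
        L <- layout$length_bp[i]
        n_co <- stats::rpois(1, config$crossover_rate)
        if (config$obligate_co) n_co <- max(1L, n_co)
        bp <- sort(sample.int(L - 1, min(n_co, L - 1)))
        first <- sample(c(a, b), 1)
        bounds <- c(0, bp, L)
        src <- rep(c(first, setdiff(c(a, b), first)),
                   length.out = length(bounds) - 1)
        chromatid[[layout$chrom[i]]] <-
          data.frame(start = bounds[-length(bounds)], end = bounds[-1],
                     source = src, stringsAsFactors = FALSE)
        breakpoints[[layout$chrom[i]]] <- bp
      }
      chromatids <- list(chromatid)
    })
  }
  structure(list(parent_id = hybrid$id, parents = hybrid$parents, mode = mode,
                 chromatids = chromatids, breakpoints = breakpoints,
                 panel = hybrid$panel),
            class = "gamete")
}

#' Fuse two gametes into an offspring genome
#'
#' The offspring's chromosome copies are the union of the two gametes'
#' chromatids: two clonal (diploid) gametes give a tetraploid carrying all
#' four grandparental haplotypes; two meiotic chromatids give a recombinant
#' diploid. Optionally one chromosome copy loses a terminal segment
#' (chromosome truncation), either at the configured random rate or as an
#' explicit injected event.
#'
#' @param gamete_m,gamete_p Two [simulate_gamete()] gametes over the same
#'   panel.
#' @param config A [sim_config()] (`truncation_prob`, `truncation_frac`).
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @param truncation Optional explicit event: data.frame with columns
#'   `copy` (index into the offspring's copies), `chrom`, `start`, `end`
#'   (0-based half-open interval to delete). Overrides the random model.
#' @return Object of class `offspring_genome` with `copies` (list of
#'   chromatid mosaics), `ploidy`, `truncations` and a `truth` record
#'   (gamete modes, all crossover breakpoints, truncations, seed).
#' @export
simulate_offspring <- function(gamete_m, gamete_p,
                               config = gamete_m$panel$config, seed,
                               sample_id = "offspring", truncation = NULL) {
  if (!identical(gamete_m$panel$layout, gamete_p$panel$layout)) {
    stop("gametes come from different genome layouts")
  }
  layout <- gamete_m$panel$layout
  copies <- c(gamete_m$chromatids, gamete_p$chromatids)
  trunc <- data.frame(copy = integer(), chrom = character(),
                      start = numeric(), end = numeric(),
                      lost_source = character(), stringsAsFactors = FALSE)
  with_seed(seed, {
    if (is.null(truncation) && config$truncation_prob > 0 &&
        stats::runif(1) < config$truncation_prob) {
      ci <- sample.int(nrow(layout), 1)
      L <- layout$length_bp[ci]
      frac <- stats::runif(1, config$truncation_frac[1],
                           config$truncation_frac[2])
      at_end <- stats::runif(1) < 0.5
      truncation <- data.frame(copy = sample.int(length(copies), 1),
                               chrom = layout$chrom[ci],
                               start = if (at_end) round(L * (1 - frac)) else 0,
                               end = if (at_end) L else round(L * frac),
                               stringsAsFactors = FALSE)
    }
  })
  if (!is.null(truncation) && nrow(truncation)) {
    for (i in seq_len(nrow(truncation))) {
      k <- truncation$copy[i]; chr <- truncation$chrom[i]
      s <- truncation$start[i]; e <- truncation$end[i]
      iv <- copies[[k]][[chr]]
      lost <- iv$source[iv$start < e & iv$end > s]
      keep <- list()
      for (j in seq_len(nrow(iv))) {
        # parts of interval j outside [s, e)
        if (iv$start[j] < s) {
          keep[[length(keep) + 1]] <- data.frame(
            start = iv$start[j], end = min(iv$end[j], s),
            source = iv$source[j], stringsAsFactors = FALSE)
        }
        if (iv$end[j] > e) {
          keep[[length(keep) + 1]] <- data.frame(
            start = max(iv$start[j], e), end = iv$end[j],
            source = iv$source[j], stringsAsFactors = FALSE)
        }
      }
      copies[[k]][[chr]] <- if (length(keep)) do.call(rbind, keep) else
        data.frame(start = numeric(), end = numeric(), source = character())
      trunc <- rbind(trunc, data.frame(
        copy = k, chrom = chr, start = s, end = e,
        lost_source = paste(unique(lost), collapse = "+"),
        stringsAsFactors = FALSE))
    }
  }
  modes <- c(gamete_m$mode, gamete_p$mode)
  truth <- list(
    sample_id = sample_id, gamete_modes = modes,
    breakpoints = list(maternal = gamete_m$breakpoints,
                       paternal = gamete_p$breakpoints),
    truncations = trunc, seed = seed
  )
  structure(list(sample_id = sample_id, ploidy = length(copies),
                 copies = copies, truncations = trunc, truth = truth,
                 panel = gamete_m$panel, layout = layout),
            class = "offspring_genome")
}

#' @export
print.offspring_genome <- function(x, ...) {
  cat(sprintf("offspring_genome '%s': ploidy %d, gamete modes %s, %d truncation(s)\n",
              x$sample_id, x$ploidy, paste(x$truth$gamete_modes, collapse = "+"),
              nrow(x$truncations)))
  invisible(x)
}

#' Copy-number segments of an offspring genome
#'
#' @param offspring An [simulate_offspring()] genome.
#' @return data.frame `chrom`, `start`, `end`, `cn` (local chromosome copy
#'   number); without truncation `cn == ploidy` everywhere.
#' @export
copy_number_segments <- function(offspring) {
  layout <- offspring$layout
  out <- list()
  for (ci in seq_len(nrow(layout))) {
    chr <- layout$chrom[ci]
    ivs <- lapply(offspring$copies, `[[`, chr)
    bounds <- sort(unique(c(0, layout$length_bp[ci],
                            unlist(lapply(ivs, function(v) c(v$start, v$end))))))
    for (j in seq_len(length(bounds) - 1)) {
      s <- bounds[j]; e <- bounds[j + 1]
      cn <- sum(vapply(ivs, function(v)
        any(v$start <= s & v$end >= e), logical(1)))
      out[[length(out) + 1]] <- data.frame(chrom = chr, start = s, end = e,
                                           cn = cn, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  # merge adjacent equal-cn segments
  keep <- c(TRUE, res$cn[-1] != res$cn[-nrow(res)] |
              res$chrom[-1] != res$chrom[-nrow(res)])
  grp <- cumsum(keep)
  data.frame(chrom = tapply(res$chrom, grp, `[`, 1),
             start = as.numeric(tapply(res$start, grp, min)),
             end = as.numeric(tapply(res$end, grp, max)),
             cn = as.numeric(tapply(res$cn, grp, `[`, 1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Per-site local copy number and alt-allele copy count of an offspring
# at the given (chrom, pos) sites. Sites absent from the panel (e.g.
# false-positive marker positions) have alt_copies = 0.
site_copy_state <- function(offspring, chrom, pos) {
  panel <- offspring$panel
  idx <- match(paste(chrom, pos), paste(panel$sites$chrom, panel$sites$pos))
  n <- length(pos)
  cn <- integer(n); alt <- integer(n)
  p0 <- pos - 1
  for (chr in unique(chrom)) {
    sel <- which(chrom == chr)
    for (cp in offspring$copies) {
      iv <- cp[[chr]]
      if (is.null(iv) || !nrow(iv)) next
      o <- order(iv$start)
      iv <- iv[o, , drop = FALSE]
      k <- findInterval(p0[sel], iv$start)
      covered <- k >= 1 & p0[sel] < iv$end[pmax(k, 1)]
      cn[sel] <- cn[sel] + covered
      src <- ifelse(covered, iv$source[pmax(k, 1)], NA)
      has_alt <- !is.na(src) & !is.na(idx[sel]) &
        panel$carriers[cbind(pmax(idx[sel], 1), match(src, panel$founder_ids))]
      has_alt[is.na(has_alt)] <- FALSE
      alt[sel] <- alt[sel] + has_alt
    }
  }
  list(cn = cn, alt_copies = alt)
}

#' True genotype of an offspring at given sites
#'
#' @param offspring An offspring genome.
#' @param sites data.frame with `chrom` and `pos` (1-based).
#' @return data.frame with `chrom`, `pos`, `cn`, `alt_copies` and
#'   `genotype` in `{hom_ref, het, hom_alt, missing}` (missing where local
#'   copy number is 0).
#' @export
offspring_genotypes <- function(offspring, sites) {
  st <- site_copy_state(offspring, sites$chrom, sites$pos)
  geno <- ifelse(st$cn == 0, "missing",
                 ifelse(st$alt_copies == 0, "hom_ref",
                        ifelse(st$alt_copies == st$cn, "hom_alt", "het")))
  data.frame(chrom = sites$chrom, pos = sites$pos, cn = st$cn,
             alt_copies = st$alt_copies, genotype = geno,
             stringsAsFactors = FALSE)
}

#' Sample sequencing read counts at marker sites
#'
#' Per site, depth is Poisson with mean `mean_depth * cn / ploidy` (local
#' copy-number losses reduce coverage proportionally) and the alt read count
#' is binomial with success probability `p' = p (1 - e) + (1 - p) e`, where
#' `p` is the local alt-copy fraction and `e` the allele miscall rate.
#' Zero-depth sites are retained with counts (0, 0).
#'
#' @param offspring An offspring genome.
#' @param sites data.frame with `chrom`, `pos`.
#' @param mean_depth Mean depth at full copy number (> 0).
#' @param error_rate Allele miscall rate in [0, 0.5).
#' @param seed Integer seed.
#' @param sample_id Label used in the output table.
#' @return A [count_table()].
#' @export
simulate_reads <- function(offspring, sites,
                           mean_depth = offspring$panel$config$mean_depth,
                           error_rate = offspring$panel$config$error_rate,
                           seed, sample_id = offspring$sample_id) {
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("error_rate must be in [0, 0.5)")
  }
  st <- site_copy_state(offspring, sites$chrom, sites$pos)
  p <- ifelse(st$cn > 0, st$alt_copies / pmax(st$cn, 1), 0)
  p_err <- p * (1 - error_rate) + (1 - p) * error_rate
  with_seed(seed, {
    depth <- stats::rpois(length(p), mean_depth * st$cn / offspring$ploidy)
    alt <- stats::rbinom(length(p), depth, p_err)
  })
  count_table(sample_id = rep(sample_id, length(p)), chrom = sites$chrom,
              pos = sites$pos, ref_count = depth - alt, alt_count = alt)
}
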