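#' Classify a window's allele-frequency state
#'
#' Diploid: frequencies near 0, 0.5 and 1 map to `hom_ref`, `het` and
#' `hom_alt`; anything between the bands is ambiguous (`NA`). Tetraploid:
#' the frequency is snapped to the nearest point of the dosage grid
#' {0, 1/4, 1/2, 3/4, 1} (states `dose_0` .. `dose_4`, counting alt copies)
#' when within `t_dose` of it, else ambiguous. Missing frequencies stay
#' unclassified.
#'
#' @param mean_af Numeric vector of window mean frequencies (may contain
#'   `NA`).
#' @param ploidy 2 or 4.
#' @param t_low Diploid homozygous band half-width (af < t_low is `hom_ref`,
#'   af > 1 - t_low is `hom_alt`).
#' @param t_het Diploid heterozygous band half-width around 0.5.
#' @param t_dose Tetraploid dosage band half-width around each grid point.
#' @return Character vector of states (`NA` = ambiguous/unclassified).
#' @export
classify_window_state <- function(mean_af, ploidy,
                                  t_low = 0.15, t_het = 0.15, t_dose = 0.08) {
  if (!ploidy %in% c(2, 4)) stop("ploidy must be 2 or 4")
  if (ploidy == 2) {
    ifelse(is.na(mean_af), NA_character_,
           ifelse(mean_af < t_low, "hom_ref",
                  ifelse(mean_af > 1 - t_low, "hom_alt",
                         ifelse(abs(mean_af - 0.5) <= t_het, "het",
                                NA_character_))))
  } else {
    grid <- 0:4 / 4
    k <- vapply(mean_af, function(a) {
      if (is.na(a)) return(NA_integer_)
      j <- which.min(abs(grid - a))
      if (abs(grid[j] - a) <= t_dose) j - 1L else NA_integer_
    }, integer(1))
    ifelse(is.na(k), NA_character_, paste0("dose_", k))
  }
}

# Balanced (fully heterozygous) state label for a ploidy.
balanced_state <- function(ploidy) if (ploidy == 2) "het" else "dose_2"

#' Segment window states into runs
#'
#' Collapses each chromosome's ordered window states into segments: runs of
#' at least `min_run` consecutive same-state windows. Shorter runs are
#' absorbed into the larger neighbouring run; ambiguous windows never break a
#' run and are absorbed into whichever segment surrounds them. Segment bounds
#' span from the first to the last *confident* window (windows whose own
#' state equals the segment state), which keeps boundary uncertainty honest.
#'
#' @param profile A `window_profile` (needs `chrom`, `win_start`, `win_end`).
#' @param state Character vector of per-window states
#'   ([classify_window_state()]).
#' @param min_run Minimum run length in windows (default 5).
#' @return data.frame of segments: `chrom`, `start`, `end`, `state`,
#'   `n_windows`, `mean_af`, plus confident-window bounds `conf_start`,
#'   `conf_end` used for crossover intervals.
#' @export
segment_states <- function(profile, state, min_run = 5) {
  stopifnot(length(state) == nrow(profile))
  segs <- list()
  for (chr in unique(profile$chrom)) {
    sel <- which(profile$chrom == chr)
    st <- state[sel]
    obs <- which(!is.na(st))
    if (!length(obs)) next
    lab <- st[obs]
    # iteratively absorb sub-minimum runs into their larger neighbour
    repeat {
      r <- rle(lab)
      if (length(r$lengths) <= 1 || all(r$lengths >= min_run)) break
      j <- which(r$lengths < min_run)[which.min(r$lengths[r$lengths < min_run])]
      ends <- cumsum(r$lengths)
      begs <- ends - r$lengths + 1
      left_len <- if (j > 1) r$lengths[j - 1] else -1
      right_len <- if (j < length(r$lengths)) r$lengths[j + 1] else -1
      take <- if (left_len >= right_len) r$values[j - 1] else r$values[j + 1]
      lab[begs[j]:ends[j]] <- take
    }
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    begs <- ends - r$lengths + 1
    for (j in seq_along(r$lengths)) {
      w <- obs[begs[j]:ends[j]]           # window indices within chromosome
      conf <- w[st[w] == r$values[j]]
      if (!length(conf)) conf <- w
      rows <- sel[w]
      segs[[length(segs) + 1]] <- data.frame(
        chrom = chr,
        start = profile$win_start[sel[w[1]]],
        end = profile$win_end[sel[w[length(w)]]],
        state = r$values[j],
        n_windows = length(w),
        mean_af = mean(profile$mean_af[rows], na.rm = TRUE),
        conf_start = profile$win_start[sel[conf[1]]],
        conf_end = profile$win_end[sel[conf[length(conf)]]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(segs)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), state = character(),
                      n_windows = integer(), mean_af = numeric(),
                      conf_start = numeric(), conf_end = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, segs)
}

#' Call crossovers from state segments
#'
#' One call per adjacent pair of same-chromosome segments with different
#' states. The breakpoint is bracketed by the last confident window of the
#' left segment and the first confident window of the right segment; the
#' point estimate is the midpoint between the left segment's confident end
#' and the right segment's confident start. With symmetric state bands the
#' windows straddling the true breakpoint classify ambiguous on both sides,
#' so the midpoint is an unbiased estimate up to window granularity.
#'
#' @param segments Output of [segment_states()].
#' @return data.frame: `chrom`, `lo`, `hi` (uncertainty interval),
#'   `midpoint`, `left_state`, `right_state`.
#' @export
call_crossovers <- function(segments) {
  out <- list()
  if (nrow(segments) > 1) {
    for (i in seq_len(nrow(segments) - 1)) {
      if (segments$chrom[i] != segments$chrom[i + 1]) next
      if (segments$state[i] == segments$state[i + 1]) next
      a <- segments$conf_end[i]
      b <- segments$conf_start[i + 1]
      out[[length(out) + 1]] <- data.frame(
        chrom = segments$chrom[i],
        lo = min(a, b), hi = max(a, b, min(a, b) + 1),
        midpoint = (a + b) / 2,
        left_state = segments$state[i],
        right_state = segments$state[i + 1],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), lo = numeric(), hi = numeric(),
                      midpoint = numeric(), left_state = character(),
                      right_state = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Detect aneuploidy / chromosome truncation from joint AF + coverage shift
#'
#' A window is anomalous when its allele frequency deviates from the expected
#' balanced value by at least `t_af` *and* its normalized coverage deviates
#' from 1 by at least `t_cov` (the AND rule: allelic bias alone, e.g. from
#' mapping artifacts, does not qualify). Runs of at least `min_run`
#' anomalous windows with a consistent coverage direction become segments.
#'
#' Boundaries are refined by the half-shift crossing: within a sliding-window
#' profile the windowed deviation ramps linearly across a true copy-number
#' breakpoint and passes half of its plateau value in the window centred on
#' the breakpoint, so the centre of the first/last window whose deviation
#' exceeds half the plateau estimates the boundary to about one window step.
#' Segments touching a chromosome end are clamped to it.
#'
#' For a balanced tetraploid (expected 0.5), loss of one copy moves the
#' frequency to 1/3 or 2/3: an upward shift means the lost copy carried the
#' reference-founder allele and vice versa; `hap_labels = c(ref = ..., alt
#' = ...)` translates that into a haplotype name.
#'
#' @param profile A `window_profile` with `mean_af` and `mean_norm_cov`.
#' @param expected_af Expected balanced allele frequency (default 0.5).
#' @param t_af Minimum absolute AF deviation (default 0.10).
#' @param t_cov Minimum absolute coverage deviation from 1 (default 0.15).
#' @param min_run Minimum run length in windows (default 5).
#' @param rule `"and"` (default) or `"or"` — whether both criteria or either
#'   must hold (the OR mode exists for sensitivity analysis only).
#' @param hap_labels Optional named character, `c(ref = , alt = )`, for
#'   naming the inferred lost haplotype in a two-founder balanced design.
#' @return data.frame of segments: `chrom`, `start`, `end`, `direction`
#'   (`loss`/`gain` from the coverage sign), `af_shift` (signed plateau
#'   deviation), `cov_ratio` (plateau normalized coverage), `n_windows`,
#'   `inferred_lost_haplotype` (`NA` when not inferable).
#' @export
detect_aneuploidy <- function(profile, expected_af = 0.5,
                              t_af = 0.10, t_cov = 0.15, min_run = 5,
                              rule = c("and", "or"), hap_labels = NULL) {
  rule <- match.arg(rule)
  if (expected_af < 0 || expected_af > 1) stop("expected_af must be in [0, 1]")
  dev_af <- profile$mean_af - expected_af
  dev_cov <- profile$mean_norm_cov - 1
  hit_af <- !is.na(dev_af) & abs(dev_af) >= t_af
  hit_cov <- !is.na(dev_cov) & abs(dev_cov) >= t_cov
  hit <- if (rule == "and") hit_af & hit_cov else hit_af | hit_cov
  out <- list()
  for (chr in unique(profile$chrom)) {
    sel <- which(profile$chrom == chr)
    h <- hit[sel]
    sgn <- sign(dev_cov[sel])
    # close sub-min_run gaps between qualifying runs so that single noisy
    # windows cannot split one event into two
    g <- rle(h)
    if (length(g$lengths) > 2) {
      ends_g <- cumsum(g$lengths)
      for (j in 2:(length(g$lengths) - 1)) {
        if (!g$values[j] && g$lengths[j] < min_run &&
            g$values[j - 1] && g$values[j + 1]) {
          h[(ends_g[j] - g$lengths[j] + 1):ends_g[j]] <- TRUE
        }
      }
    }
    r <- rle(h & TRUE)
    ends <- cumsum(r$lengths)
    begs <- ends - r$lengths + 1
    for (j in which(r$values & r$lengths >= min_run)) {
      w <- begs[j]:ends[j]
      # require a consistent coverage direction across the run
      dir_sign <- sign(sum(sgn[w], na.rm = TRUE))
      if (dir_sign == 0) dir_sign <- 1
      plateau_af <- stats::median(dev_af[sel[w]], na.rm = TRUE)
      plateau_cov <- stats::median(profile$mean_norm_cov[sel[w]], na.rm = TRUE)
      centre <- (profile$win_start[sel] + profile$win_end[sel]) / 2
      half <- abs(plateau_af) / 2
      cross <- !is.na(dev_af[sel]) & abs(dev_af[sel]) >= half &
        sign(dev_af[sel]) == sign(plateau_af)
      # walk out from the run while the half-crossing holds
      lo <- begs[j]
      while (lo > 1 && cross[lo - 1]) lo <- lo - 1
      hi_i <- ends[j]
      while (hi_i < length(sel) && cross[hi_i + 1]) hi_i <- hi_i + 1
      start <- if (lo == 1) 0 else centre[lo]
      end <- if (hi_i == length(sel)) profile$win_end[sel[length(sel)]] else
        centre[hi_i]
      lost <- NA_character_
      if (!is.null(hap_labels) && abs(expected_af - 0.5) < 1e-9) {
        lost <- if (plateau_af > 0) hap_labels[["ref"]] else
          hap_labels[["alt"]]
      }
      out[[length(out) + 1]] <- data.frame(
        chrom = chr, start = start, end = end,
        direction = if (dir_sign < 0) "loss" else "gain",
        af_shift = plateau_af, cov_ratio = plateau_cov,
        n_windows = length(w), inferred_lost_haplotype = lost,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      direction = character(), af_shift = numeric(),
                      cov_ratio = numeric(), n_windows = integer(),
                      inferred_lost_haplotype = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  # boundary refinement maps every qualifying run of one event onto the same
  # interval; merge overlapping same-direction segments into one event
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  merged <- res[1, , drop = FALSE]
  if (nrow(res) > 1) {
    for (i in 2:nrow(res)) {
      k <- nrow(merged)
      if (res$chrom[i] == merged$chrom[k] &&
          res$direction[i] == merged$direction[k] &&
          res$start[i] <= merged$end[k]) {
        w <- merged$n_windows[k] + res$n_windows[i]
        merged$af_shift[k] <- (merged$af_shift[k] * merged$n_windows[k] +
                                 res$af_shift[i] * res$n_windows[i]) / w
        merged$cov_ratio[k] <- (merged$cov_ratio[k] * merged$n_windows[k] +
                                  res$cov_ratio[i] * res$n_windows[i]) / w
        merged$end[k] <- max(merged$end[k], res$end[i])
        merged$n_windows[k] <- w
      } else {
        merged <- rbind(merged, res[i, ])
      }
    }
  }
  rownames(merged) <- NULL
  merged
}

#' Classify an offspring sample as clonal, recombinant or anomalous
#'
#' Runs the full per-sample inference: window-state classification,
#' aneuploidy detection, state segmentation and crossover calling. Windows
#' inside aneuploidy segments are masked before segmentation, so a dosage
#' anomaly explained by copy-number change is not misread as a crossover.
#' A sample is *clonal* when it has no crossover calls and at least
#' `1 - f_tol` of its classified windows are in the balanced (fully
#' heterozygous) state; *recombinant* when it has at least one crossover;
#' otherwise *anomalous*. Aneuploidy co-occurring with a clonal or
#' recombinant pattern is reported as a `+anomalous` composite label.
#'
#' @param profile A [build_profile()] result.
#' @param ploidy 2 or 4.
#' @param t_low,t_het,t_dose See [classify_window_state()].
#' @param t_af,t_cov See [detect_aneuploidy()].
#' @param min_run Minimum run length (windows) for both segmentation and
#'   aneuploidy.
#' @param f_tol Tolerated fraction of classified windows off the balanced
#'   state for a clonal call (default 0.02).
#' @param hap_labels Passed to [detect_aneuploidy()].
#' @return List of class `sample_classification`: `sample_id`, `label`,
#'   `n_crossovers`, `n_aneuploid_segments`, `fraction_balanced_windows`,
#'   plus the `segments`, `crossovers` and `aneuploidy` tables.
#' @export
classify_sample <- function(profile, ploidy,
                            t_low = 0.15, t_het = 0.15, t_dose = 0.08,
                            t_af = 0.10, t_cov = 0.15, min_run = 5,
                            f_tol = 0.02, hap_labels = NULL) {
  aneu <- detect_aneuploidy(profile, expected_af = 0.5, t_af = t_af,
                            t_cov = t_cov, min_run = min_run,
                            hap_labels = hap_labels)
  state <- classify_window_state(profile$mean_af, ploidy,
                                 t_low = t_low, t_het = t_het,
                                 t_dose = t_dose)
  centre <- (profile$win_start + profile$win_end) / 2
  if (nrow(aneu)) {
    for (i in seq_len(nrow(aneu))) {
      state[profile$chrom == aneu$chrom[i] & centre >= aneu$start[i] &
              centre < aneu$end[i]] <- NA_character_
    }
  }
  segs <- segment_states(profile, state, min_run = min_run)
  xo <- call_crossovers(segs)
  classified <- !is.na(state)
  frac_bal <- if (any(classified)) {
    mean(state[classified] == balanced_state(ploidy))
  } else NA_real_
  base <- if (nrow(xo) >= 1) "recombinant" else if (!is.na(frac_bal) &&
                                                    frac_bal >= 1 - f_tol) {
    "clonal"
  } else "anomalous"
  label <- if (nrow(aneu) && base != "anomalous") {
    paste0(base, "+anomalous")
  } else base
  structure(list(sample_id = attr(profile, "sample_id"),
                 label = label, n_crossovers = nrow(xo),
                 n_aneuploid_segments = nrow(aneu),
                 fraction_balanced_windows = frac_bal,
                 segments = segs, crossovers = xo, aneuploidy = aneu),
            class = "sample_classification")
}

#' @export
print.sample_classification <- function(x, ...) {
  cat(sprintf("sample %s: %s (%d crossover(s), %d aneuploid segment(s), %.1f%% balanced windows)\n",
              x$sample_id %||% "?", x$label, x$n_crossovers,
              x$n_aneuploid_segments, 100 * x$fraction_balanced_windows))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
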