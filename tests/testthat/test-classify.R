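test_that("window states map onto the diploid bands and tetraploid dosage grid", {
  expect_equal(classify_window_state(0.5, 2), "het")
  expect_equal(classify_window_state(0.02, 2), "hom_ref")
  expect_equal(classify_window_state(0.98, 2), "hom_alt")
  expect_true(is.na(classify_window_state(0.3, 2)))       # between bands
  expect_true(is.na(classify_window_state(NA, 2)))
  expect_equal(classify_window_state(0.68, 4), "dose_3")  # nearest 0.75
  expect_equal(classify_window_state(c(0.01, 0.26, 0.5), 4),
               c("dose_0", "dose_1", "dose_2"))
  expect_true(is.na(classify_window_state(0.6667, 4)))    # off-grid (cn loss)
  expect_error(classify_window_state(0.5, 3), "ploidy")
})

make_profile <- function(states_af, chrom = "c1", W = 1e6, s = 5e4) {
  n <- length(states_af)
  structure(data.frame(chrom = chrom, win_start = (seq_len(n) - 1) * s,
                       win_end = (seq_len(n) - 1) * s + W,
                       n_markers = 50, mean_af = states_af,
                       mean_norm_cov = 1, stringsAsFactors = FALSE),
            W = W, s = s, class = c("window_profile", "data.frame"))
}

test_that("state runs segment correctly and isolated windows are absorbed", {
  prof <- make_profile(rep(0.5, 100))
  st <- classify_window_state(prof$mean_af, 2)
  segs <- segment_states(prof, st)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$state, "het")
  expect_equal(segs$start, 0)
  expect_equal(segs$end, prof$win_end[100])

  prof2 <- make_profile(c(rep(0.5, 40), rep(0.98, 60)))
  segs2 <- segment_states(prof2, classify_window_state(prof2$mean_af, 2))
  expect_equal(segs2$state, c("het", "hom_alt"))
  expect_equal(nrow(call_crossovers(segs2)), 1)

  # one isolated hom window inside a het run is absorbed
  af3 <- rep(0.5, 60); af3[30] <- 0.98
  segs3 <- segment_states(make_profile(af3),
                          classify_window_state(af3, 2))
  expect_equal(nrow(segs3), 1)
  expect_equal(segs3$state, "het")
})

test_that("crossover calls bracket the segment junction with a midpoint estimate", {
  af <- c(rep(0.5, 40), rep(0.02, 40))
  prof <- make_profile(af)
  segs <- segment_states(prof, classify_window_state(af, 2))
  xo <- call_crossovers(segs)
  expect_equal(nrow(xo), 1)
  expect_equal(xo$left_state, "het")
  expect_equal(xo$right_state, "hom_ref")
  junction <- prof$win_start[41]
  expect_lt(abs(xo$midpoint - junction), attr(prof, "W"))
  expect_gte(xo$hi - xo$lo, 1)
  # single segment -> zero calls
  expect_equal(nrow(call_crossovers(segs[1, ])), 0)
})

test_that("simulated F2 crossovers are recovered near their true positions", {
  cfg <- two_founder_config(seed = 95, layout = small_layout(3, 2e7),
                            mean_depth = 20)
  p <- simulate_founders(cfg)
  h <- make_hybrid(p, "R", "B")
  ms <- sim_two_way_markers(p)
  W <- 1e6; s <- 5e4
  n_ok <- 0; n_tot <- 0
  for (i in 1:20) {
    f2 <- make_f2(h, cfg, seed = 1000 + i, sample_id = paste0("f2_", i))
    pr <- profile_offspring(f2, ms, seed = 2000 + i)
    cl <- classify_sample(pr$profile, ploidy = 2)
    expect_gte(cl$n_crossovers, 1)
    expect_match(cl$label, "recombinant")
    tb <- true_breakpoints(f2)
    for (j in seq_len(nrow(cl$crossovers))) {
      d <- abs(tb$pos[tb$chrom == cl$crossovers$chrom[j]] -
                 cl$crossovers$midpoint[j])
      n_tot <- n_tot + 1
      if (length(d) && min(d) <= W / 2 + s) n_ok <- n_ok + 1
    }
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("simulated clonal tetraploids classify clonal with zero crossovers", {
  cfg <- two_founder_config(seed = 105, layout = small_layout(3, 1e7))
  p <- simulate_founders(cfg)
  h <- make_hybrid(p, "R", "B")
  ms <- sim_two_way_markers(p)
  for (i in 1:10) {
    tet <- make_clonal_tetraploid(h, h, cfg, seed = 3000 + i,
                                  sample_id = paste0("mime_", i))
    pr <- profile_offspring(tet, ms, seed = 4000 + i)
    cl <- classify_sample(pr$profile, ploidy = 4)
    expect_equal(cl$label, "clonal")
    expect_equal(cl$n_crossovers, 0)
  }
})

test_that("aneuploidy requires joint AF and coverage deviation (AND rule)", {
  af <- rep(0.5, 80); cov <- rep(1, 80)
  af[41:80] <- 2 / 3; cov[41:80] <- 0.75
  prof <- make_profile(af); prof$mean_norm_cov <- cov
  seg <- detect_aneuploidy(prof, hap_labels = c(ref = "R", alt = "B"))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$direction, "loss")
  expect_equal(seg$inferred_lost_haplotype, "R")
  expect_equal(seg$cov_ratio, 0.75)
  expect_equal(seg$af_shift, 1 / 6, tolerance = 1e-6)

  # AF deviates but coverage is normal: allelic bias, not aneuploidy
  prof2 <- make_profile(af)
  expect_equal(nrow(detect_aneuploidy(prof2)), 0)
  # no deviation anywhere -> empty
  expect_equal(nrow(detect_aneuploidy(make_profile(rep(0.5, 80)))), 0)
  # but the OR mode does report the AF-only deviation
  expect_equal(nrow(detect_aneuploidy(prof2, rule = "or")), 1)
})

test_that("injected terminal losses are recovered with accurate boundaries", {
  cfg <- two_founder_config(seed = 115, layout = small_layout(3, 2e7))
  p <- simulate_founders(cfg)
  h <- make_hybrid(p, "R", "B")
  ms <- sim_two_way_markers(p)
  bp <- 1.4e7
  tr <- data.frame(copy = 1, chrom = "c2", start = bp, end = 2e7)
  tt <- make_clonal_tetraploid(h, h, cfg, seed = 7, sample_id = "t",
                               truncation = tr)
  pr <- profile_offspring(tt, ms, seed = 8)
  cl <- classify_sample(pr$profile, ploidy = 4,
                        hap_labels = c(ref = "R", alt = "B"))
  expect_match(cl$label, "clonal\\+anomalous")
  expect_equal(cl$n_crossovers, 0)
  aneu <- cl$aneuploidy
  expect_equal(nrow(aneu), 1)
  expect_equal(aneu$chrom, "c2")
  expect_equal(aneu$direction, "loss")
  expect_equal(aneu$inferred_lost_haplotype, "R")
  expect_lt(abs(aneu$start - bp), 2 * 5e4 + 1)  # within two window steps
  expect_equal(aneu$end, 2e7)                   # clamped to the chromosome end
  expect_lt(abs(aneu$cov_ratio - 0.75), 0.05)
  expect_lt(abs(0.5 + aneu$af_shift - 2 / 3), 0.03)
  # unaffected chromosomes stay clean
  expect_false(any(aneu$chrom %in% c("c1", "c3")))
})

test_that("raising deviation thresholds never increases the segment count", {
  cfg <- two_founder_config(seed = 125, layout = small_layout(2, 2e7))
  p <- simulate_founders(cfg)
  h <- make_hybrid(p, "R", "B")
  tr <- data.frame(copy = 1, chrom = "c1", start = 1.2e7, end = 2e7)
  tt <- make_clonal_tetraploid(h, h, cfg, seed = 9, sample_id = "t",
                               truncation = tr)
  pr <- profile_offspring(tt, sim_two_way_markers(p), seed = 10)
  n_prev <- Inf
  for (t_af in c(0.05, 0.10, 0.15, 0.20)) {
    n <- nrow(detect_aneuploidy(pr$profile, t_af = t_af))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  n_prev <- Inf
  for (t_cov in c(0.05, 0.15, 0.24, 0.30)) {
    n <- nrow(detect_aneuploidy(pr$profile, t_cov = t_cov))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("terminal losses of 3 Mb and larger are detected reliably", {
  cfg <- two_founder_config(seed = 135, layout = small_layout(2, 2e7))
  p <- simulate_founders(cfg)
  h <- make_hybrid(p, "R", "B")
  ms <- sim_two_way_markers(p)
  hits <- 0; false_chrom <- 0; n <- 20
  for (i in seq_len(n)) {
    tr <- data.frame(copy = 1, chrom = "c1", start = 1.7e7, end = 2e7) # 3 Mb
    tt <- make_clonal_tetraploid(h, h, cfg, seed = 5000 + i,
                                 sample_id = "t", truncation = tr)
    pr <- profile_offspring(tt, ms, seed = 6000 + i)
    aneu <- detect_aneuploidy(pr$profile)
    hits <- hits + any(aneu$chrom == "c1")
    false_chrom <- false_chrom + sum(aneu$chrom != "c1")
  }
  expect_gte(hits / n, 0.95)
  expect_equal(false_chrom, 0)
})
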