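test_that("dual-evidence intersection keeps concordant records only", {
  a <- toy_vs(c(10, 20, 30, 40), source = "hifi")
  expect_equal(as.data.frame(intersect_evidence(a, a))[, 1:5],
               as.data.frame(a)[, 1:5])   # idempotent up to source tag

  b <- toy_vs(c(10, 20), source = "illumina")
  out <- intersect_evidence(a, b)
  expect_equal(out$pos, c(10, 20))
  expect_equal(out$source, rep("hifi+illumina", 2))

  # same position, different alt allele: no match
  c1 <- toy_vs(10, alt = "G")
  expect_equal(nrow(intersect_evidence(a, c1)), 0)

  # same site, conflicting genotype class: dropped and counted
  d <- toy_vs(c(10, 20), genotype = c("het", "hom_alt"))
  out2 <- intersect_evidence(a, d)
  expect_equal(out2$pos, 20)
  expect_equal(attr(out2, "n_class_conflict"), 1L)
})

test_that("position-level subtraction removes blockers regardless of allele", {
  target <- toy_vs(seq(10, 1000, by = 10))   # 100 sites
  expect_equal(nrow(subtract_overlaps(target, list())), 100)
  blocker <- toy_vs(seq(10, 70, by = 10), alt = "G")  # 7 shared positions
  out <- subtract_overlaps(target, blocker)
  expect_equal(nrow(out), 93)
  expect_false(any(out$pos <= 70))
})

test_that("two-way markers are the homozygous dual-evidence sites minus reference SNPs", {
  target <- variant_set(rep("c1", 6), 1:6 * 100, "A", "T",
                        c(rep("hom_alt", 5), "het"))
  refsnps <- toy_vs(500)
  ms <- derive_two_way_markers(target, refsnps, haplotype = "MT")
  expect_equal(ms$pos, c(100, 200, 300, 400))
  expect_true(all(ms$allele == "alt"))
  expect_true(all(ms$haplotype == "MT"))
  # all-het target -> empty marker set
  allhet <- variant_set(rep("c1", 3), 1:3, "A", "T", "het")
  expect_equal(nrow(derive_two_way_markers(allhet, refsnps)), 0)
})

test_that("simulated two-way markers are diagnostic for exactly one founder", {
  cfg <- two_founder_config(seed = 7)
  p <- simulate_founders(cfg)
  ms <- sim_two_way_markers(p)
  expect_gt(nrow(ms), 500)
  expect_equal(nrow(verify_marker_uniqueness(ms, p)), 0)
})

test_that("four-way derivation yields four disjoint, unique marker lists", {
  cfg <- four_founder_config(seed = 17)
  p <- simulate_founders(cfg)
  ms <- sim_four_way_markers(p)
  expect_setequal(unique(ms$haplotype), c("R", "B", "C", "D"))
  expect_true(all(table(ms$haplotype) > 100))
  expect_equal(anyDuplicated(paste(ms$chrom, ms$pos)), 0L)
  expect_equal(nrow(verify_marker_uniqueness(ms, p)), 0)
  expect_true(all(ms$allele[ms$haplotype == "R"] == "ref"))
  expect_true(all(ms$allele[ms$haplotype != "R"] == "alt"))
})

test_that("founder-shared SNPs are excluded from every marker list", {
  cfg <- four_founder_config(seed = 27, share_frac = 0.2)
  p <- simulate_founders(cfg)
  ms <- sim_four_way_markers(p)
  shared <- rowSums(p$carriers[, c("B", "C", "D")]) > 1 &
    p$sites$owner != "R"
  shared_keys <- paste(p$sites$chrom[shared], p$sites$pos[shared])
  expect_gt(length(shared_keys), 50)
  expect_false(any(paste(ms$chrom, ms$pos) %in% shared_keys))
  expect_equal(nrow(verify_marker_uniqueness(ms, p)), 0)
})

test_that("reference markers require homozygous-alt evidence in every other genome", {
  # toy inputs: site 100 hom-alt in the inbred AND the hybrid; site 200 only
  # in the inbred -> only site 100 becomes a reference marker
  asm <- list(B = toy_vs(c(300)), C = toy_vs(c(400)), D = toy_vs(c(500)))
  reads_inbred <- toy_vs(c(100, 200, 300))
  reads_hybrid <- variant_set(rep("c1", 3), c(100, 400, 500), "A", "T",
                              c("hom_alt", "het", "het"))
  ms <- derive_four_way_markers("R", "B", c("C", "D"), asm,
                                reads_inbred, reads_hybrid)
  ref_m <- ms[ms$haplotype == "R", ]
  expect_equal(ref_m$pos, 100)
  expect_equal(ref_m$allele, "ref")
})

test_that("exclusion masking follows the half-open boundary convention", {
  ms <- marker_set(rep("H", 3), rep("chr9", 3),
                   c(5000000, 5000001, 6000000), "alt")
  out <- apply_exclusion(ms, region_set("chr9", 5000000, 58000000))
  expect_equal(out$pos, 5000000)   # at the 0-based start: outside
  expect_equal(as.integer(attr(out, "n_removed")["H"]), 2L)
  # empty region set is the identity
  out2 <- apply_exclusion(ms, region_set())
  expect_equal(out2$pos, ms$pos)
})

test_that("marker derivation is invariant to input record order", {
  cfg <- four_founder_config(seed = 37)
  p <- simulate_founders(cfg)
  ms1 <- sim_four_way_markers(p)
  # shuffle the evidence replicate rows; sortedness is restored on validation
  p2 <- p
  p2$evidence <- lapply(p$evidence, function(reps) lapply(reps, function(v) {
    validate_variant_set(as.data.frame(v)[sample(nrow(v)), ], p$layout)
  }))
  ms2 <- sim_four_way_markers(p2)
  expect_equal(as.data.frame(ms1), as.data.frame(ms2), ignore_attr = TRUE)
})

test_that("adding blocker SNPs never enlarges a marker list (monotonicity)", {
  target <- toy_vs(seq(100, 5000, by = 100))
  refsnps <- toy_vs(c(300, 600))
  base <- nrow(derive_two_way_markers(target, refsnps))
  for (extra in list(c(900), c(900, 1200), seq(100, 2000, 100))) {
    more <- vs_union(refsnps, toy_vs(extra))
    expect_lte(nrow(derive_two_way_markers(target, more)), base)
  }
})

test_that("deliberately corrupted markers are flagged by the uniqueness oracle", {
  cfg <- four_founder_config(seed = 47)
  p <- simulate_founders(cfg)
  ms <- sim_four_way_markers(p)
  expect_equal(nrow(verify_marker_uniqueness(ms, p)), 0)
  # reassign a C-owned site's marker to haplotype B
  c_site <- which(p$sites$owner == "C")[1]
  key <- paste(p$sites$chrom[c_site], p$sites$pos[c_site])
  bad <- rbind(as.data.frame(ms)[paste(ms$chrom, ms$pos) != key, ],
               data.frame(haplotype = "B", chrom = p$sites$chrom[c_site],
                          pos = p$sites$pos[c_site], allele = "alt"))
  bad <- marker_set(bad$haplotype, bad$chrom, bad$pos, bad$allele)
  expect_equal(nrow(verify_marker_uniqueness(bad, p)), 1)
  # empty marker set -> empty report
  expect_equal(nrow(verify_marker_uniqueness(marker_set(), p)), 0)
})

test_that("marker uniqueness holds across 100 random panels", {
  lay <- genome_layout(c("c1", "c2"), c(2e6, 2e6))
  n_viol <- 0
  for (s in 1:100) {
    cfg <- sim_config(layout = lay, founder_ids = c("R", "B", "C", "D"),
                      introgression = NULL, seed = s)
    p <- simulate_founders(cfg)
    ms <- sim_four_way_markers(p)
    n_viol <- n_viol + nrow(verify_marker_uniqueness(ms, p))
  }
  expect_equal(n_viol, 0)
})
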