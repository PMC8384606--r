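test_that("donor SNP set building applies the mask as a set difference", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tDONOR",
    "chr1D\t100\t.\tA\tG\t.\t.\t.\tGT\t1/1",
    "chr1D\t200\t.\tC\tT\t.\t.\t.\tGT\t1/1",
    "chr1D\t250\t.\tCA\tC\t.\t.\t.\tGT\t1/1",
    "chr1D\t300\t.\tG\tA\t.\t.\t.\tGT\t1/1",
    "chr1D\t400\t.\tT\tC\t.\t.\t.\tGT\t1/1"
  ), tmp)
  mask <- donor_snpset("chr1D", 200L, "T")
  expect_message(ds <- build_donor_snpset(tmp, mask, donor = "tauschii"),
                 "skipped")
  expect_equal(ds$pos, c(100L, 300L, 400L))
  expect_equal(attr(ds, "donor"), "tauschii")
  # empty donor VCF handled
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tDONOR"),
             tmp)
  expect_equal(nrow(build_donor_snpset(tmp)), 0L)
})

test_that("bin match profile counts totals and donor matches per bin", {
  # one line, 3 SNPs in bin 1: two donor-set members, one not; bin 2 empty
  gm <- genotype_matrix(
    data.frame(chrom = "chr1D", pos = c(1000L, 2000L, 3000L, 600000L),
               ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C"),
               stringsAsFactors = FALSE),
    "L1", matrix(c(2L, 2L, 2L, 0L), 4, 1))
  donor <- donor_snpset(rep("chr1D", 3), c(1000L, 2000L, 999L),
                        c("G", "T", "A"))
  prof <- bin_match_profile(gm, "L1", donor, one_chrom_sizes(1e6))
  expect_equal(prof$total, c(3L, 0L))
  expect_equal(prof$matching, c(2L, 0L))
  # all-donor and no-donor bins hit the boundaries
  all_donor <- donor_snpset(rep("chr1D", 3), c(1000L, 2000L, 3000L),
                            c("G", "T", "A"))
  expect_equal(bin_match_profile(gm, "L1", all_donor,
                                 one_chrom_sizes(1e6))$matching[1], 3L)
  none <- donor_snpset("chr9A", 1L, "A")
  expect_equal(bin_match_profile(gm, "L1", none,
                                 one_chrom_sizes(1e6))$matching, c(0L, 0L))
})

test_that("elite baseline is the arithmetic mean of per-line bin counts", {
  calls <- cbind(c(2L, 2L, 2L, 2L, 0L), c(2L, 2L, 0L, 0L, 2L))
  gm <- tiny_gm(calls, pos = c(1L, 2L, 3L, 4L, 600001L))
  base <- elite_baseline(gm, c("S01", "S02"), one_chrom_sizes(1e6))
  expect_equal(base$baseline, c(3, 0.5))  # bin1: (4+2)/2; bin2: (0+1)/2
  one <- elite_baseline(gm, "S01", one_chrom_sizes(1e6))
  expect_equal(one$baseline, c(4, 0))
  expect_error(elite_baseline(gm, character(), one_chrom_sizes(1e6)),
               "empty")
})

test_that("fold-rule classification applies threshold, floor and minimum count", {
  prof <- data.frame(chrom = "chr1D", start = c(0, 5e5, 1e6, 1.5e6),
                     end = c(5e5, 1e6, 1.5e6, 2e6),
                     total = c(60L, 20L, 12L, 9L),
                     matching = c(55L, 10L, 11L, 9L))
  base <- data.frame(chrom = "chr1D", start = prof$start, end = prof$end,
                     baseline = c(5, 5, 0, 0))
  cls <- classify_donor_bins(prof, base)
  # 60 vs 5 -> 12-fold donor; 20 vs 5 -> 4-fold, not donor;
  # 12 vs floor(1) -> donor; 9 vs floor -> fails the >= 10 SNP count
  expect_equal(cls$donor_bin, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(cls$fold_change[1], 12)
  # increasing the fold threshold never adds donor bins
  for (f in c(5, 8, 12, 20)) {
    cur <- classify_donor_bins(prof, base, fold = f)$donor_bin
    if (f > 5) expect_true(all(cur <= prev))
    prev <- cur
  }
  # matching-count mode classifies on donor-matching SNPs instead
  cls_m <- classify_donor_bins(prof, base, use_matching = TRUE)
  expect_equal(cls_m$donor_bin, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(cls_m$fold_change[2], 2)
})

test_that("segment merging respects the gap parameter", {
  cls <- data.frame(chrom = "chr1D", start = (0:4) * 5e5,
                    end = (1:5) * 5e5,
                    total = c(50L, 50L, 5L, 50L, 5L),
                    matching = c(45L, 45L, 1L, 45L, 1L),
                    baseline = 5, fold_change = c(10, 10, 1, 10, 1),
                    donor_bin = c(TRUE, TRUE, FALSE, TRUE, FALSE))
  segs0 <- merge_segments(cls, max_gap_bins = 0)
  expect_equal(nrow(segs0), 2L)
  expect_equal(segs0$start, c(0, 1.5e6))
  expect_equal(segs0$end, c(1e6, 2e6))
  segs1 <- merge_segments(cls, max_gap_bins = 1)
  expect_equal(nrow(segs1), 1L)
  expect_equal(c(segs1$start, segs1$end), c(0, 2e6))
  expect_equal(segs1$n_gap_bins, 1L)
  # adjacent donor bins on one chromosome merge into a single span
  all3 <- cls[1:3, ]
  all3$donor_bin <- TRUE
  expect_equal(merge_segments(all3)$end, 1.5e6)
  # empty input gives an empty frame
  expect_equal(nrow(merge_segments(cls[cls$donor_bin == FALSE, ])), 0L)
})

test_that("donor fraction arithmetic is exact and consistent with segments", {
  cs <- data.frame(chrom = "chr1D", length = 1e8)
  segs <- data.frame(chrom = "chr1D", start = (0:19) * 5e5,
                     end = (1:20) * 5e5)
  expect_equal(donor_fraction(segs, cs, "D"), 10)
  expect_equal(donor_fraction(segs[0, ], cs, "D"), 0)
  expect_error(donor_fraction(segs, cs, "Z"), "unknown subgenome")
})

test_that("panel union de-duplicates bins and length-weights terminal bins", {
  mk <- function(donor_starts, cs) {
    bins <- make_bins(cs, 5e5)
    bins$total <- 0L
    bins$matching <- 0L
    bins$baseline <- 0
    bins$fold_change <- 0
    bins$donor_bin <- bins$start %in% donor_starts
    bins
  }
  cs <- data.frame(chrom = "chr1D", length = 1.75e6)  # last bin 250 kbp
  a <- mk(c(0, 5e5), cs)
  b <- mk(c(5e5, 1.5e6), cs)
  u <- panel_union(list(a, b), cs, subgenome = "D")
  expect_equal(u$n_bins, 3L)
  expect_equal(u$span_bp, 5e5 + 5e5 + 2.5e5)   # truncated bin true width
  # identical bin sets: union equals either set
  expect_equal(panel_union(list(a, a))$n_bins, 2L)
  # disjoint sets add up
  expect_equal(panel_union(list(mk(0, cs), mk(1e6, cs)))$n_bins, 2L)
  # the published panel-wide case: 5301 full 500-kbp bins span 2.65 Gbp
  big_cs <- data.frame(chrom = "chr1D", length = 5301 * 5e5)
  big <- mk((0:5300) * 5e5, big_cs)
  u2 <- panel_union(list(big), big_cs, subgenome = "D")
  expect_equal(u2$n_bins, 5301L)
  expect_equal(u2$span_gbp, 2.65)
})

test_that("theoretical pedigree contribution follows the 0.5^n dilution", {
  expect_equal(theoretical_contribution(0), 100)
  expect_equal(theoretical_contribution(4), 6.25)
  expect_equal(theoretical_contribution(c(2, 6)), c(25, 1.5625))
  expect_error(theoretical_contribution(-1), "non-negative")
})

test_that("implanted donor blocks are recovered with their edges and nulls are clean", {
  cs <- data.frame(chrom = c("chr1B", "chr7D"), length = c(3e7, 3e7),
                   subgenome = c("B", "D"))
  cfg <- sim_config(seed = 77, chromosomes = cs, n_elite = 12, n_exotic = 3,
                    donor_fraction_range = c(0, 0),  # no synthetic-donor blocks
                    target_subgenome = "D",
                    alien_blocks = data.frame(
                      donor = c("rye", "rye", "ponticum"),
                      chrom = c("chr1B", "chr1B", "chr7D"),
                      start = c(0, 0, 2.2e7),
                      end = c(1.2e7, 1.2e7, 3e7),
                      line = c("EXOTIC01", "EXOTIC02", "EXOTIC03"),
                      stringsAsFactors = FALSE))
  sim <- suppressWarnings(simulate_panel(cfg))
  gm <- designated_masked(sim)
  elite <- sim$metadata$sample[sim$metadata$group == "elite"]
  base <- elite_baseline(gm, elite, sim$chrom_sizes)
  # chromosome-start rye block: segment begins at 0
  det1 <- detect_alien(gm, "EXOTIC01", sim$alien_donors$rye, base,
                       sim$chrom_sizes)
  seg1 <- det1$segments[det1$segments$chrom == "chr1B", ]
  expect_equal(nrow(seg1), 1L)
  expect_equal(seg1$start, 0)
  expect_equal(seg1$end, 1.2e7, tolerance = 5e5 / 1.2e7)
  # distal block: segment reaches the chromosome end
  det3 <- detect_alien(gm, "EXOTIC03", sim$alien_donors$ponticum, base,
                       sim$chrom_sizes)
  seg3 <- det3$segments[det3$segments$chrom == "chr7D", ]
  expect_equal(seg3$end[nrow(seg3)], 3e7)
  # an elite line scanned against the rye set yields nothing
  det0 <- detect_alien(gm, elite[1], sim$alien_donors$rye, base,
                       sim$chrom_sizes)
  expect_equal(nrow(det0$segments), 0L)
})

test_that("default-simulation recovery meets precision, recall and fraction accuracy", {
  sim <- default_sim()
  gm <- designated_masked(sim)
  meta <- sim$metadata
  elite <- meta$sample[meta$group == "elite"]
  exotic <- meta$sample[meta$group != "elite"]
  base <- elite_baseline(gm, elite, sim$chrom_sizes)
  segs <- sim$truth$segments
  tp_pred <- 0; n_pred <- 0; tp_truth <- 0; n_truth <- 0
  for (s in exotic) {
    det <- detect_alien(gm, s, sim$donor, base, sim$chrom_sizes)
    truth <- segs[segs$line == s, , drop = FALSE]
    rs <- recovery_stats(det$classified, truth)
    if (!is.na(rs$precision)) {
      tp_pred <- tp_pred + rs$precision * rs$n_pred
      n_pred <- n_pred + rs$n_pred
    }
    if (!is.na(rs$recall)) {
      tp_truth <- tp_truth + rs$recall * rs$n_truth
      n_truth <- n_truth + rs$n_truth
    }
    est <- donor_fraction(det$segments, sim$chrom_sizes, "D")
    truth_pct <- sim$truth$fractions$true_fraction_pct[
      sim$truth$fractions$line == s]
    expect_lt(abs(est - truth_pct), 1)
    # reported fraction is exactly the segment arithmetic
    expect_equal(est, 100 * sum(det$segments$end - det$segments$start) /
                   sum(sim$chrom_sizes$length[subgenome_of(sim$chrom_sizes$chrom) == "D"]))
  }
  expect_gte(tp_pred / n_pred, 0.95)   # panel-pooled bin precision
  expect_gte(tp_truth / n_truth, 0.95) # panel-pooled bin recall
})

test_that("no-donor lines contribute a negligible panel-union span", {
  cfg <- sim_config(seed = 55, donor_fraction_range = c(0, 0))
  sim <- suppressWarnings(simulate_panel(cfg))
  gm <- designated_masked(sim)
  meta <- sim$metadata
  elite <- meta$sample[meta$group == "elite"]
  exotic <- meta$sample[meta$group != "elite"]
  base <- elite_baseline(gm, elite, sim$chrom_sizes)
  cls <- lapply(exotic, function(s)
    detect_alien(gm, s, sim$donor, base, sim$chrom_sizes)$classified)
  u <- panel_union(cls, sim$chrom_sizes, subgenome = "D")
  expect_lt(u$pct_of_subgenome, 1)
})

test_that("disabling varietal masking strictly increases false-positive bins", {
  sim <- default_sim()
  gm_masked <- designated_masked(sim)
  gm_raw <- apply_reference_call_rule(sim$gm)
  meta <- sim$metadata
  elite <- meta$sample[meta$group == "elite"]
  exotic <- meta$sample[meta$group != "elite"]
  segs <- sim$truth$segments
  fp_count <- function(gm) {
    base <- elite_baseline(gm, elite, sim$chrom_sizes)
    total <- 0L
    for (s in exotic) {
      det <- detect_alien(gm, s, sim$donor, base, sim$chrom_sizes)
      cls <- det$classified
      truth <- segs[segs$line == s, , drop = FALSE]
      cover <- rep(0, nrow(cls))
      for (i in seq_len(nrow(truth))) {
        ov <- pmin(cls$end, truth$end[i]) - pmax(cls$start, truth$start[i])
        cover <- cover + ifelse(cls$chrom == truth$chrom[i], pmax(ov, 0), 0)
      }
      total <- total + sum(cls$donor_bin & cover <= 0)
    }
    total
  }
  expect_gt(fp_count(gm_raw), fp_count(gm_masked))
})
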