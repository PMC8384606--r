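test_that("per-line SNP counts match hand counts and partition by subgenome", {
  # 3 samples, 6 loci across chr1A (2), chr1B (2), chr1D (2)
  calls <- rbind(c(2L, 0L, 2L),
                 c(2L, 2L, 0L),
                 c(0L, 2L, NA),
                 c(0L, 0L, 0L),
                 c(2L, NA, 2L),
                 c(2L, 2L, 2L))
  gm <- genotype_matrix(
    data.frame(chrom = rep(c("chr1A", "chr1B", "chr1D"), each = 2),
               pos = c(10L, 20L, 10L, 20L, 10L, 20L),
               ref = "A", alt = "G", stringsAsFactors = FALSE),
    c("S1", "S2", "S3"), calls)
  by_chrom <- per_line_snp_counts(gm, "chromosome")
  expect_equal(unname(by_chrom["S1", ]), c(2L, 0L, 2L))
  expect_equal(unname(by_chrom["S2", ]), c(1L, 1L, 1L))
  expect_equal(unname(by_chrom["S3", ]), c(1L, 0L, 2L))
  by_sg <- per_line_snp_counts(gm, "subgenome")
  expect_equal(rowSums(by_sg), rowSums(by_chrom))
  # a sample with no hom-alt calls counts zero everywhere
  gm0 <- tiny_gm(matrix(c(0L, NA, 1L), 3, 1))
  expect_message(c0 <- per_line_snp_counts(gm0, "chromosome"),
                 "heterozygous")
  expect_equal(unname(c0[1, 1]), 0L)
})

test_that("subgenome inference uses the name suffix with override mapping", {
  expect_equal(subgenome_of(c("chr3D", "1B", "chr5A")), c("D", "B", "A"))
  expect_error(subgenome_of("scaffold12"), "cannot infer")
  expect_equal(subgenome_of("scaffold12", map = c(scaffold12 = "D")), "D")
})

test_that("density contrast reproduces the published per-unit percentages", {
  tbl <- utils::read.table(
    system.file("extdata", "elite_exotic_mean_snp_counts.tsv", package = "exoscan"),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  got <- vapply(seq_len(nrow(tbl)), function(i)
    density_contrast(tbl$elite_mean[i], tbl$exotic_mean[i])$pct_difference,
    numeric(1))
  expect_equal(got[tbl$unit == "D"], 62.02)
  expect_equal(got[tbl$unit == "chr3D"], 202.24)
  expect_equal(got[tbl$unit == "chr4B"], 139.84)
  expect_equal(got[tbl$unit == "A"], 5.28)
  expect_equal(got[tbl$unit == "B"], 10.20)
  expect_equal(got[tbl$unit == "chr4A"], -2.27)
})

test_that("density contrast handles equal means and a zero baseline", {
  expect_equal(density_contrast(c(5, 5), c(5, 5))$pct_difference, 0)
  expect_true(is.na(density_contrast(0, 10)$pct_difference))
  expect_error(density_contrast(numeric(), 1), "non-empty")
})

test_that("binned density splits known positions and conserves totals", {
  pos <- c(1L, 100L, 499999L, 500000L, 500001L, 700000L, 999999L)
  gm <- tiny_gm(matrix(2L, 7, 1), pos = pos)
  tr <- binned_density(gm, one_chrom_sizes(1e6), bin_width = 5e5)
  expect_equal(tr$count, c(4L, 3L))  # 1-based 500000 is in the first bin
  expect_equal(sum(tr$count), 7L)
  expect_equal(tr$start, c(0, 5e5))
  # empty matrix gives an all-zero track tiling the chromosome
  gm0 <- tiny_gm(matrix(2L, 0, 1))
  tr0 <- binned_density(gm0, one_chrom_sizes(1.2e6), bin_width = 5e5)
  expect_equal(tr0$count, c(0L, 0L, 0L))
  expect_equal(tr0$end, c(5e5, 1e6, 1.2e6))  # truncated terminal bin
  expect_error(binned_density(gm, one_chrom_sizes(1e6), bin_width = 0),
               "positive")
})

test_that("windowed Hudson Fst equals the brute-force per-SNP oracle", {
  set.seed(42)
  for (trial in 1:5) {
    n_snp <- sample(3:10, 1)
    calls <- matrix(sample(c(0L, 2L, NA), n_snp * 8, replace = TRUE,
                           prob = c(0.5, 0.45, 0.05)), n_snp, 8)
    gm <- tiny_gm(calls, pos = sort(sample.int(4e5, n_snp)))
    got <- windowed_fst(gm, paste0("S0", 1:4), paste0("S0", 5:8),
                        one_chrom_sizes(5e5))
    want <- hudson_oracle(calls, 1:4, 5:8)
    if (is.nan(want)) {
      expect_true(is.na(got$fst_raw[1]))
    } else {
      expect_equal(got$fst_raw[1], want, tolerance = 1e-12)
    }
  }
})

test_that("Fst hits the fixed-difference and identical-frequency endpoints", {
  # fixed difference at every SNP: group A all alt, group B all ref
  fixed <- tiny_gm(cbind(matrix(2L, 5, 3), matrix(0L, 5, 3)))
  got <- windowed_fst(fixed, paste0("S0", 1:3), paste0("S0", 4:6),
                      one_chrom_sizes(1e6))
  expect_equal(got$fst_raw[1], 1)
  expect_equal(got$fst[1], 1)
  # identical allele frequencies: clipped value is 0
  same <- tiny_gm(cbind(c(2L, 0L, 2L), c(0L, 2L, 0L),
                        c(2L, 0L, 2L), c(0L, 2L, 0L)))
  got2 <- windowed_fst(same, c("S01", "S02"), c("S03", "S04"),
                       one_chrom_sizes(1e6))
  expect_equal(got2$fst[1], 0)
  expect_lte(got2$fst_raw[1], 0)
  # windows without polymorphism carry NA, not 0
  mono <- tiny_gm(matrix(0L, 2, 4))
  got3 <- windowed_fst(mono, c("S01", "S02"), c("S03", "S04"),
                       one_chrom_sizes(1e6))
  expect_true(all(is.na(got3$fst_raw)))
  expect_equal(got3$n_snps, c(0L, 0L))
})

test_that("Fst input validation rejects bad groups", {
  gm <- tiny_gm(matrix(0L, 1, 4))
  expect_error(windowed_fst(gm, c("S01", "S02"), c("S02", "S03"),
                            one_chrom_sizes(1e6)), "disjoint")
  expect_error(windowed_fst(gm, "S01", c("S02", "S03"),
                            one_chrom_sizes(1e6)), ">= 2 samples")
})

test_that("pseudo-split control is seed-reproducible and near zero on a homogeneous panel", {
  set.seed(9)
  calls <- matrix(sample(c(0L, 2L), 400 * 12, replace = TRUE), 400, 12)
  gm <- tiny_gm(calls, pos = sort(sample.int(2e6, 400)))
  a <- pseudo_split_control(gm, gm$samples, one_chrom_sizes(2e6), seed = 5)
  b <- pseudo_split_control(gm, gm$samples, one_chrom_sizes(2e6), seed = 5)
  expect_identical(attr(a, "group_a"), attr(b, "group_a"))
  expect_equal(a$fst_raw, b$fst_raw)
  expect_lt(abs(mean(a$fst_raw, na.rm = TRUE)), 0.01)
  expect_error(pseudo_split_control(gm, gm$samples[1:3],
                                    one_chrom_sizes(2e6), seed = 1),
               ">= 4")
})

test_that("pseudo-split of a genuinely structured panel shows elevated Fst", {
  # two diverged groups hidden inside the 'elite' label
  set.seed(11)
  gA <- matrix(rbinom(200 * 6, 1, 0.9) * 2L, 200, 6)
  gB <- matrix(rbinom(200 * 6, 1, 0.1) * 2L, 200, 6)
  gm <- tiny_gm(cbind(gA, gB), pos = sort(sample.int(4e5, 200)))
  # a split that separates the two groups shows strong differentiation
  strat <- windowed_fst(gm, gm$samples[1:6], gm$samples[7:12],
                        one_chrom_sizes(5e5))
  expect_gt(strat$fst_raw[1], 0.5)
})

test_that("Evanno delta-K finds a planted kink and rejects degenerate input", {
  # L(K) linear in K: all interior delta-K are exactly 0
  lin <- expand.grid(K = 1:5, replicate = 1:4)
  offs <- c(0.1, -0.1, 0.2, -0.2)          # per-replicate intercepts
  lin$lnP <- -1000 + 50 * lin$K + offs[lin$replicate]
  res <- evanno_delta_k(lin)
  expect_equal(res$table$delta_k[2:4], c(0, 0, 0))
  # single kink at K = 2 dominates
  set.seed(3)
  kink <- expand.grid(K = 1:6, replicate = 1:10)
  mean_l <- c(-5000, -3000, -2900, -2800, -2700, -2600)
  kink$lnP <- mean_l[kink$K] + rnorm(nrow(kink), 0, 1)
  res2 <- evanno_delta_k(kink)
  expect_equal(res2$best_k, 2)
  # fewer than 3 K values: no interior point
  expect_error(evanno_delta_k(expand.grid(K = 1:2, replicate = 1:3,
                                          lnP = 0)), ">= 3")
  # zero replicate variance is degenerate
  degen <- expand.grid(K = 1:3, replicate = 1:3)
  degen$lnP <- c(-10, -5, -1)[degen$K]
  expect_error(evanno_delta_k(degen), "degenerate")
})
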