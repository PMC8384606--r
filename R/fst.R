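# Hudson Fst per-SNP components (Bhatia et al. 2013 formulation):
#   num = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)
#   den = p1(1-p2) + p2(1-p1)
# with p the alternate allele frequency and n the number of observed
# alleles in each group. Windows aggregate as ratio of sums, which is
# robust to sample-size imbalance across SNPs.
hudson_components <- function(ac1, n1, ac2, n2) {
  p1 <- ac1 / n1
  p2 <- ac2 / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den)
}

#' Windowed Hudson Fst between two sample groups
#'
#' Allele frequencies are taken from non-missing calls. The panel consists
#' of inbred (homozygous) lines, so each line contributes one independent
#' haplotype to the frequency and to Hudson's finite-sample correction
#' (heterozygous calls contribute half an allele). Within each fixed-width
#' window the estimator is aggregated as a ratio of sums of per-SNP
#' numerator and denominator. Windows with no informative SNP (denominator
#' sum 0, e.g. no polymorphism) carry `NA`, never 0.
#'
#' @param gm designated [genotype_matrix()].
#' @param group_a,group_b disjoint character vectors of sample names, each
#'   of size >= 2.
#' @param chrom_sizes data.frame `chrom`, `length`.
#' @param window window width in bp (default 500 kbp, tiling from 0).
#' @return data.frame `chrom`, `start`, `end`, `fst` (clipped to \[0, 1\]
#'   for reporting), `fst_raw`, `n_snps`.
#' @export
windowed_fst <- function(gm, group_a, group_b, chrom_sizes, window = 5e5) {
  if (length(intersect(group_a, group_b)) > 0)
    stop("groups must be disjoint")
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 samples")
  missing_samples <- setdiff(c(group_a, group_b), gm$samples)
  if (length(missing_samples))
    stop("unknown sample(s): ", paste(missing_samples, collapse = ", "))
  if (any(gm$calls == CALL_NO_CALL, na.rm = TRUE))
    stop("matrix contains undesignated no-calls")
  comp <- snp_fst_components(gm, group_a, group_b)
  bins <- make_bins(chrom_sizes, window)
  key <- bin_key_of(gm$loci$chrom, gm$loci$pos, window)
  informative <- !is.na(comp$den) & comp$den > 0
  num_sum <- tapply(comp$num[informative], key[informative], sum)
  den_sum <- tapply(comp$den[informative], key[informative], sum)
  n_snps <- table(key[informative])
  bins$fst_raw <- as.numeric(num_sum[bins$bin] / den_sum[bins$bin])
  bins$n_snps <- as.integer(n_snps[bins$bin])
  bins$n_snps[is.na(bins$n_snps)] <- 0L
  bins$fst <- pmin(pmax(bins$fst_raw, 0), 1)
  bins[, c("chrom", "start", "end", "fst", "fst_raw", "n_snps")]
}

# Per-SNP Hudson numerator/denominator for two groups of inbred lines.
# Homozygous lines are effectively haploid: each line contributes ONE
# allele (hom-alt = 1, hom-ref = 0, het = 1/2), so the finite-sample
# correction divides by the number of independent haplotypes. Counting
# two perfectly correlated alleles per inbred line would undercorrect and
# bias the null upward.
snp_fst_components <- function(gm, group_a, group_b) {
  dose_a <- gm$calls[, group_a, drop = FALSE] / 2
  dose_b <- gm$calls[, group_b, drop = FALSE] / 2
  ac1 <- rowSums(dose_a, na.rm = TRUE)
  n1 <- rowSums(!is.na(dose_a))
  ac2 <- rowSums(dose_b, na.rm = TRUE)
  n2 <- rowSums(!is.na(dose_b))
  ok <- n1 > 1 & n2 > 1  # unbiased terms need >= 2 observed lines
  h <- hudson_components(ac1, n1, ac2, n2)
  h$num[!ok] <- NA_real_
  h$den[!ok] <- NA_real_
  h
}

#' Pseudo-split Fst control on a homogeneous group
#'
#' Randomly halves the elite subpopulation (seeded) and computes
#' [windowed_fst()] between the two pseudo-populations. On a homogeneous
#' panel the genome-wide mean is expected to be negligibly small.
#'
#' @param gm designated [genotype_matrix()].
#' @param elite_samples character vector of >= 4 elite sample names.
#' @param chrom_sizes data.frame `chrom`, `length`.
#' @param seed integer seed controlling the split.
#' @param window window width in bp.
#' @return As [windowed_fst()], with the two halves in attributes
#'   `"group_a"`/`"group_b"`.
#' @export
pseudo_split_control <- function(gm, elite_samples, chrom_sizes, seed,
                                 window = 5e5) {
  if (length(elite_samples) < 4)
    stop("pseudo-split needs >= 4 elite samples")
  half <- withr_seed(seed, sample(elite_samples, floor(length(elite_samples) / 2)))
  other <- setdiff(elite_samples, half)
  out <- windowed_fst(gm, half, other, chrom_sizes, window)
  attr(out, "group_a") <- half
  attr(out, "group_b") <- other
  out
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
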