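#' Depth-conditioned homozygous-reference designation
#'
#' For every undesignated no-call (an individual in which no alternate
#' allele was observed at a panel locus), the call becomes homozygous
#' reference when mapping depth is at least `min_depth`, and missing
#' otherwise. Existing homozygous-alternate and heterozygous calls are
#' never touched.
#'
#' @param gm a [genotype_matrix()] with no-calls coded `-1`.
#' @param min_depth minimum mapping depth for reference designation
#'   (default 5).
#'
#' @return The designated [genotype_matrix()]; no `-1` codes remain.
#' @export
apply_reference_call_rule <- function(gm, min_depth = 5) {
  stopifnot(inherits(gm, "genotype_matrix"), min_depth >= 0)
  nc <- which(gm$calls == CALL_NO_CALL)
  if (length(nc) == 0) return(gm)
  if (is.null(gm$depth) || anyNA(gm$depth[nc])) {
    need <- if (is.null(gm$depth)) nc else nc[is.na(gm$depth[nc])]
    rc <- arrayInd(need, dim(gm$calls))
    pairs <- paste0(gm$samples[rc[, 2]], "@", gm$loci$chrom[rc[, 1]], ":",
                    gm$loci$pos[rc[, 1]])
    stop("depth required to designate no-calls but absent for: ",
         paste(utils::head(pairs, 5), collapse = ", "),
         if (length(pairs) > 5) sprintf(" (and %d more)", length(pairs) - 5))
  }
  calls <- gm$calls
  calls[nc] <- ifelse(gm$depth[nc] >= min_depth, CALL_HOM_REF, NA_integer_)
  genotype_matrix(gm$loci, gm$samples, calls, gm$depth)
}

#' Remove varietal SNPs matching a mask in position and allele
#'
#' Drops loci whose `(chrom, pos, alt)` triple appears in the mask set;
#' the same position with a different alternate allele is retained. Used to
#' strip reference-vs-germplasm varietal noise before identity-by-state
#' donor attribution.
#'
#' @param gm a [genotype_matrix()].
#' @param mask a [donor_snpset()] (or data.frame with `chrom`, `pos`, `alt`).
#'
#' @return Masked [genotype_matrix()]; removed-locus count in attribute
#'   `"n_masked"`.
#' @export
mask_varietal_snps <- function(gm, mask) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(mask) || nrow(mask) == 0) {
    attr(gm, "n_masked") <- 0L
    return(gm)
  }
  hit <- locus_keys(gm$loci) %in% locus_keys(mask)
  out <- subset_loci(gm, !hit)
  attr(out, "n_masked") <- sum(hit)
  out
}

#' Filter loci on missing data and minor allele frequency
#'
#' Retains loci with missing fraction below `max_missing` (denominator:
#' all samples) and minor allele frequency at least `min_maf`. Allele
#' frequency is computed over non-missing calls with homozygous-alternate
#' contributing two alternate alleles and heterozygous one. Loci with all
#' calls missing are removed (counted, never divided by zero).
#'
#' @param gm a designated [genotype_matrix()] (no `-1` codes).
#' @param max_missing maximum tolerated missing fraction, exclusive
#'   (default 0.10).
#' @param min_maf minimum minor allele frequency, inclusive (default 0.05).
#'
#' @return Filtered [genotype_matrix()] with a `"filter_report"` attribute:
#'   data.frame `locus`, `reason` for every removed locus.
#' @export
filter_loci <- function(gm, max_missing = 0.10, min_maf = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"),
            max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 0.5)
  if (any(gm$calls == CALL_NO_CALL, na.rm = TRUE))
    stop("matrix contains undesignated no-calls; run apply_reference_call_rule() first")
  n <- length(gm$samples)
  n_miss <- rowSums(is.na(gm$calls))
  n_obs <- n - n_miss
  alt_alleles <- rowSums(gm$calls, na.rm = TRUE)
  p <- ifelse(n_obs > 0, alt_alleles / (2 * n_obs), NA_real_)
  maf <- pmin(p, 1 - p)
  miss_frac <- n_miss / n
  keep <- miss_frac < max_missing & !is.na(maf) & maf >= min_maf
  reason <- rep(NA_character_, nrow(gm$loci))
  reason[n_obs == 0] <- "all_missing"
  reason[is.na(reason) & miss_frac >= max_missing] <- "missing"
  reason[is.na(reason) & !keep] <- "maf"
  rpt <- data.frame(
    locus = paste0(gm$loci$chrom, ":", gm$loci$pos)[!keep],
    reason = reason[!keep], stringsAsFactors = FALSE)
  out <- subset_loci(gm, keep)
  attr(out, "filter_report") <- rpt
  out
}
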