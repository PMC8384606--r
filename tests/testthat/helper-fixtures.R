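# Shared fixtures, all built in code.

# tiny genotype matrix from a compact spec: calls is a loci x samples
# matrix using the package's codes (0/1/2/NA/-1)
tiny_gm <- function(calls, chrom = "chr1D", pos = NULL, depth = NULL,
                    samples = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(calls)))
  ref <- rep(c("A", "C", "G", "T"), length.out = n)
  alt <- rep(c("G", "T", "A", "C"), length.out = n)
  genotype_matrix(
    data.frame(chrom = rep_len(chrom, n), pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE),
    samples, calls, depth)
}

one_chrom_sizes <- function(len = 1e6, chrom = "chr1D") {
  data.frame(chrom = chrom, length = len, stringsAsFactors = FALSE)
}

# the hand-enumerated 20-sample, 10-locus filtering fixture:
# survivors under (<10% missing, MAF >= 5%) are loci 1, 3, 4, 9
filter_fixture <- function() {
  n <- 20
  row <- function(n_alt = 0, n_het = 0, n_miss = 0) {
    c(rep(2L, n_alt), rep(1L, n_het), rep(NA_integer_, n_miss),
      rep(0L, n - n_alt - n_het - n_miss))
  }
  calls <- rbind(
    row(n_alt = 5),               # 1: MAF 0.25, keep
    row(n_alt = 5, n_miss = 3),   # 2: 15% missing, drop
    row(n_alt = 2, n_miss = 1),   # 3: 5% missing, MAF 4/38, keep
    row(n_alt = 1),               # 4: MAF exactly 0.05, keep (boundary)
    row(),                        # 5: monomorphic ref, drop
    row(n_alt = 20),              # 6: monomorphic alt, drop
    row(n_alt = 5, n_miss = 2),   # 7: 10% missing (not < 10%), drop
    row(n_het = 1),               # 8: MAF 1/40 = 0.025, drop
    row(n_het = 2),               # 9: MAF 2/40 = 0.05, keep (boundary)
    matrix(NA_integer_, 1, n))    # 10: all missing, drop
  tiny_gm(calls)
}

# default-conditions simulation shared across introgression tests
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(simulate_panel(sim_config(seed = 101)))
    }
    cache
  }
})

designated_masked <- function(sim) {
  mask_varietal_snps(apply_reference_call_rule(sim$gm), sim$mask)
}

# independent per-SNP Hudson Fst oracle working directly on genotype
# codes; inbred lines count as one haplotype each (hom-alt = 1 allele)
hudson_oracle <- function(calls, idx_a, idx_b) {
  num <- 0
  den <- 0
  for (i in seq_len(nrow(calls))) {
    ga <- calls[i, idx_a]
    gb <- calls[i, idx_b]
    ga <- ga[!is.na(ga)] / 2
    gb <- gb[!is.na(gb)] / 2
    n1 <- length(ga)
    n2 <- length(gb)
    if (n1 < 2 || n2 < 2) next  # uninformative SNP
    p1 <- sum(ga) / n1
    p2 <- sum(gb) / n2
    d <- p1 * (1 - p2) + p2 * (1 - p1)
    if (d > 0) {
      num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
        p2 * (1 - p2) / (n2 - 1)
      den <- den + d
    }
  }
  num / den
}

# flat spectrum at a constant reflectance on the full 1-nm grid
flat_spectrum <- function(value = 0.5) {
  wl <- 350:2500
  list(wavelength = wl, reflectance = rep(value, length(wl)))
}
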