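#' Simulate a wheat panel with donor introgressions
#'
#' Generates a complete synthetic study input set under the configured
#' conditions: an elite subpopulation carrying subgenome-specific
#' background SNP densities, exotic (synthetic-derived) lines whose target
#' subgenome carries donor haplotype blocks produced by a pedigree of
#' backcross-style recombination rounds (1-2 crossovers per chromosome per
#' cross; each round halves expected donor content), panel-vs-reference
#' varietal noise (scattered monomorphic SNPs plus low-frequency clustered
#' varietal haplotype blocks), i.i.d. missingness expressed through the
#' depth field, and ground truth for recovery testing.
#'
#' Inside a line's truth segments the line is homozygous-alternate at
#' every donor-set SNP (identity by state with the donor); elsewhere all
#' lines carry only background and varietal variation. Raw calls are
#' emitted undesignated: individuals without an observed alternate allele
#' are no-calls with a depth value, exactly what
#' [apply_reference_call_rule()] consumes.
#'
#' @param config a [sim_config()].
#' @return list of class `panel_sim`: `gm` (raw [genotype_matrix()] with
#'   depth), `donor` ([donor_snpset()]), `alien_donors` (named list of
#'   [donor_snpset()]), `mask` (varietal mask as a [donor_snpset()]),
#'   `metadata`, `chrom_sizes`, and `truth` (list: `segments` with
#'   0-based half-open donor intervals per line, `fractions` with realized
#'   donor percent of the target subgenome per exotic line, and
#'   `trait_components`).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- config$chromosomes
  if (any(chroms$length < 1e6))
    stop("chromosome(s) too short to host the crossover model (< 1 Mbp): ",
         paste(chroms$chrom[chroms$length < 1e6], collapse = ", "))
  chrom_sizes <- chroms[, c("chrom", "length")]
  n_elite <- config$n_elite
  n_exotic <- config$n_exotic
  samples <- c(sprintf("ELITE%02d", seq_len(n_elite)),
               sprintf("EXOTIC%02d", seq_len(n_exotic)))
  exotic_samples <- samples[seq_len(n_exotic) + n_elite]
  n_samp <- length(samples)
  target <- chroms[chroms$subgenome == config$target_subgenome, , drop = FALSE]

  ## --- donor SNP set over the whole target subgenome -------------------
  donor_loci <- random_loci(target, config$donor_snp_rate)
  donor <- donor_snpset(donor_loci$chrom, donor_loci$pos, donor_loci$alt,
                        donor = config$donor_name)
  attr(donor, "ref") <- stats::setNames(donor_loci$ref, locus_keys(donor_loci))

  ## --- pedigree simulation: truth segments per exotic line -------------
  seg_list <- list()
  frac <- data.frame(line = character(), n_crosses = integer(),
                     true_fraction_pct = numeric(), stringsAsFactors = FALSE)
  clipped <- FALSE
  target_len <- sum(target$length)
  for (s in exotic_samples) {
    n_cross <- sample(seq(config$n_crosses_range[1],
                          config$n_crosses_range[2]), 1)
    segs <- pedigree_segments(target, n_cross, config$crossovers_range)
    adj <- clip_to_fraction(segs, target, config$donor_fraction_range)
    if (adj$clipped) clipped <- TRUE
    segs <- adj$segments
    if (nrow(segs) > 0) {
      segs$line <- s
      segs$donor <- config$donor_name
      seg_list[[s]] <- segs
    }
    frac <- rbind(frac, data.frame(
      line = s, n_crosses = n_cross,
      true_fraction_pct = 100 * sum(segs$end - segs$start) / target_len,
      stringsAsFactors = FALSE))
  }
  if (clipped)
    warning("realized donor fractions outside donor_fraction_range for ",
            "some lines given the configured cross counts; clipped to range")
  truth_segments <- if (length(seg_list))
    do.call(rbind, c(seg_list, list(make.row.names = FALSE))) else
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 line = character(), donor = character(),
                 stringsAsFactors = FALSE)

  ## --- alien donor blocks (rye / T. ponticum style) ---------------------
  alien_donors <- list()
  alien_segments <- NULL
  if (!is.null(config$alien_blocks) && nrow(config$alien_blocks) > 0) {
    ab <- config$alien_blocks
    for (dn in unique(ab$donor)) {
      dchr <- chroms[chroms$chrom %in% ab$chrom[ab$donor == dn], , drop = FALSE]
      al <- random_loci(dchr, config$alien_snp_rate)
      alien_donors[[dn]] <- donor_snpset(al$chrom, al$pos, al$alt, donor = dn)
      attr(alien_donors[[dn]], "ref") <- stats::setNames(al$ref, locus_keys(al))
    }
    alien_segments <- ab[, c("chrom", "start", "end", "line", "donor")]
  }

  ## --- background, varietal loci ---------------------------------------
  bg_rate <- config$elite_snp_rate[chroms$subgenome]
  bg <- random_loci(chroms, bg_rate / config$background_carrier_freq)
  var_scatter <- random_loci(chroms, config$varietal_rate)
  vb <- varietal_blocks(chroms, config)

  ## --- assemble panel loci with carrier matrices ------------------------
  pieces <- list()
  # donor loci carried by exotic lines inside their truth segments
  if (nrow(donor_loci) > 0 && nrow(truth_segments) > 0) {
    carrier <- matrix(FALSE, nrow(donor_loci), n_samp,
                      dimnames = list(NULL, samples))
    for (s in unique(truth_segments$line)) {
      segs <- truth_segments[truth_segments$line == s, , drop = FALSE]
      carrier[, s] <- covered_by(donor_loci$chrom, donor_loci$pos, segs)
    }
    keep <- rowSums(carrier) > 0
    pieces$donor <- list(loci = donor_loci[keep, , drop = FALSE],
                         carrier = carrier[keep, , drop = FALSE])
  }
  # alien loci carried inside alien blocks
  if (length(alien_donors) > 0) {
    for (dn in names(alien_donors)) {
      al <- alien_donors[[dn]]
      aref <- attr(al, "ref")
      segs_all <- alien_segments[alien_segments$donor == dn, , drop = FALSE]
      carrier <- matrix(FALSE, nrow(al), n_samp,
                        dimnames = list(NULL, samples))
      for (s in unique(segs_all$line))
        carrier[, s] <- covered_by(al$chrom, al$pos,
                                   segs_all[segs_all$line == s, , drop = FALSE])
      keep <- rowSums(carrier) > 0
      pieces[[paste0("alien_", dn)]] <- list(
        loci = data.frame(chrom = al$chrom, pos = al$pos,
                          ref = unname(aref[locus_keys(al)]), alt = al$alt,
                          stringsAsFactors = FALSE)[keep, , drop = FALSE],
        carrier = carrier[keep, , drop = FALSE])
    }
  }
  # background: each line carries a background SNP independently
  if (nrow(bg) > 0)
    pieces$background <- list(
      loci = bg,
      carrier = matrix(stats::runif(nrow(bg) * n_samp) <
                         config$background_carrier_freq,
                       nrow(bg), n_samp, dimnames = list(NULL, samples)))
  # scattered varietal noise: panel-monomorphic alternate
  if (nrow(var_scatter) > 0)
    pieces$varietal <- list(
      loci = var_scatter,
      carrier = matrix(TRUE, nrow(var_scatter), n_samp,
                       dimnames = list(NULL, samples)))
  # clustered varietal haplotype blocks at low carrier frequency
  if (!is.null(vb))
    pieces$varietal_blocks <- list(loci = vb$loci, carrier = vb$carrier)

  loci <- do.call(rbind, lapply(pieces, `[[`, "loci"))
  carrier <- do.call(rbind, lapply(pieces, `[[`, "carrier"))
  # de-duplicate positional collisions across categories (first wins:
  # donor > alien > background > varietal)
  dup <- duplicated(paste0(loci$chrom, ":", loci$pos))
  loci <- loci[!dup, , drop = FALSE]
  carrier <- carrier[!dup, , drop = FALSE]
  ord <- order(match(loci$chrom, chroms$chrom), loci$pos)
  loci <- loci[ord, , drop = FALSE]
  carrier <- carrier[ord, , drop = FALSE]
  rownames(loci) <- NULL

  ## --- raw calls and depth ----------------------------------------------
  n_loci <- nrow(loci)
  miss <- matrix(stats::runif(n_loci * n_samp) < config$missing_rate,
                 n_loci, n_samp)
  calls <- matrix(CALL_NO_CALL, n_loci, n_samp)
  calls[carrier & !miss] <- CALL_HOM_ALT
  if (config$het_rate > 0) {
    het <- carrier & !miss &
      matrix(stats::runif(n_loci * n_samp) < config$het_rate, n_loci, n_samp)
    calls[het] <- CALL_HET
  }
  depth <- matrix(0L, n_loci, n_samp)
  n_hi <- sum(!miss)
  depth[!miss] <- 5L + stats::rpois(n_hi, max(config$mean_depth - 5, 0))
  depth[miss] <- sample(0:4, sum(miss), replace = TRUE)

  gm <- genotype_matrix(loci, samples, calls, depth)

  ## --- varietal mask (external varietal call set: all varietal pos) ----
  mask_loci <- rbind(var_scatter, if (is.null(vb)) NULL else vb$loci)
  if (!is.null(mask_loci) && nrow(mask_loci) > 0) {
    mask <- donor_snpset(mask_loci$chrom, mask_loci$pos, mask_loci$alt,
                         donor = "varietal_mask")
    attr(mask, "ref") <- stats::setNames(mask_loci$ref, locus_keys(mask_loci))
  } else {
    mask <- donor_snpset(character(), integer(), character(),
                         donor = "varietal_mask")
  }

  metadata <- data.frame(
    sample = samples,
    group = c(rep("elite", n_elite), rep("synthetic", n_exotic)),
    n_crosses = c(rep(NA_integer_, n_elite),
                  frac$n_crosses[match(exotic_samples, frac$line)]),
    stringsAsFactors = FALSE)

  structure(list(gm = gm, donor = donor, alien_donors = alien_donors,
                 mask = mask, metadata = metadata,
                 chrom_sizes = chrom_sizes,
                 truth = list(segments = truth_segments,
                              alien_segments = alien_segments,
                              fractions = frac,
                              trait_components = config$traits),
                 config = config),
            class = "panel_sim")
}

# uniform random biallelic SNP loci at `rate` SNPs/Mbp (recycled over
# chromosomes); returns chrom/pos/ref/alt sorted within chromosome
random_loci <- function(chroms, rate) {
  rate <- rep_len(rate, nrow(chroms))
  out <- lapply(seq_len(nrow(chroms)), function(i) {
    n <- round(rate[i] * chroms$length[i] / 1e6)
    if (n == 0)
      return(data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        stringsAsFactors = FALSE))
    pos <- sort(sample.int(chroms$length[i], n))
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    data.frame(chrom = chroms$chrom[i], pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# one pedigree: start with the whole target subgenome as donor material,
# then n_cross recombination rounds; each round draws crossover points per
# chromosome and keeps the donor intervals landing on the transmitted
# haplotype (segment-wise survival probability 1/2)
pedigree_segments <- function(target, n_cross, crossovers_range) {
  segs <- data.frame(chrom = target$chrom, start = 0, end = target$length,
                     stringsAsFactors = FALSE)
  for (round in seq_len(n_cross)) {
    new <- list()
    for (i in seq_len(nrow(target))) {
      ch <- target$chrom[i]
      len <- target$length[i]
      cur <- segs[segs$chrom == ch, , drop = FALSE]
      if (nrow(cur) == 0) next
      k <- sample(seq(crossovers_range[1], crossovers_range[2]), 1)
      bp <- sort(stats::runif(k, 0, len))
      bounds <- c(0, bp, len)
      phase <- sample(0:1, 1)
      keep_blocks <- data.frame(
        start = bounds[-length(bounds)], end = bounds[-1])[
          (seq_len(length(bounds) - 1) + phase) %% 2 == 0, , drop = FALSE]
      if (nrow(keep_blocks) == 0) next
      inter <- intersect_intervals(cur, keep_blocks)
      if (nrow(inter) > 0) {
        inter$chrom <- ch
        new[[length(new) + 1]] <- inter[, c("chrom", "start", "end")]
      }
    }
    segs <- if (length(new)) do.call(rbind, new) else
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 stringsAsFactors = FALSE)
    if (nrow(segs) == 0) break
  }
  rownames(segs) <- NULL
  segs
}

intersect_intervals <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    s <- pmax(a$start[i], b$start)
    e <- pmin(a$end[i], b$end)
    ok <- e > s
    if (any(ok))
      out[[length(out) + 1]] <- data.frame(start = s[ok], end = e[ok])
  }
  if (length(out) == 0)
    return(data.frame(start = numeric(), end = numeric()))
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

# clip a line's realized donor content into the configured fraction range:
# trim segment ends when above the maximum, extend/create a segment when
# below the minimum (block-granular adjustments)
clip_to_fraction <- function(segs, target, range) {
  total_len <- sum(target$length)
  lo <- range[1] * total_len
  hi <- range[2] * total_len
  cur <- if (nrow(segs)) sum(segs$end - segs$start) else 0
  clipped <- FALSE
  if (cur > hi) {
    clipped <- TRUE
    excess <- cur - hi
    for (i in rev(seq_len(nrow(segs)))) {
      if (excess <= 0) break
      len <- segs$end[i] - segs$start[i]
      cut <- min(len, excess)
      segs$end[i] <- segs$end[i] - cut
      excess <- excess - cut
    }
    segs <- segs[segs$end > segs$start, , drop = FALSE]
  } else if (cur < lo) {
    clipped <- TRUE
    deficit <- lo - cur
    if (nrow(segs) > 0) {
      for (i in seq_len(nrow(segs))) {
        if (deficit <= 0) break
        len_ch <- target$length[target$chrom == segs$chrom[i]]
        others <- segs[-i, , drop = FALSE]
        same <- others[others$chrom == segs$chrom[i] &
                         others$start >= segs$end[i], , drop = FALSE]
        room_end <- if (nrow(same)) min(same$start) else len_ch
        grow <- min(deficit, room_end - segs$end[i])
        segs$end[i] <- segs$end[i] + grow
        deficit <- deficit - grow
      }
    }
    if (deficit > 0) {
      # no (or insufficient) existing segments: implant a fresh block
      i <- sample.int(nrow(target), 1)
      len_ch <- target$length[i]
      block <- min(deficit, len_ch)
      start <- floor(stats::runif(1, 0, len_ch - block))
      segs <- rbind(segs, data.frame(chrom = target$chrom[i],
                                     start = start, end = start + block,
                                     stringsAsFactors = FALSE))
    }
  }
  rownames(segs) <- NULL
  list(segments = segs, clipped = clipped)
}

# TRUE where a 1-based position lies inside any 0-based half-open segment
covered_by <- function(chrom, pos, segs) {
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(segs))) {
    hit <- hit | (chrom == segs$chrom[i] & pos - 1 >= segs$start[i] &
                    pos - 1 < segs$end[i])
  }
  hit
}

# clustered varietal haplotype blocks segregating at low carrier frequency
varietal_blocks <- function(chroms, config) {
  nb <- config$n_varietal_blocks
  if (nb == 0) return(NULL)
  samples <- c(sprintf("ELITE%02d", seq_len(config$n_elite)),
               sprintf("EXOTIC%02d", seq_len(config$n_exotic)))
  block_len <- config$varietal_block_mbp * 1e6
  loci_list <- list()
  carrier_list <- list()
  for (b in seq_len(nb)) {
    ci <- sample.int(nrow(chroms), 1, prob = chroms$length)
    len <- chroms$length[ci]
    start <- floor(stats::runif(1, 0, max(len - block_len, 1)))
    n <- round(config$varietal_block_snp_rate * block_len / 1e6)
    pos <- sort(start + sample.int(block_len, n))
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    carriers <- stats::runif(length(samples)) < config$varietal_block_carrier_prob
    loci_list[[b]] <- data.frame(chrom = chroms$chrom[ci], pos = pos,
                                 ref = ref, alt = alt,
                                 stringsAsFactors = FALSE)
    carrier_list[[b]] <- matrix(rep(carriers, each = n), n,
                                length(samples),
                                dimnames = list(NULL, samples))
  }
  list(loci = do.call(rbind, loci_list),
       carrier = do.call(rbind, carrier_list))
}

#' Write a simulated panel to disk
#'
#' Emits the full input set: panel VCF (GT:DP, undesignated no-calls),
#' donor VCF(s), varietal mask VCF, metadata TSV, chromosome sizes TSV and
#' a truth BED of implanted donor segments.
#'
#' @param sim a `panel_sim` from [simulate_panel()].
#' @param dir output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "panel_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(panel = file.path(dir, "panel.vcf"),
             mask = file.path(dir, "varietal_mask.vcf"),
             metadata = file.path(dir, "metadata.tsv"),
             chrom_sizes = file.path(dir, "chrom_sizes.tsv"),
             truth = file.path(dir, "truth_segments.bed"))
  write_vcf(sim$gm, paths["panel"], sim$chrom_sizes)
  write_snpset_vcf(sim$mask, paths["mask"], sim$chrom_sizes)
  utils::write.table(sim$metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_chrom_sizes(sim$chrom_sizes, paths["chrom_sizes"])
  tr <- sim$truth$segments
  if (!is.null(sim$truth$alien_segments))
    tr <- rbind(tr, sim$truth$alien_segments[, names(tr)])
  utils::write.table(
    data.frame(tr$chrom, format(tr$start, scientific = FALSE, trim = TRUE),
               format(tr$end, scientific = FALSE, trim = TRUE),
               paste(tr$line, tr$donor, sep = ";")),
    paths["truth"], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  donor_path <- file.path(dir, paste0("donor_", attr(sim$donor, "donor"), ".vcf"))
  write_snpset_vcf(sim$donor, donor_path, sim$chrom_sizes)
  paths[paste0("donor_", attr(sim$donor, "donor"))] <- donor_path
  for (dn in names(sim$alien_donors)) {
    p <- file.path(dir, paste0("donor_", dn, ".vcf"))
    write_snpset_vcf(sim$alien_donors[[dn]], p, sim$chrom_sizes)
    paths[paste0("donor_", dn)] <- p
  }
  invisible(paths)
}

# a donor/mask SNP set as a single-sample homozygous-alternate VCF
write_snpset_vcf <- function(ss, path, chrom_sizes) {
  refs <- attr(ss, "ref")
  ref <- if (!is.null(refs)) unname(refs[locus_keys(ss)]) else
    vapply(ss$alt, function(a) setdiff(c("A", "C", "G", "T"), a)[1],
           character(1))
  gm <- genotype_matrix(
    data.frame(chrom = ss$chrom, pos = ss$pos, ref = ref, alt = ss$alt,
               stringsAsFactors = FALSE),
    attr(ss, "donor") %||% "SET",
    matrix(CALL_HOM_ALT, nrow(ss), 1))
  write_vcf(gm, path, chrom_sizes)
}
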