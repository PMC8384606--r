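#' Construct / load a donor SNP set
#'
#' A donor SNP set is the reference-relative variant set of one donor taxon
#' (e.g. an *Ae. tauschii* accession or rye), used for identity-by-state
#' matching: a panel SNP is attributed to the donor when it matches a donor
#' entry in both position and alternate allele.
#'
#' @param chrom,pos,alt vectors defining the entries (pos 1-based,
#'   single-base alleles).
#' @param donor donor name (e.g. `"Ae_tauschii"`).
#' @return data.frame of class `donor_snpset` with unique
#'   `chrom`/`pos`/`alt` rows and a `donor` attribute.
#' @export
donor_snpset <- function(chrom, pos, alt, donor = "donor") {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   alt = as.character(alt), stringsAsFactors = FALSE)
  if (nrow(df) && any(nchar(df$alt) != 1))
    stop("donor alleles must be single-base")
  df <- df[!duplicated(locus_keys(df)), , drop = FALSE]
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "donor") <- donor
  class(df) <- c("donor_snpset", "data.frame")
  df
}

#' Build a donor SNP set from a donor VCF
#'
#' Ingests a VCF of variants called between the donor taxon and the common
#' reference, keeps biallelic SNPs (indels skipped with a message) and
#' removes entries present in the varietal mask so panel-vs-reference
#' varietal noise cannot masquerade as donor identity.
#'
#' @param path donor VCF (same reference coordinates as the panel).
#' @param mask optional varietal mask ([donor_snpset()] or data.frame with
#'   `chrom`, `pos`, `alt`).
#' @param chrom_sizes optional sizes table; contig names are validated
#'   against it.
#' @param donor donor name.
#' @return A [donor_snpset()].
#' @export
build_donor_snpset <- function(path, mask = NULL, chrom_sizes = NULL,
                               donor = "donor") {
  gm <- read_vcf(path, chrom_sizes)
  ds <- donor_snpset(gm$loci$chrom, gm$loci$pos, gm$loci$alt, donor = donor)
  if (!is.null(mask) && nrow(mask) > 0)
    ds <- ds[!locus_keys(ds) %in% locus_keys(mask), , drop = FALSE]
  rownames(ds) <- NULL
  attr(ds, "donor") <- donor
  class(ds) <- c("donor_snpset", "data.frame")
  ds
}

#' Per-line donor bin profile
#'
#' Bins one line's homozygous-alternate SNPs into fixed-width bins and
#' counts, per bin, the total SNPs and those showing identity by state to
#' the donor (matching a donor entry in position and allele).
#'
#' @param gm designated [genotype_matrix()].
#' @param sample line name.
#' @param donor a [donor_snpset()].
#' @param chrom_sizes data.frame `chrom`, `length`.
#' @param bin_width bin width in bp (default 500 kbp).
#' @return data.frame `chrom`, `start`, `end`, `total`, `matching`.
#' @export
bin_match_profile <- function(gm, sample, donor, chrom_sizes,
                              bin_width = 5e5) {
  if (!sample %in% gm$samples) stop("unknown sample: ", sample)
  bins <- make_bins(chrom_sizes, bin_width)
  is_alt <- gm$calls[, sample] == CALL_HOM_ALT
  is_alt[is.na(is_alt)] <- FALSE
  keys <- locus_keys(gm$loci)
  in_donor <- keys %in% locus_keys(donor)
  bk <- bin_key_of(gm$loci$chrom, gm$loci$pos, bin_width)
  tot <- table(bk[is_alt])
  mat <- table(bk[is_alt & in_donor])
  bins$total <- as.integer(tot[bins$bin])
  bins$matching <- as.integer(mat[bins$bin])
  bins$total[is.na(bins$total)] <- 0L
  bins$matching[is.na(bins$matching)] <- 0L
  bins[, c("chrom", "start", "end", "total", "matching")]
}

#' Elite baseline: mean per-bin SNP count across elite lines
#'
#' @param gm designated [genotype_matrix()].
#' @param elite_samples character vector of elite line names (>= 1).
#' @param chrom_sizes data.frame `chrom`, `length`.
#' @param bin_width bin width in bp.
#' @return data.frame `chrom`, `start`, `end`, `baseline` (arithmetic mean
#'   of per-line homozygous-alternate counts per bin).
#' @export
elite_baseline <- function(gm, elite_samples, chrom_sizes, bin_width = 5e5) {
  if (length(elite_samples) == 0) stop("elite group is empty")
  bins <- make_bins(chrom_sizes, bin_width)
  acc <- numeric(nrow(bins))
  for (s in elite_samples) {
    tr <- binned_density(gm, chrom_sizes, bin_width, sample = s)
    acc <- acc + tr$count
  }
  bins$baseline <- acc / length(elite_samples)
  bins[, c("chrom", "start", "end", "baseline")]
}

#' Classify donor bins by the fold-over-elite-baseline rule
#'
#' A bin is classed as donor-derived when the line's bin SNP count is at
#' least `fold` times the elite baseline for that bin. Because the rule is
#' undefined at baseline 0 (and fragile where the elite subpopulation is
#' SNP-poor), the baseline is floored at `min_baseline` and a bin must
#' additionally hold at least `min_count` SNPs.
#'
#' @param profile per-line bin profile from [bin_match_profile()].
#' @param baseline elite baseline from [elite_baseline()] on the same bins.
#' @param fold fold-change threshold (default 5).
#' @param min_baseline baseline floor in SNPs per bin (default 1).
#' @param min_count minimum SNPs in a classified bin (default 10).
#' @param use_matching classify on donor-matching counts instead of totals
#'   (default `FALSE`: the rule compares total bin SNP counts, and the
#'   match proportion is reported as evidence, not used as a filter).
#' @return `profile` with added columns `baseline`, `fold_change`,
#'   `donor_bin` (logical).
#' @export
classify_donor_bins <- function(profile, baseline, fold = 5,
                                min_baseline = 1.0, min_count = 10,
                                use_matching = FALSE) {
  stopifnot(nrow(profile) == nrow(baseline),
            all(profile$start == baseline$start),
            all(profile$chrom == baseline$chrom))
  count <- if (use_matching) profile$matching else profile$total
  floor_base <- pmax(baseline$baseline, min_baseline)
  profile$baseline <- baseline$baseline
  profile$fold_change <- count / floor_base
  profile$donor_bin <- count >= fold * floor_base & count >= min_count
  profile
}

#' Merge classified donor bins into segments
#'
#' Maximal runs of donor bins separated by at most `max_gap_bins`
#' non-donor bins are merged into contiguous segments; gap bins are
#' included in the span and counted in `n_gap_bins`.
#'
#' @param classified output of [classify_donor_bins()].
#' @param max_gap_bins tolerated internal gap, in bins (default 0).
#' @param line,donor labels carried into the output.
#' @return data.frame `line`, `donor`, `chrom`, `start`, `end` (0-based
#'   half-open, bin-aligned), `n_bins`, `n_gap_bins`, `mean_fold_change`,
#'   `mean_match_prop`.
#' @export
merge_segments <- function(classified, max_gap_bins = 0,
                           line = NA_character_, donor = NA_character_) {
  out <- list()
  for (ch in unique(classified$chrom)) {
    cc <- classified[classified$chrom == ch, , drop = FALSE]
    cc <- cc[order(cc$start), , drop = FALSE]
    idx <- which(cc$donor_bin)
    if (length(idx) == 0) next
    run_start <- idx[1]
    prev <- idx[1]
    runs <- list()
    for (i in idx[-1]) {
      if (i - prev - 1 > max_gap_bins) {
        runs[[length(runs) + 1]] <- c(run_start, prev)
        run_start <- i
      }
      prev <- i
    }
    runs[[length(runs) + 1]] <- c(run_start, prev)
    for (r in runs) {
      span <- cc[r[1]:r[2], , drop = FALSE]
      donor_rows <- span[span$donor_bin, , drop = FALSE]
      mp <- sum(donor_rows$matching) / max(sum(donor_rows$total), 1)
      out[[length(out) + 1]] <- data.frame(
        line = line, donor = donor, chrom = ch,
        start = span$start[1], end = span$end[nrow(span)],
        n_bins = nrow(span), n_gap_bins = sum(!span$donor_bin),
        mean_fold_change = mean(donor_rows$fold_change),
        mean_match_prop = mp, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(line = character(), donor = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), n_bins = integer(),
                      n_gap_bins = integer(), mean_fold_change = numeric(),
                      mean_match_prop = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Donor fraction of a subgenome
#'
#' `100 * sum(segment lengths) / sum(subgenome chromosome lengths)`.
#'
#' @param segments data.frame with `chrom`, `start`, `end` (bin-aligned
#'   donor segments of one line).
#' @param chrom_sizes data.frame `chrom`, `length`.
#' @param subgenome `"A"`, `"B"` or `"D"`.
#' @param subgenome_map optional chrom -> subgenome override.
#' @return Percentage in \[0, 100\].
#' @export
donor_fraction <- function(segments, chrom_sizes, subgenome,
                           subgenome_map = NULL) {
  sg <- subgenome_of(chrom_sizes$chrom, subgenome_map)
  if (!subgenome %in% sg) stop("unknown subgenome: ", subgenome)
  denom <- sum(chrom_sizes$length[sg == subgenome])
  if (nrow(segments) == 0) return(0)
  seg_sg <- subgenome_of(segments$chrom, subgenome_map)
  keep <- segments[seg_sg == subgenome, , drop = FALSE]
  100 * sum(keep$end - keep$start) / denom
}

#' Panel-union donor bin accounting
#'
#' Unions classified donor bins across lines (non-redundant), returning the
#' bin count, total span (truncated terminal bins contribute their true
#' width) and the percentage of the subgenome covered.
#'
#' @param classified_list list of [classify_donor_bins()] outputs, one per
#'   line, on a common binning.
#' @param chrom_sizes data.frame `chrom`, `length`; when supplied with
#'   `subgenome`, the percentage denominator is that subgenome's length.
#' @param subgenome optional subgenome label for the percentage.
#' @param subgenome_map optional chrom -> subgenome override.
#' @return list with `n_bins`, `span_gbp` (rounded to 2 decimals),
#'   `span_bp`, `pct_of_subgenome` (NA without `chrom_sizes`), and `bins`
#'   (the union as a data.frame `chrom`, `start`, `end`).
#' @export
panel_union <- function(classified_list, chrom_sizes = NULL,
                        subgenome = NULL, subgenome_map = NULL) {
  stopifnot(length(classified_list) >= 1)
  donor_rows <- lapply(classified_list, function(p)
    p[p$donor_bin, c("chrom", "start", "end"), drop = FALSE])
  u <- do.call(rbind, donor_rows)
  if (nrow(u) > 0) {
    u <- u[!duplicated(paste0(u$chrom, ":", u$start)), , drop = FALSE]
    u <- u[order(u$chrom, u$start), , drop = FALSE]
  }
  rownames(u) <- NULL
  span <- sum(u$end - u$start)
  pct <- NA_real_
  if (!is.null(chrom_sizes) && !is.null(subgenome)) {
    sg <- subgenome_of(chrom_sizes$chrom, subgenome_map)
    pct <- 100 * span / sum(chrom_sizes$length[sg == subgenome])
  }
  list(n_bins = nrow(u), span_gbp = round(span / 1e9, 2), span_bp = span,
       pct_of_subgenome = pct, bins = u)
}

#' Theoretical pedigree contribution by dilution
#'
#' Each cross after the original cross with the primary donor parent halves
#' the expected donor contribution: `100 * 0.5^n` percent.
#'
#' @param n_crosses_after_primary non-negative integer (vectorised).
#' @return Percentage(s).
#' @export
theoretical_contribution <- function(n_crosses_after_primary) {
  n <- n_crosses_after_primary
  if (any(is.na(n)) || any(n < 0) || any(n != floor(n)))
    stop("number of crosses must be a non-negative integer")
  100 * 0.5^n
}

#' Detect donor segments in one line
#'
#' End-to-end identity-by-state scan for a single line and donor: bin
#' profile, fold-rule classification against the elite baseline, and
#' segment merging. The same machinery serves the synthetic-donor D-genome
#' scan and alien introgressions (rye, *T. ponticum*) on any subgenome.
#'
#' @param gm designated (and varietal-masked) [genotype_matrix()].
#' @param sample line name.
#' @param donor a [donor_snpset()].
#' @param baseline [elite_baseline()] on the same binning.
#' @param chrom_sizes data.frame `chrom`, `length`.
#' @param bin_width bin width in bp.
#' @param fold,min_baseline,min_count,use_matching see
#'   [classify_donor_bins()].
#' @param max_gap_bins see [merge_segments()].
#' @return list with `segments` (data.frame) and `classified` (per-bin
#'   table).
#' @export
detect_alien <- function(gm, sample, donor, baseline, chrom_sizes,
                         bin_width = 5e5, fold = 5, min_baseline = 1.0,
                         min_count = 10, use_matching = FALSE,
                         max_gap_bins = 0) {
  prof <- bin_match_profile(gm, sample, donor, chrom_sizes, bin_width)
  cls <- classify_donor_bins(prof, baseline, fold = fold,
                             min_baseline = min_baseline,
                             min_count = min_count,
                             use_matching = use_matching)
  segs <- merge_segments(cls, max_gap_bins = max_gap_bins, line = sample,
                         donor = attr(donor, "donor") %||% "donor")
  list(segments = segs, classified = cls)
}

#' Write segments as BED6
#'
#' `chrom  start  end  line;donor  fold  .` (0-based half-open).
#' @param segments data.frame from [merge_segments()].
#' @param path output file.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(segments$chrom, segments$start, segments$end,
                    paste(segments$line, segments$donor, sep = ";"),
                    round(segments$mean_fold_change, 3), ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Bin-level recovery statistics against a truth segment set
#'
#' Compares predicted donor bins with truth segments at bin resolution.
#' Truth bins are bins at least half covered by a truth segment; a one-bin
#' boundary tolerance is applied on both sides (a predicted bin adjacent
#' to a truth bin is not a false positive, and vice versa), matching the
#' block granularity of crossover-delimited segments.
#'
#' @param classified [classify_donor_bins()] output for one line.
#' @param truth_segments data.frame `chrom`, `start`, `end` of the line's
#'   true donor segments (0-based half-open).
#' @param min_cover minimum covered fraction for a truth bin (default 0.5).
#' @return list with `precision`, `recall`, `n_pred`, `n_truth`.
#' @export
recovery_stats <- function(classified, truth_segments, min_cover = 0.5) {
  cover <- numeric(nrow(classified))
  if (nrow(truth_segments) > 0) {
    for (i in seq_len(nrow(truth_segments))) {
      ts <- truth_segments[i, ]
      ov <- pmin(classified$end, ts$end) - pmax(classified$start, ts$start)
      same <- classified$chrom == ts$chrom
      cover <- cover + ifelse(same, pmax(ov, 0), 0)
    }
  }
  width <- classified$end - classified$start
  truth_bin <- cover / width >= min_cover
  near <- function(x) {  # dilate by one bin within each chromosome
    out <- x
    for (ch in unique(classified$chrom)) {
      ii <- which(classified$chrom == ch)
      xi <- x[ii]
      out[ii] <- xi | c(FALSE, xi[-length(xi)]) | c(xi[-1], FALSE)
    }
    out
  }
  pred <- classified$donor_bin
  tp_pred <- pred & near(truth_bin)
  tp_truth <- truth_bin & near(pred)
  list(precision = if (sum(pred) == 0) NA_real_ else mean(tp_pred[pred]),
       recall = if (sum(truth_bin) == 0) NA_real_ else mean(tp_truth[truth_bin]),
       n_pred = sum(pred), n_truth = sum(truth_bin))
}
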