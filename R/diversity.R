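#' Tile chromosomes into fixed-width bins
#'
#' Bins are 0-based half-open `[i*w, (i+1)*w)`, anchored at position 0 per
#' chromosome; the last bin is truncated at the chromosome end.
#'
#' @param chrom_sizes data.frame `chrom`, `length`.
#' @param bin_width bin width in bp (default 500 kbp).
#' @return data.frame `chrom`, `start`, `end`, `bin` (key `"chrom:start"`).
#' @export
make_bins <- function(chrom_sizes, bin_width = 5e5) {
  if (bin_width <= 0) stop("bin_width must be positive")
  out <- do.call(rbind, lapply(seq_len(nrow(chrom_sizes)), function(i) {
    len <- chrom_sizes$length[i]
    start <- seq(0, len - 1, by = bin_width)
    data.frame(chrom = chrom_sizes$chrom[i], start = start,
               end = pmin(start + bin_width, len),
               stringsAsFactors = FALSE)
  }))
  out$bin <- paste0(out$chrom, ":", format(out$start, scientific = FALSE, trim = TRUE))
  rownames(out) <- NULL
  out
}

# bin key ("chrom:start") for 1-based positions
bin_key_of <- function(chrom, pos, bin_width) {
  if (length(pos) == 0) return(character(0))
  start <- (ceiling(pos / bin_width) - 1) * bin_width
  paste0(chrom, ":", format(start, scientific = FALSE, trim = TRUE))
}

#' Per-line SNP counts by chromosome or subgenome
#'
#' A SNP is counted for a sample iff the call is homozygous alternate
#' (the panel analysis counts homozygous SNPs per line); heterozygous
#' calls are excluded with a message. Subgenome counts sum the unit's
#' chromosomes.
#'
#' @param gm designated [genotype_matrix()].
#' @param unit `"chromosome"` or `"subgenome"`.
#' @param subgenome_map optional named vector chrom -> subgenome (see
#'   [subgenome_of()]).
#' @return Integer matrix samples x units.
#' @export
per_line_snp_counts <- function(gm, unit = c("chromosome", "subgenome"),
                                subgenome_map = NULL) {
  unit <- match.arg(unit)
  n_het <- sum(gm$calls == CALL_HET, na.rm = TRUE)
  if (n_het > 0)
    message(n_het, " heterozygous call(s) excluded from per-line SNP counts")
  hom_alt <- gm$calls == CALL_HOM_ALT
  hom_alt[is.na(hom_alt)] <- FALSE
  grp <- if (unit == "chromosome") gm$loci$chrom else
    subgenome_of(gm$loci$chrom, subgenome_map)
  units <- sort(unique(grp))
  out <- sapply(units, function(u) colSums(hom_alt[grp == u, , drop = FALSE]))
  out <- matrix(as.integer(out), nrow = length(gm$samples),
                dimnames = list(gm$samples, units))
  out
}

#' Elite-vs-exotic SNP density contrast
#'
#' Percentage difference of mean per-line SNP counts,
#' `100 * (exotic - elite) / elite`, rounded to 2 decimals for reporting.
#' Accepts per-line count vectors (means are taken) or already-averaged
#' scalar means.
#'
#' @param elite_counts numeric vector of per-line counts (or a scalar mean)
#'   for the elite subpopulation.
#' @param exotic_counts same for the exotic subpopulation.
#' @param unit optional unit label carried into the result.
#' @return data.frame `unit`, `elite_mean`, `exotic_mean`, `pct_difference`
#'   (NA when the elite mean is 0).
#' @export
density_contrast <- function(elite_counts, exotic_counts, unit = NA_character_) {
  if (length(elite_counts) == 0 || length(exotic_counts) == 0)
    stop("both groups must be non-empty")
  el <- mean(elite_counts)
  ex <- mean(exotic_counts)
  pct <- if (el > 0) round(100 * (ex - el) / el, 2) else NA_real_
  data.frame(unit = unit, elite_mean = el, exotic_mean = ex,
             pct_difference = pct, stringsAsFactors = FALSE)
}

#' Contrast table across units
#'
#' Applies [density_contrast()] to every column of per-line count matrices
#' (as returned by [per_line_snp_counts()]), mirroring a per-chromosome /
#' per-subgenome contrast table.
#'
#' @param elite_counts,exotic_counts samples x units count matrices on the
#'   same units.
#' @return data.frame, one row per unit.
#' @export
density_contrast_table <- function(elite_counts, exotic_counts) {
  stopifnot(identical(colnames(elite_counts), colnames(exotic_counts)))
  do.call(rbind, lapply(colnames(elite_counts), function(u)
    density_contrast(elite_counts[, u], exotic_counts[, u], unit = u)))
}

#' Binned SNP density track
#'
#' Counts qualifying SNPs per fixed-width bin: panel-level (all loci in the
#' matrix) when `sample` is `NULL`, or a single line's homozygous-alternate
#' calls otherwise.
#'
#' @param gm a [genotype_matrix()].
#' @param chrom_sizes data.frame `chrom`, `length`.
#' @param bin_width bin width in bp; 1e5 for density heatmap tracks, 5e5
#'   for introgression work.
#' @param sample optional sample name.
#' @return data.frame `chrom`, `start`, `end`, `count` tiling every
#'   chromosome in `chrom_sizes`.
#' @export
binned_density <- function(gm, chrom_sizes, bin_width = 5e5, sample = NULL) {
  bins <- make_bins(chrom_sizes, bin_width)
  if (is.null(sample)) {
    keep <- rep(TRUE, nrow(gm$loci))
  } else {
    if (!sample %in% gm$samples) stop("unknown sample: ", sample)
    keep <- gm$calls[, sample] == CALL_HOM_ALT
    keep[is.na(keep)] <- FALSE
  }
  key <- bin_key_of(gm$loci$chrom[keep], gm$loci$pos[keep], bin_width)
  tab <- table(key)
  bins$count <- as.integer(tab[bins$bin])
  bins$count[is.na(bins$count)] <- 0L
  bins[, c("chrom", "start", "end", "count")]
}

#' Write a track as BEDGRAPH-style TSV
#'
#' @param track data.frame with `chrom`, `start`, `end` and one value column.
#' @param path output file.
#' @param value name of the value column (default: fourth column).
#' @export
write_track <- function(track, path, value = names(track)[4]) {
  utils::write.table(track[, c("chrom", "start", "end", value)], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
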