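#' Read a multi-sample VCF into a genotype matrix
#'
#' Loads biallelic SNP records in file order; multiallelic records and
#' indels are skipped with a message. Genotypes are mapped to the package's
#' integer call codes; `./.` no-calls become code `-1` awaiting
#' [apply_reference_call_rule()]. The `DP` FORMAT field is loaded when
#' present.
#'
#' @param path VCF file (v4.x, plain text or bgzipped).
#' @param chrom_sizes optional chromosome sizes (data.frame `chrom`,`length`
#'   as from [read_chrom_sizes()]); when given, positions are validated
#'   against it.
#'
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, chrom_sizes = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0) {
    samples <- colnames(v@gt)[-1]
    return(genotype_matrix(
      data.frame(chrom = character(), pos = integer(),
                 ref = character(), alt = character()),
      samples %||% character(),
      matrix(integer(), 0, length(samples))))
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!snp))
    message(sum(!snp), " non-biallelic-SNP record(s) skipped")
  loci <- data.frame(chrom = fix[snp, "CHROM"],
                     pos = as.integer(fix[snp, "POS"]),
                     ref = ref[snp], alt = alt[snp],
                     stringsAsFactors = FALSE)
  if (!is.null(chrom_sizes)) {
    len <- stats::setNames(chrom_sizes$length, chrom_sizes$chrom)
    unknown <- setdiff(unique(loci$chrom), names(len))
    if (length(unknown))
      stop("VCF contig(s) absent from chromosome sizes: ",
           paste(unknown, collapse = ", "))
    if (any(loci$pos > len[loci$chrom]))
      stop("VCF position(s) beyond chromosome length in: ",
           paste(unique(loci$chrom[loci$pos > len[loci$chrom]]), collapse = ", "))
  }
  samples <- colnames(v@gt)[-1]
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  calls <- matrix(CALL_NO_CALL, nrow(gt), ncol(gt))
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  known <- !is.na(gt) & a1 %in% c("0", "1") & a2 %in% c("0", "1")
  calls[known] <- as.integer(a1[known]) + as.integer(a2[known])
  depth <- NULL
  fmt <- if (n > 0) v@gt[1, "FORMAT"] else ""
  if (grepl("(^|:)DP(:|$)", fmt)) {
    depth <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    depth <- depth[snp, , drop = FALSE]
  }
  genotype_matrix(loci, samples, calls, depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a genotype matrix as VCFv4.2
#'
#' Emits plain-text VCF with `GT` (and `DP` when depth is present). Codes
#' map back to `0/0`, `0/1`, `1/1`; both `NA` (missing) and `-1` (no-call)
#' are written as `./.` — write/read round-trips are exact for undesignated
#' matrices.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @param chrom_sizes optional sizes table used to emit `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, chrom_sizes = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=exoscan")
  if (!is.null(chrom_sizes))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          chrom_sizes$chrom, as.integer(chrom_sizes$length)))
  hdr <- c(hdr,
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  has_dp <- !is.null(gm$depth)
  if (has_dp)
    hdr <- c(hdr,
             '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", gm$samples),
                      collapse = "\t"))
  gt_str <- matrix("./.", nrow(gm$calls), ncol(gm$calls))
  gt_str[which(gm$calls == 0L)] <- "0/0"
  gt_str[which(gm$calls == 1L)] <- "0/1"
  gt_str[which(gm$calls == 2L)] <- "1/1"
  if (has_dp) {
    dp <- gm$depth
    dp_str <- ifelse(is.na(dp), ".", as.character(dp))
    gt_str <- matrix(paste(gt_str, dp_str, sep = ":"),
                     nrow(gt_str), ncol(gt_str))
  }
  body <- if (nrow(gm$loci) == 0) character() else
    paste(gm$loci$chrom, gm$loci$pos, ".", gm$loci$ref, gm$loci$alt,
          ".", ".", ".", if (has_dp) "GT:DP" else "GT",
          apply(gt_str, 1, paste, collapse = "\t"),
          sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read/write chromosome sizes
#'
#' Two-column TSV `chrom<TAB>length` (no header).
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  if (any(df$length <= 0)) stop("chromosome lengths must be positive")
  df
}

#' @rdname read_chrom_sizes
#' @param chrom_sizes data.frame `chrom`,`length`.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  utils::write.table(chrom_sizes[, c("chrom", "length")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read panel metadata
#'
#' TSV with header `sample  group  n_crosses`; `group` is one of `elite`,
#' `landrace`, `synthetic`, `landrace_synthetic`, `introgression_line`.
#' Any non-elite label collapses to the exotic subpopulation.
#'
#' @param path file path.
#' @return data.frame with columns `sample`, `group`, `n_crosses` and a
#'   derived logical column `exotic`.
#' @export
read_panel_metadata <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(df)))
    stop("metadata must have columns 'sample' and 'group'")
  ok <- c("elite", "landrace", "synthetic", "landrace_synthetic",
          "introgression_line")
  bad <- setdiff(unique(df$group), ok)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (is.null(df$n_crosses)) df$n_crosses <- NA_integer_
  df$exotic <- df$group != "elite"
  df
}
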