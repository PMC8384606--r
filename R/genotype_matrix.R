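# Call codes used throughout: 0 = HOM_REF, 1 = HET, 2 = HOM_ALT,
# NA = MISSING (designated), -1 = NO_CALL (not yet designated).
CALL_HOM_REF <- 0L
CALL_HET <- 1L
CALL_HOM_ALT <- 2L
CALL_NO_CALL <- -1L

#' Construct a genotype matrix
#'
#' The central container of the pipeline: an ordered table of biallelic SNP
#' loci, a set of sample names, and a loci x samples integer call matrix.
#' Calls are coded `0` (homozygous reference), `1` (heterozygous), `2`
#' (homozygous alternate), `NA` (missing) and `-1` (no-call, i.e. not yet
#' designated by [apply_reference_call_rule()]).
#'
#' @param loci data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; one row per biallelic SNP, in genomic order.
#' @param samples character vector of sample names.
#' @param calls integer matrix, `nrow(loci)` x `length(samples)`.
#' @param depth optional integer matrix of per-call sequencing depth with the
#'   same dimensions as `calls`.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(loci, samples, calls, depth = NULL) {
  stopifnot(is.data.frame(loci),
            all(c("chrom", "pos", "ref", "alt") %in% names(loci)))
  if (nrow(loci) > 0) {
    if (any(loci$pos < 1)) stop("locus positions must be >= 1")
    if (any(loci$ref == loci$alt)) stop("ref and alt alleles must differ")
  }
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(loci) || ncol(calls) != length(samples))
    stop("call matrix must be nrow(loci) x length(samples)")
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% c(-1L, 0L, 1L, 2L)))
    stop("calls must be coded -1, 0, 1, 2 or NA")
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    if (!all(dim(depth) == dim(calls)))
      stop("depth matrix must match call matrix dimensions")
    if (any(depth[!is.na(depth)] < 0)) stop("depth must be non-negative")
  }
  rownames(calls) <- NULL
  colnames(calls) <- samples
  loci$chrom <- as.character(loci$chrom)
  loci$pos <- as.integer(loci$pos)
  rownames(loci) <- NULL
  structure(list(loci = loci[, c("chrom", "pos", "ref", "alt")],
                 samples = as.character(samples),
                 calls = calls, depth = depth),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d loci x %d samples\n",
              nrow(x$loci), length(x$samples)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$loci$chrom), collapse = ", ")))
  n_nc <- sum(x$calls == CALL_NO_CALL, na.rm = TRUE)
  cat(sprintf("  missing: %d, undesignated no-calls: %d, depth: %s\n",
              sum(is.na(x$calls)), n_nc,
              if (is.null(x$depth)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$loci), length(x$samples))

# "chrom:pos:alt" keys used for identity-by-state matching and masking
locus_keys <- function(loci) paste(loci$chrom, loci$pos, loci$alt, sep = ":")

# subset loci by logical/integer index, keeping matrices in step
subset_loci <- function(gm, keep) {
  genotype_matrix(gm$loci[keep, , drop = FALSE], gm$samples,
                  gm$calls[keep, , drop = FALSE],
                  if (is.null(gm$depth)) NULL else gm$depth[keep, , drop = FALSE])
}

#' Map chromosome names to subgenomes
#'
#' Wheat chromosome names end in the subgenome letter (e.g. `chr3D`, `1B`).
#' The suffix convention can be overridden with an explicit mapping.
#'
#' @param chrom character vector of chromosome names.
#' @param map optional named character vector `c(chrom = subgenome, ...)`
#'   overriding the suffix convention.
#'
#' @return Character vector of subgenome labels (`"A"`, `"B"`, `"D"`).
#' @export
subgenome_of <- function(chrom, map = NULL) {
  chrom <- as.character(chrom)
  if (!is.null(map)) {
    out <- unname(map[chrom])
    if (anyNA(out))
      stop("no subgenome mapping for: ",
           paste(unique(chrom[is.na(out)]), collapse = ", "))
    return(out)
  }
  suf <- sub(".*([ABD])$", "\\1", chrom)
  bad <- !suf %in% c("A", "B", "D")
  if (any(bad))
    stop("cannot infer subgenome from chromosome name(s): ",
         paste(unique(chrom[bad]), collapse = ", "),
         " (supply an explicit mapping)")
  suf
}
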