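#' Run the full analysis pipeline on a simulated or on-disk panel
#'
#' Orchestrates every stage end to end: call designation (depth rule),
#' varietal masking, per-line SNP counts and elite-vs-exotic density
#' contrasts, locus filtering (missing data + MAF) for the shared-locus
#' set, windowed Fst with the elite pseudo-split control, identity-by-state
#' introgression scanning against the donor set, and — when simulating —
#' spectral index computation and broad-sense heritability on generated
#' phenomics data. Introgression scanning runs on designated, masked,
#' per-line calls (before the shared-locus MAF filter, which serves the
#' population-genetic stages). A machine-readable JSON summary is written
#' alongside the tables.
#'
#' @param outdir output directory.
#' @param config a [sim_config()]; its `seed` drives every random stage.
#' @param bin_width introgression/Fst bin width in bp (default 500 kbp).
#' @param density_bin_width SNP-density track bin width (default 100 kbp).
#' @param fold,min_baseline,min_count donor-bin classification parameters
#'   (see [classify_donor_bins()]).
#' @param min_depth reference-designation depth threshold.
#' @param max_missing,min_maf locus filter thresholds.
#' @param n_spectra,n_trait_genotypes sizes of the phenomics stages.
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(outdir, config = sim_config(),
                         bin_width = 5e5, density_bin_width = 1e5,
                         fold = 5, min_baseline = 1.0, min_count = 10,
                         min_depth = 5, max_missing = 0.10, min_maf = 0.05,
                         n_spectra = 50, n_trait_genotypes = 100) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_panel(config)
  write_simulation(sim, file.path(outdir, "inputs"))
  meta <- sim$metadata
  elite <- meta$sample[meta$group == "elite"]
  exotic <- meta$sample[meta$group != "elite"]

  gm <- apply_reference_call_rule(sim$gm, min_depth = min_depth)
  gm_masked <- mask_varietal_snps(gm, sim$mask)

  counts <- per_line_snp_counts(gm_masked, unit = "subgenome")
  contrast <- if (length(exotic) > 0)
    density_contrast_table(counts[elite, , drop = FALSE],
                           counts[exotic, , drop = FALSE]) else NULL
  if (!is.null(contrast))
    utils::write.table(contrast, file.path(outdir, "density_contrast.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  gm_filt <- filter_loci(gm_masked, max_missing = max_missing,
                         min_maf = min_maf)
  dens <- binned_density(gm_filt, sim$chrom_sizes, density_bin_width)
  write_track(dens, file.path(outdir, "snp_density.bedgraph"))

  fst <- if (length(exotic) >= 2 && length(elite) >= 2)
    windowed_fst(gm_filt, elite, exotic, sim$chrom_sizes, bin_width) else NULL
  if (!is.null(fst))
    write_track(fst, file.path(outdir, "fst.bedgraph"), value = "fst")
  split_fst <- if (length(elite) >= 4)
    pseudo_split_control(gm_filt, elite, sim$chrom_sizes,
                         seed = config$seed + 3L, window = bin_width) else NULL

  baseline <- elite_baseline(gm_masked, elite, sim$chrom_sizes, bin_width)
  segments <- list()
  classified <- list()
  for (s in exotic) {
    det <- detect_alien(gm_masked, s, sim$donor, baseline, sim$chrom_sizes,
                        bin_width = bin_width, fold = fold,
                        min_baseline = min_baseline, min_count = min_count)
    segments[[s]] <- det$segments
    classified[[s]] <- det$classified
  }
  seg_all <- do.call(rbind, c(segments, list(make.row.names = FALSE)))
  if (!is.null(seg_all) && nrow(seg_all) > 0)
    write_segments_bed(seg_all, file.path(outdir, "introgressions.bed"))
  union <- if (length(classified) > 0)
    panel_union(classified, sim$chrom_sizes,
                subgenome = config$target_subgenome) else NULL
  fractions <- if (length(classified) > 0) data.frame(
    line = exotic,
    donor_fraction_pct = vapply(exotic, function(s)
      donor_fraction(segments[[s]], sim$chrom_sizes,
                     config$target_subgenome), numeric(1)),
    theoretical_pct = theoretical_contribution(
      meta$n_crosses[match(exotic, meta$sample)]),
    row.names = NULL) else NULL
  if (!is.null(fractions))
    utils::write.table(fractions, file.path(outdir, "donor_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  spec <- simulate_spectra(config, n_spectra)
  idx <- compute_all_indices(spec$spectra)
  utils::write.table(idx, file.path(outdir, "indices.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  traits <- simulate_traits(config, n_trait_genotypes)
  h2 <- heritability(traits)

  summary <- list(
    version = "1",
    seed = config$seed,
    parameters = list(bin_width = bin_width, fold = fold,
                      min_baseline = min_baseline, min_count = min_count,
                      min_depth = min_depth, max_missing = max_missing,
                      min_maf = min_maf),
    n_loci_raw = nrow(sim$gm$loci),
    n_loci_masked = nrow(gm_masked$loci),
    n_loci_filtered = nrow(gm_filt$loci),
    density_contrast = contrast,
    mean_fst = if (is.null(fst)) NA else mean(fst$fst_raw, na.rm = TRUE),
    mean_pseudo_split_fst = if (is.null(split_fst)) NA else
      mean(split_fst$fst_raw, na.rm = TRUE),
    panel_union = if (is.null(union)) NULL else
      union[c("n_bins", "span_gbp", "pct_of_subgenome")],
    donor_fractions = fractions,
    heritability = h2[c("sigma_g2", "sigma_ge2", "sigma_e2", "H2", "class")])
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  invisible(summary)
}
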