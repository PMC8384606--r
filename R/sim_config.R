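#' Default wheat-like chromosome layout
#'
#' Three chromosomes per subgenome, 55-100 Mbp each: a scaled-down
#' hexaploid layout that keeps every subgenome large enough to host
#' multi-block introgressions while staying fast to simulate.
#'
#' @return data.frame `chrom`, `length`, `subgenome`.
#' @export
default_chromosomes <- function() {
  data.frame(
    chrom = c("chr1A", "chr2A", "chr3A",
              "chr1B", "chr2B", "chr3B",
              "chr1D", "chr2D", "chr3D"),
    length = c(90e6, 70e6, 60e6,
               100e6, 80e6, 65e6,
               95e6, 75e6, 55e6),
    subgenome = rep(c("A", "B", "D"), each = 3),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defines the conditions of the emulated study panel: an elite
#' subpopulation with subgenome-specific background SNP densities (the D
#' genome is SNP-poor), an exotic subpopulation whose lines carry donor
#' haplotype blocks on the target subgenome, panel-vs-reference varietal
#' noise, per-call depth, missingness, pigment-driven leaf spectra and
#' genotype/GxE/error trait variance components.
#'
#' @param seed integer seed; identical seeds give byte-identical outputs.
#' @param chromosomes data.frame `chrom`, `length`, `subgenome`.
#' @param n_elite,n_exotic subpopulation sizes.
#' @param elite_snp_rate named per-subgenome background homozygous-SNP
#'   densities, SNPs/Mbp per line.
#' @param donor_snp_rate donor-vs-reference SNP density inside donor
#'   regions, SNPs/Mbp (at least 5x the elite rate of the target subgenome
#'   so donor blocks are detectable by the fold rule).
#' @param donor_fraction_range admissible donor fraction of the target
#'   subgenome per exotic line; realized pedigree fractions outside the
#'   range are clipped with a warning. Use `c(0, 0)` for a no-donor null
#'   panel.
#' @param crossovers_range crossovers per chromosome per cross (wheat:
#'   1-2).
#' @param n_crosses_range crosses after the primary synthetic cross; each
#'   round halves the expected donor content (dilution `0.5^n`).
#' @param target_subgenome subgenome receiving donor blocks (`"D"`).
#' @param donor_name donor taxon label.
#' @param background_carrier_freq frequency at which a background SNP is
#'   carried by a panel line (sets how many segregating background loci
#'   produce the per-line density).
#' @param varietal_rate scattered panel-monomorphic varietal SNPs
#'   (germplasm-vs-reference), SNPs/Mbp.
#' @param n_varietal_blocks,varietal_block_mbp,varietal_block_snp_rate,varietal_block_carrier_prob
#'   clustered varietal haplotype blocks segregating at low carrier
#'   frequency; these are the noise component that makes varietal masking
#'   load-bearing for introgression specificity.
#' @param missing_rate i.i.d. probability that a call is missing (low
#'   depth).
#' @param het_rate probability a carrier call is heterozygous (0 by
#'   default; the panel analysis is homozygous-call based).
#' @param mean_depth mean mapping depth of well-covered calls.
#' @param spectra list: `chl_range`, `car_range`, `water_range` (pigment /
#'   water absorption depths), `noise_sd`.
#' @param traits list: `mu`, `sigma_g2`, `sigma_ge2`, `sigma_e2`, `r`
#'   replicates, `e` environments.
#' @param alien_blocks optional data.frame `donor`, `chrom`, `start`,
#'   `end`, `line` implanting fixed alien introgressions (e.g. a rye 1B
#'   block) into named exotic lines.
#' @param alien_snp_rate SNP density of alien donor taxa vs the reference,
#'   SNPs/Mbp; alien species (rye, *T. ponticum*) are far more diverged
#'   from bread wheat than the D-lineage donor, and their blocks sit on
#'   the SNP-richer A/B backgrounds.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       chromosomes = default_chromosomes(),
                       n_elite = 20, n_exotic = 10,
                       elite_snp_rate = c(A = 16, B = 25, D = 9),
                       donor_snp_rate = 90,
                       donor_fraction_range = c(0.005, 0.43),
                       crossovers_range = c(1, 2),
                       n_crosses_range = c(2, 6),
                       target_subgenome = "D",
                       donor_name = "Ae_tauschii",
                       background_carrier_freq = 0.3,
                       varietal_rate = 2,
                       n_varietal_blocks = 8,
                       varietal_block_mbp = 2,
                       varietal_block_snp_rate = 90,
                       varietal_block_carrier_prob = 0.08,
                       missing_rate = 0.05,
                       het_rate = 0,
                       mean_depth = 20,
                       spectra = list(chl_range = c(0.2, 1.0),
                                      car_range = c(0.1, 0.5),
                                      water_range = c(0.2, 1.0),
                                      noise_sd = 0.002),
                       traits = list(mu = 50, sigma_g2 = 2, sigma_ge2 = 1,
                                     sigma_e2 = 4, r = 4, e = 2),
                       alien_blocks = NULL,
                       alien_snp_rate = 250) {
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length", "subgenome") %in% names(chromosomes)))
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be > 0")
  rates <- c(elite_snp_rate, donor_snp_rate, varietal_rate,
             varietal_block_snp_rate)
  if (any(rates < 0)) stop("rates must be >= 0")
  if (length(donor_fraction_range) != 2 ||
      donor_fraction_range[1] > donor_fraction_range[2] ||
      donor_fraction_range[1] < 0 || donor_fraction_range[2] > 1)
    stop("donor_fraction_range must satisfy 0 <= min <= max <= 1")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate in [0,1]")
  if (n_elite < 0 || n_exotic < 0) stop("subpopulation sizes must be >= 0")
  if (!target_subgenome %in% chromosomes$subgenome)
    stop("target_subgenome absent from chromosome table")
  if (any(spectra$noise_sd < 0) || any(unlist(spectra) < 0))
    stop("spectra parameters must be non-negative")
  structure(list(
    seed = seed, chromosomes = chromosomes, n_elite = n_elite,
    n_exotic = n_exotic, elite_snp_rate = elite_snp_rate,
    donor_snp_rate = donor_snp_rate,
    donor_fraction_range = donor_fraction_range,
    crossovers_range = crossovers_range,
    n_crosses_range = n_crosses_range,
    target_subgenome = target_subgenome, donor_name = donor_name,
    background_carrier_freq = background_carrier_freq,
    varietal_rate = varietal_rate,
    n_varietal_blocks = n_varietal_blocks,
    varietal_block_mbp = varietal_block_mbp,
    varietal_block_snp_rate = varietal_block_snp_rate,
    varietal_block_carrier_prob = varietal_block_carrier_prob,
    missing_rate = missing_rate, het_rate = het_rate,
    mean_depth = mean_depth, spectra = spectra, traits = traits,
    alien_blocks = alien_blocks, alien_snp_rate = alien_snp_rate),
    class = "sim_config")
}
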