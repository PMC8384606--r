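#' Simulate leaf reflectance spectra with known pigment drivers
#'
#' Builds leaf-like reflectance curves on a 350-2500 nm 1-nm grid from a
#' smooth baseline (low visible reflectance with a green bump, a
#' near-infrared plateau, declining short-wave infrared) and three
#' Gaussian absorption features whose depths are the simulated truths:
#' chlorophyll (centred 675 nm, reaching the 700 nm red-edge shoulder),
#' carotenoid (centred 490 nm) and leaf water (centred 1450 nm). Higher
#' chlorophyll therefore lowers reflectance near 675/700 nm and higher
#' water content lowers it near 1450 nm, so index-vs-truth rank
#' correlations are testable by construction. Additive Gaussian noise of
#' sd `noise_sd` is applied and reflectance clipped to \[0, 1\].
#'
#' @param config a [sim_config()] (uses `seed` and `spectra`).
#' @param n_samples number of leaves to simulate.
#' @param pigments optional data.frame `chl`, `car`, `water` overriding the
#'   random draws (recycled to `n_samples`); negative values are rejected.
#' @return list: `spectra` (wide data.frame, `wavelength_nm` + one column
#'   per sample) and `truth` (data.frame `sample`, `chl`, `car`, `water`).
#' @export
simulate_spectra <- function(config, n_samples, pigments = NULL) {
  stopifnot(inherits(config, "sim_config"), n_samples >= 1)
  sp <- config$spectra
  set.seed(config$seed + 1L)
  if (is.null(pigments)) {
    pigments <- data.frame(
      chl = stats::runif(n_samples, sp$chl_range[1], sp$chl_range[2]),
      car = stats::runif(n_samples, sp$car_range[1], sp$car_range[2]),
      water = stats::runif(n_samples, sp$water_range[1], sp$water_range[2]))
  } else {
    pigments <- as.data.frame(lapply(pigments, rep_len, n_samples))
    if (any(unlist(pigments) < 0))
      stop("pigment parameters must be non-negative")
  }
  wl <- 350:2500
  base <- leaf_baseline(wl)
  gauss <- function(centre, width) exp(-((wl - centre)^2) / (2 * width^2))
  chl_band <- gauss(675, 18) + 0.6 * gauss(430, 25)
  car_band <- gauss(490, 18)
  water_band <- gauss(1450, 45) + 0.5 * gauss(1930, 60)
  out <- matrix(NA_real_, length(wl), n_samples)
  for (i in seq_len(n_samples)) {
    refl <- base * exp(-(pigments$chl[i] * chl_band +
                           pigments$car[i] * car_band +
                           pigments$water[i] * water_band))
    if (sp$noise_sd > 0)
      refl <- refl + stats::rnorm(length(wl), 0, sp$noise_sd)
    out[, i] <- pmin(pmax(refl, 0), 1)
  }
  samples <- sprintf("LEAF%03d", seq_len(n_samples))
  spectra <- data.frame(wavelength_nm = wl, out, check.names = FALSE)
  names(spectra)[-1] <- samples
  list(spectra = spectra,
       truth = data.frame(sample = samples, pigments,
                          stringsAsFactors = FALSE))
}

# smooth leaf-like reflectance baseline before pigment/water absorption
leaf_baseline <- function(wl) {
  vis <- 0.12 + 0.08 * exp(-((wl - 550)^2) / (2 * 40^2))
  edge <- 1 / (1 + exp(-(wl - 715) / 12))        # red edge to NIR plateau
  nir <- 0.52
  swir_decay <- 1 - 0.25 * pmax(wl - 1350, 0) / 1150
  (vis * (1 - edge) + nir * edge) * swir_decay
}

#' Simulate a multi-environment trait table
#'
#' `value(g, y, rep) = mu + G_g + GY_gy + error`, with the genotype,
#' genotype-by-year and error effects drawn from centred normal
#' distributions with the configured variances — the generative model
#' matching the expected-mean-squares estimator in [heritability()].
#'
#' @param config a [sim_config()] (uses `seed` and `traits`:
#'   `mu`, `sigma_g2`, `sigma_ge2`, `sigma_e2`, `r` >= 2 replicates,
#'   `e` >= 2 environments).
#' @param n_genotypes number of genotypes.
#' @param trait trait label written into the table.
#' @return Long data.frame `genotype`, `year`, `rep`, `trait`, `value`.
#' @export
simulate_traits <- function(config, n_genotypes, trait = "trait1") {
  stopifnot(inherits(config, "sim_config"), n_genotypes >= 2)
  tc <- config$traits
  if (tc$r < 1 || tc$e < 1) stop("r and e must be >= 1")
  set.seed(config$seed + 2L)
  genotypes <- sprintf("G%04d", seq_len(n_genotypes))
  years <- sprintf("Y%02d", seq_len(tc$e))
  G <- stats::rnorm(n_genotypes, 0, sqrt(tc$sigma_g2))
  GY <- matrix(stats::rnorm(n_genotypes * tc$e, 0, sqrt(tc$sigma_ge2)),
               n_genotypes, tc$e)
  df <- expand.grid(rep = seq_len(tc$r), year = seq_len(tc$e),
                    genotype = seq_len(n_genotypes))
  df$value <- tc$mu + G[df$genotype] + GY[cbind(df$genotype, df$year)] +
    stats::rnorm(nrow(df), 0, sqrt(tc$sigma_e2))
  data.frame(genotype = genotypes[df$genotype], year = years[df$year],
             rep = df$rep, trait = trait, value = df$value,
             stringsAsFactors = FALSE)
}
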