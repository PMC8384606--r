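# Registry of leaf hyperspectral reflectance indices. Each formula is a
# function of R(), a reflectance accessor by wavelength in nm. SIPI and
# NDMI are implemented in the exact subscript form used for this index set
# (which differs from some literature variants); a literature SIPI is
# available via `sipi_variant`.
index_formulas <- list(
  GNDVI       = function(R) (R(780) - R(550)) / (R(780) + R(550)),
  RNDVI       = function(R) (R(780) - R(670)) / (R(780) + R(670)),
  NDII        = function(R) (R(850) - R(1650)) / (R(850) + R(1650)),
  NDMI        = function(R) (R(1649) - R(1722)) / (R(1649) + R(1722)),
  EVI         = function(R) 2.5 * ((R(900) - R(680)) /
                                     (R(900) + 6 * R(680) - 7.5 * R(475) + 1)),
  RARSa       = function(R) R(675) / R(700),
  PSSRa       = function(R) R(800) / R(675),
  RARSb       = function(R) R(675) / (R(650) * R(700)),
  RARSc       = function(R) R(760) / R(500),
  SIPI        = function(R) (R(800) - R(435)) / (R(415) + R(435)),
  TotalChl_550 = function(R) R(750) / R(550),
  TotalChl_700 = function(R) R(750) / R(700),
  NPQI        = function(R) (R(415) - R(435)) / (R(415) + R(435)),
  PSRI        = function(R) (R(680) - R(570)) / (R(531) - R(570)),
  WI2         = function(R) R(1100) / R(1200),
  WI3         = function(R) R(1300) / R(1450),
  WI4         = function(R) R(1300) / R(1200)
)

#' Names of the registered spectral indices
#'
#' The registry covers vegetation (GNDVI, RNDVI, NDII, NDMI, EVI), pigment
#' (RARSa, PSSRa, RARSb, RARSc, SIPI, TotalChl_550, TotalChl_700),
#' senescence (NPQI, PSRI) and water (WI2, WI3, WI4) indices.
#'
#' @return Character vector of 17 index names.
#' @export
spectral_index_registry <- function() names(index_formulas)

# reflectance accessor: nearest wavelength within 1 nm, else linear
# interpolation; errors outside the measured range
make_reflectance_accessor <- function(wavelength, reflectance) {
  ord <- order(wavelength)
  wl <- wavelength[ord]
  re <- reflectance[ord]
  function(target) {
    i <- which.min(abs(wl - target))
    if (abs(wl[i] - target) <= 1) return(re[i])
    if (target < wl[1] || target > wl[length(wl)])
      stop("wavelength ", target, " nm outside spectrum range")
    stats::approx(wl, re, xout = target)$y
  }
}

#' Compute one spectral index for a single spectrum
#'
#' Wavelength lookup is nearest-neighbour within 1 nm, with linear
#' interpolation for coarser grids. Near-zero denominators (|den| < 1e-9,
#' possible for PSRI when R531 is close to R570) yield `NA` with a warning.
#'
#' @param wavelength numeric vector of wavelengths in nm (ascending).
#' @param reflectance numeric vector of reflectances in \[0, 1\].
#' @param name a registry index name (see [spectral_index_registry()]).
#' @param sipi_variant `"as_printed"` (default) uses
#'   `(R800 - R435)/(R415 + R435)`; `"literature"` uses
#'   `(R800 - R445)/(R800 - R680)`.
#' @return Numeric index value (or `NA` on degenerate denominator).
#' @export
compute_index <- function(wavelength, reflectance, name,
                          sipi_variant = c("as_printed", "literature")) {
  sipi_variant <- match.arg(sipi_variant)
  if (!name %in% names(index_formulas))
    stop("unknown index: ", name)
  R <- make_reflectance_accessor(wavelength, reflectance)
  f <- index_formulas[[name]]
  if (name == "SIPI" && sipi_variant == "literature")
    f <- function(R) (R(800) - R(445)) / (R(800) - R(680))
  num_den <- index_num_den(name, R, sipi_variant)
  if (!is.null(num_den) && abs(num_den$den) < 1e-9) {
    warning("near-zero denominator for ", name, "; returning NA")
    return(NA_real_)
  }
  f(R)
}

# numerator/denominator decomposition used only for the degenerate-
# denominator guard
index_num_den <- function(name, R, sipi_variant) {
  den <- switch(name,
    GNDVI = R(780) + R(550), RNDVI = R(780) + R(670),
    NDII = R(850) + R(1650), NDMI = R(1649) + R(1722),
    EVI = R(900) + 6 * R(680) - 7.5 * R(475) + 1,
    RARSa = R(700), PSSRa = R(675), RARSb = R(650) * R(700),
    RARSc = R(500),
    SIPI = if (sipi_variant == "literature") R(800) - R(680) else R(415) + R(435),
    TotalChl_550 = R(550), TotalChl_700 = R(700),
    NPQI = R(415) + R(435), PSRI = R(531) - R(570),
    WI2 = R(1200), WI3 = R(1450), WI4 = R(1200),
    NULL)
  if (is.null(den)) NULL else list(den = den)
}

#' Compute all (or a subset of) registered indices for a spectra table
#'
#' @param spectra wide data.frame: first column `wavelength_nm`, one column
#'   per sample (as read by [read_spectra()]).
#' @param indices index names (default: full registry, fixed order).
#' @param sipi_variant see [compute_index()].
#' @return data.frame samples x indices with a leading `sample` column;
#'   per-cell `NA`s are propagated, not dropped.
#' @export
compute_all_indices <- function(spectra, indices = spectral_index_registry(),
                                sipi_variant = c("as_printed", "literature")) {
  sipi_variant <- match.arg(sipi_variant)
  stopifnot(names(spectra)[1] == "wavelength_nm")
  bad <- setdiff(indices, spectral_index_registry())
  if (length(bad)) stop("unknown index name(s): ", paste(bad, collapse = ", "))
  samples <- names(spectra)[-1]
  wl <- spectra$wavelength_nm
  out <- matrix(NA_real_, length(samples), length(indices),
                dimnames = list(samples, indices))
  for (s in samples) {
    for (ix in indices) {
      out[s, ix] <- suppressWarnings(
        compute_index(wl, spectra[[s]], ix, sipi_variant))
    }
  }
  data.frame(sample = samples, out, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read / write wide spectra tables
#'
#' TSV with header; first column `wavelength_nm`, one column per sample.
#' @param path file path.
#' @return data.frame.
#' @export
read_spectra <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  if (names(df)[1] != "wavelength_nm")
    stop("first column must be 'wavelength_nm'")
  df
}

#' @rdname read_spectra
#' @param spectra wide spectra data.frame.
#' @export
write_spectra <- function(spectra, path) {
  utils::write.table(spectra, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
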