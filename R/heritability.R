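#' Broad-sense heritability from a multi-environment trait table
#'
#' Estimates variance components from the balanced two-way
#' genotype x environment ANOVA with replicates, by expected mean squares:
#' `sigma_e2 = MS_error`, `sigma_ge2 = (MS_GE - MS_error) / r`,
#' `sigma_g2 = (MS_G - MS_GE) / (r * e)`, each floored at 0, then
#'
#' `H2 = sigma_g2 / (sigma_g2 + sigma_ge2 / e + sigma_e2 / (r * e))`
#'
#' with `r` replicates and `e` environments (years).
#'
#' @param table long trait data.frame with columns `genotype`, `year`,
#'   `rep`, `trait`, `value`.
#' @param trait trait name to analyse (may be omitted when the table holds
#'   a single trait).
#' @param r,e replicates and environments; inferred from the table when
#'   `NULL`. The replicate count is a design property of the measurement
#'   (e.g. 4 agronomic reps vs 2 spectral readings), so pass it explicitly
#'   when the table is a summary.
#' @return list of class `heritability_result`: `sigma_g2`, `sigma_ge2`,
#'   `sigma_e2`, `H2`, `class` (see [classify_h2()]), `r`, `e`,
#'   `n_genotypes`.
#' @export
heritability <- function(table, trait = NULL, r = NULL, e = NULL) {
  stopifnot(all(c("genotype", "year", "rep", "value") %in% names(table)))
  if (!is.null(trait)) {
    if (!"trait" %in% names(table)) stop("table has no 'trait' column")
    table <- table[table$trait == trait, , drop = FALSE]
    if (nrow(table) == 0) stop("no rows for trait: ", trait)
  }
  g <- factor(table$genotype)
  y <- factor(table$year)
  if (nlevels(g) < 2) stop("need >= 2 genotypes")
  if (nlevels(y) < 2) stop("need >= 2 environments")
  cell_n <- table(g, y)
  if (any(cell_n == 0))
    stop("unbalanced design: empty genotype x environment cell(s); ",
         "expected-mean-squares estimation needs a balanced table")
  r_obs <- unique(as.vector(cell_n))
  if (length(r_obs) > 1)
    stop("unbalanced design: replicate counts differ across cells (",
         paste(sort(r_obs), collapse = ", "), ")")
  if (r_obs < 2) stop("need >= 2 replicates per cell")
  e_n <- nlevels(y)
  if (is.null(r)) r <- r_obs
  if (is.null(e)) e <- e_n
  if (r != r_obs || e != e_n)
    warning("supplied r/e (", r, "/", e, ") differ from the table's (",
            r_obs, "/", e_n, "); using supplied values in the H2 ratio")
  fit <- stats::aov(value ~ g * y, data = data.frame(value = table$value, g = g, y = y))
  ms <- summary(fit)[[1]][["Mean Sq"]]
  names(ms) <- trimws(rownames(summary(fit)[[1]]))
  ms_g <- ms[["g"]]
  ms_ge <- ms[["g:y"]]
  ms_err <- ms[["Residuals"]]
  sigma_e2 <- max(ms_err, 0)
  sigma_ge2 <- max((ms_ge - ms_err) / r_obs, 0)
  sigma_g2 <- max((ms_g - ms_ge) / (r_obs * e_n), 0)
  H2 <- h2_from_components(sigma_g2, sigma_ge2, sigma_e2, r, e)
  structure(list(sigma_g2 = sigma_g2, sigma_ge2 = sigma_ge2,
                 sigma_e2 = sigma_e2, H2 = H2, class = classify_h2(H2),
                 r = r, e = e, n_genotypes = nlevels(g)),
            class = "heritability_result")
}

#' @export
print.heritability_result <- function(x, ...) {
  cat(sprintf("H2 = %.4f (%s)  [sigma_g2 %.4g, sigma_ge2 %.4g, sigma_e2 %.4g; r = %d, e = %d, %d genotypes]\n",
              x$H2, x$class, x$sigma_g2, x$sigma_ge2, x$sigma_e2,
              x$r, x$e, x$n_genotypes))
  invisible(x)
}

#' Broad-sense heritability from known variance components
#'
#' The entry-mean ratio
#' `H2 = sigma_g2 / (sigma_g2 + sigma_ge2 / e + sigma_e2 / (r * e))`.
#' Negative component values are truncated at 0 before the ratio.
#'
#' @param sigma_g2,sigma_ge2,sigma_e2 genotypic, genotype-by-environment
#'   and error variance components (trait units squared).
#' @param r replicates; `e` environments.
#' @param e environments (years).
#' @return H2 in \[0, 1\].
#' @export
h2_from_components <- function(sigma_g2, sigma_ge2, sigma_e2, r, e) {
  stopifnot(r >= 1, e >= 1)
  sigma_g2 <- pmax(sigma_g2, 0)
  sigma_ge2 <- pmax(sigma_ge2, 0)
  sigma_e2 <- pmax(sigma_e2, 0)
  denom <- sigma_g2 + sigma_ge2 / e + sigma_e2 / (r * e)
  ifelse(denom == 0, 0, sigma_g2 / denom)
}

#' Classify broad-sense heritability
#'
#' Low when `H2 < 0.30`, medium when `0.30 <= H2 < 0.60`, high when
#' `H2 >= 0.60`.
#'
#' @param H2 numeric in \[0, 1\] (vectorised).
#' @return Character vector in `{"low", "medium", "high"}`.
#' @export
classify_h2 <- function(H2) {
  if (any(is.na(H2)) || any(H2 < 0) || any(H2 > 1))
    stop("H2 must be in [0, 1]")
  ifelse(H2 >= 0.60, "high", ifelse(H2 >= 0.30, "medium", "low"))
}

#' Read / write long trait tables
#'
#' TSV with header `genotype  year  rep  trait  value`.
#' @param path file path.
#' @return data.frame.
#' @export
read_traits <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' @rdname read_traits
#' @param traits long trait data.frame.
#' @export
write_traits <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
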