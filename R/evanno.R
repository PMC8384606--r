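#' Evanno delta-K statistic from clustering log-likelihoods
#'
#' Given replicate log-likelihoods `L(K)` from externally produced Bayesian
#' clustering runs (one value per replicate per assumed subpopulation
#' number K), computes the rate-of-change statistic
#' `deltaK(K) = mean_r |L_r(K+1) - 2 L_r(K) + L_r(K-1)| / sd_r(L_r(K))`
#' for every interior K, and reports the argmax as the supported number of
#' subpopulations.
#'
#' @param table data.frame with columns `K`, `replicate`, `lnP` covering
#'   at least 3 consecutive K values with >= 2 replicates each.
#' @return list with `table` (data.frame `K`, `mean_lnP`, `sd_lnP`,
#'   `delta_k`; `delta_k` is `NA` at the boundary K) and `best_k`.
#' @export
evanno_delta_k <- function(table) {
  stopifnot(all(c("K", "replicate", "lnP") %in% names(table)))
  ks <- sort(unique(table$K))
  if (length(ks) < 3)
    stop("need >= 3 consecutive K values for delta-K")
  if (any(diff(ks) != 1))
    stop("K values must be consecutive integers")
  reps <- sort(unique(table$replicate))
  if (length(reps) < 2) stop("need >= 2 replicates per K")
  # replicate x K matrix of L(K), paired by replicate id
  L <- matrix(NA_real_, length(reps), length(ks),
              dimnames = list(as.character(reps), as.character(ks)))
  L[cbind(match(table$replicate, reps), match(table$K, ks))] <- table$lnP
  if (anyNA(L))
    stop("every replicate must have an lnP value at every K")
  sdL <- apply(L, 2, stats::sd)
  delta <- rep(NA_real_, length(ks))
  for (i in seq(2, length(ks) - 1)) {
    if (sdL[i] == 0)
      stop("degenerate replicates: sd(lnP) = 0 at K = ", ks[i])
    second <- abs(L[, i + 1] - 2 * L[, i] + L[, i - 1])
    delta[i] <- mean(second) / sdL[i]
  }
  out <- data.frame(K = ks, mean_lnP = colMeans(L), sd_lnP = sdL,
                    delta_k = delta)
  rownames(out) <- NULL
  list(table = out, best_k = ks[which.max(delta)])
}

#' Read an Evanno input table
#'
#' TSV with header `K  replicate  lnP`.
#' @param path file path.
#' @return data.frame suitable for [evanno_delta_k()].
#' @export
read_evanno_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
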