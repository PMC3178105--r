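# Two-point recombination-fraction estimation for an F2 intercross.
#
# Joint genotype probabilities for a pair of loci at recombination
# fraction r (genotypes coded 1=AA, 2=AB, 3=BB; both parents F1):
#   P(1,1) = P(3,3) = (1-r)^2/4        P(1,3) = P(3,1) = r^2/4
#   P(1,2) = P(2,1) = P(2,3) = P(3,2) = r(1-r)/2
#   P(2,2) = ((1-r)^2 + r^2)/2
# The double-heterozygote cell mixes 0- and 2-recombinant two-gamete
# configurations; EM resolves it with E[rec | 2,2] = 2r^2/((1-r)^2+r^2).

R_CLAMP <- c(1e-6, 0.5 - 1e-6)

# counts: P x 9 matrix, columns n11,n12,n13,n21,...,n33 (row i = locus A)
.rf_loglik10 <- function(counts, r) {
  counts <- matrix(counts, ncol = 9)
  r <- rep_len(r, nrow(counts))
  lp <- cbind(2 * log(1 - r) - log(4), log(r) + log(1 - r) - log(2),
              2 * log(r) - log(4),
              log(r) + log(1 - r) - log(2), log((1 - r)^2 + r^2) - log(2),
              log(r) + log(1 - r) - log(2),
              2 * log(r) - log(4), log(r) + log(1 - r) - log(2),
              2 * log(1 - r) - log(4))
  rowSums(counts * lp) / log(10)
}

.rf_em <- function(counts, r_start = 0.3, tol = 1e-8, maxit = 1000) {
  counts <- matrix(counts, ncol = 9)
  n2 <- 2 * rowSums(counts)                       # gametes
  # fixed recombinant-gamete counts outside the H/H cell
  k_fixed <- counts %*% c(0, 1, 2, 1, 0, 1, 2, 1, 0)
  n_hh <- counts[, 5]
  r <- rep(r_start, nrow(counts))
  est <- n2 > 0
  for (it in seq_len(maxit)) {
    e_hh <- 2 * r^2 / ((1 - r)^2 + r^2)
    r_new <- pmin(pmax((k_fixed + n_hh * e_hh) / n2, R_CLAMP[1]), R_CLAMP[2])
    delta <- abs(r_new[est] - r[est])
    r[est] <- r_new[est]
    if (!length(delta) || max(delta) < tol) break
  }
  r[!est] <- NA_real_
  lod <- .rf_loglik10(counts, ifelse(est, r, 0.25)) - .rf_loglik10(counts, 0.5)
  lod[!est] <- NA_real_
  list(r_hat = r, lod = pmax(lod, 0), n = rowSums(counts))
}

.pair_counts <- function(gA, gB) {
  ok <- !is.na(gA) & !is.na(gB)
  as.vector(t(table(factor(gA[ok], levels = 1:3), factor(gB[ok], levels = 1:3))))
}

#' Two-point recombination fraction between two markers
#'
#' Maximum-likelihood estimate of the recombination fraction between two
#' markers of an F2 intercross, via EM over the phase-ambiguous
#' double-heterozygote class.  Missing genotypes are excluded pairwise.
#' The linkage LOD is log10 L(r-hat) - log10 L(0.5).
#'
#' @param cross An [f2cross()].
#' @param markerA,markerB Marker names.
#' @return A list with `r_hat` (in `[0, 0.5]`), `lod` (`>= 0`) and
#'   `n_informative` (individuals typed at both markers).  With fewer
#'   than 2 jointly typed individuals the estimate is undefined and
#'   `r_hat`/`lod` are `NA`.
#' @examples
#' cr <- sim_cross(n = 200, map = reduced_map(), seed = 1)
#' est_rf(cr, "c01m01", "c01m02")
#' @export
est_rf <- function(cross, markerA, markerB) {
  gA <- cross$geno[, markerA]
  gB <- cross$geno[, markerB]
  counts <- .pair_counts(gA, gB)
  if (sum(counts) < 2) {
    return(list(r_hat = NA_real_, lod = NA_real_, n_informative = sum(counts)))
  }
  fit <- .rf_em(counts)
  list(r_hat = fit$r_hat, lod = fit$lod, n_informative = fit$n)
}

#' All-pairs recombination fractions and linkage LODs
#'
#' Estimates r-hat and the linkage LOD for every pair of the given
#' markers (EM run jointly over all pairs).  Used by linkage grouping,
#' marker insertion and the order diagnostics.
#'
#' @param cross An [f2cross()].
#' @param markers Marker names (default: all markers).
#' @return A list of symmetric matrices `r_hat`, `lod`, `n`.
#' @export
est_rf_all <- function(cross, markers = colnames(cross$geno)) {
  g <- cross$geno[, markers, drop = FALSE]
  m <- ncol(g)
  ind <- lapply(1:3, function(cc) {
    x <- g == cc
    x[is.na(x)] <- FALSE
    storage.mode(x) <- "double"
    x
  })
  pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  counts <- matrix(0, nrow(pairs), 9)
  col <- 0
  for (i in 1:3) for (j in 1:3) {
    col <- col + 1
    nij <- crossprod(ind[[i]], ind[[j]])   # m x m: rows marker A, cols marker B
    counts[, col] <- nij[pairs]
  }
  fit <- .rf_em(counts)
  mk <- function(v, diag_val) {
    out <- matrix(diag_val, m, m, dimnames = list(markers, markers))
    out[pairs] <- v
    out[pairs[, c(2, 1)]] <- v
    out
  }
  list(r_hat = mk(fit$r_hat, 0), lod = mk(fit$lod, NA_real_), n = mk(fit$n, NA_real_))
}
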