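#' Genotype error LOD scores
#'
#' Flags statistically unlikely genotypes (e.g. tight apparent double
#' crossovers) under the F2 hidden-Markov model.  For each individual and
#' each internal map locus with an observed genotype, the error LOD is the
#' log10 likelihood ratio of the observation having arisen by a genotyping
#' error versus being correct, given all other genotypes of that
#' individual on the chromosome:
#'
#'   error LOD = log10 \[ P(obs | rest, error) / P(obs | rest, correct) \]
#'
#' where P(obs | rest, error) spreads the error uniformly over the two
#' wrong codes and P(obs | rest, correct) is the leave-one-out posterior
#' of the observed code.  The first and last locus of each chromosome are
#' not flaggable (no flanking information on one side); chromosomes with
#' fewer than 3 loci are skipped.  Flags are advisory only: no genotype is
#' ever dropped automatically.
#'
#' @param cross An [f2cross()].
#' @param eps Assumed genotyping-error rate, in (0, 0.5).
#' @param cutoff Error-LOD threshold above which a genotype is flagged.
#' @return A data frame of class `errorflags` with one row per observed
#'   genotype at an internal locus: `individual`, `marker`, `chr`,
#'   `obs` (A/H/B), `error_lod`, `flagged`.  The number of non-missing
#'   internal-locus genotypes is attached as attribute `n_obtained`.
#' @examples
#' cr <- sim_cross(n = 100, map = reduced_map(), seed = 1)
#' fl <- calc_error_lod(cr)
#' flag_summary(fl)
#' @export
calc_error_lod <- function(cross, eps = 1e-4, cutoff = 4) {
  if (eps <= 0 || eps >= 0.5) stop("eps must lie in (0, 0.5)")
  map <- cross$map
  res <- list()
  n_obtained <- 0L
  for (chr in unique(map$chr)) {
    rows <- which(map$chr == chr)
    L <- length(rows)
    if (L < 3) next
    obs <- cross$geno[, rows, drop = FALSE]
    fb <- .fb_chr(obs, haldane_inverse(diff(map$pos[rows])), eps)
    for (l in 2:(L - 1)) {
      o <- obs[, l]
      keep <- which(!is.na(o))
      n_obtained <- n_obtained + length(keep)
      if (!length(keep)) next
      pr <- fb$q_rest[keep, , l, drop = FALSE]
      dim(pr) <- c(length(keep), 3)
      p_obs <- pr[cbind(seq_along(keep), o[keep])]
      elod <- log10((1 - p_obs) / 2) - log10(p_obs)
      res[[length(res) + 1]] <- data.frame(
        individual = rownames(cross$geno)[keep],
        marker = map$marker[rows[l]], chr = chr,
        obs = GENO_CODES[o[keep]], error_lod = elod,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(individual = character(), marker = character(),
               chr = character(), obs = character(), error_lod = numeric())
  out$flagged <- out$error_lod > cutoff
  rownames(out) <- NULL
  attr(out, "n_obtained") <- n_obtained
  attr(out, "cutoff") <- cutoff
  class(out) <- c("errorflags", "data.frame")
  out
}

#' @rdname calc_error_lod
#' @param flags The result of `calc_error_lod()`.
#' @return `flag_summary()` returns a list with `n_flagged`,
#'   `fraction_of_obtained_genotypes` (flagged fraction of non-missing
#'   genotypes at internal loci) and `max_flags_per_marker`.
#' @export
flag_summary <- function(flags) {
  n_obt <- attr(flags, "n_obtained")
  nf <- sum(flags$flagged)
  per_marker <- if (nf) max(table(flags$marker[flags$flagged])) else 0L
  list(n_flagged = nf,
       fraction_of_obtained_genotypes = if (n_obt > 0) nf / n_obt else NA_real_,
       max_flags_per_marker = as.integer(per_marker))
}
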