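# Hidden-Markov model of the F2 chromosome.
#
# Hidden states are the true genotypes {AA, AB, BB}; the chain starts from
# the F2 prior (1/4, 1/2, 1/4) and moves between adjacent loci with the
# two-gamete transition matrix at recombination fraction r (each gamete
# switches independently with probability r).  Observed codes equal the
# true genotype with probability 1 - eps and each other code with
# probability eps/2; missing observations are uninformative.  Transition
# r's are taken as the Haldane inverse of the (Kosambi) map distances --
# the standard Markov-consistent approximation.

F2_INIT <- c(0.25, 0.5, 0.25)

f2_transition <- function(r) {
  matrix(c((1 - r)^2, 2 * r * (1 - r), r^2,
           r * (1 - r), (1 - r)^2 + r^2, r * (1 - r),
           r^2, 2 * r * (1 - r), (1 - r)^2),
         3, 3, byrow = TRUE)
}

# emission matrix (n x 3) for an observation vector obs (codes 1:3 or NA)
.emission <- function(obs, eps) {
  n <- length(obs)
  e <- matrix(eps / 2, n, 3)
  e[cbind(seq_len(n), obs)] <- 1 - eps
  e[is.na(obs), ] <- 1
  e
}

# Forward-backward over one chromosome, vectorized across individuals.
# obs: n x L matrix of codes (NA = missing / pseudo-marker); r: length L-1.
# Returns posteriors q (n x 3 x L), leave-one-out posteriors q_rest
# (observation at each locus divided out), and per-individual log10
# likelihood of the whole observation sequence.
.fb_chr <- function(obs, r, eps) {
  n <- nrow(obs); L <- ncol(obs)
  Tm <- lapply(r, f2_transition)
  E <- lapply(seq_len(L), function(l) .emission(obs[, l], eps))
  alpha <- vector("list", L)
  logl <- numeric(n)
  a <- matrix(F2_INIT, n, 3, byrow = TRUE) * E[[1]]
  sc <- rowSums(a)
  logl <- log10(sc)
  alpha[[1]] <- a / sc
  if (L > 1) for (l in 2:L) {
    a <- (alpha[[l - 1]] %*% Tm[[l - 1]]) * E[[l]]
    sc <- rowSums(a)
    logl <- logl + log10(sc)
    alpha[[l]] <- a / sc
  }
  beta <- vector("list", L)
  beta[[L]] <- matrix(1, n, 3)
  if (L > 1) for (l in (L - 1):1) {
    b <- (beta[[l + 1]] * E[[l + 1]]) %*% t(Tm[[l]])
    beta[[l]] <- b / rowSums(b)
  }
  q <- array(NA_real_, c(n, 3, L))
  q_rest <- array(NA_real_, c(n, 3, L))
  for (l in seq_len(L)) {
    ab <- alpha[[l]] * beta[[l]]
    q[, , l] <- ab / rowSums(ab)
    ab_rest <- ab / E[[l]]                 # divide out the emission at l
    q_rest[, , l] <- ab_rest / rowSums(ab_rest)
  }
  list(q = q, q_rest = q_rest, logl10 = logl)
}

#' Genotype probabilities along the genome
#'
#' Forward-backward posterior P(true genotype | marker data) for every
#' individual at a grid of positions (the map loci plus multiples of
#' `step` cM along each chromosome), under the F2 hidden-Markov model
#' with genotyping-error rate `eps`.
#'
#' @param cross An [f2cross()].
#' @param step Grid step in cM; `0` restricts the grid to the map loci.
#' @param eps Assumed genotyping-error rate in `[0, 0.5)`.
#' @return An object of class `genoprob`: a list with one element per
#'   chromosome, each a list with `pos` (grid positions, cM), `marker`
#'   (locus name or `NA` for pseudo-positions) and `prob`
#'   (individuals x 3 x positions posterior array).
#' @examples
#' cr <- sim_cross(n = 50, map = reduced_map(), seed = 1)
#' gp <- genoprob(cr, step = 2)
#' @export
genoprob <- function(cross, step = 1, eps = 1e-4) {
  stopifnot(step >= 0, eps >= 0, eps < 0.5)
  map <- cross$map
  out <- list()
  for (chr in unique(map$chr)) {
    rows <- which(map$chr == chr)
    mpos <- map$pos[rows]
    ps <- if (step > 0) seq(min(mpos), max(mpos), by = step) else numeric(0)
    if (length(ps))                       # drop pseudo-positions that sit on loci
      ps <- ps[vapply(ps, function(p) all(abs(p - mpos) > 1e-9), logical(1))]
    pos <- c(mpos, ps)
    src <- c(rows, rep(NA_integer_, length(ps)))   # map row feeding each slot
    o <- order(pos)
    pos <- pos[o]; src <- src[o]
    obs <- matrix(NA_integer_, nrow(cross$geno), length(pos))
    obs[, !is.na(src)] <- cross$geno[, src[!is.na(src)], drop = FALSE]
    fb <- .fb_chr(obs, haldane_inverse(diff(pos)), eps)
    out[[chr]] <- list(pos = pos,
                       marker = ifelse(is.na(src), NA, map$marker[src]),
                       prob = fb$q)
  }
  structure(out, class = "genoprob", step = step, eps = eps)
}
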