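#' Default simulation maps
#'
#' `default_map()` builds the full-scale default genetic map used by the
#' cross simulator: 25 chromosomes of 40 loci at a uniform 2 cM spacing
#' (mean adjacent-locus density 2.0 Kosambi cM, emulating a merged
#' SNP+microsatellite zebrafish map of ~1100 loci).  `reduced_map()` is a
#' small 4-chromosome map (21 loci per chromosome, 2 cM spacing) for fast
#' tests and examples.  Both are deterministic.
#'
#' @return A [genmap()].
#' @examples
#' map_summary(default_map())
#' @export
default_map <- function() {
  chrs <- as.character(1:25)
  n_loci <- 40
  genmap(marker = paste0("c", rep(sprintf("%02d", 1:25), each = n_loci),
                         "m", sprintf("%02d", seq_len(n_loci))),
         chr = rep(chrs, each = n_loci),
         pos = rep(2 * (seq_len(n_loci) - 1), times = 25))
}

#' @rdname default_map
#' @export
reduced_map <- function() {
  chrs <- as.character(1:4)
  n_loci <- 21
  genmap(marker = paste0("c", rep(sprintf("%02d", 1:4), each = n_loci),
                         "m", sprintf("%02d", seq_len(n_loci))),
         chr = rep(chrs, each = n_loci),
         pos = rep(2 * (seq_len(n_loci) - 1), times = 4))
}

#' Two-locus penetrance model for a binary trait
#'
#' Defines P(male | g1, g2) over the 3x3 genotype classes at two loci,
#' with locus 1 acting in a recessive-male fashion (rows g1 = AA and
#' g1 = AB identical) and locus 2 additively (within each row, penetrance
#' linear in the count of male-associated B alleles).
#'
#' `default_penetrance()` returns the calibrated default model:
#' p(male) = 0.23 + 0.3358 I(g1 = BB) + 0.2171 (number of B alleles at
#' locus 2).  The three constants are the unique solution of three
#' anchors: the fully male-dose class (g1 = BB, g2 = BB) is 100% male,
#' the fully female-dose class (g1 in AA/AB, g2 = AA) is 77% female, and
#' the population marginal is 248/467 male.  Model loci default to
#' chromosome 5 at 54 cM and chromosome 16 at 32 cM when those
#' chromosomes exist on `map`, otherwise to mid-chromosome positions on
#' the first and third chromosomes.
#'
#' @param table 3x3 numeric matrix, rows = genotype at locus 1 (AA, AB,
#'   BB), columns = genotype at locus 2; entries P(male | g1, g2).
#' @param locus1,locus2 Lists/vectors `list(chr =, pos =)` giving the map
#'   location of each model locus.
#' @return An object of class `penetrance_model`.
#' @export
penetrance_model <- function(table, locus1, locus2) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(3, 3))) stop("penetrance table must be 3x3")
  if (any(table < 0 | table > 1)) stop("penetrance entries must lie in [0, 1]")
  if (max(abs(table[1, ] - table[2, ])) > 1e-8)
    stop("recessive-male locus 1: rows g1=AA and g1=AB must be identical")
  if (max(abs((table[, 2] - table[, 1]) - (table[, 3] - table[, 2]))) > 1e-8)
    stop("additive locus 2: penetrance must be linear in the B-allele count within each row")
  dimnames(table) <- list(g1 = c("AA", "AB", "BB"), g2 = c("AA", "AB", "BB"))
  structure(list(table = table,
                 locus1 = list(chr = as.character(locus1$chr), pos = locus1$pos),
                 locus2 = list(chr = as.character(locus2$chr), pos = locus2$pos)),
            class = "penetrance_model")
}

#' @rdname penetrance_model
#' @param map A `genmap` on which the default model loci are placed.
#' @export
default_penetrance <- function(map = default_map()) {
  marg <- 248 / 467          # observed male fraction among phenotyped progeny
  a <- 0.23                  # male fraction of the fully female-dose class
  cc <- (4 * (marg - a) - (1 - a)) / 2
  b <- (1 - a) - 2 * cc
  tab <- a + outer(c(0, 0, b), cc * (0:2), "+")
  chrs <- unique(map$chr)
  place <- function(chr, target) {
    p <- map$pos[map$chr == chr]
    list(chr = chr, pos = p[which.min(abs(p - target))])
  }
  if (all(c("5", "16") %in% chrs)) {
    l1 <- place("5", 54); l2 <- place("16", 32)
  } else {
    mid <- function(chr) place(chr, mean(range(map$pos[map$chr == chr])))
    l1 <- mid(chrs[1]); l2 <- mid(chrs[min(3, length(chrs))])
  }
  penetrance_model(tab, l1, l2)
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat("Two-locus penetrance model P(male | g1, g2)\n")
  cat("  locus 1 (recessive male): chr", x$locus1$chr, "at", x$locus1$pos, "cM\n")
  cat("  locus 2 (additive):       chr", x$locus2$chr, "at", x$locus2$pos, "cM\n")
  print(round(x$table, 3))
  invisible(x)
}

locus_index <- function(map, chr, pos) {
  i <- which(map$chr == as.character(chr) & abs(map$pos - pos) < 1e-9)
  if (length(i) != 1)
    stop("model locus chr", chr, ":", pos, " cM is not a map locus")
  i
}

#' Simulate an F2 intercross with a two-locus binary trait
#'
#' Simulates genotypes along a genetic map and a binary sex phenotype
#' driven by a two-locus penetrance model.  Each individual's two gametes
#' are simulated independently per chromosome as a Markov chain along the
#' ordered loci: the allele at the first locus is grandmaternal or
#' grandpaternal with probability 1/2 each, and between adjacent loci at
#' Kosambi distance d the allele switches with probability
#' `kosambi_inverse(d)` (no crossover interference).  Sex is drawn
#' Bernoulli with p = `model$table[g1, g2]` from the true genotypes at the
#' two model loci; `n_unknown` randomly chosen individuals are then set to
#' unknown sex; finally genotypes are masked to missing at `missing_rate`
#' and corrupted to a uniformly random different code at `error_rate`.
#'
#' @param n Number of F2 progeny.
#' @param map A [genmap()]; model loci must be loci of this map.
#' @param model A [penetrance_model()].
#' @param n_unknown Number of progeny with unknown sex.
#' @param missing_rate Fraction of genotypes masked to missing.
#' @param error_rate Fraction of genotypes replaced by a random wrong code.
#' @param seed Integer seed; the same seed gives a bit-identical cross.
#' @return An [f2cross()] with a `truth` attribute: a list with the true
#'   (pre-masking, pre-corruption) genotype matrix `geno`, the logical
#'   corruption mask `errors`, the model, and `model_cols` (column indices
#'   of the two model loci).
#' @examples
#' cr <- sim_cross(n = 100, map = reduced_map(), seed = 1)
#' summary(cr)
#' @export
sim_cross <- function(n = 520, map = default_map(),
                      model = default_penetrance(map),
                      n_unknown = 53, missing_rate = 0.01,
                      error_rate = 5e-4, seed = 1) {
  stopifnot(n >= 1, n_unknown >= 0, n_unknown <= n,
            missing_rate >= 0, missing_rate <= 1,
            error_rate >= 0, error_rate <= 1)
  i1 <- locus_index(map, model$locus1$chr, model$locus1$pos)
  i2 <- locus_index(map, model$locus2$chr, model$locus2$pos)
  set.seed(as.integer(seed))
  geno <- matrix(NA_integer_, n, nrow(map),
                 dimnames = list(paste0("ind", seq_len(n)), map$marker))
  for (chr in unique(map$chr)) {
    cols <- which(map$chr == chr)
    r <- kosambi_inverse(diff(map$pos[cols]))
    g1 <- stats::rbinom(n, 1, 0.5)   # 0 = grandmaternal (A), 1 = grandpaternal (B)
    g2 <- stats::rbinom(n, 1, 0.5)
    geno[, cols[1]] <- g1 + g2 + 1L
    for (k in seq_along(r)) {
      g1 <- ifelse(stats::runif(n) < r[k], 1L - g1, g1)
      g2 <- ifelse(stats::runif(n) < r[k], 1L - g2, g2)
      geno[, cols[k + 1]] <- g1 + g2 + 1L
    }
  }
  p_male <- model$table[cbind(geno[, i1], geno[, i2])]
  pheno <- as.integer(stats::runif(n) < p_male)
  if (n_unknown > 0)
    pheno[sample.int(n, n_unknown)] <- NA_integer_
  true_geno <- geno
  if (missing_rate > 0)
    geno[stats::runif(length(geno)) < missing_rate] <- NA_integer_
  errors <- matrix(FALSE, n, ncol(geno))
  if (error_rate > 0) {
    hit <- !is.na(geno) & stats::runif(length(geno)) < error_rate
    # replace by one of the two other codes, uniformly
    geno[hit] <- 1L + (geno[hit] - 1L + sample(1:2, sum(hit), replace = TRUE)) %% 3L
    errors <- hit
  }
  cross <- f2cross(geno, pheno, map)
  attr(cross, "truth") <- list(geno = true_geno, errors = errors,
                               model = model, model_cols = c(i1, i2))
  cross
}

#' Synthetic physical map matching a genetic map
#'
#' Assigns each map locus a 1-based bp coordinate assuming a constant
#' recombination rate (cM/Mb) per chromosome, so genetic and physical
#' orders agree by construction.  Used to exercise the map diagnostics on
#' simulated data.
#'
#' @param map A [genmap()].
#' @param cM_per_Mb Recombination rate; a single value or one per
#'   chromosome (recycled in chromosome order).
#' @return A `physmap` data frame (columns `marker`, `chr`, `bp`).
#' @export
sim_physical_map <- function(map, cM_per_Mb = 1.2) {
  chrs <- unique(map$chr)
  rate <- rep_len(cM_per_Mb, length(chrs))
  bp <- numeric(nrow(map))
  for (i in seq_along(chrs)) {
    rows <- map$chr == chrs[i]
    bp[rows] <- round(1 + map$pos[rows] * 1e6 / rate[i])
  }
  out <- data.frame(marker = map$marker, chr = map$chr, bp = bp,
                    stringsAsFactors = FALSE)
  class(out) <- c("physmap", "data.frame")
  out
}
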