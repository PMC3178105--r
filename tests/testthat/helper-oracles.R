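# Independent oracles, written against the model definitions directly --
# never against the package internals they are used to check.

# F2 two-point joint genotype probabilities (1=AA, 2=AB, 3=BB)
oracle_pair_probs <- function(r) {
  matrix(c((1 - r)^2 / 4, r * (1 - r) / 2, r^2 / 4,
           r * (1 - r) / 2, ((1 - r)^2 + r^2) / 2, r * (1 - r) / 2,
           r^2 / 4, r * (1 - r) / 2, (1 - r)^2 / 4),
         3, 3, byrow = TRUE)
}

# grid-search ML recombination fraction for a 3x3 count table
oracle_rf_grid <- function(counts, grid = seq(1e-4, 0.4999, by = 1e-4)) {
  counts <- matrix(counts, 3, 3, byrow = TRUE)
  ll <- vapply(grid, function(r) {
    p <- oracle_pair_probs(r)
    sum(counts[counts > 0] * log(p[counts > 0]))
  }, numeric(1))
  list(r_hat = grid[which.max(ll)],
       lod = (max(ll) - sum(counts[counts > 0] *
                              log(oracle_pair_probs(0.5)[counts > 0]))) / log(10))
}

oracle_f2_transition <- function(r) {
  matrix(c((1 - r)^2, 2 * r * (1 - r), r^2,
           r * (1 - r), (1 - r)^2 + r^2, r * (1 - r),
           r^2, 2 * r * (1 - r), (1 - r)^2), 3, 3, byrow = TRUE)
}

# brute-force enumeration over all 3^L hidden paths for one individual.
# obs: codes 1:3/NA; d_cM: adjacent distances; returns total likelihood and
# the error LOD at locus m (log10 P(obs_m | rest, error)/P(obs_m | rest, ok))
oracle_enum <- function(obs, d_cM, eps, m = NULL) {
  L <- length(obs)
  r <- (1 - exp(-d_cM / 50)) / 2
  Tm <- lapply(r, oracle_f2_transition)
  emis <- function(o, g) if (is.na(o)) 1 else if (o == g) 1 - eps else eps / 2
  paths <- as.matrix(expand.grid(rep(list(1:3), L)))
  path_prob <- function(path, skip = integer()) {
    p <- c(0.25, 0.5, 0.25)[path[1]]
    for (l in seq_len(L - 1)) p <- p * Tm[[l]][path[l], path[l + 1]]
    for (l in setdiff(seq_len(L), skip)) p <- p * emis(obs[l], path[l])
    p
  }
  total <- sum(apply(paths, 1, path_prob))
  out <- list(total = total)
  if (!is.null(m)) {
    pg <- vapply(1:3, function(g)
      sum(apply(paths[paths[, m] == g, , drop = FALSE], 1, path_prob, skip = m)),
      numeric(1))
    pg <- pg / sum(pg)
    out$error_lod <- log10(sum(pg[-obs[m]]) / 2) - log10(pg[obs[m]])
  }
  out
}

# closed-form binary LOD from the 3x2 genotype-by-trait table
oracle_binom_lod <- function(g, y) {
  ll <- 0
  for (gc in 1:3) {
    n1 <- sum(y[g == gc]); n0 <- sum(g == gc) - n1
    p <- n1 / (n1 + n0)
    ll <- ll + (if (n1 > 0) n1 * log10(p) else 0) +
      (if (n0 > 0) n0 * log10(1 - p) else 0)
  }
  pbar <- mean(y)
  ll - (sum(y) * log10(pbar) + sum(1 - y) * log10(1 - pbar))
}

# genmap() requires loci already ordered; sort fixture inputs first
sorted_genmap <- function(marker, chr, pos) {
  o <- order(factor(chr, levels = unique(chr)), pos)
  genmap(marker[o], chr[o], pos[o])
}

# deterministic little cross used by several tests
tiny_cross <- function() {
  geno <- matrix(c(1L, 2L, 3L,
                   2L, NA, 1L), nrow = 3,
                 dimnames = list(c("i1", "i2", "i3"), c("mA", "mB")))
  f2cross(geno, c(0, 1, NA), genmap(c("mA", "mB"), c("1", "1"), c(0, 5)))
}

# map with two 20 cM chromosomes of loci every 0.25 cM (dense enough for
# single-genotype errors to be flaggable at the default cutoff)
dense_test_map <- function() {
  genmap(paste0("d", rep(1:2, each = 81), "m", sprintf("%02d", 1:81)),
         rep(c("1", "2"), each = 81), rep(0.25 * (0:80), 2))
}
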