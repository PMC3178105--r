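test_that("genotype posteriors are point masses at clean typed markers", {
  cr <- sim_cross(n = 20, map = reduced_map(), n_unknown = 0,
                  missing_rate = 0, error_rate = 0, seed = 41)
  gp <- genoprob(cr, step = 1, eps = 0)
  slot <- which(gp[["1"]]$marker == "c01m05")
  for (i in 1:20) {
    q <- gp[["1"]]$prob[i, , slot]
    expect_equal(q[cr$geno[i, "c01m05"]], 1, tolerance = 1e-12)
  }
})

test_that("midpoint posteriors match the two-marker closed form", {
  # two markers 10 cM apart, every genotype combination
  map <- genmap(c("L", "R"), c("1", "1"), c(0, 10))
  combos <- expand.grid(gL = 1:3, gR = 1:3)
  geno <- as.matrix(combos)
  colnames(geno) <- c("L", "R")
  cx <- f2cross(geno, rep(c(0L, 1L, NA), 3), map)
  gp <- genoprob(cx, step = 5, eps = 0)
  mid <- which(abs(gp[["1"]]$pos - 5) < 1e-9)
  r <- (1 - exp(-2 * 5 / 100)) / 2
  Tm <- oracle_f2_transition(r)
  for (i in seq_len(nrow(combos))) {
    expected <- Tm[combos$gL[i], ] * Tm[, combos$gR[i]]
    expected <- expected / sum(expected)
    expect_equal(gp[["1"]]$prob[i, , mid], expected, tolerance = 1e-12)
  }
})

test_that("posteriors sum to one at every grid position", {
  cr <- sim_cross(n = 30, map = reduced_map(), missing_rate = 0.05,
                  error_rate = 0.01, n_unknown = 0, seed = 42)
  gp <- genoprob(cr, step = 1, eps = 1e-4)
  for (chr in names(gp)) {
    sums <- apply(gp[[chr]]$prob, c(1, 3), sum)
    expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-12)
  }
})

test_that("the scan at a fully typed marker equals the closed-form LOD", {
  cr <- sim_cross(n = 200, map = reduced_map(), n_unknown = 0,
                  missing_rate = 0, error_rate = 0, seed = 43)
  sc <- scan_binary(cr, step = 0, eps = 0, tol = 1e-12)
  for (mk in c("c01m11", "c03m11", "c04m01")) {
    i <- which(sc$result$marker == mk)
    expect_equal(sc$result$lod[i],
                 oracle_binom_lod(cr$geno[, mk], cr$pheno),
                 tolerance = 1e-9)
  }
  expect_true(all(sc$result$lod >= 0))
})

test_that("a fully penetrant predictor gives the expected huge LOD", {
  y <- c(rep(0L, 219), rep(1L, 248))
  geno <- matrix(ifelse(y == 1, 3L, 1L), 467, 2,
                 dimnames = list(NULL, c("m1", "m2")))
  cx <- f2cross(geno, y, genmap(c("m1", "m2"), c("1", "1"), c(0, 5)))
  sc <- scan_binary(cx, step = 0, eps = 0)
  closed <- -(219 * log10(219 / 467) + 248 * log10(248 / 467))
  expect_equal(max(sc$result$lod), closed, tolerance = 1e-3)
})

test_that("a constant phenotype warns and returns a flat zero scan", {
  cr <- sim_cross(n = 30, map = reduced_map(), n_unknown = 0, seed = 44)
  expect_warning(sc <- scan_binary(cr, step = 0, pheno = rep(1L, 30)),
                 "constant")
  expect_true(all(sc$result$lod == 0))
})

test_that("LOD-drop intervals do the right arithmetic", {
  pos <- seq(0, 60, by = 1)
  tri <- structure(list(result = data.frame(
    chr = "1", pos = pos, marker = NA, lod = pmax(0, 9 - 0.5 * abs(pos - 30)))),
    class = "binscan")
  expect_equal(lod_drop_interval(tri, "1", drop = 1.5), c(27, 33))
  flat <- structure(list(result = data.frame(
    chr = "1", pos = pos, marker = NA, lod = rep(5, 61))), class = "binscan")
  expect_equal(lod_drop_interval(flat, "1"), c(0, 60))
})

test_that("permutation thresholds are ordered and reproducible", {
  cr <- sim_cross(n = 120, map = reduced_map(), n_unknown = 10, seed = 45)
  gp <- genoprob(cr, step = 0)
  pt <- perm_threshold(cr, n_perm = 30, alphas = c(0.01, 0.05, 0.10),
                       step = 0, seed = 7, gp = gp)
  th <- pt$thresholds
  expect_true(th["0.01"] >= th["0.05"] && th["0.05"] >= th["0.10"])
  pt2 <- perm_threshold(cr, n_perm = 30, alphas = c(0.01, 0.05, 0.10),
                        step = 0, seed = 7, gp = gp)
  expect_identical(pt$thresholds, pt2$thresholds)
})

test_that("variance explained is 100% for a perfect predictor, ~0% for noise", {
  y <- rep(c(0L, 1L), each = 50)
  geno <- cbind(m1 = ifelse(y == 1, 3L, 1L),
                m2 = rep(c(1L, 2L, 3L, 2L), 25))
  cx <- f2cross(geno, y, genmap(c("m1", "m2"), c("1", "2"), c(0, 0)))
  ve <- variance_explained(cx, data.frame(chr = "1", pos = 0), step = 0, eps = 0)
  expect_equal(ve$joint, 100, tolerance = 1e-6)
  # an independent locus explains next to nothing at n = 520
  indep <- vapply(1:11, function(s) {
    cr <- sim_cross(n = 520, map = reduced_map(), n_unknown = 0, seed = 50 + s)
    variance_explained(cr, data.frame(chr = "2", pos = 20), step = 0)$joint
  }, numeric(1))
  expect_lt(median(indep), 1)
})

test_that("Wilson intervals behave at the boundary seen in all-male classes", {
  ci <- binqtl:::wilson_ci(32, 32)
  expect_equal(ci[1], 0.893, tolerance = 1e-3)
  expect_equal(ci[2], 1)
  expect_equal(binqtl:::wilson_ci(0, 10)[1], 0)
  expect_true(all(is.na(binqtl:::wilson_ci(0, 0))))
})

test_that("two-locus tables degrade gracefully for a constant phenotype", {
  cr <- sim_cross(n = 200, map = reduced_map(), n_unknown = 0,
                  missing_rate = 0, error_rate = 0, seed = 46)
  tl <- two_locus_table(f2cross(cr$geno, rep(1L, 200), cr$map),
                        list(chr = "1", pos = 20), list(chr = "3", pos = 20))
  expect_true(all(tl$table$p_male[tl$table$n > 0] == 1))
  expect_lt(tl$epistasis_lod, 1e-3)   # only the penetrance clamp remains
  expect_equal(sum(tl$table$n), 200)
})
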