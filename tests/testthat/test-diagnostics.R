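uniform_maps <- function(n_mb = 10, cM_per_Mb = 1) {
  mk <- paste0("u", 0:n_mb)
  list(map = genmap(mk, rep("1", n_mb + 1), cM_per_Mb * (0:n_mb)),
       phys = structure(data.frame(marker = mk, chr = rep("1", n_mb + 1),
                                   bp = 1e6 * (0:n_mb) + 1),
                        class = c("physmap", "data.frame")))
}

test_that("uniform maps give uniform window rates and genome mean", {
  um <- uniform_maps(10, 1)
  rw <- recomb_rate(um$map, um$phys, window_bp = 5e6, step_bp = 1e6)
  expect_equal(rw$rate[!is.na(rw$rate)], rep(1, sum(!is.na(rw$rate))),
               tolerance = 1e-6)
  expect_equal(attr(rw, "genome_mean"), 1, tolerance = 1e-6)
  # doubling the genetic length doubles every rate
  um2 <- um
  um2$map$pos <- 2 * um2$map$pos
  rw2 <- recomb_rate(um2$map, um2$phys, window_bp = 5e6, step_bp = 1e6)
  expect_equal(rw2$rate, 2 * rw$rate, tolerance = 1e-9)
})

test_that("a piecewise rate profile is recovered by the sliding windows", {
  # 30 Mb chromosome: 4 cM/Mb on the outer 5 Mb, 0.5 cM/Mb in the middle
  bp <- seq(0, 30e6, by = 5e5)
  rate <- ifelse(bp < 5e6 | bp >= 25e6, 4, 0.5)
  pos <- cumsum(c(0, diff(bp) / 1e6 * rate[-1]))
  mk <- paste0("p", seq_along(bp))
  map <- genmap(mk, rep("1", length(bp)), pos)
  phys <- structure(data.frame(marker = mk, chr = "1", bp = bp + 1),
                    class = c("physmap", "data.frame"))
  rw <- recomb_rate(map, phys, window_bp = 5e6, step_bp = 1e6)
  mid <- rw$start_bp >= 6e6 & rw$end_bp <= 24e6
  expect_equal(rw$rate[mid], rep(0.5, sum(mid)), tolerance = 0.05)
  expect_gt(rw$rate[1], 3)   # telomeric window
  # windows spanning the breakpoint are intermediate
  expect_true(all(rw$rate >= 0.5 - 1e-9 & rw$rate <= 4 + 1e-9, na.rm = TRUE))
})

test_that("the genome mean does not depend on the window width", {
  um <- uniform_maps(12, 1.7)
  a <- attr(recomb_rate(um$map, um$phys, window_bp = 5e6), "genome_mean")
  b <- attr(recomb_rate(um$map, um$phys, window_bp = 2e6), "genome_mean")
  expect_equal(a, b, tolerance = 1e-12)
  expect_equal(a, 1.7, tolerance = 1e-6)
})

test_that("discordant markers are excluded by the concordance filter", {
  um <- uniform_maps(10, 1)
  # marker u5 physically out of order; u8 on the wrong chromosome
  um$phys$bp[um$phys$marker == "u5"] <- 9.6e6
  um$phys$chr[um$phys$marker == "u8"] <- "2"
  conc <- concordant_markers(um$map, um$phys)
  expect_false(any(conc$marker %in% c("u5", "u8")))
  expect_equal(nrow(conc), 9)
  expect_true(all(diff(conc$bp) > 0))
})

test_that("assignment support separates genetic truth from a physical mislabel", {
  cr <- sim_cross(n = 520, map = reduced_map(), n_unknown = 0,
                  missing_rate = 0.01, error_rate = 0, seed = 61)
  phys <- sim_physical_map(cr$map)
  # marker truly on chr 1 gets mislabeled as chr 2 in the assembly
  phys$chr[phys$marker == "c01m10"] <- "2"
  sup <- assignment_support(cr, cr$map, phys, "c01m10")
  expect_gt(sup$genetic_lod, 50)
  expect_lt(sup$physical_lod, 3)
  expect_gte(sup$physical_lod, 0)
  expect_gte(sup$genetic_lod, 0)

  # a genuinely unlinked marker has no genetic support at its position
  set.seed(3)
  geno <- cbind(cr$geno, stray = sample(c(1L, 2L, 2L, 3L), 520, TRUE))
  map2 <- sorted_genmap(c(cr$map$marker, "stray"), c(cr$map$chr, "4"),
                        c(cr$map$pos, 17))
  cx <- f2cross(geno[, map2$marker], cr$pheno, map2)
  phys2 <- rbind(phys, data.frame(marker = "stray", chr = "1", bp = 5e6))
  sup2 <- assignment_support(cx, map2, phys2, "stray")
  expect_lt(sup2$genetic_lod, 1)
})

test_that("order comparisons are exact, antisymmetric and decisive", {
  cr <- sim_cross(n = 520, map = reduced_map(), n_unknown = 0,
                  missing_rate = 0, error_rate = 0, seed = 62)
  mks <- paste0("c02m", sprintf("%02d", 1:6))
  expect_identical(order_lod(cr, mks, mks), 0)
  swapped <- mks; swapped[3:4] <- mks[4:3]
  ab <- order_lod(cr, mks, swapped)
  expect_equal(ab, -order_lod(cr, swapped, mks), tolerance = 1e-9)
  expect_error(order_lod(cr, mks, mks[-1]), "permutations")

  # a swap of markers with zero recombinants between them is a wash
  geno <- cbind(cr$geno[, mks], twin = cr$geno[, "c02m03"])
  map <- sorted_genmap(c(mks, "twin"), rep("1", 7), c(cr$map$pos[1:6], 4))
  cx <- f2cross(geno[, map$marker], cr$pheno, map)
  oA <- map$marker
  oB <- oA
  i <- match(c("c02m03", "twin"), oA)
  oB[i] <- oA[rev(i)]
  expect_lt(abs(order_lod(cx, oA, oB)), 0.01)
})

test_that("true marker order beats a local inversion almost always", {
  map6 <- genmap(paste0("w", 1:6), rep("1", 6), 5 * (0:5))
  model <- penetrance_model(matrix(0.5, 3, 3),
                            list(chr = "1", pos = 0), list(chr = "1", pos = 5))
  wins <- vapply(1:100, function(s) {
    cr <- sim_cross(n = 520, map = map6, model = model, n_unknown = 0,
                    missing_rate = 0, error_rate = 0, seed = s)
    swapped <- map6$marker
    swapped[3:4] <- swapped[4:3]
    order_lod(cr, map6$marker, swapped) < 0
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
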