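test_that("identical genotype vectors collapse into multi-name loci", {
  # n large enough that adjacent 2 cM markers essentially never coincide
  cr <- sim_cross(n = 200, map = reduced_map(), n_unknown = 0,
                  missing_rate = 0, error_rate = 0, seed = 3)
  # duplicate one column under a new name at the same position
  geno <- cbind(cr$geno[, 1:5], dup = cr$geno[, "c01m03"])
  map <- sorted_genmap(c(colnames(cr$geno)[1:5], "dup"), rep("1", 6),
                       c(cr$map$pos[1:5], cr$map$pos[3]))
  cx <- f2cross(geno[, map$marker], cr$pheno, map)
  col <- collapse_identical(cx)
  expect_equal(ncol(col$geno), 5)
  expect_true("c01m03;dup" %in% col$map$marker)

  # a single differing individual keeps markers apart
  geno2 <- geno
  geno2[1, "dup"] <- if (geno2[1, "dup"] == 1L) 2L else 1L
  cx2 <- f2cross(geno2[, map$marker], cr$pheno, map)
  expect_equal(ncol(collapse_identical(cx2)$geno), 6)

  # markers built as copies of known base vectors collapse to the number of
  # distinct underlying vectors
  set.seed(11)
  base <- matrix(sample(1:3, 200 * 7, TRUE), 200, 7)
  picks <- sample(1:7, 30, TRUE)
  copies <- base[, picks]
  colnames(copies) <- paste0("s", 1:30)
  mp <- genmap(colnames(copies), rep("1", 30), rep(0, 30))
  cx3 <- f2cross(copies, cr$pheno, mp)
  expect_equal(ncol(collapse_identical(cx3)$geno), length(unique(picks)))
})

test_that("linkage grouping recovers the simulated chromosomes", {
  cr <- sim_cross(n = 520, map = reduced_map(), n_unknown = 0,
                  missing_rate = 0.01, error_rate = 5e-4, seed = 13)
  groups <- group_markers(cr)
  expect_equal(length(groups), 4)
  truth <- split(cr$map$marker, cr$map$chr)
  for (g in groups)
    expect_true(any(vapply(truth, setequal, logical(1), y = g)))
})

test_that("unlinked markers split and tightly linked markers join", {
  cr <- sim_cross(n = 300, map = reduced_map(), n_unknown = 0,
                  missing_rate = 0, error_rate = 0, seed = 14)
  two <- f2cross(cr$geno[, c("c01m01", "c02m01")], cr$pheno,
                 genmap(c("c01m01", "c02m01"), c("1", "2"), c(0, 0)))
  expect_equal(length(group_markers(two)), 2)
  one_chr <- f2cross(cr$geno[, cr$map$chr == "1"], cr$pheno,
                     cr$map[cr$map$chr == "1", ])
  expect_equal(length(group_markers(one_chr)), 1)
})

test_that("marker insertion places, supports and rejects correctly", {
  cr <- sim_cross(n = 520, map = reduced_map(), n_unknown = 0,
                  missing_rate = 0.01, error_rate = 0, seed = 15)
  # identical to a framework locus: co-located with strong support
  geno <- cbind(cr$geno, newmk = cr$geno[, "c02m10"])
  cx <- f2cross(geno, cr$pheno,
                genmap(c(cr$map$marker, "newmk"), c(cr$map$chr, "9"),
                       c(cr$map$pos, 0)))
  im <- insert_marker(cr$map, cx, "newmk")
  expect_true(im$placed)
  expect_equal(im$type, "at_locus")
  expect_equal(im$chr, "2")
  expect_equal(im$pos, cr$map$pos[cr$map$marker == "c02m10"])
  expect_gte(im$support_lod, 7)

  # unlinked random marker: unplaced
  set.seed(1)
  geno2 <- cbind(cr$geno, rnd = sample(c(1L, 2L, 2L, 3L), 520, TRUE))
  cx2 <- f2cross(geno2, cr$pheno,
                 genmap(c(cr$map$marker, "rnd"), c(cr$map$chr, "9"),
                        c(cr$map$pos, 0)))
  im2 <- insert_marker(cr$map, cx2, "rnd")
  expect_false(im2$placed)
  expect_lt(im2$support_lod, 7)

  expect_error(insert_marker(cr$map, {
    g <- cx2; g$geno[, "rnd"] <- NA_integer_; g
  }, "rnd"), "untyped")
})

test_that("a marker 1 cM inside an interval lands in the right interval", {
  # framework loci every 6 cM; hidden marker at 31 cM (interval 30-36)
  full <- sorted_genmap(c(paste0("f", 1:11), "hidden"), rep("1", 12),
                        c(6 * (0:10), 31))
  framework <- genmap(paste0("f", 1:11), rep("1", 11), 6 * (0:10))
  model <- penetrance_model(matrix(0.5, 3, 3),
                            list(chr = "1", pos = 0), list(chr = "1", pos = 6))
  hits <- vapply(1:100, function(s) {
    cr <- sim_cross(n = 520, map = full, model = model, n_unknown = 0,
                    missing_rate = 0, error_rate = 0, seed = s)
    im <- insert_marker(framework, cr, "hidden")
    im$type == "interval" && im$nearest == "f6;f7"
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})

test_that("locus ordering recovers the truth and flags ties", {
  cr <- sim_cross(n = 520, map = reduced_map(), n_unknown = 0,
                  missing_rate = 0, error_rate = 0, seed = 16)
  mks <- paste0("c01m", sprintf("%02d", 1:8))
  ord <- order_loci(cr, sample(mks))
  expect_true(identical(ord$order, mks) || identical(ord$order, rev(mks)))
  expect_equal(nrow(ord$ambiguities), 0)

  # a duplicated marker (zero recombinants) is order-ambiguous with its twin
  geno <- cbind(cr$geno[, mks], twin = cr$geno[, "c01m04"])
  map <- sorted_genmap(c(mks, "twin"), rep("1", 9), c(cr$map$pos[1:8], 6))
  cx <- f2cross(geno[, map$marker], cr$pheno, map)
  ord2 <- order_loci(cx, map$marker)
  pairs <- paste(ord2$ambiguities$markerA, ord2$ambiguities$markerB)
  expect_true(any(grepl("twin", pairs) | grepl("c01m04 ", paste0(pairs, " "))))
})

test_that("map summaries compute density, gaps and meiotic resolution", {
  expect_equal(map_summary(default_map(), n_meioses = 1040)$resolution_cM, 0.1)
  m <- genmap(c("a", "b", "c"), rep("1", 3), c(0, 2, 4))
  s <- map_summary(m)
  expect_equal(s$mean_gap_cM, 2)
  expect_equal(s$largest_gap_cM, 2)
  # single-locus chromosome contributes no gaps
  m2 <- genmap(c("a", "b", "c", "solo"), c("1", "1", "1", "2"), c(0, 2, 4, 0))
  expect_equal(map_summary(m2)$mean_gap_cM, 2)
})

test_that("de novo map building reconstructs chromosomes end to end", {
  cr <- sim_cross(n = 520, map = reduced_map(), n_unknown = 0,
                  missing_rate = 0.01, error_rate = 0, seed = 17)
  sub <- cr$map$chr %in% c("1", "2")
  cx <- f2cross(cr$geno[, sub], cr$pheno, cr$map[sub, ])
  built <- build_map(cx)
  expect_equal(length(unique(built$chr)), 2)
  expect_equal(sort(lengths(split(built$marker, built$chr)),
                    decreasing = TRUE), c(LG1 = 21, LG2 = 21),
               ignore_attr = TRUE)
  # each built group spans roughly the simulated 40 cM
  for (lg in unique(built$chr))
    expect_equal(max(built$pos[built$chr == lg]), 40, tolerance = 0.35)
})
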