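GENO_CODES <- c("A", "H", "B")

geno_encode <- function(x, na_token = "-") {
  g <- match(x, GENO_CODES)
  bad <- !is.na(x) & x != na_token & is.na(g)
  if (any(bad))
    stop("invalid genotype code(s): ", paste(unique(x[bad]), collapse = ", "),
         " (expected A, H, B or '", na_token, "')")
  g
}

geno_decode <- function(g, na_token = "-") {
  out <- GENO_CODES[g]
  out[is.na(g)] <- na_token
  out
}

#' Construct an F2 intercross object
#'
#' Bundles a genotype matrix (individuals x markers, integer codes
#' 1 = A = grandmaternal homozygote, 2 = H = heterozygote,
#' 3 = B = grandpaternal homozygote, `NA` = missing), a binary phenotype
#' (0 = female, 1 = male, `NA` = unknown) and a [genmap()].  Genotype
#' columns must match the map's loci in order.
#'
#' @param geno Integer matrix of genotype codes, or character matrix of
#'   A/H/B codes.
#' @param pheno Numeric vector of 0/1/`NA` phenotypes, one per individual.
#' @param map A `genmap` whose loci match `colnames(geno)` in order.
#' @return An object of class `f2cross`.
#' @export
f2cross <- function(geno, pheno, map) {
  if (is.character(geno)) {
    dn <- dimnames(geno)
    geno <- matrix(geno_encode(geno), nrow(geno), dimnames = dn)
  }
  storage.mode(geno) <- "integer"
  validate_genmap(map)
  class(map) <- c("genmap", "data.frame")
  if (is.null(colnames(geno))) colnames(geno) <- map$marker
  if (is.null(rownames(geno))) rownames(geno) <- paste0("ind", seq_len(nrow(geno)))
  if (ncol(geno) != nrow(map) || !all(colnames(geno) == map$marker))
    stop("genotype columns must match map loci (same names, same order)")
  if (length(pheno) != nrow(geno))
    stop("phenotype length (", length(pheno), ") != number of individuals (",
         nrow(geno), ")")
  if (!all(pheno %in% c(0, 1, NA)))
    stop("phenotype must be 0 (female), 1 (male) or NA (unknown)")
  if (any(!geno %in% c(1L, 2L, 3L, NA)))
    stop("genotypes must be coded 1/2/3 or NA")
  structure(list(geno = geno, pheno = as.integer(pheno), map = map),
            class = "f2cross")
}

#' @export
print.f2cross <- function(x, ...) {
  cat("F2 intercross: ", nrow(x$geno), " individuals, ", ncol(x$geno),
      " loci on ", length(unique(x$map$chr)), " chromosomes\n", sep = "")
  ph <- table(factor(x$pheno, levels = 0:1, labels = c("female", "male")),
              useNA = "ifany")
  cat("  phenotype:", paste(names(ph), ph, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
summary.f2cross <- function(object, ...) {
  out <- list(n_ind = nrow(object$geno),
              n_loci = ncol(object$geno),
              n_chr = length(unique(object$map$chr)),
              n_female = sum(object$pheno == 0, na.rm = TRUE),
              n_male = sum(object$pheno == 1, na.rm = TRUE),
              n_unknown = sum(is.na(object$pheno)),
              missing_frac = mean(is.na(object$geno)),
              map = map_summary(object$map, n_meioses = 2 * nrow(object$geno)))
  class(out) <- "summary.f2cross"
  out
}

#' @export
print.summary.f2cross <- function(x, ...) {
  cat("F2 intercross\n")
  cat(sprintf("  %d individuals (%d female / %d male / %d unknown)\n",
              x$n_ind, x$n_female, x$n_male, x$n_unknown))
  cat(sprintf("  %d loci on %d chromosomes; %.2f%% genotypes missing\n",
              x$n_loci, x$n_chr, 100 * x$missing_frac))
  cat(sprintf("  map: mean gap %.2f cM, largest gap %.2f cM, resolution %.1f cM (%d meioses)\n",
              x$map$mean_gap_cM, x$map$largest_gap_cM, x$map$resolution_cM,
              2 * x$n_ind))
  invisible(x)
}

#' Read / write an F2 cross file
#'
#' The cross file is a CSV with a three-row header: row 1 gives column names
#' (`id`, the phenotype column, then marker names), row 2 the chromosome
#' label of each marker (blank for `id` and the phenotype), row 3 the
#' Kosambi cM position of each marker.  Each subsequent row is one
#' individual: its id, phenotype (0 = female, 1 = male, missing = unknown)
#' and genotype codes A/H/B with `-` for missing.
#'
#' @param path Path to a cross CSV file.
#' @param na_token Token used for missing genotypes/phenotypes.
#' @return `read_cross()` returns an [f2cross()]; `write_cross()` returns
#'   `path` invisibly.
#' @export
read_cross <- function(path, na_token = "-") {
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE)
  if (nrow(raw) < 4) stop("cross file must have 3 header rows plus >= 1 individual")
  hdr <- as.character(unlist(raw[1, ]))
  chrrow <- as.character(unlist(raw[2, ]))
  posrow <- as.character(unlist(raw[3, ]))
  nonmark <- which(chrrow == "" | is.na(chrrow))
  if (!identical(nonmark, 1:2))
    stop("cross file must have exactly two non-marker columns (id, phenotype) ",
         "with blank chromosome cells")
  markers <- hdr[-(1:2)]
  if (anyDuplicated(markers))
    stop("duplicated marker column: ", markers[duplicated(markers)][1])
  pos <- suppressWarnings(as.numeric(posrow[-(1:2)]))
  if (any(is.na(pos)))
    stop("non-numeric cM position for marker ", markers[which(is.na(pos))[1]])
  map <- tryCatch(genmap(markers, chrrow[-(1:2)], pos),
                  error = function(e) stop("invalid map in cross file: ",
                                           conditionMessage(e), call. = FALSE))
  body <- raw[-(1:3), , drop = FALSE]
  if (any(nchar(body[[1]]) == 0)) stop("blank individual id at data row ",
                                       which(nchar(body[[1]]) == 0)[1])
  ids <- body[[1]]
  if (anyDuplicated(ids)) stop("duplicated individual id: ", ids[duplicated(ids)][1])
  ph <- body[[2]]
  ph[ph == na_token | ph == ""] <- NA
  phn <- suppressWarnings(as.numeric(ph))
  if (any(!is.na(ph) & (is.na(phn) | !phn %in% c(0, 1))))
    stop("phenotype must be 0, 1 or '", na_token, "'; offending individual ",
         ids[which(!is.na(ph) & (is.na(phn) | !phn %in% c(0, 1)))[1]])
  gm <- as.matrix(body[, -(1:2), drop = FALSE])
  gm[gm == ""] <- na_token
  enc <- tryCatch(geno_encode(gm, na_token),
                  error = function(e) {
                    badm <- matrix(!(gm %in% c(GENO_CODES, na_token)), nrow(gm))
                    bad <- which(badm, arr.ind = TRUE)[1, ]
                    stop("invalid genotype code '", gm[bad[1], bad[2]],
                         "' for individual ", ids[bad[1]], " at marker ",
                         markers[bad[2]], call. = FALSE)
                  })
  geno <- matrix(enc, nrow = nrow(gm), dimnames = list(ids, markers))
  f2cross(geno, phn, map)
}

#' @rdname read_cross
#' @param cross An [f2cross()] object.
#' @export
write_cross <- function(cross, path, na_token = "-") {
  m <- cross$map
  hdr <- c("id", "sex", m$marker)
  chrrow <- c("", "", m$chr)
  posrow <- c("", "", format(m$pos, trim = TRUE, scientific = FALSE))
  ph <- ifelse(is.na(cross$pheno), na_token, as.character(cross$pheno))
  gm <- matrix(geno_decode(cross$geno, na_token), nrow(cross$geno))
  body <- cbind(rownames(cross$geno), ph, gm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = ","), con)
  writeLines(paste(chrrow, collapse = ","), con)
  writeLines(paste(posrow, collapse = ","), con)
  writeLines(apply(body, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read a physical map table
#'
#' A tab-separated table with columns `marker`, `chromosome` and `bp`
#' (1-based assembly coordinate) giving each marker's physical position.
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `physmap` with columns `marker`, `chr`,
#'   `bp`, one row per marker.
#' @export
read_physical_map <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("marker", "chromosome", "bp")
  if (!all(need %in% names(tab)))
    stop("physical map must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$marker))
    stop("duplicated marker in physical map: ",
         tab$marker[duplicated(tab$marker)][1])
  bp <- suppressWarnings(as.numeric(tab$bp))
  bad <- is.na(bp) | bp != round(bp) | bp <= 0
  if (any(bad))
    stop("invalid bp position at row ", which(bad)[1], " (marker ",
         tab$marker[which(bad)[1]], "): must be a positive integer")
  out <- data.frame(marker = tab$marker, chr = tab$chromosome, bp = bp,
                    stringsAsFactors = FALSE)
  class(out) <- c("physmap", "data.frame")
  out
}

#' @rdname read_physical_map
#' @param physmap A `physmap` data frame.
#' @param path Output path.
#' @export
write_physical_map <- function(physmap, path) {
  out <- data.frame(marker = physmap$marker, chromosome = physmap$chr,
                    bp = format(physmap$bp, trim = TRUE, scientific = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# individuals with a known (0/1) phenotype
phenotyped <- function(cross) which(!is.na(cross$pheno))
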