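#' Construct a genetic map
#'
#' A genetic map is a data frame with one row per locus and columns
#' `marker` (locus name; co-segregating markers collapsed onto one locus are
#' semicolon-joined), `chr` (chromosome label) and `pos` (Kosambi cM,
#' nondecreasing within a chromosome, anchored at 0 at the first locus of
#' each chromosome).
#'
#' @param marker Character vector of locus names.
#' @param chr Chromosome label per locus.
#' @param pos Position per locus in Kosambi cM.
#' @param anchor If `TRUE`, shift positions so each chromosome starts at 0.
#' @return A data frame of class `genmap`.
#' @export
genmap <- function(marker, chr, pos, anchor = FALSE) {
  if (length(marker) != length(chr) || length(chr) != length(pos))
    stop("marker, chr and pos must have equal length")
  m <- data.frame(marker = as.character(marker), chr = as.character(chr),
                  pos = as.numeric(pos), stringsAsFactors = FALSE)
  rownames(m) <- NULL
  if (anchor)
    m$pos <- m$pos - ave(m$pos, m$chr, FUN = min)
  validate_genmap(m)
  class(m) <- c("genmap", "data.frame")
  m
}

validate_genmap <- function(m) {
  stopifnot(is.data.frame(m), all(c("marker", "chr", "pos") %in% names(m)))
  if (anyDuplicated(m$marker))
    stop("duplicated locus name in map: ", m$marker[duplicated(m$marker)][1])
  if (any(m$pos < 0)) stop("map positions must be >= 0")
  # positions must be nondecreasing within each chromosome
  decreasing <- unlist(tapply(seq_len(nrow(m)),
                              factor(m$chr, levels = unique(m$chr)),
                              function(i) i[c(FALSE, diff(m$pos[i]) < 0)]),
                       use.names = FALSE)
  if (length(decreasing))
    stop("map position decreases at marker ", m$marker[min(decreasing)],
         " (chromosome ", m$chr[min(decreasing)], ")")
  invisible(m)
}

#' @export
print.genmap <- function(x, ...) {
  nchr <- length(unique(x$chr))
  cat("Genetic map: ", nrow(x), " loci on ", nchr, " chromosome",
      if (nchr != 1) "s", "\n", sep = "")
  s <- map_summary(x)
  cat(sprintf("  mean adjacent gap %.2f cM, largest gap %.2f cM\n",
              s$mean_gap_cM, s$largest_gap_cM))
  invisible(x)
}

#' Summarize a genetic map
#'
#' Adjacent-locus gap statistics plus the mapping resolution implied by a
#' number of meioses (100/n meioses, in cM, rounded to one decimal — e.g.
#' 1040 meioses from 520 F2 progeny give 0.1 cM).
#'
#' @param map A `genmap`.
#' @param n_meioses Optional number of informative meioses.
#' @return A list with `n_loci`, `n_chr`, `mean_gap_cM`, `largest_gap_cM`,
#'   and, when `n_meioses` is given, `resolution_cM`.
#' @export
map_summary <- function(map, n_meioses = NULL) {
  gaps <- unlist(tapply(map$pos, factor(map$chr, levels = unique(map$chr)),
                        diff), use.names = FALSE)
  out <- list(n_loci = nrow(map), n_chr = length(unique(map$chr)),
              mean_gap_cM = if (length(gaps)) mean(gaps) else NA_real_,
              largest_gap_cM = if (length(gaps)) max(gaps) else NA_real_)
  if (!is.null(n_meioses)) out$resolution_cM <- round(100 / n_meioses, 1)
  out
}
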