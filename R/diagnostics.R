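# longest (strictly) increasing subsequence; returns indices
.lis <- function(x) {
  n <- length(x)
  if (!n) return(integer())
  best <- rep(1L, n); prev <- rep(NA_integer_, n)
  for (i in seq_len(n)[-1]) for (j in seq_len(i - 1)) {
    if (x[j] < x[i] && best[j] + 1L > best[i]) {
      best[i] <- best[j] + 1L; prev[i] <- j
    }
  }
  i <- which.max(best)
  out <- integer(best[i])
  for (k in rev(seq_len(best[i]))) { out[k] <- i; i <- prev[i] }
  out
}

#' Concordant markers between genetic and physical maps
#'
#' Markers concordant in chromosome assignment (same label in both maps)
#' and in rank order: within each chromosome the longest increasing
#' subsequence of physical positions taken in genetic order is kept.
#'
#' @param map A [genmap()].
#' @param physmap A `physmap` (see [read_physical_map()]).
#' @return A data frame `marker`, `chr`, `pos` (cM), `bp` of concordant
#'   markers, in genetic order.
#' @export
concordant_markers <- function(map, physmap) {
  pm <- physmap[match(map$marker, physmap$marker), ]
  keep <- !is.na(pm$marker) & pm$chr == map$chr
  dat <- data.frame(marker = map$marker, chr = map$chr, pos = map$pos,
                    bp = pm$bp, stringsAsFactors = FALSE)[keep, ]
  out <- do.call(rbind, lapply(unique(dat$chr), function(chr) {
    sub <- dat[dat$chr == chr, ]
    sub[.lis(sub$bp), ]
  }))
  rownames(out) <- NULL
  out
}

#' Sliding-window recombination rate (cM/Mb)
#'
#' Estimates the local recombination rate along each chromosome from
#' markers concordant between the genetic and physical maps: in each
#' window of `window_bp` bases (advanced by `step_bp`, anchored at 0),
#' rate = (cM span of the markers in the window) / (their bp span in
#' Mb).  Windows with fewer than 2 markers get an undefined (`NA`) rate.
#' The genome-wide mean uses whole-chromosome spans (total concordant cM
#' over total concordant Mb), so it does not depend on the window width.
#'
#' @param map A [genmap()].
#' @param physmap A `physmap`.
#' @param window_bp Window width in bases (default 5 Mb).
#' @param step_bp Window step in bases (default 1 Mb).
#' @return A data frame `chr`, `start_bp`, `end_bp`, `n_markers`, `rate`
#'   with the genome mean attached as attribute `genome_mean`.
#' @export
recomb_rate <- function(map, physmap, window_bp = 5e6, step_bp = 1e6) {
  conc <- concordant_markers(map, physmap)
  res <- list(); span_cM <- 0; span_Mb <- 0
  for (chr in unique(conc$chr)) {
    sub <- conc[conc$chr == chr, ]
    if (nrow(sub) >= 2) {
      span_cM <- span_cM + diff(range(sub$pos))
      span_Mb <- span_Mb + diff(range(sub$bp)) / 1e6
    }
    starts <- seq(0, max(sub$bp), by = step_bp)
    for (s in starts) {
      inw <- sub$bp >= s & sub$bp < s + window_bp
      rate <- if (sum(inw) >= 2 && diff(range(sub$bp[inw])) > 0)
        diff(range(sub$pos[inw])) / (diff(range(sub$bp[inw])) / 1e6)
      else NA_real_
      res[[length(res) + 1]] <- data.frame(
        chr = chr, start_bp = s, end_bp = s + window_bp,
        n_markers = sum(inw), rate = rate, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  attr(out, "genome_mean") <- if (span_Mb > 0) span_cM / span_Mb else NA_real_
  out
}

#' Support LODs for a discordant chromosome assignment
#'
#' For a marker whose genetic and physical maps disagree on the
#' chromosome, compares the linkage support at its genetic position (sum
#' of two-point LODs to its flanking genetic-map loci, evaluated at the
#' recombination fractions implied by the map distances) with the best
#' linkage anywhere on its physically assigned chromosome (maximum
#' two-point ML LOD against all genetic-map loci of that chromosome).
#'
#' @param cross An [f2cross()] typed at the marker and the map loci.
#' @param map A [genmap()] containing `marker`.
#' @param physmap A `physmap` giving the marker's physical chromosome.
#' @param marker Marker name.
#' @return List with `genetic_lod` and `physical_lod` (both `>= 0`).
#' @export
assignment_support <- function(cross, map, physmap, marker) {
  i <- match(marker, map$marker)
  if (is.na(i)) stop("marker ", marker, " not on the genetic map")
  chr_g <- map$chr[i]
  rows <- which(map$chr == chr_g)
  k <- match(i, rows)
  nb <- c(if (k > 1) rows[k - 1], if (k < length(rows)) rows[k + 1])
  glod <- 0
  for (j in nb) {
    counts <- .pair_counts(cross$geno[, marker], cross$geno[, map$marker[j]])
    r_imp <- max(haldane_inverse(abs(map$pos[i] - map$pos[j])), R_CLAMP[1])
    glod <- glod + max(.rf_loglik10(matrix(counts, 1), r_imp) -
                       .rf_loglik10(matrix(counts, 1), 0.5), 0)
  }
  chr_p <- physmap$chr[match(marker, physmap$marker)]
  if (is.na(chr_p)) stop("marker ", marker, " not in the physical map")
  prows <- which(map$chr == chr_p & map$marker != marker)
  if (!length(prows))
    stop("physical chromosome ", chr_p, " has no loci on the genetic map")
  ova <- .rf_one_vs_all(cross$geno[, marker],
                        cross$geno[, map$marker[prows], drop = FALSE])
  plod <- max(c(ova$fit$lod, 0), na.rm = TRUE)
  list(genetic_lod = glod, physical_lod = plod)
}

#' Marker-order LOD comparison
#'
#' Multipoint log10 likelihood of the genotype data under order B minus
#' under order A, with adjacent recombination fractions re-estimated for
#' each order and an error-tolerant HMM (error rate `eps`).  Negative
#' values support order A; an order-A-vs-itself comparison is exactly 0.
#'
#' @param cross An [f2cross()].
#' @param orderA,orderB Marker-name vectors; must be permutations of the
#'   same set.
#' @param eps Genotyping-error rate for the multipoint HMM.
#' @return log10 likelihood difference (B minus A).
#' @export
order_lod <- function(cross, orderA, orderB, eps = 1e-4) {
  if (!setequal(orderA, orderB) || length(orderA) != length(orderB))
    stop("orderA and orderB must be permutations of the same markers")
  if (identical(orderA, orderB)) return(0)
  .order_loglik10(cross, orderB, eps) - .order_loglik10(cross, orderA, eps)
}
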