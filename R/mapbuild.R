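#' Collapse markers with identical genotype vectors
#'
#' Markers whose observed genotype vectors are exactly identical
#' (including the missing-data pattern) carry no recombination
#' information about each other and are merged into a single locus whose
#' name joins all member markers with `;`.  Identity is strict: markers
#' with zero observed recombinants but different missingness remain
#' separate loci.
#'
#' @param cross An [f2cross()].
#' @return An [f2cross()] with one column per distinct genotype vector;
#'   the map keeps the first member's position and the joined name.
#' @examples
#' cr <- sim_cross(n = 60, map = reduced_map(), seed = 1)
#' cr2 <- collapse_identical(cr)
#' @export
collapse_identical <- function(cross) {
  key <- apply(cross$geno, 2, function(col) paste(ifelse(is.na(col), "-", col),
                                                  collapse = ""))
  # keep within-chromosome grouping: identical vectors on different
  # chromosomes would be a data artifact, not the same locus
  key <- paste(cross$map$chr, key, sep = "|")
  first <- !duplicated(key)
  grp <- match(key, key[first])
  newname <- vapply(seq_len(sum(first)), function(g)
    paste(cross$map$marker[grp == g], collapse = ";"), character(1))
  geno <- cross$geno[, first, drop = FALSE]
  colnames(geno) <- newname
  map <- cross$map[first, , drop = FALSE]
  map$marker <- newname
  rownames(map) <- NULL
  class(map) <- c("genmap", "data.frame")
  f2cross(geno, cross$pheno, map)
}

#' Linkage grouping of markers
#'
#' Single-linkage clustering of markers on pairwise linkage: two markers
#' join the same group when the chi-square (1 df) P-value of their
#' two-point linkage LOD (P from 2 ln(10) LOD, an approximation) is below
#' `p_threshold`.
#'
#' @param cross An [f2cross()].
#' @param p_threshold Linkage P-value threshold (default 1e-6).
#' @param rf Optional precomputed [est_rf_all()] result.
#' @return A list of character vectors, one per linkage group, largest
#'   first.
#' @export
group_markers <- function(cross, p_threshold = 1e-6, rf = NULL) {
  markers <- colnames(cross$geno)
  m <- length(markers)
  if (is.null(rf)) rf <- est_rf_all(cross, markers)
  pval <- stats::pchisq(2 * log(10) * rf$lod, df = 1, lower.tail = FALSE)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  link <- which(upper.tri(pval) & !is.na(pval) & pval < p_threshold, arr.ind = TRUE)
  for (k in seq_len(nrow(link))) {
    a <- find(link[k, 1]); b <- find(link[k, 2])
    if (a != b) parent[a] <- b
  }
  root <- vapply(seq_len(m), find, integer(1))
  groups <- split(markers, root)
  names(groups) <- NULL
  groups[order(-lengths(groups))]
}

# multipoint log10 likelihood of a marker order (adjacent r re-estimated
# from two-point EM; error-tolerant HMM so single bad genotypes don't
# dominate the comparison)
.order_loglik10 <- function(cross, markers, eps = 1e-4) {
  obs <- cross$geno[, markers, drop = FALSE]
  L <- ncol(obs)
  if (L < 2) return(0)
  r <- vapply(seq_len(L - 1), function(k) {
    fit <- .rf_em(.pair_counts(obs[, k], obs[, k + 1]))
    if (is.na(fit$r_hat)) 0.5 - 1e-6 else fit$r_hat
  }, numeric(1))
  sum(.fb_chr(obs, r, eps)$logl10)
}

#' Order loci within a linkage group
#'
#' A seriation heuristic: greedy chaining on the smallest pairwise
#' recombination fraction (starting from the tightest pair and extending
#' whichever chain end is closest to an unplaced marker), followed by a
#' ripple pass over windows of 3 accepted on the multipoint log10
#' likelihood (adjacent recombination fractions re-estimated for each
#' candidate order).  Adjacent pairs whose swap changes the multipoint
#' log10 likelihood by less than `ambiguity_lod` are reported as order
#' ambiguities.
#'
#' @param cross An [f2cross()].
#' @param markers Markers of one linkage group.
#' @param eps Error rate for the multipoint likelihood HMM.
#' @param ambiguity_lod Log10-likelihood difference below which an
#'   adjacent swap counts as ambiguous (default 0.5).
#' @return List with `order` (marker names), `loglik10`, and
#'   `ambiguities` (data frame of ambiguous adjacent pairs and the
#'   log10-likelihood change of their swap).
#' @export
order_loci <- function(cross, markers, eps = 1e-4, ambiguity_lod = 0.5) {
  m <- length(markers)
  if (m < 2)
    return(list(order = markers, loglik10 = 0,
                ambiguities = data.frame(markerA = character(),
                                         markerB = character(),
                                         delta_loglik10 = numeric())))
  rf <- est_rf_all(cross, markers)
  R <- rf$r_hat
  diag(R) <- Inf
  R[is.na(R)] <- Inf
  start <- which(R == min(R), arr.ind = TRUE)[1, ]
  chain <- as.integer(start)
  left <- setdiff(seq_len(m), chain)
  while (length(left)) {
    d_head <- R[chain[1], left]
    d_tail <- R[chain[length(chain)], left]
    if (min(d_head) <= min(d_tail)) {
      k <- left[which.min(d_head)]; chain <- c(k, chain)
    } else {
      k <- left[which.min(d_tail)]; chain <- c(chain, k)
    }
    left <- setdiff(left, chain)
  }
  ord <- markers[chain]
  # ripple: windows of 3, accept any permutation improving the
  # multipoint likelihood; repeat until stable
  ll <- .order_loglik10(cross, ord, eps)
  if (m >= 3) {
    perms <- list(c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    repeat {
      improved <- FALSE
      for (w in seq_len(m - 2)) {
        for (p in perms) {
          cand <- ord
          cand[w:(w + 2)] <- ord[w:(w + 2)][p]
          llc <- .order_loglik10(cross, cand, eps)
          if (llc > ll + 1e-9) { ord <- cand; ll <- llc; improved <- TRUE }
        }
      }
      if (!improved) break
    }
  }
  amb <- list()
  for (k in seq_len(m - 1)) {
    cand <- ord
    cand[k:(k + 1)] <- cand[(k + 1):k]
    delta <- .order_loglik10(cross, cand, eps) - ll
    if (abs(delta) < ambiguity_lod)
      amb[[length(amb) + 1]] <- data.frame(markerA = ord[k], markerB = ord[k + 1],
                                           delta_loglik10 = delta,
                                           stringsAsFactors = FALSE)
  }
  list(order = ord, loglik10 = ll,
       ambiguities = if (length(amb)) do.call(rbind, amb) else
         data.frame(markerA = character(), markerB = character(),
                    delta_loglik10 = numeric()))
}

# two-point r/lod of one genotype vector against many
.rf_one_vs_all <- function(g, G) {
  counts <- matrix(0, ncol(G), 9)
  col <- 0
  for (i in 1:3) for (j in 1:3) {
    col <- col + 1
    counts[, col] <- colSums((!is.na(g) & g == i) * (!is.na(G) & G == j),
                             na.rm = TRUE)
  }
  list(fit = .rf_em(counts), counts = counts)
}

#' Place a marker on a framework map
#'
#' Evaluates candidate placements of `marker` on `map` by a multipoint
#' profile built from two-point likelihoods: a placement at position x
#' scores the sum, over every framework locus of the chromosome, of the
#' two-point log10 LOD between the marker and that locus evaluated at the
#' recombination fraction implied by their map distance.  Candidates are
#' co-location at each framework locus (allowed only when the pair table
#' shows no visible recombinant, i.e. only diagonal and
#' double-heterozygote cells are occupied) and insertion into each marker
#' interval (profile maximized over a 0.25 cM grid inside the interval).
#' The support LOD is the score difference between the best placement and
#' the best alternative that shares no flanking framework locus with it;
#' placements with support below `support_lod` are reported as unplaced.
#'
#' @param map A framework [genmap()] whose loci are typed in `cross`.
#' @param cross An [f2cross()] containing both the framework loci and
#'   `marker` (the cross's own map need not include `marker`).
#' @param marker Name of the marker to place.
#' @param support_lod Minimum support LOD for a placement (default 7).
#' @return List with `placed`, `chr`, `pos`, `type` (`"at_locus"` or
#'   `"interval"`), `nearest` (framework locus/loci), `support_lod` and
#'   `best_score`.
#' @export
insert_marker <- function(map, cross, marker, support_lod = 7) {
  g <- cross$geno[, marker]
  if (all(is.na(g))) stop("marker ", marker, " is untyped in all individuals")
  G <- cross$geno[, map$marker, drop = FALSE]
  ova <- .rf_one_vs_all(g, G)
  # co-location is only a candidate when the pair table shows no visible
  # recombinant (only diagonal and double-heterozygote cells occupied)
  colocatable <- rowSums(ova$counts[, c(2, 3, 4, 6, 7, 8), drop = FALSE]) == 0 &
    rowSums(ova$counts) > 0
  ll05 <- .rf_loglik10(ova$counts, 0.5)
  cand <- list()
  for (chr in unique(map$chr)) {
    rows <- which(map$chr == chr)
    L <- length(rows)
    cnt <- ova$counts[rows, , drop = FALSE]
    profile <- function(x) {          # multipoint score of position x
      r <- pmax(haldane_inverse(abs(x - map$pos[rows])), R_CLAMP[1])
      sum(.rf_loglik10(cnt, r) - ll05[rows])
    }
    for (k in seq_len(L)) {           # co-location at locus k
      if (!colocatable[rows[k]]) next
      cand[[length(cand) + 1]] <- list(
        chr = chr, type = "at_locus", pos = map$pos[rows[k]],
        nearest = map$marker[rows[k]], flanks = rows[k],
        score = profile(map$pos[rows[k]]))
    }
    for (k in seq_len(L - 1)) {       # interval (k, k+1)
      a <- rows[k]; b <- rows[k + 1]
      d <- map$pos[b] - map$pos[a]
      if (d <= 0.5) next              # too narrow to place between
      xs <- seq(0.25, d - 0.25, by = 0.25)
      prof <- vapply(map$pos[a] + xs, profile, numeric(1))
      cand[[length(cand) + 1]] <- list(
        chr = chr, type = "interval", pos = map$pos[a] + xs[which.max(prof)],
        nearest = paste(map$marker[a], map$marker[b], sep = ";"),
        flanks = c(a, b), score = max(prof))
    }
  }
  scores <- vapply(cand, `[[`, numeric(1), "score")
  types <- vapply(cand, `[[`, character(1), "type")
  # prefer co-location when it is within the profile's flatness scale
  # (~2 LOD over a 0.25 cM shift) of the best score
  best <- which.max(scores)
  al <- which(types == "at_locus")
  if (length(al) && max(scores[al]) >= scores[best] - 2)
    best <- al[which.max(scores[al])]
  rivals <- which(vapply(cand, function(cc)
    !any(cc$flanks %in% cand[[best]]$flanks), logical(1)))
  # support on the positive-LOD scale: a placement fitting worse than
  # "unlinked everywhere" (negative profile) lends no support
  support <- max(scores[best], 0) -
    max(c(if (length(rivals)) scores[rivals], 0))
  out <- cand[[best]]
  list(placed = support >= support_lod, chr = out$chr, pos = out$pos,
       type = out$type, nearest = out$nearest,
       support_lod = support, best_score = scores[best])
}

#' Build a genetic map de novo from genotypes
#'
#' Convenience wrapper: collapse identical markers, form linkage groups,
#' order each group, and assign Kosambi cM positions from the adjacent
#' two-point recombination fractions.
#'
#' @param cross An [f2cross()].
#' @param p_threshold Linkage-group P-value threshold.
#' @param collapse Collapse identical genotype vectors first?
#' @return A [genmap()] with linkage groups labelled `LG1`, `LG2`, ...
#'   (largest first) and an `ambiguities` attribute listing order-ambiguous
#'   adjacent pairs.
#' @export
build_map <- function(cross, p_threshold = 1e-6, collapse = TRUE) {
  if (collapse) cross <- collapse_identical(cross)
  groups <- group_markers(cross, p_threshold)
  maps <- list(); ambs <- list()
  for (i in seq_along(groups)) {
    og <- order_loci(cross, groups[[i]])
    ord <- og$order
    r <- vapply(seq_len(length(ord) - 1), function(k)
      est_rf(cross, ord[k], ord[k + 1])$r_hat, numeric(1))
    r[is.na(r)] <- 0.5 - 1e-6
    pos <- cumsum(c(0, kosambi(pmin(r, 0.4999))))
    maps[[i]] <- data.frame(marker = ord, chr = paste0("LG", i), pos = pos,
                            stringsAsFactors = FALSE)
    if (nrow(og$ambiguities)) {
      og$ambiguities$group <- paste0("LG", i)
      ambs[[length(ambs) + 1]] <- og$ambiguities
    }
  }
  out <- do.call(rbind, maps)
  out <- genmap(out$marker, out$chr, out$pos)
  attr(out, "ambiguities") <- if (length(ambs)) do.call(rbind, ambs) else NULL
  out
}
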