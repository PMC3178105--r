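# Binary-trait interval mapping.
#
# At each grid position the trait model is P(y = 1 | g) = pi_g for the
# three F2 genotype classes; with genotype uncertainty the individual
# likelihood is sum_g q_ig Bern(y_i; pi_g), maximized by EM over the
# posterior mixture.  LOD compares the fitted model with a single
# Bernoulli at the overall trait mean.

PI_CLAMP <- c(1e-6, 1 - 1e-6)

# EM across all grid positions of one chromosome simultaneously.
# prob: n x 3 x G posteriors (phenotyped individuals only), y: 0/1.
.scan_em_block <- function(prob, y, tol = 1e-6, maxit = 200) {
  n <- dim(prob)[1]; G <- dim(prob)[3]
  Q <- lapply(1:3, function(g) matrix(prob[, g, ], n, G))
  i1 <- y == 1
  n1 <- sum(i1); n0 <- n - n1
  Q1 <- lapply(Q, function(m) m[i1, , drop = FALSE])
  Q0 <- lapply(Q, function(m) m[!i1, , drop = FALSE])
  # one M-step from the genotype posteriors as starting value
  pi <- vapply(1:3, function(g) colSums(Q[[g]] * y) / colSums(Q[[g]]),
               numeric(G))
  pi[!is.finite(pi)] <- mean(y)      # genotype class with no posterior mass
  pi <- t(pmin(pmax(pi, PI_CLAMP[1]), PI_CLAMP[2]))      # 3 x G
  ll_prev <- rep(-Inf, G)
  for (it in seq_len(maxit)) {
    den1 <- Q1[[1]] * rep(pi[1, ], each = n1) +
            Q1[[2]] * rep(pi[2, ], each = n1) +
            Q1[[3]] * rep(pi[3, ], each = n1)
    den0 <- Q0[[1]] * rep(1 - pi[1, ], each = n0) +
            Q0[[2]] * rep(1 - pi[2, ], each = n0) +
            Q0[[3]] * rep(1 - pi[3, ], each = n0)
    ll <- colSums(log10(den1)) + colSums(log10(den0))
    if (any(ll - ll_prev < -1e-8))
      stop("EM log-likelihood decreased; this should not happen")
    ll_prev <- ll
    S1 <- t(vapply(1:3, function(g) colSums(Q1[[g]] / den1), numeric(G)))
    S0 <- t(vapply(1:3, function(g) colSums(Q0[[g]] / den0), numeric(G)))
    num <- pi * S1
    pi_new <- num / (num + (1 - pi) * S0)
    pi_new[!is.finite(pi_new)] <- pi[!is.finite(pi_new)]
    pi_new <- pmin(pmax(pi_new, PI_CLAMP[1]), PI_CLAMP[2])
    delta <- max(abs(pi_new - pi))
    pi <- pi_new
    if (delta < tol) break
  }
  list(pi = pi, loglik10 = ll_prev)
}

.scan_lods <- function(problist, y, tol, maxit) {
  pbar <- mean(y)
  ll0 <- sum(y) * log10(pbar) + sum(1 - y) * log10(1 - pbar)
  lod <- list(); pi <- list()
  for (chr in names(problist)) {
    fit <- .scan_em_block(problist[[chr]], y, tol, maxit)
    lod[[chr]] <- pmax(fit$loglik10 - ll0, 0)
    pi[[chr]] <- fit$pi
  }
  list(lod = lod, pi = pi, pbar = pbar, loglik0 = ll0)
}

.keep_prob <- function(gp, keep) {
  lapply(gp, function(ch) ch$prob[keep, , , drop = FALSE])
}

#' Binary-trait interval mapping scan
#'
#' Scans the genome for loci affecting a binary trait in an F2
#' intercross.  At each grid position (map loci plus multiples of `step`
#' cM) the three genotype-class penetrances pi_g = P(trait = 1 | g) are
#' fitted by EM over the hidden-Markov genotype posteriors, and the LOD
#' compares the fitted model to a single Bernoulli at the overall trait
#' mean.  Individuals with unknown phenotype are excluded.
#'
#' @param cross An [f2cross()].
#' @param step Scan grid step in cM (0 = map loci only).
#' @param eps Assumed genotyping-error rate for the genotype HMM.
#' @param tol EM convergence tolerance on the penetrances.
#' @param maxit Maximum EM iterations.
#' @param gp Optional precomputed [genoprob()] (must match `step`/`eps`).
#' @param pheno Optional phenotype vector overriding `cross$pheno`.
#' @return An object of class `binscan`: list with `result` (data frame
#'   `chr`, `pos`, `marker`, `lod`), `pi` (3 x positions penetrance
#'   estimates), `pbar`, `n1`/`n0` (phenotyped counts) and the scan
#'   settings.
#' @examples
#' cr <- sim_cross(n = 150, map = reduced_map(), seed = 1)
#' sc <- scan_binary(cr, step = 0)
#' summary(sc)
#' @export
scan_binary <- function(cross, step = 1, eps = 1e-4, tol = 1e-6,
                        maxit = 200, gp = NULL, pheno = NULL) {
  y_all <- if (is.null(pheno)) cross$pheno else pheno
  keep <- which(!is.na(y_all))
  y <- y_all[keep]
  if (length(unique(y)) < 2) {
    warning("phenotype is constant among phenotyped individuals; LOD = 0 everywhere")
    constant <- TRUE
  } else constant <- FALSE
  if (is.null(gp)) gp <- genoprob(cross, step = step, eps = eps)
  res <- do.call(rbind, lapply(names(gp), function(chr)
    data.frame(chr = chr, pos = gp[[chr]]$pos, marker = gp[[chr]]$marker,
               lod = NA_real_, stringsAsFactors = FALSE)))
  if (constant) {
    res$lod <- 0
    pi <- matrix(mean(y), 3, nrow(res))
    sl <- list(pbar = mean(y))
  } else {
    sl <- .scan_lods(.keep_prob(gp, keep), y, tol, maxit)
    res$lod <- unlist(sl$lod, use.names = FALSE)
    pi <- do.call(cbind, sl$pi)
  }
  structure(list(result = res, pi = pi, pbar = mean(y),
                 n1 = sum(y == 1), n0 = sum(y == 0),
                 step = step, eps = eps, call = match.call()),
            class = "binscan")
}

#' @export
print.binscan <- function(x, ...) {
  cat("Binary-trait interval mapping scan\n")
  cat(sprintf("  %d phenotyped individuals (%d/%d), %d positions, step %g cM\n",
              x$n1 + x$n0, x$n0, x$n1, nrow(x$result), x$step))
  top <- x$result[which.max(x$result$lod), ]
  cat(sprintf("  max LOD %.2f on chr %s at %.1f cM\n", top$lod, top$chr, top$pos))
  invisible(x)
}

#' @export
summary.binscan <- function(object, thresholds = NULL, drop = 1.5, ...) {
  res <- object$result
  out <- do.call(rbind, lapply(unique(res$chr), function(chr) {
    sub <- res[res$chr == chr, ]
    i <- which.max(sub$lod)            # leftmost on ties (which.max is first)
    ci <- lod_drop_interval(object, chr, drop = drop)
    data.frame(chr = chr, pos = sub$pos[i], lod = sub$lod[i],
               ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
  }))
  if (!is.null(thresholds))
    out$signif <- out$lod > min(thresholds)
  rownames(out) <- NULL
  class(out) <- c("summary.binscan", "data.frame")
  attr(out, "thresholds") <- thresholds
  out
}

#' @export
print.summary.binscan <- function(x, ...) {
  cat("Per-chromosome LOD peaks (with", attr(x, "drop", exact = TRUE) %||% 1.5,
      "LOD-drop support intervals)\n")
  print.data.frame(cbind.data.frame(x), digits = 4)
  th <- attr(x, "thresholds")
  if (!is.null(th))
    cat("thresholds:", paste(names(th), round(th, 2), sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
plot.binscan <- function(x, thresholds = NULL, ...) {
  res <- x$result
  chrs <- unique(res$chr)
  offs <- c(0, cumsum(vapply(chrs, function(c) max(res$pos[res$chr == c]) + 5,
                             numeric(1))))
  names(offs) <- c(chrs, "end")
  xx <- res$pos + offs[res$chr]
  plot(xx, res$lod, type = "n", xlab = "chromosome", ylab = "LOD",
       xaxt = "n", ...)
  for (c in chrs)
    graphics::lines(xx[res$chr == c], res$lod[res$chr == c])
  mid <- vapply(chrs, function(c) mean(range(xx[res$chr == c])), numeric(1))
  graphics::axis(1, at = mid, labels = chrs, tick = FALSE, cex.axis = 0.7)
  if (!is.null(thresholds))
    graphics::abline(h = thresholds, lty = 2, col = "grey40")
  invisible(x)
}

#' @export
coef.binscan <- function(object, ...) {
  res <- object$result
  do.call(rbind, lapply(unique(res$chr), function(chr) {
    i <- which(res$chr == chr)[which.max(res$lod[res$chr == chr])]
    data.frame(chr = chr, pos = res$pos[i], lod = res$lod[i],
               piA = object$pi[1, i], piH = object$pi[2, i],
               piB = object$pi[3, i], stringsAsFactors = FALSE)
  }))
}

#' Permutation-based genome-wide LOD thresholds
#'
#' Permutes the phenotype labels among phenotyped individuals, rescans
#' the genome, and records the genome-wide maximum LOD of each
#' permutation; the alpha-level threshold is the (1 - alpha) empirical
#' quantile of those maxima.
#'
#' @inheritParams scan_binary
#' @param n_perm Number of permutation replicates.
#' @param alphas Significance levels.
#' @param seed Seed for the permutations.
#' @return A list with `thresholds` (named by alpha), `max_lods` and
#'   `n_perm`.
#' @export
perm_threshold <- function(cross, n_perm = 1000, alphas = c(0.05, 0.01),
                           step = 1, eps = 1e-4, seed = 1, tol = 1e-6,
                           maxit = 200, gp = NULL, pheno = NULL) {
  stopifnot(n_perm >= 2)
  y_all <- if (is.null(pheno)) cross$pheno else pheno
  keep <- which(!is.na(y_all))
  y <- y_all[keep]
  if (is.null(gp)) gp <- genoprob(cross, step = step, eps = eps)
  pk <- .keep_prob(gp, keep)
  set.seed(as.integer(seed))
  max_lods <- vapply(seq_len(n_perm), function(i) {
    sl <- .scan_lods(pk, sample(y), tol, maxit)
    max(unlist(sl$lod, use.names = FALSE))
  }, numeric(1))
  th <- stats::quantile(max_lods, 1 - alphas, names = FALSE)
  names(th) <- format(alphas)
  list(thresholds = th, max_lods = max_lods, n_perm = n_perm)
}

#' LOD-drop support interval
#'
#' The widest contiguous interval around a chromosome's LOD peak over
#' which the LOD stays within `drop` of the peak; endpoints are linearly
#' interpolated between grid positions.
#'
#' @param scan A [scan_binary()] result.
#' @param chromosome Chromosome label.
#' @param drop LOD drop defining the interval (default 1.5).
#' @return Numeric `c(left, right)` in cM.
#' @export
lod_drop_interval <- function(scan, chromosome, drop = 1.5) {
  sub <- scan$result[scan$result$chr == as.character(chromosome), ]
  if (!nrow(sub)) stop("no scan positions on chromosome ", chromosome)
  lod <- sub$lod; pos <- sub$pos
  ip <- which.max(lod)
  thr <- lod[ip] - drop
  i <- ip
  while (i > 1 && lod[i - 1] >= thr) i <- i - 1
  left <- if (i == 1) pos[1] else
    pos[i] - (pos[i] - pos[i - 1]) * (lod[i] - thr) / (lod[i] - lod[i - 1])
  j <- ip
  while (j < length(lod) && lod[j + 1] >= thr) j <- j + 1
  right <- if (j == length(lod)) pos[j] else
    pos[j] + (pos[j + 1] - pos[j]) * (lod[j] - thr) / (lod[j] - lod[j + 1])
  c(left, right)
}

.find_grid <- function(gp, chr, pos) {
  chr <- as.character(chr)
  if (is.null(gp[[chr]])) stop("chromosome ", chr, " not in genotype probabilities")
  which.min(abs(gp[[chr]]$pos - pos))
}

#' Variance explained by scan loci
#'
#' Regresses the 0/1 trait on expected additive dosage and a dominance
#' indicator derived from the genotype posteriors at each given locus
#' (additive = P(BB) - P(AA), dominance = P(AB)), and reports
#' 100 (1 - RSS/TSS) for each locus alone and for all loci fitted
#' jointly.  Only phenotyped individuals contribute.
#'
#' @param cross An [f2cross()].
#' @param loci A data frame (or list of `list(chr=, pos=)`) of grid loci.
#' @inheritParams scan_binary
#' @return List with `per_locus` (percent, one per locus) and `joint`
#'   (percent for the joint fit).
#' @export
variance_explained <- function(cross, loci, step = 1, eps = 1e-4, gp = NULL) {
  if (is.data.frame(loci))
    loci <- lapply(seq_len(nrow(loci)), function(i)
      list(chr = loci$chr[i], pos = loci$pos[i]))
  if (is.null(gp)) gp <- genoprob(cross, step = step, eps = eps)
  keep <- which(!is.na(cross$pheno))
  y <- cross$pheno[keep]
  X <- lapply(loci, function(lc) {
    g <- .find_grid(gp, lc$chr, lc$pos)
    q <- gp[[as.character(lc$chr)]]$prob[keep, , g]
    cbind(add = q[, 3] - q[, 1], dom = q[, 2])
  })
  pct <- function(xm) {
    fit <- stats::lm.fit(cbind(1, xm), y)
    100 * (1 - sum(fit$residuals^2) / sum((y - mean(y))^2))
  }
  list(per_locus = vapply(X, pct, numeric(1)),
       joint = pct(do.call(cbind, X)))
}

wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Two-locus genotype-class table and epistasis test
#'
#' Cross-tabulates the binary trait against the 3 x 3 genotype classes at
#' two loci (each mapped to the nearest, most completely typed marker on
#' its chromosome), with Wilson 95% confidence intervals for the
#' proportion of trait-positive (male) individuals per class.  The
#' epistasis LOD is log10 L(9 free penetrances) minus log10 L(best
#' additive+dominance model per locus with no interaction, fitted on the
#' probability scale by maximum likelihood).
#'
#' @param cross An [f2cross()].
#' @param locusA,locusB `list(chr =, pos =)` locations of the two loci.
#' @param conf Confidence level for the Wilson intervals.
#' @return An object of class `twolocus`: list with `table` (data frame
#'   `g1`, `g2`, `n`, `n_male`, `p_male`, `lo`, `hi`), `epistasis_lod`
#'   and the marker names used.
#' @export
two_locus_table <- function(cross, locusA, locusB, conf = 0.95) {
  map <- cross$map
  pick <- function(lc) {
    rows <- which(map$chr == as.character(lc$chr))
    if (!length(rows)) stop("chromosome ", lc$chr, " not on map")
    d <- abs(map$pos[rows] - lc$pos)
    cand <- rows[d < min(d) + 1e-9]
    typed <- colSums(!is.na(cross$geno[, cand, drop = FALSE]))
    cand[which.max(typed)]
  }
  iA <- pick(locusA); iB <- pick(locusB)
  gA <- cross$geno[, iA]; gB <- cross$geno[, iB]
  use <- !is.na(cross$pheno) & !is.na(gA) & !is.na(gB)
  y <- cross$pheno[use]; gA <- gA[use]; gB <- gB[use]
  cls <- expand.grid(g1 = 1:3, g2 = 1:3)
  tab <- do.call(rbind, lapply(seq_len(nrow(cls)), function(k) {
    sel <- gA == cls$g1[k] & gB == cls$g2[k]
    n <- sum(sel); nm <- sum(y[sel])
    ci <- wilson_ci(nm, n, conf)
    data.frame(g1 = c("AA", "AB", "BB")[cls$g1[k]],
               g2 = c("AA", "AB", "BB")[cls$g2[k]],
               n = n, n_male = nm,
               p_male = if (n > 0) nm / n else NA_real_,
               lo = ci[1], hi = ci[2], stringsAsFactors = FALSE)
  }))
  # epistasis: 9 free penetrances vs additive+dominance per locus
  nm <- tab$n_male; nf <- tab$n - tab$n_male
  phat <- ifelse(tab$n > 0, nm / tab$n, 0.5)
  ll_full <- sum(ifelse(nm > 0, nm * log10(phat), 0) +
                 ifelse(nf > 0, nf * log10(1 - phat), 0))
  X <- cbind(1, cls$g1 - 2, as.numeric(cls$g1 == 2),
             cls$g2 - 2, as.numeric(cls$g2 == 2))
  nll <- function(beta) {
    p <- pmin(pmax(drop(X %*% beta), PI_CLAMP[1]), PI_CLAMP[2])
    -sum(nm * log(p) + nf * log(1 - p))
  }
  nz <- tab$n > 0
  start <- stats::coef(stats::lm(phat[nz] ~ X[nz, -1], weights = tab$n[nz]))
  start[is.na(start)] <- 0
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  opt2 <- stats::optim(opt$par, nll, method = "BFGS",
                       control = list(maxit = 500))
  ll_red <- -min(opt$value, opt2$value) / log(10)
  structure(list(table = tab,
                 epistasis_lod = max(ll_full - ll_red, 0),
                 markerA = map$marker[iA], markerB = map$marker[iB]),
            class = "twolocus")
}

#' @export
print.twolocus <- function(x, ...) {
  cat("Two-locus trait table:", x$markerA, "x", x$markerB, "\n")
  print.data.frame(x$table, digits = 3)
  cat(sprintf("epistasis LOD (9 free penetrances vs additive+dominance): %.3f\n",
              x$epistasis_lod))
  invisible(x)
}
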