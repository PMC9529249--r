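# Classic four-taxon ABBA-BABA D with per-block pattern counts and
# block-resampling standard errors. The outgroup enters through
# polarization: code 0 is the ancestral ("A") state, code 1 derived ("B").

#' Count weighted ABBA/BABA patterns per block
#'
#' For single samples a site adds 1 to nABBA when the (H1, H2, H3) calls
#' are (0, 1, 1) and 1 to nBABA when they are (1, 0, 1). For groups the
#' site contributes the product-of-frequencies expectation:
#' \eqn{(1-p_1) p_2 p_3} to nABBA and \eqn{p_1 (1-p_2) p_3} to nBABA, where
#' \eqn{p_i} is the group derived-allele frequency among non-missing calls.
#' Single samples are the degenerate frequency-0/1 case of the same
#' formula. Sites where any panel is entirely missing are skipped.
#'
#' @param x a polarized \code{\link{SiteMatrix}}.
#' @param h1,h2,h3 sample names, or a group name resolved via \code{groups}.
#' @param blocks a \code{\link{BlockPartition}} over the sites of \code{x};
#'   computed at 5 Mb if omitted.
#' @param groups optional group table (columns sample, group) used to
#'   resolve group names.
#' @return A \code{\link{PatternCounts}}.
#' @export
countPatterns <- function(x, h1, h2, h3, blocks = NULL, groups = NULL) {
  if (!isPolarized(x))
    stop("countPatterns requires a polarized SiteMatrix (run polarize() first)")
  i1 <- .resolvePanel(x, h1, groups, "h1")
  i2 <- .resolvePanel(x, h2, groups, "h2")
  i3 <- .resolvePanel(x, h3, groups, "h3")
  shared <- c(intersect(i1, i2), intersect(i1, i3), intersect(i2, i3))
  if (length(shared))
    stop("H1/H2/H3 panels share sample(s): ",
         paste(unique(colnames(x)[shared]), collapse = ", "))
  if (is.null(blocks)) blocks <- assignBlocks(x)
  m <- callMatrix(x)
  p1 <- .panelFreq(m, i1)
  p2 <- .panelFreq(m, i2)
  p3 <- .panelFreq(m, i3)
  use <- !is.na(p1) & !is.na(p2) & !is.na(p3)
  abba <- (1 - p1) * p2 * p3
  baba <- p1 * (1 - p2) * p3
  counts <- .perBlock(cbind(nABBA = abba, nBABA = baba)[use, , drop = FALSE],
                      blockIds(blocks)[use], nBlocks(blocks))
  new("PatternCounts", counts = counts, nSitesUsed = sum(use),
      labels = c(h1 = paste(h1, collapse = ","),
                 h2 = paste(h2, collapse = ","),
                 h3 = paste(h3, collapse = ",")))
}

# sum site weights into a full nBlocks x 2 matrix (zero rows for blocks
# without informative sites)
.perBlock <- function(w, ids, nb) {
  out <- matrix(0, nb, 2L, dimnames = list(NULL, colnames(w)))
  if (nrow(w)) {
    s <- rowsum(w, group = ids)
    out[as.integer(rownames(s)), ] <- s
  }
  out
}

#' Point estimate of D from pattern counts
#'
#' \eqn{D = (\sum nABBA - \sum nBABA) / (\sum nABBA + \sum nBABA)} over all
#' blocks. A zero total is an explicit error, never a silent 0.
#'
#' @param counts a \code{\link{PatternCounts}}.
#' @return The D value.
#' @export
dFromCounts <- function(counts) {
  tot <- colSums(counts@counts)
  if (sum(tot) <= 0)
    stop("D is undefined: zero informative sites (nABBA + nBABA = 0)")
  unname((tot["nABBA"] - tot["nBABA"]) / (tot["nABBA"] + tot["nBABA"]))
}

#' Block-resampling standard error and Z score for a D-type statistic
#'
#' Blocks carrying zero informative mass are excluded. The jackknife is the
#' weighted delete-one-block jackknife (Busing et al. 1999) with block
#' weights equal to the block's informative pattern mass; the bootstrap
#' resamples \code{nBlocks} blocks with replacement \code{nReps} times and
#' takes the standard deviation of the replicate statistics. With a seed,
#' bootstrap replicate \code{b} draws from seed + b, so results are
#' reproducible and parallelizable.
#'
#' @param counts a \code{\link{PatternCounts}}.
#' @param method "jackknife" or "bootstrap".
#' @param nReps bootstrap replicate count (>= 2).
#' @param seed optional integer base seed; identical seed and input give
#'   bit-identical results.
#' @return A \code{\link{DStatResult}}.
#' @export
blockResample <- function(counts, method = c("jackknife", "bootstrap"),
                          nReps = 1000L, seed = NULL) {
  method <- match.arg(method)
  cm <- counts@counts
  mass <- rowSums(cm)
  cm <- cm[mass > 0, , drop = FALSE]
  nb <- nrow(cm)
  if (nb < 2L)
    stop("insufficient blocks: need >= 2 non-empty blocks for a standard error")
  A <- sum(cm[, "nABBA"]); B <- sum(cm[, "nBABA"])
  theta <- (A - B) / (A + B)
  if (method == "jackknife") {
    a <- cm[, "nABBA"]; b <- cm[, "nBABA"]
    loo <- ((A - a) - (B - b)) / ((A - a) + (B - b))
    mj <- a + b
    n <- sum(mj)
    h <- n / mj
    thetaJ <- nb * theta - sum((1 - mj / n) * loo)
    tau <- h * theta - (h - 1) * loo
    se <- sqrt(mean((tau - thetaJ)^2 / (h - 1)))
    nReps <- NA_integer_
  } else {
    if (nReps < 2L) stop("bootstrap requires nReps >= 2")
    a <- cm[, "nABBA"]; b <- cm[, "nBABA"]
    reps <- .withSeed(seed, vapply(seq_len(nReps), function(r) {
      if (!is.null(seed)) set.seed(seed + r)   # replicate r draws from seed + r
      idx <- sample.int(nb, nb, replace = TRUE)
      sa <- sum(a[idx]); sb <- sum(b[idx])
      (sa - sb) / (sa + sb)
    }, numeric(1L)))
    se <- stats::sd(reps)
  }
  z <- if (is.na(se) || se == 0) {
    warning("standard error is 0; Z is undefined")
    NA_real_
  } else theta / se
  new("DStatResult", value = theta, se = se, z = z,
      nABBA = A, nBABA = B, nBlocks = nb, nSites = counts@nSitesUsed,
      method = method,
      nReps = as.integer(if (is.na(nReps)) NA else nReps),
      seed = as.integer(if (is.null(seed)) NA else seed),
      labels = counts@labels)
}

#' Classic ABBA-BABA D with block-resampled error
#'
#' Convenience wrapper: \code{\link{countPatterns}} then
#' \code{\link{dFromCounts}}/\code{\link{blockResample}}. Positive D means
#' H2 shares more derived alleles with H3 than H1 does.
#'
#' @inheritParams countPatterns
#' @inheritParams blockResample
#' @return A \code{\link{DStatResult}}.
#' @export
dStat <- function(x, h1, h2, h3, blocks = NULL, groups = NULL,
                  method = c("jackknife", "bootstrap"),
                  nReps = 1000L, seed = NULL) {
  pc <- countPatterns(x, h1, h2, h3, blocks = blocks, groups = groups)
  dFromCounts(pc)  # errors early on zero informative sites
  blockResample(pc, method = match.arg(method), nReps = nReps, seed = seed)
}

#' Pearson correlation between two matched sets of statistic values
#'
#' Used to compare statistic batteries computed under different
#' ascertainments, references or alignments (tests matched by identity).
#'
#' @param a,b numeric vectors of equal length >= 3 (or lists of
#'   \code{DStatResult} objects, from which values are taken).
#' @return Pearson's r, or \code{NA} with a warning when either vector has
#'   zero variance.
#' @export
correlateResultSets <- function(a, b) {
  val <- function(v) {
    if (is.list(v)) vapply(v, function(r) r@value, numeric(1L)) else as.numeric(v)
  }
  a <- val(a); b <- val(b)
  if (length(a) != length(b)) stop("result sets differ in length")
  if (length(a) < 3L) stop("need at least 3 matched results")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in a result set; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}
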