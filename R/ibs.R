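# Identity-by-state distances, neighbour-joining trees with genomic-region
# pseudo-bootstrap supports, classical MDS and distance-to-outgroup QC.

#' Pairwise identity-by-state distance matrix
#'
#' d(i, j) is the proportion of mismatching calls among sites where both
#' samples are called (pairwise deletion of missing data). Optionally
#' restricted to a genomic region (1-based, fully closed) and/or filtered
#' via the \code{\link{filterSites}} parameters.
#'
#' @param x a \code{\link{SiteMatrix}} (polarization is irrelevant: the
#'   distance only compares codes).
#' @param region optional \code{c(chrom, start, end)} restriction.
#' @param transversionsOnly,dropCpG,minCalled,minMaf,whitelist forwarded to
#'   \code{\link{filterSites}}.
#' @param verbose log filter drop counts.
#' @return An \code{\link{IBSMatrix}}; pairs with zero co-called sites are
#'   \code{NA}.
#' @export
ibsMatrix <- function(x, region = NULL, transversionsOnly = FALSE,
                      dropCpG = FALSE, minCalled = 0L, minMaf = 0,
                      whitelist = NULL, verbose = FALSE) {
  if (ncol(x) < 2L) stop("need at least 2 samples")
  if (!is.null(region)) {
    stopifnot(length(region) == 3L)
    info <- siteInfo(x)
    keep <- info$chrom == as.character(region[1L]) &
      info$pos >= as.numeric(region[2L]) & info$pos <= as.numeric(region[3L])
    if (!any(keep)) stop("no sites in the requested region")
    x <- x[keep, ]
  }
  x <- filterSites(x, transversionsOnly = transversionsOnly, dropCpG = dropCpG,
                   minCalled = minCalled, minMaf = minMaf,
                   whitelist = whitelist, verbose = verbose)
  m <- callMatrix(x)
  one <- m; one[is.na(one)] <- 0L
  zero <- 1L - m; zero[is.na(zero)] <- 0L
  called <- !is.na(m)
  storage.mode(one) <- "double"
  storage.mode(zero) <- "double"
  storage.mode(called) <- "double"
  nComp <- crossprod(called)
  same <- crossprod(one) + crossprod(zero)
  d <- 1 - same / nComp            # NaN where nComp == 0
  d[nComp == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- dimnames(nComp) <- list(colnames(m), colnames(m))
  new("IBSMatrix", d = d, nCompared = nComp)
}

#' Neighbour-joining tree from an IBS matrix
#'
#' Standard Saitou-Nei agglomeration (via \code{ape::nj}); negative branch
#' lengths are clamped to zero with a warning. Optional rooting on an
#' outgroup leaf.
#'
#' @param dm an \code{\link{IBSMatrix}} (or plain symmetric matrix).
#' @param rootOn optional outgroup label to root on.
#' @return An \code{ape} \code{phylo} tree.
#' @export
njTree <- function(dm, rootOn = NULL) {
  d <- if (is(dm, "IBSMatrix")) ibsDist(dm) else as.matrix(dm)
  if (nrow(d) < 3L) stop("neighbour joining needs at least 3 labels")
  if (anyNA(d)) {
    bad <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    stop("undefined distance for pair(s): ",
         paste(sprintf("%s-%s", rownames(d)[bad[, 1L]], colnames(d)[bad[, 2L]]),
               collapse = ", "))
  }
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning(sprintf("clamped %d negative branch length(s) to 0",
                    sum(tr$edge.length < 0)))
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  if (!is.null(rootOn)) {
    if (!rootOn %in% tr$tip.label) stop("rootOn label not in tree")
    tr <- ape::root(tr, outgroup = rootOn, resolve.root = TRUE)
  }
  tr
}

#' Pseudo-bootstrap node supports from genomic regions
#'
#' Each replicate samples \code{nRegions} distinct genomic blocks without
#' replacement, recomputes the IBS matrix from their sites and rebuilds the
#' NJ tree; the support of each internal edge of the base tree (built from
#' all sites) is the percentage of replicate trees containing the same
#' bipartition, so the rooting choice cannot alter supports. Deterministic
#' under a fixed seed (replicate b draws from seed + b).
#'
#' @param x a \code{\link{SiteMatrix}} (already filtered as desired).
#' @param blocks a \code{\link{BlockPartition}}; 5 Mb blocks are computed
#'   if omitted.
#' @param nRegions blocks sampled per replicate (default 50).
#' @param nReps replicates (default 100).
#' @param seed optional integer seed.
#' @param rootOn optional outgroup label used to root the returned tree
#'   (after support computation).
#' @return The base \code{phylo} tree with percentage supports in
#'   \code{node.label}.
#' @export
nodeSupportPseudobootstrap <- function(x, blocks = NULL, nRegions = 50L,
                                       nReps = 100L, seed = NULL,
                                       rootOn = NULL) {
  if (is.null(blocks)) blocks <- assignBlocks(x)
  if (nBlocks(blocks) < nRegions)
    stop(sprintf(
      "only %d non-empty blocks but nRegions = %d; use a smaller nRegions",
      nBlocks(blocks), nRegions))
  base <- njTree(ibsMatrix(x, verbose = FALSE))
  ids <- blockIds(blocks)
  repTrees <- lapply(seq_len(nReps), function(r) {
    pick <- .withSeed(if (is.null(seed)) NULL else seed + r,
                      sample.int(nBlocks(blocks), nRegions))
    njTree(ibsMatrix(x[ids %in% pick, ], verbose = FALSE))
  })
  counts <- ape::prop.clades(base, repTrees, rooted = FALSE)
  supports <- 100 * counts / nReps
  base$node.label <- supports
  if (!is.null(rootOn)) {
    tr <- ape::root(base, outgroup = rootOn, resolve.root = TRUE,
                    edgelabel = TRUE)
    return(tr)
  }
  base
}

#' Classical (Torgerson) multidimensional scaling of an IBS matrix
#'
#' Double-centres the squared distances and embeds on the top-k eigenpairs
#' (via \code{stats::cmdscale}). Axis signs follow a fixed convention: the
#' largest-magnitude loading of each axis is positive. Negative
#' eigenvalues among the top k draw a warning (the distances are then not
#' exactly Euclidean in k dimensions).
#'
#' @param dm an \code{\link{IBSMatrix}} or symmetric matrix.
#' @param k embedding dimension (< number of samples).
#' @return A samples x k coordinate matrix with the eigenvalues in
#'   \code{attr(, "eig")}.
#' @export
classicalMDS <- function(dm, k = 2L) {
  d <- if (is(dm, "IBSMatrix")) ibsDist(dm) else as.matrix(dm)
  n <- nrow(d)
  if (k >= n) stop("k must be smaller than the number of samples")
  if (anyNA(d)) stop("MDS requires a fully defined distance matrix")
  fit <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
  if (any(fit$eig[seq_len(k)] < -1e-8))
    warning("negative eigenvalue(s) among the top k; embedding is approximate")
  pts <- fit$points
  if (ncol(pts) < k) {           # degenerate: pad zero axes
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  }
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (length(i) && pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(d)
  attr(pts, "eig") <- fit$eig
  pts
}

#' Distance-to-outgroup QC table
#'
#' High-error samples (particularly ancient, pseudo-haploid ones) inflate
#' their distance to the outgroup. Each sample's distance is compared with
#' the mean and sd of its comparison set -- the other members of its group
#' (leave-one-out); samples more than 3 sd above are flagged "high", more
#' than 3 sd below "low". Groups with fewer than 3 members yield no flag.
#'
#' @param dm an \code{\link{IBSMatrix}} including the outgroup.
#' @param outgroup the outgroup label.
#' @param groupTable data.frame with columns \code{sample}, \code{group}.
#' @return A data.frame: sample, group, distance, group mean/sd, flag.
#' @export
outgroupDistanceQC <- function(dm, outgroup, groupTable) {
  d <- ibsDist(dm)
  if (!outgroup %in% rownames(d)) stop("outgroup not in the distance matrix")
  samples <- setdiff(rownames(d), outgroup)
  gt <- groupTable[match(samples, groupTable$sample), , drop = FALSE]
  dist <- d[samples, outgroup]
  out <- data.frame(sample = samples, group = gt$group,
                    dist_to_outgroup = dist, row.names = NULL)
  # leave-one-out comparison set: peers of the same group, excluding self
  loo <- vapply(seq_len(nrow(out)), function(i) {
    peers <- out$dist_to_outgroup[out$group == out$group[i] & seq_len(nrow(out)) != i]
    if (length(peers) < 2L) c(NA_real_, NA_real_) else c(mean(peers), stats::sd(peers))
  }, numeric(2L))
  out$group_mean <- loo[1L, ]
  out$group_sd <- loo[2L, ]
  out$flag <- "ok"
  hi <- !is.na(out$group_sd) & out$group_sd > 0 &
    out$dist_to_outgroup > out$group_mean + 3 * out$group_sd
  lo <- !is.na(out$group_sd) & out$group_sd > 0 &
    out$dist_to_outgroup < out$group_mean - 3 * out$group_sd
  out$flag[hi] <- "high"
  out$flag[lo] <- "low"
  out
}
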