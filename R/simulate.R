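# Synthetic genotype matrices and mtDNA alignments with the statistical
# structure the analyses assume: population-tree drift (Balding-Nichols per
# branch), optional ghost-lineage admixture into a target population,
# pseudo-haploid sampling with per-sample missingness and per-call error.
# Every emitted site carries a ground-truth record. All randomness flows
# from the single scenario seed.

#' Define a simulation scenario
#'
#' The population tree is given as a node table: one row per node with its
#' parent (NA for the root) and the Balding-Nichols drift parameter F of
#' the branch leading to it. Allele frequencies start at the root (drawn
#' per site from \code{Uniform(rootFreqRange)}) and evolve down each branch
#' as \code{Beta(p (1-F)/F, (1-p)(1-F)/F)} (F = 0 copies the parent
#' frequency). A ghost lineage is an ordinary leaf whose frequency is mixed
#' into a target population: \code{(1 - alpha) local + alpha ghost},
#' optionally only within a genomic region (introgressed-block scenarios).
#' Pseudo-haploid sampling then draws one allele per sample and site from
#' the population frequency, flips it with \code{errorRate} and masks it
#' with \code{1 - callRate}.
#'
#' @param tree data.frame with columns \code{node}, \code{parent},
#'   \code{f}; exactly one root (parent NA), all F in [0, 1).
#' @param samplesPerPop named integer vector: leaf populations to sample.
#' @param nSites number of biallelic sites to emit.
#' @param chromLengths named numeric vector of chromosome lengths (bp);
#'   positions are uniform.
#' @param ghost optional list \code{(pop, target, alpha, region)};
#'   \code{region = c(chrom, start, end)} restricts the admixture,
#'   \code{NULL} applies it genome wide. \code{alpha} in [0, 1).
#' @param callRate scalar or per-sample-named vector in (0, 1].
#' @param errorRate per-call flip probability.
#' @param tsFraction fraction of sites whose allele pair is a transition
#'   (A/G or C/T); the rest are transversions.
#' @param cpgFraction fraction of sites flagged as CpG context.
#' @param rootFreqRange root derived-frequency prior bounds.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return A validated \code{SimScenario} (list).
#' @export
simScenario <- function(tree, samplesPerPop, nSites, chromLengths,
                        ghost = NULL, callRate = 0.9, errorRate = 0.002,
                        tsFraction = 2 / 3, cpgFraction = 0.05,
                        rootFreqRange = c(0.05, 0.95), seed = 1L) {
  stopifnot(is.data.frame(tree), all(c("node", "parent", "f") %in% names(tree)))
  if (sum(is.na(tree$parent)) != 1L) stop("tree must have exactly one root")
  if (any(tree$f < 0 | tree$f >= 1)) stop("drift parameters must lie in [0, 1)")
  if (!all(tree$parent[!is.na(tree$parent)] %in% tree$node))
    stop("tree parent(s) not defined as nodes")
  if (!all(names(samplesPerPop) %in% tree$node))
    stop("sampled population(s) absent from the tree")
  if (!is.null(ghost)) {
    stopifnot(all(c("pop", "target", "alpha") %in% names(ghost)))
    if (ghost$alpha < 0 || ghost$alpha >= 1) stop("alpha must lie in [0, 1)")
    if (!ghost$pop %in% tree$node || !ghost$target %in% tree$node)
      stop("ghost pop/target absent from the tree")
    if (ghost$alpha > 0 && nrow(tree) < 3L)
      stop("degenerate tree: admixture needs distinct populations")
  }
  if (any(callRate <= 0 | callRate > 1)) stop("call rates must lie in (0, 1]")
  stopifnot(errorRate >= 0, errorRate < 0.5, nSites >= 1,
            length(chromLengths) >= 1, !is.null(names(chromLengths)))
  structure(list(tree = tree, samplesPerPop = samplesPerPop, nSites = nSites,
                 chromLengths = chromLengths, ghost = ghost,
                 callRate = callRate, errorRate = errorRate,
                 tsFraction = tsFraction, cpgFraction = cpgFraction,
                 rootFreqRange = rootFreqRange, seed = as.integer(seed)),
            class = "SimScenario")
}

#' Simulate a pseudo-haploid genotype matrix from a scenario
#'
#' @param scn a \code{\link{simScenario}}.
#' @return A list: \code{matrix} (unpolarized \code{\link{SiteMatrix}} whose
#'   \code{ancestral} annotation is the true root allele), \code{truth}
#'   (root/derived alleles, per-population derived frequencies including
#'   the post-admixture target frequency, ghost-origin flag) and
#'   \code{groups} (sample/group/role table).
#' @export
simulateScenario <- function(scn) {
  stopifnot(inherits(scn, "SimScenario"))
  .withSeed(scn$seed, .simulateScenarioImpl(scn))
}

.simulateScenarioImpl <- function(scn) {
  n <- scn$nSites
  tree <- scn$tree

  # positions: uniform over chromosomes, then sorted
  chrom <- sample(names(scn$chromLengths), n, replace = TRUE,
                  prob = scn$chromLengths / sum(scn$chromLengths))
  pos <- floor(stats::runif(n) * scn$chromLengths[chrom]) + 1
  o <- order(chrom, pos, method = "radix")
  chrom <- chrom[o]; pos <- as.integer(pos[o])

  # frequencies down the tree
  root <- tree$node[is.na(tree$parent)]
  freq <- list()
  freq[[root]] <- stats::runif(n, scn$rootFreqRange[1L], scn$rootFreqRange[2L])
  pending <- tree[!is.na(tree$parent), , drop = FALSE]
  while (nrow(pending)) {
    ready <- pending$parent %in% names(freq)
    if (!any(ready)) stop("tree is not connected")
    for (i in which(ready)) {
      p <- freq[[pending$parent[i]]]
      f <- pending$f[i]
      child <- p
      if (f > 0) {
        inner <- p > 0 & p < 1
        child[inner] <- stats::rbeta(sum(inner),
                                     p[inner] * (1 - f) / f,
                                     (1 - p[inner]) * (1 - f) / f)
      }
      freq[[pending$node[i]]] <- child
    }
    pending <- pending[!ready, , drop = FALSE]
  }

  pops <- names(scn$samplesPerPop)
  popFreq <- vapply(pops, function(p) freq[[p]], numeric(n))

  # ghost admixture into the target population
  admixedFreq <- popFreq
  ghostOrigin <- rep(FALSE, n)
  if (!is.null(scn$ghost) && scn$ghost$alpha > 0) {
    gf <- freq[[scn$ghost$pop]]
    sel <- rep(TRUE, n)
    if (!is.null(scn$ghost$region)) {
      r <- scn$ghost$region
      sel <- chrom == as.character(r[1L]) &
        pos >= as.numeric(r[2L]) & pos <= as.numeric(r[3L])
    }
    tcol <- match(scn$ghost$target, pops)
    admixedFreq[sel, tcol] <- (1 - scn$ghost$alpha) * popFreq[sel, tcol] +
      scn$ghost$alpha * gf[sel]
    others <- setdiff(seq_along(pops), match(scn$ghost$pop, pops))
    ghostOrigin <- gf > 0 &
      rowSums(popFreq[, others, drop = FALSE] > 0) == 0
  }

  # pseudo-haploid sampling
  sampleNames <- unlist(lapply(pops, function(p)
    sprintf("%s_%d", p, seq_len(scn$samplesPerPop[[p]]))))
  samplePop <- rep(pops, times = scn$samplesPerPop[pops])
  cr <- if (length(scn$callRate) == 1L)
    stats::setNames(rep(scn$callRate, length(sampleNames)), sampleNames)
  else scn$callRate[sampleNames]
  gcall <- matrix(NA_integer_, n, length(sampleNames),
                  dimnames = list(NULL, sampleNames))
  e <- scn$errorRate
  for (j in seq_along(sampleNames)) {
    p <- admixedFreq[, match(samplePop[j], pops)]
    # a symmetric per-call flip error folds into the draw probability
    g <- stats::rbinom(n, 1L, p * (1 - e) + (1 - p) * e)
    g[stats::runif(n) > cr[j]] <- NA_integer_
    gcall[, j] <- g
  }

  # allele nucleotides: ancestral base, derived chosen as transition or
  # transversion partner at the stated fractions (integer-coded, A C G T)
  bases <- c("A", "C", "G", "T")
  ai <- sample.int(4L, n, replace = TRUE)
  isTs <- stats::runif(n) < scn$tsFraction
  tsMap <- c(3L, 4L, 1L, 2L)            # A<->G, C<->T
  tv1Map <- c(2L, 1L, 2L, 1L)           # one transversion partner
  tv2Map <- c(4L, 3L, 4L, 3L)           # the other
  tvPick <- stats::runif(n) < 0.5
  di <- ifelse(isTs, tsMap[ai], ifelse(tvPick, tv1Map[ai], tv2Map[ai]))
  anc <- bases[ai]
  der <- bases[di]
  isCpG <- stats::runif(n) < scn$cpgFraction

  # randomize which allele is written first (alleleA)
  swap <- stats::runif(n) < 0.5
  alleleA <- ifelse(swap, der, anc)
  alleleB <- ifelse(swap, anc, der)
  code <- gcall
  code[swap, ] <- 1L - code[swap, , drop = FALSE]

  sm <- SiteMatrix(code, chrom = chrom, pos = pos,
                   alleleA = alleleA, alleleB = alleleB,
                   ancestral = anc, isCpG = isCpG, polarized = FALSE)
  # SiteMatrix re-sorts identically (input already sorted), so truth rows align
  truth <- data.frame(chrom = chrom, pos = pos, rootAllele = anc,
                      derivedAllele = unname(der), ghostOrigin = ghostOrigin)
  truth <- cbind(truth, stats::setNames(as.data.frame(popFreq),
                                        paste0("freq_", pops)))
  truth$freqAdmixedTarget <- if (!is.null(scn$ghost))
    admixedFreq[, match(scn$ghost$target, pops)] else NA_real_
  groups <- data.frame(sample = sampleNames, group = samplePop, role = "none")
  list(matrix = sm, truth = truth, groups = groups)
}

#' Built-in simulation scenarios
#'
#' \describe{
#'   \item{null_panmictic}{No structure among the four ingroup populations
#'     (drift 0 below their common ancestor) plus a diverged outgroup;
#'     alpha = 0. The calibration null for D and D_ex.}
#'   \item{tur_like_ghost}{An outgroup; a wild clade holding a
#'     two-population pair (tur-like) and, sister to that pair, a severely
#'     bottlenecked ghost lineage (drift F = 0.85, so its derived alleles
#'     are essentially private and internally fixed) sampled four times; a
#'     bezoar-like population; and two domestic-like populations of which
#'     one receives alpha = 0.1 ghost admixture genome wide.}
#'   \item{introgressed_block}{Same topology, but the admixture
#'     (alpha = 0.9, a locally fixed introgressed haplotype) is confined to
#'     one 5 Mb block, for region-restricted IBS work.}
#' }
#'
#' @param name preset name.
#' @param seed scenario seed.
#' @param nSites override the preset's site count.
#' @return A \code{\link{simScenario}}.
#' @export
presetScenario <- function(name = c("null_panmictic", "tur_like_ghost",
                                    "introgressed_block"),
                           seed = 1L, nSites = NULL) {
  name <- tryCatch(match.arg(name),
                   error = function(e) stop(
                     "unknown preset; available: null_panmictic, tur_like_ghost, introgressed_block"))
  if (name == "null_panmictic") {
    tree <- data.frame(
      node   = c("root", "outgroup", "ingroup", "pop1", "pop2", "pop3", "pop4"),
      parent = c(NA, "root", "root", "ingroup", "ingroup", "ingroup", "ingroup"),
      f      = c(0, 0.5, 0, 0, 0, 0, 0))
    return(simScenario(
      tree,
      samplesPerPop = c(outgroup = 4L, pop1 = 4L, pop2 = 4L, pop3 = 4L, pop4 = 4L),
      nSites = if (is.null(nSites)) 5e5 else nSites,
      chromLengths = stats::setNames(rep(5e7, 20), paste0("chr", 1:20)),
      ghost = NULL, callRate = 0.9, errorRate = 0.002, seed = seed))
  }
  tree <- data.frame(
    node   = c("root", "outgroup", "capra", "wild", "turclade", "turpair",
               "tur_east", "tur_west", "ghost", "bezclade", "bezoar",
               "domanc", "dom_ref", "dom_target"),
    parent = c(NA, "root", "root", "capra", "wild", "turclade", "turpair",
               "turpair", "turclade", "capra", "bezclade", "bezclade",
               "domanc", "domanc"),
    f      = c(0, 0.50, 0.10, 0.05, 0.05, 0.05, 0.10, 0.10, 0.85,
               0.05, 0.08, 0.05, 0.03, 0.03))
  samples <- c(outgroup = 4L, tur_east = 2L, tur_west = 2L, ghost = 4L,
               bezoar = 4L, dom_ref = 4L, dom_target = 4L)
  if (name == "tur_like_ghost") {
    simScenario(tree, samplesPerPop = samples,
                nSites = if (is.null(nSites)) 5e5 else nSites,
                chromLengths = stats::setNames(rep(5e7, 20), paste0("chr", 1:20)),
                ghost = list(pop = "ghost", target = "dom_target", alpha = 0.10),
                callRate = 0.9, errorRate = 0.002, seed = seed)
  } else {
    simScenario(tree, samplesPerPop = samples,
                nSites = if (is.null(nSites)) 1e5 else nSites,
                chromLengths = stats::setNames(rep(2.5e7, 4), paste0("chr", 1:4)),
                ghost = list(pop = "ghost", target = "dom_target", alpha = 0.90,
                             region = c("chr1", 1, 5e6)),
                callRate = 0.9, errorRate = 0.002, seed = seed)
  }
}

#' Simulate an mtDNA alignment along a tree
#'
#' Jukes-Cantor evolution from a random root sequence: on a branch of
#' length \code{d = branch length x rate} each position differs from its
#' parent with probability \eqn{3/4 (1 - e^{-4d/3})}, replaced by a
#' uniformly chosen other base (the exact JC transition probability,
#' multiple hits included). Each leaf sequence is then N-masked at the
#' stated per-position rate.
#'
#' @param tree an \code{ape} \code{phylo} with branch lengths.
#' @param seqLength alignment length.
#' @param rate substitutions per site per unit branch length.
#' @param maskRate per-position probability of masking to 'N'.
#' @param seed integer seed.
#' @return A list: \code{alignment} (\code{DNAStringSet} over the tips) and
#'   \code{tree} (the input tree).
#' @export
simulateMtdna <- function(tree, seqLength = 16000L, rate = 1,
                          maskRate = 0.02, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            rate >= 0, maskRate >= 0, maskRate <= 1, seqLength >= 1)
  .withSeed(seed, {
    bases <- c("A", "C", "G", "T")
    nTip <- length(tree$tip.label)
    rootNode <- nTip + 1L
    seqs <- vector("list", nTip + tree$Nnode)
    seqs[[rootNode]] <- sample(bases, seqLength, replace = TRUE)
    # preorder edge traversal
    edges <- ape::reorder.phylo(tree, "cladewise")$edge
    edgeLen <- ape::reorder.phylo(tree, "cladewise")$edge.length
    for (k in seq_len(nrow(edges))) {
      parent <- edges[k, 1L]; child <- edges[k, 2L]
      d <- edgeLen[k] * rate
      pDiff <- 0.75 * (1 - exp(-4 * d / 3))
      s <- seqs[[parent]]
      hit <- which(stats::runif(seqLength) < pDiff)
      if (length(hit)) {
        shift <- sample.int(3L, length(hit), replace = TRUE)
        s[hit] <- bases[(match(s[hit], bases) - 1L + shift) %% 4L + 1L]
      }
      seqs[[child]] <- s
    }
    out <- vapply(seq_len(nTip), function(i) {
      s <- seqs[[i]]
      if (maskRate > 0) s[stats::runif(seqLength) < maskRate] <- "N"
      paste(s, collapse = "")
    }, character(1L))
    names(out) <- tree$tip.label
    list(alignment = Biostrings::DNAStringSet(out), tree = tree)
  })
}
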