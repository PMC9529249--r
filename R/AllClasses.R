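#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- rowRanges rowRanges<-
NULL

#' SiteMatrix: pseudo-haploid calls at biallelic sites
#'
#' An S4 container for a sites-by-samples matrix of pseudo-haploid genotype
#' calls, extending \linkS4class{RangedSummarizedExperiment}. The single
#' assay, \code{"calls"}, holds integer codes per site and sample: \code{0}
#' for the site's first allele (\code{alleleA}), \code{1} for the second
#' (\code{alleleB}), \code{NA} for missing. After \code{\link{polarize}},
#' code 0 is the outgroup-matching (ancestral) allele at every retained site
#' and the \code{polarized} slot is \code{TRUE}.
#'
#' Row metadata carries per-site annotation: \code{alleleA}, \code{alleleB}
#' (nucleotides; \code{alleleB} may be \code{NA} when only one allele was
#' observed), \code{ancestral} (nucleotide or \code{NA}),
#' \code{isTransversion} (\code{FALSE} iff the allele pair is A/G or C/T)
#' and \code{isCpG}. Sites are kept sorted by (chromosome, position);
#' positions are 1-based. Chromosome names are opaque strings.
#'
#' @slot polarized logical scalar; whether code 0 means "ancestral".
#'
#' @aliases SiteMatrix-class
#' @exportClass SiteMatrix
setClass("SiteMatrix",
  contains = "RangedSummarizedExperiment",
  slots = c(polarized = "logical"),
  prototype = prototype(polarized = FALSE)
)

.validSiteMatrix <- function(object) {
  msg <- character()
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'calls' is required")
  else {
    m <- SummarizedExperiment::assay(object, "calls")
    rg <- suppressWarnings(range(m, na.rm = TRUE))
    if (is.finite(rg[1L]) && (rg[1L] < 0L || rg[2L] > 1L))
      msg <- c(msg, "calls must be 0, 1 or NA")
  }
  if (length(object@polarized) != 1L || is.na(object@polarized))
    msg <- c(msg, "'polarized' must be TRUE or FALSE")
  mc <- S4Vectors::mcols(GenomicRanges::granges(SummarizedExperiment::rowRanges(object), use.mcols = TRUE))
  need <- c("alleleA", "alleleB", "ancestral", "isTransversion", "isCpG")
  if (!all(need %in% colnames(mc)))
    msg <- c(msg, paste("missing site annotation column(s):",
                        paste(setdiff(need, colnames(mc)), collapse = ", ")))
  else {
    same <- !is.na(mc$alleleA) & !is.na(mc$alleleB) & mc$alleleA == mc$alleleB
    if (any(same)) msg <- c(msg, "alleleA and alleleB must differ at every site")
  }
  if (nrow(object) > 1L) {
    # sortedness: chromosome runs must be unique and lexicographically
    # increasing, positions non-decreasing within each run
    rle <- S4Vectors::runValue(GenomicRanges::seqnames(object))
    ch <- as.character(rle)
    ps <- GenomicRanges::start(object)
    lens <- S4Vectors::runLength(GenomicRanges::seqnames(object))
    bounds <- cumsum(lens)[-length(lens)]
    unsortedPos <- {
      d <- diff(ps)
      d[bounds] <- 0L
      any(d < 0L)
    }
    if (anyDuplicated(ch) || is.unsorted(ch) || unsortedPos)
      msg <- c(msg, "sites must be sorted by (chromosome, position)")
  }
  if (nrow(object) && any(GenomicRanges::start(object) < 1L))
    msg <- c(msg, "positions must be >= 1")
  if (length(msg)) msg else TRUE
}
setValidity("SiteMatrix", .validSiteMatrix)

#' @describeIn SiteMatrix Constructor.
#' @param calls sites x samples matrix of codes in \{0, 1, NA\}; column names
#'   are sample identifiers (generated if absent).
#' @param chrom,pos chromosome name and 1-based position per site.
#' @param alleleA,alleleB the two site alleles (A/C/G/T); \code{alleleB} may
#'   be \code{NA} for sites where a second allele was never observed.
#' @param ancestral ancestral (outgroup) nucleotide per site, or \code{NA}.
#' @param isCpG logical CpG-context flag per site (recycled).
#' @param siteId optional site identifiers carried through tped round trips.
#' @param polarized whether code 0 already means "ancestral".
#' @return A \code{SiteMatrix} with sites sorted by (chromosome, position).
#' @export
SiteMatrix <- function(calls, chrom, pos, alleleA, alleleB,
                       ancestral = NA_character_, isCpG = FALSE,
                       siteId = NULL, polarized = FALSE) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  n <- nrow(calls)
  chrom <- rep_len(as.character(chrom), n)
  pos <- as.integer(pos)
  stopifnot(length(pos) == n)
  alleleA <- toupper(rep_len(as.character(alleleA), n))
  alleleB <- toupper(rep_len(as.character(alleleB), n))
  ancestral <- toupper(rep_len(as.character(ancestral), n))
  isCpG <- rep_len(as.logical(isCpG), n)
  if (is.null(siteId))
    siteId <- rep(NA_character_, n)     # generated on demand by writers
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("S", seq_len(ncol(calls)))
  o <- order(chrom, pos, method = "radix")
  gr <- GenomicRanges::GRanges(chrom[o], IRanges::IRanges(pos[o], width = 1L))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    siteId = as.character(siteId)[o],
    alleleA = alleleA[o],
    alleleB = alleleB[o],
    ancestral = ancestral[o],
    isTransversion = transversionFlag(alleleA, alleleB)[o],
    isCpG = isCpG[o]
  )
  rownames(calls) <- NULL
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls[o, , drop = FALSE]),
    rowRanges = gr
  )
  new("SiteMatrix", se, polarized = isTRUE(polarized))
}

#' Classify an allele pair as transversion
#'
#' \code{FALSE} iff the pair is \{A,G\} or \{C,T\} (a transition); \code{NA}
#' when either allele is unknown.
#' @param a,b nucleotide vectors.
#' @return logical vector.
#' @export
transversionFlag <- function(a, b) {
  lev <- c("A", "G", "C", "T")
  isPurine <- c(TRUE, TRUE, FALSE, FALSE)
  pa <- isPurine[match(toupper(as.character(a)), lev)]
  pb <- isPurine[match(toupper(as.character(b)), lev)]
  pa != pb
}

# ---- accessors ---------------------------------------------------------

#' @rdname SiteMatrix-accessors
#' @export
setGeneric("callMatrix", function(x) standardGeneric("callMatrix"))

#' Accessors for SiteMatrix
#'
#' \code{callMatrix} returns the integer call matrix (0/1/NA);
#' \code{siteInfo} the per-site annotation as a \code{DataFrame} with
#' \code{chrom} and \code{pos} columns; \code{isPolarized} the polarization
#' flag; \code{nSites} the number of sites.
#'
#' @param x a \code{SiteMatrix}.
#' @return See description.
#' @name SiteMatrix-accessors
#' @aliases callMatrix siteInfo isPolarized nSites
NULL

#' @rdname SiteMatrix-accessors
#' @export
setMethod("callMatrix", "SiteMatrix", function(x)
  SummarizedExperiment::assay(x, "calls"))

#' @rdname SiteMatrix-accessors
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))

#' @rdname SiteMatrix-accessors
#' @export
setMethod("siteInfo", "SiteMatrix", function(x) {
  gr <- SummarizedExperiment::rowRanges(x)
  cbind(S4Vectors::DataFrame(chrom = as.character(GenomicRanges::seqnames(gr)),
                             pos = GenomicRanges::start(gr)),
        S4Vectors::mcols(gr))
})

#' @rdname SiteMatrix-accessors
#' @export
setGeneric("isPolarized", function(x) standardGeneric("isPolarized"))

#' @rdname SiteMatrix-accessors
#' @export
setMethod("isPolarized", "SiteMatrix", function(x) x@polarized)

#' @rdname SiteMatrix-accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname SiteMatrix-accessors
#' @export
setMethod("nSites", "SiteMatrix", function(x) nrow(x))

setMethod("show", "SiteMatrix", function(object) {
  cat(sprintf("SiteMatrix: %d sites x %d samples (%s)\n",
              nrow(object), ncol(object),
              if (object@polarized) "polarized" else "unpolarized"))
  ch <- unique(as.character(GenomicRanges::seqnames(object)))
  cat(sprintf("  chromosomes: %s\n",
              paste(utils::head(ch, 6), collapse = ", ")))
  miss <- mean(is.na(SummarizedExperiment::assay(object, "calls")))
  cat(sprintf("  missingness: %.1f%%\n", 100 * miss))
})

# ---- BlockPartition ----------------------------------------------------

#' BlockPartition: contiguous genomic blocks for resampling
#'
#' Maps every site of a \code{\link{SiteMatrix}} to a contiguous genomic
#' block (default 5 Mb). Within a chromosome the raw block index is
#' \code{floor((pos - 1) / blockSize)}; sites on different chromosomes never
#' share a block. Only non-empty blocks carry an id; ids are consecutive
#' integers in genomic order, so they are non-decreasing within a chromosome
#' for position-sorted sites.
#'
#' @slot blockSize block size in bases.
#' @slot blockIds integer block id per site (1..nBlocks).
#' @slot blockKeys "chrom:index" key per non-empty block.
#' @exportClass BlockPartition
setClass("BlockPartition",
  slots = c(blockSize = "numeric", blockIds = "integer", blockKeys = "character"))

setValidity("BlockPartition", function(object) {
  msg <- character()
  if (length(object@blockSize) != 1L || object@blockSize <= 0)
    msg <- c(msg, "blockSize must be a single positive number")
  if (length(object@blockIds) &&
      (min(object@blockIds) < 1L || max(object@blockIds) > length(object@blockKeys)))
    msg <- c(msg, "blockIds out of range of blockKeys")
  if (length(msg)) msg else TRUE
})

#' @rdname BlockPartition-class
#' @param x a \code{BlockPartition}.
#' @export
setGeneric("nBlocks", function(x) standardGeneric("nBlocks"))

#' @rdname BlockPartition-class
#' @export
setMethod("nBlocks", "BlockPartition", function(x) length(x@blockKeys))

#' @rdname BlockPartition-class
#' @export
setGeneric("blockIds", function(x) standardGeneric("blockIds"))

#' @rdname BlockPartition-class
#' @export
setMethod("blockIds", "BlockPartition", function(x) x@blockIds)

setMethod("show", "BlockPartition", function(object) {
  cat(sprintf("BlockPartition: %d sites in %d non-empty blocks of %s bp\n",
              length(object@blockIds), length(object@blockKeys),
              format(object@blockSize, big.mark = ",", scientific = FALSE)))
})

# ---- PatternCounts -----------------------------------------------------

#' PatternCounts: per-block weighted ABBA/BABA mass
#'
#' Per-block weighted counts of the two informative site patterns feeding a
#' D-type statistic. For the classic D, columns are nABBA and nBABA; for the
#' extended D they are nABBA_ex (H2 sharing of the H3-specific derived
#' allele) and nBABA_ex (H1 sharing). Sites with missing calls in any
#' required panel contribute nothing.
#'
#' @slot counts nBlocks x 2 numeric matrix, columns \code{nABBA}, \code{nBABA}.
#' @slot nSitesUsed number of sites evaluated (all panels non-missing).
#' @slot labels named character vector describing the test (h1/h2/h3/...).
#' @exportClass PatternCounts
setClass("PatternCounts",
  slots = c(counts = "matrix", nSitesUsed = "integer", labels = "character"))

setValidity("PatternCounts", function(object) {
  msg <- character()
  if (ncol(object@counts) != 2L ||
      !identical(colnames(object@counts), c("nABBA", "nBABA")))
    msg <- c(msg, "counts must have columns nABBA, nBABA")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PatternCounts", function(object) {
  tot <- colSums(object@counts)
  cat(sprintf("PatternCounts: %d blocks, %d sites used; nABBA=%.2f nBABA=%.2f\n",
              nrow(object@counts), object@nSitesUsed, tot[1], tot[2]))
})

# ---- DStatResult -------------------------------------------------------

#' DStatResult: a D-type statistic with resampling error
#'
#' Holds a D or D_ex point estimate together with its total pattern counts,
#' block-resampling standard error and Z score. \code{Z} is \code{NA} when
#' the standard error is zero (degenerate resampling distribution).
#'
#' @slot value the statistic, in [-1, 1].
#' @slot se resampling standard error.
#' @slot z value / se (NA if se is 0).
#' @slot nABBA,nBABA total weighted pattern counts.
#' @slot nBlocks number of blocks with informative mass.
#' @slot nSites number of sites evaluated.
#' @slot method "jackknife" or "bootstrap".
#' @slot nReps bootstrap replicate count (NA for jackknife).
#' @slot seed base RNG seed (NA if none supplied).
#' @slot labels test description carried from \linkS4class{PatternCounts}.
#' @exportClass DStatResult
setClass("DStatResult",
  slots = c(value = "numeric", se = "numeric", z = "numeric",
            nABBA = "numeric", nBABA = "numeric",
            nBlocks = "integer", nSites = "integer",
            method = "character", nReps = "integer", seed = "integer",
            labels = "character"))

setValidity("DStatResult", function(object) {
  msg <- character()
  if (!is.na(object@value) && abs(object@value) > 1 + 1e-12)
    msg <- c(msg, "|value| must be <= 1")
  if (!object@method %in% c("jackknife", "bootstrap"))
    msg <- c(msg, "method must be 'jackknife' or 'bootstrap'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DStatResult", function(object) {
  cat(sprintf("DStatResult (%s): D = %.4f, se = %.4g, Z = %s\n",
              object@method, object@value, object@se,
              if (is.na(object@z)) "NA" else sprintf("%.2f", object@z)))
  cat(sprintf("  nABBA = %.2f, nBABA = %.2f, %d sites, %d blocks\n",
              object@nABBA, object@nBABA, object@nSites, object@nBlocks))
  if (length(object@labels))
    cat("  test:", paste(names(object@labels), object@labels,
                         sep = "=", collapse = " "), "\n")
})

#' @describeIn DStatResult Flatten to a one-row data.frame
#'   (h-labels, counts, value, se, Z, n_sites, n_blocks).
#' @param x a \code{DStatResult}.
#' @param row.names,optional,... ignored; present for generic consistency.
#' @export
setMethod("as.data.frame", "DStatResult",
  function(x, row.names = NULL, optional = FALSE, ...) {
    lab <- as.list(x@labels)
    data.frame(c(lab, list(
      nABBA = x@nABBA, nBABA = x@nBABA, D = x@value, se = x@se, Z = x@z,
      n_sites = x@nSites, n_blocks = x@nBlocks, method = x@method)),
      stringsAsFactors = FALSE)
  })

# ---- DexAscertainment --------------------------------------------------

#' DexAscertainment: sites carrying an H3-specific derived allele
#'
#' The result of \code{\link{ascertainDexSites}}: the set of polarized sites
#' where the H3 lineage carries the derived allele while a series of
#' conditioning "outgroup" panels (and always the root-outgroup panel) are
#' fixed ancestral (strict mode) or carry it only at low frequency
#' (window mode).
#'
#' @slot mode "strict" or "window".
#' @slot window numeric(2), the (low, high] derived-frequency window.
#' @slot retained integer indices of retained sites in the source matrix.
#' @slot h3 sample names of the H3 panel.
#' @slot conditioning named list of conditioning-panel sample names.
#' @slot rootFixed sample names of the always-ancestral-fixed panel.
#' @slot h3Rule "fixed" (all non-missing H3 calls derived) or "any".
#' @slot nEvaluated number of sites in the source matrix.
#' @exportClass DexAscertainment
setClass("DexAscertainment",
  slots = c(mode = "character", window = "numeric", retained = "integer",
            h3 = "character", conditioning = "list", rootFixed = "character",
            h3Rule = "character", nEvaluated = "integer"))

setMethod("show", "DexAscertainment", function(object) {
  cat(sprintf("DexAscertainment (%s%s): %d / %d sites retained\n",
              object@mode,
              if (object@mode == "window")
                sprintf(", (%g, %g]", object@window[1], object@window[2]) else "",
              length(object@retained), object@nEvaluated))
  cat(sprintf("  H3 = {%s} [%s]; %d conditioning group(s); root-fixed = {%s}\n",
              paste(object@h3, collapse = ","), object@h3Rule,
              length(object@conditioning),
              paste(object@rootFixed, collapse = ",")))
})

# ---- IBSMatrix ---------------------------------------------------------

#' IBSMatrix: pairwise identity-by-state distances
#'
#' Symmetric matrix of pairwise mismatch proportions among co-called sites
#' (1 - IBS), with the per-pair co-called site counts. Entries for pairs
#' with zero co-called sites are \code{NA}.
#'
#' @slot d symmetric distance matrix in [0, 1], labelled.
#' @slot nCompared symmetric matrix of co-called site counts.
#' @exportClass IBSMatrix
setClass("IBSMatrix", slots = c(d = "matrix", nCompared = "matrix"))

setValidity("IBSMatrix", function(object) {
  msg <- character()
  d <- object@d
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    msg <- c(msg, "d must have matching row/col labels")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12, check.attributes = FALSE)))
    msg <- c(msg, "d must be symmetric")
  if (any(diag(d) != 0, na.rm = TRUE)) msg <- c(msg, "diagonal must be 0")
  off <- d[upper.tri(d)]
  if (any(off < -1e-12 | off > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "distances must lie in [0, 1]")
  if (!identical(dim(object@nCompared), dim(d)))
    msg <- c(msg, "nCompared must match d in shape")
  if (length(msg)) msg else TRUE
})

#' @rdname IBSMatrix-class
#' @param x an \code{IBSMatrix}.
#' @export
setGeneric("ibsDist", function(x) standardGeneric("ibsDist"))

#' @rdname IBSMatrix-class
#' @export
setMethod("ibsDist", "IBSMatrix", function(x) x@d)

#' @rdname IBSMatrix-class
#' @export
setGeneric("nCompared", function(x) standardGeneric("nCompared"))

#' @rdname IBSMatrix-class
#' @export
setMethod("nCompared", "IBSMatrix", function(x) x@nCompared)

setMethod("show", "IBSMatrix", function(object) {
  n <- nrow(object@d)
  cat(sprintf("IBSMatrix: %d samples; mean pairwise distance %.4g\n",
              n, mean(object@d[upper.tri(object@d)], na.rm = TRUE)))
  undef <- sum(is.na(object@d[upper.tri(object@d)]))
  if (undef) cat(sprintf("  %d undefined pair(s) (no co-called sites)\n", undef))
})
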