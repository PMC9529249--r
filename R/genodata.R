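# Polarization, site filtering and block partitioning of SiteMatrix objects.

#' Polarize a SiteMatrix against an ancestral-allele track
#'
#' Recodes calls so that code 0 is the ancestral (outgroup-matching) allele
#' and code 1 the derived allele. Sites whose ancestral nucleotide is
#' unknown or matches neither site allele are dropped; the drop count is
#' reported and attached as \code{attr(, "dropped")}. Polarizing an already
#' polarized matrix is a no-op on retained sites (idempotent).
#'
#' @param x a \code{\link{SiteMatrix}}.
#' @param ancestral optional per-site nucleotide vector (in the site order
#'   of \code{x}); defaults to the \code{ancestral} site annotation.
#' @param verbose report the number of dropped sites.
#' @return A polarized \code{SiteMatrix} containing the retained sites.
#' @export
polarize <- function(x, ancestral = NULL, verbose = TRUE) {
  info <- siteInfo(x)
  if (is.null(ancestral)) {
    ancestral <- info$ancestral
  } else if (length(ancestral) != nrow(x)) {
    stop(sprintf("ancestral track has length %d but matrix has %d sites",
                 length(ancestral), nrow(x)))
  }
  anc <- toupper(as.character(ancestral))
  anc[!anc %in% c("A", "C", "G", "T")] <- NA_character_
  matchA <- !is.na(anc) & !is.na(info$alleleA) & anc == info$alleleA
  matchB <- !is.na(anc) & !is.na(info$alleleB) & anc == info$alleleB
  keep <- matchA | matchB
  dropped <- sum(!keep)
  if (verbose && dropped)
    message(sprintf("polarize: dropped %d site(s) with unknown or mismatching ancestral state",
                    dropped))
  y <- x[keep, ]
  m <- callMatrix(y)
  swap <- matchB[keep]
  if (any(swap)) {
    m[swap, ] <- 1L - m[swap, , drop = FALSE]
    gr <- SummarizedExperiment::rowRanges(y)
    mc <- S4Vectors::mcols(gr)
    a <- mc$alleleA[swap]
    mc$alleleA[swap] <- mc$alleleB[swap]
    mc$alleleB[swap] <- a
    S4Vectors::mcols(gr) <- mc
    SummarizedExperiment::rowRanges(y) <- gr
    SummarizedExperiment::assay(y, "calls") <- m
  }
  gr <- SummarizedExperiment::rowRanges(y)
  S4Vectors::mcols(gr)$ancestral <- anc[keep]
  SummarizedExperiment::rowRanges(y) <- gr
  y@polarized <- TRUE
  validObject(y)
  attr(y, "dropped") <- dropped
  y
}

#' Filter sites of a SiteMatrix
#'
#' Applies the enabled filters in a fixed order -- whitelist, CpG removal,
#' transversion-only, minimum call count, minimum minor-allele frequency --
#' reporting the number of sites dropped by each. The minor-allele
#' frequency of a pseudo-haploid site is computed from the non-missing
#' haploid calls (each sample contributes a single allele).
#'
#' @param x a \code{\link{SiteMatrix}}.
#' @param transversionsOnly drop transition (A/G, C/T) sites; sites whose
#'   second allele is unknown are also dropped (their class is undecidable).
#' @param dropCpG drop sites flagged as CpG context.
#' @param minCalled minimum number of non-missing calls per site.
#' @param minMaf minimum minor-allele frequency in [0, 0.5]; sites with no
#'   non-missing call are dropped when this filter is enabled.
#' @param whitelist optional data.frame with columns \code{chrom} and
#'   \code{pos}; only sites present in it are retained.
#' @param verbose log per-filter drop counts.
#' @return The filtered \code{SiteMatrix}; errors if no site survives.
#' @export
filterSites <- function(x, transversionsOnly = FALSE, dropCpG = FALSE,
                        minCalled = 0L, minMaf = 0, whitelist = NULL,
                        verbose = TRUE) {
  stopifnot(minMaf >= 0, minMaf <= 0.5, minCalled >= 0)
  note <- function(stage, before, after) {
    if (verbose && before != after)
      message(sprintf("filterSites: %s removed %d site(s)", stage, before - after))
  }
  keep <- rep(TRUE, nrow(x))
  info <- siteInfo(x)
  if (!is.null(whitelist)) {
    n0 <- sum(keep)
    keep <- keep & paste(info$chrom, info$pos) %in%
      paste(whitelist$chrom, whitelist$pos)
    note("whitelist", n0, sum(keep))
  }
  if (dropCpG) {
    n0 <- sum(keep)
    keep <- keep & !(info$isCpG %in% TRUE)
    note("CpG removal", n0, sum(keep))
  }
  if (transversionsOnly) {
    n0 <- sum(keep)
    keep <- keep & (info$isTransversion %in% TRUE)
    note("transversion-only", n0, sum(keep))
  }
  m <- callMatrix(x)
  if (minCalled > 0L) {
    n0 <- sum(keep)
    keep <- keep & rowSums(!is.na(m)) >= minCalled
    note("min-called", n0, sum(keep))
  }
  if (minMaf > 0) {
    n0 <- sum(keep)
    f <- rowMeans(m, na.rm = TRUE)          # allele-B (derived if polarized)
    maf <- pmin(f, 1 - f)
    keep <- keep & !is.na(maf) & maf >= minMaf
    note("min-MAF", n0, sum(keep))
  }
  if (!any(keep))
    stop("all sites removed by filtering; review the thresholds")
  x[keep, ]
}

#' Partition sites into contiguous genomic blocks
#'
#' Assigns each site to a block of \code{blockSize} bases: within a
#' chromosome the raw index is \code{floor((pos - 1) / blockSize)}, and
#' sites on different chromosomes never share a block. Only non-empty
#' blocks receive an id.
#'
#' @param x a \code{\link{SiteMatrix}} (sites position-sorted, as enforced
#'   by the class).
#' @param blockSize block size in bases (default 5 Mb).
#' @return A \code{\link{BlockPartition}}.
#' @export
assignBlocks <- function(x, blockSize = 5e6) {
  if (length(blockSize) != 1L || !is.finite(blockSize) || blockSize <= 0)
    stop("blockSize must be a single positive number")
  info <- siteInfo(x)
  key <- paste(info$chrom, (info$pos - 1L) %/% blockSize, sep = ":")
  keys <- unique(key)
  new("BlockPartition", blockSize = as.numeric(blockSize),
      blockIds = match(key, keys), blockKeys = keys)
}

#' Flag CpG-context sites from a reference sequence
#'
#' Helper for building the CpG annotation when it is not provided upstream:
#' a site is flagged when its reference dinucleotide context (site plus next
#' base, or previous base plus site) is CG.
#'
#' @param x a \code{\link{SiteMatrix}}.
#' @param reference a named list/\code{DNAStringSet} of chromosome sequences.
#' @return \code{x} with the \code{isCpG} annotation replaced.
#' @export
flagCpG <- function(x, reference) {
  info <- siteInfo(x)
  seqs <- lapply(reference, function(s) strsplit(toupper(as.character(s)), "")[[1L]])
  isCpG <- vapply(seq_len(nrow(x)), function(i) {
    s <- seqs[[info$chrom[i]]]
    p <- info$pos[i]
    if (is.null(s) || p > length(s)) return(NA)
    nxt <- if (p < length(s)) s[p + 1L] else NA_character_
    prv <- if (p > 1L) s[p - 1L] else NA_character_
    isTRUE(s[p] == "C" && nxt == "G") || isTRUE(prv == "C" && s[p] == "G")
  }, logical(1L))
  gr <- SummarizedExperiment::rowRanges(x)
  S4Vectors::mcols(gr)$isCpG <- isCpG
  SummarizedExperiment::rowRanges(x) <- gr
  x
}

# ---- shared helpers ----------------------------------------------------

# Resolve a test-side specification (sample names or one group name) to
# column indices of the call matrix.
.resolvePanel <- function(x, who, groups = NULL, what = "panel") {
  sn <- colnames(x)
  who <- as.character(who)
  if (length(who) == 0L) stop(sprintf("empty %s", what))
  if (all(who %in% sn)) return(match(who, sn))
  if (!is.null(groups) && length(who) == 1L && who %in% groups$group) {
    members <- groups$sample[groups$group == who]
    missing <- setdiff(members, sn)
    if (length(missing))
      stop(sprintf("group '%s' lists sample(s) absent from the matrix: %s",
                   who, paste(missing, collapse = ", ")))
    return(match(members, sn))
  }
  stop(sprintf("cannot resolve %s '%s' to samples or a known group",
               what, paste(who, collapse = ",")))
}

# Per-site derived(allele-B)-frequency of a panel; NaN where the panel has
# no non-missing call.
.panelFreq <- function(m, idx) {
  if (length(idx) == 1L) as.numeric(m[, idx]) else
    rowMeans(m[, idx, drop = FALSE], na.rm = TRUE)
}

# Evaluate expr with a deterministic, restored RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}
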