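# N-masked pairwise difference counts on aligned mtDNA consensus sequences
# and within-group summaries.

#' Read an aligned mtDNA FASTA
#'
#' All sequences must have equal length (it is an alignment) and unique
#' names.
#'
#' @param path FASTA file.
#' @return A \code{Biostrings} \code{DNAStringSet}.
#' @export
readMtAlignment <- function(path) {
  aln <- Biostrings::readDNAStringSet(path)
  if (length(unique(Biostrings::width(aln))) > 1L)
    stop("sequences differ in length; input must be a multiple alignment")
  if (anyDuplicated(names(aln))) stop("duplicate sequence names")
  aln
}

#' N-masked pairwise differences between two aligned sequences
#'
#' Positions where either sequence is missing data ('N', and by default
#' also the gap character '-') are excluded from the comparison; the
#' difference count is the number of remaining positions with unequal
#' bases.
#'
#' @param a,b aligned sequences (character strings or
#'   \code{DNAString}-like); equal length required.
#' @param ignoreGaps treat '-' as missing (default TRUE).
#' @return Named numeric vector \code{c(diffs, compared)}.
#' @export
pairwiseDifferences <- function(a, b, ignoreGaps = TRUE) {
  ca <- .seqChars(a)
  cb <- .seqChars(b)
  if (length(ca) != length(cb))
    stop(sprintf("sequence lengths differ (%d vs %d)", length(ca), length(cb)))
  missing <- c("N", if (ignoreGaps) "-")
  cmp <- !(ca %in% missing) & !(cb %in% missing)
  c(diffs = sum(ca[cmp] != cb[cmp]), compared = sum(cmp))
}

.seqChars <- function(s) {
  if (is.character(s) && length(s) > 1L) return(toupper(s))
  strsplit(toupper(as.character(s)), "")[[1L]]
}

#' Within-group mean pairwise differences
#'
#' For each group (after removing excluded samples) computes the mean over
#' all unordered within-group pairs of the raw N-masked difference counts
#' (counts, not per-site rates). Pairs with zero comparable positions are
#' reported as NA. Groups left with fewer than 2 members are skipped with a
#' warning.
#'
#' @param aln a \code{DNAStringSet} alignment (see
#'   \code{\link{readMtAlignment}}).
#' @param groups data.frame with columns \code{sample}, \code{group}, or a
#'   named list of sample-name vectors.
#' @param exclusions sample names to drop before pairing (e.g. sequences
#'   called at lower stringency).
#' @param ignoreGaps treat '-' as missing.
#' @return A list: \code{summary} (group, n_pairs, mean_diffs) and
#'   \code{pairs} (per-pair counts and compared-site totals).
#' @export
groupMeanDifferences <- function(aln, groups, exclusions = character(),
                                 ignoreGaps = TRUE) {
  if (is.data.frame(groups))
    groups <- split(groups$sample, groups$group)
  chars <- lapply(as.character(aln), function(s) .seqChars(s))
  pairRows <- list()
  sumRows <- list()
  for (g in names(groups)) {
    members <- setdiff(intersect(groups[[g]], names(aln)), exclusions)
    if (length(members) < 2L) {
      warning(sprintf("group '%s' has fewer than 2 usable sequences; skipped", g))
      next
    }
    pr <- utils::combn(members, 2L)
    res <- apply(pr, 2L, function(p) {
      pd <- pairwiseDifferences(chars[[p[1L]]], chars[[p[2L]]],
                                ignoreGaps = ignoreGaps)
      if (pd["compared"] == 0L) pd["diffs"] <- NA_real_
      pd
    })
    pairRows[[g]] <- data.frame(group = g, sample1 = pr[1L, ], sample2 = pr[2L, ],
                                diffs = res["diffs", ], compared = res["compared", ],
                                row.names = NULL)
    sumRows[[g]] <- data.frame(group = g, n_pairs = ncol(pr),
                               mean_diffs = mean(res["diffs", ]),
                               row.names = NULL)
  }
  list(summary = do.call(rbind, c(sumRows, list(make.row.names = FALSE))),
       pairs = do.call(rbind, c(pairRows, list(make.row.names = FALSE))))
}
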