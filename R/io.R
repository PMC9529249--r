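# Readers and writers for the plain-text interchange formats: PLINK
# transposed text (.tped/.tfam) as emitted by haploid callers, a per-site
# annotation TSV, a group-assignment TSV and the square IBS matrix layout.
# All writers emit tab-separated text with header lines beginning '#'.

.MISSING_TOKENS <- c("0", "N")

#' Read a pseudo-haploid PLINK transposed-text fileset
#'
#' Parses a \code{.tped}/\code{.tfam} pair in the dialect produced by
#' haploid callers: each sample carries two identical allele tokens per site
#' (a haploid call written as a homozygous diploid genotype). Identical
#' tokens collapse to that allele; \code{"0 0"} and \code{"N N"} are
#' missing; discordant non-missing token pairs are a hard error naming the
#' site and sample. Site alleles are inferred from the observed non-missing
#' tokens; sites presenting more than two distinct alleles are rejected with
#' a warning.
#'
#' @param tpedPath path to the .tped file (4 leading columns: chrom, site
#'   id, genetic position, bp position; then two tokens per sample).
#' @param tfamPath path to the .tfam file; sample ids are taken from its
#'   second column, in tped column order.
#' @return An unpolarized \code{\link{SiteMatrix}}.
#' @export
readTped <- function(tpedPath, tfamPath) {
  tfam <- data.table::fread(tfamPath, header = FALSE, colClasses = "character",
                            data.table = FALSE)
  samples <- tfam[[min(2L, ncol(tfam))]]
  tp <- data.table::fread(tpedPath, header = FALSE, colClasses = "character",
                          data.table = FALSE)
  if (ncol(tp) != 4L + 2L * length(samples))
    stop(sprintf(
      "tped has %d genotype columns but tfam lists %d samples (expected %d columns)",
      ncol(tp) - 4L, length(samples), 4L + 2L * length(samples)))
  chrom <- tp[[1L]]
  siteId <- tp[[2L]]
  pos <- as.integer(tp[[4L]])
  tokA <- toupper(as.matrix(tp[, seq(5L, ncol(tp), by = 2L), drop = FALSE]))
  tokB <- toupper(as.matrix(tp[, seq(6L, ncol(tp), by = 2L), drop = FALSE]))
  dimnames(tokA) <- dimnames(tokB) <- NULL

  ok <- tokA %in% c(.MISSING_TOKENS, "A", "C", "G", "T") &
        tokB %in% c(.MISSING_TOKENS, "A", "C", "G", "T")
  if (!all(ok))
    stop("unrecognized allele token(s) in tped (expected A/C/G/T/0/N)")
  missA <- matrix(tokA %in% .MISSING_TOKENS, nrow(tokA))
  missB <- matrix(tokB %in% .MISSING_TOKENS, nrow(tokB))
  miss <- missA & missB
  discord <- !miss & (tokA != tokB | missA != missB)
  if (any(discord)) {
    w <- which(discord, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "discordant token pair '%s %s' at site %s for sample %s: not a duplicated haploid call",
      tokA[w[1L], w[2L]], tokB[w[1L], w[2L]], siteId[w[1L]], samples[w[2L]]))
  }
  tok <- tokA
  tok[miss] <- NA_character_

  # per-site allele inventory
  present <- sapply(c("A", "C", "G", "T"), function(b)
    rowSums(tok == b, na.rm = TRUE) > 0L)
  if (nrow(tokA) == 1L) present <- matrix(present, nrow = 1L,
                                          dimnames = list(NULL, c("A", "C", "G", "T")))
  nAlleles <- rowSums(present)
  multi <- nAlleles > 2L
  if (any(multi)) {
    warning(sprintf("rejected %d site(s) with >2 observed alleles: %s",
                    sum(multi),
                    paste(utils::head(siteId[multi], 5L), collapse = ", ")))
  }
  keep <- !multi
  tok <- tok[keep, , drop = FALSE]
  present <- present[keep, , drop = FALSE]
  bases <- c("A", "C", "G", "T")
  firstAllele <- bases[apply(present, 1L, function(p) which(p)[1L])]
  secondAllele <- vapply(seq_len(nrow(present)), function(i) {
    w <- which(present[i, ])
    if (length(w) >= 2L) bases[w[2L]] else NA_character_
  }, character(1L))

  callCode <- matrix(NA_integer_, nrow(tok), ncol(tok))
  callCode[which(tok == rep(firstAllele, ncol(tok)))] <- 0L
  callCode[which(tok == rep(secondAllele, ncol(tok)))] <- 1L
  colnames(callCode) <- samples

  SiteMatrix(callCode, chrom = chrom[keep], pos = pos[keep],
             alleleA = firstAllele, alleleB = secondAllele,
             siteId = siteId[keep], polarized = FALSE)
}

#' Write a SiteMatrix as PLINK transposed text
#'
#' Inverse of \code{\link{readTped}}: each call is written as a duplicated
#' allele token, missing as \code{"0 0"}.
#'
#' @param x a \code{SiteMatrix}.
#' @param prefix output path prefix; writes \code{<prefix>.tped} and
#'   \code{<prefix>.tfam}.
#' @return Invisibly, the two paths written.
#' @export
writeTped <- function(x, prefix) {
  info <- siteInfo(x)
  if (anyNA(info$siteId))
    info$siteId <- paste(info$chrom, info$pos, sep = "_")
  m <- callMatrix(x)
  tokens <- matrix("0", nrow(m), ncol(m))
  i0 <- which(m == 0L)
  i1 <- which(m == 1L)
  tokens[i0] <- rep(info$alleleA, ncol(m))[i0]
  tokens[i1] <- rep(info$alleleB, ncol(m))[i1]
  geno <- matrix(paste(tokens, tokens), nrow(m), ncol(m))
  lines <- paste(info$chrom, info$siteId, 0L, info$pos,
                 apply(geno, 1L, paste, collapse = " "))
  tped <- paste0(prefix, ".tped")
  tfam <- paste0(prefix, ".tfam")
  writeLines(lines, tped)
  writeLines(paste(colnames(m), colnames(m), 0L, 0L, 0L, -9L), tfam)
  invisible(c(tped = tped, tfam = tfam))
}

#' Read / write a per-site annotation table
#'
#' Tab-separated with a '#'-prefixed header: columns \code{chrom},
#' \code{pos}, \code{allele_a}, \code{allele_b}, \code{ancestral},
#' \code{is_cpg}.
#'
#' @param path file path.
#' @return \code{readSiteInfo}: a data.frame.
#' @export
readSiteInfo <- function(path) {
  first <- readLines(path, n = 1L)
  cn <- strsplit(sub("^#\\s*", "", first), "\t")[[1L]]
  df <- data.table::fread(path, header = FALSE, skip = 1L, sep = "\t",
                          data.table = FALSE)
  names(df) <- cn
  df$pos <- as.integer(df$pos)
  if ("is_cpg" %in% names(df)) df$is_cpg <- as.logical(df$is_cpg)
  df
}

#' @rdname readSiteInfo
#' @param x a \code{SiteMatrix}.
#' @export
writeSiteInfo <- function(x, path) {
  info <- siteInfo(x)
  df <- data.frame(chrom = info$chrom, pos = info$pos,
                   allele_a = info$alleleA, allele_b = info$alleleB,
                   ancestral = info$ancestral, is_cpg = info$isCpG)
  .writeTsv(df, path)
  invisible(path)
}

#' Apply a site-annotation table to a SiteMatrix
#'
#' Joins on (chrom, pos) and fills the \code{ancestral} and \code{isCpG}
#' annotations (and \code{alleleB} where it was unobserved); the
#' transversion flag is recomputed. Sites absent from the table keep their
#' current annotation.
#'
#' @param x a \code{SiteMatrix}.
#' @param info data.frame as returned by \code{\link{readSiteInfo}}.
#' @return The annotated \code{SiteMatrix}.
#' @export
annotateSites <- function(x, info) {
  gr <- SummarizedExperiment::rowRanges(x)
  key <- paste(as.character(GenomicRanges::seqnames(gr)), GenomicRanges::start(gr))
  idx <- match(key, paste(info$chrom, info$pos))
  hit <- !is.na(idx)
  mc <- S4Vectors::mcols(gr)
  if ("ancestral" %in% names(info))
    mc$ancestral[hit] <- toupper(info$ancestral[idx[hit]])
  if ("is_cpg" %in% names(info))
    mc$isCpG[hit] <- as.logical(info$is_cpg[idx[hit]])
  if ("allele_b" %in% names(info)) {
    fill <- hit & is.na(mc$alleleB)
    mc$alleleB[fill] <- toupper(info$allele_b[idx[fill]])
  }
  mc$isTransversion <- transversionFlag(mc$alleleA, mc$alleleB)
  S4Vectors::mcols(gr) <- mc
  SummarizedExperiment::rowRanges(x) <- gr
  validObject(x)
  x
}

#' Read / write a group-assignment table
#'
#' Tab-separated, '#'-prefixed header, columns \code{sample}, \code{group},
#' \code{role}. Roles are one of H1, H2, H3, conditioning, root_outgroup,
#' none.
#'
#' @param path file path.
#' @return \code{readGroups}: a data.frame with columns sample, group, role.
#' @export
readGroups <- function(path) {
  df <- data.table::fread(path, header = FALSE, skip = 1L, sep = "\t",
                          data.table = FALSE)
  names(df) <- c("sample", "group", "role")[seq_len(ncol(df))]
  if (!"role" %in% names(df)) df$role <- "none"
  bad <- setdiff(unique(df$role),
                 c("H1", "H2", "H3", "conditioning", "root_outgroup", "none"))
  if (length(bad))
    stop("unknown role(s) in group table: ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$sample))
    stop("sample(s) listed more than once in group table: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  df
}

#' @rdname readGroups
#' @param groups data.frame with columns sample, group and optionally role.
#' @export
writeGroups <- function(groups, path) {
  if (!"role" %in% names(groups)) groups$role <- "none"
  .writeTsv(groups[, c("sample", "group", "role")], path)
  invisible(path)
}

#' Write an IBS distance matrix
#'
#' \code{labeled = FALSE} mirrors the bare square ".ibsMat" layout: no
#' header, tab-separated, row order equal to sample order. The labeled
#' variant prepends a '#' header of sample names and a leading label column.
#'
#' @param dm an \code{\link{IBSMatrix}}.
#' @param path output path.
#' @param labeled write the labeled variant.
#' @export
writeIbsMat <- function(dm, path, labeled = FALSE) {
  d <- ibsDist(dm)
  if (labeled) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#sample\t", paste(colnames(d), collapse = "\t")), con)
    utils::write.table(cbind(rownames(d), format(d, trim = TRUE)), con,
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# shared TSV writer: '#' header line then tab-separated rows
.writeTsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
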