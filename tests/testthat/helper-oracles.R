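# Fixture builders and independent per-site loop oracles. The oracles are
# deliberately naive (explicit loops over sites and pairs) so they cannot
# share code paths with the vectorized implementations they check.

# A random polarized SiteMatrix built directly through the constructor.
# Every site is guaranteed biallelic-observed (at least one 0 and one 1).
makeRandomSiteMatrix <- function(nSitesTotal = 200L, nSamples = 8L, seed = 1L,
                                 missingRate = 0.15, nChrom = 2L,
                                 chromLen = 1e7, polarized = TRUE) {
  set.seed(seed)
  calls <- matrix(NA_integer_, nSitesTotal, nSamples)
  for (i in seq_len(nSitesTotal)) {
    repeat {
      v <- stats::rbinom(nSamples, 1L, stats::runif(1, 0.1, 0.9))
      v[stats::runif(nSamples) < missingRate] <- NA_integer_
      if (any(v == 0L, na.rm = TRUE) && any(v == 1L, na.rm = TRUE)) break
    }
    calls[i, ] <- v
  }
  colnames(calls) <- paste0("s", seq_len(nSamples))
  chrom <- sample(paste0("chr", seq_len(nChrom)), nSitesTotal, replace = TRUE)
  pos <- sample.int(chromLen, nSitesTotal, replace = TRUE)
  pairs <- list(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"),
                c("A", "T"), c("C", "G"))
  al <- pairs[sample.int(6L, nSitesTotal, replace = TRUE)]
  a <- vapply(al, `[`, "", 1L)
  b <- vapply(al, `[`, "", 2L)
  SiteMatrix(calls, chrom = chrom, pos = pos, alleleA = a, alleleB = b,
             ancestral = if (polarized) a else NA_character_,
             isCpG = stats::runif(nSitesTotal) < 0.2, polarized = polarized)
}

oracleFreq <- function(m, idx) {
  v <- m[, idx, drop = FALSE]
  out <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    x <- v[i, ][!is.na(v[i, ])]
    out[i] <- if (length(x)) sum(x) / length(x) else NA_real_
  }
  out
}

# per-site loop oracle for ABBA/BABA totals
oracleCountPatterns <- function(m, i1, i2, i3) {
  nABBA <- 0; nBABA <- 0; used <- 0L
  for (i in seq_len(nrow(m))) {
    p <- vapply(list(i1, i2, i3), function(ii) {
      x <- m[i, ii]
      x <- x[!is.na(x)]
      if (length(x)) mean(x) else NA_real_
    }, numeric(1L))
    if (anyNA(p)) next
    used <- used + 1L
    nABBA <- nABBA + (1 - p[1]) * p[2] * p[3]
    nBABA <- nBABA + p[1] * (1 - p[2]) * p[3]
  }
  list(nABBA = nABBA, nBABA = nBABA, used = used)
}

# per-site loop oracle for the D_ex strict/window ascertainment
oracleAscertain <- function(m, i3, condList, iRoot, mode = "strict",
                            window = c(0, 0.10), h3Rule = "fixed") {
  keep <- integer()
  for (i in seq_len(nrow(m))) {
    f <- function(ii) {
      x <- m[i, ii]
      x <- x[!is.na(x)]
      if (length(x)) mean(x) else NA_real_
    }
    f3 <- f(i3)
    h3ok <- if (h3Rule == "fixed") !is.na(f3) && f3 == 1 else !is.na(f3) && f3 > 0
    if (!h3ok) next
    fr <- f(iRoot)
    if (is.na(fr) || fr != 0) next
    fc <- vapply(condList, f, numeric(1L))
    if (anyNA(fc)) next
    if (mode == "strict") {
      if (all(fc == 0)) keep <- c(keep, i)
    } else {
      if (any(fc > window[1] & fc <= window[2])) keep <- c(keep, i)
    }
  }
  keep
}

# per-pair loop oracle for the IBS distance
oracleIBS <- function(m) {
  n <- ncol(m)
  d <- matrix(NA_real_, n, n, dimnames = list(colnames(m), colnames(m)))
  nc <- matrix(0, n, n, dimnames = dimnames(d))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    both <- !is.na(m[, i]) & !is.na(m[, j])
    nc[i, j] <- sum(both)
    if (any(both)) d[i, j] <- mean(m[both, i] != m[both, j])
  }
  diag(d) <- 0
  list(d = d, n = nc)
}

# textbook Pearson correlation
oraclePearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# a tiny hand-built polarized matrix from a call-code matrix
tinyMatrix <- function(codes, chrom = NULL, pos = NULL) {
  codes <- as.matrix(codes)
  n <- nrow(codes)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(colnames(codes))) colnames(codes) <- paste0("s", seq_len(ncol(codes)))
  SiteMatrix(codes, chrom = chrom, pos = pos,
             alleleA = "A", alleleB = "C", ancestral = "A", polarized = TRUE)
}
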