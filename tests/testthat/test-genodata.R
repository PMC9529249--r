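# Reading, polarizing, annotating, filtering and block-partitioning of
# pseudo-haploid genotype matrices.

writeTmpTped <- function(tpedLines, samples) {
  prefix <- tempfile()
  writeLines(tpedLines, paste0(prefix, ".tped"))
  writeLines(paste(samples, samples, 0, 0, 0, -9), paste0(prefix, ".tfam"))
  prefix
}

test_that("tped parsing collapses duplicated haploid tokens and handles missing codes", {
  prefix <- writeTmpTped(c("1 snp1 0 100 A A G G 0 0",
                           "1 snp2 0 200 C C C C N N"),
                         c("ind1", "ind2", "ind3"))
  sm <- readTped(paste0(prefix, ".tped"), paste0(prefix, ".tfam"))
  expect_s4_class(sm, "SiteMatrix")
  expect_identical(colnames(sm), c("ind1", "ind2", "ind3"))
  info <- siteInfo(sm)
  expect_identical(info$alleleA, c("A", "C"))
  expect_identical(info$alleleB, c("G", NA))
  m <- callMatrix(sm)
  expect_identical(m[1, ], c(ind1 = 0L, ind2 = 1L, ind3 = NA))
  expect_identical(m[2, ], c(ind1 = 0L, ind2 = 0L, ind3 = NA))
  expect_false(isPolarized(sm))
})

test_that("tped contract violations are hard errors or logged rejections", {
  # discordant non-missing tokens name site and sample
  p1 <- writeTmpTped("1 snp1 0 100 A C G G", c("ind1", "ind2"))
  expect_error(readTped(paste0(p1, ".tped"), paste0(p1, ".tfam")),
               "snp1.*ind1|ind1.*snp1")
  # half-missing token pair is equally discordant
  p2 <- writeTmpTped("1 snp1 0 100 A 0 G G", c("ind1", "ind2"))
  expect_error(readTped(paste0(p2, ".tped"), paste0(p2, ".tfam")), "discordant")
  # >2 alleles: site rejected with a warning, others survive
  p3 <- writeTmpTped(c("1 snp1 0 100 A A C C T T",
                       "1 snp2 0 200 A A G G A A"),
                     c("i1", "i2", "i3"))
  expect_warning(sm <- readTped(paste0(p3, ".tped"), paste0(p3, ".tfam")),
                 "snp1")
  expect_equal(nSites(sm), 1L)
  expect_identical(siteInfo(sm)$siteId, "snp2")
  # sample count mismatch between tped and tfam
  p4 <- writeTmpTped("1 snp1 0 100 A A G G", c("i1", "i2", "i3"))
  expect_error(readTped(paste0(p4, ".tped"), paste0(p4, ".tfam")), "samples")
})

test_that("write-then-read round trip reproduces a random matrix exactly", {
  sm <- makeRandomSiteMatrix(nSitesTotal = 50L, nSamples = 6L, seed = 42L)
  prefix <- tempfile()
  writeTped(sm, prefix)
  back <- readTped(paste0(prefix, ".tped"), paste0(prefix, ".tfam"))
  expect_identical(dim(back), dim(sm))
  info0 <- siteInfo(sm); info1 <- siteInfo(back)
  expect_identical(info1$chrom, info0$chrom)
  expect_identical(info1$pos, info0$pos)
  # site alleles are inferred from observed tokens: alleleA is the
  # alphabetically first, so compare calls after mapping onto nucleotides
  nuc0 <- ifelse(callMatrix(sm) == 0L, info0$alleleA[row(callMatrix(sm))],
                 info0$alleleB[row(callMatrix(sm))])
  nuc1 <- ifelse(callMatrix(back) == 0L, info1$alleleA[row(callMatrix(back))],
                 info1$alleleB[row(callMatrix(back))])
  expect_identical(nuc1, nuc0)
})

test_that("polarization recodes against the ancestral allele and drops unresolved sites", {
  calls <- rbind(c(0L, 1L, NA), c(1L, 0L, 0L), c(0L, 0L, 1L))
  sm <- SiteMatrix(calls, chrom = "chr1", pos = c(10L, 20L, 30L),
                   alleleA = c("A", "G", "C"), alleleB = c("G", "A", "T"),
                   ancestral = c("A", "A", "G"))  # site 3 unresolvable
  expect_message(pol <- polarize(sm), "dropped 1")
  expect_true(isPolarized(pol))
  expect_equal(attr(pol, "dropped"), 1L)
  expect_equal(nSites(pol), 2L)
  info <- siteInfo(pol)
  expect_identical(info$alleleA, c("A", "A"))      # code 0 now ancestral
  m <- callMatrix(pol)
  expect_identical(unname(m[1, ]), c(0L, 1L, NA))  # already ancestral-first
  expect_identical(unname(m[2, ]), c(0L, 1L, 1L))  # swapped
})

test_that("polarize is idempotent on retained sites", {
  sm <- makeRandomSiteMatrix(100L, 5L, seed = 9L, polarized = FALSE)
  # give half the sites a usable ancestral state, half a mismatching one
  info <- siteInfo(sm)
  anc <- ifelse(seq_len(nSites(sm)) %% 2 == 0, info$alleleB, "N")
  p1 <- polarize(sm, ancestral = anc, verbose = FALSE)
  p2 <- polarize(p1, verbose = FALSE)
  expect_identical(callMatrix(p2), callMatrix(p1))
  expect_identical(as.data.frame(siteInfo(p2)), as.data.frame(siteInfo(p1)))
  expect_equal(attr(p2, "dropped"), 0L)
})

test_that("polarized code 0 equals the simulator root allele at every retained site", {
  sim <- simulateScenario(presetScenario("null_panmictic", seed = 3L,
                                         nSites = 2000L))
  pol <- polarize(sim$matrix, verbose = FALSE)
  expect_identical(siteInfo(pol)$alleleA, siteInfo(pol)$ancestral)
  expect_identical(siteInfo(pol)$alleleA, sim$truth$rootAllele)
})

test_that("site filters match an independent per-site reimplementation", {
  sm <- makeRandomSiteMatrix(300L, 10L, seed = 5L)
  info <- siteInfo(sm)
  m <- callMatrix(sm)
  keep <- rep(TRUE, nSites(sm))
  for (i in seq_len(nSites(sm))) {           # naive per-site predicates
    if (isTRUE(info$isCpG[i])) keep[i] <- FALSE
    if (!isTRUE(info$isTransversion[i])) keep[i] <- FALSE
    x <- m[i, ][!is.na(m[i, ])]
    if (length(x) < 6L) keep[i] <- FALSE
    else {
      f <- mean(x)
      if (min(f, 1 - f) < 0.1) keep[i] <- FALSE
    }
  }
  out <- filterSites(sm, transversionsOnly = TRUE, dropCpG = TRUE,
                     minCalled = 6L, minMaf = 0.1, verbose = FALSE)
  expect_equal(nSites(out), sum(keep))
  expect_identical(siteInfo(out)$pos, info$pos[keep])
})

test_that("filter conventions: transversions, MAF threshold, whitelist, errors", {
  calls <- rbind(rep(c(0L, 1L), 5), c(1L, rep(0L, 9)), rep(0L, 10))
  sm <- SiteMatrix(calls, chrom = "chr1", pos = c(100L, 200L, 300L),
                   alleleA = c("A", "C", "A"), alleleB = c("G", "A", "T"),
                   ancestral = c("A", "C", "A"), polarized = TRUE)
  # {A,G} transition dropped; {C,A} transversion retained
  tv <- filterSites(sm, transversionsOnly = TRUE, verbose = FALSE)
  expect_identical(siteInfo(tv)$pos, c(200L, 300L))
  # 1 derived call in 10: freq 0.1 passes 0.05, fails 0.15
  expect_true(200L %in% siteInfo(filterSites(sm, minMaf = 0.05, verbose = FALSE))$pos)
  expect_false(200L %in% siteInfo(filterSites(sm, minMaf = 0.15, verbose = FALSE))$pos)
  # whitelist intersects on (chrom, pos)
  wl <- filterSites(sm, whitelist = data.frame(chrom = "chr1", pos = 300L),
                    verbose = FALSE)
  expect_equal(nSites(wl), 1L)
  # removing everything is an explicit error
  expect_error(filterSites(sm, minCalled = 11L, verbose = FALSE), "all sites")
  # filter output is a subset and invariant to sample order
  perm <- sample(ncol(sm))
  smPerm <- SiteMatrix(calls[, perm], chrom = "chr1", pos = c(100L, 200L, 300L),
                       alleleA = c("A", "C", "A"), alleleB = c("G", "A", "T"),
                       ancestral = c("A", "C", "A"), polarized = TRUE)
  expect_identical(siteInfo(filterSites(smPerm, minMaf = 0.05, verbose = FALSE))$pos,
                   siteInfo(filterSites(sm, minMaf = 0.05, verbose = FALSE))$pos)
})

test_that("block assignment follows the floor-division convention", {
  sm <- tinyMatrix(matrix(0L, 4, 2),
                   chrom = c("chr1", "chr1", "chr1", "chr2"),
                   pos = c(1L, 5000000L, 5000001L, 10L))
  bp <- assignBlocks(sm, 5e6)
  expect_equal(blockIds(bp), c(1L, 1L, 2L, 3L))  # 5,000,000 still in block 1
  expect_equal(nBlocks(bp), 3L)
  expect_error(assignBlocks(sm, 0), "positive")
  # two chromosomes, one site each -> 2 blocks
  sm2 <- tinyMatrix(matrix(0L, 2, 2), chrom = c("chrA", "chrB"),
                    pos = c(1L, 1L))
  expect_equal(nBlocks(assignBlocks(sm2, 5e6)), 2L)
})

test_that("random positions give the floor-division block count, ids non-decreasing", {
  set.seed(11)
  pos <- sort(sample.int(1e8, 400L))
  sm <- tinyMatrix(matrix(0L, 400L, 2L), chrom = rep("chr1", 400L), pos = pos)
  bp <- assignBlocks(sm, 5e6)
  expect_equal(nBlocks(bp), length(unique((pos - 1) %/% 5e6)))
  expect_true(all(diff(blockIds(bp)) >= 0))
  # 100 Mb uniform: expect all 20 blocks occupied at this density
  expect_equal(nBlocks(bp), 20L)
})

test_that("site annotation tables round trip and fill ancestral/CpG states", {
  sm <- makeRandomSiteMatrix(30L, 4L, seed = 2L, polarized = FALSE)
  path <- tempfile(fileext = ".tsv")
  writeSiteInfo(sm, path)
  info <- readSiteInfo(path)
  expect_identical(info$pos, siteInfo(sm)$pos)
  # wipe annotations, re-apply from the table
  bare <- SiteMatrix(callMatrix(sm), chrom = siteInfo(sm)$chrom,
                     pos = siteInfo(sm)$pos,
                     alleleA = siteInfo(sm)$alleleA,
                     alleleB = siteInfo(sm)$alleleB)
  anno <- annotateSites(bare, info)
  expect_identical(siteInfo(anno)$ancestral, siteInfo(sm)$ancestral)
  expect_identical(siteInfo(anno)$isCpG, siteInfo(sm)$isCpG)
})

test_that("group tables validate roles and reject duplicate samples", {
  path <- tempfile()
  writeGroups(data.frame(sample = c("a", "b"), group = c("g1", "g1"),
                         role = c("H3", "conditioning")), path)
  gt <- readGroups(path)
  expect_identical(gt$sample, c("a", "b"))
  writeLines(c("#sample\tgroup\trole", "a\tg1\tbogus"), path)
  expect_error(readGroups(path), "unknown role")
  writeLines(c("#sample\tgroup\trole", "a\tg1\tnone", "a\tg2\tnone"), path)
  expect_error(readGroups(path), "more than once")
})

test_that("CpG flagging uses the reference dinucleotide context", {
  #            123456
  ref <- list(chr1 = "AACGTA")
  sm <- tinyMatrix(matrix(0L, 3, 2), chrom = rep("chr1", 3),
                   pos = c(3L, 4L, 5L))  # C of CG, G of CG, T
  fl <- flagCpG(sm, ref)
  expect_identical(siteInfo(fl)$isCpG, c(TRUE, TRUE, FALSE))
})
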