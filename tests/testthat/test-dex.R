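# Extended D: multi-outgroup ascertainment, the D_ex statistic, and the
# disentangling attribution of shared low-frequency derived alleles.

# columns: s1 = H3, s2-s3 = condA, s4-s5 = condB, s6 = root, s7 = h1, s8 = h2
dexToy <- function(rows) tinyMatrix(rows)

test_that("strict ascertainment applies the stated coverage and fixation rules", {
  sm <- dexToy(rbind(
    c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 1L),   # retained
    c(1L, NA, NA, 0L, 0L, 0L, 1L, 0L),   # condA entirely missing -> excluded
    c(1L, 0L, 1L, 0L, 0L, 0L, 0L, 1L),   # condA carries derived -> excluded
    c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 1L),   # H3 ancestral -> excluded
    c(1L, 0L, 0L, 0L, 0L, 1L, 0L, 1L),   # root not fixed -> excluded
    c(1L, 0L, NA, 0L, 0L, 0L, 1L, 1L)))  # condA covered once -> retained
  asc <- ascertainDexSites(sm, "s1",
                           conditioning = list(condA = c("s2", "s3"),
                                               condB = c("s4", "s5")),
                           rootFixed = "s6", mode = "strict")
  expect_identical(asc@retained, c(1L, 6L))
})

test_that("window ascertainment keeps low-frequency sharing and excludes strict sites", {
  sm <- makeRandomSiteMatrix(400L, 12L, seed = 31L, missingRate = 0.2)
  cond <- list(g1 = paste0("s", 2:5), g2 = paste0("s", 6:9))
  strict <- ascertainDexSites(sm, "s1", cond, rootFixed = paste0("s", 10:11),
                              mode = "strict")
  win <- ascertainDexSites(sm, "s1", cond, rootFixed = paste0("s", 10:11),
                           mode = "window", window = c(0, 0.5))
  # a site cannot be both fixed-ancestral and segregating in the outgroups
  expect_length(intersect(strict@retained, win@retained), 0L)
  # both match the naive per-site loop
  m <- callMatrix(sm)
  expect_identical(strict@retained,
                   oracleAscertain(m, 1L, list(2:5, 6:9), 10:11, "strict"))
  expect_identical(win@retained,
                   oracleAscertain(m, 1L, list(2:5, 6:9), 10:11, "window",
                                   window = c(0, 0.5)))
})

test_that("adding a conditioning group never increases the strict retained count", {
  for (s in 1:5) {
    sm <- makeRandomSiteMatrix(200L, 12L, seed = 40L + s, missingRate = 0.1)
    cond1 <- list(g1 = paste0("s", 2:4))
    cond2 <- c(cond1, list(g2 = paste0("s", 5:7)))
    n1 <- length(ascertainDexSites(sm, "s1", cond1, rootFixed = "s12",
                                   mode = "strict")@retained)
    n2 <- length(ascertainDexSites(sm, "s1", cond2, rootFixed = "s12",
                                   mode = "strict")@retained)
    expect_lte(n2, n1)
  }
})

test_that("ascertainment guards: modes, windows, panel overlap", {
  sm <- makeRandomSiteMatrix(50L, 8L, seed = 3L)
  expect_error(ascertainDexSites(sm, "s1", list(), rootFixed = "s8",
                                 mode = "strict"), "conditioning")
  expect_error(ascertainDexSites(sm, "s1", list(g = "s2"), rootFixed = "s8",
                                 mode = "window", window = c(0, 0.7)),
               "window")
  expect_error(ascertainDexSites(sm, "s1", list(g = c("s1", "s2")),
                                 rootFixed = "s8"), "H3")
  up <- makeRandomSiteMatrix(10L, 8L, seed = 3L, polarized = FALSE)
  expect_error(ascertainDexSites(up, "s1", list(g = "s2"), rootFixed = "s8"),
               "polarized")
})

test_that("D_ex formula, symmetry and anti-symmetry", {
  sm <- makeRandomSiteMatrix(300L, 10L, seed = 23L)
  bp <- assignBlocks(sm, 1e6)
  cond <- list(g = paste0("s", 5:7))
  asc <- ascertainDexSites(sm, "s4", cond, rootFixed = "s8", mode = "strict")
  expect_gt(length(asc@retained), 0L)
  # identical H1 and H2 panels give exactly zero (se degenerates to 0)
  expect_warning(
    r0 <- dexStatistic(sm, asc, "s1", "s1", blocks = bp, nReps = 50L, seed = 1L),
    "undefined")
  expect_identical(r0@value, 0)
  # swapping H1 and H2 negates the statistic bit-exactly
  rf <- dexStatistic(sm, asc, "s1", "s2", blocks = bp, nReps = 100L, seed = 2L)
  rb <- dexStatistic(sm, asc, "s2", "s1", blocks = bp, nReps = 100L, seed = 2L)
  expect_identical(rf@value, -rb@value)
  # counts match a direct per-site recount
  m <- callMatrix(sm)
  ret <- asc@retained
  p1v <- m[ret, 1]; p2v <- m[ret, 2]
  ok <- !is.na(p1v) & !is.na(p2v)
  expect_equal(rf@nBABA, sum(p1v[ok]), tolerance = 1e-12)
  expect_equal(rf@nABBA, sum(p2v[ok]), tolerance = 1e-12)
})

test_that("H1/H2 reuse of H3 or conditioning samples is rejected", {
  sm <- makeRandomSiteMatrix(100L, 8L, seed = 29L)
  asc <- ascertainDexSites(sm, "s4", list(g = paste0("s", 5:6)),
                           rootFixed = "s8", mode = "strict")
  expect_error(dexStatistic(sm, asc, "s4", "s2", nReps = 10L), "H3|conditioning")
  expect_error(dexStatistic(sm, asc, "s1", "s5", nReps = 10L), "H3|conditioning")
})

test_that("ghost admixture produces a positive D_ex recovered against a recount oracle", {
  hits <- 0L
  for (s in 1:3) {
    sim <- simulateScenario(presetScenario("tur_like_ghost", seed = 500L + s,
                                           nSites = 200000L))
    sm <- polarize(sim$matrix, verbose = FALSE)
    bp <- assignBlocks(sm)
    cond <- list(tur = c(paste0("tur_east_", 1:2), paste0("tur_west_", 1:2)),
                 bez = paste0("bezoar_", 1:4))
    asc <- ascertainDexSites(sm, "ghost_1", cond,
                             rootFixed = paste0("outgroup_", 1:4),
                             mode = "strict")
    r <- dexStatistic(sm, asc, paste0("dom_ref_", 1:4),
                      paste0("dom_target_", 1:4),
                      blocks = bp, nReps = 400L, seed = 500L + s)
    if (r@value > 0 && r@z >= 3) hits <- hits + 1L
    # per-site recount oracle on the ascertained set
    m <- callMatrix(sm)[asc@retained, , drop = FALSE]
    p1 <- oracleFreq(m, match(paste0("dom_ref_", 1:4), colnames(m)))
    p2 <- oracleFreq(m, match(paste0("dom_target_", 1:4), colnames(m)))
    ok <- !is.na(p1) & !is.na(p2)
    expect_equal(r@nABBA, sum(p2[ok]), tolerance = 1e-10)
    expect_equal(r@nBABA, sum(p1[ok]), tolerance = 1e-10)
  }
  expect_gte(hits, 2L)
})

test_that("disentangling attributes shared variants site-by-site", {
  # retained sites (all rows ascertain): h2 = s8 carries derived at rows 1-3
  sm <- dexToy(rbind(
    c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 1L),
    c(1L, 0L, 1L, 0L, 0L, 0L, 0L, 1L),
    c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 1L),
    c(1L, 0L, 1L, 0L, 0L, 0L, 0L, 0L)))
  asc <- ascertainDexSites(sm, "s1",
                           conditioning = list(condA = c("s2", "s3")),
                           rootFixed = "s6", mode = "window",
                           window = c(0, 0.5))
  expect_identical(asc@retained, c(2L, 3L, 4L))   # row 1 is strict-like
  att <- disentangleAttribution(sm, asc, "s8", c("s2", "s3"))
  # shared sites: rows 2 and 3; s3 derived at row 2 only -> 1/2
  expect_equal(att$n_shared, c(2L, 2L))
  expect_equal(att$count, c(1L, 1L))
  expect_equal(att$prop_sites, c(0.5, 0.5))
  # an individual missing at all shared sites: proportion 0 of n informative
  sm2 <- dexToy(rbind(c(1L, 0L, 1L, 0L, 0L, 0L, 0L, 1L),
                      c(1L, NA, 1L, 0L, 0L, 0L, 0L, 1L)))
  asc2 <- ascertainDexSites(sm2, "s1", list(condA = c("s2", "s3")),
                            rootFixed = "s6", mode = "window",
                            window = c(0, 0.5))
  att2 <- disentangleAttribution(sm2, asc2, "s8", c("s2"))
  expect_equal(att2$count, 0L)
  expect_equal(att2$n_informative, 1L)
  expect_equal(att2$prop_sites, 0)
  # zero shared sites -> NA row with warning
  sm3 <- dexToy(rbind(c(1L, 0L, 1L, 0L, 0L, 0L, 1L, 0L)))
  asc3 <- ascertainDexSites(sm3, "s1", list(condA = c("s2", "s3")),
                            rootFixed = "s6", mode = "window",
                            window = c(0, 0.5))
  expect_warning(att3 <- disentangleAttribution(sm3, asc3, "s8", "s2"),
                 "no shared")
  expect_true(all(is.na(att3$prop_sites)))
  # strict-mode ascertainment cannot be disentangled
  ascS <- ascertainDexSites(sm3, "s1", list(condA = c("s2", "s3")),
                            rootFixed = "s6", mode = "strict")
  expect_error(disentangleAttribution(sm3, ascS, "s8", "s2"), "window")
})

test_that("the full attribution table equals a brute-force loop", {
  sm <- makeRandomSiteMatrix(300L, 12L, seed = 77L, missingRate = 0.25)
  cond <- list(g1 = paste0("s", 2:5), g2 = paste0("s", 6:9))
  asc <- ascertainDexSites(sm, "s1", cond, rootFixed = "s10",
                           mode = "window", window = c(0, 0.5))
  inds <- paste0("s", 2:9)
  att <- disentangleAttribution(sm, asc, "s11", inds)
  m <- callMatrix(sm)
  shared <- asc@retained[which(m[asc@retained, "s11"] == 1L)]
  for (k in seq_along(inds)) {
    cnt <- 0L
    for (i in shared) if (isTRUE(m[i, inds[k]] == 1L)) cnt <- cnt + 1L
    expect_equal(att$count[k], cnt)
    expect_equal(att$prop_sites[k], cnt / length(shared))
  }
  mat <- disentangleMatrix(sm, asc, c("s11", "s12"), inds)
  expect_identical(mat["s11", ], setNames(att$prop_sites, inds))
})

test_that("result-set correlation matches the textbook formula and handles edge cases", {
  expect_equal(correlateResultSets(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(correlateResultSets(c(1, 2, 3), c(-1, -2, -3)), -1)
  set.seed(55)
  a <- rnorm(10); b <- 0.7 * a + rnorm(10)
  expect_equal(correlateResultSets(a, b), oraclePearson(a, b), tolerance = 1e-12)
  expect_warning(r <- correlateResultSets(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_true(is.na(r))
  expect_error(correlateResultSets(1:3, 1:4), "length")
  expect_error(correlateResultSets(1:2, 1:2), "at least 3")
})
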