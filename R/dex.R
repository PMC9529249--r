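# Extended D (D_ex): ascertain derived variants specific to an H3 lineage
# against multiple conditioning "outgroup" panels, compute the normalized
# sharing statistic with a block-bootstrap Z, and attribute low-frequency
# shared variants to individual outgroup genomes ("disentangling").

#' Ascertain H3-specific derived sites
#'
#' A polarized site is retained iff (a) the H3 panel carries the derived
#' allele (single sample: call = 1; group: all non-missing calls derived
#' under the default \code{h3Rule = "fixed"}, or any derived call under
#' \code{"any"}); (b) every conditioning panel and the root-fixed panel is
#' covered at least once (>= 1 non-missing call); and (c) in strict mode
#' the derived-allele frequency is 0 in every conditioning panel and in the
#' root-fixed panel, while in window mode it is 0 in the root-fixed panel
#' and falls within \code{(window[1], window[2]]} in at least one
#' conditioning panel (optionally \code{<= window[2]} in all of them).
#'
#' @param x a polarized \code{\link{SiteMatrix}}.
#' @param h3 sample name(s) or a group name (the lineage whose "specific"
#'   alleles are sought).
#' @param conditioning a named list of sample-name vectors, or a character
#'   vector of group names resolved via \code{groups}.
#' @param rootFixed sample names/group name of the panel that must always be
#'   fixed ancestral (the sheep-analog root outgroup).
#' @param mode "strict" or "window".
#' @param window numeric(2): derived-frequency bounds (low, high] for
#'   window mode; low must be >= 0 and high in (low, 0.5].
#' @param groups optional group table for name resolution.
#' @param h3Rule "fixed" or "any" (see above).
#' @param constrainAllGroups window mode: additionally require the derived
#'   frequency to be <= \code{window[2]} in every conditioning panel.
#' @return A \code{\link{DexAscertainment}}.
#' @export
ascertainDexSites <- function(x, h3, conditioning, rootFixed,
                              mode = c("strict", "window"),
                              window = c(0, 0.10), groups = NULL,
                              h3Rule = c("fixed", "any"),
                              constrainAllGroups = FALSE) {
  mode <- match.arg(mode)
  h3Rule <- match.arg(h3Rule)
  if (!isPolarized(x))
    stop("ascertainDexSites requires a polarized SiteMatrix")
  if (mode == "strict" && length(conditioning) == 0L)
    stop("strict mode requires at least one conditioning group")
  cond <- .resolveGroupList(x, conditioning, groups, "conditioning")
  if (mode == "window") {
    if (length(window) != 2L || window[1] < 0 || window[2] > 0.5 ||
        window[2] <= window[1])
      stop("window bounds must satisfy 0 <= low < high <= 0.5")
  }
  i3 <- .resolvePanel(x, h3, groups, "h3")
  iRoot <- .resolvePanel(x, rootFixed, groups, "rootFixed")
  for (g in names(cond)) {
    if (length(intersect(cond[[g]], i3)))
      stop(sprintf("conditioning group '%s' shares sample(s) with H3", g))
  }
  m <- callMatrix(x)

  f3 <- .panelFreq(m, i3)
  h3ok <- if (h3Rule == "fixed") !is.na(f3) & f3 == 1 else !is.na(f3) & f3 > 0
  fRoot <- .panelFreq(m, iRoot)
  ok <- h3ok & !is.na(fRoot) & fRoot == 0

  condFreq <- lapply(cond, function(idx) .panelFreq(m, idx))
  for (f in condFreq) ok <- ok & !is.na(f)          # covered at least once
  if (mode == "strict") {
    for (f in condFreq) ok <- ok & f == 0
  } else {
    inWin <- Reduce(`|`, lapply(condFreq, function(f)
      !is.na(f) & f > window[1] & f <= window[2]), rep(FALSE, nrow(m)))
    ok <- ok & inWin
    if (constrainAllGroups)
      for (f in condFreq) ok <- ok & f <= window[2]
  }
  ok[is.na(ok)] <- FALSE
  new("DexAscertainment", mode = mode,
      window = if (mode == "window") as.numeric(window) else c(NA_real_, NA_real_),
      retained = which(ok),
      h3 = colnames(x)[i3],
      conditioning = lapply(cond, function(idx) colnames(x)[idx]),
      rootFixed = colnames(x)[iRoot],
      h3Rule = h3Rule, nEvaluated = nrow(x))
}

# conditioning spec -> named list of column-index vectors
.resolveGroupList <- function(x, spec, groups, what) {
  if (is.null(spec) || length(spec) == 0L) return(list())
  if (is.character(spec)) {
    spec <- as.list(spec)
    names(spec) <- vapply(spec, paste, character(1L), collapse = ",")
  }
  if (is.null(names(spec)) || any(names(spec) == ""))
    names(spec) <- paste0(what, seq_along(spec))
  lapply(spec, function(g) .resolvePanel(x, g, groups, what))
}

#' Extended D statistic over ascertained sites
#'
#' Per retained site, nBABA_ex accrues the derived-allele frequency in the
#' reference panel H1 and nABBA_ex the frequency in the target panel H2
#' (single genomes contribute 0/1, the frequency-weighted rule's degenerate
#' case). Sites where H1 or H2 is entirely missing are skipped. The
#' statistic is \eqn{D_{ex} = (nABBA_{ex} - nBABA_{ex}) /
#' (nABBA_{ex} + nBABA_{ex})}; its Z score comes from block resampling
#' (bootstrap with 1000 replicates over 5 Mb blocks by default).
#'
#' @param x the polarized \code{\link{SiteMatrix}} the ascertainment was
#'   computed on.
#' @param ascertainment a \code{\link{DexAscertainment}}.
#' @param h1,h2 reference and target panels (sample names or group name).
#' @param blocks a \code{\link{BlockPartition}} over the sites of \code{x};
#'   5 Mb blocks are computed if omitted.
#' @param groups optional group table for name resolution.
#' @param method,nReps,seed see \code{\link{blockResample}}.
#' @return A \code{\link{DStatResult}}.
#' @export
dexStatistic <- function(x, ascertainment, h1, h2, blocks = NULL,
                         groups = NULL, method = c("bootstrap", "jackknife"),
                         nReps = 1000L, seed = NULL) {
  method <- match.arg(method)
  pc <- dexCounts(x, ascertainment, h1, h2, blocks = blocks, groups = groups)
  dFromCounts(pc)
  blockResample(pc, method = method, nReps = nReps, seed = seed)
}

#' @rdname dexStatistic
#' @details \code{dexCounts} returns the per-block
#'   \code{\link{PatternCounts}} without resampling.
#' @export
dexCounts <- function(x, ascertainment, h1, h2, blocks = NULL, groups = NULL) {
  stopifnot(is(ascertainment, "DexAscertainment"))
  if (ascertainment@nEvaluated != nrow(x))
    stop("ascertainment was computed on a matrix with a different site count")
  i1 <- .resolvePanel(x, h1, groups, "h1")
  i2 <- .resolvePanel(x, h2, groups, "h2")
  reserved <- match(c(ascertainment@h3, unlist(ascertainment@conditioning)),
                    colnames(x))
  clash <- intersect(c(i1, i2), reserved)
  if (length(clash))
    stop("H1/H2 overlap H3 or a conditioning group: ",
         paste(colnames(x)[clash], collapse = ", "))
  if (length(intersect(i1, i2)) &&
      !identical(sort(i1), sort(i2)))  # identical panels allowed (D_ex = 0 check)
    stop("H1 and H2 share sample(s)")
  if (is.null(blocks)) blocks <- assignBlocks(x)
  ret <- ascertainment@retained
  m <- callMatrix(x)
  p1 <- .panelFreq(m, i1)[ret]
  p2 <- .panelFreq(m, i2)[ret]
  use <- !is.na(p1) & !is.na(p2)
  counts <- .perBlock(cbind(nABBA = p2, nBABA = p1)[use, , drop = FALSE],
                      blockIds(blocks)[ret][use], nBlocks(blocks))
  new("PatternCounts", counts = counts, nSitesUsed = sum(use),
      labels = c(h1 = paste(h1, collapse = ","),
                 h2 = paste(h2, collapse = ","),
                 h3 = paste(ascertainment@h3, collapse = ","),
                 mode = ascertainment@mode))
}

#' Attribute shared low-frequency derived alleles to outgroup individuals
#'
#' Window-mode disentangling: restrict to ascertained sites where the
#' target genome H2 carries the derived allele (the "shared variants"),
#' then for each outgroup individual count the sites at which that
#' individual's call is also derived. The default proportion divides by the
#' number of shared-variant sites; the proportion of total sharing
#' observations (summed over individuals) is reported alongside.
#'
#' @param x the polarized \code{\link{SiteMatrix}}.
#' @param ascertainment a window-mode \code{\link{DexAscertainment}}.
#' @param h2 a single target sample name.
#' @param outgroupIndividuals sample names drawn from the conditioning
#'   groups.
#' @return A data.frame with one row per individual: shared-allele count,
#'   number of shared sites at which the individual is non-missing, and the
#'   two proportion variants. Zero shared sites gives an all-NA row with a
#'   warning.
#' @export
disentangleAttribution <- function(x, ascertainment, h2, outgroupIndividuals) {
  stopifnot(is(ascertainment, "DexAscertainment"))
  if (ascertainment@mode != "window")
    stop("disentangling requires a window-mode ascertainment")
  if (length(h2) != 1L) stop("h2 must be a single sample")
  i2 <- .resolvePanel(x, h2, NULL, "h2")
  iOut <- .resolvePanel(x, outgroupIndividuals, NULL, "outgroup individual")
  m <- callMatrix(x)[ascertainment@retained, , drop = FALSE]
  shared <- which(m[, i2] == 1L)
  nShared <- length(shared)
  if (nShared == 0L) {
    warning(sprintf("no shared-variant sites for h2 = %s", h2))
    return(data.frame(h2 = h2, individual = outgroupIndividuals,
                      count = NA_integer_, n_informative = NA_integer_,
                      n_shared = 0L,
                      prop_sites = NA_real_, prop_obs = NA_real_))
  }
  sub <- m[shared, iOut, drop = FALSE]
  count <- colSums(sub == 1L, na.rm = TRUE)
  nInf <- colSums(!is.na(sub))
  data.frame(h2 = h2, individual = colnames(x)[iOut],
             count = as.integer(count), n_informative = as.integer(nInf),
             n_shared = nShared,
             prop_sites = count / nShared,
             prop_obs = if (sum(count) > 0) count / sum(count) else NA_real_,
             row.names = NULL)
}

#' Attribution matrix over many target genomes
#'
#' Runs \code{\link{disentangleAttribution}} for each target in \code{h2s}
#' and assembles the site-proportion matrix used for heatmap display
#' (targets x outgroup individuals).
#'
#' @inheritParams disentangleAttribution
#' @param h2s character vector of target samples.
#' @return A numeric matrix with one row per target.
#' @export
disentangleMatrix <- function(x, ascertainment, h2s, outgroupIndividuals) {
  rows <- lapply(h2s, function(h2)
    disentangleAttribution(x, ascertainment, h2, outgroupIndividuals)$prop_sites)
  out <- do.call(rbind, rows)
  dimnames(out) <- list(h2s, outgroupIndividuals)
  out
}
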