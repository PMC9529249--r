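# Config-driven pipeline: validated declarative runs, structured logging,
# deterministic output layout with an append-only checksum manifest.

.CONFIG_KEYS <- list(
  top = c("seed", "output_dir", "inputs", "simulate", "filters", "block_size",
          "resampling", "dstat", "dex", "disentangle", "ibs", "mds", "mtdiff"),
  inputs = c("tped", "tfam", "sites", "groups", "fasta"),
  simulate = c("preset", "n_sites"),
  filters = c("transversions_only", "drop_cpg", "min_called", "min_maf"),
  resampling = c("method", "n_reps"),
  dex_test = c("h1", "h2", "h3", "conditioning", "root_fixed", "mode",
               "window_low", "window_high"),
  dstat_test = c("h1", "h2", "h3"),
  disentangle = c("h2", "individuals", "conditioning", "root_fixed", "h3",
                  "window_low", "window_high"),
  ibs = c("region", "root_on", "support_regions", "support_reps"),
  mds = c("k"),
  mtdiff = c("groups", "exclusions")
)

.checkKeys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop(sprintf("unknown key(s) in %s: %s", where, paste(extra, collapse = ", ")),
         call. = FALSE)
}

#' Read and validate a pipeline run configuration
#'
#' The configuration is declarative YAML. Unknown keys anywhere are
#' rejected before any computation. Either \code{simulate:} (a preset) or
#' \code{inputs:} (tped/tfam/sites/groups paths) must provide the genotype
#' data; analysis stages (\code{dstat}, \code{dex}, \code{disentangle},
#' \code{ibs}, \code{mds}, \code{mtdiff}) are optional lists.
#'
#' @param path YAML file path, or an already-parsed list.
#' @return The validated config (list).
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  .checkKeys(cfg, .CONFIG_KEYS$top, "config")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$output_dir)) stop("config requires output_dir", call. = FALSE)
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop("config requires either 'simulate' or 'inputs'", call. = FALSE)
  if (!is.null(cfg$inputs)) .checkKeys(cfg$inputs, .CONFIG_KEYS$inputs, "inputs")
  if (!is.null(cfg$simulate)) .checkKeys(cfg$simulate, .CONFIG_KEYS$simulate, "simulate")
  if (!is.null(cfg$filters)) .checkKeys(cfg$filters, .CONFIG_KEYS$filters, "filters")
  if (!is.null(cfg$resampling))
    .checkKeys(cfg$resampling, .CONFIG_KEYS$resampling, "resampling")
  for (i in seq_along(cfg$dstat))
    .checkKeys(cfg$dstat[[i]], .CONFIG_KEYS$dstat_test, sprintf("dstat[%d]", i))
  for (i in seq_along(cfg$dex)) {
    t <- cfg$dex[[i]]
    .checkKeys(t, .CONFIG_KEYS$dex_test, sprintf("dex[%d]", i))
    if (is.null(t$conditioning) || length(t$conditioning) == 0L)
      stop(sprintf("dex[%d]: conditioning groups are required", i), call. = FALSE)
    if (is.null(t$root_fixed))
      stop(sprintf("dex[%d]: root_fixed group is required", i), call. = FALSE)
  }
  if (!is.null(cfg$disentangle))
    .checkKeys(cfg$disentangle, .CONFIG_KEYS$disentangle, "disentangle")
  if (!is.null(cfg$ibs)) .checkKeys(cfg$ibs, .CONFIG_KEYS$ibs, "ibs")
  if (!is.null(cfg$mds)) .checkKeys(cfg$mds, .CONFIG_KEYS$mds, "mds")
  if (!is.null(cfg$mtdiff)) .checkKeys(cfg$mtdiff, .CONFIG_KEYS$mtdiff, "mtdiff")
  cfg
}

#' Run a configured pipeline
#'
#' Executes the requested stages in dependency order (simulate/load ->
#' polarize + filter -> statistics / trees / mtDNA summaries), writing
#' tab-separated outputs and a newick tree into the output directory, a
#' timestamped log, and an append-only \code{manifest.tsv} recording
#' (file, stage, md5). Identical config and seed give identical checksums
#' for the deterministic stages. Any stage error aborts the run naming the
#' stage.
#'
#' @param config path to a YAML config or a config list
#'   (see \code{\link{readRunConfig}}).
#' @return Invisibly, the manifest data.frame of this run.
#' @export
runPipeline <- function(config) {
  cfg <- readRunConfig(config)
  outDir <- cfg$output_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outDir, "run.log")
  manifestPath <- file.path(outDir, "manifest.tsv")
  manifest <- data.frame(file = character(), stage = character(),
                         md5 = character())
  log <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(...))
    cat(line, "\n", sep = "", file = logPath, append = TRUE)
    message(line)
  }
  record <- function(path, stage) {
    manifest <<- rbind(manifest, data.frame(
      file = basename(path), stage = stage,
      md5 = unname(tools::md5sum(path))))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  log("run start (seed %d, package version %s)", cfg$seed,
      as.character(utils::packageVersion("ghostDex")))

  groups <- NULL
  sm <- NULL
  if (!is.null(cfg$simulate)) {
    stage("simulate", {
      scn <- presetScenario(cfg$simulate$preset, seed = cfg$seed,
                            nSites = cfg$simulate$n_sites)
      sim <- simulateScenario(scn)
      sm <- polarize(sim$matrix, verbose = FALSE)
      groups <- sim$groups
      writeTped(sim$matrix, file.path(outDir, "simulated"))
      writeSiteInfo(sim$matrix, file.path(outDir, "simulated.sites.tsv"))
      writeGroups(sim$groups, file.path(outDir, "simulated.groups.tsv"))
      .writeTsv(sim$truth, file.path(outDir, "simulated.truth.tsv"))
      for (f in c("simulated.tped", "simulated.tfam", "simulated.sites.tsv",
                  "simulated.groups.tsv", "simulated.truth.tsv"))
        record(file.path(outDir, f), "simulate")
      log("simulate: %d sites, %d samples (preset %s)",
          nrow(sm), ncol(sm), cfg$simulate$preset)
    })
  } else {
    stage("load", {
      sm <- readTped(cfg$inputs$tped, cfg$inputs$tfam)
      if (!is.null(cfg$inputs$sites))
        sm <- annotateSites(sm, readSiteInfo(cfg$inputs$sites))
      if (!is.null(cfg$inputs$groups)) groups <- readGroups(cfg$inputs$groups)
      sm <- polarize(sm, verbose = FALSE)
      log("load: %d sites, %d samples", nrow(sm), ncol(sm))
    })
  }
  if (!is.null(cfg$filters)) {
    stage("filter", {
      sm <- filterSites(sm,
        transversionsOnly = isTRUE(cfg$filters$transversions_only),
        dropCpG = isTRUE(cfg$filters$drop_cpg),
        minCalled = cfg$filters$min_called %||% 0L,
        minMaf = cfg$filters$min_maf %||% 0,
        verbose = FALSE)
      log("filter: %d sites retained", nrow(sm))
    })
  }
  blockSize <- cfg$block_size %||% 5e6
  blocks <- assignBlocks(sm, blockSize)
  method <- cfg$resampling$method %||% "jackknife"
  nReps <- cfg$resampling$n_reps %||% 1000L

  if (length(cfg$dstat)) {
    stage("dstat", {
      rows <- lapply(cfg$dstat, function(t)
        as.data.frame(dStat(sm, t$h1, t$h2, t$h3, blocks = blocks,
                            groups = groups, method = method,
                            nReps = nReps, seed = cfg$seed)))
      p <- file.path(outDir, "dstat.tsv")
      .writeTsv(do.call(rbind, rows), p)
      record(p, "dstat")
      log("dstat: %d test(s)", length(rows))
    })
  }
  if (length(cfg$dex)) {
    stage("dex", {
      rows <- lapply(cfg$dex, function(t) {
        asc <- ascertainDexSites(sm, t$h3, conditioning = t$conditioning,
          rootFixed = t$root_fixed, mode = t$mode %||% "strict",
          window = c(t$window_low %||% 0, t$window_high %||% 0.10),
          groups = groups)
        as.data.frame(dexStatistic(sm, asc, t$h1, t$h2, blocks = blocks,
                                   groups = groups, method = "bootstrap",
                                   nReps = nReps, seed = cfg$seed))
      })
      p <- file.path(outDir, "dex.tsv")
      .writeTsv(do.call(rbind, rows), p)
      record(p, "dex")
      log("dex: %d test(s)", length(rows))
    })
  }
  if (!is.null(cfg$disentangle)) {
    stage("disentangle", {
      t <- cfg$disentangle
      asc <- ascertainDexSites(sm, t$h3, conditioning = t$conditioning,
        rootFixed = t$root_fixed, mode = "window",
        window = c(t$window_low %||% 0, t$window_high %||% 0.10),
        groups = groups)
      mat <- disentangleMatrix(sm, asc, t$h2, t$individuals)
      p <- file.path(outDir, "disentangle.tsv")
      .writeTsv(cbind(data.frame(h2 = rownames(mat)), as.data.frame(mat)), p)
      record(p, "disentangle")
      log("disentangle: %d target(s) x %d individual(s)", nrow(mat), ncol(mat))
    })
  }
  if (!is.null(cfg$ibs)) {
    stage("ibs", {
      dm <- ibsMatrix(sm, region = cfg$ibs$region)
      writeIbsMat(dm, file.path(outDir, "ibs.ibsMat"))
      writeIbsMat(dm, file.path(outDir, "ibs.labeled.tsv"), labeled = TRUE)
      record(file.path(outDir, "ibs.ibsMat"), "ibs")
      record(file.path(outDir, "ibs.labeled.tsv"), "ibs")
      tr <- if (!is.null(cfg$ibs$support_regions)) {
        nodeSupportPseudobootstrap(sm, blocks,
          nRegions = cfg$ibs$support_regions,
          nReps = cfg$ibs$support_reps %||% 100L,
          seed = cfg$seed, rootOn = cfg$ibs$root_on)
      } else njTree(dm, rootOn = cfg$ibs$root_on)
      p <- file.path(outDir, "nj.nwk")
      ape::write.tree(tr, p)
      record(p, "nj")
      log("ibs/nj: %d samples", nrow(ibsDist(dm)))
      if (!is.null(cfg$mds)) {
        pts <- classicalMDS(dm, k = cfg$mds$k %||% 2L)
        p <- file.path(outDir, "mds.tsv")
        .writeTsv(cbind(data.frame(sample = rownames(pts)),
                        as.data.frame(pts)), p)
        record(p, "mds")
      }
    })
  }
  if (!is.null(cfg$mtdiff)) {
    stage("mtdiff", {
      aln <- readMtAlignment(cfg$inputs$fasta)
      gt <- readGroups(cfg$mtdiff$groups)
      res <- groupMeanDifferences(aln, gt[, c("sample", "group")],
                                  exclusions = cfg$mtdiff$exclusions %||% character())
      .writeTsv(res$summary, file.path(outDir, "mtdiff.summary.tsv"))
      .writeTsv(res$pairs, file.path(outDir, "mtdiff.pairs.tsv"))
      record(file.path(outDir, "mtdiff.summary.tsv"), "mtdiff")
      record(file.path(outDir, "mtdiff.pairs.tsv"), "mtdiff")
      log("mtdiff: %d group(s)", nrow(res$summary))
    })
  }

  # append-only manifest for the run directory
  newFile <- !file.exists(manifestPath)
  utils::write.table(manifest, manifestPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = newFile, append = !newFile)
  log("run complete: %d output file(s)", nrow(manifest))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
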