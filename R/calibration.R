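# Canonical calibration experiments on the built-in scenarios: one
# replicate = simulate a preset, polarize, ascertain, compute D_ex with a
# 1000-replicate block bootstrap over 5 Mb blocks. These fix the panel
# layout so that tests, scripts and documentation all run the same
# experiment.

#' One D_ex calibration replicate on a built-in scenario
#'
#' \code{dexNullReplicate} runs the exchangeable null: on the
#' \code{null_panmictic} preset it takes one population pair as H1/H2, a
#' sample from a third population as H3, the fourth population as the
#' conditioning panel and the diverged outgroup as the root-fixed panel --
#' every ingroup population shares one frequency history, so the expected
#' D_ex is 0 and the bootstrap Z should be standard normal.
#'
#' \code{dexGhostReplicate} runs the recovery scenario: on the
#' \code{tur_like_ghost} preset (alpha = 0.1 into the target population)
#' H3 is the sampled ghost genome, the conditioning panels are the
#' unadmixed relatives (the two tur-like populations and the bezoar-like
#' population) and H1/H2 are the unadmixed and admixed domestic
#' populations. It returns both the open test and the specificity control
#' in which the remaining ghost samples join the conditioning set,
#' stripping the lineage-specific sites, computed on the same simulated
#' matrix.
#'
#' @param seed integer seed for both the simulation and the bootstrap.
#' @param nSites sites to simulate (defaults to the preset's 5e5).
#' @param nReps bootstrap replicates.
#' @return \code{dexNullReplicate}: a \code{\link{DStatResult}}, or
#'   \code{NULL} when the ascertainment retains no informative site.
#'   \code{dexGhostReplicate}: a list with elements \code{open} and
#'   \code{conditioned}, each a \code{DStatResult} or \code{NULL}.
#' @export
dexNullReplicate <- function(seed, nSites = 5e5, nReps = 1000L) {
  sim <- simulateScenario(presetScenario("null_panmictic", seed = seed,
                                         nSites = nSites))
  sm <- polarize(sim$matrix, verbose = FALSE)
  blocks <- assignBlocks(sm)
  asc <- ascertainDexSites(sm, "pop3_1",
                           conditioning = list(pop4 = paste0("pop4_", 1:4)),
                           rootFixed = paste0("outgroup_", 1:4),
                           mode = "strict")
  tryCatch(suppressWarnings(
    dexStatistic(sm, asc, paste0("pop1_", 1:4), paste0("pop2_", 1:4),
                 blocks = blocks, nReps = nReps, seed = seed)),
    error = function(e) NULL)
}

#' @rdname dexNullReplicate
#' @export
dexGhostReplicate <- function(seed, nSites = 5e5, nReps = 1000L) {
  sim <- simulateScenario(presetScenario("tur_like_ghost", seed = seed,
                                         nSites = nSites))
  sm <- polarize(sim$matrix, verbose = FALSE)
  blocks <- assignBlocks(sm)
  cond <- list(tur = c("tur_east_1", "tur_east_2", "tur_west_1", "tur_west_2"),
               bez = paste0("bezoar_", 1:4))
  h1 <- paste0("dom_ref_", 1:4)
  h2 <- paste0("dom_target_", 1:4)
  root <- paste0("outgroup_", 1:4)
  run <- function(conditioning) {
    asc <- ascertainDexSites(sm, "ghost_1", conditioning, rootFixed = root,
                             mode = "strict")
    tryCatch(suppressWarnings(
      dexStatistic(sm, asc, h1, h2, blocks = blocks, nReps = nReps,
                   seed = seed)),
      error = function(e) NULL)
  }
  list(open = run(cond),
       conditioned = run(c(cond, list(ghost = paste0("ghost_", 2:4)))))
}
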