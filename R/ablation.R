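#' The eight-arm ablation design
#'
#' Experiment matrix crossing input channels (3D: x,y,z; 4D adds RI),
#' voxel-to-cloud sampling (random vs segmented equilibrium) and selector
#' strategy (FPS-only, RIIES-only, hybrid):
#' 3D-R-FPS, 3D-S-FPS, 4D-R-FPS, 4D-S-FPS, 4D-R-RIIES, 4D-S-RIIES,
#' 4D-R-Hybrid, 4D-S-Hybrid.
#'
#' @return data.frame with columns \code{id}, \code{name},
#'   \code{channels}, \code{cloudSampling}, \code{strategy}.
#' @export
ablationArms <- function() {
  data.frame(
    id = 1:8,
    name = c("3D-R-FPS", "3D-S-FPS", "4D-R-FPS", "4D-S-FPS",
             "4D-R-RIIES", "4D-S-RIIES", "4D-R-Hybrid", "4D-S-Hybrid"),
    channels = c(3L, 3L, 4L, 4L, 4L, 4L, 4L, 4L),
    cloudSampling = c("random", "segmented", "random", "segmented",
                      "random", "segmented", "random", "segmented"),
    strategy = c("fps", "fps", "fps", "fps", "riies", "riies",
                 "hybrid", "hybrid"),
    stringsAsFactors = FALSE)
}

# internal: selector configuration for one arm strategy
strategyRipcs <- function(strategy, k, nFps, nRiies,
                          riInterval = c(1.345, 1.355)) {
  switch(strategy,
         fps = RIPCSConfig(k, k, 0L, riInterval),
         riies = RIPCSConfig(k, 0L, k, riInterval),
         hybrid = RIPCSConfig(k, nFps, nRiies, riInterval),
         stop("unknown strategy: ", strategy))
}

#' Run the ablation experiment matrix on phantom volumes
#'
#' For each requested arm and seed: converts the volumes to clouds with
#' the arm's sampling mode, normalizes to unit spheres, splits 8:2
#' stratified, trains the arm's network and reports held-out accuracy.
#' On phantoms whose classes differ only in nucleolar RI, arms carrying
#' the RI channel and nucleolar-band enhancement are expected to dominate
#' the coordinate-only arms.
#'
#' @param volumes list of labeled \linkS4class{VoxelVolume}.
#' @param arms subset of [ablationArms()] names (default all eight).
#' @param seeds integer vector; each seed reruns conversion, split,
#'   training and evaluation.
#' @param m,l cloud size and interval count for voxel-to-cloud sampling.
#' @param k,nFps,nRiies selector sizes for the hybrid strategy.
#' @param trainConfig a \linkS4class{TrainConfig} (its seed is overridden
#'   per run).
#' @param modelConfigFactory function(channels) returning an
#'   \linkS4class{RPNetConfig}; default [smallRPNetConfig()].
#' @param riStandardize RI-channel standardization
#'   \code{c(center, scale[, clip])} passed to [trainRPNet()]; the harness
#'   default (1.35, 0.01, 1) centers on the nucleolar band, scales to
#'   organelle-level RI differences and saturates at one unit, so the
#'   channel's dynamic range is spent on the band that carries the class
#'   signal rather than on droplet outliers.
#' @param nDraws deterministic selector draws averaged at evaluation.
#' @param splitRatio training fraction.
#' @param verbose print per-run progress lines.
#' @return data.frame with one row per (arm, seed): name, seed, accuracy,
#'   macro F1.
#' @export
runAblation <- function(volumes, arms = ablationArms()$name,
                        seeds = 1:5, m = 2048L, l = 6L,
                        k = 256L, nFps = 200L, nRiies = 56L,
                        trainConfig = TrainConfig(epochs = 50L),
                        modelConfigFactory = smallRPNetConfig,
                        riStandardize = c(1.35, 0.01, 1), nDraws = 5L,
                        splitRatio = 0.8, verbose = FALSE) {
  design <- ablationArms()
  design <- design[design$name %in% arms, , drop = FALSE]
  if (!nrow(design)) stop("no matching arms")
  labels <- vapply(volumes, cellLabel, integer(1))
  out <- list()
  for (seed in seeds) {
    baseClouds <- lapply(volumes, voxelToPoints)
    for (a in seq_len(nrow(design))) {
      arm <- design[a, ]
      sCfg <- SamplerConfig(m = m, l = l, mode = "segmented")
      clouds <- withSeed(seed * 1000L + arm$id, lapply(baseClouds,
        function(cl) {
          sub <- if (arm$cloudSampling == "segmented")
            segmentedEquilibriumSample(cl, sCfg)
          else randomSample(cl, m)
          normalizeUnitSphere(sub)
        }))
      sp <- stratifiedSplit(labels, splitRatio, seed = seed)
      rCfg <- strategyRipcs(arm$strategy, k, nFps, nRiies)
      tCfg <- initialize(trainConfig, seed = as.integer(seed))
      fit <- trainRPNet(clouds[sp$train],
                        modelConfig = modelConfigFactory(arm$channels),
                        config = tCfg, ripcsConfig = rCfg,
                        riStandardize = riStandardize)
      rep_ <- evaluateModel(fit$model, clouds[sp$test],
                            ripcsConfig = rCfg, seed = seed,
                            nDraws = nDraws)
      out[[length(out) + 1L]] <- data.frame(
        name = arm$name, seed = seed, accuracy = rep_@accuracy,
        f1 = rep_@f1, stringsAsFactors = FALSE)
      if (verbose)
        message(sprintf("[ablation] %s seed %d: accuracy %.3f",
                        arm$name, seed, rep_@accuracy))
    }
  }
  do.call(rbind, out)
}

#' Selector-stochasticity robustness
#'
#' Re-evaluates a fitted model under repeated stochastic selector draws
#' (random FPS start, fresh seeds) and reports the mean and standard
#' deviation of accuracy — the robustness companion to the deterministic
#' evaluation path.
#'
#' @param model a fitted \linkS4class{RPNetModel}.
#' @param clouds labeled normalized test clouds.
#' @param ripcsConfig selector parameters.
#' @param nRuns repeated draws (default 10).
#' @param seed base seed.
#' @return list with \code{mean}, \code{sd} and the per-run accuracies.
#' @export
ripcsRobustness <- function(model, clouds, ripcsConfig, nRuns = 10L,
                            seed = 1L) {
  labels <- vapply(clouds, cellLabel, integer(1))
  acc <- vapply(seq_len(nRuns), function(r) {
    sets <- withSeed(seed + r, lapply(clouds, ripcsSelect,
                                      config = ripcsConfig))
    logp <- rpnetForward(model, sets)
    mean(max.col(logp, ties.method = "first") - 1L == labels)
  }, numeric(1))
  list(mean = mean(acc), sd = sd(acc), accuracies = acc)
}
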