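# Experiment driver: phantom -> degrade -> train -> infer -> evaluate,
# wired from a plain-list (or YAML) run configuration with a single seed.

#' Default run configuration
#'
#' The desk-scale experiment: a 25-phantom cohort of 64^3 volumes split
#' 64/16/20% (20 volumes for training+validation, 5 held out), a 3D
#' network with 8 initial filters trained 15 epochs on 16^3 patches at
#' scaling factor 2. Full-scale replication (256^3 volumes, 64 filters,
#' 32^3 patches, 100 epochs) is expressible with the same keys.
#'
#' @return A nested list of configuration values.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    out_dir = "voxsr-run",
    cohort = list(n = 25L, shape = c(64L, 64L, 64L), n_shells = 3L,
                  levels = c(0.35, 0.55, 0.8), texture_scale = 2.0,
                  noise_sd = 0.01),
    fractions = c(0.64, 0.16, 0.20),
    factors = 2L,
    network = list(dims = 3L, initial_filters = 8L, conv_kernel = 3L,
                   pool = 2L),
    train = list(epochs = 15L, batch_size = 12L, lr0 = 1e-4,
                 plateau_patience = 4L, lr_min = 1e-5, patch_size = 16L,
                 augment = TRUE),
    evaluate = list(masked = FALSE, global_ssim = FALSE)
  )
}

.validKeys <- list(
  top = c("seed", "out_dir", "cohort", "fractions", "factors", "network",
          "train", "evaluate"),
  cohort = c("n", "shape", "n_shells", "levels", "texture_scale", "noise_sd"),
  network = c("dims", "initial_filters", "conv_kernel", "pool",
              "stage_blocks"),
  train = c("epochs", "batch_size", "lr0", "plateau_patience", "lr_min",
            "patch_size", "augment"),
  evaluate = c("masked", "global_ssim"))

#' Validate and complete a run configuration
#'
#' Unknown keys fail fast with the offending key named; missing keys are
#' filled from [defaultRunConfig()]. Scaling factors are restricted to
#' \{1, 2, 3, 4\} (1 allowed for tests).
#'
#' @param config nested list (e.g. from [readRunConfig()]).
#' @return The completed, validated configuration.
#' @export
validateRunConfig <- function(config) {
  def <- defaultRunConfig()
  bad <- setdiff(names(config), .validKeys$top)
  if (length(bad)) stop("invalid config key: '", bad[1], "'")
  for (sect in c("cohort", "network", "train", "evaluate")) {
    if (!is.null(config[[sect]])) {
      bad <- setdiff(names(config[[sect]]), .validKeys[[sect]])
      if (length(bad)) stop("invalid config key: '", sect, ".", bad[1], "'")
      def[[sect]][names(config[[sect]])] <- config[[sect]]
    }
  }
  for (key in setdiff(.validKeys$top, c("cohort", "network", "train",
                                        "evaluate"))) {
    if (!is.null(config[[key]])) def[[key]] <- config[[key]]
  }
  def$factors <- as.integer(def$factors)
  if (!all(def$factors %in% 1:4))
    stop("invalid config value: factors restricted to {1, 2, 3, 4}")
  if (abs(sum(def$fractions) - 1) > 1e-8)
    stop("invalid config value: fractions must sum to 1")
  if (!def$network$dims %in% c(2L, 3L))
    stop("invalid config value: network.dims must be 2 or 3")
  def
}

#' Read a YAML run configuration
#' @param path YAML file with the keys of [defaultRunConfig()].
#' @return The validated configuration list.
#' @export
readRunConfig <- function(path) {
  validateRunConfig(yaml::read_yaml(path))
}

#' Run a full super-resolution experiment
#'
#' Executes the pipeline on synthetic phantoms: cohort generation,
#' train/validation/test split, degradation at each configured scaling
#' factor, network training with best-checkpoint selection, whole-volume
#' inference on the held-out test volumes, and evaluation of the CNN
#' against bicubic interpolation (PSNR, MAE, SSIM). Every artifact —
#' checkpoints, per-epoch history, per-volume report, summary table, the
#' resolved configuration — is written under \code{config$out_dir} and is
#' reproducible from the configuration plus its seed.
#'
#' @param config nested configuration list (validated with
#'   [validateRunConfig()]).
#' @param dryRun print the resolved plan and return it without computing.
#' @param verbose print progress.
#' @return Invisibly, a list with the evaluation \code{report} and
#'   \code{summary} data frames, per-factor training \code{histories},
#'   and the \code{outDir}.
#' @export
runExperiment <- function(config = defaultRunConfig(), dryRun = FALSE,
                          verbose = FALSE) {
  config <- validateRunConfig(config)
  methodName <- if (config$network$dims == 3L) "cnn3d" else "cnn2d"
  plan_desc <- sprintf(
    "cohort n=%d shape=%s | split %s | factors %s | %s filters=%d patches=%d | epochs=%d",
    config$cohort$n, paste(config$cohort$shape, collapse = "x"),
    paste(config$fractions, collapse = "/"),
    paste(config$factors, collapse = ","), methodName,
    config$network$initial_filters, config$train$patch_size,
    config$train$epochs)
  if (dryRun) {
    cat("dry run:", plan_desc, "\n")
    return(invisible(list(plan = plan_desc, config = config)))
  }
  outDir <- config$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(outDir, "config-resolved.yaml"))
  logFile <- file.path(outDir, "run.log")
  logLine <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = logFile, append = TRUE)
  logLine("plan: %s", plan_desc)

  pspec <- PhantomSpec(shape = config$cohort$shape,
                       nTissueShells = config$cohort$n_shells,
                       intensityLevels = config$cohort$levels,
                       textureScale = config$cohort$texture_scale,
                       noiseSd = config$cohort$noise_sd,
                       seed = config$seed)
  cohort <- generateCohort(config$cohort$n, pspec, seed = config$seed)
  ids <- vapply(cohort, function(p) p$volume@id, character(1))
  names(cohort) <- ids
  plan <- makeSplits(ids, config$fractions, seed = config$seed)
  logLine("split: %d train / %d val / %d test", length(plan@trainIds),
          length(plan@valIds), length(plan@testIds))

  sb <- config$network$stage_blocks
  spec <- NetworkSpec(dims = config$network$dims,
                      initialFilters = config$network$initial_filters,
                      stageBlocks = if (is.null(sb))
                        c(2L, 2L, 3L, 3L, 3L, 3L, 3L, 2L, 2L)
                      else as.integer(sb),
                      convKernel = config$network$conv_kernel,
                      pool = config$network$pool)

  evalEntries <- list()
  histories <- list()
  for (fac in config$factors) {
    if (verbose) message("factor x", fac, ": simulating pairs")
    dspec <- DegradationSpec(fac)
    pairs <- lapply(cohort, function(ph) {
      hr <- homogenizeBackground(ph$volume, ph$mask)
      simulatePair(hr, ph$mask, dspec)
    })
    names(pairs) <- ids
    tcfg <- TrainConfig(epochs = config$train$epochs, factor = fac,
                        lr0 = config$train$lr0,
                        plateauPatience = config$train$plateau_patience,
                        lrMin = config$train$lr_min,
                        batchSize = config$train$batch_size,
                        seed = config$seed)
    net0 <- buildNetwork(spec, seed = config$seed)
    if (verbose) message("factor x", fac, ": training ", methodName)
    fit <- trainNetwork(net0, pairs, plan, tcfg,
                        patchSize = config$train$patch_size,
                        augment = isTRUE(config$train$augment))
    histories[[paste0("x", fac)]] <- fit$history
    utils::write.csv(fit$history@history,
                     file.path(outDir, sprintf("history-x%d.csv", fac)),
                     row.names = FALSE)
    saveCheckpoint(fit$net,
                   file.path(outDir, sprintf("checkpoint-x%d.rds", fac)))
    logLine("factor x%d: best epoch %d", fac, fit$history@bestEpoch)
    for (id in plan@testIds) {
      pair <- pairs[[id]]
      sr <- superResolve(fit$net, pair@lrUp, mask = pair@mask,
                         patchSize = config$train$patch_size)
      evalEntries[[paste0(id, "-x", fac)]] <- list(
        id = id, factor = fac, hr = pair@hr, mask = pair@mask,
        sr = stats::setNames(list(pair@lrUp, sr), c("interp", methodName)))
    }
  }
  ev <- evaluateCohort(evalEntries,
                       masked = isTRUE(config$evaluate$masked),
                       globalSSIM = isTRUE(config$evaluate$global_ssim))
  utils::write.csv(ev$report, file.path(outDir, "report.csv"),
                   row.names = FALSE)
  utils::write.csv(ev$summary, file.path(outDir, "summary.csv"),
                   row.names = FALSE)
  logLine("evaluation: %d rows", nrow(ev$report))
  invisible(list(report = ev$report, summary = ev$summary,
                 histories = histories, outDir = outDir))
}
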