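# Training: tissue-masked L1+gradient loss, deterministic cohort splits,
# reduce-on-plateau learning-rate schedule, the training loop with
# best-checkpoint selection, transfer learning, and whole-volume inference.

#' Tissue-masked L1 + gradient loss
#'
#' The training objective: the mean absolute intensity error over tissue
#' voxels plus the mean absolute error of forward finite differences,
#' averaged over the three axes and over stencils whose two voxels are both
#' tissue. The gradient term rewards agreement of edges and contours that
#' plain MAE underweights. An empty mask yields 0. Evaluated in double
#' precision.
#'
#' @param pred,target numeric arrays of equal shape (2D or 3D).
#' @param mask binary array of the same shape (1 = tissue).
#' @return A non-negative scalar; 0 iff pred equals target on the mask.
#' @examples
#' a <- array(runif(4^3), dim = c(4, 4, 4))
#' maskedL1GradientLoss(a + 0.1, a, array(1, dim = dim(a)))  # exactly 0.1
#' @export
maskedL1GradientLoss <- function(pred, target, mask) {
  if (is.matrix(pred)) {
    pred <- array(pred, dim = c(dim(pred), 1L))
    target <- array(target, dim = dim(pred))
    mask <- array(mask, dim = dim(pred))
  }
  if (!identical(dim(pred), dim(target)) || !identical(dim(pred), dim(mask)))
    stop("shape mismatch between pred, target and mask")
  .cpp_l1grad_loss(pred, target, array(as.double(mask != 0), dim = dim(mask)))
}

#' Deterministically split a cohort
#'
#' Shuffles the ids with the seed and partitions them by the rounded
#' train/validation fractions; the remainder is the test set. A zero
#' validation fraction yields an empty validation group (the adult-cohort
#' convention).
#'
#' @param cohort character vector of ids.
#' @param fractions numeric(3) (train, val, test) summing to 1.
#' @param seed integer seed.
#' @return A [SplitPlan-class].
#' @examples
#' makeSplits(sprintf("s%02d", 1:33), c(0.8, 0, 0.2), seed = 1)  # 26/0/7
#' @export
makeSplits <- function(cohort, fractions, seed = 1L) {
  if (length(cohort) == 0L) stop("empty cohort")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  ids <- sample(cohort)
  n <- length(ids)
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  methods::new("SplitPlan",
               trainIds = ids[seq_len(n_train)],
               valIds = if (n_val > 0) ids[n_train + seq_len(n_val)]
                        else character(),
               testIds = ids[setdiff(seq_len(n), seq_len(n_train + n_val))],
               fractions = as.numeric(fractions))
}

#' Reduce-on-plateau learning-rate schedule
#'
#' Replays the recorded history: starting from \code{lr0}, the rate is
#' divided by e^0.2 (multiplied by \code{lrDecayFactor}) whenever the
#' validation loss has not improved for more than \code{plateauPatience}
#' epochs, never dropping below \code{lrMin}; the patience counter resets
#' on improvement or reduction. Returns the rate to use after the last
#' recorded epoch. Histories without validation losses keep \code{lr0}.
#'
#' @param history a [TrainHistory-class] or a data.frame with a
#'   \code{valLoss} column.
#' @param config a [TrainConfig-class].
#' @return The new learning rate.
#' @export
lrScheduleStep <- function(history, config) {
  h <- if (methods::is(history, "TrainHistory")) history@history else history
  if (nrow(h) < 1L) stop("at least one epoch must be recorded")
  vl <- h$valLoss
  lr <- config@lr0
  if (all(is.na(vl))) return(lr)
  best <- Inf
  wait <- 0L
  for (v in vl) {
    if (is.na(v)) next
    if (v < best) {
      best <- v
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > config@plateauPatience) {
        lr <- max(lr * config@lrDecayFactor, config@lrMin)
        wait <- 0L
      }
    }
  }
  lr
}

# rotate a paired sample (hr, lrUp with shared angles; mask by thresholded
# nearest support) for on-the-fly augmentation
.augmentPair <- function(pair, seed) {
  angles <- withr_seed_runif(seed, 3L, -30, 30)
  hr <- rotateVolume(pair@hr@data, angles)
  lr <- rotateVolume(pair@lrUp@data, angles)
  mk <- rotateVolume(array(as.double(pair@mask@data), dim = dim(pair@mask@data)),
                     angles) >= 0.5
  hr[hr < 0] <- 0; hr[hr > 1] <- 1
  lr[lr < 0] <- 0; lr[lr > 1] <- 1
  list(hr = hr, lr = lr, mask = mk)
}

# gather training patch arrays (x = lrUp, y = hr, m = mask) from a set of
# paired samples, optionally augmented, at the training stride (= size)
.collectPatches <- function(pairs, ids, patchSize, augment, seedBase, epoch) {
  xs <- list(); ys <- list(); ms <- list()
  for (ivol in seq_along(ids)) {
    pair <- pairs[[ids[ivol]]]
    if (augment) {
      rs <- as.integer((as.numeric(seedBase) + 131071 * epoch + 8191 * ivol) %%
                       2147483647)
      aug <- .augmentPair(pair, rs)
      hr <- aug$hr; lr <- aug$lr; mk <- aug$mask
    } else {
      hr <- pair@hr@data; lr <- pair@lrUp@data; mk <- pair@mask@data
    }
    grid <- makeGrid(dim(hr), patchSize, patchSize)
    xs <- c(xs, extractPatches(lr, grid)@patches)
    ys <- c(ys, extractPatches(hr, grid)@patches)
    ms <- c(ms, extractPatches(array(as.double(mk), dim = dim(mk)),
                               grid)@patches)
  }
  list(x = xs, y = ys, m = ms)
}

.stack4d <- function(lst, idx) {
  d <- dim(lst[[idx[1]]])
  out <- array(0, dim = c(d, length(idx)))
  for (i in seq_along(idx)) out[, , , i] <- lst[[idx[i]]]
  out
}

#' Train a super-resolution network
#'
#' Runs mini-batch Adam over patch pairs extracted at the training stride
#' (stride = patch size, no overlap) from the plan's training volumes,
#' with optional on-the-fly rotation augmentation (one randomly rotated
#' copy of each volume per epoch, seeded from (seed, epoch, volume)).
#' After each epoch the validation loss is evaluated and the learning rate
#' follows the reduce-on-plateau schedule. The returned network carries
#' the weights of the epoch with minimal validation loss (earliest on
#' ties); if the plan has no validation group, the final epoch is kept.
#' Fully deterministic given the config seed.
#'
#' @param net an [SRNetwork-class] providing the initialization.
#' @param pairs named list of [PairedSample-class] objects; names (or HR
#'   volume ids) must cover the plan's train and validation ids.
#' @param plan a [SplitPlan-class].
#' @param config a [TrainConfig-class].
#' @param patchSize training patch side for the 3D network (default 32).
#' @param augment logical; rotation augmentation on the training set only
#'   (validation is never augmented).
#' @param verbose print per-epoch losses.
#' @return A list with \code{net} (best checkpoint, [SRNetwork-class]) and
#'   \code{history} ([TrainHistory-class]).
#' @export
trainNetwork <- function(net, pairs, plan, config, patchSize = 32L,
                         augment = TRUE, verbose = FALSE) {
  stopifnot(methods::is(net, "SRNetwork"), methods::is(plan, "SplitPlan"),
            methods::is(config, "TrainConfig"))
  if (is.null(names(pairs)) || any(names(pairs) == ""))
    names(pairs) <- vapply(pairs, function(p) p@hr@id, character(1))
  if (!all(plan@trainIds %in% names(pairs)))
    stop("plan train ids not found among pairs")
  if (length(plan@trainIds) == 0L) stop("empty training set")
  if (config@epochs == 0L) {
    return(list(net = net,
                history = methods::new("TrainHistory",
                                       history = data.frame(epoch = integer(),
                                                            trainLoss = numeric(),
                                                            valLoss = numeric(),
                                                            lr = numeric()),
                                       bestEpoch = 0L)))
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config@seed)

  is2d <- net@spec@dims == 2L
  ptr <- .makeEngine(net)
  # validation patches are fixed across epochs (no augmentation)
  valPatches <- if (length(plan@valIds))
    .collectPatches(pairs, plan@valIds, patchSize, FALSE, 0L, 0L) else NULL

  evalLoss <- function(patches) {
    tot <- 0; nb <- 0L
    idxs <- split(seq_along(patches$x),
                  ceiling(seq_along(patches$x) / config@batchSize))
    for (idx in idxs) {
      tot <- tot + .cpp_unet_eval_loss(ptr, .stack4d(patches$x, idx),
                                       .stack4d(patches$y, idx),
                                       .stack4d(patches$m, idx))
      nb <- nb + 1L
    }
    tot / nb
  }

  hist_df <- data.frame(epoch = integer(), trainLoss = numeric(),
                        valLoss = numeric(), lr = numeric())
  lr <- config@lr0
  bestVal <- Inf
  bestEpoch <- 0L
  bestWeights <- net@weights
  for (epoch in seq_len(config@epochs)) {
    patches <- .collectPatches(pairs, plan@trainIds, patchSize, augment,
                               config@seed, epoch)
    ord <- sample(seq_along(patches$x))
    idxs <- split(ord, ceiling(seq_along(ord) / config@batchSize))
    tot <- 0
    for (idx in idxs) {
      L <- .cpp_unet_train_batch(ptr, .stack4d(patches$x, idx),
                                 .stack4d(patches$y, idx),
                                 .stack4d(patches$m, idx), lr)
      if (!is.finite(L)) stop("divergent training: non-finite loss at epoch ",
                              epoch)
      tot <- tot + L
    }
    trainLoss <- tot / length(idxs)
    valLoss <- if (!is.null(valPatches)) evalLoss(valPatches) else NA_real_
    hist_df <- rbind(hist_df, data.frame(epoch = epoch, trainLoss = trainLoss,
                                         valLoss = valLoss, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %s  lr %.3g", epoch,
                      trainLoss,
                      if (is.na(valLoss)) "NA" else sprintf("%.5f", valLoss),
                      lr))
    if (!is.na(valLoss) && valLoss < bestVal) {
      bestVal <- valLoss
      bestEpoch <- epoch
      bestWeights <- .cpp_unet_get_state(ptr)
    }
    lr <- lrScheduleStep(hist_df, config)
  }
  if (is.null(valPatches)) {
    bestEpoch <- config@epochs
    bestWeights <- .cpp_unet_get_state(ptr)
  }
  outNet <- methods::new("SRNetwork", spec = net@spec, weights = bestWeights,
                         structure = net@structure)
  list(net = outNet,
       history = methods::new("TrainHistory", history = hist_df,
                              bestEpoch = as.integer(bestEpoch)))
}

#' Transfer learning from a pretrained network
#'
#' Initializes every parameter from the base network (all parameters stay
#' trainable) and retrains on the new cohort; with \code{epochs = 0} the
#' base network is returned unchanged. The base must be structurally
#' compatible with the target spec.
#'
#' @param base pretrained [SRNetwork-class].
#' @param pairs,plan,config,patchSize,augment,verbose as in
#'   [trainNetwork()].
#' @param spec optional target [NetworkSpec-class]; when given, the base
#'   must match it structurally.
#' @return As [trainNetwork()].
#' @export
transferLearn <- function(base, pairs, plan, config, patchSize = 32L,
                          augment = TRUE, verbose = FALSE, spec = NULL) {
  stopifnot(methods::is(base, "SRNetwork"))
  if (!is.null(spec)) {
    b <- base@spec
    if (!identical(b@dims, spec@dims) ||
        !identical(b@initialFilters, spec@initialFilters) ||
        !identical(b@stageBlocks, spec@stageBlocks) ||
        !identical(b@convKernel, spec@convKernel) ||
        !identical(b@pool, spec@pool))
      stop("incompatible network structure between base and target spec")
  }
  trainNetwork(base, pairs, plan, config, patchSize = patchSize,
               augment = augment, verbose = verbose)
}

#' Super-resolve a whole volume
#'
#' Decomposes an upsampled, normalized low-resolution volume into
#' overlapping patches (3D network; inference stride = patchSize / 2) or
#' slices (2D network), runs the forward pass, and reassembles the full
#' volume by inner-cube stitching (3D) or restacking (2D). Because the
#' training loss is computed only on tissue voxels, the network's output
#' in the background is unconstrained; when a tissue mask is supplied the
#' output background is therefore homogenized to exactly 0, consistent
#' with the preprocessing applied to every input volume.
#'
#' @param net a trained [SRNetwork-class].
#' @param lrVol [MRIVolume-class], already upsampled to the HR grid and
#'   normalized to [0, 1].
#' @param mask optional [TissueMask-class] for output background
#'   homogenization.
#' @param patchSize inference patch side for the 3D network (default 32).
#' @param sliceAxis slicing axis for the 2D network (default 1).
#' @param batchSize patches/slices per forward call.
#' @return The super-resolved [MRIVolume-class], values in [0, 1].
#' @export
superResolve <- function(net, lrVol, mask = NULL, patchSize = 32L,
                         sliceAxis = 1L, batchSize = 16L) {
  stopifnot(methods::is(net, "SRNetwork"), methods::is(lrVol, "MRIVolume"))
  ptr <- .makeEngine(net)
  d <- dim(lrVol@data)
  if (net@spec@dims == 3L) {
    grid <- makeGrid(d, patchSize, patchSize %/% 2L)
    ps <- extractPatches(lrVol@data, grid)
    outs <- vector("list", length(ps@patches))
    idxs <- split(seq_along(ps@patches),
                  ceiling(seq_along(ps@patches) / batchSize))
    for (idx in idxs) {
      x <- .stack4d(ps@patches, idx)
      .checkDivisible(dim(x)[1:3], net@spec)
      y <- .cpp_unet_predict(ptr, x)
      for (i in seq_along(idx))
        outs[[idx[i]]] <- array(y[, , , i], dim = dim(x)[1:3])
    }
    sr <- stitchPatches(ps, outs)
  } else {
    slices <- extractSlices(lrVol@data, sliceAxis)
    outs <- vector("list", length(slices))
    idxs <- split(seq_along(slices), ceiling(seq_along(slices) / batchSize))
    for (idx in idxs) {
      x <- array(0, dim = c(1L, dim(slices[[1]]), length(idx)))
      for (i in seq_along(idx)) x[1, , , i] <- slices[[idx[i]]]
      .checkDivisible(dim(x)[1:3], net@spec)
      y <- .cpp_unet_predict(ptr, x)
      for (i in seq_along(idx))
        outs[[idx[i]]] <- array(y[1, , , i], dim = dim(slices[[1]]))
    }
    sr <- stackSlices(outs, sliceAxis)
  }
  out <- MRIVolume(sr, spacing = lrVol@spacing,
                   id = paste0(lrVol@id, "-sr"))
  if (!is.null(mask)) out <- homogenizeBackground(out, mask)
  out
}
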