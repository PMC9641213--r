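#' @title Core classes for volumetric super-resolution
#' @name VoxSR-classes
#' @description S4 containers used across the pipeline: intensity volumes,
#'   tissue masks, degradation and network specifications, paired training
#'   samples, patch grids, training configuration and split plans.
NULL

#' MRIVolume: a 3D scalar intensity grid
#'
#' Wraps a 3D array of finite intensities together with its voxel spacing
#' (mm per axis, as stored in a NIfTI header) and a volume identifier.
#' The axis order is the storage order of the array; no anatomical
#' reorientation is applied anywhere in the package.
#'
#' @slot data 3D numeric array of finite intensities.
#' @slot spacing numeric(3), strictly positive voxel size in mm.
#' @slot id character(1) volume identifier.
#' @exportClass MRIVolume
setClass("MRIVolume",
  representation(data = "array", spacing = "numeric", id = "character"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be a 3D array")
    if (!all(is.finite(object@data))) return("all intensities must be finite")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      return("spacing must be 3 strictly positive values")
    if (length(object@id) != 1L) return("id must be a single string")
    TRUE
  })

#' Construct an MRIVolume
#'
#' @param data 3D numeric array.
#' @param spacing voxel size in mm per axis (default 1 mm isotropic).
#' @param id volume identifier.
#' @return An [MRIVolume-class] object.
#' @examples
#' v <- MRIVolume(array(runif(8^3), dim = c(8, 8, 8)), id = "demo")
#' dim(v)
#' @export
MRIVolume <- function(data, spacing = c(1, 1, 1), id = "volume") {
  methods::new("MRIVolume", data = data, spacing = as.numeric(spacing),
               id = as.character(id))
}

#' TissueMask: binary tissue-vs-background grid
#'
#' @slot data 3D logical array, TRUE on tissue.
#' @exportClass TissueMask
setClass("TissueMask",
  representation(data = "array"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("mask must be a 3D array")
    if (!is.logical(object@data)) return("mask values must be logical")
    if (anyNA(object@data)) return("mask must not contain NA")
    TRUE
  })

#' Construct a TissueMask
#' @param data 3D logical (or 0/1) array.
#' @return A [TissueMask-class] object.
#' @export
TissueMask <- function(data) {
  if (!is.logical(data)) {
    if (!all(data %in% c(0, 1))) stop("mask values must be in {0, 1}")
    data <- array(data != 0, dim = dim(data))
  }
  methods::new("TissueMask", data = data)
}

#' NormalizationParams: reference extrema for min-max normalization
#'
#' In simulation, a low-resolution volume is normalized with the extrema of
#' its paired high-resolution image, so both live on the same [0, 1] scale.
#'
#' @slot minRef reference minimum intensity.
#' @slot maxRef reference maximum intensity; must exceed \code{minRef}.
#' @exportClass NormalizationParams
setClass("NormalizationParams",
  representation(minRef = "numeric", maxRef = "numeric"),
  validity = function(object) {
    if (!is.finite(object@minRef) || !is.finite(object@maxRef))
      return("extrema must be finite")
    if (object@maxRef <= object@minRef)
      return("maxRef must be strictly greater than minRef")
    TRUE
  })

#' @rdname NormalizationParams-class
#' @param minRef,maxRef reference extrema.
#' @export
NormalizationParams <- function(minRef, maxRef) {
  methods::new("NormalizationParams", minRef = as.numeric(minRef),
               maxRef = as.numeric(maxRef))
}

#' DegradationSpec: forward degradation model parameters
#'
#' Scaling factor N and the Gaussian smoothing kernel applied before
#' subsampling: a cubic kernel of \code{kernelSize} voxels per side with
#' standard deviation \code{sigma} voxels, normalized to unit sum.
#'
#' @slot factor integer subsampling factor per axis (>= 1).
#' @slot kernelSize odd kernel side length in voxels (default 5).
#' @slot sigma Gaussian standard deviation in voxels (default 1).
#' @exportClass DegradationSpec
setClass("DegradationSpec",
  representation(factor = "integer", kernelSize = "integer", sigma = "numeric"),
  validity = function(object) {
    if (object@factor < 1L) return("factor must be >= 1")
    if (object@kernelSize < 1L || object@kernelSize %% 2L == 0L)
      return("kernelSize must be odd and >= 1")
    if (!is.finite(object@sigma) || object@sigma <= 0)
      return("sigma must be > 0")
    TRUE
  })

#' @rdname DegradationSpec-class
#' @param factor,kernelSize,sigma see slots.
#' @export
DegradationSpec <- function(factor, kernelSize = 5L, sigma = 1.0) {
  methods::new("DegradationSpec", factor = as.integer(factor),
               kernelSize = as.integer(kernelSize), sigma = as.numeric(sigma))
}

#' PairedSample: an (HR, upsampled LR) training pair
#'
#' Both members are normalized to [0, 1] and share one shape; the mask marks
#' tissue voxels of the high-resolution member.
#'
#' @slot hr normalized high-resolution [MRIVolume-class].
#' @slot lrUp normalized, bicubically re-upsampled low-resolution volume.
#' @slot mask [TissueMask-class] aligned to \code{hr}.
#' @slot factor integer scaling factor that produced the pair.
#' @slot params [NormalizationParams-class] taken from the HR image.
#' @exportClass PairedSample
setClass("PairedSample",
  representation(hr = "MRIVolume", lrUp = "MRIVolume", mask = "TissueMask",
                 factor = "integer", params = "NormalizationParams"),
  validity = function(object) {
    if (!identical(dim(object@hr@data), dim(object@lrUp@data)))
      return("hr and lrUp shapes must be equal")
    if (!identical(dim(object@hr@data), dim(object@mask@data)))
      return("mask shape must match hr")
    rng <- range(object@hr@data, object@lrUp@data)
    if (rng[1] < -1e-8 || rng[2] > 1 + 1e-8)
      return("paired volumes must lie within [0, 1]")
    TRUE
  })

#' PatchGrid: origins of cubic patches over a volume
#'
#' Origins are 0-based voxel offsets, sorted lexicographically; each origin
#' plus the patch size stays within the source volume.
#'
#' @slot patchSize integer cube side in voxels.
#' @slot stride integer step between origins (1 <= stride <= patchSize).
#' @slot origins integer matrix (n x 3) of 0-based offsets.
#' @slot sourceShape integer(3) shape of the gridded volume.
#' @exportClass PatchGrid
setClass("PatchGrid",
  representation(patchSize = "integer", stride = "integer",
                 origins = "matrix", sourceShape = "integer"),
  validity = function(object) {
    if (object@stride < 1L || object@stride > object@patchSize)
      return("stride must satisfy 1 <= stride <= patchSize")
    if (ncol(object@origins) != 3L) return("origins must be n x 3")
    if (any(object@origins < 0L))
      return("origins must be non-negative 0-based offsets")
    lim <- rep(object@sourceShape, each = nrow(object@origins))
    if (any(object@origins + object@patchSize >
            matrix(object@sourceShape, nrow(object@origins), 3, byrow = TRUE)))
      return("every origin + patchSize must stay within the volume")
    TRUE
  })

#' PatchSet: patches extracted on a grid
#'
#' @slot patches list of patchSize^3 arrays, aligned 1:1 with grid origins.
#' @slot grid the [PatchGrid-class] used for extraction.
#' @slot sourceShape integer(3) source volume shape.
#' @exportClass PatchSet
setClass("PatchSet",
  representation(patches = "list", grid = "PatchGrid",
                 sourceShape = "integer"),
  validity = function(object) {
    if (length(object@patches) != nrow(object@grid@origins))
      return("number of patches must equal number of grid origins")
    TRUE
  })

#' NetworkSpec: declarative residual U-Net layout
#'
#' Nine stages: four encoder stages, one latent stage, four decoder stages.
#' \code{stageBlocks} gives the number of conv blocks per stage and must be
#' symmetric; the default (2,2,3,3,3,3,3,2,2) yields 23 conv blocks and,
#' with the 4 transposed convolutions and the final 1-kernel head, 28
#' convolutional layers in total.
#'
#' @slot dims 2 or 3 (2D slice network or 3D patch network).
#' @slot initialFilters filters of the first stage (doubled per encoder
#'   stage; default 64).
#' @slot stageBlocks integer(9), conv blocks per stage.
#' @slot convKernel conv kernel side (default 3).
#' @slot pool pooling/upsampling factor per stage (default 2).
#' @exportClass NetworkSpec
setClass("NetworkSpec",
  representation(dims = "integer", initialFilters = "integer",
                 stageBlocks = "integer", convKernel = "integer",
                 pool = "integer"),
  validity = function(object) {
    if (!object@dims %in% c(2L, 3L)) return("dims must be 2 or 3")
    if (length(object@stageBlocks) != 9L)
      return("stageBlocks must have length 9")
    if (!identical(object@stageBlocks, rev(object@stageBlocks)))
      return("stageBlocks must be symmetric")
    if (any(object@stageBlocks < 1L)) return("stageBlocks must be >= 1")
    if (object@initialFilters < 1L) return("initialFilters must be >= 1")
    if (object@pool < 2L) return("pool must be >= 2")
    if (object@convKernel < 1L || object@convKernel %% 2L == 0L)
      return("convKernel must be odd and >= 1")
    TRUE
  })

#' @rdname NetworkSpec-class
#' @param dims,initialFilters,stageBlocks,convKernel,pool see slots.
#' @export
NetworkSpec <- function(dims = 3L, initialFilters = 64L,
                        stageBlocks = c(2L, 2L, 3L, 3L, 3L, 3L, 3L, 2L, 2L),
                        convKernel = 3L, pool = 2L) {
  methods::new("NetworkSpec", dims = as.integer(dims),
               initialFilters = as.integer(initialFilters),
               stageBlocks = as.integer(stageBlocks),
               convKernel = as.integer(convKernel), pool = as.integer(pool))
}

#' SRNetwork: an instantiated residual U-Net
#'
#' Holds the [NetworkSpec-class], all learnable parameters (plus batch-norm
#' running statistics) as named matrices, and an ordered table of layer
#' descriptors used for structural introspection with [countLayers()].
#'
#' @slot spec the [NetworkSpec-class].
#' @slot weights named list of parameter matrices.
#' @slot structure data.frame of ordered layer descriptors.
#' @exportClass SRNetwork
setClass("SRNetwork",
  representation(spec = "NetworkSpec", weights = "list",
                 structure = "data.frame"))

#' TrainConfig: optimization schedule and experiment parameters
#'
#' Defaults follow the reference training protocol: Adam with initial
#' learning rate 1e-4, divided by e^0.2 when the validation loss fails to
#' improve for more than 4 epochs, floored at 1e-5; batch size 12 for the
#' 3D network (8 for 2D).
#'
#' @slot lr0 initial learning rate.
#' @slot lrDecayFactor multiplicative decay on plateau (default exp(-0.2)).
#' @slot plateauPatience epochs without improvement before decay (default 4).
#' @slot lrMin learning-rate floor.
#' @slot epochs training epochs (>= 0; 0 means no retraining).
#' @slot batchSize patches per parameter update.
#' @slot seed integer seed controlling all randomness of a run.
#' @slot factor scaling factor of the experiment (1 allowed for tests).
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(lr0 = "numeric", lrDecayFactor = "numeric",
                 plateauPatience = "integer", lrMin = "numeric",
                 epochs = "integer", batchSize = "integer", seed = "integer",
                 factor = "integer"),
  validity = function(object) {
    if (!(object@lrMin > 0 && object@lrMin <= object@lr0))
      return("0 < lrMin <= lr0 required")
    if (!(object@lrDecayFactor > 0 && object@lrDecayFactor < 1))
      return("lrDecayFactor must be in (0, 1)")
    if (object@epochs < 0L) return("epochs must be >= 0")
    if (object@batchSize < 1L) return("batchSize must be >= 1")
    if (!object@factor %in% 1:4)
      return("factor restricted to {1, 2, 3, 4} (1 allowed for tests)")
    TRUE
  })

#' @rdname TrainConfig-class
#' @param lr0,lrDecayFactor,plateauPatience,lrMin,epochs,batchSize,seed,factor
#'   see slots.
#' @export
TrainConfig <- function(epochs, factor = 2L, lr0 = 1e-4,
                        lrDecayFactor = exp(-0.2), plateauPatience = 4L,
                        lrMin = 1e-5, batchSize = 12L, seed = 1L) {
  methods::new("TrainConfig", lr0 = lr0, lrDecayFactor = lrDecayFactor,
               plateauPatience = as.integer(plateauPatience), lrMin = lrMin,
               epochs = as.integer(epochs), batchSize = as.integer(batchSize),
               seed = as.integer(seed), factor = as.integer(factor))
}

#' SplitPlan: disjoint train/validation/test partition of a cohort
#'
#' @slot trainIds,valIds,testIds disjoint character id vectors.
#' @slot fractions numeric(3) target fractions (train, val, test).
#' @exportClass SplitPlan
setClass("SplitPlan",
  representation(trainIds = "character", valIds = "character",
                 testIds = "character", fractions = "numeric"),
  validity = function(object) {
    all_ids <- c(object@trainIds, object@valIds, object@testIds)
    if (anyDuplicated(all_ids)) return("splits must be disjoint")
    if (length(object@fractions) != 3L) return("fractions must have length 3")
    TRUE
  })

#' TrainHistory: per-epoch losses and learning rates
#'
#' @slot history data.frame with columns epoch, trainLoss, valLoss, lr.
#' @slot bestEpoch epoch minimizing validation loss (earliest on ties);
#'   the final epoch when the plan has no validation group.
#' @exportClass TrainHistory
setClass("TrainHistory",
  representation(history = "data.frame", bestEpoch = "integer"))

#' PhantomSpec: synthetic brain-like phantom parameters
#'
#' Nested smoothed ellipsoid shells (CSF/GM/WM-like) with per-shell base
#' intensity, band-limited texture, optional additive Gaussian noise, and
#' an exactly-zero background. Ground-truth tissue support and shell labels
#' are returned with every phantom.
#'
#' @slot shape integer(3) grid shape, each >= 32.
#' @slot nTissueShells number of nested shells (default 3).
#' @slot intensityLevels increasing base intensities in (0, 1], one per
#'   shell, outermost first.
#' @slot textureScale correlation length (voxels) of the smooth random
#'   texture field; 0 disables texture.
#' @slot noiseSd additive Gaussian noise standard deviation (>= 0).
#' @slot seed integer seed.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(shape = "integer", nTissueShells = "integer",
                 intensityLevels = "numeric", textureScale = "numeric",
                 noiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(object@shape) != 3L || any(object@shape < 32L))
      return("shape must be 3 integers, each >= 32")
    if (length(object@intensityLevels) != object@nTissueShells)
      return("one intensity level per shell required")
    lv <- object@intensityLevels
    if (any(lv <= 0) || any(lv > 1)) return("levels must be in (0, 1]")
    if (any(diff(lv) <= 0)) return("levels must be distinct and increasing")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (object@textureScale < 0) return("textureScale must be >= 0")
    TRUE
  })

#' @rdname PhantomSpec-class
#' @param shape,nTissueShells,intensityLevels,textureScale,noiseSd,seed
#'   see slots.
#' @export
PhantomSpec <- function(shape = c(64L, 64L, 64L), nTissueShells = 3L,
                        intensityLevels = c(0.35, 0.55, 0.8),
                        textureScale = 2.0, noiseSd = 0.01, seed = 1L) {
  methods::new("PhantomSpec", shape = as.integer(shape),
               nTissueShells = as.integer(nTissueShells),
               intensityLevels = as.numeric(intensityLevels),
               textureScale = as.numeric(textureScale),
               noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

# ---- accessors and show methods ----

#' @describeIn MRIVolume-class intensity array
#' @param object,x an object of the documented class.
#' @export
setGeneric("volData", function(object) standardGeneric("volData"))
#' @rdname MRIVolume-class
#' @export
setMethod("volData", "MRIVolume", function(object) object@data)

#' @rdname MRIVolume-class
#' @export
setGeneric("volSpacing", function(object) standardGeneric("volSpacing"))
#' @rdname MRIVolume-class
#' @export
setMethod("volSpacing", "MRIVolume", function(object) object@spacing)

#' @rdname MRIVolume-class
#' @export
setGeneric("volId", function(object) standardGeneric("volId"))
#' @rdname MRIVolume-class
#' @export
setMethod("volId", "MRIVolume", function(object) object@id)

#' @rdname MRIVolume-class
#' @export
setMethod("dim", "MRIVolume", function(x) dim(x@data))

#' @describeIn TissueMask-class logical tissue array
#' @export
setGeneric("maskData", function(object) standardGeneric("maskData"))
#' @rdname TissueMask-class
#' @param object,x a TissueMask.
#' @export
setMethod("maskData", "TissueMask", function(object) object@data)
#' @rdname TissueMask-class
#' @export
setMethod("dim", "TissueMask", function(x) dim(x@data))

setMethod("show", "MRIVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("MRIVolume '%s': %d x %d x %d voxels, spacing %s mm, range [%.4g, %.4g]\n",
              object@id, d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x "),
              min(object@data), max(object@data)))
})

setMethod("show", "TissueMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("TissueMask: %d x %d x %d, %d tissue voxels (%.1f%%)\n",
              d[1], d[2], d[3], sum(object@data),
              100 * mean(object@data)))
})

setMethod("show", "NetworkSpec", function(object) {
  cat(sprintf("NetworkSpec: %dD residual U-Net, %d initial filters, stages [%s], kernel %d, pool %d\n",
              object@dims, object@initialFilters,
              paste(object@stageBlocks, collapse = ","),
              object@convKernel, object@pool))
})

setMethod("show", "SRNetwork", function(object) {
  cc <- countLayers(object)
  cat(sprintf("SRNetwork (%dD): %d stages, %d conv blocks, %d transposed convs, %d conv layers, %d shortcut projections; %d parameter tensors\n",
              object@spec@dims, cc$stages, cc$conv_blocks,
              cc$transposed_convs, cc$total_conv_layers,
              cc$shortcut_projections, length(object@weights)))
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan: %d train / %d validation / %d test\n",
              length(object@trainIds), length(object@valIds),
              length(object@testIds)))
})

setMethod("show", "TrainHistory", function(object) {
  cat(sprintf("TrainHistory: %d epochs, best epoch %d\n",
              nrow(object@history), object@bestEpoch))
  if (nrow(object@history) > 0) print(utils::tail(object@history, 3))
})
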