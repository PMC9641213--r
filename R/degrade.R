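#' Smooth and subsample a volume (forward degradation)
#'
#' Applies the forward degradation model: a normalized cubic Gaussian
#' kernel (\code{kernelSize} voxels per side, standard deviation
#' \code{sigma}) is evaluated at one of each N voxels per axis, so the
#' output shape is \code{floor(dim / N)} and output voxel k reads the input
#' neighborhood centered at index k*N (0-based, anchored at voxel 0).
#' Borders are handled by symmetric reflection. Equivalent to dense
#' Gaussian convolution followed by strided decimation.
#'
#' @param vol an [MRIVolume-class]; every dimension must be at least
#'   \code{kernelSize}.
#' @param spec a [DegradationSpec-class].
#' @return The degraded [MRIVolume-class]; spacing is multiplied by N.
#' @examples
#' v <- MRIVolume(array(runif(20^3), dim = c(20, 20, 20)))
#' dim(smoothSubsample(v, DegradationSpec(2)))
#' @export
smoothSubsample <- function(vol, spec) {
  stopifnot(methods::is(vol, "MRIVolume"), methods::is(spec, "DegradationSpec"))
  d <- dim(vol@data)
  if (any(d < spec@kernelSize))
    stop("volume smaller than the smoothing kernel (", spec@kernelSize,
         " voxels)")
  out <- .cpp_gauss_subsample(vol@data, spec@factor, spec@kernelSize,
                              spec@sigma)
  MRIVolume(array(out, dim = d %/% spec@factor),
            spacing = vol@spacing * spec@factor, id = vol@id)
}

#' Upsample a volume with tricubic interpolation
#'
#' Separable order-3 (cubic-convolution) interpolation per axis to the
#' target shape, the 3D reading of bicubic-spline upsampling. This is the
#' operator that brings a low-resolution volume back to the
#' high-resolution grid before it is fed to the network. The grid mapping
#' is anchored at index 0, the inverse of the degradation model's
#' decimation anchor, so the upsampled volume is registered to the
#' high-resolution grid with no sub-voxel shift: output voxel i reads
#' input coordinate i / factor (i times inShape/outShape when no factor
#' is given).
#'
#' @param vol an [MRIVolume-class].
#' @param targetShape integer(3), componentwise >= the input shape.
#' @param factor optional integer subsampling factor that produced the
#'   input; fixes the exact grid step even when the target shape is not a
#'   multiple of the input shape.
#' @return The upsampled [MRIVolume-class].
#' @export
upsampleBicubic <- function(vol, targetShape, factor = NULL) {
  stopifnot(methods::is(vol, "MRIVolume"))
  targetShape <- as.integer(targetShape)
  if (any(targetShape < dim(vol@data)))
    stop("targetShape must be componentwise >= the input shape")
  d <- dim(vol@data)
  step <- if (is.null(factor)) d / targetShape else rep(1 / factor, 3)
  out <- .cpp_resize_cubic_origin(vol@data, targetShape[1], targetShape[2],
                                  targetShape[3], step[1], step[2], step[3])
  MRIVolume(array(out, dim = targetShape),
            spacing = vol@spacing * d / targetShape, id = vol@id)
}

#' Simulate a paired (HR, upsampled-LR) training sample
#'
#' Runs the full low-resolution simulation chain on a
#' background-homogenized high-resolution volume: Gaussian smoothing +
#' subsampling at the spec's factor, tricubic upsampling back to the HR
#' shape, and min-max normalization of both members using the HR extrema
#' as the common reference.
#'
#' @param hr background-homogenized high-resolution [MRIVolume-class].
#' @param mask [TissueMask-class] aligned to \code{hr}.
#' @param spec a [DegradationSpec-class].
#' @param noiseSd optional additive Gaussian noise injected into the
#'   low-resolution image before upsampling (default 0: the simulation
#'   chain itself adds no noise beyond interpolation error).
#' @return A [PairedSample-class].
#' @export
simulatePair <- function(hr, mask, spec, noiseSd = 0) {
  stopifnot(methods::is(hr, "MRIVolume"), methods::is(mask, "TissueMask"))
  if (!identical(dim(hr@data), dim(mask@data)))
    stop("shape mismatch between hr and mask")
  r <- range(hr@data)
  if (r[2] <= r[1]) stop("constant volume cannot be paired")
  params <- NormalizationParams(r[1], r[2])
  lr <- smoothSubsample(hr, spec)
  if (noiseSd > 0) {
    lr@data <- lr@data + array(stats::rnorm(length(lr@data), sd = noiseSd),
                               dim = dim(lr@data))
  }
  lr_up <- upsampleBicubic(lr, dim(hr@data), factor = spec@factor)
  methods::new("PairedSample",
               hr = minmaxNormalize(hr, params),
               lrUp = minmaxNormalize(lr_up, params),
               mask = mask, factor = spec@factor, params = params)
}
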