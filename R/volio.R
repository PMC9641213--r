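#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file into an [MRIVolume-class], casting intensities to
#' double and taking the voxel spacing from the header. Only 3D images are
#' accepted.
#'
#' @param path path to a .nii or .nii.gz file.
#' @param id volume identifier; defaults to the file name without extension.
#' @return An [MRIVolume-class].
#' @export
readVolume <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  d <- dim(img)
  if (length(d) != 3L) {
    stop("non-3D image: '", path, "' has ", length(d), " dimensions")
  }
  if (is.null(id)) {
    id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(1, 1, 1)
  MRIVolume(array(as.double(img), dim = d), spacing = sp, id = id)
}

#' Write an MRIVolume or TissueMask to NIfTI
#'
#' Volumes are stored as float32; masks as uint8. Voxel spacing is written
#' into the header.
#'
#' @param x an [MRIVolume-class] or [TissueMask-class].
#' @param path output file path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
writeVolume <- function(x, path) {
  if (methods::is(x, "TissueMask")) {
    img <- RNifti::asNifti(array(as.integer(x@data), dim = dim(x@data)))
    RNifti::pixdim(img) <- c(1, 1, 1)
    RNifti::writeNifti(img, path, datatype = "uint8")
  } else {
    stopifnot(methods::is(x, "MRIVolume"))
    img <- RNifti::asNifti(x@data)
    RNifti::pixdim(img) <- x@spacing
    RNifti::writeNifti(img, path, datatype = "float")
  }
  invisible(path)
}

#' Read a NIfTI mask
#' @param path path to a mask NIfTI file.
#' @return A [TissueMask-class].
#' @export
readMask <- function(path) {
  v <- readVolume(path)
  TissueMask(v@data != 0)
}

#' Zero-pad a volume to a cube
#'
#' Pads every axis with zeros so the output is \code{target^3}, keeping the
#' original data centered. When the deficit along an axis is odd, the extra
#' zero plane goes on the trailing side (a fixed convention so patch and
#' stitching coordinates are reproducible).
#'
#' @param vol an [MRIVolume-class].
#' @param target cube side length; every input dimension must be <= target.
#' @return A padded [MRIVolume-class]; padded voxels are exactly 0.
#' @examples
#' v <- MRIVolume(array(1, dim = c(30, 32, 32)))
#' dim(padToCube(v, 32))
#' @export
padToCube <- function(vol, target) {
  stopifnot(methods::is(vol, "MRIVolume"))
  target <- as.integer(target)
  d <- dim(vol@data)
  if (any(d > target))
    stop("dimension exceeds target (", paste(d, collapse = "x"), " > ",
         target, "); resize first")
  lo <- (target - d) %/% 2L
  out <- array(0, dim = rep(target, 3L))
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <-
    vol@data
  MRIVolume(out, spacing = vol@spacing, id = vol@id)
}

#' Resize a volume by cubic interpolation
#'
#' Separable cubic-convolution (Catmull-Rom) resampling to an arbitrary
#' target shape, with pixel-center grid alignment. Voxel spacing is
#' rescaled so physical extent is preserved.
#'
#' @param vol an [MRIVolume-class].
#' @param targetShape integer(3), all positive.
#' @return The resampled [MRIVolume-class].
#' @export
resizeVolume <- function(vol, targetShape) {
  stopifnot(methods::is(vol, "MRIVolume"))
  targetShape <- as.integer(targetShape)
  if (length(targetShape) != 3L || any(targetShape < 1L))
    stop("targetShape must be 3 positive integers")
  d <- dim(vol@data)
  out <- .cpp_resize_cubic(vol@data, targetShape[1], targetShape[2],
                           targetShape[3])
  MRIVolume(array(out, dim = targetShape),
            spacing = vol@spacing * d / targetShape, id = vol@id)
}

# Global Otsu threshold from a 256-bin histogram.
.otsuThreshold <- function(x) {
  r <- range(x)
  br <- seq(r[1], r[2], length.out = 257L)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1] + br[-257]) / 2
  mu <- cumsum(p * mids)
  muT <- mu[256]
  denom <- omega * (1 - omega)
  sigma2 <- (muT * omega - mu)^2 / ifelse(denom > 0, denom, NA)
  k <- which.max(sigma2)
  mids[k]
}

#' Compute a binary tissue mask
#'
#' Global Otsu thresholding, followed by extraction of the largest
#' 6-connected above-threshold component, morphological closing with a
#' 3-voxel cubic structuring element, and interior hole filling.
#'
#' @param vol a non-constant [MRIVolume-class].
#' @return A [TissueMask-class].
#' @export
computeTissueMask <- function(vol) {
  stopifnot(methods::is(vol, "MRIVolume"))
  x <- vol@data
  if (diff(range(x)) == 0) stop("cannot threshold constant image")
  thr <- .otsuThreshold(as.vector(x))
  m <- as.vector(x > thr)
  d <- dim(x)
  m <- .cpp_largest_component(m, d)
  m <- .cpp_binary_dilate(m, d, 3L)
  m <- .cpp_binary_erode(m, d, 3L)
  m <- .cpp_fill_holes(m, d)
  TissueMask(array(m, dim = d))
}

#' Homogenize the background of a volume
#'
#' Sets voxels outside the mask to exactly 0; tissue voxels are unchanged.
#' Idempotent.
#'
#' @param vol an [MRIVolume-class].
#' @param mask a [TissueMask-class] of the same shape.
#' @return The background-homogenized [MRIVolume-class].
#' @export
homogenizeBackground <- function(vol, mask) {
  stopifnot(methods::is(vol, "MRIVolume"), methods::is(mask, "TissueMask"))
  if (!identical(dim(vol@data), dim(mask@data)))
    stop("shape mismatch between volume and mask")
  out <- vol@data
  out[!mask@data] <- 0
  MRIVolume(out, spacing = vol@spacing, id = vol@id)
}

#' Min-max normalize a volume
#'
#' Maps intensities through \code{(v - minRef) / (maxRef - minRef)} and
#' clips to [0, 1]. With the volume's own extrema (the default), the output
#' attains exactly 0 and 1. In simulation, low-resolution volumes are
#' normalized with the extrema of their paired high-resolution image;
#' values pushed outside [0, 1] by that reference are clipped, keeping the
#' codomain consistent with the network's sigmoid head. At inference on a
#' genuine LR volume with no HR counterpart, the volume's own extrema are
#' the only definable reference.
#'
#' @param vol an [MRIVolume-class].
#' @param params a [NormalizationParams-class]; defaults to the volume's
#'   own extrema.
#' @return The normalized [MRIVolume-class] with values in [0, 1].
#' @export
minmaxNormalize <- function(vol, params = NULL) {
  stopifnot(methods::is(vol, "MRIVolume"))
  if (is.null(params)) {
    r <- range(vol@data)
    if (r[2] <= r[1]) stop("degenerate normalization: constant volume")
    params <- NormalizationParams(r[1], r[2])
  }
  out <- (vol@data - params@minRef) / (params@maxRef - params@minRef)
  out[out < 0] <- 0
  out[out > 1] <- 1
  MRIVolume(out, spacing = vol@spacing, id = vol@id)
}
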