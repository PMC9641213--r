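#' Build a patch grid over a volume shape
#'
#' Origins along each axis are \code{0, stride, 2*stride, ...} (0-based),
#' with the final origin clamped to \code{dim - patchSize} so coverage is
#' complete; duplicates created by clamping are removed. Training uses
#' stride = patchSize (no overlap); inference uses stride = patchSize / 2.
#'
#' @param shape integer(3) volume shape; every dimension >= patchSize.
#' @param patchSize cubic patch side (default 32).
#' @param stride step between origins, 1 <= stride <= patchSize.
#' @return A [PatchGrid-class] with lexicographically sorted origins.
#' @examples
#' nrow(makeGrid(c(256, 256, 256), 32, 32)@origins)  # 512
#' nrow(makeGrid(c(256, 256, 256), 32, 16)@origins)  # 3375
#' @export
makeGrid <- function(shape, patchSize = 32L, stride = patchSize) {
  shape <- as.integer(shape); patchSize <- as.integer(patchSize)
  stride <- as.integer(stride)
  if (any(shape < patchSize))
    stop("volume dimension smaller than patch size (", patchSize, ")")
  ax <- lapply(shape, function(d) {
    o <- seq.int(0L, d - patchSize, by = stride)
    if (o[length(o)] != d - patchSize) o <- c(o, d - patchSize)
    unique(o)
  })
  g <- as.matrix(expand.grid(a3 = ax[[3]], a2 = ax[[2]], a1 = ax[[1]]))
  origins <- cbind(g[, "a1"], g[, "a2"], g[, "a3"])
  origins <- origins[order(origins[, 1], origins[, 2], origins[, 3]),
                     , drop = FALSE]
  storage.mode(origins) <- "integer"
  dimnames(origins) <- NULL
  methods::new("PatchGrid", patchSize = patchSize, stride = stride,
               origins = origins, sourceShape = shape)
}

#' Extract cubic patches on a grid
#'
#' @param vol an [MRIVolume-class] (or bare 3D array).
#' @param grid a [PatchGrid-class] valid for the volume's shape.
#' @return A [PatchSet-class]; patch i is the unmodified sub-grid at
#'   origin i.
#' @export
extractPatches <- function(vol, grid) {
  x <- if (methods::is(vol, "MRIVolume")) vol@data else vol
  if (!identical(dim(x), as.integer(grid@sourceShape)) &&
      !identical(as.integer(dim(x)), grid@sourceShape))
    stop("grid was built for a different volume shape")
  p <- grid@patchSize
  patches <- lapply(seq_len(nrow(grid@origins)), function(i) {
    o <- grid@origins[i, ]
    x[o[1] + seq_len(p), o[2] + seq_len(p), o[3] + seq_len(p)]
  })
  methods::new("PatchSet", patches = patches, grid = grid,
               sourceShape = grid@sourceShape)
}

#' Extract 2D slices along an axis
#'
#' One 2D grid per index along the slicing axis, order preserved. The 2D
#' network consumes complete slices, so the two in-plane dimensions can be
#' checked against the expected network input size.
#'
#' @param vol an [MRIVolume-class] (or 3D array).
#' @param axis slicing axis (1, 2 or 3); default 1, the zero-padded axis.
#' @param inPlane optional integer(2); if given, the in-plane dimensions
#'   must match exactly.
#' @return A list of 2D matrices.
#' @export
extractSlices <- function(vol, axis = 1L, inPlane = NULL) {
  x <- if (methods::is(vol, "MRIVolume")) vol@data else vol
  axis <- as.integer(axis)
  stopifnot(axis %in% 1:3)
  d <- dim(x)
  if (!is.null(inPlane) && !identical(as.integer(d[-axis]),
                                      as.integer(inPlane)))
    stop("wrong in-plane size: expected ", paste(inPlane, collapse = "x"),
         ", got ", paste(d[-axis], collapse = "x"))
  lapply(seq_len(d[axis]), function(i) {
    switch(axis,
           x[i, , , drop = TRUE],
           x[, i, , drop = TRUE],
           x[, , i, drop = TRUE])
  })
}

#' Restack slices into a volume
#' @param slices list of 2D matrices from [extractSlices()].
#' @param axis the axis they were extracted along.
#' @return A 3D array.
#' @export
stackSlices <- function(slices, axis = 1L) {
  d2 <- dim(slices[[1]])
  n <- length(slices)
  d <- switch(axis, c(n, d2), c(d2[1], n, d2[2]), c(d2, n))
  out <- array(0, dim = d)
  for (i in seq_len(n)) {
    switch(axis,
           out[i, , ] <- slices[[i]],
           out[, i, ] <- slices[[i]],
           out[, , i] <- slices[[i]])
  }
  out
}

#' Randomly rotate a volume (augmentation)
#'
#' Draws three angles uniformly from [-30, 30] degrees, one per rotation
#' plane — (1,2), (1,3), then (2,3), applied successively in that fixed
#' order — about the volume center, with cubic interpolation and zero fill
#' outside the grid. Deterministic given the seed.
#'
#' @param vol an [MRIVolume-class] (or 3D array).
#' @param seed integer seed.
#' @param maxAngle half-width of the angle interval in degrees (default 30,
#'   the maximum plausible subject shift inside the scanner bore).
#' @return The rotated volume, same class as the input.
#' @export
randomRotate <- function(vol, seed, maxAngle = 30) {
  x <- if (methods::is(vol, "MRIVolume")) vol@data else vol
  angles <- withr_seed_runif(seed, 3L, -maxAngle, maxAngle)
  y <- rotateVolume(x, angles)
  if (methods::is(vol, "MRIVolume"))
    MRIVolume(y, spacing = vol@spacing, id = vol@id)
  else y
}

# uniform draws under a local RNG state, leaving the global stream intact
withr_seed_runif <- function(seed, n, lo, hi) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::runif(n, lo, hi)
}

#' Rotate a volume by fixed plane angles
#'
#' @param x 3D array.
#' @param angles numeric(3): degrees for planes (1,2), (1,3), (2,3).
#' @return Rotated 3D array (cubic interpolation, zero fill).
#' @export
rotateVolume <- function(x, angles) {
  stopifnot(length(angles) == 3L)
  planes <- list(c(0L, 1L), c(0L, 2L), c(1L, 2L))
  for (i in 1:3) {
    if (angles[i] != 0)
      x <- array(.cpp_rotate_plane(x, planes[[i]][1], planes[[i]][2],
                                   angles[i]), dim = dim(x))
  }
  x
}

#' Stitch patch predictions into a whole volume
#'
#' Inner-cube fusion for overlapping inference patches (stride =
#' patchSize / 2): each patch contributes only its central cube of side
#' \code{stride}, except that patches touching a volume face also keep
#' their outer margin on that face, so the full volume is covered. Every
#' voxel is written exactly once; incomplete coverage or a double write is
#' an internal error.
#'
#' @param patchSet the [PatchSet-class] the inputs were extracted with
#'   (supplies the grid and source shape).
#' @param outputs list of model-output patches aligned 1:1 with the grid
#'   origins; defaults to the input patches (identity model).
#' @return A 3D array of the stitched volume.
#' @export
stitchPatches <- function(patchSet, outputs = NULL) {
  stopifnot(methods::is(patchSet, "PatchSet"))
  grid <- patchSet@grid
  p <- grid@patchSize
  s <- grid@stride
  if (2L * s != p)
    stop("stitching requires the inference convention stride = patchSize/2")
  if (is.null(outputs)) outputs <- patchSet@patches
  if (length(outputs) != nrow(grid@origins))
    stop("outputs must align 1:1 with grid origins")
  shape <- grid@sourceShape
  out <- array(0, dim = shape)
  count <- array(0L, dim = shape)
  half <- s %/% 2L
  for (i in seq_len(nrow(grid@origins))) {
    o <- grid@origins[i, ]
    lo <- integer(3); hi <- integer(3)
    for (a in 1:3) {
      lo[a] <- if (o[a] == 0L) 0L else half
      hi[a] <- if (o[a] == shape[a] - p) p else half + s
    }
    blk <- outputs[[i]][(lo[1] + 1):hi[1], (lo[2] + 1):hi[2],
                        (lo[3] + 1):hi[3], drop = FALSE]
    ix <- (o[1] + lo[1] + 1):(o[1] + hi[1])
    iy <- (o[2] + lo[2] + 1):(o[2] + hi[2])
    iz <- (o[3] + lo[3] + 1):(o[3] + hi[3])
    out[ix, iy, iz] <- blk
    count[ix, iy, iz] <- count[ix, iy, iz] + 1L
  }
  if (any(count != 1L))
    stop("internal stitching error: coverage map is not exactly 1 ",
         "(volume dimensions must be multiples of the stride)")
  out
}
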