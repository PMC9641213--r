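# Residual U-Net construction, forward passes, structural introspection
# and checkpointing. The numerical engine lives in compiled code; an
# SRNetwork object holds the spec, all parameters as named matrices, and
# an ordered layer-descriptor table.

# walk the spec and emit one row per structural element, in network order
.buildStructure <- function(spec) {
  f0 <- spec@initialFilters
  rows <- list()
  add <- function(stage, role, type, cin, cout, kernel) {
    rows[[length(rows) + 1L]] <<- data.frame(
      stage = stage, role = role, type = type, channels_in = cin,
      channels_out = cout, kernel = kernel, stringsAsFactors = FALSE)
  }
  for (s in 1:4) {
    cin <- if (s == 1) 1L else f0 * 2L^(s - 2L)
    cout <- f0 * 2L^(s - 1L)
    for (b in seq_len(spec@stageBlocks[s]))
      add(s, "encoder", "conv_block", if (b == 1) cin else cout, cout,
          spec@convKernel)
    add(s, "encoder", "shortcut_projection", cin, cout, 1L)
    add(s, "encoder", "max_pool", cout, cout, spec@pool)
  }
  cin <- f0 * 8L; cout <- f0 * 16L
  for (b in seq_len(spec@stageBlocks[5]))
    add(5L, "latent", "conv_block", if (b == 1) cin else cout, cout,
        spec@convKernel)
  for (s in 1:4) {
    cin <- if (s == 1) f0 * 16L else f0 * 2L^(5L - s)
    g <- f0 * 2L^(4L - s)
    add(5L + s, "decoder", "transposed_conv", cin, g, spec@pool)
    add(5L + s, "decoder", "skip_concatenation", 2L * g, 2L * g, NA_integer_)
    for (b in seq_len(spec@stageBlocks[5L + s]))
      add(5L + s, "decoder", "conv_block", if (b == 1) 2L * g else g, g,
          spec@convKernel)
    add(5L + s, "decoder", "shortcut_projection", g, g, 1L)
  }
  add(9L, "head", "head_conv", f0, 1L, 1L)
  do.call(rbind, rows)
}

# instantiate the compiled engine for a network (fresh Adam state)
.makeEngine <- function(net, seed = 0) {
  ptr <- .cpp_unet_create(net@spec@dims, net@spec@initialFilters,
                          net@spec@stageBlocks, net@spec@convKernel,
                          net@spec@pool, seed)
  if (length(net@weights)) .cpp_unet_set_state(ptr, net@weights)
  ptr
}

#' Build a residual U-Net from its specification
#'
#' Instantiates the 9-stage residual U-Net: four encoder stages
#' (filters doubling from \code{initialFilters}), a latent stage, and four
#' decoder stages (filters halving), each stage made of conv blocks
#' (convolution, batch normalization, ReLU). A residual shortcut — the
#' stage input projected by a 1-kernel convolution and added elementwise
#' to the stage output — sits before each max pooling and after each
#' transposed convolution; skip connections concatenate each decoder
#' stage with its homologous encoder stage; the head is a 1-kernel
#' convolution with a sigmoid, bounding outputs to [0, 1]. Weights are
#' randomly initialized with fan-in scaling, deterministically in the
#' seed. The 2D and 3D variants differ only in kernel dimensionality.
#'
#' @param spec a [NetworkSpec-class].
#' @param seed integer weight-initialization seed.
#' @return An [SRNetwork-class].
#' @examples
#' net <- buildNetwork(NetworkSpec(initialFilters = 2L))
#' countLayers(net)
#' @export
buildNetwork <- function(spec, seed = 1L) {
  methods::validObject(spec)
  ptr <- .cpp_unet_create(spec@dims, spec@initialFilters, spec@stageBlocks,
                          spec@convKernel, spec@pool, seed)
  methods::new("SRNetwork", spec = spec, weights = .cpp_unet_get_state(ptr),
               structure = .buildStructure(spec))
}

#' Count structural elements of a network
#'
#' Counts are derived by walking the network's ordered layer-descriptor
#' table, not hard-coded. \code{total_conv_layers} counts conv blocks,
#' transposed convolutions and the head; the 1-kernel shortcut projections
#' are tallied separately.
#'
#' @param net an [SRNetwork-class].
#' @return A list with \code{stages}, \code{conv_blocks},
#'   \code{transposed_convs}, \code{total_conv_layers},
#'   \code{shortcut_projections}.
#' @export
countLayers <- function(net) {
  st <- net@structure
  list(stages = length(unique(st$stage)),
       conv_blocks = sum(st$type == "conv_block"),
       transposed_convs = sum(st$type == "transposed_conv"),
       total_conv_layers = sum(st$type %in%
                               c("conv_block", "transposed_conv", "head_conv")),
       shortcut_projections = sum(st$type == "shortcut_projection"))
}

# normalize input batches to a (d1, d2, d3, B) array; 2D inputs become
# degenerate-depth volumes (1, h, w)
.batchToArray <- function(batch, dims) {
  if (!is.list(batch)) batch <- list(batch)
  shp <- lapply(batch, function(b) {
    d <- dim(b)
    if (dims == 2L) {
      if (length(d) != 2L) stop("2D network expects 2D slices")
      c(1L, d)
    } else {
      if (length(d) != 3L) stop("3D network expects 3D patches")
      d
    }
  })
  if (length(unique(shp)) != 1L) stop("all batch items must share one shape")
  d <- shp[[1]]
  x <- array(0, dim = c(d, length(batch)))
  for (i in seq_along(batch)) x[, , , i] <- batch[[i]]
  x
}

.checkDivisible <- function(d, spec) {
  div <- spec@pool^4L
  sp <- if (spec@dims == 2L) d[2:3] else d
  if (any(sp %% div != 0L))
    stop("input spatial dimensions (", paste(sp, collapse = "x"),
         ") must be divisible by ", div, " (four pooling stages)")
}

#' Run a forward pass
#'
#' Evaluation-mode (deterministic) forward pass over a batch of patches
#' (3D network) or slices (2D network). Spatial dimensions must be
#' divisible by \code{pool^4} = 16 for the default spec.
#'
#' @param net an [SRNetwork-class].
#' @param batch a single patch/slice or a list of them, all one shape.
#' @return A list of output grids, same spatial shapes, values in [0, 1].
#' @export
forwardPass <- function(net, batch) {
  single <- !is.list(batch)
  x <- .batchToArray(batch, net@spec@dims)
  .checkDivisible(dim(x)[1:3], net@spec)
  ptr <- .makeEngine(net)
  y <- .cpp_unet_predict(ptr, x)
  out <- lapply(seq_len(dim(y)[4]), function(i) {
    z <- y[, , , i, drop = FALSE]
    if (net@spec@dims == 2L) array(z, dim = dim(y)[2:3])
    else array(z, dim = dim(y)[1:3])
  })
  if (single) out[[1]] else out
}

#' Save a network checkpoint
#'
#' Writes the spec and all parameters (RDS) plus a JSON structure manifest
#' (spec fields and structural counts) for cross-checking.
#'
#' @param net an [SRNetwork-class].
#' @param path checkpoint path (.rds); the manifest is written alongside
#'   with extension .json.
#' @return \code{path}, invisibly.
#' @export
saveCheckpoint <- function(net, path) {
  spec <- net@spec
  obj <- list(spec = list(dims = spec@dims,
                          initialFilters = spec@initialFilters,
                          stageBlocks = spec@stageBlocks,
                          convKernel = spec@convKernel, pool = spec@pool),
              weights = net@weights)
  saveRDS(obj, path)
  manifest <- c(obj$spec, countLayers(net))
  jsonlite::write_json(manifest, sub("\\.rds$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a network checkpoint
#' @param path path written by [saveCheckpoint()].
#' @return An [SRNetwork-class].
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  spec <- NetworkSpec(dims = obj$spec$dims,
                      initialFilters = obj$spec$initialFilters,
                      stageBlocks = obj$spec$stageBlocks,
                      convKernel = obj$spec$convKernel, pool = obj$spec$pool)
  methods::new("SRNetwork", spec = spec, weights = obj$weights,
               structure = .buildStructure(spec))
}
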