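#' Specify a synthetic tube phantom
#'
#' A tube phantom is a stack of 2-D label images in which each "neurite" is a
#' disk of fixed radius per slice, following a per-slice center track. Phantoms
#' provide exact ground truth for contact quantification: every pixel's label
#' is known analytically from the disk geometry.
#'
#' @param n_slices number of z slices.
#' @param image_shape integer pair (height, width) in pixels.
#' @param tubes list of tubes, each a list with elements `label` (unique
#'   positive integer), `centers` (an `n_slices` x 2 matrix of (row, col)
#'   pixel coordinates, or a single (row, col) pair reused on every slice) and
#'   `radius` (positive, pixels).
#' @param pixel_size x-y pixel size in nm.
#' @param z_spacing slice spacing in nm.
#' @return an object of class `tube_phantom_spec`.
#' @seealso [make_tube_phantom()]
#' @export
tube_phantom_spec <- function(n_slices, image_shape, tubes,
                              pixel_size, z_spacing) {
  stop_if(n_slices < 1, "n_slices must be positive")
  stop_if(length(image_shape) != 2 || any(image_shape < 1),
          "image_shape must be two positive integers")
  stop_if(pixel_size <= 0 || z_spacing <= 0,
          "pixel_size and z_spacing must be positive")
  labels <- vapply(tubes, function(t) as.integer(t$label), integer(1))
  stop_if(any(labels <= 0), "tube labels must be > 0")
  stop_if(anyDuplicated(labels) > 0, "tube labels must be unique")
  tubes <- lapply(tubes, function(t) {
    stop_if(t$radius <= 0, "tube radii must be positive")
    if (is.null(dim(t$centers))) t$centers <- matrix(t$centers, n_slices, 2,
                                                     byrow = TRUE)
    stop_if(nrow(t$centers) != n_slices, "centers must have one row per slice")
    t
  })
  structure(list(n_slices = as.integer(n_slices),
                 image_shape = as.integer(image_shape),
                 tubes = tubes,
                 pixel_size = pixel_size, z_spacing = z_spacing),
            class = "tube_phantom_spec")
}

#' Rasterize a tube phantom into a label volume
#'
#' Pixel (z, r, c) receives the label of the tube whose disk contains it
#' (Euclidean distance from the pixel center to the tube center `<=` radius),
#' and 0 otherwise. Overlapping disks are rejected: labels are exclusive per
#' pixel, as in EM segmentations.
#'
#' @param spec a [tube_phantom_spec()].
#' @return a [label_volume()].
#' @export
make_tube_phantom <- function(spec) {
  stopifnot(inherits(spec, "tube_phantom_spec"))
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  slices <- vector("list", spec$n_slices)
  for (z in seq_len(spec$n_slices)) {
    img <- matrix(0L, h, w)
    for (tube in spec$tubes) {
      ctr <- tube$centers[z, ]
      inside <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= tube$radius^2
      clash <- inside & img != 0L
      if (any(clash)) {
        other <- unique(img[clash])
        stop(sprintf(
          "overlapping disks on slice %d: labels %s and %d share pixels",
          z, paste(other, collapse = ","), tube$label), call. = FALSE)
      }
      img[inside] <- as.integer(tube$label)
    }
    slices[[z]] <- img
  }
  label_volume(slices, pixel_size = spec$pixel_size,
               z_spacing = spec$z_spacing)
}

#' Specify a planted-block adjacency matrix
#'
#' Planted-block matrices emulate the stratified structure of real
#' contactomes: contact quantities within a block are drawn from a
#' high-mean distribution and between blocks from a low-mean one, so the
#' block labels are recoverable ground truth for clustering.
#'
#' @param block_sizes integer vector of block sizes (each >= 2, at least 2
#'   blocks for recovery tests).
#' @param within_mean,within_sd Gaussian parameters for within-block weights.
#' @param between_mean,between_sd Gaussian parameters for between-block
#'   weights.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return an object of class `planted_adjacency_spec`.
#' @export
planted_adjacency_spec <- function(block_sizes,
                                   within_mean = 100, within_sd = 10,
                                   between_mean = 1, between_sd = 1,
                                   seed = 1L) {
  stop_if(length(block_sizes) < 2, "need at least 2 blocks")
  stop_if(any(block_sizes < 2), "each block must have size >= 2")
  stop_if(any(block_sizes != round(block_sizes)) || any(block_sizes <= 0),
          "block sizes must be positive integers")
  structure(list(block_sizes = as.integer(block_sizes),
                 within_mean = within_mean, within_sd = within_sd,
                 between_mean = between_mean, between_sd = between_sd,
                 seed = as.integer(seed)),
            class = "planted_adjacency_spec")
}

#' Generate a planted-block adjacency matrix
#'
#' Draws symmetric nonnegative weights (negatives clipped to 0: contact
#' quantities are counts) with zero diagonal. Deterministic under the spec's
#' seed; no global RNG state is left behind.
#'
#' @param spec a [planted_adjacency_spec()].
#' @return a list with `adjacency` (labeled symmetric matrix) and
#'   `ground_truth` (integer block id per node, named by node label).
#' @export
make_planted_adjacency <- function(spec) {
  stopifnot(inherits(spec, "planted_adjacency_spec"))
  n <- sum(spec$block_sizes)
  blocks <- rep(seq_along(spec$block_sizes), spec$block_sizes)
  A <- matrix(0, n, n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(spec$seed)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      w <- if (blocks[i] == blocks[j]) {
        stats::rnorm(1, spec$within_mean, spec$within_sd)
      } else {
        stats::rnorm(1, spec$between_mean, spec$between_sd)
      }
      A[i, j] <- A[j, i] <- max(0, w)
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  labs <- sprintf("n%03d", seq_len(n))
  dimnames(A) <- list(labs, labs)
  names(blocks) <- labs
  list(adjacency = A, ground_truth = blocks)
}

#' Generate labeled Gaussian blobs
#'
#' Unit-test input for the condensation loop: points scatter around known
#' centers, so merge order is predictable (well-separated blobs condense
#' internally before any cross-blob merge).
#'
#' @param blob_centers numeric matrix, one center per row.
#' @param n_per_blob points per blob.
#' @param sd isotropic Gaussian standard deviation (>= 0).
#' @param seed integer seed.
#' @return numeric matrix of points with rownames `b<blob>_<i>` and an
#'   attribute `blob` giving the generating blob of each row.
#' @export
make_point_cloud <- function(blob_centers, n_per_blob, sd, seed = 1L) {
  blob_centers <- as.matrix(blob_centers)
  stop_if(sd < 0, "sd must be >= 0")
  k <- nrow(blob_centers); d <- ncol(blob_centers)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  pts <- do.call(rbind, lapply(seq_len(k), function(b) {
    sweep(matrix(stats::rnorm(n_per_blob * d, 0, sd), n_per_blob, d),
          2, blob_centers[b, ], "+")
  }))
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  blob <- rep(seq_len(k), each = n_per_blob)
  rownames(pts) <- sprintf("b%d_%d", blob, sequence(rep(n_per_blob, k)))
  attr(pts, "blob") <- blob
  pts
}
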