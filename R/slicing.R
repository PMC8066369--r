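#' Slice-feature length per direction
#'
#' Direction 1 slices the first axis (each slice is a D2 x D3 section),
#' direction 2 the second (D1 x D3), direction 3 the third (D1 x D2).
#'
#' @param shape Integer vector of length 3.
#' @param direction 1, 2 or 3.
#' @return Number of voxels in one flattened slice of that direction.
#' @export
slice_length <- function(shape, direction) {
  stopifnot(length(shape) == 3L, direction %in% 1:3)
  as.integer(prod(shape[-direction]))
}

# Fast path: flattened slice values at 0-based `position` of `direction`.
# Flattening is row-major over the two remaining axes in ascending axis
# order (the later remaining axis varies fastest).
slice_values <- function(arr, direction, position) {
  dims <- dim(arr)
  ix <- list(seq_len(dims[1L]), seq_len(dims[2L]), seq_len(dims[3L]))
  ix[[direction]] <- position + 1L
  sl <- do.call(`[`, c(list(arr), ix, list(drop = FALSE)))
  sl <- array(sl, dim = dims[-direction])
  as.vector(t(sl))
}

#' Extract one flattened slice from a volume
#'
#' Takes the 2D section at the given 0-based index along the given axis
#' and flattens it row-major over the two remaining axes in ascending
#' axis order, so a `121x145x121` volume yields direction-1 slice vectors
#' of length `145 * 121 = 17545`. The same code path is used for training
#' and prediction, so the feature order is consistent by construction.
#'
#' @param volume An [mri_volume] (or bare 3D array).
#' @param direction 1, 2 or 3.
#' @param position 0-based slice index, `0 <= position < dim[direction]`.
#' @return A `slice_vector`: list with `direction`, `position`, `values`.
#' @export
extract_slice <- function(volume, direction, position) {
  arr <- if (inherits(volume, "mri_volume")) volume$data else volume
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  if (!direction %in% 1:3) stop("`direction` must be 1, 2 or 3")
  position <- as.integer(position)
  if (position < 0L || position >= dim(arr)[direction])
    stop("position ", position, " out of range [0, ",
         dim(arr)[direction] - 1L, "] for direction ", direction)
  structure(
    list(direction = as.integer(direction), position = position,
         values = slice_values(arr, direction, position)),
    class = "slice_vector"
  )
}

#' Rebuild volume data from a full set of slices of one direction
#'
#' Inverse of [extract_slice()]; used mainly to verify that slicing is
#' lossless. The slices must cover positions `0 .. D-1` of a single
#' direction, in order.
#'
#' @param slices List of `slice_vector` objects, one per position, in
#'   ascending position order.
#' @param shape Target shape (length-3 integer vector).
#' @return A 3D array `a` such that `extract_slice(a, d, m)` reproduces
#'   every input exactly.
#' @export
reconstruct_volume <- function(slices, shape) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L)
  if (!length(slices) || !all(vapply(slices, inherits, logical(1), "slice_vector")))
    stop("`slices` must be a non-empty list of slice_vector objects")
  d <- slices[[1L]]$direction
  if (!all(vapply(slices, function(s) s$direction, integer(1)) == d))
    stop("all slices must share one direction")
  pos <- vapply(slices, function(s) s$position, integer(1))
  if (!identical(pos, seq.int(0L, shape[d] - 1L)))
    stop("slices must cover positions 0..", shape[d] - 1L,
         " of direction ", d, " exactly once, in order")
  flen <- slice_length(shape, d)
  rem <- shape[-d]
  arr <- array(0, dim = shape)
  ix <- list(seq_len(shape[1L]), seq_len(shape[2L]), seq_len(shape[3L]))
  for (s in slices) {
    if (length(s$values) != flen)
      stop("slice at position ", s$position, " has length ",
           length(s$values), ", expected ", flen)
    sl <- t(matrix(s$values, nrow = rem[2L], ncol = rem[1L]))
    ixs <- ix
    ixs[[d]] <- s$position + 1L
    arr <- do.call(`[<-`, c(list(arr), ixs, list(array(sl, dim = replace(shape, d, 1L)))))
  }
  arr
}

#' Assemble the design matrix for one (direction, position)
#'
#' Stacks the flattened slices of every cohort member at one position of
#' one direction into a subjects x features matrix. Each row inherits its
#' subject's diagnosis label verbatim (the weak-label scheme: every slice
#' of a patient is labeled 1, even slices through normal tissue; the
#' downstream run-length filter absorbs the resulting label noise).
#'
#' @param cohort An [mri_cohort].
#' @param direction 1, 2 or 3.
#' @param position 0-based slice index.
#' @return List with `x` (matrix, rows in cohort order), `y` (integer
#'   labels), `direction`, `position`.
#' @export
build_design_matrix <- function(cohort, direction, position) {
  stopifnot(inherits(cohort, "mri_cohort"))
  n <- length(cohort$volumes)
  flen <- slice_length(cohort$shape, direction)
  x <- matrix(0, nrow = n, ncol = flen)
  for (i in seq_len(n))
    x[i, ] <- slice_values(cohort$volumes[[i]]$data, direction, position)
  rownames(x) <- cohort_ids(cohort)
  list(x = x, y = cohort_labels(cohort),
       direction = as.integer(direction), position = as.integer(position))
}
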