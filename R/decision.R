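#' Keep only runs of at least k consecutive positive slices
#'
#' A maximal block of consecutive 1s shorter than `k` is treated as
#' classifier noise and zeroed; blocks of length >= `k` are retained and
#' reported as suspected lesion runs. `k = 1` leaves the vector
#' unchanged (useful for ablation; the operating default elsewhere is
#' `k = 3`).
#'
#' @param v Binary vector (entries 0/1).
#' @param k Minimum run length, >= 1.
#' @return An object of class `run_filter`: list with `filtered` (binary
#'   integer vector, same length), `runs` (data.frame with 0-based
#'   `start` and `length` of every retained maximal run), and `k`.
#' @export
run_filter <- function(v, k) {
  if (!length(v)) stop("`v` must be non-empty")
  if (!all(v %in% c(0, 1))) stop("`v` must be binary (0/1)")
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be >= 1")
  v <- as.integer(v)
  r <- rle(v)
  keep <- r$values == 1L & r$lengths >= k
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based
  filtered <- integer(length(v))
  for (i in which(keep)) filtered[(starts[i] + 1L):ends[i]] <- 1L
  structure(
    list(filtered = filtered,
         runs = data.frame(start = starts[keep], length = r$lengths[keep]),
         k = k),
    class = "run_filter"
  )
}

# Accept either a run_filter result or a bare binary vector.
as_filtered <- function(f) {
  if (inherits(f, "run_filter")) f$filtered else {
    if (!all(f %in% c(0, 1))) stop("expected a binary vector or run_filter")
    as.integer(f)
  }
}

#' Separable 3D intersection of three filtered decision vectors
#'
#' The voxel `(a, b, c)` of the mask is positive iff all three filtered
#' vectors are positive at `a`, `b` and `c` respectively (a boolean
#' outer product). The mask is nonempty iff every direction retained at
#' least one run.
#'
#' @param f1,f2,f3 [run_filter()] results (or bare binary vectors) for
#'   directions 1..3; lengths define the mask shape.
#' @return A [lesion_mask] of shape `(length(f1), length(f2),
#'   length(f3))`.
#' @export
intersect_mask <- function(f1, f2, f3) {
  a <- as_filtered(f1); b <- as_filtered(f2); c_ <- as_filtered(f3)
  lesion_mask(outer(outer(a, b), c_))
}

#' Subject-level diagnosis from decision vectors
#'
#' Applies the k-run filter to each direction's decision vector and
#' diagnoses disorder (1) iff the three filtered vectors produce a
#' nonempty 3D intersection — equivalently, iff every direction contains
#' at least one run of `k` or more consecutive positive slices.
#' Monotone non-increasing in `k`.
#'
#' @param dv A `decision_vectors` object (see
#'   [predict_decision_vectors()]).
#' @param k Run-length threshold (default 3, the selected operating
#'   point).
#' @return Integer 0 or 1.
#' @export
diagnose <- function(dv, k = 3L) {
  stopifnot(inherits(dv, "decision_vectors"))
  fs <- lapply(dv[c("y1", "y2", "y3")], run_filter, k = k)
  as.integer(all(vapply(fs, function(f) any(f$filtered == 1L), logical(1))))
}

#' Suspected-lesion mask for one subject
#'
#' Convenience wrapper: k-filters the three decision vectors and returns
#' their separable intersection. Empty (all-zero) iff [diagnose()] is 0.
#'
#' @inheritParams diagnose
#' @return A [lesion_mask].
#' @export
subject_mask <- function(dv, k = 3L) {
  stopifnot(inherits(dv, "decision_vectors"))
  intersect_mask(run_filter(dv$y1, k), run_filter(dv$y2, k),
                 run_filter(dv$y3, k))
}

#' Common incidence region across subjects
#'
#' Voxelwise AND of several subjects' lesion masks: the region flagged in
#' every one of them. Adding a mask can only shrink the result.
#'
#' @param masks Non-empty list of [lesion_mask] objects of equal shape.
#' @return A [lesion_mask].
#' @export
common_region <- function(masks) {
  if (!length(masks)) stop("`masks` must be non-empty")
  shp <- dim(masks[[1L]])
  for (m in masks) {
    if (!inherits(m, "lesion_mask")) stop("all elements must be lesion_mask")
    if (!identical(dim(m), shp)) stop("all masks must share one shape")
  }
  out <- Reduce(function(a, b) pmin(a, b), lapply(masks, unclass))
  lesion_mask(array(out, dim = shp))
}
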