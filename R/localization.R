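#' Axis-aligned boxes from filtered decision vectors
#'
#' The separable intersection of k-filtered decision vectors decomposes
#' exactly into one axis-aligned box per combination of retained runs
#' across the three directions (maximal runs are disjoint, so the boxes
#' are the connected components of the mask). Intervals are half-open,
#' 0-based; centroids are mean voxel indices.
#'
#' @param f1,f2,f3 [run_filter()] results for directions 1..3.
#' @return data.frame with columns `a0,a1,b0,b1,c0,c1` (half-open
#'   bounds), `voxel_count`, `centroid_a`, `centroid_b`, `centroid_c`;
#'   zero rows when any direction has no retained run.
#' @export
mask_to_boxes <- function(f1, f2, f3) {
  fs <- list(f1, f2, f3)
  if (!all(vapply(fs, inherits, logical(1), "run_filter")))
    stop("inputs must be run_filter results")
  runs <- lapply(fs, `[[`, "runs")
  empty <- data.frame(a0 = integer(0), a1 = integer(0), b0 = integer(0),
                      b1 = integer(0), c0 = integer(0), c1 = integer(0),
                      voxel_count = integer(0), centroid_a = numeric(0),
                      centroid_b = numeric(0), centroid_c = numeric(0))
  if (any(vapply(runs, nrow, integer(1)) == 0L)) return(empty)
  g <- expand.grid(i = seq_len(nrow(runs[[1L]])),
                   j = seq_len(nrow(runs[[2L]])),
                   k = seq_len(nrow(runs[[3L]])))
  box <- function(r, idx) cbind(lo = r$start[idx], hi = r$start[idx] + r$length[idx])
  A <- box(runs[[1L]], g$i); B <- box(runs[[2L]], g$j); C <- box(runs[[3L]], g$k)
  data.frame(
    a0 = A[, 1], a1 = A[, 2], b0 = B[, 1], b1 = B[, 2],
    c0 = C[, 1], c1 = C[, 2],
    voxel_count = (A[, 2] - A[, 1]) * (B[, 2] - B[, 1]) * (C[, 2] - C[, 1]),
    centroid_a = (A[, 1] + A[, 2] - 1) / 2,
    centroid_b = (B[, 1] + B[, 2] - 1) / 2,
    centroid_c = (C[, 1] + C[, 2] - 1) / 2
  )
}

#' Summarize a lesion mask as connected components
#'
#' Reports total positive voxels and, per 6-connected component, the
#' bounding box (half-open, 0-based), voxel count and centroid. Works on
#' any binary mask — in particular on [common_region()] outputs, which
#' need not be separable. When a reference volume with a NIfTI header is
#' supplied, world-coordinate centroids (affine-transformed) are
#' appended.
#'
#' @param mask A [lesion_mask].
#' @param reference Optional [mri_volume] supplying an affine.
#' @return List with `total_voxels`, `n_components`, and `components`
#'   (data.frame; zero rows for an empty mask). Component voxel counts
#'   sum to `total_voxels`.
#' @export
region_report <- function(mask, reference = NULL) {
  stopifnot(inherits(mask, "lesion_mask"))
  dims <- dim(mask)
  idx <- which(mask == 1L)
  empty <- data.frame(component = integer(0), voxel_count = integer(0),
                      a0 = integer(0), a1 = integer(0), b0 = integer(0),
                      b1 = integer(0), c0 = integer(0), c1 = integer(0),
                      centroid_a = numeric(0), centroid_b = numeric(0),
                      centroid_c = numeric(0))
  if (!length(idx))
    return(list(total_voxels = 0L, n_components = 0L, components = empty))
  co <- arrayInd(idx, dims)  # 1-based
  # 6-connectivity edges between positive voxels via linear-index offsets
  pos <- integer(prod(dims)); pos[idx] <- seq_along(idx)
  edges <- integer(0)
  strides <- c(1L, dims[1L], dims[1L] * dims[2L])
  for (ax in 1:3) {
    ok <- co[, ax] < dims[ax]
    nb <- idx[ok] + strides[ax]
    hit <- pos[nb] > 0L
    if (any(hit))
      edges <- c(edges, rbind(pos[idx[ok]][hit], pos[nb][hit]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- as.integer(igraph::components(g)$membership)
  co0 <- co - 1L  # 0-based voxel indices
  rows <- lapply(sort(unique(comp)), function(cc) {
    sub <- co0[comp == cc, , drop = FALSE]
    data.frame(
      component = cc, voxel_count = nrow(sub),
      a0 = min(sub[, 1]), a1 = max(sub[, 1]) + 1L,
      b0 = min(sub[, 2]), b1 = max(sub[, 2]) + 1L,
      c0 = min(sub[, 3]), c1 = max(sub[, 3]) + 1L,
      centroid_a = mean(sub[, 1]), centroid_b = mean(sub[, 2]),
      centroid_c = mean(sub[, 3]))
  })
  components <- do.call(rbind, rows)
  if (!is.null(reference) && !is.null(reference$header)) {
    aff <- RNifti::xform(reference$header)
    w <- t(aff %*% rbind(components$centroid_a, components$centroid_b,
                         components$centroid_c, 1))
    components$world_x <- w[, 1]; components$world_y <- w[, 2]
    components$world_z <- w[, 3]
  }
  list(total_voxels = length(idx),
       n_components = max(comp),
       components = components)
}

#' Intersection-over-union of two masks
#'
#' Voxelwise Jaccard overlap between a predicted and a reference lesion
#' mask; defined as 1 when both masks are empty. Symmetric, and equal to
#' 1 iff the masks are identical.
#'
#' @param pred,truth [lesion_mask] objects of identical shape.
#' @return Numeric in `[0, 1]`.
#' @export
localization_overlap <- function(pred, truth) {
  stopifnot(inherits(pred, "lesion_mask"), inherits(truth, "lesion_mask"))
  if (!identical(dim(pred), dim(truth)))
    stop("mask shapes differ")
  inter <- sum(pred == 1L & truth == 1L)
  uni <- sum(pred == 1L | truth == 1L)
  if (uni == 0L) return(1)
  inter / uni
}
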