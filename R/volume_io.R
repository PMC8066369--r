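#' Construct a subject volume
#'
#' Wraps one subject's 3D gray-value grid together with an identifier, a
#' binary diagnosis label and (optionally) the NIfTI header of the file it
#' was read from. The header is carried along only so that masks derived
#' from the volume can be written back into the same physical space; it
#' plays no role in classification.
#'
#' @param data 3D numeric array of gray values (all finite).
#' @param subject_id Character scalar identifying the subject.
#' @param label Diagnosis label: `0` (typically developing), `1`
#'   (patient), or `NA` when unknown (e.g. at prediction time).
#' @param header Optional NIfTI header (as returned by
#'   [RNifti::niftiHeader()]) used as spatial reference on export.
#' @return An object of class `mri_volume` with elements `data`,
#'   `subject_id`, `label`, `header`.
#' @seealso [read_volume()], [mri_cohort()]
#' @export
mri_volume <- function(data, subject_id, label = NA_integer_, header = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array, got ", paste(dim(data), collapse = "x"))
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  if (!all(is.finite(data)))
    stop("volume '", subject_id, "' contains non-finite voxels")
  if (!is.character(subject_id) || length(subject_id) != 1L)
    stop("`subject_id` must be a single string")
  label <- as.integer(label)
  if (length(label) != 1L || (!is.na(label) && !label %in% c(0L, 1L)))
    stop("`label` must be 0, 1 or NA")
  structure(
    list(data = data, subject_id = subject_id, label = label, header = header),
    class = "mri_volume"
  )
}

#' @export
print.mri_volume <- function(x, ...) {
  cat("<mri_volume> ", x$subject_id,
      "  shape ", paste(dim(x$data), collapse = "x"),
      "  label ", ifelse(is.na(x$label), "NA", x$label), "\n", sep = "")
  invisible(x)
}

#' Construct a cohort of co-registered volumes
#'
#' A cohort is an ordered collection of [mri_volume] objects sharing a
#' common grid shape, with unique subject identifiers. All training and
#' cross-validation functions operate on cohorts.
#'
#' @param volumes List of `mri_volume` objects.
#' @return An object of class `mri_cohort` with elements `volumes`
#'   (named by subject id, in input order) and `shape`.
#' @export
mri_cohort <- function(volumes) {
  if (!length(volumes)) stop("cohort must contain at least one volume")
  ok <- vapply(volumes, inherits, logical(1), "mri_volume")
  if (!all(ok)) stop("all elements must be mri_volume objects")
  ids <- vapply(volumes, function(v) v$subject_id, character(1))
  if (anyDuplicated(ids)) stop("subject ids must be unique")
  shp <- dim(volumes[[1L]]$data)
  for (v in volumes)
    if (!identical(dim(v$data), shp))
      stop("volume '", v$subject_id, "' has shape ",
           paste(dim(v$data), collapse = "x"), ", cohort shape is ",
           paste(shp, collapse = "x"))
  names(volumes) <- ids
  structure(list(volumes = volumes, shape = shp), class = "mri_cohort")
}

#' @export
print.mri_cohort <- function(x, ...) {
  lab <- cohort_labels(x)
  cat("<mri_cohort> ", length(x$volumes), " subjects, shape ",
      paste(x$shape, collapse = "x"),
      " (", sum(lab == 0L, na.rm = TRUE), " control / ",
      sum(lab == 1L, na.rm = TRUE), " patient)\n", sep = "")
  invisible(x)
}

#' Subject labels and ids of a cohort
#'
#' @param cohort An `mri_cohort`.
#' @return `cohort_labels()`: named integer vector of labels;
#'   `cohort_ids()`: character vector of subject ids.
#' @export
cohort_labels <- function(cohort) {
  stopifnot(inherits(cohort, "mri_cohort"))
  vapply(cohort$volumes, function(v) v$label, integer(1))
}

#' @rdname cohort_labels
#' @export
cohort_ids <- function(cohort) names(cohort$volumes)

#' Subset a cohort by subject id
#'
#' @param cohort An `mri_cohort`.
#' @param ids Character vector of subject ids to keep (order preserved).
#' @return An `mri_cohort` containing exactly the requested subjects.
#' @export
cohort_subset <- function(cohort, ids) {
  missing <- setdiff(ids, cohort_ids(cohort))
  if (length(missing))
    stop("unknown subject ids: ", paste(missing, collapse = ", "))
  mri_cohort(cohort$volumes[ids])
}

#' Construct a binary lesion mask
#'
#' @param data 3D array with values in `{0, 1}`.
#' @return An object of class `lesion_mask`: an integer 3D array with a
#'   class attribute.
#' @export
lesion_mask <- function(data) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask must be a 3D array")
  if (!all(data %in% c(0, 1))) stop("mask values must be 0 or 1")
  storage.mode(data) <- "integer"
  structure(data, class = c("lesion_mask", "array"))
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat("<lesion_mask> shape ", paste(dim(x), collapse = "x"),
      ", ", sum(x), " positive voxels\n", sep = "")
  invisible(x)
}

#' Read a volume from a NIfTI-1 file
#'
#' Reads a 3D image (a 4D image with a trailing singleton dimension is
#' squeezed) in its native axis order. The file's header is retained so
#' derived masks can be exported into the same space.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param subject_id Subject identifier; defaults to the file name without
#'   NIfTI extensions.
#' @param label Optional diagnosis label (0/1/NA).
#' @return An [mri_volume].
#' @export
read_volume <- function(path, subject_id = NULL, label = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  arr <- as.array(img)
  arr <- array(as.double(arr), dim = dim(arr))  # drop image attributes
  d <- dim(arr)
  if (length(d) == 4L && d[4L] == 1L) {
    arr <- array(arr, dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop("image in ", path, " is ", length(d), "-dimensional, expected 3D")
  if (!all(is.finite(arr)))
    stop("image in ", path, " contains non-finite voxels")
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  mri_volume(arr, subject_id, label, header = hdr)
}

#' Write a lesion mask as a NIfTI-1 file
#'
#' The mask is written as 8-bit unsigned integers in the spatial frame of
#' the reference volume, so it overlays correctly in standard viewers.
#'
#' @param mask A [lesion_mask].
#' @param reference The [mri_volume] the mask refers to (shapes must
#'   match); its header supplies the affine.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, reference, path) {
  stopifnot(inherits(mask, "lesion_mask"), inherits(reference, "mri_volume"))
  if (!identical(dim(mask), dim(reference$data)))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match reference shape ",
         paste(dim(reference$data), collapse = "x"))
  arr <- array(as.integer(mask), dim = dim(mask))
  img <- if (is.null(reference$header)) RNifti::asNifti(arr)
         else RNifti::asNifti(arr, reference = reference$header)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Write a volume as a NIfTI-1 file
#'
#' @param volume An [mri_volume].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "mri_volume"))
  img <- if (is.null(volume$header)) RNifti::asNifti(volume$data)
         else RNifti::asNifti(volume$data, reference = volume$header)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a cohort from a manifest CSV
#'
#' The manifest is a two-column CSV with header `path,label`; paths are
#' resolved relative to the manifest's directory unless absolute.
#'
#' @param manifest Path to the manifest file.
#' @return An [mri_cohort].
#' @export
read_cohort <- function(manifest) {
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(tab)))
    stop("manifest must have columns 'path' and 'label'")
  root <- dirname(manifest)
  vols <- lapply(seq_len(nrow(tab)), function(i) {
    p <- tab$path[i]
    if (!file.exists(p)) p <- file.path(root, tab$path[i])
    read_volume(p, label = tab$label[i])
  })
  mri_cohort(vols)
}

#' Write a cohort (and optional truth mask) to a directory
#'
#' Writes one NIfTI file per subject plus a `manifest.csv` usable with
#' [read_cohort()]. For phantom cohorts the planted truth mask is written
#' as `truth_mask.nii.gz`.
#'
#' @param x An [mri_cohort] or `phantom_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(x, dir) {
  truth <- NULL
  if (inherits(x, "phantom_cohort")) {
    truth <- x$truth_mask
    x <- x$cohort
  }
  stopifnot(inherits(x, "mri_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (v in x$volumes) {
    f <- paste0(v$subject_id, ".nii.gz")
    write_volume(v, file.path(dir, f))
    files <- c(files, f)
  }
  man <- file.path(dir, "manifest.csv")
  utils::write.csv(
    data.frame(path = files, label = cohort_labels(x), row.names = NULL),
    man, row.names = FALSE)
  if (!is.null(truth))
    write_mask(truth, x$volumes[[1L]], file.path(dir, "truth_mask.nii.gz"))
  invisible(man)
}

#' Stratified cross-validation folds
#'
#' Partitions the cohort's subject ids into `n_folds` disjoint test sets,
#' stratified by label: within each class the ids are shuffled
#' (deterministically, from `seed`) and dealt round-robin to the folds,
#' with the dealing pointer continuing across classes so that total fold
#' sizes differ by at most one.
#'
#' @param cohort An [mri_cohort] with both classes present.
#' @param n_folds Number of folds (>= 2, <= cohort size).
#' @param seed Integer seed controlling the shuffle.
#' @return List of `n_folds` elements, each `list(train = ids, test =
#'   ids)`; the test sets form a partition of all subject ids.
#' @export
split_folds <- function(cohort, n_folds, seed) {
  labels <- cohort_labels(cohort)
  ids <- names(labels)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L || n_folds > length(ids))
    stop("`n_folds` must be between 2 and the cohort size")
  for (lab in c(0L, 1L))
    if (sum(labels == lab, na.rm = TRUE) < n_folds)
      stop("class ", lab, " has fewer than ", n_folds, " subjects")
  test_sets <- rep(list(character(0)), n_folds)
  with_local_seed(seed, {
    ptr <- 0L
    for (lab in c(0L, 1L)) {
      cls <- sample(ids[!is.na(labels) & labels == lab])
      for (id in cls) {
        f <- ptr %% n_folds + 1L
        test_sets[[f]] <- c(test_sets[[f]], id)
        ptr <- ptr + 1L
      }
    }
  })
  lapply(test_sets, function(te) list(train = setdiff(ids, te), test = te))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}
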