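#' Define a lesion box
#'
#' Half-open, 0-based index intervals along the three axes, e.g.
#' `lesion_box(c(10, 14), c(12, 17), c(10, 14))` is a 4 x 5 x 4 box.
#'
#' @param a,b,c Integer vectors `c(lo, hi)` with `lo < hi`.
#' @return A `lesion_box`: 3 x 2 integer matrix of bounds.
#' @export
lesion_box <- function(a, b, c) {
  m <- rbind(as.integer(a), as.integer(b), as.integer(c))
  if (ncol(m) != 2L || any(m[, 1L] >= m[, 2L]) || any(m[, 1L] < 0L))
    stop("each interval must be c(lo, hi) with 0 <= lo < hi")
  structure(m, class = "lesion_box")
}

#' Phantom cohort configuration
#'
#' Describes a synthetic cohort of co-registered volumes in which the
#' patient class carries a localized intensity perturbation in one or two
#' compact boxes on a shared noisy baseline — the statistical structure
#' (a local volume/intensity change against common anatomy) that the
#' slice-ensemble method assumes. Defaults describe a small,
#' fully-recoverable testbed: a 24 x 28 x 24 grid, 20 controls + 20
#' patients, one 4 x 5 x 4 lesion with a +10 intensity-unit mean shift
#' against voxel noise of SD 2 (effect/noise = 5), on a soft-ellipsoid
#' "brain" baseline.
#'
#' @param shape Grid shape, length-3 integer vector.
#' @param n_controls,n_patients Class sizes (both >= 1).
#' @param lesions List of [lesion_box()] objects (1 or 2 typical), all
#'   inside `shape`.
#' @param effect Mean intensity shift added to lesion voxels of patients
#'   (arbitrary units; with `lesion_mode = "multiplicative"`, the
#'   fractional change, i.e. voxels are scaled by `1 + effect`).
#' @param noise_sd SD of i.i.d. voxel noise (>= 0).
#' @param baseline `"ellipsoid"` (soft centered ellipsoid, intensity 100
#'   inside fading to 0 outside) or `"flat"` (constant 100).
#' @param subject_jitter_sd SD of a smooth per-subject intensity field
#'   (low-resolution Gaussian field upsampled trilinearly and
#'   standardized to unit SD before scaling), emulating residual
#'   between-subject anatomical variability; 0 by default (volumes are
#'   assumed co-registered).
#' @param lesion_mode `"additive"` or `"multiplicative"`.
#' @param seed Integer seed; the cohort is fully determined by it.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(24L, 28L, 24L),
                           n_controls = 20L, n_patients = 20L,
                           lesions = list(lesion_box(c(10L, 14L),
                                                     c(12L, 17L),
                                                     c(10L, 14L))),
                           effect = 10, noise_sd = 2,
                           baseline = c("ellipsoid", "flat"),
                           subject_jitter_sd = 0,
                           lesion_mode = c("additive", "multiplicative"),
                           seed = 1L) {
  baseline <- match.arg(baseline)
  lesion_mode <- match.arg(lesion_mode)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            n_controls >= 1L, n_patients >= 1L,
            noise_sd >= 0, subject_jitter_sd >= 0)
  if (!length(lesions) || !all(vapply(lesions, inherits, logical(1), "lesion_box")))
    stop("`lesions` must be a non-empty list of lesion_box objects")
  for (bx in lesions)
    if (any(bx[, 2L] > shape))
      stop("lesion box exceeds the volume shape")
  structure(
    list(shape = shape, n_controls = as.integer(n_controls),
         n_patients = as.integer(n_patients), lesions = lesions,
         effect = effect, noise_sd = noise_sd, baseline = baseline,
         subject_jitter_sd = subject_jitter_sd, lesion_mode = lesion_mode,
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' True lesion mask of a phantom configuration
#'
#' @param config A [phantom_config()].
#' @return A [lesion_mask]: union of the configured boxes.
#' @export
truth_mask <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  m <- array(0L, dim = config$shape)
  for (bx in config$lesions)
    m[(bx[1, 1] + 1L):bx[1, 2], (bx[2, 1] + 1L):bx[2, 2],
      (bx[3, 1] + 1L):bx[3, 2]] <- 1L
  lesion_mask(m)
}

# Soft centered ellipsoid baseline: intensity 100 well inside, fading to
# 0 across a sigmoidal shell, giving slices brain-like nonstationary
# structure without any MRI physics.
baseline_field <- function(shape, type) {
  if (type == "flat") return(array(100, dim = shape))
  ctr <- (shape - 1) / 2
  semi <- 0.42 * shape
  u <- lapply(1:3, function(i) ((seq_len(shape[i]) - 1 - ctr[i]) / semi[i])^2)
  r2 <- outer(outer(u[[1]], u[[2]], `+`), u[[3]], `+`)
  100 / (1 + exp((sqrt(r2) - 1) / 0.08))
}

# Smooth random field: coarse iid Gaussian grid, trilinear upsampling,
# standardized to unit SD (so `sd` is the pointwise SD of the result).
smooth_field <- function(shape, sd, coarse = 5L) {
  if (sd == 0) return(array(0, dim = shape))
  cd <- pmax(2L, pmin(as.integer(coarse), shape))
  f <- array(stats::rnorm(prod(cd)), dim = cd)
  for (ax in 1:3) {
    if (cd[ax] == shape[ax]) next
    xin <- seq(0, 1, length.out = dim(f)[ax])
    xout <- seq(0, 1, length.out = shape[ax])
    f <- apply(f, setdiff(1:3, ax), function(col)
      stats::approx(xin, col, xout = xout)$y)
    # apply() puts the interpolated axis first; rotate it back into place
    perm <- order(c(ax, setdiff(1:3, ax)))
    f <- aperm(f, perm)
  }
  f <- f - mean(f)
  s <- stats::sd(as.vector(f))
  if (s > 0) f <- f / s
  f * sd
}

#' Generate a synthetic phantom cohort
#'
#' Each subject's volume is
#' `baseline + smooth subject jitter + i.i.d. voxel noise`, and patients
#' additionally receive the lesion effect inside the configured boxes
#' (an additive mean shift by default). Controls come first, then
#' patients. The result is fully determined by `config$seed`; the
#' caller's RNG state is left untouched.
#'
#' @param config A [phantom_config()].
#' @return An object of class `phantom_cohort`: list with `cohort` (an
#'   [mri_cohort]), `truth_mask` (a [lesion_mask]) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  shape <- config$shape
  base <- baseline_field(shape, config$baseline)
  tm <- truth_mask(config)
  les <- array(as.numeric(tm), dim = shape)
  n <- config$n_controls + config$n_patients
  labels <- rep(c(0L, 1L), c(config$n_controls, config$n_patients))
  ids <- sprintf("%s%03d", ifelse(labels == 0L, "control", "patient"),
                 c(seq_len(config$n_controls), seq_len(config$n_patients)))
  vols <- vector("list", n)
  with_local_seed(config$seed, {
    for (i in seq_len(n)) {
      v <- base + smooth_field(shape, config$subject_jitter_sd)
      if (config$noise_sd > 0)
        v <- v + array(stats::rnorm(prod(shape), 0, config$noise_sd),
                       dim = shape)
      if (labels[i] == 1L) {
        v <- if (config$lesion_mode == "additive")
          v + config$effect * les
        else v * (1 + config$effect * les)
      }
      vols[[i]] <- mri_volume(v, ids[i], labels[i])
    }
  })
  structure(list(cohort = mri_cohort(vols), truth_mask = tm,
                 config = config),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("<phantom_cohort> ")
  print(x$cohort)
  cat("  lesion voxels: ", sum(x$truth_mask), ", effect ", x$config$effect,
      ", noise_sd ", x$config$noise_sd, ", seed ", x$config$seed, "\n",
      sep = "")
  invisible(x)
}
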