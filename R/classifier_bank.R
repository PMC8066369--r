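#' Configuration of the per-position classifier bank
#'
#' Defaults follow the reference operating point for this method: 700
#' trees per forest, maximum depth 100, and nodes split down to 2 samples
#' (mapped to a minimal terminal-node size of 1). `features_per_split`
#' uses the square-root rule, the standard random-forest default.
#'
#' Two vote-aggregation rules are available for turning a forest into a
#' binary slice decision:
#' \describe{
#'   \item{`"oob"` (default)}{each tree votes the majority label of the
#'     *out-of-bag* training samples that fall in the test point's leaf;
#'     a leaf with no out-of-bag samples, or an exact tie, votes 0
#'     (normal). The slice is flagged as disorder iff a strict majority
#'     of trees vote disorder. Because the weak-label scheme labels every
#'     slice of a patient as positive, slice positions that carry no
#'     class signal would otherwise be decided by memorized in-bag noise;
#'     out-of-bag leaf evidence is unbiased there and, with the
#'     conservative tie rule, keeps the false-positive rate of no-signal
#'     positions low.}
#'   \item{`"inbag"`}{the plain rule: each tree votes its own predicted
#'     class (in-bag leaf majority) and the slice is the strict majority
#'     of tree votes, ties to 0.}
#' }
#'
#' @param n_trees Number of trees per forest.
#' @param max_depth Maximum tree depth.
#' @param min_samples_split Minimum node size eligible for splitting.
#' @param features_per_split `"sqrt"` or a positive integer (mtry).
#' @param seed Integer base seed; each (direction, position) model is
#'   seeded deterministically from `(seed, direction, position)`.
#' @param vote `"oob"` or `"inbag"` (see Details).
#' @param class_weights Optional numeric length-2 vector of weights for
#'   classes 0 and 1 (off by default; classes are used as-is).
#' @return An object of class `bank_config`.
#' @export
bank_config <- function(n_trees = 700L, max_depth = 100L,
                        min_samples_split = 2L,
                        features_per_split = "sqrt", seed = 1L,
                        vote = c("oob", "inbag"), class_weights = NULL) {
  vote <- match.arg(vote)
  n_trees <- as.integer(n_trees)
  max_depth <- as.integer(max_depth)
  min_samples_split <- as.integer(min_samples_split)
  stopifnot(n_trees >= 1L, max_depth >= 1L, min_samples_split >= 2L)
  if (!identical(features_per_split, "sqrt")) {
    features_per_split <- as.integer(features_per_split)
    stopifnot(features_per_split >= 1L)
  }
  if (!is.null(class_weights)) stopifnot(length(class_weights) == 2L)
  structure(
    list(n_trees = n_trees, max_depth = max_depth,
         min_samples_split = min_samples_split,
         features_per_split = features_per_split,
         seed = as.integer(seed), vote = vote,
         class_weights = class_weights),
    class = "bank_config"
  )
}

# Deterministic per-model seed below 2^31, mixing (seed, direction, position).
model_seed <- function(seed, direction, position) {
  (as.double(seed) * 7919 + direction * 104729 + position * 1299709 +
     1e6) %% 2147483629
}

fit_slice_model <- function(x, y, config, seed) {
  if (length(unique(y)) < 2L)
    stop("design matrix contains a single class; training needs both")
  # Features constant across the training sample admit no split and are
  # removed, so the per-split feature draw samples only informative
  # voxels (the reference splitter behaves likewise by skipping constant
  # candidates). A position whose slices are entirely constant carries
  # no class information at all and gets a degenerate always-normal
  # classifier.
  const <- colSums(abs(x - rep(x[1L, ], each = nrow(x)))) == 0
  if (all(const))
    return(list(constant = TRUE, forest = NULL, votes = NULL,
                features = integer(0)))
  features <- which(!const)
  x <- x[, features, drop = FALSE]
  colnames(x) <- paste0("v", seq_len(ncol(x)))
  mtry <- if (identical(config$features_per_split, "sqrt"))
    max(1L, floor(sqrt(ncol(x)))) else min(config$features_per_split, ncol(x))
  rf <- ranger::ranger(
    x = x, y = factor(y, levels = c(0L, 1L)),
    num.trees = config$n_trees,
    mtry = mtry,
    min.node.size = max(1L, config$min_samples_split - 1L),
    max.depth = config$max_depth,
    class.weights = config$class_weights,
    keep.inbag = TRUE,
    seed = seed, num.threads = 1L,
    verbose = FALSE
  )
  votes <- NULL
  if (config$vote == "oob") {
    nt <- stats::predict(rf, data = x, type = "terminalNodes",
                         num.threads = 1L)$predictions
    inb <- matrix(unlist(rf$inbag.counts), nrow = nrow(x))
    votes <- vector("list", config$n_trees)
    for (t in seq_len(config$n_trees)) {
      # a tree votes "disorder" for a leaf iff the out-of-bag training
      # samples reaching that leaf have a strict "disorder" majority;
      # ties and leaves without out-of-bag evidence vote "normal"
      vec <- integer(max(nt[, t]) + 1L)  # node ids are 0-based
      oob <- inb[, t] == 0L
      if (any(oob)) {
        lv <- nt[oob, t]
        n1 <- rowsum(as.integer(y[oob] == 1L), lv)
        n0 <- rowsum(as.integer(y[oob] == 0L), lv)
        vec[as.integer(rownames(n1)) + 1L] <- as.integer(n1 > n0)
      }
      votes[[t]] <- vec
    }
    rf$inbag.counts <- NULL  # no longer needed; keep the bank light
  }
  list(constant = FALSE, forest = rf, votes = votes, features = features)
}

# Predict binary slice decisions for a test matrix with one model.
predict_slice_model <- function(model, x, config) {
  if (isTRUE(model$constant)) return(integer(nrow(x)))
  x <- x[, model$features, drop = FALSE]
  colnames(x) <- paste0("v", seq_len(ncol(x)))
  n_trees <- config$n_trees
  if (config$vote == "oob") {
    nt <- stats::predict(model$forest, data = x, type = "terminalNodes",
                         num.threads = 1L)$predictions
    count1 <- integer(nrow(x))
    for (t in seq_len(n_trees)) {
      vec <- model$votes[[t]]
      leaf <- nt[, t] + 1L  # node ids are 0-based
      v <- integer(nrow(x))
      ok <- leaf <= length(vec)
      v[ok] <- vec[leaf[ok]]
      count1 <- count1 + v
    }
  } else {
    pr <- stats::predict(model$forest, data = x, predict.all = TRUE,
                         num.threads = 1L)$predictions
    # ranger returns factor-level indices (1 = class 0, 2 = class 1)
    count1 <- rowSums(pr == 2L)
  }
  as.integer(count1 * 2L > n_trees)  # strict majority; ties -> 0
}

#' Train the full per-(direction, position) classifier bank
#'
#' Fits one random forest per slice position of each of the three
#' directions (`D1 + D2 + D3` models in total). Models are trained one at
#' a time on the corresponding design matrix, so memory use stays at one
#' design matrix regardless of volume size. Each model is seeded
#' deterministically from `(config$seed, direction, position)`, so the
#' bank is reproducible regardless of training order.
#'
#' @param cohort Training [mri_cohort]; must contain both classes.
#' @param config A [bank_config()].
#' @param verbose Print progress per direction.
#' @return An object of class `trained_bank` with elements `models`
#'   (named `"d<dir>_p<pos>"`), `shape`, `config`.
#' @export
train_bank <- function(cohort, config = bank_config(), verbose = FALSE) {
  stopifnot(inherits(cohort, "mri_cohort"), inherits(config, "bank_config"))
  labs <- cohort_labels(cohort)
  if (length(unique(labs)) < 2L)
    stop("training cohort must contain both classes")
  shape <- cohort$shape
  models <- list()
  for (d in 1:3) {
    if (verbose) message("training direction ", d, " (", shape[d], " positions)")
    for (m in seq.int(0L, shape[d] - 1L)) {
      dm <- build_design_matrix(cohort, d, m)
      models[[sprintf("d%d_p%03d", d, m)]] <-
        fit_slice_model(dm$x, dm$y, config, model_seed(config$seed, d, m))
    }
  }
  structure(list(models = models, shape = shape, config = config),
            class = "trained_bank")
}

#' @export
print.trained_bank <- function(x, ...) {
  cat("<trained_bank> ", length(x$models), " models for shape ",
      paste(x$shape, collapse = "x"), ", ", x$config$n_trees,
      " trees each, vote rule '", x$config$vote, "'\n", sep = "")
  invisible(x)
}

# Batch prediction: decision vectors for a list of volumes sharing the
# bank's shape. One predict call per model over all volumes.
predict_bank_batch <- function(bank, volumes) {
  shape <- bank$shape
  n <- length(volumes)
  out <- lapply(seq_len(n), function(i)
    structure(list(y1 = integer(shape[1L]), y2 = integer(shape[2L]),
                   y3 = integer(shape[3L])), class = "decision_vectors"))
  for (d in 1:3) {
    flen <- slice_length(shape, d)
    for (m in seq.int(0L, shape[d] - 1L)) {
      x <- matrix(0, nrow = n, ncol = flen)
      for (i in seq_len(n)) x[i, ] <- slice_values(volumes[[i]], d, m)
      p <- predict_slice_model(bank$models[[sprintf("d%d_p%03d", d, m)]],
                               x, bank$config)
      for (i in seq_len(n)) out[[i]][[d]][m + 1L] <- p[i]
    }
  }
  out
}

#' Predict per-direction decision vectors for a volume or cohort
#'
#' Applies every model of the bank to the matching slice of the input:
#' entry `m` (0-based) of `y_d` is the vote of model `(d, m)` on
#' `extract_slice(volume, d, m)`. Predictions at a position depend only
#' on that slice of the input.
#'
#' @param bank A [train_bank()] result.
#' @param volume An [mri_volume] (or an [mri_cohort], in which case a
#'   named list of results is returned).
#' @return A `decision_vectors` object: list of binary vectors `y1`,
#'   `y2`, `y3` of lengths `(D1, D2, D3)`; or a named list of them.
#' @export
predict_decision_vectors <- function(bank, volume) {
  stopifnot(inherits(bank, "trained_bank"))
  if (inherits(volume, "mri_cohort")) {
    if (!identical(volume$shape, bank$shape))
      stop("cohort shape does not match bank shape")
    res <- predict_bank_batch(bank, lapply(volume$volumes, `[[`, "data"))
    names(res) <- cohort_ids(volume)
    return(res)
  }
  arr <- if (inherits(volume, "mri_volume")) volume$data else volume
  if (!identical(dim(arr), bank$shape))
    stop("volume shape ", paste(dim(arr), collapse = "x"),
         " does not match bank shape ", paste(bank$shape, collapse = "x"))
  predict_bank_batch(bank, list(arr))[[1L]]
}

#' @export
print.decision_vectors <- function(x, ...) {
  cat("<decision_vectors> positives per direction: ",
      sum(x$y1), "/", length(x$y1), ", ",
      sum(x$y2), "/", length(x$y2), ", ",
      sum(x$y3), "/", length(x$y3), "\n", sep = "")
  invisible(x)
}

#' Persist a trained bank to a directory
#'
#' Writes one RDS file per model plus a JSON manifest holding the shape
#' and configuration.
#'
#' @param bank A `trained_bank`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_bank <- function(bank, dir) {
  stopifnot(inherits(bank, "trained_bank"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bank$config
  cfg$class_weights <- as.numeric(cfg$class_weights)
  manifest <- list(shape = as.integer(bank$shape),
                   config = unclass(cfg),
                   models = names(bank$models))
  jsonlite::write_json(manifest, file.path(dir, "bank.json"),
                       auto_unbox = TRUE, null = "null")
  for (nm in names(bank$models))
    saveRDS(bank$models[[nm]], file.path(dir, paste0(nm, ".rds")))
  invisible(dir)
}

#' Load a trained bank saved by [save_bank()]
#'
#' @param dir Directory containing `bank.json` and per-model RDS files.
#' @return A `trained_bank`.
#' @export
load_bank <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "bank.json"),
                             simplifyVector = TRUE)
  cfg <- man$config
  config <- bank_config(
    n_trees = cfg$n_trees, max_depth = cfg$max_depth,
    min_samples_split = cfg$min_samples_split,
    features_per_split = cfg$features_per_split, seed = cfg$seed,
    vote = cfg$vote,
    class_weights = if (length(cfg$class_weights)) cfg$class_weights)
  models <- lapply(man$models, function(nm)
    readRDS(file.path(dir, paste0(nm, ".rds"))))
  names(models) <- man$models
  structure(list(models = models, shape = as.integer(man$shape),
                 config = config),
            class = "trained_bank")
}
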