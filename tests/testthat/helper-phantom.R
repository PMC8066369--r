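# Small builders shared across tests. Scales are deliberately tiny so the
# full pipeline stays fast; the acceptance tests use the standard phantom.

tiny_config <- function(noise_sd = 0, effect = 10, shape = c(8L, 9L, 8L),
                        n_controls = 6L, n_patients = 6L, seed = 1L,
                        lesions = list(lesion_box(c(3L, 6L), c(3L, 6L),
                                                  c(3L, 6L))),
                        ...) {
  phantom_config(shape = shape, n_controls = n_controls,
                 n_patients = n_patients, lesions = lesions,
                 effect = effect, noise_sd = noise_sd, seed = seed, ...)
}

fast_bank <- function(n_trees = 25L, seed = 1L, ...) {
  bank_config(n_trees = n_trees, seed = seed, ...)
}

random_volume <- function(shape, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(prod(shape)), dim = shape)
}

random_mask <- function(shape, p = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lesion_mask(array(stats::rbinom(prod(shape), 1L, p), dim = shape))
}

random_dv <- function(shape, p = 0.5) {
  structure(list(y1 = stats::rbinom(shape[1L], 1L, p),
                 y2 = stats::rbinom(shape[2L], 1L, p),
                 y3 = stats::rbinom(shape[3L], 1L, p)),
            class = "decision_vectors")
}

# Independent run-length oracle: position i survives iff it lies in a
# window of k consecutive ones (checked by direct window enumeration,
# not by run-length encoding).
oracle_run_filter <- function(v, k) {
  n <- length(v)
  out <- integer(n)
  if (n >= k) {
    for (s in seq_len(n - k + 1L)) {
      if (all(v[s:(s + k - 1L)] == 1L)) out[s:(s + k - 1L)] <- 1L
    }
  }
  out
}

# Independent separable-mask oracle: explicit triple loop.
oracle_intersect <- function(f1, f2, f3) {
  m <- array(0L, dim = c(length(f1), length(f2), length(f3)))
  for (a in seq_along(f1)) for (b in seq_along(f2)) for (c in seq_along(f3))
    m[a, b, c] <- f1[a] * f2[b] * f3[c]
  m
}
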