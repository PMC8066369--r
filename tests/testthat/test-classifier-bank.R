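# A globally separable phantom: the patient class is shifted everywhere,
# so every slice position of every direction carries class signal.
offset_cohort <- function(shape = c(6L, 7L, 6L), n = 5L, offset = 10,
                          noise_sd = 0.5, seed = 2L) {
  set.seed(seed)
  vols <- list()
  for (i in seq_len(2 * n)) {
    lab <- as.integer(i > n)
    arr <- array(rnorm(prod(shape), 100, noise_sd), dim = shape) +
      lab * offset
    vols[[i]] <- mri_volume(arr, sprintf("s%02d", i), lab)
  }
  mri_cohort(vols)
}

test_that("bank_config defaults match the reference operating point", {
  cfg <- bank_config()
  expect_identical(cfg$n_trees, 700L)
  expect_identical(cfg$max_depth, 100L)
  expect_identical(cfg$min_samples_split, 2L)
  expect_identical(cfg$features_per_split, "sqrt")
  expect_identical(cfg$vote, "oob")
  expect_error(bank_config(min_samples_split = 1L))
})

test_that("the bank holds one model per slice position", {
  ph <- generate_cohort(tiny_config())
  bank <- train_bank(ph$cohort, fast_bank())
  expect_identical(length(bank$models), 8L + 9L + 8L)
  expect_s3_class(bank, "trained_bank")
  # single-class cohorts are rejected
  ctrl <- cohort_subset(ph$cohort, cohort_ids(ph$cohort)[1:6])
  expect_error(train_bank(ctrl, fast_bank()), "both classes")
})

test_that("decision vectors have the shape contract and are deterministic", {
  co <- offset_cohort()
  bank1 <- train_bank(co, fast_bank(seed = 5L))
  bank2 <- train_bank(co, fast_bank(seed = 5L))
  held <- mri_volume(array(rnorm(prod(co$shape), 100, 0.5) + 10, dim = co$shape),
                     "held", NA_integer_)
  dv1 <- predict_decision_vectors(bank1, held)
  dv2 <- predict_decision_vectors(bank2, held)
  expect_identical(dv1, dv2)
  expect_length(dv1$y1, co$shape[1])
  expect_length(dv1$y2, co$shape[2])
  expect_length(dv1$y3, co$shape[3])
  expect_true(all(unlist(dv1) %in% 0:1))
  # a different seed is allowed to produce a different bank
  bank3 <- train_bank(co, fast_bank(seed = 6L))
  expect_s3_class(bank3, "trained_bank")
  # shape mismatch rejected
  expect_error(predict_decision_vectors(
    bank1, mri_volume(array(0, c(3, 3, 3)), "x")), "shape")
})

test_that("separable classes give all-ones / all-zeros vectors", {
  co <- offset_cohort(noise_sd = 0.5, offset = 20)
  bank <- train_bank(co, fast_bank(n_trees = 40L))
  set.seed(77)
  patient_like <- mri_volume(
    array(rnorm(prod(co$shape), 100, 0.5) + 20, dim = co$shape), "p")
  control_like <- mri_volume(
    array(rnorm(prod(co$shape), 100, 0.5), dim = co$shape), "c")
  dvp <- predict_decision_vectors(bank, patient_like)
  dvc <- predict_decision_vectors(bank, control_like)
  expect_true(all(unlist(dvp) == 1L))
  expect_true(all(unlist(dvc) == 0L))
})

test_that("training-set predictions are perfect on a noise-free global shift", {
  co <- offset_cohort(noise_sd = 0, offset = 5)
  bank <- train_bank(co, fast_bank(n_trees = 40L))
  for (id in cohort_ids(co)) {
    dv <- predict_decision_vectors(bank, co$volumes[[id]])
    expect_true(all(unlist(dv) == co$volumes[[id]]$label))
  }
})

test_that("a position's prediction depends only on its own slice", {
  ph <- generate_cohort(tiny_config(noise_sd = 1))
  bank <- train_bank(ph$cohort, fast_bank())
  vol <- ph$cohort$volumes[["patient003"]]
  dv <- predict_decision_vectors(bank, vol)
  # perturb everything except direction-1 slice at position 4
  pert <- vol
  pert$data[-5, , ] <- pert$data[-5, , ] + 50
  dvp <- predict_decision_vectors(bank, pert)
  expect_identical(dvp$y1[5], dv$y1[5])
  # and the untouched slice of direction 2 at position 0
  pert2 <- vol
  pert2$data[, -1, ] <- 0
  dvp2 <- predict_decision_vectors(bank, pert2)
  expect_identical(dvp2$y2[1], dv$y2[1])
})

test_that("banks survive a save/load round trip", {
  co <- offset_cohort(n = 4L)
  bank <- train_bank(co, fast_bank(n_trees = 15L, seed = 9L))
  d <- tempfile()
  save_bank(bank, d)
  expect_true(file.exists(file.path(d, "bank.json")))
  back <- load_bank(d)
  expect_identical(back$shape, bank$shape)
  expect_identical(back$config, bank$config)
  set.seed(3)
  probe <- mri_volume(array(rnorm(prod(co$shape), 100, 1), dim = co$shape), "q")
  expect_identical(predict_decision_vectors(back, probe),
                   predict_decision_vectors(bank, probe))
})

test_that("cohort-level prediction matches per-volume prediction", {
  ph <- generate_cohort(tiny_config(noise_sd = 1, seed = 4L))
  bank <- train_bank(ph$cohort, fast_bank())
  sub <- cohort_subset(ph$cohort, c("control002", "patient005"))
  both <- predict_decision_vectors(bank, sub)
  expect_named(both, c("control002", "patient005"))
  expect_identical(both[["patient005"]],
                   predict_decision_vectors(bank, ph$cohort$volumes[["patient005"]]))
})
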