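test_that("run_filter keeps exactly the maximal runs of length >= k", {
  r <- run_filter(c(1, 1, 1, 0, 1, 1), 3)
  expect_identical(r$filtered, c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_identical(r$runs, data.frame(start = 0L, length = 3L))
  # all zeros: nothing retained
  z <- run_filter(rep(0, 7), 2)
  expect_identical(z$filtered, integer(7))
  expect_identical(nrow(z$runs), 0L)
  # k = 1 is the identity
  set.seed(1)
  v <- rbinom(30, 1, 0.5)
  expect_identical(run_filter(v, 1)$filtered, as.integer(v))
  # validation
  expect_error(run_filter(c(0, 2, 1), 2), "binary")
  expect_error(run_filter(integer(0), 2), "non-empty")
  expect_error(run_filter(c(0, 1), 0), ">= 1")
})

test_that("run_filter agrees with window enumeration on random vectors", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(1:15, 1)
    v <- rbinom(n, 1, runif(1))
    k <- sample(1:5, 1)
    r <- run_filter(v, k)
    expect_identical(r$filtered, oracle_run_filter(v, k))
    # reported runs tile the filtered vector exactly
    rebuilt <- integer(n)
    if (nrow(r$runs))
      for (i in seq_len(nrow(r$runs)))
        rebuilt[(r$runs$start[i] + 1):(r$runs$start[i] + r$runs$length[i])] <- 1L
    expect_identical(rebuilt, r$filtered)
    expect_true(all(r$runs$length >= k))
  }
})

test_that("run_filter is idempotent and monotone in k", {
  set.seed(5)
  for (rep in 1:100) {
    v <- rbinom(sample(2:20, 1), 1, 0.6)
    k <- sample(1:4, 1)
    f1 <- run_filter(v, k)$filtered
    expect_identical(run_filter(f1, k)$filtered, f1)
    f2 <- run_filter(v, k + 1L)$filtered
    expect_true(all(f2 <= f1))
  }
})

test_that("intersect_mask is the boolean outer product", {
  # worked example: ones exactly at {1,2} x {0} x {0,1} (0-based)
  m <- intersect_mask(c(0, 1, 1), c(1, 0), c(1, 1))
  expect_identical(sum(m), 4L)
  expect_identical(unclass(m), oracle_intersect(c(0L, 1L, 1L), c(1L, 0L),
                                                c(1L, 1L)))
  expect_identical(m[2, 1, 1] + m[2, 1, 2] + m[3, 1, 1] + m[3, 1, 2], 4L)
  # all ones -> full; an all-zero direction annihilates
  expect_identical(sum(intersect_mask(c(1, 1), c(1, 1), c(1, 1))), 8L)
  expect_identical(sum(intersect_mask(c(1, 1), c(0, 0), c(1, 1))), 0L)
  # random triples against the triple loop
  set.seed(12)
  for (rep in 1:50) {
    f1 <- rbinom(sample(1:10, 1), 1, 0.5)
    f2 <- rbinom(sample(1:10, 1), 1, 0.5)
    f3 <- rbinom(sample(1:10, 1), 1, 0.5)
    expect_identical(unclass(intersect_mask(f1, f2, f3)),
                     oracle_intersect(as.integer(f1), as.integer(f2),
                                      as.integer(f3)))
  }
  # run_filter results are accepted directly
  rf <- run_filter(c(1, 1, 0), 2)
  expect_identical(unclass(intersect_mask(rf, rf$filtered, rf)),
                   oracle_intersect(c(1L, 1L, 0L), c(1L, 1L, 0L),
                                    c(1L, 1L, 0L)))
})

test_that("diagnose flags a subject iff every direction retains a run", {
  mk <- function(r1, r2, r3) structure(list(y1 = r1, y2 = r2, y3 = r3),
                                       class = "decision_vectors")
  three <- c(0, 1, 1, 1, 0)
  two <- c(0, 1, 1, 0, 0)
  expect_identical(diagnose(mk(three, three, three), 3), 1L)
  expect_identical(diagnose(mk(three, three, two), 3), 0L)
  expect_identical(diagnose(mk(rep(0, 5), rep(0, 6), rep(0, 5)), 2), 0L)
  # equivalence with nonempty intersection, and monotonicity in k
  set.seed(8)
  for (rep in 1:100) {
    dv <- random_dv(c(6, 7, 6), p = 0.6)
    prev <- 1L
    for (k in 1:5) {
      d <- diagnose(dv, k)
      expect_identical(d, as.integer(sum(subject_mask(dv, k)) > 0))
      expect_true(d <= prev)
      prev <- d
    }
  }
})

test_that("common_region is the voxelwise AND and only shrinks", {
  set.seed(21)
  m1 <- random_mask(c(4, 4, 4))
  m2 <- random_mask(c(4, 4, 4))
  # single mask: identity
  expect_identical(common_region(list(m1)), m1)
  # any empty mask annihilates
  e <- lesion_mask(array(0L, c(4, 4, 4)))
  expect_identical(sum(common_region(list(m1, m2, e))), 0L)
  # two random masks: voxelwise minimum, against a triple loop
  cr <- common_region(list(m1, m2))
  for (a in 1:4) for (b in 1:4) for (c in 1:4)
    expect_identical(cr[a, b, c], min(m1[a, b, c], m2[a, b, c]))
  # commutative and shrinking
  expect_identical(common_region(list(m2, m1)), cr)
  expect_true(sum(cr) <= min(sum(m1), sum(m2)))
  m3 <- random_mask(c(4, 4, 4))
  expect_true(sum(common_region(list(m1, m2, m3))) <= sum(cr))
  expect_error(common_region(list()), "non-empty")
  expect_error(common_region(list(m1, random_mask(c(3, 4, 4)))), "shape")
})
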