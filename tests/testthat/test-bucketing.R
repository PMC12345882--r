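test_that("bucket assignment follows the half-open convention with top-edge closure", {
  grid <- bucket_grid(rt_width = 20, mz_width = 2,
                      rt_range = c(0, 810), mz_range = c(100, 1000))
  a <- assign_bucket(mz = 101.3, rt = 25, grid)
  expect_equal(c(a$rt_idx, a$mz_idx), c(1L, 0L))
  expect_equal(a$bucket, "1_0")
  # lower edge of an interior bucket belongs to that bucket
  expect_equal(assign_bucket(100, 20.0, grid)$rt_idx, 1L)
  expect_equal(assign_bucket(102, 0, grid)$rt_idx, 0L)
  # top edges close into the final bucket instead of falling out
  expect_equal(assign_bucket(100, 810, grid)$rt_idx, grid$n_rt - 1L)
  expect_equal(assign_bucket(1000, 10, grid)$mz_idx, grid$n_mz - 1L)
  # out-of-range values are flagged, not dropped
  oor <- assign_bucket(c(99, 100, 1001), c(-1, 5, 5), grid)
  expect_equal(oor$in_range, c(FALSE, TRUE, FALSE))
  expect_true(all(is.na(oor$bucket[!oor$in_range])))
})

test_that("bucket sums match a brute-force peak-by-bucket oracle", {
  grid <- bucket_grid(rt_width = 20, mz_width = 5,
                      rt_range = c(0, 100), mz_range = c(100, 150))
  # hand case: two peaks in one bucket sum, others stay separate
  pk <- tibble::tibble(mz = c(101, 101.5, 149), rt = c(5, 8, 95),
                       intensity = c(2, 3, 7))
  v <- bucket_peaklist(pk, grid)
  expect_equal(unname(v[["0_0"]]), 5)
  expect_equal(unname(v[["4_9"]]), 7)
  expect_equal(sum(v), 12)

  withr::with_seed(42, {
    for (i in 1:20) {
      pk <- random_peaklist(80, grid, frac_outside = 1)
      v <- bucket_peaklist(pk, grid)
      expect_equal(as.numeric(v), as.numeric(oracle_bucket_vector(pk, grid)))
      expect_equal(names(v), names(oracle_bucket_vector(pk, grid)))
      n_in <- sum(assign_bucket(pk$mz, pk$rt, grid)$in_range)
      expect_equal(attr(v, "n_out_of_range"), 80 - n_in)
    }
  })
})

test_that("empty and corrupt peak lists are handled explicitly", {
  grid <- small_grid()
  expect_warning(v <- bucket_peaklist(tibble::tibble(mz = numeric(), rt = numeric(),
                                                     intensity = numeric()), grid),
                 "empty peak list")
  expect_true(all(v == 0))
  expect_error(bucket_peaklist(tibble::tibble(mz = 100, rt = 1, intensity = -2), grid),
               "negative")
})

test_that("total-intensity normalization behaves as a simplex projection", {
  expect_equal(normalize_total(c(2, 3, 5)), c(0.2, 0.3, 0.5))
  expect_equal(normalize_total(7), 1)
  withr::with_seed(1, {
    for (i in 1:20) {
      x <- rlnorm(50, 3, 2)
      expect_lt(abs(sum(normalize_total(x)) - 1), 1e-12)
    }
  })
  expect_warning(z <- normalize_total(numeric(3)), "all-zero")
  expect_equal(z, numeric(3))
  expect_error(normalize_total(c(1, -1)), "negative")
})

test_that("feature matrices have normalized rows and a grid-determined column set", {
  grid <- bucket_grid(rt_width = 50, mz_width = 100,
                      rt_range = c(0, 100), mz_range = c(100, 500))  # 2 x 4 buckets
  peaks <- tibble::tibble(
    sample_id = rep(c("s1", "s2", "s3"), each = 2),
    mz = c(150, 250, 150, 450, 250, 450),
    rt = c(10, 60, 20, 70, 10, 90),
    intensity = c(1, 3, 2, 2, 5, 5)
  )
  fm <- build_matrix(peaks, grid)
  expect_s3_class(fm, "feature_matrix")
  expect_length(fm_buckets(fm), 8)
  v <- fm_values(fm)
  expect_equal(unname(rowSums(v)), rep(1, 3))
  expect_equal(unname(v["s1", c("0_0", "1_1")]), c(0.25, 0.75))

  # dropping all-empty buckets keeps a recorded, shared kept-bucket list
  fmd <- build_matrix(peaks, grid, drop_all_empty = TRUE)
  expect_setequal(fm_buckets(fmd), c("0_0", "1_1", "0_1", "1_3"))
  expect_equal(unname(rowSums(fm_values(fmd))), rep(1, 3))

  # projecting onto an explicit kept-bucket list reproduces the column set
  fmp <- build_matrix(peaks, grid, keep_buckets = fm_buckets(fmd))
  expect_identical(fm_buckets(fmp), fm_buckets(fmd))
})

test_that("within-bucket retention-time jitter leaves the matrix bit-identical", {
  grid <- small_grid()
  cohort <- generate_cohort(tiny_design(seed = 13))
  fm <- build_matrix(cohort, grid, drop_all_empty = FALSE)
  peaks <- cohort$peaks
  # jitter each rt toward its bucket centre by less than half the distance
  # to the nearest boundary, so no peak can cross a boundary
  idx <- floor((peaks$rt - grid$rt_range[1]) / grid$rt_width)
  centre <- grid$rt_range[1] + (idx + 0.5) * grid$rt_width
  withr::with_seed(8, jit <- runif(nrow(peaks), 0, 0.49))
  peaks$rt <- peaks$rt + (centre - peaks$rt) * jit
  fm2 <- build_matrix(peaks, grid, metadata = cohort$samples)
  expect_identical(fm_values(fm), fm_values(fm2))
})

test_that("normalized vectors are invariant to global intensity scaling", {
  grid <- small_grid()
  cohort <- generate_cohort(tiny_design(seed = 21))
  fm <- build_matrix(cohort, grid, drop_all_empty = TRUE)
  scaled <- dplyr::mutate(cohort$peaks,
                          intensity = intensity * 7.3)
  fm2 <- build_matrix(scaled, grid, metadata = cohort$samples,
                      keep_buckets = fm_buckets(fm))
  expect_equal(fm_values(fm), fm_values(fm2), tolerance = 1e-12)
})

test_that("two cohorts bucketed separately share one column structure", {
  grid <- small_grid()
  fm1 <- build_matrix(generate_cohort(tiny_design(seed = 1)), grid)
  fm2 <- build_matrix(generate_cohort(tiny_design(seed = 2)), grid)
  expect_identical(fm_buckets(fm1), fm_buckets(fm2))
  expect_identical(fm_buckets(fm1), bucketforest:::all_bucket_ids(grid))
})
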