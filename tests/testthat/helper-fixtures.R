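# small reusable designs and independent oracles

tiny_design <- function(seed = 7, ...) {
  args <- modifyList(list(
    origin_counts = c(A = 10, B = 10),
    region_counts = NULL, production_counts = NULL, variety_counts = NULL,
    n_background = 30, n_markers = 4, n_days = 2,
    noise_sigma = 0.1, dropout = 0, seed = seed
  ), list(...))
  do.call(cohort_design, args)
}

small_grid <- function() bucket_grid(rt_width = 20, mz_width = 2,
                                     rt_range = c(0, 810), mz_range = c(100, 1000))

# naive O(peaks x buckets) bucketing: loop over every bucket's boundaries
oracle_bucket_vector <- function(peaks, grid) {
  out <- numeric(grid$n_rt * grid$n_mz)
  nm <- character(length(out))
  k <- 0L
  for (i in seq_len(grid$n_rt) - 1L) {
    rt_lo <- grid$rt_range[1] + i * grid$rt_width
    rt_hi <- min(rt_lo + grid$rt_width, grid$rt_range[2])
    rt_in <- peaks$rt >= rt_lo &
      (peaks$rt < rt_hi | (i == grid$n_rt - 1L & peaks$rt == grid$rt_range[2]))
    for (j in seq_len(grid$n_mz) - 1L) {
      mz_lo <- grid$mz_range[1] + j * grid$mz_width
      mz_hi <- min(mz_lo + grid$mz_width, grid$mz_range[2])
      mz_in <- peaks$mz >= mz_lo &
        (peaks$mz < mz_hi | (j == grid$n_mz - 1L & peaks$mz == grid$mz_range[2]))
      k <- k + 1L
      out[k] <- sum(peaks$intensity[rt_in & mz_in])
      nm[k] <- paste0(i, "_", j)
    }
  }
  stats::setNames(out, nm)
}

# exclusive intersections by per-member membership enumeration
oracle_intersections <- function(sets) {
  members <- unique(unlist(sets, use.names = FALSE))
  issue_names <- names(sets)
  labels <- vapply(members, function(m) {
    paste(issue_names[vapply(sets, function(s) m %in% s, logical(1))], collapse = " & ")
  }, character(1))
  table(labels)
}

random_peaklist <- function(n, grid, frac_outside = 0) {
  rt_lim <- grid$rt_range + c(-50, 50) * (frac_outside > 0)
  mz_lim <- grid$mz_range + c(-20, 20) * (frac_outside > 0)
  tibble::tibble(
    mz = runif(n, mz_lim[1], mz_lim[2]),
    rt = runif(n, rt_lim[1], rt_lim[2]),
    intensity = rlnorm(n, 5, 1)
  )
}

# gaussian feature matrix with labels, as a plain tibble train_forest accepts
sim_labeled_matrix <- function(n_per_class, p, shift_features = integer(),
                               shift = 0, classes = c("A", "B")) {
  n <- sum(n_per_class)
  y <- rep(classes, n_per_class)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  x[y == classes[2], shift_features] <- x[y == classes[2], shift_features] + shift
  fm <- tibble::as_tibble(x)
  fm$sample_id <- sprintf("S%03d", seq_len(n))
  fm$label <- y
  fm
}
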