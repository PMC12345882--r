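test_that("library honours design counts and marker-layer disjointness", {
  design <- cohort_design(
    origin_counts = c(A = 5, B = 5), region_counts = c(N = 4, S = 4),
    production_counts = c(c1 = 4, c2 = 4), variety_counts = c(v1 = 5, v2 = 5),
    n_background = 100, n_markers = 10, seed = 3
  )
  lib <- generate_library(design)
  expect_equal(nrow(lib), 140)
  expect_equal(sum(lib$role == "background"), 100)
  by_layer <- split(lib$compound_id[lib$role == "marker"],
                    purrr::map_chr(lib$marker[lib$role == "marker"], ~ .x$layer[1]))
  expect_setequal(names(by_layer), c("origin", "region", "production", "variety"))
  expect_true(all(lengths(by_layer) == 10))
  # pairwise disjoint compound sets at overlap 0
  expect_equal(anyDuplicated(unlist(by_layer)), 0L)
  # background compounds carry no marker annotation
  expect_true(all(purrr::map_int(lib$marker[lib$role == "background"], nrow) == 0L))
  # markers have exactly one (layer, class) row and effect != 1
  mk <- lib$marker[lib$role == "marker"]
  expect_true(all(purrr::map_int(mk, nrow) == 1L))
  expect_true(all(purrr::map_dbl(mk, ~ .x$effect) != 1))
  expect_identical(lib, generate_library(design))  # seed determinism
})

test_that("marker overlap plants shared compounds across two layers", {
  design <- cohort_design(
    origin_counts = c(A = 5, B = 5), region_counts = NULL,
    production_counts = NULL,
    variety_counts = c(v1 = 5, v2 = 5),
    n_background = 20, n_markers = 10,
    marker_overlap = c("origin:variety" = 0.5), seed = 3
  )
  lib <- generate_library(design)
  expect_equal(nrow(lib), 20 + 10 + 5)  # 5 variety markers merged into origin markers
  n_layers <- purrr::map_int(lib$marker, ~ length(unique(.x$layer)))
  expect_equal(sum(n_layers == 2), 5)
  shared <- lib$marker[n_layers == 2]
  expect_true(all(purrr::map_lgl(shared, ~ setequal(.x$layer, c("origin", "variety")))))
})

test_that("sample generation follows the stated intensity and rt formulas", {
  design <- tiny_design(n_background = 10, n_markers = 2, noise_sigma = 0, dropout = 0)
  lib <- generate_library(design)
  bg <- lib[lib$role == "background", ]
  attr(bg, "run_span") <- attr(lib, "run_span")
  attr(bg, "layers") <- attr(lib, "layers")

  withr::with_seed(1, {
    # identity batch effect, zero noise, all-background: intensities = base
    s <- generate_sample(bg, list(origin = "A"))
    expect_equal(sort(s$intensity), sort(bg$base_intensity))
    expect_equal(sort(s$rt), sort(bg$rt))

    # marker effect multiplies only in the labeled class
    mk <- lib[lib$role == "marker", ][1, ]
    cls <- mk$marker[[1]]$class
    eff <- mk$marker[[1]]$effect
    one <- bg[1, ]
    two <- dplyr::bind_rows(one, mk)
    attr(two, "run_span") <- attr(lib, "run_span")
    hit <- generate_sample(two, stats::setNames(list(cls), mk$marker[[1]]$layer))
    miss <- generate_sample(two, list(origin = setdiff(c("A", "B"), cls)))
    expect_equal(sort(hit$intensity), sort(c(one$base_intensity, mk$base_intensity * eff)))
    expect_equal(sort(miss$intensity), sort(c(one$base_intensity, mk$base_intensity)))

    # rt shift and stretch: rt' = rt * stretch + shift
    sh <- generate_sample(bg, list(origin = "A"),
                          effects = batch_effect(rt_shift = 5, rt_stretch = 1))
    expect_equal(sort(sh$rt), sort(bg$rt + 5))

    # intensity_scale multiplies every peak
    sc <- generate_sample(bg, list(origin = "A"),
                          effects = batch_effect(intensity_scale = 2))
    expect_equal(sort(sc$intensity), sort(2 * bg$base_intensity))
  })

  expect_error(generate_sample(lib, list(origin = "nope")), "unknown class")
})

test_that("default cohort reproduces the study's per-layer label counts", {
  cohort <- generate_cohort(cohort_design(seed = 1))
  s <- cohort$samples
  expect_equal(nrow(s), 193)
  expect_equal(as.vector(table(s$origin)[c("German", "non-German")]), c(117, 76))
  expect_equal(as.vector(table(s$region)[c("North", "South")]), c(79, 38))
  expect_equal(sum(!is.na(s$region)), 117)
  expect_equal(as.vector(table(s$production)[c("conventional", "organic")]), c(113, 40))
  expect_equal(sum(!is.na(s$production)), 153)
  expect_equal(sum(!is.na(s$variety)), 80)
  expect_equal(as.vector(table(s$variety)[c("Boskoop", "Braeburn", "Cripps Pink",
                                            "Elstar", "Gala", "Jonagold")]),
               c(9, 11, 12, 12, 28, 8))
  # day is assigned round-robin within class: no layer confounded with day
  expect_true(all(table(s$day) >= 1))
  tab <- table(s$day, s$origin)
  expect_true(max(abs(tab[, 1] / sum(tab[, 1]) - tab[, 2] / sum(tab[, 2]))) < 0.15)
})

test_that("cohort generation is deterministic and single-day designs share one batch", {
  d <- tiny_design(seed = 99)
  c1 <- generate_cohort(d)
  c2 <- generate_cohort(d)
  expect_identical(rlang::hash(c1$peaks), rlang::hash(c2$peaks))
  expect_identical(rlang::hash(c1$samples), rlang::hash(c2$samples))

  d1 <- tiny_design(seed = 99, n_days = 1)
  c3 <- generate_cohort(d1)
  expect_true(all(c3$samples$day == 1L))
  expect_length(c3$batch_effects, 1L)
})

test_that("classes differ exactly in their layer's differentially modulated markers", {
  design <- tiny_design(noise_sigma = 0, dropout = 0, n_days = 1,
                        rt_shift_max = 0, rt_stretch_max = 0,
                        scale_sigma = 0, sensitivity_sigma = 0)
  lib <- generate_library(design)
  withr::with_seed(2, {
    sa <- generate_sample(lib, list(origin = "A"))
    sb <- generate_sample(lib, list(origin = "B"))
  })
  joined <- dplyr::inner_join(sa, sb, by = c("mz", "rt"), suffix = c("_a", "_b"))
  expect_equal(nrow(joined), nrow(lib))
  differing <- joined$mz[joined$intensity_a != joined$intensity_b]
  is_diff_marker <- purrr::map_lgl(lib$marker, function(mk) {
    nrow(mk) > 0 && xor("A" %in% mk$class, "B" %in% mk$class)
  })
  expect_setequal(differing, lib$mz[is_diff_marker])
})

test_that("measurement day dominates the first principal component", {
  cohort <- generate_cohort(cohort_design(seed = 5))
  fm <- build_matrix(cohort, small_grid(), drop_all_empty = TRUE)
  ps <- pca_scores(fm, k = 2)
  eta2 <- function(v, f) summary(stats::lm(v ~ factor(f)))$r.squared
  r2_day <- eta2(ps$PC1, ps$day)
  r2_labels <- purrr::map_dbl(c("origin", "region", "production", "variety"), function(l) {
    ok <- !is.na(ps[[l]])
    eta2(ps$PC1[ok], ps[[l]][ok])
  })
  expect_gt(r2_day, max(r2_labels))
  expect_gt(r2_day, 0.5)
})

test_that("invalid designs are rejected as configuration errors", {
  expect_error(cohort_design(origin_counts = c(A = 0, B = 5)), "zero samples")
  expect_error(cohort_design(origin_counts = c(A = 3, B = 3),
                             region_counts = c(N = 5, S = 5),
                             production_counts = NULL, variety_counts = NULL),
               "labels more samples")
  expect_error(cohort_design(mz_range = c(500, 100)), "nonempty")
  expect_error(cohort_design(rt_range = c(0, 900), run_span = c(0, 810)), "run_span")
  expect_error(cohort_design(dropout = 1.5), "dropout")
  expect_error(cohort_design(marker_overlap = c("origin:nope" = 0.5)), "marker_overlap")
})
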