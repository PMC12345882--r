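test_that("inverse-class case weights equalize class totals and sum to one", {
  expect_equal(class_weights(c("A", "A", "B", "B")), rep(0.25, 4))
  w <- class_weights(c("A", "A", "A", "B"))
  expect_equal(w, c(1 / 6, 1 / 6, 1 / 6, 1 / 2))
  expect_equal(sum(w), 1)
  # class totals equal across arbitrary imbalance
  withr::with_seed(4, labs <- sample(rep(c("x", "y", "z"), c(50, 12, 3))))
  w3 <- class_weights(labs)
  expect_equal(as.vector(tapply(w3, labs, sum)), rep(1 / 3, 3))
  expect_equal(class_weights(letters[c(1, 1, 2, 2, 2)], mode = "uniform"), rep(0.2, 5))
  expect_error(class_weights(c("A", "A")), ">= 2 classes")
})

test_that("a perfectly separated cohort is classified near-perfectly out of bag", {
  withr::with_seed(11, fm <- sim_labeled_matrix(c(20, 20), 10,
                                                shift_features = 1, shift = 8))
  fit <- train_forest(fm, "label", rf_config(n_trees = 500, seed = 2))
  expect_gte(glance(fit)$accuracy, 95)
  cm <- oob_confusion(fit)
  expect_equal(sum(cm), 40)  # everyone OOB-evaluable at 500 trees
})

test_that("permuted labels give chance-level OOB accuracy", {
  withr::with_seed(12, {
    fm <- sim_labeled_matrix(c(30, 30), 10)  # no signal at all
    fm$label <- sample(fm$label)
  })
  fit <- train_forest(fm, "label", rf_config(n_trees = 500, seed = 3))
  acc <- glance(fit)$accuracy / 100
  bound <- 3 * sqrt(0.25 / 60)
  expect_gt(acc, 0.5 - bound)
  expect_lt(acc, 0.5 + bound)
})

test_that("package OOB bookkeeping agrees with the forest's own OOB predictions", {
  withr::with_seed(13, fm <- sim_labeled_matrix(c(25, 25), 8,
                                                shift_features = 1:2, shift = 1.5))
  fit <- train_forest(fm, "label", rf_config(n_trees = 500, seed = 5))
  ours <- fit$oob$estimate
  theirs <- fit$forest$predictions
  ok <- !is.na(ours) & !is.na(theirs)
  # identical up to vote ties, which are broken by class order on our side
  expect_gte(mean(ours[ok] == theirs[ok]), 0.98)
  # vote fractions sum to one wherever at least one tree was out of bag
  sums <- rowSums(fit$votes)[fit$oob$n_oob_trees > 0]
  expect_equal(unname(sums), rep(1, length(sums)))
})

test_that("samples drawn into every bootstrap are flagged and excluded from the table", {
  withr::with_seed(14, fm <- sim_labeled_matrix(c(15, 15), 5))
  expect_warning(fit <- train_forest(fm, "label", rf_config(n_trees = 3, seed = 1)),
                 "no OOB prediction")
  n_na <- sum(is.na(fit$oob$estimate))
  expect_gt(n_na, 0)
  cm <- oob_confusion(fit)
  expect_equal(sum(cm), 30 - n_na)           # OOB conservation
  expect_equal(attr(cm, "n_unscored"), n_na)
})

test_that("confusion tabulation counts true against OOB-predicted classes", {
  oob <- tibble::tibble(truth = factor(c("A", "A", "B")),
                        estimate = factor(c("A", "B", "B")),
                        n_oob_trees = 1L)
  cm <- oob_confusion(oob)
  expect_equal(unclass(cm)[, "A"], c(A = 1, B = 1))
  expect_equal(unclass(cm)[, "B"], c(A = 0, B = 1))
  all_right <- tibble::tibble(truth = factor(rep(c("A", "B"), 3)),
                              estimate = factor(rep(c("A", "B"), 3)))
  expect_equal(accuracy(oob_confusion(all_right)), 100)
})

test_that("training is deterministic under a fixed seed", {
  withr::with_seed(15, fm <- sim_labeled_matrix(c(20, 20), 10,
                                                shift_features = 1, shift = 1))
  f1 <- train_forest(fm, "label", rf_config(n_trees = 200, seed = 7))
  f2 <- train_forest(fm, "label", rf_config(n_trees = 200, seed = 7))
  expect_identical(f1$oob$estimate, f2$oob$estimate)
  expect_identical(f1$inbag, f2$inbag)
  f3 <- train_forest(fm, "label", rf_config(n_trees = 200, seed = 8))
  expect_false(identical(f1$inbag, f3$inbag))
})

test_that("inverse-class weighting lifts minority sensitivity on imbalanced cohorts", {
  # 113-vs-40 with weak minority signal, aggregated over seeded replicates
  sens <- sapply(1:2, function(s) {
    withr::with_seed(100 + s, fm <- sim_labeled_matrix(c(113, 40), 30,
                                                       shift_features = 1:5, shift = 0.6))
    sapply(c("inverse_class", "uniform"), function(m) {
      fit <- train_forest(fm, "label", rf_config(n_trees = 400,
                                                 case_weight_mode = m, seed = s))
      sensitivity(oob_confusion(fit), "B")
    })
  })
  expect_gte(mean(sens["inverse_class", ]), mean(sens["uniform", ]))
})

test_that("degenerate inputs are rejected", {
  withr::with_seed(16, fm <- sim_labeled_matrix(c(10, 10), 4))
  fm$label <- "same"
  expect_error(train_forest(fm, "label"), "single class")
  fm$label <- c(NA, rep(c("A", "B"), length.out = 19))
  expect_error(train_forest(fm, "label"), "unlabeled")
  expect_error(train_forest(fm, "nope"), "no label column")
})
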