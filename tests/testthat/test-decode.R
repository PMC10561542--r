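test_that("windowed features have the documented counts and values", {
  set.seed(1)
  ep <- make_test_epochs(2, 12)
  fm <- extract_features(ep, window = c(-1000, 1000))
  expect_equal(fm$n_per_electrode, 79)
  expect_equal(ncol(fm$X), 2 * 79)
  fm2 <- extract_features(ep, window = c(-500, 500))
  expect_equal(fm2$n_per_electrode, 39)
  # constant trace: every feature equals the constant
  ep$power[1, , ] <- 4.2
  fm3 <- extract_features(ep, window = c(-1000, 1000))
  expect_true(all(fm3$X[, fm3$map$electrode == "e01"] == 4.2))
  expect_error(extract_features(ep, window = c(0, 30)), "width")
  expect_error(extract_features(ep, window = c(-3000, 0)), "span")
})

test_that("mRMR ranks an informative feature first and is deterministic", {
  set.seed(2)
  y <- rep(c("a", "b", "c"), each = 30)
  X <- matrix(rnorm(90 * 12), 90, 12)
  X[, 7] <- as.integer(factor(y)) + rnorm(90, sd = 0.05)
  sel <- mrmr_select(X, y, 5)
  expect_equal(sel[1], 7)
  expect_identical(sel, mrmr_select(X, y, 5))
  expect_identical(sort(mrmr_select(X, y, 50)), 1:12)
  expect_error(mrmr_select(X, rep("a", 90), 3), "single class")
})

test_that("redundant copies of the informative feature are down-ranked", {
  set.seed(3)
  y <- rep(c("a", "b"), each = 40)
  X <- matrix(rnorm(80 * 10), 80, 10)
  X[, 1] <- as.integer(factor(y)) + rnorm(80, sd = 0.1)
  X[, 2] <- X[, 1] + rnorm(80, sd = 0.01)       # near-duplicate
  X[, 3] <- as.integer(factor(y)) * -1 + rnorm(80, sd = 0.3)  # complementary
  sel <- mrmr_select(X, y, 3)
  expect_equal(sel[1], 1)
  expect_false(sel[2] == 2)  # the duplicate is penalized for redundancy
})

test_that("cross-validated LDA separates planted classes and stays at chance on nulls", {
  set.seed(4)
  ep <- make_test_epochs(4, 120, tuned = 1:4, unit = "vowel", label = "i",
                         effect = 2)
  # make all three vowels separable by tuning different electrodes
  ep$power[2, ep$trials$vowel == "u", ] <- ep$power[2, ep$trials$vowel == "u", ] + 4
  fm <- extract_features(ep, window = c(-1000, 1000))
  res <- crossval_lda(fm, ep$trials$vowel, n_features = 60,
                      stratify_by = ep$trials$syllable)
  expect_gte(res$accuracy, 95)
  expect_equal(res$accuracy, 100 * mean(res$correct))
  expect_length(res$correct, 120)
  # folds partition trials
  expect_setequal(unique(res$folds), 1:5)
  expect_true(all(table(res$folds) >= 20))
  # label permutation destroys the signal: accuracy within the binomial band
  perm <- crossval_lda(fm$X, sample(ep$trials$vowel), n_features = 20)
  band <- qbinom(c(0.005, 0.995), 120, 1 / 3) / 120 * 100
  expect_gte(perm$accuracy, band[1])
  expect_lte(perm$accuracy, band[2])
})

test_that("leave-one-out cross-validation degenerates correctly", {
  set.seed(5)
  y <- rep(c("a", "b"), each = 6)
  X <- cbind(ifelse(y == "a", 1, -1) + rnorm(12, sd = 0.1),
             matrix(rnorm(24), 12))
  res <- crossval_lda(X, y, n_folds = 12, n_features = NULL)
  expect_equal(sort(unique(res$folds)), 1:12)
  expect_true(all(table(res$folds) == 1))
  expect_gte(res$accuracy, 90)
})

test_that("shrinkage LDA agrees with classic LDA when it is well conditioned", {
  skip_if_not_installed("MASS")
  set.seed(6)
  n <- 200
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 4), n, 4)
  X[y == "b", 1] <- X[y == "b", 1] + 2
  fit <- hgspeech:::lda_shrink_fit(X, y)
  pred <- hgspeech:::lda_shrink_predict(fit, X)
  ref <- as.character(predict(MASS::lda(X, grouping = y), X)$class)
  expect_gte(mean(pred == ref), 0.95)
})

test_that("encoding strength isolates informative electrodes", {
  set.seed(7)
  ep <- make_test_epochs(6, 96, tuned = 1, unit = "vowel", label = "i",
                         effect = 2)
  fm <- extract_features(ep, window = c(-1000, 1000))
  st <- electrode_encoding_strength(fm, ep$trials$vowel, n_features = 40)
  expect_s3_class(st, "encoding_result")
  tuned <- st$strength[st$electrode == "e01"]
  nulls <- st$strength[st$electrode != "e01"]
  full <- attr(st, "full")
  # the sole informative electrode carries roughly the full margin over chance
  expect_gt(tuned, full$accuracy - 100 / 3 - 15)
  expect_true(all(abs(nulls) <= 10))
  expect_true(all(abs(st$strength) <= full$accuracy))
  expect_error(
    electrode_encoding_strength(
      structure(list(X = fm$X[, 1:79],
                     map = fm$map[1:79, ], labels = fm$labels,
                     n_per_electrode = 79), class = "feature_matrix"),
      ep$trials$vowel),
    "2 electrodes")
})

test_that("null electrodes have near-zero strength across seeds", {
  deltas <- numeric(10)
  for (s in 1:10) {
    set.seed(100 + s)
    ep <- make_test_epochs(4, 72, tuned = 1, unit = "vowel", label = "i",
                           effect = 2)
    fm <- extract_features(ep, window = c(0, 500))
    st <- electrode_encoding_strength(fm, ep$trials$vowel, n_features = 20)
    deltas[s] <- mean(st$strength[st$electrode != "e01"])
  }
  expect_lt(abs(mean(deltas)), 2)
})

test_that("duplicated informative electrodes share (and cancel) credit", {
  set.seed(8)
  ep <- make_test_epochs(4, 96, tuned = 1, unit = "vowel", label = "i",
                         effect = 2)
  ep$power[2, , ] <- ep$power[1, , ]            # exact duplicate
  fm <- extract_features(ep, window = c(-1000, 1000))
  st <- electrode_encoding_strength(fm, ep$trials$vowel, n_features = 40)
  dup <- st$strength[st$electrode %in% c("e01", "e02")]
  expect_true(all(abs(dup) <= 10))              # redundancy nullifies each copy
})

test_that("top-encoder selection flags the right count with a tie policy", {
  s <- setNames(c(5, 4, 3, 2, 1, 0, -1, -2, -3, -4), paste0("e", 1:10))
  fl <- select_top_encoders(s, 0.30)
  expect_equal(sum(fl), 3)
  expect_true(all(fl[1:3]))
  expect_warning(select_top_encoders(setNames(rep(1, 10), paste0("e", 1:10))),
                 "tied")
})

test_that("cluster-specific windows tile the landmark interval", {
  set.seed(9)
  ep <- make_test_epochs(3, 60, tuned = 1:3, unit = "vowel", label = "i",
                         effect = 1.5)
  # a fabricated assignment whose only cluster spans the full decoding window
  lm <- structure(list(start_ms = -1000, onset_slope = 1, peak_ms = 0,
                       offset_slope = -1, end_ms = 1000, censored = FALSE),
                  class = "cluster_landmarks")
  asg <- structure(list(membership = rep(1L, 3), centroids = NULL,
                        landmarks = list(lm), share = 100,
                        time_ms = ep$time_ms), class = "cluster_assignment")
  res <- classify_cluster_windows(ep, ep$trials$vowel, asg,
                                  n_folds = 5, n_features = 30,
                                  stratify_by = ep$trials$syllable)
  expect_length(res, 1)
  expect_equal(attr(res[[1]], "window"), c(-1000, 1000))
  # width = 2L/80 = 50 ms, stride 25 ms: identical to the fixed-window grid
  fm <- extract_features(ep, window = c(-1000, 1000))
  set.seed(10)
  fixed <- crossval_lda(fm, ep$trials$vowel, n_features = 30,
                        stratify_by = ep$trials$syllable)
  expect_equal(res[[1]]$n_features, fixed$n_features)
  # paired subject-level comparison runs
  tt <- compare_windows(c(36, 40, 35), c(35, 41, 33))
  expect_s3_class(tt, "htest")
})

test_that("pooled and per-subject chance decisions use the exact binomial", {
  # 9/10 correct in a 2-class problem is significant (P(9) = 11/1024)
  res <- chance_significance(list(s1 = c(rep(1, 9), 0)), n_classes = 2)
  expect_true(res$pooled$significant)
  # exactly at 1/c with large n is not significant
  v <- rep(c(1, 0, 0, 0), 100)
  res2 <- chance_significance(list(s1 = v), n_classes = 4)
  expect_false(res2$pooled$significant)
  # pooling concatenates subjects
  res3 <- chance_significance(list(a = c(1, 1, 0), b = c(1, 0)), n_classes = 2)
  expect_equal(res3$pooled$n, 5)
  expect_equal(res3$pooled$n_correct, 3)
  expect_equal(nrow(res3$per_subject), 2)
})
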