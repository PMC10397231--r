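test_that("t-test filter matches stats::t.test and excludes constants", {
  tb <- generate_feature_dataset(20L, 30L, 4L, 3, seed = 1L)
  sel <- ttest_filter(tb, 0.05)
  for (j in c(1L, 9L, 23L)) {
    p_ref <- stats::t.test(tb$x[tb$y == 0L, j], tb$x[tb$y == 1L, j],
                           var.equal = TRUE)$p.value
    expect_equal(sel$stats$p[j], p_ref, tolerance = 1e-12)
  }
  expect_true(all(sprintf("feature_%03d", 1:4) %in% sel$selected))
  tb$x[, 7L] <- 3.14
  expect_warning(sel2 <- ttest_filter(tb), "constant")
  expect_false("feature_007" %in% sel2$selected)
  expect_error(ttest_filter(feature_table(tb$x, rep(0L, 20L))), "class")
})

test_that("t-test filter is calibrated under the null and powered at effect 3", {
  rates <- vapply(1:20, function(s) {
    tb <- generate_feature_dataset(20L, 500L, 0L, 0, seed = 100L + s)
    length(ttest_filter(tb, 0.05)$selected) / 500
  }, numeric(1L))
  expect_lt(abs(mean(rates) - 0.05), 0.02)
  hits <- vapply(1:60, function(s) {
    tb <- generate_feature_dataset(20L, 20L, 1L, 3, seed = 200L + s)
    "feature_001" %in% ttest_filter(tb, 0.05)$selected
  }, logical(1L))
  expect_gte(mean(hits), 0.95)
})

test_that("F-test scan finds the informative feature and honours tie rules", {
  tb <- generate_feature_dataset(20L, 15L, 1L, 3, seed = 5L)
  res <- ftest_threshold_scan(tb, "svm", seed = 1L)
  expect_true("feature_001" %in% res$selected)
  expect_gte(res$accuracy, 0.75)
  # a 1-threshold grid is a plain filter at that threshold
  one <- ftest_threshold_scan(tb, "svm", grid = 0.01, seed = 1L)
  expect_setequal(one$selected,
                  res$stats$feature[!is.na(res$stats$p) & res$stats$p < 0.01])
  # all-noise: near-chance accuracy; tie rule returns a smallest subset
  nz <- generate_feature_dataset(20L, 15L, 0L, 0, seed = 6L)
  rn <- ftest_threshold_scan(nz, "knn", grid = seq(0.01, 0.10, 0.01), seed = 1L)
  sc <- rn$scan
  best_acc <- max(sc$accuracy, na.rm = TRUE)
  expect_equal(length(rn$selected),
               min(sc$n_features[!is.na(sc$accuracy) & sc$accuracy == best_acc]))
  expect_error(ftest_threshold_scan(tb, grid = numeric(0)), "empty")
  expect_error(ftest_threshold_scan(nz, grid = 1e-9), "no threshold")
})

test_that("best-first search finds the unique separating pair (vs enumeration)", {
  set.seed(31)
  n <- 16L
  y <- rep(0:1, each = 8L)
  u <- runif(n, -1, 1)
  x <- cbind(f1 = u + ifelse(y == 1L, 1.2, 0) + rnorm(n, 0, 0.1),
             f2 = -u + ifelse(y == 1L, 1.2, 0) + rnorm(n, 0, 0.1),
             f3 = rnorm(n), f4 = rnorm(n))
  tb <- feature_table(x, y)
  # neither informative feature separates on its own
  expect_lt(loocv_accuracy(tb, "f1", "knn", seed = 1L)$accuracy, 1)
  expect_lt(loocv_accuracy(tb, "f2", "knn", seed = 1L)$accuracy, 1)
  # oracle: exhaustive enumeration of all 15 non-empty subsets
  subs <- unlist(lapply(1:4, function(k)
    utils::combn(colnames(x), k, simplify = FALSE)), recursive = FALSE)
  accs <- vapply(subs, function(s)
    loocv_accuracy(tb, s, "knn", seed = 1L)$accuracy, numeric(1L))
  best_minimal <- subs[accs == max(accs)]
  best_minimal <- best_minimal[[which.min(lengths(best_minimal))]]
  bf <- best_first_search(tb, "knn", seed = 1L)
  expect_setequal(bf$selected, best_minimal)
  expect_setequal(bf$selected, c("f1", "f2"))
  expect_equal(bf$accuracy, max(accs))
})

test_that("best-first with one feature keeps it only if it beats the baseline", {
  set.seed(8)
  y <- rep(0:1, each = 8L)
  good <- feature_table(cbind(f1 = y * 3 + rnorm(16L, 0, 0.3)), y)
  bf <- best_first_search(good, "knn", seed = 1L)
  expect_equal(bf$selected, "f1")
  noise <- feature_table(cbind(f1 = rnorm(16L)), y)
  bfn <- best_first_search(noise, "knn", seed = 1L)
  base <- loocv_accuracy(noise, character(0), "knn", seed = 1L)$accuracy
  if (length(bfn$selected) > 0L) expect_gt(bfn$accuracy, base)
})

test_that("permuted labels keep the best-first incumbent inside the chance band", {
  set.seed(9)
  tb <- generate_feature_dataset(20L, 6L, 2L, 2, seed = 10L)
  tb_perm <- feature_table(tb$x, sample(tb$y))
  bf <- best_first_search(tb_perm, "knn", max_no_improve = 3L, seed = 1L)
  expect_lte(bf$accuracy, 0.9)
})

test_that("the classifier battery runs LOOCV for every classifier", {
  tb <- generate_feature_dataset(20L, 10L, 3L, 4, seed = 3L)
  sel <- ttest_filter(tb)
  acc <- evaluate_classifiers(tb, sel, seed = 1L)
  expect_named(acc, classifier_names())
  expect_true(all(acc[c("svm", "knn", "logistic")] >= 0.9, na.rm = TRUE))
  lo <- loocv_accuracy(tb, sel$selected, "svm", seed = 1L)
  expect_length(lo$predictions, 20L)
  expect_equal(lo$accuracy, mean(lo$predictions == tb$y))
  expect_error(evaluate_classifiers(tb, character(0)), "empty")
  expect_error(loocv_accuracy(tb, "nope", "svm"), "unknown features")
  expect_error(loocv_accuracy(tb, sel$selected, "fancy_net"), "unknown classifier")
})

test_that("label-independent features give near-chance LOOCV accuracy", {
  set.seed(14)
  accs <- vapply(1:10, function(s) {
    tb <- generate_feature_dataset(20L, 5L, 0L, 0, seed = 300L + s)
    loocv_accuracy(tb, colnames(tb$x)[1:3], "svm", seed = s)$accuracy
  }, numeric(1L))
  expect_true(mean(accs >= 0.2 & accs <= 0.8) >= 0.8)
})

test_that("nested selection never sees the held-out subject and is honest", {
  tb <- generate_feature_dataset(16L, 25L, 2L, 2.5, seed = 4L)
  flat <- classify_with_selection(tb, function(t) ttest_filter(t, 0.05),
                                  "svm", nested = FALSE, seed = 1L)
  nest <- classify_with_selection(tb, function(t) ttest_filter(t, 0.05),
                                  "svm", nested = TRUE, seed = 1L)
  expect_false(flat$nested)
  expect_true(nest$nested)
  expect_true(nest$accuracy >= 0 && nest$accuracy <= 1)
  expect_s3_class(flat$selection, "selection_result")
})
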