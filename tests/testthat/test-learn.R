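test_that("balanced splits have equal classes and no position overlap", {
  sim <- simulate_biased(length = 20000, beta = 10, n_reads = 40000, seed = 19)
  cfg <- pool_config(scale = 0.05, seed = 7)
  pool <- suppressWarnings(build_pool(sim$ref, sim$track, cfg))
  for (mr in c(1L, 6L, 11L)) {
    split <- suppressWarnings(make_split(pool, min_reads = mr,
                                         feature_set = "all", seed = 3))
    for (ds in list(split$train, split$test)) {
      expect_equal(sum(ds$y == 0L), sum(ds$y == 1L))
    }
    # brute-force overlap scan on (chrom, pos)
    key <- function(ds) paste(ds$ids$chrom, ds$ids$pos)
    expect_length(intersect(key(split$train), key(split$test)), 0L)
    # class-1 rows really have freq >= mr, class-0 rows freq 0
    freq_at <- function(ds) {
      m <- match(ds$ids$pos, pool$instances$pos)
      pool$instances$freq[m]
    }
    expect_true(all(freq_at(split$train)[split$train$y == 1L] >= mr))
    expect_true(all(freq_at(split$train)[split$train$y == 0L] == 0L))
  }
})

test_that("split halves follow the documented counting rules", {
  # 10 class-0 and plentiful class-1: 5+5 / 5+5
  wins <- random_windows(30, 41, seed = 44)
  pool <- make_pool(wins, freqs = c(rep(0, 10), rep(3, 20)))
  split <- make_split(pool, min_reads = 1, feature_set = "mono", seed = 1)
  expect_equal(as.integer(table(split$train$y)), as.integer(table(split$test$y)))
  expect_equal(sum(split$train$y == 0L), 5L)
  expect_equal(sum(split$test$y == 0L), 5L)

  # scarce class 1 shrinks both classes to floor(7/2) = 3 per half
  pool2 <- make_pool(wins[1:17], freqs = c(rep(0, 10), rep(2, 7)))
  expect_warning(split2 <- make_split(pool2, 1, "mono", seed = 1), "shrinking")
  expect_equal(as.integer(table(split2$train$y)), c(3L, 3L))
  expect_equal(as.integer(table(split2$test$y)), c(3L, 3L))

  # odd class-0 count: extra instance goes to train
  pool3 <- make_pool(wins, freqs = c(rep(0, 11), rep(2, 19)))
  split3 <- make_split(pool3, 1, "mono", seed = 1)
  expect_equal(sum(split3$train$y == 0L), 6L)
  expect_equal(sum(split3$test$y == 0L), 5L)

  pool4 <- make_pool(wins[1:10], freqs = rep(0, 10))
  expect_error(make_split(pool4, 1, "mono"), "frequency >= 1")
})

test_that("label shuffling preserves the class multiset and is seeded", {
  ds <- make_gaussian_dataset(30, 5, shift = 1, seed = 2)
  reps <- shuffle_labels(ds, times = 10, seed = 6)
  expect_length(reps, 10L)
  for (r in reps) {
    expect_equal(sort(r$y), sort(ds$y))
    expect_identical(r$x, ds$x)
  }
  expect_false(all(vapply(reps, function(r) identical(r$y, ds$y), logical(1))))
  reps2 <- shuffle_labels(ds, times = 10, seed = 6)
  expect_identical(lapply(reps, `[[`, "y"), lapply(reps2, `[[`, "y"))
})

test_that("3-NN follows proximity and plurality rules", {
  # coincident neighbors with one label win outright
  train <- labeled_dataset(rbind(c(0, 0), c(0, 0), c(0, 0), c(9, 9)),
                           c(1L, 1L, 1L, 0L))
  test <- labeled_dataset(rbind(c(0, 0)), 1L)
  expect_equal(knn_classify(train, test)$predicted, 1L)

  # majority beats proximity: nearest is class 0, two at distance 2 are class 1
  train2 <- labeled_dataset(rbind(1, 2, 2), c(0L, 1L, 1L))
  test2 <- labeled_dataset(rbind(0), 1L)
  expect_equal(knn_classify(train2, test2)$predicted, 1L)

  expect_error(knn_classify(labeled_dataset(rbind(1, 2), c(0L, 1L)), test2),
               "smaller than K")
})

test_that("3-NN matches the exhaustive-sort oracle on random data", {
  for (s in 1:25) {
    tr <- make_gaussian_dataset(15, 4, shift = 0.8, seed = s)
    te <- make_gaussian_dataset(10, 4, shift = 0.8, seed = s + 1000)
    got <- knn_classify(tr, te)
    want <- knn_oracle(tr, te)
    expect_identical(got$predicted, want$predicted)
    expect_equal(got$accuracy, want$accuracy)
  }
})

test_that("3-NN agrees with an established reference implementation", {
  tr <- make_gaussian_dataset(40, 6, shift = 0.7, seed = 99)
  te <- make_gaussian_dataset(25, 6, shift = 0.7, seed = 100)
  got <- knn_classify(tr, te)$predicted
  ref <- as.integer(as.character(class::knn(tr$x, te$x, factor(tr$y), k = 3)))
  expect_identical(got, ref)
})

test_that("PEI arithmetic matches its definition", {
  expect_equal(compute_pei(52.41), 0.0482)
  expect_equal(compute_pei(100), 1)
  expect_equal(compute_pei(50), 0)
  expect_lt(compute_pei(49), 0)
  expect_error(compute_pei(101), "percentage")
  expect_error(compute_pei(-2), "percentage")
  # strictly increasing in accuracy
  acc <- seq(0, 100, by = 0.5)
  expect_true(all(diff(compute_pei(acc)) > 0))
})

test_that("measure_pei reports replicates, derived seeds and the affected flag", {
  sim <- simulate_biased(length = 20000, order = 2, beta = 20,
                         n_reads = 40000, seed = 27)
  res <- suppressWarnings(
    measure_pei(sim$ref, sim$track, min_reads = 1, feature_set = "all",
                pool_config = pool_config(scale = 0.04), replicates = 5,
                seed = 70))
  expect_length(res$replicates, 5L)
  expect_equal(res$seeds, 71:75)
  expect_equal(res$mean_accuracy, mean(res$replicates))
  expect_equal(res$pei, (res$mean_accuracy - 50) / 50)
  expect_identical(res$affected, res$pei > 0.05)
  expect_true(res$affected)

  res2 <- suppressWarnings(
    measure_pei(sim$ref, sim$track, min_reads = 1, feature_set = "all",
                pool_config = pool_config(scale = 0.04), replicates = 5,
                seed = 70))
  expect_identical(res$replicates, res2$replicates)
})
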