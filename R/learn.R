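# Balanced classification datasets, the 3-nearest-neighbor classifier, the
# label-shuffling null and the Pattern Effect Index.

#' Construct a labeled dataset
#'
#' @param x numeric feature matrix, one row per instance.
#' @param y integer class labels in \{0, 1\}.
#' @param ids data frame with `chrom` and `pos` identifying each instance
#'   (optional, used to verify train/test disjointness).
#' @param meta list of dataset metadata (problem, feature set, seed).
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(x, y, ids = NULL, meta = list()) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop("feature matrix and labels disagree in length")
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0 or 1")
  if (!is.null(ids) && nrow(ids) != length(y)) stop("ids and labels disagree in length")
  structure(list(x = x, y = y, ids = ids, meta = meta),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d instances x %d features (class 0: %d, class 1: %d)\n",
              nrow(x$x), ncol(x$x), sum(x$y == 0L), sum(x$y == 1L)))
  invisible(x)
}

#' Build a balanced train/test split from a sequence pool
#'
#' The three classification problems contrast positions with no read
#' against positions with at least `min_reads` reads (1, 6 or 11). The
#' frequency-0 instances are split into two equal halves (odd count: the
#' extra instance goes to train) and labeled class 0; an equal number of
#' instances with frequency >= `min_reads` is sampled without replacement
#' for each half and labeled class 1, so train and test are each balanced
#' and no (chrom, pos) appears in both. If class 1 is scarcer than class 0
#' both classes shrink to the largest feasible equal per-half size, with a
#' warning.
#'
#' @param pool a `sequence_pool`.
#' @param min_reads minimum read count defining class 1 (1, 6 or 11).
#' @param feature_set one of `"all"`, `"mono"`, `"multi"` (see
#'   [extract_features()]).
#' @param seed integer seed controlling the sampling.
#' @return An object of class `split_pair`: list with `train` and `test`
#'   `labeled_dataset`s.
#' @export
make_split <- function(pool, min_reads = 1L, feature_set = c("all", "mono", "multi"),
                       seed = 1L) {
  stopifnot(inherits(pool, "sequence_pool"))
  feature_set <- match.arg(feature_set)
  min_reads <- as.integer(min_reads)
  inst <- pool$instances
  i0 <- which(inst$freq == 0L)
  i1 <- which(inst$freq >= min_reads)
  if (length(i0) == 0L) stop("no frequency-0 instances in pool")
  if (length(i1) == 0L) stop("no instances with frequency >= ", min_reads)

  n0 <- length(i0); n1 <- length(i1)
  if (n1 >= n0) {
    n_train0 <- ceiling(n0 / 2); n_test0 <- n0 - n_train0
  } else {
    m <- floor(n1 / 2)
    if (m == 0L) stop("too few class-1 instances to form a split")
    warning(sprintf("only %d class-1 instances for %d class-0; shrinking both classes to %d per half",
                    n1, n0, m))
    n_train0 <- n_test0 <- m
  }
  sel <- with_seed(seed, {
    o0 <- sample(i0)
    o1 <- sample(i1)
    list(train0 = o0[seq_len(n_train0)],
         test0 = o0[n_train0 + seq_len(n_test0)],
         train1 = o1[seq_len(n_train0)],
         test1 = o1[n_train0 + seq_len(n_test0)])
  })
  problem <- sprintf("0vs%d+", min_reads)
  build <- function(r0, r1) {
    rows <- c(r0, r1)
    labeled_dataset(extract_feature_matrix(inst$window[rows], feature_set),
                    y = rep(c(0L, 1L), c(length(r0), length(r1))),
                    ids = inst[rows, c("chrom", "pos")],
                    meta = list(problem = problem, feature_set = feature_set,
                                seed = seed))
  }
  structure(list(train = build(sel$train0, sel$train1),
                 test = build(sel$test0, sel$test1)),
            class = "split_pair")
}

#' @export
print.split_pair <- function(x, ...) {
  cat("<split_pair>\n  train: "); print(x$train)
  cat("  test:  "); print(x$test)
  invisible(x)
}

#' Randomly shuffle dataset labels
#'
#' Produces label-permuted replicates of a dataset for the null
#' calibration: each replicate permutes the labels uniformly at random, so
#' the class counts are preserved while any feature-label association is
#' destroyed.
#'
#' @param ds a `labeled_dataset`.
#' @param times number of replicates (>= 1).
#' @param seed integer seed.
#' @return List of `times` `labeled_dataset`s.
#' @export
shuffle_labels <- function(ds, times = 10L, seed = 1L) {
  stopifnot(inherits(ds, "labeled_dataset"), times >= 1L)
  with_seed(seed, lapply(seq_len(times), function(i) {
    out <- ds
    out$y <- sample(ds$y)
    out
  }))
}

#' K-nearest-neighbor classification
#'
#' For each test instance the K training instances with smallest Euclidean
#' distance vote; the majority label is assigned (with K = 3 and binary
#' labels no vote can tie). Distance ties at the K-th neighbor are broken
#' by lower training-instance index so results are reproducible.
#'
#' @param train,test `labeled_dataset`s over the same feature space.
#' @param K number of neighbors (default 3).
#' @return List of class `classifier_result`: `accuracy` (percent),
#'   `predicted` and `truth` label vectors.
#' @export
knn_classify <- function(train, test, K = 3L) {
  stopifnot(inherits(train, "labeled_dataset"), inherits(test, "labeled_dataset"))
  K <- as.integer(K)
  if (nrow(train$x) < K) stop("training set smaller than K")
  if (ncol(train$x) != ncol(test$x)) stop("train and test feature spaces differ")
  tr <- train$x; te <- test$x
  # squared Euclidean distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2ab
  d2 <- outer(rowSums(te^2), rowSums(tr^2), "+") - 2 * tcrossprod(te, tr)
  d2[d2 < 0] <- 0  # numerical noise
  pred <- integer(nrow(te))
  for (i in seq_len(nrow(te))) {
    nb <- order(d2[i, ])[seq_len(K)]  # stable: ties keep lower train index
    votes <- train$y[nb]
    pred[i] <- as.integer(sum(votes) * 2L > K)
  }
  acc <- 100 * mean(pred == test$y)
  structure(list(accuracy = acc, predicted = pred, truth = test$y, K = K),
            class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf("<classifier_result> %d-NN accuracy %.2f%% on %d test instances\n",
              x$K, x$accuracy, length(x$truth)))
  invisible(x)
}

#' Pattern Effect Index from a classification accuracy
#'
#' PEI = (accuracy% - 50) / 50. A value of 1 means read positioning
#' completely follows the sequence pattern; values at or below 0 mean
#' positioning is random with respect to it. Values above 0.05 (three null
#' standard deviations above chance) are interpreted as affected.
#'
#' @param accuracy classification accuracy in percent, in \[0, 100\].
#' @return PEI in \[-1, 1\].
#' @export
compute_pei <- function(accuracy) {
  if (!is.numeric(accuracy) || any(accuracy < 0 | accuracy > 100)) {
    stop("accuracy must be a percentage in [0, 100]")
  }
  (accuracy - 50) / 50
}

#' PEI threshold above which positioning counts as pattern-affected
#' @export
PEI_AFFECTED_THRESHOLD <- 0.05

#' Measure the Pattern Effect Index of a read-start track
#'
#' Repeats \{build pool -> balanced split -> 3-NN classification -> PEI\}
#' `replicates` times with per-replicate seeds derived as `seed + i`, and
#' averages. The returned PEI is computed from the mean accuracy; tracks
#' with PEI > 0.05 are flagged as affected by the sequence pattern.
#'
#' @param refs reference sequence(s).
#' @param tracks read-start track(s).
#' @param min_reads class-1 definition (1, 6 or 11).
#' @param feature_set `"all"`, `"mono"` or `"multi"`.
#' @param pool_config a [pool_config()]; its seed field is overridden per
#'   replicate.
#' @param replicates number of measurement replicates (default 5).
#' @param seed base seed.
#' @param K neighbors for the classifier (default 3).
#' @return An object of class `pei_result` with fields `replicates`
#'   (accuracy percentages), `mean_accuracy`, `sd_accuracy`, `pei`,
#'   `affected` and `seeds`.
#' @export
measure_pei <- function(refs, tracks, min_reads = 1L,
                        feature_set = c("all", "mono", "multi"),
                        pool_config = startbias::pool_config(),
                        replicates = 5L, seed = 1L, K = 3L) {
  feature_set <- match.arg(feature_set)
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 1L)
  seeds <- as.integer(seed) + seq_len(replicates)
  accs <- vapply(seeds, function(s) {
    cfg <- pool_config
    cfg$seed <- s
    pool <- build_pool(refs, tracks, cfg)
    split <- make_split(pool, min_reads = min_reads, feature_set = feature_set,
                        seed = s)
    knn_classify(split$train, split$test, K = K)$accuracy
  }, numeric(1))
  mean_acc <- mean(accs)
  pei <- compute_pei(mean_acc)
  structure(list(replicates = accs, mean_accuracy = mean_acc,
                 sd_accuracy = stats::sd(accs), pei = pei,
                 affected = pei > PEI_AFFECTED_THRESHOLD, seeds = seeds,
                 problem = sprintf("0vs%d+", as.integer(min_reads)),
                 feature_set = feature_set),
            class = "pei_result")
}

#' @export
print.pei_result <- function(x, ...) {
  cat(sprintf("<pei_result> %s, features: %s\n", x$problem, x$feature_set))
  cat(sprintf("  accuracies: %s\n", paste(sprintf("%.2f", x$replicates), collapse = " ")))
  cat(sprintf("  mean %.2f%% (sd %.2f) -> PEI %.4f (%s)\n",
              x$mean_accuracy, if (is.na(x$sd_accuracy)) 0 else x$sd_accuracy,
              x$pei, if (x$affected) "affected" else "not affected"))
  invisible(x)
}
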