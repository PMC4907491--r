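# Shared fixtures and independent oracles, all built in code.

# sequence_pool built directly from windows + frequencies, bypassing
# build_pool, for unit tests of the summary tables
make_pool <- function(windows, freqs, chrom = "chrT") {
  h <- (nchar(windows[1]) - 1L) %/% 2L
  inst <- data.frame(chrom = chrom,
                     pos = seq_along(windows) - 1L + h,
                     freq = as.integer(freqs),
                     stratum = ifelse(freqs >= 11, "11+", as.character(freqs)),
                     window = windows,
                     stringsAsFactors = FALSE)
  structure(list(instances = inst,
                 provenance = list(chroms = chrom, seed = NA, halfwidth = h,
                                   strata = table(inst$stratum))),
            class = "sequence_pool")
}

# random labeled dataset: two Gaussian clouds, continuous features, so
# distance ties have probability zero
make_gaussian_dataset <- function(n_per_class, p, shift = 0, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(stats::rnorm(n_per_class * p), ncol = p),
               matrix(stats::rnorm(n_per_class * p, mean = shift), ncol = p))
    colnames(x) <- paste0("f", seq_len(p))
    labeled_dataset(x, rep(c(0L, 1L), each = n_per_class))
  })
}

# Independent K-nearest-neighbor oracle: per test point, explicit
# distance computation and full sort, majority vote.
knn_oracle <- function(train, test, K = 3L) {
  pred <- integer(nrow(test$x))
  for (i in seq_len(nrow(test$x))) {
    d <- apply(train$x, 1L, function(row) sqrt(sum((test$x[i, ] - row)^2)))
    nb <- sort.int(d, index.return = TRUE)$ix[seq_len(K)]
    pred[i] <- as.integer(mean(train$y[nb]) > 0.5)
  }
  list(accuracy = 100 * mean(pred == test$y), predicted = pred)
}

# brute-force k-mer counter by substring extraction (independent of
# Biostrings), used as the counting oracle
count_kmers_oracle <- function(window, k) {
  km <- vapply(seq_len(nchar(window) - k + 1L),
               function(i) substr(window, i, i + k - 1L), "")
  counts <- table(factor(km, levels = startbias_all_kmers(k)))
  as.integer(counts)
}

# count of a named class in a table, 0 when absent
tab_count <- function(tab, name) {
  v <- suppressWarnings(tab[name])
  if (is.na(v)) 0L else as.integer(v)
}

startbias_all_kmers <- function(k) {
  grid <- expand.grid(rep(list(c("A", "C", "G", "T")), k),
                      stringsAsFactors = FALSE)
  do.call(paste0, rev(grid))
}

# random ACGT window strings
random_windows <- function(n, width, seed = 1) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
    }, "")
  })
}

# toy split where only some feature columns carry the class signal
make_toy_split <- function(n_per_class = 25, p = 8, informative = 3,
                           sep = 3, seed = 1) {
  withr::with_seed(seed, {
    gen <- function() {
      x <- matrix(stats::runif(2 * n_per_class * p), ncol = p)
      y <- rep(c(0L, 1L), each = n_per_class)
      x[, informative] <- x[, informative] + sep * y
      colnames(x) <- paste0("f", seq_len(p))
      labeled_dataset(x, y)
    }
    structure(list(train = gen(), test = gen()), class = "split_pair")
  })
}

# exhaustive fitness search over all non-empty masks (p <= 10)
best_mask_oracle <- function(split, p) {
  best <- -Inf; best_mask <- NULL
  for (code in seq_len(2^p - 1L)) {
    mask <- as.integer(intToBits(code)[1:p])
    ms <- list(train = split$train, test = split$test)
    ms$train$x <- split$train$x[, mask == 1L, drop = FALSE]
    ms$test$x <- split$test$x[, mask == 1L, drop = FALSE]
    acc <- knn_classify(ms$train, ms$test)$accuracy
    if (acc > best) {
      best <- acc
      best_mask <- mask
    }
  }
  list(mask = best_mask, accuracy = best)
}

# simulate a reference + biased track with an order-k model whose
# background is the reference's own global k-mer distribution
simulate_biased <- function(length = 50000, gc = 0.4, order = 2L, beta = 0,
                            n_reads = 1e5, seed = 1) {
  ref <- simulate_reference(length, gc_distribution(gc), seed = seed)
  bg <- global_distribution(ref, order)
  model <- bias_model(order = order, beta = beta, background = bg)
  track <- place_reads(ref, model, n_reads, seed = seed + 1000L)
  list(ref = ref, track = track, model = model)
}
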