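# k-mer distribution features and the sequence-complexity score.
#
# Feature order is fixed lexicographic (A < C < G < T) within each k-mer
# order, so serialized feature matrices are bit-stable across runs.

#' Construct a k-mer distribution
#'
#' A normalized frequency vector over all 4^k k-mers of one order, indexed
#' lexicographically (A < C < G < T).
#'
#' @param k k-mer order (1-4).
#' @param freqs numeric vector of length 4^k; normalized to sum 1 unless it
#'   is all zero. May be named (names must then match the lexicographic
#'   k-mer order) or unnamed.
#' @return An object of class `kmer_distribution` with fields `k` and
#'   `freqs` (named, sums to 1).
#' @export
kmer_distribution <- function(k, freqs) {
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= 4L)
  km <- all_kmers(k)
  if (length(freqs) != length(km)) {
    stop("expected ", length(km), " frequencies for order ", k)
  }
  if (!is.null(names(freqs))) {
    if (!setequal(names(freqs), km)) stop("frequency names are not the 4^k k-mers")
    freqs <- freqs[km]
  }
  freqs <- as.numeric(freqs)
  if (any(freqs < 0)) stop("negative frequency")
  tot <- sum(freqs)
  if (tot == 0) stop("empty k-mer distribution (all frequencies zero)")
  if (abs(tot - 1) > 1e-9) freqs <- freqs / tot
  names(freqs) <- km
  structure(list(k = k, freqs = freqs), class = "kmer_distribution")
}

#' Uniform k-mer distribution of a given order
#' @param k k-mer order (1-4).
#' @export
uniform_distribution <- function(k) {
  kmer_distribution(k, rep(1 / 4^k, 4^k))
}

#' Mono-nucleotide distribution with a given GC fraction
#'
#' G and C share the GC mass equally, A and T the remainder; convenient for
#' parameterizing reference simulations by GC content.
#'
#' @param gc GC fraction in \[0,1\].
#' @export
gc_distribution <- function(gc) {
  stopifnot(gc >= 0, gc <= 1)
  kmer_distribution(1L, c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2))
}

#' @export
print.kmer_distribution <- function(x, ...) {
  cat(sprintf("<kmer_distribution> order %d (%d k-mers)\n", x$k, 4^x$k))
  if (x$k == 1L) print(round(x$freqs, 4))
  invisible(x)
}

#' Count overlapping k-mers in a window
#'
#' @param window sequence string over \{A,C,G,T\} (N is an error; pooled
#'   windows are N-free by construction).
#' @param k k-mer order (1-4).
#' @return Named integer vector over all 4^k k-mers in lexicographic order;
#'   counts total `nchar(window) - k + 1`.
#' @export
count_kmers <- function(window, k) {
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= 4L, is.character(window), length(window) == 1L)
  if (nchar(window) < k) stop("window shorter than k")
  if (grepl("[^ACGT]", window)) stop("window contains non-ACGT characters")
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(window),
                                                 width = k)
  counts[all_kmers(k)]
}

#' Extract normalized k-mer distribution features from a window
#'
#' Counts the mono-, di-, tri- and tetra-nucleotides in the window and
#' normalizes each order's counts by that order's total, giving per-order
#' frequency blocks that each sum to 1. The three feature sets are
#' `mono` (4 mono-nucleotide features), `multi` (16 + 64 + 256 di-, tri-
#' and tetra-nucleotide features) and `all` (340 features, mono + multi).
#'
#' @param window sequence string over \{A,C,G,T\}, length >= 4.
#' @param feature_set one of `"mono"`, `"multi"`, `"all"`.
#' @return Named numeric feature vector (length 4, 336 or 340).
#' @export
extract_features <- function(window, feature_set = c("all", "mono", "multi")) {
  feature_set <- match.arg(feature_set)
  if (nchar(window) < 4L) stop("window shorter than 4 bp")
  drop(extract_feature_matrix(window, feature_set))
}

#' Extract features for many windows at once
#'
#' Batch version of [extract_features()]: one row per window, columns in
#' fixed lexicographic k-mer order.
#'
#' @param windows character vector of N-free windows (all of equal length
#'   >= 4).
#' @param feature_set one of `"mono"`, `"multi"`, `"all"`.
#' @return Numeric matrix, one row per window.
#' @export
extract_feature_matrix <- function(windows, feature_set = c("all", "mono", "multi")) {
  feature_set <- match.arg(feature_set)
  orders <- switch(feature_set, mono = 1L, multi = 2:4, all = 1:4)
  if (any(grepl("[^ACGT]", windows))) stop("windows contain non-ACGT characters")
  set <- Biostrings::DNAStringSet(windows)
  blocks <- lapply(orders, function(k) {
    cnt <- Biostrings::oligonucleotideFrequency(set, width = k,
                                                simplify.as = "matrix")
    cnt <- cnt[, all_kmers(k), drop = FALSE]
    cnt / rowSums(cnt)
  })
  do.call(cbind, blocks)
}

#' Euclidean distance between two feature vectors or distributions
#'
#' The distance sqrt(sum_x (F1(x) - F2(x))^2) used both for the global/local
#' distribution comparison and as the nearest-neighbor metric.
#'
#' @param u,v numeric vectors of equal length (or two `kmer_distribution`
#'   objects of the same order). If both are named, names must agree
#'   elementwise.
#' @return Non-negative distance; zero iff `u == v`.
#' @export
euclidean <- function(u, v) {
  if (inherits(u, "kmer_distribution")) u <- u$freqs
  if (inherits(v, "kmer_distribution")) v <- v$freqs
  if (length(u) != length(v)) stop("length mismatch: ", length(u), " vs ", length(v))
  if (!is.null(names(u)) && !is.null(names(v)) && !identical(names(u), names(v))) {
    stop("feature names do not match")
  }
  sqrt(sum((u - v)^2))
}

#' Sequence complexity score
#'
#' The geometric-mean combination sqrt((q/q_max) * (h/h_max)) of two
#' normalized terms: q, the number of transitions (adjacent unequal base
#' pairs, maximum length - 1), and h, the Shannon entropy of the
#' within-sequence base frequencies (natural log; maximum ln 4 for the full
#' 4-letter alphabet). Lies in \[0,1\]: 0 for a homopolymer, 1 for a
#' sequence that alternates at every step with equal base usage.
#'
#' @param seq sequence string over \{A,C,G,T\}, length >= 2; or a character
#'   vector of such sequences (vectorized).
#' @return Numeric complexity in \[0,1\], one value per input sequence.
#' @export
complexity <- function(seq) {
  stopifnot(is.character(seq))
  vapply(seq, function(s) {
    n <- nchar(s)
    if (n < 2L) stop("sequence shorter than 2 bp")
    if (grepl("[^ACGT]", s)) stop("sequence contains non-ACGT characters")
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    q <- sum(ch[-1] != ch[-n])
    p <- table(ch) / n
    h <- -sum(p * log(p))  # 0 * log(0) never occurs: table drops absent bases
    sqrt((q / (n - 1)) * (h / log(4)))
  }, numeric(1), USE.NAMES = FALSE)
}
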