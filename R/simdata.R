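# Synthetic references and biased read-start tracks with known ground-truth
# bias strength, so every downstream stage is testable without external data.

#' Define a composition-bias model for read placement
#'
#' Placement weight at an eligible position p is exp(beta * d(p)), where
#' d(p) is the Euclidean distance between the local k-mer distribution of
#' the +/- halfwidth window around p and the `background` distribution.
#' This exponential tilt makes beta = 0 the exact uniform null (all weights
#' equal) while keeping weights positive for any beta; it instantiates the
#' recognized pattern that reads start where the local nucleotide
#' distribution is dissimilar from the global one.
#'
#' @param order k of the k-mer composition driving the bias (1-4).
#' @param beta bias strength, >= 0 and dimensionless; 0 means uniform
#'   placement.
#' @param halfwidth window half-width in bp (default 20, i.e. 41-bp
#'   windows); must be >= `order`.
#' @param background `kmer_distribution` of order `order` acting as the
#'   global reference distribution in the distance term; defaults to the
#'   uniform distribution.
#' @return An object of class `bias_model`.
#' @export
bias_model <- function(order = 1L, beta = 0, halfwidth = 20L, background = NULL) {
  order <- as.integer(order)
  if (!order %in% 1:4) stop("order must be in 1..4")
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0) {
    stop("beta must be a single non-negative number")
  }
  halfwidth <- as.integer(halfwidth)
  if (halfwidth < order) stop("halfwidth must be >= order")
  if (is.null(background)) background <- uniform_distribution(order)
  if (!inherits(background, "kmer_distribution") || background$k != order) {
    stop("background must be a kmer_distribution of the model's order")
  }
  structure(list(order = order, beta = beta, halfwidth = halfwidth,
                 background = background),
            class = "bias_model")
}

#' @export
print.bias_model <- function(x, ...) {
  cat(sprintf("<bias_model> order %d, beta %.3g, halfwidth %d bp\n",
              x$order, x$beta, x$halfwidth))
  invisible(x)
}

#' Simulate a random reference sequence
#'
#' Bases are drawn i.i.d. from a mono-nucleotide composition; empirical
#' frequencies converge to `composition` as length grows.
#'
#' @param length sequence length in bp (>= 41, one full default window).
#' @param composition `kmer_distribution` of order 1 (default uniform).
#' @param seed integer seed; the same seed reproduces the same sequence.
#' @param name chromosome name for the simulated sequence.
#' @return A `reference_sequence`.
#' @export
simulate_reference <- function(length, composition = uniform_distribution(1L),
                               seed = 1L, name = "sim") {
  length <- as.integer(length)
  if (length < 41L) stop("sequence shorter than one window")
  if (!inherits(composition, "kmer_distribution") || composition$k != 1L) {
    stop("composition must be a mono-nucleotide (order 1) distribution")
  }
  bases <- with_seed(seed, sample(DNA_BASES, length, replace = TRUE,
                                  prob = composition$freqs))
  reference_sequence(name, paste(bases, collapse = ""))
}

#' Positions whose window is fully inside the reference and N-free
#'
#' Eligible positions (0-based) have index in \[halfwidth,
#' length - 1 - halfwidth\] and a +/- halfwidth window without N.
#'
#' @param ref a `reference_sequence`.
#' @param halfwidth window half-width in bp.
#' @return Integer vector of 0-based eligible positions.
#' @export
eligible_positions <- function(ref, halfwidth) {
  L <- length(ref)
  halfwidth <- as.integer(halfwidth)
  if (L < 2L * halfwidth + 1L) return(integer(0))
  centers <- halfwidth:(L - 1L - halfwidth)  # 0-based
  cs <- c(0L, cumsum(is.na(encode_bases(ref$seq))))
  # number of Ns in the 0-based window [p - halfwidth, p + halfwidth]
  n_in_window <- cs[centers + halfwidth + 2L] - cs[centers - halfwidth + 1L]
  centers[n_in_window == 0L]
}

# Local k-mer distance profile: for every window center in `centers`
# (0-based), the Euclidean distance between the window's order-k
# distribution and `background`. Sliding-window counts via per-category
# cumulative sums.
local_distance_profile <- function(ref, centers, order, halfwidth, background) {
  codes <- encode_bases(ref$seq)
  idx <- kmer_indices(codes, order)       # k-mer index at each start, NA over N
  ncat <- 4L^order
  nk <- 2L * halfwidth + 2L - order       # k-mers per window
  # cumulative count per category over k-mer start positions
  cs <- matrix(0L, nrow = length(idx) + 1L, ncol = ncat)
  ok <- !is.na(idx)
  ind <- matrix(0L, nrow = length(idx), ncol = ncat)
  ind[cbind(which(ok), idx[ok])] <- 1L
  cs[-1L, ] <- apply(ind, 2L, cumsum)
  # window at center p (0-based) spans k-mer starts p-halfwidth .. p+halfwidth-order+1
  lo <- centers - halfwidth + 1L          # 1-based row into idx
  hi <- centers + halfwidth - order + 2L
  counts <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
  freq <- counts / nk
  diffs <- sweep(freq, 2L, background$freqs[all_kmers(order)])
  sqrt(rowSums(diffs^2))
}

#' Place reads on a reference under a bias model
#'
#' Read starts are multinomial draws over the eligible positions with
#' weight exp(beta * d(p)); multiple reads may share a start position. With
#' beta = 0 every eligible position has identical weight and placement is
#' uniform.
#'
#' @param ref a `reference_sequence`.
#' @param model a `bias_model`.
#' @param n_reads number of reads to place (>= 0).
#' @param seed integer seed; (ref, model, n_reads, seed) fully determine
#'   the returned track.
#' @return A `read_start_track` whose total equals `n_reads`.
#' @export
place_reads <- function(ref, model, n_reads, seed = 1L) {
  stopifnot(inherits(ref, "reference_sequence"), inherits(model, "bias_model"))
  n_reads <- as.integer(n_reads)
  if (n_reads < 0L) stop("n_reads must be >= 0")
  centers <- eligible_positions(ref, model$halfwidth)
  if (length(centers) == 0L) stop("no eligible positions in reference")
  if (n_reads == 0L) return(read_start_track(ref$name))
  if (model$beta == 0) {
    w <- rep(1, length(centers))
  } else {
    d <- local_distance_profile(ref, centers, model$order, model$halfwidth,
                                model$background)
    w <- exp(model$beta * d)
  }
  draws <- with_seed(seed,
                     sample.int(length(centers), n_reads, replace = TRUE, prob = w))
  tab <- tabulate(draws, nbins = length(centers))
  hit <- tab > 0L
  read_start_track(ref$name, positions = centers[hit], counts = tab[hit])
}

#' Placement weights of a bias model over a reference
#'
#' Exposes the exact per-position multinomial weights used by
#' [place_reads()], normalized to probabilities — useful for checking
#' observed enrichment against expectation.
#'
#' @inheritParams place_reads
#' @return Data frame with 0-based `pos` and probability `prob`.
#' @export
placement_weights <- function(ref, model) {
  centers <- eligible_positions(ref, model$halfwidth)
  if (length(centers) == 0L) stop("no eligible positions in reference")
  if (model$beta == 0) {
    w <- rep(1, length(centers))
  } else {
    d <- local_distance_profile(ref, centers, model$order, model$halfwidth,
                                model$background)
    w <- exp(model$beta * d)
  }
  data.frame(pos = centers, prob = w / sum(w))
}
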