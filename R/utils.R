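# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring RNG state after
#'
#' @param seed integer seed, or NULL to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

#' All k-mers over A,C,G,T in lexicographic order (A < C < G < T)
#' @noRd
all_kmers <- function(k) {
  stopifnot(k >= 1L)
  grid <- expand.grid(rep(list(DNA_BASES), k), stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reverse columns so the
  # leftmost base is the most significant digit, giving lexicographic order
  do.call(paste0, rev(grid))
}

#' Encode a sequence string as integer base codes 1..4 (NA for N)
#' @noRd
encode_bases <- function(seq) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], DNA_BASES)
  codes
}

#' Per-position k-mer index (1..4^k) for overlapping k-mers; NA where the
#' k-mer contains a non-ACGT base
#' @noRd
kmer_indices <- function(codes, k) {
  n <- length(codes) - k + 1L
  if (n < 1L) return(integer(0))
  idx <- rep(0, n)
  for (j in seq_len(k)) {
    idx <- idx * 4 + (codes[j:(j + n - 1L)] - 1L)
  }
  as.integer(idx + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_num <- function(x, digits = 6L) {
  # fixed-width float formatting so serialized tables are byte-stable
  formatC(x, format = "f", digits = digits)
}
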