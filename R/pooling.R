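# Sequence data pools: stratified random genomic positions with their
# +/- halfwidth windows and read-start frequencies, plus the global/local
# distribution and GC summaries computed from them.

#' Configure pool construction
#'
#' @param strata named integer vector of requested position counts per
#'   read-start frequency class. Class names are `"0"`, `"1"`, ..., `"10"`
#'   and `"11+"` (frequency 11 or more). The default is a desk-scale
#'   version of a genome-study stratification (5000 / 500 x 10 / 5000)
#'   multiplied by `scale`.
#' @param halfwidth window half-width in bp (default 20; windows are
#'   2 * halfwidth + 1 = 41 positional features).
#' @param seed integer seed for the stratified sampling.
#' @param scale multiplier applied to the default strata (ignored when
#'   `strata` is given explicitly).
#' @return An object of class `pool_config`.
#' @export
pool_config <- function(strata = NULL, halfwidth = 20L, seed = 1L, scale = 1) {
  halfwidth <- as.integer(halfwidth)
  if (halfwidth < 1L) stop("halfwidth must be >= 1")
  if (is.null(strata)) {
    strata <- round(c("0" = 5000, "1" = 500, "2" = 500, "3" = 500, "4" = 500,
                      "5" = 500, "6" = 500, "7" = 500, "8" = 500, "9" = 500,
                      "10" = 500, "11+" = 5000) * scale)
  }
  valid <- c(as.character(0:10), "11+")
  if (is.null(names(strata)) || !all(names(strata) %in% valid)) {
    stop("strata names must be among ", paste(valid, collapse = ", "))
  }
  nm <- names(strata)
  strata <- as.integer(strata)
  names(strata) <- nm
  if (any(strata < 0L)) stop("requested stratum counts must be >= 0")
  structure(list(strata = strata, halfwidth = halfwidth, seed = seed),
            class = "pool_config")
}

# frequency -> stratum label ("0".."10", "11+")
freq_class <- function(freq) ifelse(freq >= 11L, "11+", as.character(freq))

#' Build a sequence data pool
#'
#' Scans every eligible position of each reference (window fully inside
#' the sequence and N-free), attaches its read-start frequency from the
#' matching track (0 where absent), and samples positions uniformly
#' without replacement within each requested frequency stratum. Classes
#' with fewer available positions than requested are exhausted with a
#' warning. Windows are forward-strand reference substrings of length
#' 2 * halfwidth + 1 centered on the position.
#'
#' @param refs a `reference_sequence` or list of them.
#' @param tracks a `read_start_track` or list of them; chromosome names
#'   must match `refs` (a reference without a track contributes frequency-0
#'   positions only).
#' @param config a [pool_config()].
#' @return An object of class `sequence_pool`: a list with `instances`
#'   (data frame `chrom`, `pos` 0-based, `freq`, `stratum`, `window`) and
#'   `provenance`.
#' @export
build_pool <- function(refs, tracks, config = pool_config()) {
  if (inherits(refs, "reference_sequence")) refs <- list(refs)
  if (inherits(tracks, "read_start_track")) tracks <- list(tracks)
  if (length(refs) == 0L) stop("no references")
  refnames <- vapply(refs, function(r) r$name, "")
  for (tr in tracks) {
    if (!tr$name %in% refnames) stop("track chromosome not in references: ", tr$name)
  }
  h <- config$halfwidth
  cand <- lapply(refs, function(ref) {
    pos <- eligible_positions(ref, h)
    if (length(pos) == 0L) return(NULL)
    freq <- integer(length(pos))
    tr <- Filter(function(t) t$name == ref$name, tracks)
    if (length(tr)) {
      tr <- tr[[1]]
      m <- match(tr$positions, pos)
      keep <- !is.na(m)
      freq[m[keep]] <- tr$counts[keep]
    }
    data.frame(chrom = ref$name, pos = pos, freq = freq,
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0L) stop("no eligible positions in any reference")
  cand$stratum <- freq_class(cand$freq)

  picked <- with_seed(config$seed, {
    out <- list()
    for (cls in names(config$strata)) {
      req <- config$strata[[cls]]
      if (req == 0L) next
      avail <- which(cand$stratum == cls)
      if (length(avail) < req) {
        warning(sprintf("stratum %s: only %d of %d requested positions available",
                        cls, length(avail), req))
      }
      take <- if (length(avail) <= req) avail else sample(avail, req)
      out[[cls]] <- take
    }
    out
  })
  if (length(picked) == 0L || all(lengths(picked) == 0L)) {
    stop("all requested strata are empty")
  }
  inst <- cand[sort(unlist(picked, use.names = FALSE)), , drop = FALSE]
  rownames(inst) <- NULL
  seqs <- stats::setNames(vapply(refs, function(r) r$seq, ""), refnames)
  inst$window <- substr(seqs[inst$chrom], inst$pos - h + 1L, inst$pos + h + 1L)
  structure(list(instances = inst,
                 provenance = list(chroms = refnames, seed = config$seed,
                                   halfwidth = h, strata = config$strata)),
            class = "sequence_pool")
}

#' @export
print.sequence_pool <- function(x, ...) {
  cat(sprintf("<sequence_pool> %d instances, %d-bp windows, chromosomes: %s\n",
              nrow(x$instances), 2L * x$provenance$halfwidth + 1L,
              paste(x$provenance$chroms, collapse = ", ")))
  print(table(x$instances$stratum))
  invisible(x)
}

#' Global k-mer distribution of a set of references
#'
#' Overlapping k-mers are counted across each reference; k-mers containing
#' N are skipped. Counts are normalized to sum 1.
#'
#' @param refs a `reference_sequence` or list of them.
#' @param k k-mer order (1-4).
#' @return A `kmer_distribution`.
#' @export
global_distribution <- function(refs, k) {
  if (inherits(refs, "reference_sequence")) refs <- list(refs)
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= 4L)
  set <- Biostrings::DNAStringSet(vapply(refs, function(r) r$seq, ""))
  counts <- colSums(Biostrings::oligonucleotideFrequency(set, width = k,
                                                         simplify.as = "matrix"))
  counts <- counts[all_kmers(k)]
  if (sum(counts) == 0) stop("no countable k-mers (all windows contain N?)")
  kmer_distribution(k, counts)
}

# default read-frequency grouping used by the distance and GC summaries
default_groups <- function() {
  list("0" = c(0, 0), "1-5" = c(1, 5), "6-10" = c(6, 10), "11+" = c(11, Inf))
}

group_of <- function(freq, groups) {
  lab <- rep(NA_character_, length(freq))
  for (g in names(groups)) {
    rng <- groups[[g]]
    lab[freq >= rng[1] & freq <= rng[2]] <- g
  }
  lab
}

#' Euclidean distance between local and global nucleotide distributions
#'
#' For each read-frequency group, all windows in the group are pooled and
#' their mono- and di-nucleotide distributions computed (each order
#' normalized by its own total). The group's concatenated mono+di vector is
#' compared with the concatenated global vector by Euclidean distance. With
#' unbiased placement the local distributions converge to the global one
#' and all distances shrink toward 0; composition-biased placement inflates
#' the distances of the read-bearing groups.
#'
#' @param pool a `sequence_pool`.
#' @param global_mono,global_di global `kmer_distribution`s of order 1
#'   and 2 (see [global_distribution()]).
#' @param groups named list of `c(lo, hi)` frequency ranges; default
#'   `0, 1-5, 6-10, 11+`.
#' @param orders k-mer orders entering the concatenated vector; default
#'   `c(1, 2)` (mono + di). `orders = 2` compares di-nucleotides only.
#' @return Data frame with `group`, `n` (windows in group) and `distance`
#'   (NA for empty groups).
#' @export
pool_distance_table <- function(pool, global_mono, global_di,
                                groups = default_groups(), orders = c(1L, 2L)) {
  stopifnot(inherits(pool, "sequence_pool"))
  glob <- list(`1` = global_mono, `2` = global_di)
  lab <- group_of(pool$instances$freq, groups)
  res <- lapply(names(groups), function(g) {
    win <- pool$instances$window[lab == g & !is.na(lab)]
    if (length(win) == 0L) {
      return(data.frame(group = g, n = 0L, distance = NA_real_))
    }
    set <- Biostrings::DNAStringSet(win)
    local_vec <- unlist(lapply(orders, function(k) {
      cnt <- colSums(Biostrings::oligonucleotideFrequency(set, width = k,
                                                          simplify.as = "matrix"))
      cnt <- cnt[all_kmers(k)]
      cnt / sum(cnt)
    }))
    global_vec <- unlist(lapply(orders, function(k) {
      gd <- glob[[as.character(k)]]
      if (is.null(gd) || gd$k != k) stop("missing global distribution of order ", k)
      gd$freqs
    }))
    data.frame(group = g, n = length(win),
               distance = euclidean(local_vec, global_vec))
  })
  do.call(rbind, res)
}

#' GC content of pooled windows per read-frequency group
#'
#' GC fraction = (#G + #C) / (window length x group size) over all windows
#' of the group.
#'
#' @inheritParams pool_distance_table
#' @return Data frame with `group`, `n` and `gc` (NA for empty groups).
#' @export
pool_gc_table <- function(pool, groups = default_groups()) {
  stopifnot(inherits(pool, "sequence_pool"))
  lab <- group_of(pool$instances$freq, groups)
  res <- lapply(names(groups), function(g) {
    win <- pool$instances$window[lab == g & !is.na(lab)]
    if (length(win) == 0L) {
      return(data.frame(group = g, n = 0L, gc = NA_real_))
    }
    set <- Biostrings::DNAStringSet(win)
    gc <- sum(Biostrings::letterFrequency(set, letters = "GC"))
    data.frame(group = g, n = length(win),
               gc = gc / sum(Biostrings::width(set)))
  })
  do.call(rbind, res)
}

#' Write a sequence pool as TSV
#'
#' Columns `chrom pos freq window` with 1-based positions (stated in the
#' header comment).
#'
#' @param pool a `sequence_pool`.
#' @param path output path.
#' @export
write_pool_tsv <- function(pool, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chrom\tpos(1-based)\tfreq\twindow", con)
  with(pool$instances,
       writeLines(sprintf("%s\t%d\t%d\t%s", chrom, pos + 1L, freq, window), con))
  invisible(path)
}

#' Read a sequence pool from TSV
#'
#' Inverse of [write_pool_tsv()]; positions are converted back to the
#' internal 0-based convention.
#'
#' @param path path to a pool TSV.
#' @return A `sequence_pool`.
#' @export
read_pool_tsv <- function(path) {
  if (!file.exists(path)) stop("pool file not found: ", path)
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = c("chrom", "pos", "freq", "window"),
                          colClasses = c("character", "integer", "integer",
                                         "character"))
  if (nrow(df) == 0L) stop("empty pool file: ", path)
  w <- nchar(df$window)
  if (length(unique(w)) != 1L || w[1] %% 2L != 1L) {
    stop("pool windows must share one odd length")
  }
  df$pos <- df$pos - 1L
  df$stratum <- freq_class(df$freq)
  df <- df[, c("chrom", "pos", "freq", "stratum", "window")]
  structure(list(instances = df,
                 provenance = list(chroms = unique(df$chrom), seed = NA,
                                   halfwidth = (w[1] - 1L) %/% 2L,
                                   strata = table(df$stratum))),
            class = "sequence_pool")
}
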