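# Input/output for the formats the pipeline touches: FASTA references,
# sparse read-start count tracks (TSV / BED3), and optional BAM extraction.
#
# Conventions: all internal coordinates are 0-based; every user-facing file
# is 1-based, and the writers say so in their header comments.

#' Construct a reference sequence
#'
#' A named chromosome-scale sequence over the alphabet \{A,C,G,T,N\}.
#' Lowercase letters are uppercased and IUPAC ambiguity codes other than N
#' are mapped to N, so downstream feature extraction only ever sees a strict
#' 4-letter alphabet plus the N placeholder.
#'
#' @param name chromosome identifier.
#' @param seq character string of bases; normalized on construction.
#' @return An object of class `reference_sequence` with fields `name` and
#'   `seq`; its `length()` is the sequence length in bp.
#' @export
reference_sequence <- function(name, seq) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  seq <- gsub("[^ACGTN]", "N", seq)
  structure(list(name = name, seq = seq), class = "reference_sequence")
}

#' @export
length.reference_sequence <- function(x) nchar(x$seq)

#' @export
print.reference_sequence <- function(x, ...) {
  cat(sprintf("<reference_sequence> %s: %d bp\n", x$name, length(x)))
  invisible(x)
}

#' Construct a read-start track
#'
#' Sparse per-position counts of reads starting at each 0-based coordinate
#' of one chromosome. Positions absent from the track have count zero.
#'
#' @param name chromosome identifier.
#' @param positions integer vector of 0-based coordinates (unique, sorted on
#'   construction).
#' @param counts positive integer counts, one per position.
#' @return An object of class `read_start_track` with fields `name`,
#'   `positions`, `counts` and `total`.
#' @export
read_start_track <- function(name, positions = integer(0), counts = integer(0)) {
  stopifnot(length(positions) == length(counts))
  positions <- as.integer(positions)
  counts <- as.integer(counts)
  if (anyNA(positions) || anyNA(counts)) stop("NA in track positions/counts")
  if (any(positions < 0L)) stop("track positions must be >= 0")
  if (any(counts < 1L)) stop("sparse track counts must be >= 1")
  if (anyDuplicated(positions)) {
    counts <- as.integer(tapply(counts, positions, sum))
    positions <- sort(unique(positions))
  } else {
    o <- order(positions)
    positions <- positions[o]
    counts <- counts[o]
  }
  structure(list(name = name, positions = positions, counts = counts,
                 total = sum(counts)),
            class = "read_start_track")
}

#' @export
print.read_start_track <- function(x, ...) {
  cat(sprintf("<read_start_track> %s: %d reads at %d positions\n",
              x$name, x$total, length(x$positions)))
  invisible(x)
}

#' Read a FASTA file of reference sequences
#'
#' Records are returned in file order. Sequences are uppercased and any
#' base outside \{A,C,G,T,N\} becomes N (see [reference_sequence()]).
#'
#' @param path path to a FASTA file.
#' @return A list of `reference_sequence` objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed FASTA: ", conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    reference_sequence(nm[i], as.character(set[[i]]))
  })
}

#' Write reference sequences as FASTA
#'
#' @param refs a `reference_sequence` or list of them.
#' @param path output path; lines wrapped at 60 columns.
#' @export
write_fasta <- function(refs, path) {
  if (inherits(refs, "reference_sequence")) refs <- list(refs)
  set <- Biostrings::DNAStringSet(vapply(refs, function(r) r$seq, ""))
  names(set) <- vapply(refs, function(r) r$name, "")
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a read-start count table
#'
#' Accepts the tab-separated dialect `chrom<TAB>pos<TAB>count` with 1-based
#' positions; lines starting with `#` are ignored. Rows sharing a
#' (chrom, pos) pair are summed. Positions are converted to the package's
#' internal 0-based convention.
#'
#' @param path path to the TSV file.
#' @return A list of `read_start_track` objects, one per chromosome, in
#'   order of first appearance.
#' @export
read_starts_tsv <- function(path) {
  if (!file.exists(path)) stop("read-start table not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop("line ", lineno[bad[1]], ": expected 3 tab-separated columns")
  chrom <- vapply(parts, `[[`, "", 1L)
  pos <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  count <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(pos) | pos != floor(pos) | pos < 1)
  if (length(bad)) stop("line ", lineno[bad[1]], ": position must be a positive integer")
  bad <- which(is.na(count) | count != floor(count) | count <= 0)
  if (length(bad)) stop("line ", lineno[bad[1]], ": count must be a positive integer")
  out <- lapply(unique(chrom), function(ch) {
    sel <- chrom == ch
    read_start_track(ch, positions = pos[sel] - 1, counts = count[sel])
  })
  out
}

#' Write read-start tracks as TSV
#'
#' @param tracks a `read_start_track` or list of them.
#' @param path output path. Columns are `chrom pos count` with 1-based
#'   positions, stated in the header comment.
#' @export
write_starts_tsv <- function(tracks, path) {
  if (inherits(tracks, "read_start_track")) tracks <- list(tracks)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chrom\tpos(1-based)\tcount", con)
  for (tr in tracks) {
    if (length(tr$positions)) {
      writeLines(sprintf("%s\t%d\t%d", tr$name, tr$positions + 1L, tr$counts), con)
    }
  }
  invisible(path)
}

#' Read read starts from a BED3 file
#'
#' Each interval's 0-based `start` is taken as one read start (count 1 per
#' row; duplicate rows accumulate).
#'
#' @param path path to a BED3 (or wider) file.
#' @return A list of `read_start_track` objects.
#' @export
read_starts_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) return(list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) stop("BED requires at least 3 columns")
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- as.integer(vapply(parts, `[[`, "", 2L))
  lapply(unique(chrom), function(ch) {
    sel <- chrom == ch
    tab <- table(start[sel])
    read_start_track(ch, positions = as.integer(names(tab)),
                     counts = as.integer(tab))
  })
}

#' Extract read starts from a coordinate-sorted, indexed BAM
#'
#' For each mapped, primary, non-duplicate alignment on `chrom` the count at
#' its start coordinate is incremented. Secondary, supplementary and
#' unmapped records are skipped. This reader is optional: the rest of the
#' pipeline runs from FASTA + TSV without any BAM (or Rsamtools) present.
#'
#' @param path path to an indexed BAM file.
#' @param chrom chromosome to extract.
#' @param start_mode `"leftmost"` (default) counts the leftmost aligned
#'   reference coordinate regardless of strand; `"five-prime"` counts the
#'   5' end of each alignment (rightmost coordinate for reverse-strand
#'   reads).
#' @param skip_duplicates drop duplicate-flagged records (default TRUE), so
#'   PCR duplicates are not double-counted.
#' @return A `read_start_track` (0-based positions).
#' @export
starts_from_bam <- function(path, chrom, start_mode = c("leftmost", "five-prime"),
                            skip_duplicates = TRUE) {
  start_mode <- match.arg(start_mode)
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("BAM input requires the Rsamtools package")
  }
  if (!file.exists(path)) stop("BAM file not found: ", path)
  idx <- paste0(path, ".bai")
  if (!file.exists(idx) && !file.exists(sub("\\.bam$", ".bai", path))) {
    stop("missing BAM index: ", idx)
  }
  hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
  if (!chrom %in% names(hdr)) stop("chromosome not in BAM header: ", chrom)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = if (skip_duplicates) FALSE else NA)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("rname", "pos", "strand", "cigar"))
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  sel <- !is.na(res$pos) & as.character(res$rname) == chrom
  if (!any(sel)) return(read_start_track(chrom))
  pos0 <- res$pos[sel] - 1L  # BAM pos is 1-based leftmost
  if (start_mode == "five-prime") {
    rev <- as.character(res$strand[sel]) == "-"
    if (any(rev)) {
      w <- cigar_ref_width(res$cigar[sel][rev])
      pos0[rev] <- pos0[rev] + w - 1L
    }
  }
  tab <- table(pos0)
  read_start_track(chrom, positions = as.integer(names(tab)),
                   counts = as.integer(tab))
}

# reference-consumed width from CIGAR (M/D/N/=/X consume reference)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", toks))
    op <- sub("^\\d+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}
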