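#' Construct a read set
#'
#' Reads are stored column-wise: ids, uppercase ACGTN sequences, and
#' per-base Phred qualities as a list of integer vectors.
#'
#' @param id character vector of read ids.
#' @param sequence character vector of ACGTN sequences.
#' @param quality list of integer Phred vectors, one per read.
#' @return a `read_set` object.
#' @export
read_set <- function(id, sequence, quality) {
  sequence <- toupper(sequence)
  assert_that(length(id) == length(sequence) && length(id) == length(quality),
              "id, sequence and quality must have equal length")
  nq <- lengths(quality)
  bad <- which(nchar(sequence) != nq)
  if (length(bad))
    stop(sprintf("malformed record %d: sequence length %d != quality length %d",
                 bad[1], nchar(sequence)[bad[1]], nq[bad[1]]), call. = FALSE)
  if (length(sequence) && any(grepl("[^ACGTN]", sequence)))
    stop("sequences restricted to alphabet ACGTN", call. = FALSE)
  structure(list(id = as.character(id), sequence = sequence,
                 quality = quality), class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$id)

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set with %d reads (lengths %s)\n", length(x),
              if (length(x)) paste(range(nchar(x$sequence)), collapse = "-") else "-"))
  invisible(x)
}

subset_reads <- function(x, i) read_set(x$id[i], x$sequence[i], x$quality[i])

#' Parse a FASTQ file (Phred+33)
#'
#' @param path FASTQ file path (optionally gzip-compressed).
#' @return a [read_set()].
#' @export
parse_fastq <- function(path) {
  lines <- readLines(path)
  assert_that(length(lines) %% 4 == 0,
              sprintf("truncated FASTQ: %d lines not a multiple of 4", length(lines)))
  n <- length(lines) %/% 4
  if (n == 0) return(read_set(character(), character(), list()))
  idx <- seq_len(n)
  hdr <- lines[4 * idx - 3]
  seqs <- toupper(lines[4 * idx - 2])
  quals <- lines[4 * idx]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop(sprintf("malformed record %d: header does not start with '@'", bad[1]),
         call. = FALSE)
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop(sprintf("malformed record %d: sequence length %d != quality length %d",
                 bad[1], nchar(seqs)[bad[1]], nchar(quals)[bad[1]]), call. = FALSE)
  qual <- lapply(quals, function(q) utf8ToInt(q) - 33L)
  read_set(sub("^@", "", hdr), seqs, qual)
}

#' Write reads as FASTQ (Phred+33)
#'
#' `parse_fastq(write_fastq(x))` is the identity on well-formed records.
#'
#' @param reads a [read_set()].
#' @param path output path (".gz" suffix enables compression).
#' @export
write_fastq <- function(reads, path) {
  n <- length(reads)
  out <- character(4 * n)
  if (n) {
    idx <- seq_len(n)
    out[4 * idx - 3] <- paste0("@", reads$id)
    out[4 * idx - 2] <- reads$sequence
    out[4 * idx - 1] <- "+"
    out[4 * idx] <- vapply(reads$quality,
                           function(q) intToUtf8(q + 33L), character(1))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Sliding-window trim policy
#'
#' Two regimes are used in practice: the population-read regime
#' (window 4, mean quality 20, minimum length 75, Trimmomatic
#' `SLIDINGWINDOW:4:20 MINLEN:75`) and the long-read polishing regime
#' (window 4, quality 30, minimum length 100).
#'
#' @param window window size in bases.
#' @param mean_quality_threshold minimum mean Phred quality per window.
#' @param min_length reads shorter than this after trimming are discarded.
#' @return a `trim_policy` object.
#' @export
trim_policy <- function(window = 4L, mean_quality_threshold = 20,
                        min_length = 75L) {
  assert_that(window >= 1, "window must be >= 1")
  assert_that(min_length >= 1, "min_length must be >= 1")
  structure(list(window = as.integer(window),
                 mean_quality_threshold = mean_quality_threshold,
                 min_length = as.integer(min_length)), class = "trim_policy")
}

# Trim a single quality vector; returns kept length (0 = discarded).
# Windows are scanned from the 5' end; at the first window whose mean
# quality falls below threshold the cut point starts at that window's start
# and then extends through any leading bases whose individual quality still
# meets the threshold (the published trimmer's SLIDINGWINDOW behaviour).
# A trailing partial window uses the mean of the remaining bases.
trim_keep_length <- function(qual, policy) {
  n <- length(qual)
  if (n == 0) return(0L)
  w <- policy$window
  thr <- policy$mean_quality_threshold
  cs <- cumsum(c(0, qual))
  starts <- seq_len(n)
  ends <- pmin(starts + w - 1L, n)
  means <- (cs[ends + 1L] - cs[starts]) / (ends - starts + 1L)
  fail <- which(means < thr)
  if (!length(fail)) {
    keep <- n
  } else {
    keep <- fail[1] - 1L
    while (keep < n && qual[keep + 1L] >= thr) keep <- keep + 1L
  }
  if (keep < policy$min_length) 0L else keep
}

#' Quality-trim reads with a sliding window
#'
#' Scans windows from the 5' end; at the first window whose mean quality
#' drops below the threshold the read is cut at that window's start,
#' retaining any leading bases of the window that individually meet the
#' threshold. Survivors shorter than `min_length` are discarded. Matches
#' the published trimmer's SLIDINGWINDOW/MINLEN semantics.
#'
#' @param reads a [read_set()].
#' @param policy a [trim_policy()].
#' @return a trimmed [read_set()] (discarded reads removed).
#' @export
trim_reads <- function(reads, policy = trim_policy()) {
  keep_len <- vapply(reads$quality, trim_keep_length, integer(1), policy = policy)
  sel <- which(keep_len > 0L)
  read_set(reads$id[sel],
           substr(reads$sequence[sel], 1L, keep_len[sel]),
           mapply(function(q, k) q[seq_len(k)], reads$quality[sel],
                  keep_len[sel], SIMPLIFY = FALSE))
}

#' Trim a single read
#'
#' @param sequence ACGTN string.
#' @param quality integer Phred vector.
#' @param policy a [trim_policy()].
#' @return list(sequence, quality) or NULL if discarded.
#' @export
sliding_window_trim <- function(sequence, quality, policy = trim_policy()) {
  k <- trim_keep_length(quality, policy)
  if (k == 0L) return(NULL)
  list(sequence = substr(sequence, 1L, k), quality = quality[seq_len(k)])
}
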