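#' Build a k-mer index over reference transcripts
#'
#' Every k-mer of every transcript is retrievable with all of its
#' (transcript, offset) occurrences. This is the reference implementation of
#' the seed index; [align_reads()] uses an equivalent compiled index.
#'
#' @param reference named character vector of transcript sequences.
#' @param k seed length (>= 11 for alignment; smaller k is allowed for
#'   index inspection).
#' @return a `kmer_index` object.
#' @export
build_kmer_index <- function(reference, k = 21L) {
  assert_that(k >= 2, "k must be >= 2")
  ids <- names(reference)
  assert_that(!is.null(ids) && !anyDuplicated(ids),
              "duplicate or missing transcript ids")
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (t in seq_along(reference)) {
    s <- reference[[t]]
    L <- nchar(s)
    if (L < k) {
      warning(sprintf("transcript '%s' shorter than k = %d: contributes no seeds",
                      ids[t], k))
      next
    }
    starts <- seq_len(L - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    ok <- !grepl("[^ACGT]", kmers)
    for (i in which(ok)) {
      key <- kmers[i]
      env[[key]] <- rbind(env[[key]], c(t, starts[i] - 1L))
    }
  }
  structure(list(map = env, k = as.integer(k), ids = ids,
                 lengths = nchar(reference), sequences = unname(reference)),
            class = "kmer_index")
}

#' Look up a k-mer in the index
#'
#' @param index a [build_kmer_index()] object.
#' @param kmer a string of length `index$k`.
#' @return data.frame(transcript, offset) of 0-based occurrences.
#' @export
index_lookup <- function(index, kmer) {
  hits <- index$map[[kmer]]
  if (is.null(hits))
    return(data.frame(transcript = character(), offset = integer()))
  data.frame(transcript = index$ids[hits[, 1]], offset = hits[, 2],
             stringsAsFactors = FALSE)
}

#' Align one read against an index (seed and ungapped extend)
#'
#' Candidate placements come from non-overlapping k-mer seeds, extended
#' ungapped over the full read. The best placement is returned only when its
#' mismatch count is within `max_mismatch_frac * length` AND strictly better
#' than the runner-up; ties and over-budget placements are unaligned
#' (multi-mapping reads are discarded).
#'
#' @param sequence read sequence.
#' @param index a [build_kmer_index()] object.
#' @param max_mismatch_frac maximum mismatch fraction (default 0.04).
#' @return data.frame(transcript, offset, mismatches, unique) or NULL.
#' @export
align_read <- function(sequence, index, max_mismatch_frac = 0.04) {
  len <- nchar(sequence)
  k <- index$k
  assert_that(len > k, "read must be longer than k")
  budget <- floor(max_mismatch_frac * len + 1e-9)
  seed_starts <- seq(1L, len - k + 1L, by = k)
  cand <- list()
  for (sp in seed_starts) {
    hits <- index$map[[substr(sequence, sp, sp + k - 1L)]]
    if (is.null(hits)) next
    off <- hits[, 2] - (sp - 1L)
    ok <- off >= 0L & off + len <= index$lengths[hits[, 1]]
    if (any(ok)) cand[[length(cand) + 1L]] <- cbind(hits[ok, 1], off[ok])
  }
  if (!length(cand)) return(NULL)
  cand <- unique(do.call(rbind, cand))
  rd <- utf8ToInt(sequence)
  mm <- vapply(seq_len(nrow(cand)), function(i) {
    ref <- utf8ToInt(substr(index$sequences[cand[i, 1]], cand[i, 2] + 1L,
                            cand[i, 2] + len))
    sum(ref != rd)
  }, numeric(1))
  o <- order(mm)
  best <- o[1]
  if (mm[best] > budget) return(NULL)
  if (length(mm) > 1 && mm[o[2]] <= mm[best]) return(NULL)
  data.frame(transcript = index$ids[cand[best, 1]], offset = cand[best, 2],
             mismatches = mm[best], unique = TRUE, stringsAsFactors = FALSE)
}

#' Align a read set against reference transcripts (compiled batch path)
#'
#' Same placement semantics as [align_read()], run over all reads with a
#' compiled k-mer index.
#'
#' @param reads a [read_set()].
#' @param reference named character vector of transcripts.
#' @param k seed length.
#' @param max_mismatch_frac mismatch budget as a fraction of read length.
#' @return data.frame(read_id, transcript, offset, mismatches) for uniquely
#'   placed reads, plus attribute `n_input`.
#' @export
align_reads <- function(reads, reference, k = 21L, max_mismatch_frac = 0.04) {
  assert_that(k >= 11, "k must be >= 11")
  assert_that(!is.null(names(reference)) && !anyDuplicated(names(reference)),
              "duplicate or missing transcript ids")
  m <- cpp_align_reads(unname(reference), reads$sequence, as.integer(k),
                       max_mismatch_frac)
  hit <- which(m[, 1] > 0L)
  out <- data.frame(read_id = reads$id[hit],
                    transcript = names(reference)[m[hit, 1]],
                    offset = m[hit, 2],
                    mismatches = m[hit, 3],
                    stringsAsFactors = FALSE)
  attr(out, "n_input") <- length(reads)
  attr(out, "read_index") <- hit
  out
}

#' Build per-position pileup columns from placements
#'
#' Tallies the read base at every covered reference position. Uncovered
#' positions are omitted.
#'
#' @param placements data.frame from [align_reads()] (needs `read_index`
#'   attribute) or columns (read_id, transcript, offset) matching `reads`.
#' @param reads the [read_set()] the placements refer to.
#' @param reference named character vector of transcripts.
#' @return data.frame(transcript, position, depth, A, C, G, T, N) with
#'   0-based positions.
#' @export
build_pileup <- function(placements, reads, reference) {
  ids <- names(reference)
  tx <- match(placements$transcript, ids)
  assert_that(!anyNA(tx), "placement refers to unknown transcript")
  ridx <- attr(placements, "read_index") %||% match(placements$read_id, reads$id)
  assert_that(!anyNA(ridx), "placement refers to unknown read")
  lens <- nchar(reference)
  rlen <- nchar(reads$sequence[ridx])
  if (any(placements$offset < 0 | placements$offset + rlen > lens[tx]))
    stop("placement out of transcript bounds", call. = FALSE)
  tx_start <- c(0L, cumsum(lens))[seq_along(lens)]
  counts <- cpp_pileup(reads$sequence[ridx], tx, as.integer(placements$offset),
                       as.integer(tx_start), sum(lens))
  depth <- colSums(counts)
  covered <- which(depth > 0L)
  if (!length(covered))
    return(data.frame(transcript = character(), position = integer(),
                      depth = integer(), A = integer(), C = integer(),
                      G = integer(), T = integer(), N = integer()))
  tx_of <- findInterval(covered - 1L, tx_start)
  data.frame(transcript = ids[tx_of],
             position = covered - 1L - tx_start[tx_of],
             depth = depth[covered],
             A = counts[1, covered], C = counts[2, covered],
             G = counts[3, covered], T = counts[4, covered],
             N = counts[5, covered], stringsAsFactors = FALSE)
}
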