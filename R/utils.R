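#' Derive a reproducible sub-seed from a master seed
#'
#' Stages of the pipeline draw their randomness from independent substreams
#' so toggling one stage never perturbs another's output. Substreams are
#' derived by hashing the master seed with a stage label; results stay below
#' 2^31 so they are valid R integer seeds.
#'
#' @param seed master integer seed.
#' @param label character stage label.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(paste0(label, ":", seed)))
    h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

BASES <- c("A", "C", "G", "T")

# rbind a list of data.frames, ignoring NULLs; NULL if nothing remains
rbind_all <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (!length(lst)) return(NULL)
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Read a FASTA file into a named character vector
#'
#' Minimal multi-line FASTA reader; sequences are uppercased.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  assert_that(length(lines) > 0 && hdr[1], sprintf("not a FASTA file: %s", path))
  id <- sub("^>\\s*", "", lines[hdr])
  id <- sub("\\s.*$", "", id)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  out <- toupper(seqs)
  names(out) <- id
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  assert_that(!is.null(names(seqs)) && all(nzchar(names(seqs))),
              "sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", names(seqs)[i]),
                 substring(s, starts, pmin(starts + width - 1L, nchar(s)))), con)
  }
  invisible(path)
}
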