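#' Homozygous SNP-calling regimes
#'
#' Two presets are used: `"polish"` (minimum coverage 10, alternative-base
#' fraction >= 0.95) for iterative pseudo-reference construction, and
#' `"population"` (minimum coverage 5, fraction strictly > 0.80) for
#' per-accession population genotyping. Both thresholds stay configurable.
#'
#' @param name `"polish"`, `"population"`, or `"custom"`.
#' @param min_coverage minimum read depth.
#' @param min_alt_fraction minimum alternative-base fraction.
#' @param strict logical: if TRUE the fraction comparison is strict (>).
#' @return a `call_regime` object.
#' @export
call_regime <- function(name = c("polish", "population", "custom"),
                        min_coverage = NULL, min_alt_fraction = NULL,
                        strict = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    polish     = list(min_coverage = 10L, min_alt_fraction = 0.95, strict = FALSE),
    population = list(min_coverage = 5L,  min_alt_fraction = 0.80, strict = TRUE),
    custom     = list(min_coverage = 5L,  min_alt_fraction = 0.80, strict = FALSE))
  structure(list(name = name,
                 min_coverage = as.integer(min_coverage %||% defaults$min_coverage),
                 min_alt_fraction = min_alt_fraction %||% defaults$min_alt_fraction,
                 strict = strict %||% defaults$strict),
            class = "call_regime")
}

#' Call homozygous SNPs from pileup columns
#'
#' A column yields a call iff its depth is at least the regime's minimum
#' coverage AND the single most frequent non-reference base reaches the
#' regime's alternative fraction (>= for the polish regime, strictly > for
#' the population regime). N bases are excluded from fraction denominators.
#'
#' @param pileup data.frame from [build_pileup()].
#' @param reference named character vector of transcripts.
#' @param regime a [call_regime()].
#' @return data.frame(transcript, position, ref_base, alt_base, depth,
#'   alt_fraction); positions are 0-based.
#' @export
call_snps <- function(pileup, reference, regime = call_regime("population")) {
  if (nrow(pileup) == 0)
    return(data.frame(transcript = character(), position = integer(),
                      ref_base = character(), alt_base = character(),
                      depth = integer(), alt_fraction = numeric()))
  tx <- match(pileup$transcript, names(reference))
  assert_that(!anyNA(tx), "pileup refers to unknown transcript")
  assert_that(all(pileup$position >= 0 &
                  pileup$position < nchar(reference)[tx]),
              "pileup position outside reference")
  ref_base <- substr(rep(reference[tx], 1L), pileup$position + 1L,
                     pileup$position + 1L)
  counts <- as.matrix(pileup[, BASES])
  # zero out the reference base column, then take the top remaining base
  ref_col <- match(ref_base, BASES)
  nonref <- counts
  known <- !is.na(ref_col)
  nonref[cbind(which(known), ref_col[known])] <- 0L
  alt_idx <- max.col(nonref, ties.method = "first")
  alt_count <- nonref[cbind(seq_len(nrow(nonref)), alt_idx)]
  denom <- rowSums(counts) # non-N depth
  frac <- ifelse(denom > 0, alt_count / denom, 0)
  pass_cov <- pileup$depth >= regime$min_coverage
  pass_frac <- if (regime$strict) frac > regime$min_alt_fraction else
    frac >= regime$min_alt_fraction
  keep <- which(pass_cov & pass_frac & alt_count > 0 & known)
  data.frame(transcript = pileup$transcript[keep],
             position = pileup$position[keep],
             ref_base = ref_base[keep],
             alt_base = BASES[alt_idx[keep]],
             depth = pileup$depth[keep],
             alt_fraction = frac[keep],
             stringsAsFactors = FALSE)
}

#' Substitute called SNPs into a reference
#'
#' Output is identical to the input except for the alternative base at each
#' call position; lengths are preserved. A reference-base mismatch at a call
#' position indicates a stale call set and is a hard error.
#'
#' @param reference named character vector of transcripts.
#' @param calls data.frame from [call_snps()].
#' @return the substituted reference.
#' @export
substitute_reference <- function(reference, calls) {
  if (nrow(calls) == 0) return(reference)
  tx <- match(calls$transcript, names(reference))
  assert_that(!anyNA(tx), "call refers to unknown transcript")
  cur <- substr(rep(reference[tx], 1L), calls$position + 1L, calls$position + 1L)
  bad <- which(cur != calls$ref_base)
  if (length(bad))
    stop(sprintf("stale call set: reference base at %s:%d is %s, call expects %s",
                 calls$transcript[bad[1]], calls$position[bad[1]],
                 cur[bad[1]], calls$ref_base[bad[1]]), call. = FALSE)
  for (i in seq_len(nrow(calls)))
    substr(reference[[tx[i]]], calls$position[i] + 1L,
           calls$position[i] + 1L) <- calls$alt_base[i]
  reference
}

#' Iteratively polish a pseudo-reference
#'
#' Repeats align -> call (polish regime) -> substitute, recording the number
#' of detected SNPs per iteration, until the count reaches zero, the change
#' between successive iterations is within `stop_tolerance`, or
#' `max_iterations` is hit. The per-site divergence between the reads'
#' source and the initial reference must be within the aligner's mismatch
#' budget for reads to place at all.
#'
#' @param reads a [read_set()] of quality-trimmed reads.
#' @param initial_reference named character vector of transcripts.
#' @param max_iterations iteration cap (default 16).
#' @param stop_tolerance absolute SNP-count change treated as a plateau
#'   (default 0, i.e. an exact plateau).
#' @param regime calling regime, default [call_regime("polish")].
#' @param k,max_mismatch_frac aligner parameters.
#' @return list(reference, trajectory, calls_per_iteration) where trajectory
#'   is a `snp_trajectory` with fields counts, converged_at, max_iterations.
#' @export
polish_reference <- function(reads, initial_reference, max_iterations = 16L,
                             stop_tolerance = 0L,
                             regime = call_regime("polish"),
                             k = 21L, max_mismatch_frac = 0.04) {
  assert_that(max_iterations >= 1, "max_iterations must be >= 1")
  reference <- initial_reference
  counts <- integer(0)
  calls_hist <- list()
  converged_at <- NA_integer_
  for (it in seq_len(max_iterations)) {
    pl <- align_reads(reads, reference, k = k,
                      max_mismatch_frac = max_mismatch_frac)
    if (it == 1L && nrow(pl) == 0)
      stop("no reads aligned in iteration 1: reference and reads look unrelated",
           call. = FALSE)
    pile <- build_pileup(pl, reads, reference)
    calls <- call_snps(pile, reference, regime)
    counts[it] <- nrow(calls)
    calls_hist[[it]] <- calls
    reference <- substitute_reference(reference, calls)
    if (counts[it] == 0L ||
        (it > 1L && abs(counts[it] - counts[it - 1L]) <= stop_tolerance)) {
      converged_at <- it
      break
    }
  }
  trajectory <- structure(list(counts = counts, converged_at = converged_at,
                               max_iterations = as.integer(max_iterations)),
                          class = "snp_trajectory")
  list(reference = reference, trajectory = trajectory,
       calls_per_iteration = calls_hist)
}

#' @export
print.snp_trajectory <- function(x, ...) {
  cat("SNP-count trajectory:", paste(x$counts, collapse = " -> "), "\n")
  cat(if (is.na(x$converged_at)) "not converged" else
    sprintf("converged at iteration %d", x$converged_at), "\n")
  invisible(x)
}

#' Construct a genotype matrix
#'
#' Haploid-coded biallelic calls: 0 = reference allele, 1 = alternative,
#' NA = missing. No heterozygous state exists in the coding.
#'
#' @param loci data.frame(transcript, position, ref, alt).
#' @param calls integer matrix, loci x accessions, values 0/1/NA.
#' @param depth integer matrix of supporting (non-N) read depth per cell.
#' @return a `genotype_matrix` object.
#' @export
genotype_matrix <- function(loci, calls, depth) {
  assert_that(nrow(loci) == nrow(calls) && all(dim(calls) == dim(depth)),
              "loci, calls and depth dimensions disagree")
  assert_that(all(calls %in% c(0L, 1L, NA)), "calls must be coded 0/1/NA")
  structure(list(loci = loci, calls = calls, depth = depth,
                 accessions = colnames(calls)), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d loci x %d accessions (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Assemble a genotype matrix from per-accession calls and pileups
#'
#' Takes the union of called loci across accessions. Per accession and
#' locus the code is: alternative if called; reference if not called but the
#' position has confirmed (non-N) coverage; missing otherwise. Loci with two
#' or more distinct alternative bases across accessions are excluded as
#' non-biallelic (kept in attribute `multiallelic`).
#'
#' @param call_sets named list (by accession) of [call_snps()] outputs under
#'   the population regime against one shared reference.
#' @param pileups named list (by accession) of [build_pileup()] outputs.
#' @param reference the shared reference transcripts.
#' @return a [genotype_matrix()].
#' @export
build_genotype_matrix <- function(call_sets, pileups, reference) {
  accs <- names(call_sets)
  assert_that(!is.null(accs) && identical(sort(accs), sort(names(pileups))),
              "call_sets and pileups must be named by the same accessions")
  all_calls <- rbind_all(lapply(accs, function(a) {
    cs <- call_sets[[a]]
    if (nrow(cs)) cbind(cs, accession = a) else NULL
  }))
  if (is.null(all_calls) || nrow(all_calls) == 0)
    return(genotype_matrix(
      data.frame(transcript = character(), position = integer(),
                 ref = character(), alt = character()),
      matrix(NA_integer_, 0, length(accs), dimnames = list(NULL, accs)),
      matrix(0L, 0, length(accs), dimnames = list(NULL, accs))))
  key <- paste(all_calls$transcript, all_calls$position, sep = ":")
  loci_key <- sort(unique(key))
  n_alt <- vapply(split(all_calls$alt_base, key),
                  function(b) length(unique(b)), integer(1))[loci_key]
  biallelic <- n_alt == 1L
  first <- all_calls[!duplicated(key), ]
  first <- first[match(loci_key, paste(first$transcript, first$position,
                                       sep = ":")), ]
  loci <- data.frame(transcript = first$transcript, position = first$position,
                     ref = first$ref_base, alt = first$alt_base,
                     stringsAsFactors = FALSE)
  L <- length(loci_key)
  calls <- matrix(NA_integer_, L, length(accs), dimnames = list(NULL, accs))
  depth <- matrix(0L, L, length(accs), dimnames = list(NULL, accs))
  for (a in accs) {
    pile <- pileups[[a]]
    pk <- paste(pile$transcript, pile$position, sep = ":")
    hit <- match(loci_key, pk)
    conf <- rowSums(as.matrix(pile[, BASES]))  # confirmed = non-N coverage
    covered <- !is.na(hit) & conf[hit] > 0
    depth[covered, a] <- conf[hit[covered]]
    calls[covered, a] <- 0L
    cs <- call_sets[[a]]
    if (nrow(cs)) {
      ci <- match(paste(cs$transcript, cs$position, sep = ":"), loci_key)
      calls[ci, a] <- 1L
    }
  }
  gm <- genotype_matrix(loci[biallelic, , drop = FALSE],
                        calls[biallelic, , drop = FALSE],
                        depth[biallelic, , drop = FALSE])
  attr(gm, "multiallelic") <- loci[!biallelic, , drop = FALSE]
  gm
}

#' Coverage-stratified SNP sets
#'
#' Keeps loci where the fraction of accessions with at least `min_reads`
#' supporting reads and a confirmed base is at least `coverage_quantile`.
#' The 100% set additionally contains no missing cells. The three published
#' strata nest: 100% set is a subset of the 95% set is a subset of the 90% set.
#'
#' @param gm a [genotype_matrix()].
#' @param coverage_quantile one of 1.00, 0.95, 0.90.
#' @param min_reads minimum supporting reads per cell (default 3).
#' @return the filtered [genotype_matrix()].
#' @export
filter_covered_set <- function(gm, coverage_quantile = c(1.00, 0.95, 0.90),
                               min_reads = 3L) {
  coverage_quantile <- coverage_quantile[1]
  assert_that(coverage_quantile %in% c(1.00, 0.95, 0.90),
              "coverage_quantile must be one of 1.00, 0.95, 0.90")
  ok_cell <- gm$depth >= min_reads & !is.na(gm$calls)
  frac <- rowMeans(ok_cell)
  keep <- frac >= coverage_quantile
  if (coverage_quantile == 1.00)
    keep <- keep & rowSums(is.na(gm$calls)) == 0L
  genotype_matrix(gm$loci[keep, , drop = FALSE],
                  gm$calls[keep, , drop = FALSE],
                  gm$depth[keep, , drop = FALSE])
}

#' Write calls or a genotype matrix as minimal VCFv4.2
#'
#' Internal 0-based positions are shifted to 1-based VCF coordinates.
#' Genotypes are haploid: `0`, `1`, or `.`.
#'
#' @param x a [call_snps()] data.frame or a [genotype_matrix()].
#' @param path output path.
#' @export
write_vcf <- function(x, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=umbpipe",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">")
  if (inherits(x, "genotype_matrix")) {
    cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", x$accessions)
    gt <- matrix(".", nrow(x$calls), ncol(x$calls))
    gt[!is.na(x$calls)] <- as.character(x$calls[!is.na(x$calls)])
    body <- cbind(x$loci$transcript, x$loci$position + 1L, ".",
                  x$loci$ref, x$loci$alt, ".", "PASS", ".", "GT", gt)
  } else {
    cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
    body <- cbind(x$transcript, x$position + 1L, ".", x$ref_base, x$alt_base,
                  ".", "PASS", paste0("DP=", x$depth))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(body)) writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a minimal VCF back
#'
#' @param path VCF path written by [write_vcf()] (or any site-list VCF).
#' @return data.frame(transcript, position (0-based), ref, alt) plus a
#'   `genotypes` attribute (0/1/NA matrix) when sample columns are present.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM", lines)
  assert_that(length(hdr_i) == 1, "no #CHROM header line")
  cols <- strsplit(lines[hdr_i], "\t")[[1]]
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(body)]
  if (!length(body)) {
    out <- data.frame(transcript = character(), position = integer(),
                      ref = character(), alt = character())
    return(out)
  }
  f <- do.call(rbind, strsplit(body, "\t"))
  out <- data.frame(transcript = f[, 1], position = as.integer(f[, 2]) - 1L,
                    ref = f[, 4], alt = f[, 5], stringsAsFactors = FALSE)
  if (length(cols) > 9) {
    gt <- f[, 10:length(cols), drop = FALSE]
    mode(gt) <- "character"
    g <- suppressWarnings(matrix(as.integer(gt), nrow(gt), ncol(gt)))
    colnames(g) <- cols[10:length(cols)]
    attr(out, "genotypes") <- g
  }
  out
}
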