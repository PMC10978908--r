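# Shared fixture builders. Everything is generated in code; no data files.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# A tiny genotype matrix built by hand: loci x accessions, 0/1/NA.
toy_gm <- function(calls, ref = NULL, alt = NULL, depth = NULL) {
  L <- nrow(calls)
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("s%02d", seq_len(ncol(calls)))
  if (is.null(ref)) ref <- rep("A", L)
  if (is.null(alt)) alt <- rep("G", L)
  if (is.null(depth)) depth <- matrix(10L, L, ncol(calls),
                                      dimnames = dimnames(calls))
  genotype_matrix(
    data.frame(transcript = sprintf("tx%03d", seq_len(L)), position = 0L,
               ref = ref, alt = alt, stringsAsFactors = FALSE),
    calls, depth)
}

# Random pileup columns over a given reference (for filter-oracle tests).
random_pileup <- function(reference, n, seed = 1) {
  set.seed(seed)
  lens <- nchar(reference)
  tx <- sample(names(reference), n, replace = TRUE)
  pos <- vapply(lens[tx], function(L) sample.int(L, 1) - 1L, integer(1))
  counts <- matrix(rpois(5 * n, lambda = 3), n, 5,
                   dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  data.frame(transcript = tx, position = unname(pos),
             depth = rowSums(counts),
             A = counts[, 1], C = counts[, 2], G = counts[, 3],
             T = counts[, 4], N = counts[, 5], stringsAsFactors = FALSE)
}

# Independent brute-force SNP-filter oracle (deliberately written from the
# threshold sentences, not sharing code with call_snps).
oracle_call <- function(pileup, reference, min_cov, min_frac, strict) {
  out <- list()
  for (i in seq_len(nrow(pileup))) {
    row <- pileup[i, ]
    if (row$depth < min_cov) next
    rb <- substr(reference[[row$transcript]], row$position + 1,
                 row$position + 1)
    cnt <- c(A = row$A, C = row$C, G = row$G, T = row$T)
    nonref <- cnt[setdiff(names(cnt), rb)]
    ab <- names(nonref)[which.max(nonref)]
    denom <- sum(cnt)
    if (denom == 0 || nonref[ab] == 0) next
    fr <- nonref[ab] / denom
    pass <- if (strict) fr > min_frac else fr >= min_frac
    if (pass)
      out[[length(out) + 1]] <- data.frame(
        transcript = row$transcript, position = row$position,
        ref_base = rb, alt_base = ab, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(transcript = character(), position = integer(),
               ref_base = character(), alt_base = character())
}

# Phenotype design helper.
make_design <- function(n_acc, lineages, seasons, reps = 2) {
  accs <- sprintf("a%03d", seq_len(n_acc))
  lin <- setNames(rep(lineages, length.out = n_acc), accs)
  d <- expand.grid(accession = accs, season = seasons,
                   replicate = seq_len(reps), stringsAsFactors = FALSE)
  d$lineage <- lin[d$accession]
  d
}

# Independent per-locus variance-component oracle, written directly from the
# haploid ANOVA definitions (mean squares, not the packaged component form).
oracle_fst <- function(calls, groups) {
  num <- 0; den <- 0
  glev <- sort(unique(groups))
  for (l in seq_len(nrow(calls))) {
    n_i <- c(); p_i <- c()
    for (g in glev) {
      x <- calls[l, groups == g]
      x <- x[!is.na(x)]
      if (length(x)) { n_i <- c(n_i, length(x)); p_i <- c(p_i, mean(x)) }
    }
    if (length(n_i) < 2 || sum(n_i - 1) == 0) next
    N <- sum(n_i); r <- length(n_i)
    pbar <- sum(n_i * p_i) / N
    if (pbar %in% c(0, 1)) next
    MSP <- sum(n_i * (p_i - pbar)^2) / (r - 1)
    MSG <- sum(n_i * p_i * (1 - p_i)) / sum(n_i - 1)
    nc <- (N - sum(n_i^2) / N) / (r - 1)
    num <- num + (MSP - MSG) / nc
    den <- den + (MSP - MSG) / nc + MSG
  }
  num / den
}
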