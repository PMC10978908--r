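# Per-locus Weir-Cockerham variance components for haploid samples.
# With r groups of sizes n_i and allele frequencies p_i:
#   MSP = sum n_i (p_i - pbar)^2 / (r - 1)        (among populations)
#   MSG = sum n_i p_i (1 - p_i) / sum (n_i - 1)   (within populations)
#   n_c = (N - sum n_i^2 / N) / (r - 1)
#   sigma2_a = (MSP - MSG) / n_c ;  sigma2_b = MSG
# Returns NA components for loci unusable in every group.
wc_components <- function(calls, groups) {
  glev <- sort(unique(groups))
  r <- length(glev)
  L <- nrow(calls)
  a <- b <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    n_i <- p_i <- numeric(0)
    for (g in glev) {
      x <- calls[l, groups == g]
      x <- x[!is.na(x)]
      if (length(x) >= 1) {
        n_i <- c(n_i, length(x))
        p_i <- c(p_i, mean(x))
      }
    }
    if (length(n_i) < 2 || sum(n_i - 1) == 0) next
    N <- sum(n_i)
    pbar <- sum(n_i * p_i) / N
    if (pbar == 0 || pbar == 1) { a[l] <- 0; b[l] <- 0; next } # monomorphic
    MSP <- sum(n_i * (p_i - pbar)^2) / (length(n_i) - 1)
    MSG <- sum(n_i * p_i * (1 - p_i)) / sum(n_i - 1)
    n_c <- (N - sum(n_i^2) / N) / (length(n_i) - 1)
    a[l] <- (MSP - MSG) / n_c
    b[l] <- MSG
  }
  data.frame(a = a, b = b)
}

#' Pairwise Weir-Cockerham F_ST between assigned lineages
#'
#' Haploid variance-components estimator: per locus, among- and
#' within-population components from allele frequencies and sample sizes;
#' the multi-locus estimate is the ratio of summed numerators to summed
#' denominators. Unassigned accessions are excluded. A matrix monomorphic
#' across a pair yields NA for that pair.
#'
#' @param gm a [genotype_matrix()].
#' @param assignment a [assign_lineages()] result, or a named vector
#'   (accession -> group label, NA = excluded).
#' @return data.frame(group1, group2, fst, n_loci).
#' @export
fst_weir_cockerham <- function(gm, assignment) {
  groups <- if (inherits(assignment, "lineage_assignment"))
    assignment$cluster else assignment
  groups <- groups[gm$accessions]
  keep <- !is.na(groups)
  glev <- sort(unique(groups[keep]))
  assert_that(length(glev) >= 2, "need >= 2 assigned groups")
  assert_that(all(table(groups[keep]) >= 2),
              "each group needs >= 2 accessions")
  pairs <- utils::combn(glev, 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    fst = NA_real_, n_loci = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    sel <- keep & groups %in% pairs[, i]
    comp <- wc_components(gm$calls[, sel, drop = FALSE], groups[sel])
    use <- !is.na(comp$a)
    denom <- sum(comp$a[use] + comp$b[use])
    out$n_loci[i] <- sum(use)
    out$fst[i] <- if (sum(use) == 0 || denom == 0) NA_real_ else
      sum(comp$a[use]) / denom
  }
  out
}
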