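#' Kimura two-parameter distances between accessions
#'
#' For each accession pair the SNP alleles at loci observed in both form a
#' concatenated pseudo-sequence. With P the transition proportion (A<->G,
#' C<->T) and Q the transversion proportion,
#' d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q). Saturated pairs (log of a
#' non-positive argument) are reported NA rather than raising an error.
#'
#' @param gm a [genotype_matrix()]; loci must carry ref/alt base identities.
#' @param dedupe drop loci with identical genotype columns before computing
#'   distances ("non-redundant SNPs"); default FALSE.
#' @return list(taxa, D = symmetric matrix with zero diagonal, model =
#'   "K2P", saturated = logical matrix).
#' @export
k2p_distance <- function(gm, dedupe = FALSE) {
  calls <- gm$calls
  loci <- gm$loci
  if (dedupe) {
    key <- apply(calls, 1, paste, collapse = ",")
    keep <- !duplicated(key)
    calls <- calls[keep, , drop = FALSE]
    loci <- loci[keep, , drop = FALSE]
  }
  n <- ncol(calls)
  taxa <- gm$accessions
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ref_pur <- purine[loci$ref]
  alt_pur <- purine[loci$alt]
  transition <- ref_pur == alt_pur  # same chemical class => transition
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  sat <- matrix(FALSE, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(calls[, i]) & !is.na(calls[, j])
    m <- sum(ok)
    assert_that(m >= 1, sprintf("no shared loci between %s and %s",
                                taxa[i], taxa[j]))
    diffs <- ok & (calls[, i] != calls[, j])
    P <- sum(diffs & transition) / m
    Qv <- sum(diffs & !transition) / m
    w1 <- 1 - 2 * P - Qv
    w2 <- 1 - 2 * Qv
    if (w1 <= 0 || w2 <= 0) {
      D[i, j] <- D[j, i] <- NA_real_
      sat[i, j] <- sat[j, i] <- TRUE
    } else {
      d <- -0.5 * log(w1) - 0.25 * log(w2)
      D[i, j] <- D[j, i] <- d
    }
  }
  list(taxa = taxa, D = D, model = "K2P", saturated = sat)
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining with the canonical Q-criterion
#' Q(i,j) = (r-2) d(i,j) - R_i - R_j; on additive distance matrices the
#' generating topology and branch lengths are recovered exactly. The result
#' is an unrooted `ape::phylo` tree. Note: published trees for this kind of
#' data were maximum-likelihood; distance-based NJ on the same K2P model is
#' used here instead (recorded in the tree's `method` attribute).
#'
#' @param dist a [k2p_distance()] result or a complete symmetric matrix.
#' @return an `ape` phylo object (attribute `method` = "NJ/K2P").
#' @export
nj_tree <- function(dist) {
  D <- if (is.list(dist)) dist$D else dist
  taxa <- rownames(D)
  n <- length(taxa)
  assert_that(n >= 3, "need >= 3 taxa")
  if (any(is.na(D))) {
    miss <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
    stop("incomplete distance matrix; missing pairs: ",
         paste(sprintf("%s-%s", taxa[miss[, 1]], taxa[miss[, 2]]),
               collapse = ", "), call. = FALSE)
  }
  # active nodes are labelled by newick subtrees built bottom-up
  labels <- taxa
  active <- seq_len(n)
  Dw <- D
  while (length(active) > 3) {
    r <- length(active)
    Ds <- Dw[active, active]
    R <- rowSums(Ds)
    Qm <- (r - 2) * Ds - outer(R, R, `+`)
    diag(Qm) <- Inf
    ij <- which(Qm == min(Qm), arr.ind = TRUE)[1, ]
    i <- active[ij[1]]; j <- active[ij[2]]
    dij <- Dw[i, j]
    vi <- 0.5 * dij + (R[ij[1]] - R[ij[2]]) / (2 * (r - 2))
    vj <- dij - vi
    vi <- max(vi, 0); vj <- max(vj, 0)
    new_lab <- sprintf("(%s:%.10g,%s:%.10g)", labels[i], vi, labels[j], vj)
    # distances from the new node u to every other active node
    rest <- setdiff(active, c(i, j))
    du <- 0.5 * (Dw[i, rest] + Dw[j, rest] - dij)
    Dw <- rbind(cbind(Dw, 0), 0)
    u <- nrow(Dw)
    Dw[u, rest] <- Dw[rest, u] <- du
    labels <- c(labels, new_lab)
    active <- c(rest, u)
  }
  a <- active
  d12 <- Dw[a[1], a[2]]; d13 <- Dw[a[1], a[3]]; d23 <- Dw[a[2], a[3]]
  v1 <- max(0, (d12 + d13 - d23) / 2)
  v2 <- max(0, (d12 + d23 - d13) / 2)
  v3 <- max(0, (d13 + d23 - d12) / 2)
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    labels[a[1]], v1, labels[a[2]], v2, labels[a[3]], v3)
  tree <- ape::read.tree(text = newick)
  attr(tree, "method") <- "NJ/K2P"
  tree
}

# Internal-edge bipartitions of an unrooted phylo tree, canonicalized as the
# sorted leaf-label side not containing the first taxon.
tree_bipartitions <- function(tree, all_taxa) {
  n <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  out <- character(0)
  for (p in parts) {
    side <- sort(tree$tip.label[p])
    if (length(side) <= 1 || length(side) >= n - 1) next  # trivial splits
    if (all_taxa[1] %in% side)
      side <- sort(setdiff(all_taxa, side))
    out <- c(out, paste(side, collapse = "|"))
  }
  unique(out)
}

#' Bootstrap support for the NJ/K2P tree
#'
#' Resamples loci with replacement, rebuilds the K2P distances and NJ tree,
#' and reports for each internal bipartition of the point-estimate tree the
#' percentage of replicates containing it. Replicates with saturated
#' (undefined) distances are skipped with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @param n_replicates bootstrap replicates (published protocol: 1000).
#' @param seed integer seed.
#' @param dedupe passed to [k2p_distance()].
#' @return the point-estimate tree with `node.label` holding support (%)
#'   and attribute `support` (named vector by bipartition).
#' @export
bootstrap_support <- function(gm, n_replicates = 1000L, seed = 1L,
                              dedupe = FALSE) {
  tree <- nj_tree(k2p_distance(gm, dedupe = dedupe))
  taxa <- sort(gm$accessions)
  ref_parts <- tree_bipartitions(tree, taxa)
  hits <- setNames(numeric(length(ref_parts)), ref_parts)
  set.seed(seed)
  used <- 0L
  L <- nrow(gm$calls)
  for (b in seq_len(n_replicates)) {
    idx <- sample.int(L, L, replace = TRUE)
    gmb <- genotype_matrix(gm$loci[idx, , drop = FALSE],
                           gm$calls[idx, , drop = FALSE],
                           gm$depth[idx, , drop = FALSE])
    kb <- k2p_distance(gmb, dedupe = FALSE)
    if (any(is.na(kb$D))) next
    tb <- nj_tree(kb)
    pb <- tree_bipartitions(tb, taxa)
    found <- ref_parts %in% pb
    hits[found] <- hits[found] + 1
    used <- used + 1L
  }
  if (used < n_replicates)
    warning(sprintf("%d/%d replicates skipped (saturated distances)",
                    n_replicates - used, n_replicates))
  support <- if (used > 0) 100 * hits / used else hits * NA
  # attach node labels: map each internal node's bipartition to its support
  lab <- rep(NA_character_, tree$Nnode)
  parts <- ape::prop.part(tree)
  for (k in seq_along(parts)) {
    side <- sort(tree$tip.label[parts[[k]]])
    if (length(side) <= 1 || length(side) >= length(taxa) - 1) next
    if (taxa[1] %in% side) side <- sort(setdiff(taxa, side))
    key <- paste(side, collapse = "|")
    if (key %in% names(support)) lab[k] <- sprintf("%.0f", support[key])
  }
  tree$node.label <- lab
  attr(tree, "support") <- support
  attr(tree, "n_replicates_used") <- used
  tree
}
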