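#' Admixture-model population structure by Gibbs sampling
#'
#' Classic admixture model on haploid-coded biallelic genotypes: each allele
#' copy has a latent cluster of origin z, cluster allele frequencies carry a
#' Beta(1,1) prior, per-accession membership vectors q a symmetric
#' Dirichlet(alpha) prior. Memberships are the posterior mean of q after
#' burn-in and thinning; missing cells are skipped in the likelihood. The
#' model evidence ln P(X|K) is estimated from the recorded log-likelihood
#' trace as mean(lnL) - var(lnL)/2.
#'
#' @param gm a [genotype_matrix()].
#' @param K number of clusters (>= 1).
#' @param n_sweeps total Gibbs sweeps (the published budget is 110,000).
#' @param burnin sweeps discarded (published budget 10,000).
#' @param thin record every `thin`-th sweep after burn-in.
#' @param alpha symmetric Dirichlet concentration (default 1).
#' @param seed integer seed.
#' @return a `q_matrix`: list(memberships (accession x K), loglik_trace,
#'   lnPK, K, seed).
#' @export
admixture_gibbs <- function(gm, K, n_sweeps = 2000L, burnin = 500L,
                            thin = 1L, alpha = 1.0, seed = 1L) {
  assert_that(K >= 1, "K must be >= 1")
  g <- t(gm$calls)  # accessions x loci
  poly <- apply(g, 2, function(x) length(unique(x[!is.na(x)])) > 1)
  assert_that(any(poly), "matrix has zero polymorphic loci")
  assert_that(burnin < n_sweeps, "burnin must be below n_sweeps")
  set.seed(seed)
  res <- cpp_admixture_gibbs(g, as.integer(K), as.integer(n_sweeps),
                             as.integer(burnin), as.integer(thin), alpha)
  Q <- res$Q
  rownames(Q) <- gm$accessions
  colnames(Q) <- paste0("cluster", seq_len(K))
  ll <- res$loglik
  structure(list(memberships = Q, loglik_trace = ll,
                 lnPK = mean(ll) - var(ll) / 2, K = K, seed = seed),
            class = "q_matrix")
}

#' @export
print.q_matrix <- function(x, ...) {
  cat(sprintf("q_matrix: %d accessions x K = %d, lnPK = %.1f\n",
              nrow(x$memberships), x$K, x$lnPK))
  invisible(x)
}

#' Run the admixture sampler repeatedly over a range of K
#'
#' Performs `n_runs` independent runs per K (the published protocol used 10
#' runs for K = 1..5), deriving each run's seed from the master seed.
#'
#' @param gm a [genotype_matrix()].
#' @param K_range integer vector of K values.
#' @param n_runs runs per K.
#' @param ... passed to [admixture_gibbs()] (sweeps, burnin, alpha, ...).
#' @param seed master seed.
#' @return named list (by K) of `structure_run_set`: list(runs, lnPK, K).
#' @export
structure_runs <- function(gm, K_range = 1:5, n_runs = 10L, ..., seed = 1L) {
  out <- lapply(K_range, function(K) {
    runs <- lapply(seq_len(n_runs), function(r)
      admixture_gibbs(gm, K, ..., seed = derive_seed(seed, sprintf("K%d-run%d", K, r))))
    structure(list(runs = runs, lnPK = vapply(runs, `[[`, numeric(1), "lnPK"),
                   K = K), class = "structure_run_set")
  })
  names(out) <- as.character(K_range)
  out
}

#' Evanno delta-K table for choosing the number of clusters
#'
#' For each interior K: L'(K) = L(K) - L(K-1) per run index, L''(K) =
#' L'(K+1) - L'(K), and delta-K = mean(|L''(K)|) / sd(L(K)). Endpoint K
#' values have no delta-K (reported NA). A zero between-run sd yields an
#' infinite delta-K with a warning.
#'
#' @param runsets output of [structure_runs()] over >= 3 consecutive K.
#' @return data.frame(K, mean_lnPK, sd_lnPK, delta_K).
#' @export
evanno_delta_k <- function(runsets) {
  Ks <- vapply(runsets, `[[`, numeric(1), "K")
  o <- order(Ks)
  runsets <- runsets[o]; Ks <- Ks[o]
  assert_that(length(Ks) >= 3 && all(diff(Ks) == 1),
              "need >= 3 consecutive K values")
  lnPK <- lapply(runsets, `[[`, "lnPK")
  assert_that(all(lengths(lnPK) >= 2), "need >= 2 runs per K for sd")
  m <- vapply(lnPK, mean, numeric(1))
  s <- vapply(lnPK, sd, numeric(1))
  dK <- rep(NA_real_, length(Ks))
  for (i in seq_along(Ks)[-c(1, length(Ks))]) {
    sec <- abs(lnPK[[i + 1]] - 2 * lnPK[[i]] + lnPK[[i - 1]])
    if (s[i] == 0) {
      warning(sprintf("zero sd of lnPK at K = %d: delta-K infinite", Ks[i]))
      dK[i] <- Inf
    } else dK[i] <- mean(sec) / s[i]
  }
  data.frame(K = Ks, mean_lnPK = m, sd_lnPK = s, delta_K = dK,
             row.names = NULL)
}

permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Align cluster labels across runs and form a consensus Q matrix
#'
#' Cluster labels are arbitrary per run; each run's columns are permuted to
#' minimize the Frobenius distance to run 1 (exhaustive over K! for K <= 6),
#' and the consensus is the element-wise mean. Rows still sum to 1.
#'
#' @param runs list of `q_matrix` objects sharing K and accessions.
#' @return a consensus `q_matrix` (lnPK = mean of run lnPK).
#' @export
align_runs <- function(runs) {
  assert_that(length(runs) >= 1, "need >= 1 run")
  K <- runs[[1]]$K
  assert_that(all(vapply(runs, `[[`, numeric(1), "K") == K),
              "runs must share K")
  if (K > 6)
    stop("exhaustive label alignment is bounded at K <= 6; use a heuristic",
         call. = FALSE)
  ref <- runs[[1]]$memberships
  perms <- permutations(K)
  aligned <- lapply(runs, function(r) {
    Q <- r$memberships
    cost <- apply(perms, 1, function(p) sum((Q[, p, drop = FALSE] - ref)^2))
    Q[, perms[which.min(cost), ], drop = FALSE]
  })
  cons <- Reduce(`+`, aligned) / length(aligned)
  colnames(cons) <- colnames(ref)
  structure(list(memberships = cons,
                 loglik_trace = numeric(0),
                 lnPK = mean(vapply(runs, `[[`, numeric(1), "lnPK")),
                 K = K, seed = runs[[1]]$seed), class = "q_matrix")
}

#' Assign accessions to lineages by the Q-value rule
#'
#' An accession is classified into its maximum-membership cluster iff that
#' membership strictly exceeds the threshold (default 0.8); otherwise it is
#' left unassigned ("intermediate").
#'
#' @param consensus a `q_matrix` (typically from [align_runs()]).
#' @param threshold Q cutoff in (1/K, 1].
#' @return a `lineage_assignment`: list(assignment (named integer, NA =
#'   unassigned), cluster (named character), threshold).
#' @export
assign_lineages <- function(consensus, threshold = 0.8) {
  K <- consensus$K
  assert_that(threshold > 1 / K && threshold <= 1,
              "threshold must lie in (1/K, 1]")
  Q <- consensus$memberships
  best <- max.col(Q, ties.method = "first")
  bestq <- Q[cbind(seq_len(nrow(Q)), best)]
  idx <- ifelse(bestq > threshold, best, NA_integer_)
  structure(list(assignment = setNames(idx, rownames(Q)),
                 cluster = setNames(ifelse(is.na(idx), NA_character_,
                                           colnames(Q)[best]), rownames(Q)),
                 threshold = threshold), class = "lineage_assignment")
}

#' @export
print.lineage_assignment <- function(x, ...) {
  n <- length(x$assignment)
  cat(sprintf("lineage_assignment: %d/%d assigned at Q > %.2f\n",
              sum(!is.na(x$assignment)), n, x$threshold))
  invisible(x)
}
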