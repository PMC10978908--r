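#' Cast a long phenotype table to an accession x trait matrix
#'
#' Replicate measurements are averaged; with `rows = "accession_season"`
#' each accession-season combination is a row (traits measured over several
#' seasons enter once per season, the layout used for phenotype PCA).
#'
#' @param table long data.frame(accession, trait, season, replicate, value).
#' @param rows `"accession_season"` or `"accession"` (means over seasons).
#' @return numeric matrix with NA for unmeasured cells.
#' @export
pheno_matrix <- function(table, rows = c("accession_season", "accession")) {
  rows <- match.arg(rows)
  key <- if (rows == "accession_season")
    paste(table$accession, table$season, sep = "|") else table$accession
  ag <- aggregate(value ~ k + trait,
                  data = data.frame(k = key, trait = table$trait,
                                    value = table$value),
                  FUN = mean, na.action = stats::na.omit)
  rk <- sort(unique(key))
  ck <- sort(unique(table$trait))
  m <- matrix(NA_real_, length(rk), length(ck), dimnames = list(rk, ck))
  m[cbind(match(ag$k, rk), match(ag$trait, ck))] <- ag$value
  m
}

#' Unit-variance scaling
#'
#' Per column: subtract the mean and divide by the standard deviation of the
#' non-missing values. Missing cells remain missing.
#'
#' @param x numeric matrix (columns = traits/variables).
#' @return scaled matrix with attributes `center` and `scale`.
#' @export
scale_uv <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2, sd, na.rm = TRUE)
  bad <- which(!is.finite(sdv) | sdv == 0)
  if (length(bad))
    stop(sprintf("zero-variance column: %s",
                 paste(colnames(x)[bad] %||% bad, collapse = ", ")),
         call. = FALSE)
  n_obs <- colSums(!is.na(x))
  assert_that(all(n_obs >= 2), "each column needs >= 2 non-missing values")
  out <- sweep(sweep(x, 2, mu), 2, sdv, `/`)
  attr(out, "center") <- mu
  attr(out, "scale") <- sdv
  out
}

# Observed-data log-likelihood of a centered PPCA model, summed over rows.
ppca_loglik <- function(x, W, sigma2) {
  ll <- 0
  for (i in seq_len(nrow(x))) {
    o <- which(!is.na(x[i, ]))
    if (!length(o)) next
    C <- W[o, , drop = FALSE] %*% t(W[o, , drop = FALSE]) +
      diag(sigma2, length(o))
    ll <- ll + mvn_logdens(x[i, o], C)
  }
  ll
}

mvn_logdens <- function(v, C) {
  ch <- chol(C)
  -0.5 * (length(v) * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, v, transpose = TRUE)^2))
}

#' Impute missing cells by probabilistic PCA (EM, Bayesian-style shrinkage)
#'
#' EM for the probabilistic PCA model x = W z + eps on a unit-variance
#' scaled matrix, treating latent scores and missing entries as hidden
#' variables. With `ard = TRUE` each component of W carries an
#' automatic-relevance prior whose precision is re-estimated every step, so
#' superfluous components shrink toward zero. Observed cells are never
#' altered. The procedure is deterministic given the input (SVD
#' initialization); `seed` is accepted for interface stability.
#'
#' @param x scaled numeric matrix with missing values (no all-missing row
#'   or column).
#' @param n_components latent dimension; must be < min(dim(x)). Default
#'   min(dim(x)) - 1.
#' @param n_steps EM steps (published protocol: 100).
#' @param ard apply automatic-relevance shrinkage of components.
#' @param seed unused (kept for call-signature stability).
#' @return completed matrix with attributes `W`, `sigma2`, `loglik`
#'   (observed-data log-likelihood trace).
#' @export
bpca_impute <- function(x, n_components = NULL, n_steps = 100L, ard = TRUE,
                        seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  assert_that(!any(rowSums(!is.na(x)) == 0), "all-missing row")
  assert_that(!any(colSums(!is.na(x)) == 0), "all-missing column")
  q <- n_components %||% (min(n, d) - 1L)
  assert_that(q >= 1 && q < min(n, d),
              "n_components must satisfy 1 <= q < min(dim(x))")
  miss <- is.na(x)
  if (!any(miss) && n_steps == 0) return(x)
  # deterministic init: SVD of the zero-imputed matrix
  x0 <- x; x0[miss] <- 0
  sv <- svd(x0, nu = 0, nv = q)
  W <- sv$v %*% diag(sv$d[seq_len(q)] / sqrt(n), q)
  sigma2 <- max(mean(x0^2) / 10, 1e-6)
  alpha <- rep(1e-10, q)
  ll_trace <- numeric(0)
  Ez_all <- matrix(0, n, q)
  for (step in seq_len(n_steps)) {
    S_zz <- matrix(0, q, q)
    A <- matrix(0, d, q)      # sum_i E[x_i z_i']
    Ex2 <- numeric(d)         # sum_i E[x_ij^2]
    Ezz_list <- vector("list", n)
    for (i in seq_len(n)) {
      o <- which(!miss[i, ])
      Wo <- W[o, , drop = FALSE]
      M <- crossprod(Wo) + diag(sigma2, q)
      Minv <- solve(M)
      Ez <- drop(Minv %*% crossprod(Wo, x[i, o]))
      Ezz <- sigma2 * Minv + tcrossprod(Ez)
      Ez_all[i, ] <- Ez
      Ezz_list[[i]] <- Ezz
      S_zz <- S_zz + Ezz
      A[o, ] <- A[o, ] + outer(x[i, o], Ez)
      Ex2[o] <- Ex2[o] + x[i, o]^2
      m <- which(miss[i, ])
      if (length(m)) {
        Wm <- W[m, , drop = FALSE]
        A[m, ] <- A[m, ] + Wm %*% Ezz
        Ex2[m] <- Ex2[m] + rowSums((Wm %*% Ezz) * Wm) + sigma2
      }
    }
    W_new <- A %*% solve(S_zz + sigma2 * diag(alpha, q))
    s2 <- sum(Ex2) - 2 * sum(A * W_new) +
      sum(vapply(seq_len(n), function(i)
        sum((W_new %*% Ezz_list[[i]]) * W_new), numeric(1)))
    sigma2 <- max(s2 / (n * d), 1e-12)
    W <- W_new
    if (ard) alpha <- d / (colSums(W^2) + 1e-12)
    ll_trace[step] <- ppca_loglik(x, W, sigma2)
  }
  out <- x
  if (any(miss)) {
    fill <- Ez_all %*% t(W)
    out[miss] <- fill[miss]
  }
  attr(out, "W") <- W
  attr(out, "sigma2") <- sigma2
  attr(out, "loglik") <- ll_trace
  out
}

#' Principal component analysis with contributions
#'
#' Eigendecomposition of the covariance of the (already scaled) matrix.
#' Contributions are eigenvalue shares in percent. Sign convention: within
#' each component the largest-magnitude loading is positive.
#'
#' @param x complete numeric matrix (samples x variables).
#' @return a `pca_result`: list(scores, loadings, contributions, sdev).
#' @export
run_pca <- function(x) {
  x <- as.matrix(x)
  assert_that(!anyNA(x), "matrix must be complete (impute first)")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  contrib <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 contributions = contrib, sdev = pc$sdev),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(4, length(x$contributions))
  cat(sprintf("pca_result: %d samples x %d PCs; contributions %s%%\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.2f", x$contributions[1:k]), collapse = ", ")))
  invisible(x)
}

#' Cluster traits by their PCA loadings
#'
#' Euclidean distances between trait loading vectors over the first
#' `n_components` components, agglomerated with Ward linkage.
#'
#' @param loadings variable x component loading matrix (or `pca_result`).
#' @param n_components number of leading components to use.
#' @return an `hclust` object.
#' @export
cluster_traits <- function(loadings, n_components = 4L) {
  if (inherits(loadings, "pca_result")) loadings <- loadings$loadings
  assert_that(nrow(loadings) >= 2, "need >= 2 traits")
  k <- min(n_components, ncol(loadings))
  hclust(dist(loadings[, seq_len(k), drop = FALSE]), method = "ward.D2")
}

#' Split-chain Gelman-Rubin statistic
#'
#' Each chain is split in half; with m resulting chains of length n,
#' Rhat = sqrt(((n-1)/n * W + B/n) / W) where W is the mean within-chain
#' variance and B/n the between-chain variance of chain means. Zero
#' within-chain variance is defined as Rhat = 1 with a warning.
#'
#' @param chains list of equal-length numeric vectors (>= 2 chains,
#'   length >= 4), or a draws x chains matrix.
#' @return the Rhat statistic.
#' @export
rhat <- function(chains) {
  if (is.matrix(chains)) chains <- asplit(chains, 2)
  chains <- lapply(chains, as.numeric)
  assert_that(length(chains) >= 2, "need >= 2 chains")
  len <- unique(lengths(chains))
  assert_that(length(len) == 1 && len >= 4,
              "chains must have equal length >= 4")
  half <- len %/% 2
  split_chains <- unlist(lapply(chains, function(x)
    list(x[seq_len(half)], x[half + seq_len(half)])), recursive = FALSE)
  n <- half
  means <- vapply(split_chains, mean, numeric(1))
  W <- mean(vapply(split_chains, var, numeric(1)))
  B <- n * var(means)
  if (W == 0) {
    warning("zero within-chain variance: Rhat defined as 1")
    return(1)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Bayesian lineage-by-season linear mixed model (Gibbs sampler)
#'
#' Normal linear mixed model for one trait:
#' y = X beta + gamma_accession + eps, with fixed effects intercept,
#' lineage, season and their interaction (treatment coding, alphabetically
#' first level as reference), accession random intercepts
#' gamma ~ N(0, sigma_gamma^2) and residual sd sigma_eps. Conjugate updates:
#' beta ~ N(0, 1e6) componentwise, variances ~ Inverse-Gamma(0.01, 0.01).
#' The published budget (4 chains x 5000 iterations, 1000 burn-in) retains
#' 16,000 draws.
#'
#' @param data data.frame with columns value, lineage, season, accession
#'   (rows = individual measurements; replicates share their accession's
#'   random intercept).
#' @param chains number of chains.
#' @param iterations sweeps per chain.
#' @param burnin discarded sweeps per chain.
#' @param seed integer seed.
#' @return a `posterior_summary`: list(summary data.frame(parameter, mean,
#'   lower, upper, rhat), draws matrix, chains, draws_retained, converged).
#' @export
fit_glmm <- function(data, chains = 4L, iterations = 5000L, burnin = 1000L,
                     seed = 1L) {
  assert_that(all(c("value", "lineage", "season", "accession") %in%
                    names(data)), "data needs value, lineage, season, accession")
  data <- data[!is.na(data$value), , drop = FALSE]
  assert_that(length(unique(data$lineage)) >= 2 &&
                length(unique(data$season)) >= 2,
              "need >= 2 lineages and >= 2 seasons")
  assert_that(burnin < iterations, "burnin must be below iterations")
  data$lineage <- factor(data$lineage)
  data$season <- factor(data$season)
  X <- stats::model.matrix(~ lineage * season, data = data)
  acc <- factor(data$accession)
  n_acc <- nlevels(acc)
  ai <- as.integer(acc)
  y <- data$value
  N <- length(y); p <- ncol(X)
  XtX <- crossprod(X)
  se <- tabulate(ai, n_acc)
  a0 <- 0.01; b0 <- 0.01; tau_beta <- 1e6
  keep <- iterations - burnin
  draws <- array(NA_real_, c(keep, chains, p + 2))
  for (ch in seq_len(chains)) {
    set.seed(derive_seed(seed, sprintf("glmm-chain%d", ch)))
    beta <- rnorm(p, 0, 1)
    gamma <- rep(0, n_acc)
    s2g <- var(y) * runif(1, 0.3, 3)
    s2e <- var(y) * runif(1, 0.3, 3)
    for (it in seq_len(iterations)) {
      # beta | .
      r <- y - gamma[ai]
      V <- XtX / s2e + diag(1 / tau_beta, p)
      ch_V <- chol(V)
      mu <- backsolve(ch_V, backsolve(ch_V, crossprod(X, r) / s2e,
                                      transpose = TRUE))
      beta <- drop(mu + backsolve(ch_V, rnorm(p)))
      # gamma | .
      e <- y - drop(X %*% beta)
      sum_e <- drop(rowsum(e, ai, reorder = TRUE))
      prec <- se / s2e + 1 / s2g
      gm <- (sum_e / s2e) / prec
      gamma <- rnorm(n_acc, gm, sqrt(1 / prec))
      # variances | .
      s2g <- 1 / rgamma(1, a0 + n_acc / 2, b0 + sum(gamma^2) / 2)
      resid <- e - gamma[ai]
      s2e <- 1 / rgamma(1, a0 + N / 2, b0 + sum(resid^2) / 2)
      if (it > burnin)
        draws[it - burnin, ch, ] <- c(beta, sqrt(s2g), sqrt(s2e))
    }
  }
  par_names <- c(colnames(X), "sigma_gamma", "sigma_eps")
  summ <- data.frame(parameter = par_names,
                     mean = NA_real_, lower = NA_real_, upper = NA_real_,
                     rhat = NA_real_, stringsAsFactors = FALSE)
  flat <- matrix(NA_real_, keep * chains, p + 2,
                 dimnames = list(NULL, par_names))
  for (j in seq_len(p + 2)) {
    m <- draws[, , j, drop = TRUE]
    if (chains == 1) m <- matrix(m, ncol = 1)
    flat[, j] <- as.vector(m)
    summ$mean[j] <- mean(flat[, j])
    qs <- quantile(flat[, j], c(0.025, 0.975), names = FALSE)
    summ$lower[j] <- qs[1]; summ$upper[j] <- qs[2]
    summ$rhat[j] <- if (chains >= 2) rhat(m) else NA_real_
  }
  structure(list(summary = summ, draws = flat, chains = chains,
                 draws_retained = keep * chains,
                 converged = all(is.na(summ$rhat) | summ$rhat < 1.1)),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("posterior_summary: %d draws (%d chains)%s\n",
              x$draws_retained, x$chains,
              if (x$converged) "" else " [NOT CONVERGED: some Rhat >= 1.1]"))
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Flowering-time dendrogram over accessions
#'
#' Z-normalizes days-to-flowering within each season, computes Euclidean
#' distances over season vectors (missing seasons pairwise-excluded with the
#' distance rescaled, as in `stats::dist`), and clusters with Ward linkage.
#'
#' @param x accession x season matrix of days to flowering.
#' @return an `hclust` object; convert with `ape::as.phylo` for Newick.
#' @export
flowering_dendrogram <- function(x) {
  x <- as.matrix(x)
  assert_that(nrow(x) >= 2, "need >= 2 accessions")
  all_na <- rowSums(!is.na(x)) == 0
  if (any(all_na)) {
    warning(sprintf("excluding %d accession(s) missing all seasons",
                    sum(all_na)))
    x <- x[!all_na, , drop = FALSE]
  }
  z <- scale_uv(x)
  hclust(dist(z), method = "ward.D2")
}
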