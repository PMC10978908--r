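test_that("unit-variance scaling centers and scales per trait", {
  m <- cbind(t1 = c(1, 2, 3), t2 = c(10, 20, 60))
  sc <- scale_uv(m)
  expect_equal(mean(sc[, "t1"]), 0, tolerance = 1e-12)
  expect_equal(sd(sc[, "t1"]), 1, tolerance = 1e-12)
  # all-equal trait errors with its name
  expect_error(scale_uv(cbind(ok = c(1, 2), flat = c(5, 5))), "flat")
  # random table: recompute directly
  set.seed(1)
  x <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("v", 1:5)))
  x[sample(200, 20)] <- NA
  sc2 <- scale_uv(x)
  expect_true(all(abs(colMeans(sc2, na.rm = TRUE)) < 1e-12))
  expect_true(all(abs(apply(sc2, 2, sd, na.rm = TRUE) - 1) < 1e-12))
  expect_equal(is.na(sc2), is.na(x))
})

test_that("imputation leaves complete matrices untouched", {
  set.seed(2)
  x <- scale_uv(matrix(rnorm(60), 12, 5))
  out <- bpca_impute(x, n_components = 3, n_steps = 10)
  expect_equal(unname(out), unname(x), ignore_attr = TRUE)
})

test_that("held-out rank-1 cells are reconstructed to 1e-3", {
  set.seed(3)
  u <- rnorm(30); v <- rnorm(8)
  x <- tcrossprod(u, v)
  miss <- sample(length(x), round(0.1 * length(x)))
  xm <- x
  xm[miss] <- NA
  out <- bpca_impute(xm, n_components = 2, n_steps = 200)
  expect_lt(max(abs(out[miss] - x[miss])), 1e-3)
  # observed cells unchanged
  expect_equal(out[-miss], x[-miss], tolerance = 0)
})

test_that("EM log-likelihood is non-decreasing over 100 steps", {
  set.seed(4)
  x <- matrix(rnorm(25 * 6), 25, 6) %*% diag(c(3, 2, 1, .5, .5, .5))
  x <- scale_uv(x)
  x[sample(length(x), 15)] <- NA
  out <- bpca_impute(x, n_components = 3, n_steps = 100, ard = FALSE)
  ll <- attr(out, "loglik")
  expect_length(ll, 100)
  expect_true(all(diff(ll) > -1e-8))
  # validation
  expect_error(bpca_impute(x, n_components = 6), "n_components")
  bad <- x; bad[3, ] <- NA
  expect_error(bpca_impute(bad, 2), "all-missing row")
})

test_that("PCA contributions match closed-form eigenvalues", {
  # orthogonal centered columns with sample covariance diag(4, 2, 1)
  p1 <- c(1, -1, 1, -1); p2 <- c(1, 1, -1, -1); p3 <- c(1, -1, -1, 1)
  x <- cbind(p1 * sqrt(3), p2 * sqrt(1.5), p3 * sqrt(0.75))
  pc <- run_pca(x)
  expect_equal(pc$contributions, c(4, 2, 1) / 7 * 100, tolerance = 1e-9)
  expect_equal(round(pc$contributions, 2), c(57.14, 28.57, 14.29))
  # loadings orthonormal
  expect_equal(crossprod(pc$loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  # full-rank reconstruction of the centered data
  centered <- scale(x, center = TRUE, scale = FALSE)
  expect_equal(pc$scores %*% t(pc$loadings), centered, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("perfectly correlated variables load on a single component", {
  set.seed(5)
  a <- rnorm(20)
  pc <- run_pca(cbind(a, 2 * a))
  expect_equal(pc$contributions[1], 100, tolerance = 1e-9)
  expect_true(sum(pc$contributions) <= 100 + 1e-9)
})

test_that("trait clustering matches an exhaustive Ward oracle", {
  # brute-force ward.D2 agglomeration via Lance-Williams
  ward_oracle <- function(d) {
    n <- attr(d, "Size")
    D <- as.matrix(d)^2
    sizes <- rep(1, n)
    active <- 1:n
    merges <- list()
    repeat {
      if (length(active) < 2) break
      best <- c(NA, NA); bd <- Inf
      for (i in active) for (j in active) if (i < j && D[i, j] < bd) {
        bd <- D[i, j]; best <- c(i, j)
      }
      merges[[length(merges) + 1]] <- sort(best)
      i <- best[1]; j <- best[2]
      ni <- sizes[i]; nj <- sizes[j]
      for (k in setdiff(active, best)) {
        nk <- sizes[k]
        D[i, k] <- D[k, i] <- ((ni + nk) * D[i, k] + (nj + nk) * D[j, k] -
                                 nk * D[i, j]) / (ni + nj + nk)
      }
      sizes[i] <- ni + nj
      active <- setdiff(active, j)
    }
    merges
  }
  set.seed(6)
  load <- matrix(rnorm(5 * 3), 5, 3,
                 dimnames = list(paste0("trait", 1:5), NULL))
  hc <- cluster_traits(load, n_components = 3)
  oracle <- ward_oracle(dist(load))
  # compare merge partner sets step by step
  labels_of <- function(merge_row, hc) {
    unlist(lapply(merge_row, function(v)
      if (v < 0) -v else NA))
  }
  # reconstruct cluster members from hclust merge matrix
  members <- list()
  for (s in seq_len(nrow(hc$merge))) {
    m <- hc$merge[s, ]
    got <- sort(unlist(lapply(m, function(v)
      if (v < 0) -v else members[[v]])))
    members[[s]] <- got
  }
  omembers <- list(); oa <- as.list(1:5)
  for (s in seq_along(oracle)) {
    i <- oracle[[s]][1]; j <- oracle[[s]][2]
    oa[[i]] <- sort(c(oa[[i]], oa[[j]]))
    omembers[[s]] <- oa[[i]]
    oa[j] <- list(NULL)
  }
  for (s in seq_along(omembers))
    expect_equal(members[[s]], unname(omembers[[s]]))
  # duplicated traits merge first at height 0
  load2 <- rbind(load, trait5_copy = load[5, ])
  hc2 <- cluster_traits(load2, 3)
  expect_equal(hc2$height[1], 0, tolerance = 1e-12)
  expect_setequal(-hc2$merge[1, ], c(5, 6))
  # Ward merge heights are non-decreasing
  expect_true(all(diff(hc$height) > -1e-10))
})

test_that("highly correlated traits are merged first", {
  set.seed(7)
  base <- rnorm(60)
  x <- cbind(days_to_heading = base + rnorm(60, 0, 0.1),
             days_to_flowering = base + rnorm(60, 0, 0.1),
             awn_length = rnorm(60), spike_length = rnorm(60),
             plant_height = rnorm(60))
  pc <- run_pca(scale_uv(x))
  hc <- cluster_traits(pc, n_components = 4)
  first <- sort(rownames(pc$loadings)[-hc$merge[1, ]])
  expect_equal(first, c("days_to_flowering", "days_to_heading"))
})

test_that("rhat matches longhand evaluation and detects divergence", {
  # identical chains: B = 0 so Rhat = 1
  expect_equal(rhat(list(c(1, 2, 3, 4), c(1, 2, 3, 4))),
               rhat_longhand <- {
                 # longhand: split chains (1,2),(3,4),(1,2),(3,4); n = 2
                 sc <- list(c(1, 2), c(3, 4), c(1, 2), c(3, 4))
                 W <- mean(vapply(sc, var, numeric(1)))
                 B <- 2 * var(vapply(sc, mean, numeric(1)))
                 sqrt(((2 - 1) / 2 * W + B / 2) / W)
               }, tolerance = 1e-12)
  set.seed(8)
  c1 <- rnorm(1000); c2 <- rnorm(1000, 5)
  expect_gt(rhat(list(c1, c2)), 1.5)
  expect_warning(r0 <- rhat(list(rep(2, 10), rep(2, 10))), "zero")
  expect_equal(r0, 1)
  expect_error(rhat(list(1:10)), ">= 2 chains")
})

test_that("GLMM recovers zero effects and reports its budget", {
  spec <- glmm_spec(beta0 = 10, beta1 = c(A = 0, B = 0),
                    beta2 = c(s1 = 0, s2 = 0), sigma_gamma = 0.3,
                    sigma_eps = 0.5)
  d <- make_design(24, c("A", "B"), c("s1", "s2"), reps = 2)
  ph <- simulate_phenotypes(spec, d, seed = 9)
  dat <- data.frame(value = ph$value, lineage = d$lineage,
                    season = ph$season, accession = ph$accession)
  fit <- fit_glmm(dat, chains = 2, iterations = 1200, burnin = 400, seed = 10)
  expect_equal(fit$draws_retained, 2 * 800)
  s <- fit$summary
  eff <- s[s$parameter != "(Intercept)" &
             !s$parameter %in% c("sigma_gamma", "sigma_eps"), ]
  expect_true(all(eff$lower <= 0 & eff$upper >= 0))
  expect_true(all(s$lower <= s$mean & s$mean <= s$upper))
  expect_error(fit_glmm(dat[dat$lineage == "A", ]), ">= 2 lineages")
})

test_that("flowering dendrogram separates early and late groups", {
  set.seed(11)
  n <- 20
  early <- matrix(rnorm(n / 2 * 4, 140, 1), n / 2, 4)
  late <- matrix(rnorm(n / 2 * 4, 160, 1), n / 2, 4)
  x <- rbind(early, late)
  rownames(x) <- sprintf("a%02d", 1:n)
  colnames(x) <- paste0("season", 1:4)   # 4 seasons accepted
  hc <- flowering_dendrogram(x)
  grp <- cutree(hc, 2)
  expect_equal(length(unique(grp[1:10])), 1)
  expect_equal(length(unique(grp[11:20])), 1)
  expect_false(grp[1] == grp[11])
  # identical accessions merge first at distance 0
  x2 <- x
  x2[2, ] <- x2[1, ]
  hc2 <- flowering_dendrogram(x2)
  expect_equal(hc2$height[1], 0, tolerance = 1e-12)
  expect_setequal(-hc2$merge[1, ], c(1, 2))
  # all-missing accession excluded with warning
  x3 <- x
  x3[3, ] <- NA
  expect_warning(hc3 <- flowering_dendrogram(x3), "excluding")
  expect_equal(length(hc3$order), n - 1)
})

test_that("pheno_matrix casts long tables with replicate means", {
  tab <- data.frame(accession = c("a1", "a1", "a2"),
                    trait = "t", season = "s1",
                    replicate = c(1, 2, 1), value = c(10, 12, 20))
  m <- pheno_matrix(tab, rows = "accession_season")
  expect_equal(m["a1|s1", "t"], 11)
  expect_equal(m["a2|s1", "t"], 20)
})
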