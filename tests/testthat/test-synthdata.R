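test_that("zero mutation rates give an undiverged population", {
  tree <- list(name = "root", rate = 0, children = list(
    list(name = "L1", rate = 0), list(name = "L2", rate = 0)))
  sim <- simulate_population(6, 5, 300L, tree, seed = 1)
  expect_equal(nrow(sim$truth$divergent_sites), 0)
  for (s in sim$sequences) expect_identical(unname(s), unname(sim$ancestor))
})

test_that("the three-sublineage configuration yields exactly 3 lineages", {
  sim <- simulate_population(12, 10, 300L, default_lineage_tree(0.01), seed = 2)
  labs <- sim$truth$lineage_labels
  expect_setequal(unique(labs[!is.na(labs)]),
                  c("UmbL1e", "UmbL1w", "UmbL2"))
  # admixture fractions are a simplex per accession
  expect_true(all(abs(rowSums(sim$truth$admixture_fractions) - 1) < 1e-9))
})

test_that("divergent-site count falls in the binomial 99% interval", {
  # rate 0.01 over ~100 kb; oracle: per-site Bernoulli expectation
  rate <- 0.01
  tree <- list(name = "root", rate = 0, children = list(
    list(name = "L1", rate = rate), list(name = "L2", rate = 0)))
  sim <- simulate_population(2, 100, 1000L, tree, seed = 3)
  total_sites <- 100 * 1000
  observed <- sum(sim$truth$divergent_sites$lineage == "L1")
  ci <- qbinom(c(0.005, 0.995), total_sites, rate)
  expect_gte(observed, ci[1])
  expect_lte(observed, ci[2])
  # conservation: recorded sites equal exhaustive consensus-vs-ancestor diff
  cons <- sim$truth$lineage_consensus[["L1"]]
  n_diff <- sum(vapply(names(sim$ancestor), function(tx)
    sum(utf8ToInt(sim$ancestor[[tx]]) != utf8ToInt(cons[[tx]])), integer(1)))
  expect_equal(observed, n_diff)
})

test_that("generator validates its configuration", {
  bad_tree <- list(name = "root", rate = 0.7)
  expect_error(simulate_population(2, 2, 100L, bad_tree), "0.5")
  expect_error(simulate_population(2, 2, 0L), "zero-length")
  expect_error(simulate_population(2, 0, 100L), "n_transcripts")
  expect_error(simulate_reads(c(t1 = "ACGTACGT"), depth = 0), "depth")
  expect_error(simulate_reads(c(t1 = strrep("A", 200)), 5, error_rate = 0.4),
               "error_rate")
  expect_error(simulate_reads(c(t1 = strrep("A", 100)), 5, read_length = 150),
               "shortest")
})

test_that("reads are exact substrings at error rate 0 and always 150 bp", {
  set.seed(4)
  tx <- setNames(vapply(rep(400, 6), rand_seq, character(1)), paste0("t", 1:6))
  rs <- simulate_reads(tx, depth = 8, error_rate = 0, seed = 5)
  expect_true(all(nchar(rs$sequence) == 150))
  for (i in seq_len(length(rs))) {
    meta <- strsplit(rs$id[i], ":")[[1]]
    src <- substr(tx[[meta[2]]], as.integer(meta[3]) + 1,
                  as.integer(meta[3]) + 150)
    expect_identical(rs$sequence[i], src)
  }
})

test_that("empirical mismatch rate matches the configured error rate", {
  set.seed(6)
  tx <- setNames(vapply(rep(500, 10), rand_seq, character(1)), paste0("t", 1:10))
  rs <- simulate_reads(tx, depth = 70, error_rate = 0.01, seed = 7)
  total <- 0; mism <- 0
  for (i in seq_len(length(rs))) {
    meta <- strsplit(rs$id[i], ":")[[1]]
    src <- substr(tx[[meta[2]]], as.integer(meta[3]) + 1,
                  as.integer(meta[3]) + 150)
    mism <- mism + sum(utf8ToInt(src) != utf8ToInt(rs$sequence[i]))
    total <- total + 150
  }
  expect_gt(total, 1e5)
  se <- sqrt(0.01 * 0.99 / total)
  expect_lt(abs(mism / total - 0.01), 3 * se)
})

test_that("three-prime bias shifts read starts toward transcript ends", {
  set.seed(8)
  tx <- c(t1 = rand_seq(2000))
  uni <- simulate_reads(tx, depth = 400, error_rate = 0,
                        three_prime_bias = 0, seed = 9)
  bia <- simulate_reads(tx, depth = 400, error_rate = 0,
                        three_prime_bias = 0.05, seed = 9)
  start_of <- function(rs) as.integer(vapply(strsplit(rs$id, ":"), `[`,
                                             character(1), 3))
  expect_gt(mean(start_of(bia)), mean(start_of(uni)))
})

test_that("identical seed and config give byte-identical artifacts", {
  sim1 <- simulate_population(4, 5, 300L, default_lineage_tree(0.01),
                              admixed_fraction = 0.25, seed = 10)
  sim2 <- simulate_population(4, 5, 300L, default_lineage_tree(0.01),
                              admixed_fraction = 0.25, seed = 10)
  expect_identical(sim1, sim2)
  r1 <- simulate_reads(sim1$sequences[[1]], 10, seed = 11)
  r2 <- simulate_reads(sim2$sequences[[1]], 10, seed = 11)
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(r1, f1); write_fastq(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("degenerate phenotype spec returns the intercept everywhere", {
  spec <- glmm_spec(beta0 = 100, beta1 = c(A = 0, B = 0),
                    beta2 = c(s1 = 0, s2 = 0),
                    sigma_gamma = 0, sigma_eps = 0)
  d <- make_design(8, c("A", "B"), c("s1", "s2"))
  ph <- simulate_phenotypes(spec, d, seed = 12)
  expect_true(all(ph$value == 100))
})

test_that("a 10-day lineage contrast appears in group means", {
  spec <- glmm_spec(beta0 = 150, beta1 = c(UmbL1e = 0, UmbL1w = 10),
                    beta2 = c(s1 = 0, s2 = 3),
                    sigma_gamma = 1, sigma_eps = 1)
  d <- make_design(60, c("UmbL1e", "UmbL1w"), c("s1", "s2"), reps = 3)
  ph <- simulate_phenotypes(spec, d, seed = 13)
  ph$lineage <- d$lineage[match(paste(ph$accession, ph$season, ph$replicate),
                                paste(d$accession, d$season, d$replicate))]
  gap <- mean(ph$value[ph$lineage == "UmbL1w"]) -
    mean(ph$value[ph$lineage == "UmbL1e"])
  expect_lt(abs(gap - 10), 1)
})

test_that("group-mean contrasts match analytic expectation at n = 200", {
  spec <- glmm_spec(beta0 = 50, beta1 = c(A = 0, B = 4),
                    beta2 = c(s1 = 0, s2 = -2),
                    beta3 = matrix(c(0, 0, 0, 1.5), 2, 2,
                                   dimnames = list(c("A", "B"), c("s1", "s2"))),
                    sigma_gamma = 1.5, sigma_eps = 1)
  d <- make_design(200, c("A", "B"), c("s1", "s2"), reps = 2)
  ph <- simulate_phenotypes(spec, d, seed = 14)
  ph$lineage <- ifelse(ph$accession %in% d$accession[d$lineage == "A"], "A", "B")
  cell <- function(l, s) mean(ph$value[ph$lineage == l & ph$season == s])
  # Monte-Carlo error ~ sigma_total/sqrt(200): use 4 sd
  tol <- 4 * sqrt(1.5^2 + 1^2) / sqrt(200)
  expect_lt(abs(cell("B", "s1") - cell("A", "s1") - 4), 2 * tol)
  expect_lt(abs(cell("B", "s2") - cell("A", "s2") - 5.5), 2 * tol)
  expect_error(glmm_spec(1, c(A = 0), c(s = 0), sigma_gamma = -1,
                         sigma_eps = 1), "standard deviations")
})

test_that("noiseless climate gradient gives perfect latitude correlation", {
  labs <- setNames(rep(c("L1", "L2"), each = 10), sprintf("a%02d", 1:20))
  geo <- simulate_geoclimate(labs, list(L1 = c(34, 37), L2 = c(38, 41)),
                             gradients = list(srad = -300), noise_sd = 0,
                             seed = 15)
  seas <- seasonal_means(geo)
  ct <- cline_test(geo$lat, seas$srad_1, "lat", "srad_1")
  expect_equal(ct$r, -1, tolerance = 1e-12)
  expect_equal(ct$slope, -300, tolerance = 1e-9)
})

test_that("disjoint lineage latitude ranges separate lineages", {
  labs <- setNames(rep(c("UmbL2", "UmbL1w", "UmbL1e"), each = 8),
                   sprintf("a%02d", 1:24))
  geo <- simulate_geoclimate(labs, list(UmbL2 = c(35, 38),
                                        UmbL1w = c(36, 40),
                                        UmbL1e = c(30, 37)),
                             seed = 16)
  rng <- tapply(geo$lat, geo$lineage, range)
  expect_true(all(geo$lat[geo$lineage == "UmbL2"] >= 35 &
                    geo$lat[geo$lineage == "UmbL2"] <= 38))
  expect_true(all(geo$lat[geo$lineage == "UmbL1e"] <= 37))
})

test_that("OLS recovers the generating slope within its 99% CI", {
  labs <- setNames(rep("L1", 114), sprintf("a%03d", 1:114))
  geo <- simulate_geoclimate(labs, list(L1 = c(30, 42)),
                             gradients = list(temp = -0.4), noise_sd = 1,
                             seed = 17)
  seas <- seasonal_means(geo)
  # oracle: lm-based OLS with its own CI
  fit <- lm(seas$temp_1 ~ geo$lat)
  ci <- confint(fit, level = 0.99)[2, ]
  expect_gte(-0.4, ci[1])
  expect_lte(-0.4, ci[2])
})

test_that("island-model genotypes hit the target differentiation", {
  g <- simulate_structured_genotypes(c(A = 20, B = 20, C = 20), 400,
                                     fst = 0.3, n_admixed = 4, seed = 18)
  expect_equal(dim(g$gm), c(400L, 64L))
  expect_equal(sum(is.na(g$truth$labels)), 4)
  expect_true(all(abs(rowSums(g$truth$fractions) - 1) < 1e-9))
  fst <- fst_weir_cockerham(g$gm, g$truth$labels)
  expect_equal(nrow(fst), 3)
  expect_lt(max(abs(fst$fst - 0.3)), 0.1)
})
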