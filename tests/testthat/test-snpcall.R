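test_that("regime thresholds gate calls as published", {
  ref <- c(t1 = strrep("A", 50))
  col <- function(depth, G) data.frame(
    transcript = "t1", position = 10L, depth = depth,
    A = depth - G, C = 0L, G = G, T = 0L, N = 0L)
  polish <- call_regime("polish")
  # depth 9, 9/9 alt: below coverage 10, discarded
  expect_equal(nrow(call_snps(col(9, 9), ref, polish)), 0)
  # depth 12, 12/12 alt: unanimous call
  got <- call_snps(col(12, 12), ref, polish)
  expect_equal(nrow(got), 1)
  expect_equal(got$alt_fraction, 1.0)
  expect_equal(got$ref_base, "A")
  expect_equal(got$alt_base, "G")
  # population regime: exactly 80% is NOT a call (strict >), 81% is
  pop <- call_regime("population")
  expect_equal(nrow(call_snps(col(10, 8), ref, pop)), 0)
  expect_equal(nrow(call_snps(col(100, 81), ref, pop)), 1)
  # polish regime: exactly 95% IS a call (>=)
  expect_equal(nrow(call_snps(col(100, 95), ref, polish)), 1)
})

test_that("call_snps matches the exhaustive threshold oracle on random columns", {
  set.seed(31)
  ref <- c(a = rand_seq(300), b = rand_seq(300))
  pile <- random_pileup(ref, 1000, seed = 32)
  for (rg in list(call_regime("polish"), call_regime("population"))) {
    got <- call_snps(pile, ref, rg)
    want <- oracle_call(pile, ref, rg$min_coverage, rg$min_alt_fraction,
                        rg$strict)
    key_got <- sprintf("%s:%d:%s>%s", got$transcript, got$position,
                       got$ref_base, got$alt_base)
    key_want <- sprintf("%s:%d:%s>%s", want$transcript, want$position,
                        want$ref_base, want$alt_base)
    expect_setequal(key_got, key_want)
  }
})

test_that("substitution rewrites exactly the called bases", {
  ref <- c(t1 = "AAAAAAAAAA", t2 = "CCCCCCCCCC")
  expect_identical(substitute_reference(ref, call_snps(
    data.frame(transcript = character(), position = integer(), depth = integer(),
               A = integer(), C = integer(), G = integer(), T = integer(),
               N = integer()), ref, call_regime("polish"))), ref)
  calls <- data.frame(transcript = "t1", position = 5L, ref_base = "A",
                      alt_base = "T", depth = 20L, alt_fraction = 1)
  out <- substitute_reference(ref, calls)
  expect_equal(out[["t1"]], "AAAAATAAAA")
  expect_equal(out[["t2"]], ref[["t2"]])
  # stale ref base is a hard error
  calls$ref_base <- "G"
  expect_error(substitute_reference(ref, calls), "stale")
})

test_that("substitute-then-recall removes previously called sites", {
  set.seed(33)
  sim <- simulate_population(1, 10, 500L, default_lineage_tree(0.015),
                             seed = 34, site_region = c(0.2, 0.8))
  rs <- simulate_reads(sim$sequences[[1]], depth = 60, error_rate = 0, seed = 35)
  pl <- align_reads(rs, sim$ancestor)
  pile <- build_pileup(pl, rs, sim$ancestor)
  calls <- call_snps(pile, sim$ancestor, call_regime("polish"))
  expect_gt(nrow(calls), 0)
  newref <- substitute_reference(sim$ancestor, calls)
  pl2 <- align_reads(rs, newref)
  pile2 <- build_pileup(pl2, rs, newref)
  calls2 <- call_snps(pile2, newref, call_regime("polish"))
  old_keys <- sprintf("%s:%d", calls$transcript, calls$position)
  new_keys <- sprintf("%s:%d", calls2$transcript, calls2$position)
  expect_length(intersect(old_keys, new_keys), 0)
})

test_that("polishing a matching reference yields trajectory [0]", {
  set.seed(36)
  sim <- simulate_population(1, 6, 400L, default_lineage_tree(0), seed = 37)
  rs <- simulate_reads(sim$sequences[[1]], depth = 40, error_rate = 0, seed = 38)
  pr <- polish_reference(rs, sim$ancestor)
  expect_equal(pr$trajectory$counts, 0L)
  expect_equal(pr$trajectory$converged_at, 1L)
  expect_identical(pr$reference, sim$ancestor)
})

test_that("polish trajectory is capped and errors when nothing aligns", {
  set.seed(39)
  sim <- simulate_population(1, 4, 400L, default_lineage_tree(0), seed = 40)
  rs <- simulate_reads(sim$sequences[[1]], depth = 20, error_rate = 0, seed = 41)
  pr <- polish_reference(rs, sim$ancestor, max_iterations = 16)
  expect_lte(length(pr$trajectory$counts), 16)
  unrelated <- setNames(vapply(rep(400, 4), rand_seq, character(1)),
                        names(sim$ancestor))
  expect_error(polish_reference(rs, unrelated), "no reads aligned")
})

test_that("VCF round-trips calls exactly, including boundary positions", {
  ref <- c(t1 = strrep("ACGT", 25))  # length 100
  calls <- data.frame(transcript = "t1", position = c(0L, 50L, 99L),
                      ref_base = c("A", "G", "T"), alt_base = c("G", "A", "C"),
                      depth = c(12L, 15L, 20L), alt_fraction = 1)
  f <- tempfile(fileext = ".vcf")
  write_vcf(calls, f)
  lines <- readLines(f)
  pos_col <- as.integer(vapply(strsplit(grep("^t1", lines, value = TRUE),
                                        "\t"), `[`, character(1), 2))
  expect_equal(pos_col, c(1L, 51L, 100L))   # 1-based on disk
  back <- read_vcf(f)
  expect_equal(back$position, calls$position)
  expect_equal(back$ref, calls$ref_base)
  expect_equal(back$alt, calls$alt_base)
  # genotype-matrix VCF with samples round-trips GT codes
  gm <- toy_gm(matrix(c(0L, 1L, NA, 1L, 0L, 1L), nrow = 3,
                      dimnames = list(NULL, c("s1", "s2"))))
  write_vcf(gm, f)
  back2 <- read_vcf(f)
  expect_equal(attr(back2, "genotypes")[, "s1"], c(0L, 1L, NA))
  expect_equal(attr(back2, "genotypes")[, "s2"], c(1L, 0L, 1L))
})

test_that("genotype matrix assembly codes alt/ref/missing and drops multiallelics", {
  ref <- c(t1 = strrep("A", 30))
  mkcall <- function(pos, alt) data.frame(
    transcript = rep("t1", length(pos)), position = pos,
    ref_base = rep("A", length(pos)), alt_base = alt,
    depth = rep(10L, length(pos)), alt_fraction = rep(1, length(pos)),
    stringsAsFactors = FALSE)
  mkpile <- function(pos) data.frame(
    transcript = "t1", position = pos, depth = 10L, A = 10L, C = 0L,
    G = 0L, T = 0L, N = 0L, stringsAsFactors = FALSE)
  # acc1 has the SNP at 5; acc2 is covered there but not called
  gm <- build_genotype_matrix(
    list(acc1 = mkcall(5L, "G"),
         acc2 = mkcall(integer(0), character(0))),
    list(acc1 = mkpile(c(5L, 6L)), acc2 = mkpile(c(5L, 6L))), ref)
  expect_equal(nrow(gm$calls), 1)
  expect_equal(gm$calls[1, ], c(acc1 = 1L, acc2 = 0L))
  # uncovered in acc2 => missing
  gm2 <- build_genotype_matrix(
    list(acc1 = mkcall(5L, "G"), acc2 = mkcall(integer(0), character(0))),
    list(acc1 = mkpile(5L), acc2 = mkpile(7L)), ref)
  expect_true(is.na(gm2$calls[1, "acc2"]))
  # alt C in one accession, alt T in another => non-biallelic, excluded
  gm3 <- build_genotype_matrix(
    list(acc1 = mkcall(5L, "C"), acc2 = mkcall(5L, "T")),
    list(acc1 = mkpile(5L), acc2 = mkpile(5L)), ref)
  expect_equal(nrow(gm3$calls), 0)
  expect_equal(nrow(attr(gm3, "multiallelic")), 1)
})

test_that("coverage-stratified sets nest and match a row-count oracle", {
  set.seed(42)
  L <- 200; n <- 40
  calls <- matrix(sample(c(0L, 1L, NA), L * n, replace = TRUE,
                         prob = c(0.55, 0.35, 0.10)), L, n,
                  dimnames = list(NULL, sprintf("s%02d", 1:n)))
  depth <- matrix(rpois(L * n, 5), L, n, dimnames = dimnames(calls))
  gm <- toy_gm(calls, depth = depth)
  g100 <- filter_covered_set(gm, 1.00)
  g95 <- filter_covered_set(gm, 0.95)
  g90 <- filter_covered_set(gm, 0.90)
  key <- function(g) sprintf("%s:%d", g$loci$transcript, g$loci$position)
  expect_true(all(key(g100) %in% key(g95)))
  expect_true(all(key(g95) %in% key(g90)))
  # oracle: explicit per-row counting
  ok <- !is.na(calls) & depth >= 3
  frac <- apply(ok, 1, mean)
  expect_equal(nrow(g90$calls), sum(frac >= 0.90))
  expect_equal(nrow(g95$calls), sum(frac >= 0.95))
  expect_equal(nrow(g100$calls),
               sum(frac >= 1 & apply(!is.na(calls), 1, all)))
  expect_equal(sum(is.na(g100$calls)), 0)
  # all loci fully covered: 100% set is the identity
  gm_full <- toy_gm(matrix(1L, 5, 3), depth = matrix(5L, 5, 3))
  expect_equal(nrow(filter_covered_set(gm_full, 1.00)$calls), 5)
})

test_that("genotype TSV round-trips loci and calls", {
  set.seed(43)
  calls <- matrix(sample(c(0L, 1L, NA), 30, replace = TRUE), 10, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  gm <- toy_gm(calls)
  f <- tempfile(fileext = ".tsv")
  write_genotype_tsv(gm, f)
  back <- read_genotype_tsv(f)
  expect_equal(back$loci, gm$loci, ignore_attr = TRUE)
  expect_equal(unname(back$calls), unname(gm$calls))
})
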