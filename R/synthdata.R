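#' Default three-lineage tree
#'
#' Mirrors a species split into one deep lineage plus a second lineage
#' divided into two sublineages (e.g. UmbL2 vs UmbL1e/UmbL1w). Each node
#' carries a per-site branch mutation probability. The default branch
#' geometry keeps the sublineage split comparable in depth to the deep
#' split (a short shared internal branch), matching the near-equidistant
#' pairwise differentiation reported for the three real lineages.
#'
#' @param rate per-site mutation probability on the deep branch.
#' @param internal_rate shared branch of the two sublineages.
#' @param sublineage_rate private branch of each sublineage.
#' @return nested list usable as `lineage_tree` in [simulate_population()].
#' @export
default_lineage_tree <- function(rate = 0.005, internal_rate = rate / 5,
                                 sublineage_rate = 0.8 * rate) {
  list(name = "root", rate = 0, children = list(
    list(name = "UmbL2", rate = rate),
    list(name = "UmbL1", rate = internal_rate, children = list(
      list(name = "UmbL1e", rate = sublineage_rate),
      list(name = "UmbL1w", rate = sublineage_rate)))))
}

mutate_seq <- function(seq, rate, region = c(0, 1)) {
  if (rate == 0) return(seq)
  L <- nchar(seq)
  lo <- max(1L, floor(region[1] * L) + 1L)
  hi <- min(L, ceiling(region[2] * L))
  idx <- lo:hi
  hit <- idx[runif(length(idx)) < rate]
  if (!length(hit)) return(seq)
  chars <- strsplit(seq, "")[[1]]
  chars[hit] <- vapply(chars[hit],
                       function(b) sample(setdiff(BASES, b), 1L), character(1))
  paste(chars, collapse = "")
}

walk_lineages <- function(node, seqs, region) {
  derived <- lapply(seqs, mutate_seq, rate = node$rate, region = region)
  if (is.null(node$children))
    return(setNames(list(derived), node$name))
  out <- list()
  for (ch in node$children)
    out <- c(out, walk_lineages(ch, derived, region))
  out
}

diff_sites <- function(ancestor, derived) {
  out <- lapply(names(ancestor), function(tx) {
    a <- utf8ToInt(ancestor[[tx]])
    d <- utf8ToInt(derived[[tx]])
    pos <- which(a != d)
    if (!length(pos)) return(NULL)
    data.frame(transcript = tx, position = pos - 1L,
               ancestral = intToUtf8(a[pos], multiple = TRUE),
               derived = intToUtf8(d[pos], multiple = TRUE),
               stringsAsFactors = FALSE)
  })
  rbind_all(out)
}

#' Simulate a structured population of transcript sets
#'
#' Generates an ancestral transcriptome, derives lineage consensus sequences
#' by per-site substitutions along a lineage tree, and assigns accessions to
#' lineages (with optional per-accession private mutations and admixed
#' accessions whose transcripts are per-transcript mosaics of two parent
#' lineages). Ground truth records lineage labels, admixture fractions and
#' every lineage-divergent site (by exhaustive comparison to the ancestor).
#'
#' @param n_accessions number of accessions.
#' @param n_transcripts number of transcripts (>= 1).
#' @param transcript_length integer length, or a range `c(min, max)` sampled
#'   uniformly per transcript.
#' @param lineage_tree nested list of lineages with branch mutation rates in
#'   [0, 0.5); see [default_lineage_tree()].
#' @param admixed_fraction proportion of accessions drawn as two-lineage
#'   mosaics.
#' @param private_rate per-site private mutation probability per accession.
#' @param site_region relative interval of each transcript in which
#'   mutations may occur (default the whole transcript); restricting it
#'   keeps divergent sites away from coverage-starved transcript ends.
#' @param seed integer seed.
#' @return list(ancestor, sequences = per-accession named list of transcript
#'   vectors, truth = `population_truth`).
#' @export
simulate_population <- function(n_accessions, n_transcripts,
                                transcript_length = 600L,
                                lineage_tree = default_lineage_tree(),
                                admixed_fraction = 0, private_rate = 0,
                                site_region = c(0, 1), seed = 1L) {
  assert_that(n_transcripts >= 1, "n_transcripts must be >= 1")
  assert_that(all(transcript_length > 0), "zero-length transcripts rejected")
  check_rates <- function(node) {
    assert_that(node$rate >= 0 && node$rate < 0.5, "rates must be in [0, 0.5)")
    for (ch in node$children %||% list()) check_rates(ch)
  }
  check_rates(lineage_tree)
  assert_that(admixed_fraction >= 0 && admixed_fraction < 1,
              "admixed_fraction must be in [0, 1)")
  set.seed(seed)
  lens <- if (length(transcript_length) == 2)
    sample(transcript_length[1]:transcript_length[2], n_transcripts,
           replace = TRUE) else rep(transcript_length, n_transcripts)
  ancestor <- setNames(vapply(lens, random_seq, character(1)),
                       sprintf("tx%04d", seq_len(n_transcripts)))
  consensus <- walk_lineages(lineage_tree, as.list(ancestor), site_region)
  lineages <- names(consensus)
  div <- rbind_all(lapply(lineages, function(ln) {
    d <- diff_sites(as.list(ancestor), consensus[[ln]])
    if (is.null(d) || nrow(d) == 0) return(NULL)
    cbind(lineage = ln, d)
  }))
  if (is.null(div))
    div <- data.frame(lineage = character(), transcript = character(),
                      position = integer(), ancestral = character(),
                      derived = character())

  n_adm <- floor(admixed_fraction * n_accessions)
  acc_ids <- sprintf("acc%03d", seq_len(n_accessions))
  labels <- setNames(rep(lineages, length.out = n_accessions), acc_ids)
  adm_idx <- if (n_adm > 0) seq_len(n_adm) * floor(n_accessions / (n_adm + 1L)) else integer(0)
  frac <- matrix(0, n_accessions, length(lineages),
                 dimnames = list(acc_ids, lineages))
  frac[cbind(seq_len(n_accessions), match(labels, lineages))] <- 1
  sequences <- vector("list", n_accessions)
  names(sequences) <- acc_ids
  for (i in seq_len(n_accessions)) {
    if (i %in% adm_idx) {
      parents <- sample(lineages, 2L)
      f <- runif(1, 0.3, 0.7)
      pick <- runif(n_transcripts) < f
      seqs <- ifelse(pick, unlist(consensus[[parents[1]]]),
                     unlist(consensus[[parents[2]]]))
      names(seqs) <- names(ancestor)
      obs_f <- mean(pick)
      frac[i, ] <- 0
      frac[i, parents] <- c(obs_f, 1 - obs_f)
      labels[i] <- NA_character_
    } else {
      seqs <- unlist(consensus[[labels[i]]])
      names(seqs) <- names(ancestor)
    }
    if (private_rate > 0)
      seqs <- vapply(seqs, mutate_seq, character(1), rate = private_rate,
                     region = site_region)
    sequences[[i]] <- seqs
  }
  truth <- structure(list(lineage_labels = labels,
                          admixture_fractions = frac,
                          divergent_sites = div,
                          lineage_consensus = consensus,
                          seed = seed), class = "population_truth")
  list(ancestor = ancestor, sequences = sequences, truth = truth)
}

#' Simulate 3'-tag single-end reads from transcripts
#'
#' Read starts are drawn with a truncated-geometric bias toward the 3' end
#' (`three_prime_bias = 0` gives uniform starts). Substitution errors are
#' injected per base; Phred qualities are drawn from a clipped normal
#' quality model. Read ids record accession, source transcript and 0-based
#' start for provenance checks.
#'
#' @param transcripts named character vector (one accession's transcripts).
#' @param depth mean reads per transcript (Poisson; > 0).
#' @param read_length read length in bp (default 150; must not exceed the
#'   shortest transcript).
#' @param error_rate per-base substitution probability in [0, 0.25].
#' @param three_prime_bias geometric decay weight in [0, 1) on the distance
#'   of the read start from its 3'-most position.
#' @param accession id prefix for read names.
#' @param seed integer seed.
#' @return a [read_set()].
#' @export
simulate_reads <- function(transcripts, depth, read_length = 150L,
                           error_rate = 0.002, three_prime_bias = 0,
                           accession = "acc", seed = 1L) {
  assert_that(depth > 0, "depth must be > 0")
  assert_that(error_rate >= 0 && error_rate <= 0.25,
              "error_rate must be in [0, 0.25]")
  assert_that(read_length <= min(nchar(transcripts)),
              "read_length exceeds shortest transcript")
  set.seed(seed)
  ids <- seqs <- list(); quals <- list()
  n_tx <- length(transcripts)
  counter <- 0L
  for (t in seq_len(n_tx)) {
    n <- rpois(1, depth)
    if (n == 0) next
    L <- nchar(transcripts[[t]])
    M <- L - read_length  # 0-based start range is 0..M
    d <- if (M == 0) rep(0L, n) else if (three_prime_bias == 0)
      sample(0:M, n, replace = TRUE)
    else
      sample(0:M, n, replace = TRUE,
             prob = (1 - three_prime_bias)^(0:M))
    start <- M - d
    sq <- substring(transcripts[[t]], start + 1L, start + read_length)
    if (error_rate > 0) {
      mat <- matrix(unlist(strsplit(sq, "")), nrow = read_length)
      err <- which(matrix(runif(length(mat)) < error_rate, nrow = read_length))
      if (length(err)) {
        mat[err] <- vapply(mat[err],
                           function(b) sample(setdiff(BASES, b), 1L),
                           character(1))
        sq <- apply(mat, 2, paste, collapse = "")
      }
    }
    q <- lapply(seq_len(n), function(i)
      pmin(40L, pmax(2L, as.integer(round(rnorm(read_length, 38, 2))))))
    ids[[t]] <- sprintf("%s:%s:%d:%d", accession, names(transcripts)[t],
                        start, counter + seq_len(n))
    counter <- counter + n
    seqs[[t]] <- sq
    quals[[t]] <- q
  }
  read_set(unlist(ids) %||% character(0),
           unlist(seqs) %||% character(0),
           do.call(c, quals) %||% list())
}

#' Specification of the lineage-by-season mixed model generator
#'
#' Houses the generative parameters of the phenotype model
#' y = b0 + b1[lineage] + b2[season] + b3[lineage, season] + gamma_acc + eps,
#' with gamma ~ N(0, sigma_gamma^2) per accession and eps ~ N(0, sigma_eps^2)
#' per measurement.
#'
#' @param beta0 intercept (trait units).
#' @param beta1 named numeric vector of lineage effects.
#' @param beta2 named numeric vector of season effects.
#' @param beta3 lineage x season interaction matrix (dimnames must match
#'   beta1/beta2 names); defaults to zero.
#' @param sigma_gamma accession random-effect sd (>= 0).
#' @param sigma_eps residual sd (>= 0).
#' @return a `glmm_spec` object.
#' @export
glmm_spec <- function(beta0, beta1, beta2, beta3 = NULL,
                      sigma_gamma, sigma_eps) {
  assert_that(sigma_gamma >= 0 && sigma_eps >= 0,
              "standard deviations must be >= 0")
  assert_that(!is.null(names(beta1)) && !is.null(names(beta2)),
              "beta1 and beta2 must be named by lineage / season")
  if (is.null(beta3))
    beta3 <- matrix(0, length(beta1), length(beta2),
                    dimnames = list(names(beta1), names(beta2)))
  assert_that(identical(rownames(beta3), names(beta1)) &&
              identical(colnames(beta3), names(beta2)),
              "beta3 dimnames must match beta1/beta2")
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 sigma_gamma = sigma_gamma, sigma_eps = sigma_eps),
            class = "glmm_spec")
}

#' Simulate phenotypes from the mixed-model generator
#'
#' @param spec a [glmm_spec()].
#' @param design data.frame(accession, lineage, season, replicate); lineages
#'   and seasons must be declared in `spec`.
#' @param trait trait name for the output table.
#' @param missing_rate missing-at-random masking rate.
#' @param seed integer seed.
#' @return long data.frame(accession, trait, season, replicate, value) plus
#'   attribute `gamma` (the accession random effects drawn).
#' @export
simulate_phenotypes <- function(spec, design, trait = "trait",
                                missing_rate = 0, seed = 1L) {
  assert_that(all(design$lineage %in% names(spec$beta1)),
              "design references undeclared lineages")
  assert_that(all(design$season %in% names(spec$beta2)),
              "design references undeclared seasons")
  set.seed(seed)
  accs <- unique(design$accession)
  gamma <- setNames(rnorm(length(accs), 0, spec$sigma_gamma), accs)
  mu <- spec$beta0 + spec$beta1[design$lineage] + spec$beta2[design$season] +
    spec$beta3[cbind(design$lineage, design$season)] + gamma[design$accession]
  value <- mu + rnorm(nrow(design), 0, spec$sigma_eps)
  if (missing_rate > 0)
    value[runif(length(value)) < missing_rate] <- NA_real_
  out <- data.frame(accession = design$accession, trait = trait,
                    season = design$season, replicate = design$replicate,
                    value = as.numeric(value), stringsAsFactors = FALSE)
  attr(out, "gamma") <- gamma
  out
}

#' Default monthly baseline profiles for the climate generator
#' @keywords internal
climate_baselines <- function() {
  m <- 1:12
  list(temp = 12 + 10 * cos(2 * pi * (m - 7) / 12) * -1,
       prec = 60 + 30 * cos(2 * pi * (m - 1) / 12),
       srad = 15000 + 6000 * cos(2 * pi * (m - 7) / 12),
       vapr = 1.2 + 0.8 * cos(2 * pi * (m - 7) / 12),
       wind = 3 + 0.5 * cos(2 * pi * (m - 1) / 12))
}

#' Simulate a geo-climate table structured by latitude
#'
#' Latitude is drawn uniformly within each lineage's range; each monthly
#' climate value is a seasonal baseline plus a linear-in-latitude term plus
#' Gaussian noise. Elevation is uniform within a per-lineage range.
#'
#' @param lineage_labels named character vector (accession -> lineage;
#'   NA-labelled accessions draw from the pooled latitude range).
#' @param lat_ranges named list of `c(min, max)` per lineage.
#' @param lon_ranges like `lat_ranges` (default 20-48 shared).
#' @param elev_ranges like `lat_ranges` in metres (default 0-1500 shared).
#' @param gradients named list: per-variable slope against latitude
#'   (variables among temp, prec, srad, vapr, wind).
#' @param noise_sd Gaussian noise sd added to every monthly value.
#' @param seed integer seed.
#' @return data.frame(accession, lineage, lat, lon, elev,
#'   `{var}_{01..12}` for the five climate variables).
#' @export
simulate_geoclimate <- function(lineage_labels, lat_ranges,
                                lon_ranges = NULL, elev_ranges = NULL,
                                gradients = list(srad = -300, temp = -0.4),
                                noise_sd = 0, seed = 1L) {
  assert_that(all(vapply(lat_ranges, function(r) diff(r) > 0, logical(1))),
              "latitude ranges must be non-degenerate")
  assert_that(all(is.finite(unlist(gradients))), "slopes must be finite")
  set.seed(seed)
  accs <- names(lineage_labels)
  n <- length(accs)
  pool <- range(unlist(lat_ranges))
  lat <- vapply(lineage_labels, function(ln) {
    r <- if (is.na(ln) || is.null(lat_ranges[[ln]])) pool else lat_ranges[[ln]]
    runif(1, r[1], r[2])
  }, numeric(1))
  pick_range <- function(ranges, default) vapply(lineage_labels, function(ln) {
    r <- if (is.na(ln) || is.null(ranges[[ln]])) default else ranges[[ln]]
    runif(1, r[1], r[2])
  }, numeric(1))
  lon <- pick_range(lon_ranges %||% list(), c(20, 48))
  elev <- pick_range(elev_ranges %||% list(), c(0, 1500))
  base <- climate_baselines()
  out <- data.frame(accession = accs, lineage = unname(lineage_labels),
                    lat = unname(lat), lon = unname(lon), elev = unname(elev),
                    stringsAsFactors = FALSE)
  for (v in names(base)) {
    slope <- gradients[[v]] %||% 0
    for (m in 1:12)
      out[[sprintf("%s_%02d", v, m)]] <-
        base[[v]][m] + slope * out$lat + rnorm(n, 0, noise_sd)
  }
  rownames(out) <- NULL
  out
}

#' Simulate haploid genotypes under an island model
#'
#' Balding-Nichols allele frequencies: ancestral frequencies are uniform in
#' `maf_range`; each lineage draws per-locus frequencies from
#' Beta(p(1-F)/F, (1-p)(1-F)/F), so the expected Weir-Cockerham F_ST equals
#' `fst`. Accessions carry one allele per locus (haploid-coded); admixed
#' accessions draw each locus from one of two parent lineages with a
#' recorded mixing fraction.
#'
#' @param n_per_lineage named integer vector (lineage -> sample size).
#' @param n_loci number of biallelic loci.
#' @param fst target differentiation in (0, 1).
#' @param n_admixed number of additional 50:50 admixed accessions.
#' @param maf_range ancestral allele-frequency range.
#' @param seed integer seed.
#' @return list(gm = [genotype_matrix()], truth = list(labels, fractions,
#'   freqs = lineage x locus allele frequencies)).
#' @export
simulate_structured_genotypes <- function(n_per_lineage, n_loci, fst = 0.3,
                                          n_admixed = 0,
                                          maf_range = c(0.1, 0.9), seed = 1L) {
  assert_that(fst > 0 && fst < 1, "fst must be in (0, 1)")
  set.seed(seed)
  lineages <- names(n_per_lineage)
  assert_that(!is.null(lineages), "n_per_lineage must be named")
  p_anc <- runif(n_loci, maf_range[1], maf_range[2])
  a <- p_anc * (1 - fst) / fst
  b <- (1 - p_anc) * (1 - fst) / fst
  freqs <- t(vapply(lineages, function(ln) rbeta(n_loci, a, b),
                    numeric(n_loci)))
  rownames(freqs) <- lineages
  n_total <- sum(n_per_lineage) + n_admixed
  accs <- sprintf("acc%03d", seq_len(n_total))
  labels <- setNames(c(rep(lineages, n_per_lineage),
                       rep(NA_character_, n_admixed)), accs)
  frac <- matrix(0, n_total, length(lineages),
                 dimnames = list(accs, lineages))
  calls <- matrix(NA_integer_, n_loci, n_total, dimnames = list(NULL, accs))
  i <- 0L
  for (ln in lineages)
    for (j in seq_len(n_per_lineage[[ln]])) {
      i <- i + 1L
      calls[, i] <- rbinom(n_loci, 1L, freqs[ln, ])
      frac[i, ln] <- 1
    }
  for (j in seq_len(n_admixed)) {
    i <- i + 1L
    parents <- if (length(lineages) >= 2) sample(lineages, 2L) else lineages
    pick <- runif(n_loci) < 0.5
    p <- ifelse(pick, freqs[parents[1], ], freqs[parents[2], ])
    calls[, i] <- rbinom(n_loci, 1L, p)
    frac[i, parents] <- c(mean(pick), 1 - mean(pick))
  }
  ref <- sample(BASES, n_loci, replace = TRUE)
  alt <- vapply(ref, function(bse) sample(setdiff(BASES, bse), 1L), character(1))
  loci <- data.frame(transcript = sprintf("tx%05d", seq_len(n_loci)),
                     position = 0L, ref = ref, alt = unname(alt),
                     stringsAsFactors = FALSE)
  depth <- matrix(10L, n_loci, n_total, dimnames = list(NULL, accs))
  list(gm = genotype_matrix(loci, calls, depth),
       truth = list(labels = labels, fractions = frac, freqs = freqs))
}
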