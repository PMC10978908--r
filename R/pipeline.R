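#' Pipeline configuration
#'
#' Builds a validated nested configuration for [run_pipeline()]. Any block
#' can be overridden; unknown fields are rejected. `stages` toggles stage
#' execution; parameter blocks echo the published defaults (trim 4/20/75,
#' polish regime 10/0.95 with a 16-iteration cap, population regime 5/0.80,
#' coverage quantile 1.00 with 3 supporting reads, Q threshold 0.8).
#' Sampler budgets default to desk scale; the published budgets (110,000
#' sweeps / 10,000 burn-in; 4 x 5000 / 1000) are configuration values.
#'
#' @param out_dir artifact directory.
#' @param seed master seed; per-stage substreams derive from it.
#' @param ... overrides, e.g. `structure = list(K_range = 1:4, n_runs = 5)`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, ...) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed), resume = FALSE,
    stages = list(simulate = TRUE, trim = TRUE, polish = TRUE, align = TRUE,
                  callsnps = TRUE, snpset = TRUE, structure = TRUE,
                  fst = TRUE, tree = TRUE, pheno = TRUE, climate = TRUE),
    simulate = list(n_accessions = 12L, n_transcripts = 200L,
                    transcript_length = 300L, lineage_rate = 0.01,
                    admixed_fraction = 0, private_rate = 0.003,
                    site_region = c(0.25, 0.75), depth = 30, read_length = 150L,
                    error_rate = 0.002, three_prime_bias = 0,
                    flowering_contrast = 10),
    trim = list(window = 4L, mean_quality_threshold = 20, min_length = 75L),
    align = list(k = 21L, max_mismatch_frac = 0.04),
    polish = list(max_iterations = 16L, stop_tolerance = 0L),
    snpset = list(coverage_quantile = 1.00, min_reads = 3L),
    structure = list(K_range = 1:4, n_runs = 3L, n_sweeps = 600L,
                     burnin = 200L, alpha = 1.0, q_threshold = 0.8),
    tree = list(n_bootstrap = 100L, dedupe = FALSE),
    pheno = list(chains = 2L, iterations = 1500L, burnin = 500L,
                 trait = "days_to_flowering", n_components = 3L,
                 bpca_steps = 100L),
    climate = list(gradients = list(srad = -300, temp = -0.4), noise_sd = 5)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    assert_that(nm %in% names(cfg), sprintf("unknown config block '%s'", nm))
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      for (f in names(dots[[nm]])) {
        assert_that(f %in% names(cfg[[nm]]),
                    sprintf("unknown field '%s' in block '%s'", f, nm))
        cfg[[nm]][[f]] <- dots[[nm]][[f]]
      }
    } else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with the same nesting as [pipeline_config()].
#' @param out_dir overrides the configured artifact directory if given.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  od <- out_dir %||% raw$out_dir
  assert_that(!is.null(od), "config must carry out_dir")
  raw$out_dir <- NULL
  seed <- raw$seed %||% 1L
  raw$seed <- NULL
  do.call(pipeline_config, c(list(out_dir = od, seed = seed), raw))
}

#' Write a genotype matrix as TSV
#'
#' Columns: transcript, position (0-based), ref, alt, then one 0/1/NA
#' column per accession.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotype_tsv <- function(gm, path) {
  df <- cbind(gm$loci, as.data.frame(gm$calls))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix TSV (depths are not stored; filled with NA-aware 3)
#' @param path TSV written by [write_genotype_tsv()].
#' @return a [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  loci <- df[, c("transcript", "position", "ref", "alt")]
  calls <- as.matrix(df[, -(1:4), drop = FALSE])
  mode(calls) <- "integer"
  depth <- matrix(ifelse(is.na(calls), 0L, 3L), nrow(calls), ncol(calls),
                  dimnames = dimnames(calls))
  genotype_matrix(loci, calls, depth)
}

stage_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

# Generic stage runner with manifest-based caching: recompute unless the
# manifest (parameter echo + upstream hashes) matches and a cached result
# exists.
run_stage <- function(name, cfg, inputs_hash, compute, report_env) {
  cache_dir <- file.path(cfg$out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(cache_dir, paste0(name, ".manifest.json"))
  cache_path <- file.path(cache_dir, paste0(name, ".rds"))
  want <- list(stage = name, params = cfg[[name]] %||% list(),
               inputs = inputs_hash, seed = cfg$seed)
  want_hash <- stage_hash(want)
  t0 <- proc.time()[3]
  cached <- FALSE
  if (isTRUE(cfg$resume) && file.exists(manifest_path) &&
      file.exists(cache_path)) {
    old <- tryCatch(jsonlite::read_json(manifest_path), error = function(e) NULL)
    if (!is.null(old) && identical(old$hash[[1]], want_hash)) {
      result <- readRDS(cache_path)
      cached <- TRUE
    }
  }
  if (!cached) {
    result <- tryCatch(compute(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    saveRDS(result, cache_path)
    jsonlite::write_json(list(hash = want_hash), manifest_path,
                         auto_unbox = TRUE)
  }
  elapsed <- proc.time()[3] - t0
  rpt <- report_env$report
  rpt[[length(rpt) + 1]] <- data.frame(
    stage = name, n_in = result$n_in %||% NA_integer_,
    n_out = result$n_out %||% NA_integer_, seconds = round(elapsed, 2),
    cached = cached, note = result$note %||% "", stringsAsFactors = FALSE)
  report_env$report <- rpt
  report_env$hashes[[name]] <- want_hash
  result
}

#' Run the pipeline end to end
#'
#' Executes, in dependency order: simulate (optional) -> trim -> polish ->
#' align -> callsnps -> snpset -> structure (delta-K, run alignment, Q-rule
#' assignment) -> fst -> tree -> pheno -> climate. Each stage's outputs are
#' the next stage's inputs; all artifacts are plain-text standard formats
#' under `cfg$out_dir`. A single master seed derives independent per-stage
#' substreams. With `resume = TRUE`, stages whose parameter/input manifest
#' is unchanged reuse cached outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return list(report = per-stage data.frame, results = named list of
#'   stage outputs).
#' @export
run_pipeline <- function(cfg) {
  assert_that(inherits(cfg, "pipeline_config"), "cfg must be a pipeline_config")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env()
  env$report <- list()
  env$hashes <- list()
  res <- list()
  on <- function(s) isTRUE(cfg$stages[[s]])
  hash_of <- function(...) env$hashes[c(...)]

  if (on("simulate")) {
    res$simulate <- run_stage("simulate", cfg, list(), function() {
      p <- cfg$simulate
      sim <- simulate_population(
        p$n_accessions, p$n_transcripts, p$transcript_length,
        lineage_tree = default_lineage_tree(p$lineage_rate),
        admixed_fraction = p$admixed_fraction, private_rate = p$private_rate,
        site_region = p$site_region, seed = derive_seed(cfg$seed, "pop"))
      write_fasta(sim$ancestor, file.path(cfg$out_dir, "ancestor.fa"))
      reads_dir <- file.path(cfg$out_dir, "reads")
      dir.create(reads_dir, showWarnings = FALSE)
      for (a in names(sim$sequences)) {
        rs <- simulate_reads(sim$sequences[[a]], depth = p$depth,
                             read_length = p$read_length,
                             error_rate = p$error_rate,
                             three_prime_bias = p$three_prime_bias,
                             accession = a,
                             seed = derive_seed(cfg$seed, paste0("reads-", a)))
        write_fastq(rs, file.path(reads_dir, paste0(a, ".fastq")))
      }
      labels <- sim$truth$lineage_labels
      lineages <- sort(unique(labels[!is.na(labels)]))
      seasons <- c("2017-2018", "2018-2019", "2019-2020")
      design <- expand.grid(accession = names(labels)[!is.na(labels)],
                            season = seasons, replicate = 1:3,
                            stringsAsFactors = FALSE)
      design$lineage <- labels[design$accession]
      lin_fx <- function(second, third) {
        b <- setNames(rep(0, length(lineages)), lineages)
        if (length(lineages) >= 2) b[2] <- second
        if (length(lineages) >= 3) b[3] <- third
        b
      }
      traits <- list(
        list(name = cfg$pheno$trait, beta0 = 150,
             b1 = lin_fx(p$flowering_contrast, p$flowering_contrast / 2),
             b2 = c(0, 4, -3), sg = 2, se = 2, miss = 0),
        list(name = "days_to_heading", beta0 = 145,
             b1 = lin_fx(p$flowering_contrast * 0.9,
                         p$flowering_contrast * 0.45),
             b2 = c(0, 4, -3), sg = 2, se = 2, miss = 0.02),
        list(name = "spike_length", beta0 = 40, b1 = lin_fx(-5, 2),
             b2 = c(0, 1, -1), sg = 1.5, se = 1.5, miss = 0.05),
        list(name = "plant_height", beta0 = 60, b1 = lin_fx(3, -4),
             b2 = c(0, 2, 1), sg = 3, se = 2, miss = 0.05),
        list(name = "awn_length", beta0 = 25, b1 = lin_fx(2, 4),
             b2 = c(0, -1, 1), sg = 1, se = 1, miss = 0.05),
        list(name = "culm_diameter", beta0 = 3, b1 = lin_fx(0.4, -0.2),
             b2 = c(0, 0.1, -0.1), sg = 0.2, se = 0.2, miss = 0.05))
      phen <- rbind_all(lapply(traits, function(tr) {
        spec <- glmm_spec(beta0 = tr$beta0, beta1 = tr$b1,
                          beta2 = setNames(tr$b2, seasons),
                          sigma_gamma = tr$sg, sigma_eps = tr$se)
        simulate_phenotypes(spec, design, trait = tr$name,
                            missing_rate = tr$miss,
                            seed = derive_seed(cfg$seed,
                                               paste0("pheno-", tr$name)))
      }))
      write.table(phen, file.path(cfg$out_dir, "phenotypes.csv"),
                  sep = ",", quote = FALSE, row.names = FALSE)
      lat <- setNames(as.list(seq_along(lineages)), lineages)
      lat <- lapply(seq_along(lineages), function(i) c(33 + 3 * (i - 1),
                                                       36 + 3 * (i - 1)))
      names(lat) <- lineages
      geo <- simulate_geoclimate(labels, lat, gradients = cfg$climate$gradients,
                                 noise_sd = cfg$climate$noise_sd,
                                 seed = derive_seed(cfg$seed, "geo"))
      write.table(geo, file.path(cfg$out_dir, "geoclimate.csv"),
                  sep = ",", quote = FALSE, row.names = FALSE)
      write.table(sim$truth$divergent_sites,
                  file.path(cfg$out_dir, "truth_sites.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      list(sim = sim, phenotypes = phen, geo = geo,
           n_in = p$n_transcripts, n_out = p$n_accessions,
           note = sprintf("%d lineages", length(lineages)))
    }, env)
  }
  downstream <- setdiff(names(cfg$stages), "simulate")
  if (!any(unlist(cfg$stages[downstream]))) {
    report <- if (length(env$report)) do.call(rbind, env$report) else
      data.frame(stage = character(), n_in = integer(), n_out = integer(),
                 seconds = numeric(), cached = logical(), note = character())
    write.table(report, file.path(cfg$out_dir, "run_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    return(list(report = report, results = res))
  }
  sim <- res$simulate$sim
  assert_that(!is.null(sim), "pipeline currently requires the simulate stage")
  accs <- names(sim$sequences)

  if (on("trim")) {
    res$trim <- run_stage("trim", cfg, hash_of("simulate"), function() {
      pol <- trim_policy(cfg$trim$window, cfg$trim$mean_quality_threshold,
                         cfg$trim$min_length)
      dir.create(file.path(cfg$out_dir, "trimmed"), showWarnings = FALSE)
      n_in <- 0L; n_out <- 0L
      reads <- list()
      for (a in accs) {
        rs <- parse_fastq(file.path(cfg$out_dir, "reads", paste0(a, ".fastq")))
        n_in <- n_in + length(rs)
        tr <- trim_reads(rs, pol)
        n_out <- n_out + length(tr)
        write_fastq(tr, file.path(cfg$out_dir, "trimmed", paste0(a, ".fastq")))
        reads[[a]] <- tr
      }
      list(reads = reads, n_in = n_in, n_out = n_out)
    }, env)
  }
  reads <- res$trim$reads

  if (on("polish")) {
    res$polish <- run_stage("polish", cfg, hash_of("trim"), function() {
      pr <- polish_reference(reads[[1]], sim$ancestor,
                             max_iterations = cfg$polish$max_iterations,
                             stop_tolerance = cfg$polish$stop_tolerance,
                             k = cfg$align$k,
                             max_mismatch_frac = cfg$align$max_mismatch_frac)
      write_fasta(pr$reference, file.path(cfg$out_dir, "polished.fa"))
      traj <- data.frame(iteration = seq_along(pr$trajectory$counts),
                         snp_count = pr$trajectory$counts)
      write.table(traj, file.path(cfg$out_dir, "polish_trajectory.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      for (i in seq_along(pr$calls_per_iteration))
        write_vcf(pr$calls_per_iteration[[i]],
                  file.path(cfg$out_dir, sprintf("polish_iter%02d.vcf", i)))
      list(reference = pr$reference, trajectory = pr$trajectory,
           n_in = length(reads[[1]]), n_out = length(pr$trajectory$counts),
           note = sprintf("converged_at=%s", pr$trajectory$converged_at))
    }, env)
  }
  reference <- res$polish$reference %||% sim$ancestor

  if (on("align")) {
    res$align <- run_stage("align", cfg, hash_of("trim", "polish"), function() {
      placements <- list(); pileups <- list()
      n_in <- 0L; n_out <- 0L
      for (a in accs) {
        pl <- align_reads(reads[[a]], reference, k = cfg$align$k,
                          max_mismatch_frac = cfg$align$max_mismatch_frac)
        placements[[a]] <- pl
        pileups[[a]] <- build_pileup(pl, reads[[a]], reference)
        n_in <- n_in + length(reads[[a]]); n_out <- n_out + nrow(pl)
      }
      list(placements = placements, pileups = pileups,
           n_in = n_in, n_out = n_out)
    }, env)
  }
  pileups <- res$align$pileups

  if (on("callsnps")) {
    res$callsnps <- run_stage("callsnps", cfg, hash_of("align"), function() {
      regime <- call_regime("population")
      calls <- lapply(pileups, call_snps, reference = reference,
                      regime = regime)
      dir.create(file.path(cfg$out_dir, "vcf"), showWarnings = FALSE)
      for (a in accs)
        write_vcf(calls[[a]], file.path(cfg$out_dir, "vcf", paste0(a, ".vcf")))
      list(calls = calls, n_in = length(accs),
           n_out = sum(vapply(calls, nrow, integer(1))))
    }, env)
  }

  if (on("snpset")) {
    res$snpset <- run_stage("snpset", cfg, hash_of("callsnps"), function() {
      gm <- build_genotype_matrix(res$callsnps$calls, pileups, reference)
      gmf <- filter_covered_set(gm, cfg$snpset$coverage_quantile,
                                cfg$snpset$min_reads)
      write_genotype_tsv(gmf, file.path(cfg$out_dir, "genotypes.tsv"))
      write_vcf(gmf, file.path(cfg$out_dir, "genotypes.vcf"))
      list(gm = gmf, n_in = nrow(gm$calls), n_out = nrow(gmf$calls))
    }, env)
  }
  gm <- res$snpset$gm

  if (on("structure")) {
    res$structure <- run_stage("structure", cfg, hash_of("snpset"), function() {
      p <- cfg$structure
      runsets <- structure_runs(gm, K_range = p$K_range, n_runs = p$n_runs,
                                n_sweeps = p$n_sweeps, burnin = p$burnin,
                                alpha = p$alpha,
                                seed = derive_seed(cfg$seed, "structure"))
      dk <- evanno_delta_k(runsets)
      write.table(dk, file.path(cfg$out_dir, "evanno.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      best_K <- if (all(is.na(dk$delta_K))) max(dk$K) else
        dk$K[which.max(dk$delta_K)]
      cons <- align_runs(runsets[[as.character(best_K)]]$runs)
      qdf <- data.frame(accession = rownames(cons$memberships),
                        cons$memberships)
      write.table(qdf, file.path(cfg$out_dir, "qmatrix.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      assign <- assign_lineages(cons, threshold = p$q_threshold)
      adf <- data.frame(accession = names(assign$cluster),
                        cluster = unname(assign$cluster))
      write.table(adf, file.path(cfg$out_dir, "assignment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      list(runsets = runsets, delta_k = dk, best_K = best_K,
           consensus = cons, assignment = assign,
           n_in = nrow(gm$calls), n_out = sum(!is.na(assign$assignment)),
           note = sprintf("best_K=%d", best_K))
    }, env)
  }

  if (on("fst")) {
    res$fst <- run_stage("fst", cfg, hash_of("snpset", "structure"), function() {
      fst <- fst_weir_cockerham(gm, res$structure$assignment)
      write.table(fst, file.path(cfg$out_dir, "fst.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      list(fst = fst, n_in = nrow(gm$calls), n_out = nrow(fst))
    }, env)
  }

  if (on("tree")) {
    res$tree <- run_stage("tree", cfg, hash_of("snpset"), function() {
      tr <- bootstrap_support(gm, n_replicates = cfg$tree$n_bootstrap,
                              seed = derive_seed(cfg$seed, "tree"),
                              dedupe = cfg$tree$dedupe)
      ape::write.tree(tr, file.path(cfg$out_dir, "tree.nwk"))
      list(tree = tr, n_in = nrow(gm$calls), n_out = length(tr$tip.label),
           note = attr(tr, "method"))
    }, env)
  }

  if (on("pheno")) {
    res$pheno <- run_stage("pheno", cfg, hash_of("simulate", "structure"),
                           function() {
      p <- cfg$pheno
      phen <- res$simulate$phenotypes
      m <- pheno_matrix(phen, rows = "accession_season")
      sc <- scale_uv(m)
      comp <- bpca_impute(sc, n_components = min(p$n_components,
                                                 min(dim(sc)) - 1L),
                          n_steps = p$bpca_steps)
      pca <- run_pca(comp)
      write.table(data.frame(sample = rownames(pca$scores), pca$scores),
                  file.path(cfg$out_dir, "pheno_pca_scores.csv"), sep = ",",
                  quote = FALSE, row.names = FALSE)
      dat <- phen[phen$trait == p$trait, ]
      labels <- sim$truth$lineage_labels
      dat$lineage <- labels[dat$accession]
      dat <- dat[!is.na(dat$lineage), ]
      fit <- fit_glmm(dat, chains = p$chains, iterations = p$iterations,
                      burnin = p$burnin,
                      seed = derive_seed(cfg$seed, "glmm"))
      write.table(fit$summary, file.path(cfg$out_dir, "glmm_summary.csv"),
                  sep = ",", quote = FALSE, row.names = FALSE)
      # accession x season matrix for the flowering dendrogram
      flm <- tapply(dat$value, list(dat$accession, dat$season), mean)
      dnd <- flowering_dendrogram(flm)
      ape::write.tree(ape::as.phylo(dnd),
                      file.path(cfg$out_dir, "flowering_dendrogram.nwk"))
      list(pca = pca, glmm = fit, dendrogram = dnd,
           n_in = nrow(phen), n_out = fit$draws_retained,
           note = if (fit$converged) "converged" else "NOT converged")
    }, env)
  }

  if (on("climate")) {
    res$climate <- run_stage("climate", cfg, hash_of("simulate", "pheno"),
                             function() {
      geo <- res$simulate$geo
      seas <- seasonal_means(geo)
      pca <- climate_pca(seas, elevation = geo$elev)
      ct <- cline_test(geo$lat, seas$srad_1, "latitude", "srad_1")
      if (!is.null(res$pheno)) {
        sc2 <- res$pheno$pca$scores[, min(2, ncol(res$pheno$pca$scores))]
        acc_of_row <- sub("\\|.*$", "", rownames(res$pheno$pca$scores))
        lat <- geo$lat[match(acc_of_row, geo$accession)]
        ct <- rbind(ct, cline_test(lat, sc2, "latitude", "pheno_PC2"))
      }
      write.table(ct, file.path(cfg$out_dir, "cline_tests.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      list(seasonal = seas, pca = pca, clines = ct,
           n_in = nrow(geo), n_out = nrow(ct))
    }, env)
  }

  report <- if (length(env$report))
    do.call(rbind, env$report) else
    data.frame(stage = character(), n_in = integer(), n_out = integer(),
               seconds = numeric(), cached = logical(), note = character())
  rownames(report) <- NULL
  write.table(report, file.path(cfg$out_dir, "run_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(report = report, results = res)
}

#' Emit the bundled smoke-test fixture configuration
#'
#' 12 accessions in 3 lineages over 200 transcripts, with phenotypes and
#' geo-climate tables; end-to-end the pipeline should recover all 12 truth
#' labels.
#'
#' @param out_dir artifact directory.
#' @param seed master seed.
#' @return a [pipeline_config()].
#' @export
pipeline_fixture <- function(out_dir, seed = 1L) {
  pipeline_config(out_dir, seed = seed)
}
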