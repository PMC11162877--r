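#' Default demonstration pipeline configuration
#'
#' A small but complete configuration exercising every stage: a
#' four-population tree plus outgroup, ascertained SNPs, two ancient
#' pseudo-haploid samples drawn from one population, planted ROH, sexed
#' coverage profiles and insertion read sets.
#'
#' @param seed master integer seed; per-stage seeds are derived from it
#'   during validation and can be overridden individually.
#' @return A named list accepted by [validate_pipeline_config()].
#' @export
demo_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    simulation = list(
      tree = list(
        edges = data.frame(
          parent = c("root", "root", "anc1", "anc1", "anc2", "anc2"),
          child = c("Outgroup", "anc1", "PopA", "anc2", "PopB", "PopC"),
          f = c(0.2, 0.05, 0.05, 0.02, 0.05, 0.05)),
        outgroup = "Outgroup"),
      n_snps = 4000,
      n_per_pop = list(Outgroup = 4, PopA = 10, PopB = 10, PopC = 10),
      chrom_lengths = list("1" = 60e6, "2" = 50e6, "3" = 40e6, X = 30e6),
      ancient = list(source_pop = "PopA", n_ind = 3, mean_depth = 2,
                     damage_rate = 0.05, error_rate = 0.001,
                     missing_rate = 0.05),
      roh = list(individual = "PopA_001",
                 segments = data.frame(chrom = "1", start = 10e6,
                                       end = 14e6)),
      sexes = c(sample1 = "female", sample2 = "male"),
      insertion_carriers = c(sample1 = TRUE, sample2 = FALSE),
      n_insertion_reads = 30),
    filters = list(max_missing = 0.05, min_maf = 0.05,
                   transversions_only = TRUE),
    analyses = c("f3", "mismatch", "pca", "roh", "continuity",
                 "sexdet", "insgeno"),
    block_size = 10e6,
    pca = list(k = 2))
}

pipeline_known_keys <- c("seed", "seeds", "simulation", "filters",
                         "analyses", "block_size", "pca", "out_dir")

#' Validate and normalize a pipeline configuration
#'
#' Rejects unknown keys, injects documented defaults, derives explicit
#' per-stage seeds from the master seed where not given, and returns the
#' normalized configuration; errors are aggregated into one message.
#'
#' @param config named list, or path to a YAML file holding one.
#' @return The normalized configuration list.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  errors <- character(0)
  unknown <- setdiff(names(config), pipeline_known_keys)
  if (length(unknown))
    errors <- c(errors, paste("unknown config keys:",
                              paste(unknown, collapse = ", ")))
  if (is.null(config$seed))
    errors <- c(errors, "missing master seed (stage: all)")
  if (is.null(config$simulation))
    errors <- c(errors, "missing simulation section")
  f <- config$filters
  if (!is.null(f$min_maf) && f$min_maf < 0)
    errors <- c(errors, "negative min_maf")
  if (!is.null(f$max_missing) && (f$max_missing < 0 || f$max_missing > 1))
    errors <- c(errors, "max_missing must be in [0, 1]")
  if (length(errors))
    stop(paste(errors, collapse = "\n"))
  base <- as.integer(config$seed)
  stage_names <- c("frequencies", "diploids", "roh_plant", "pileup",
                   "haploidize", "mismatch", "coverage", "insertion")
  seeds <- stats::setNames(as.list((base * 131L + seq_along(stage_names)) %%
                                     .Machine$integer.max), stage_names)
  for (nm in names(config$seeds %||% list())) seeds[[nm]] <- config$seeds[[nm]]
  config$seeds <- seeds
  if (is.null(config$filters))
    config$filters <- list(max_missing = 0.01, min_maf = 0.01,
                           transversions_only = TRUE)
  config$filters$max_missing <- config$filters$max_missing %||% 0.01
  config$filters$min_maf <- config$filters$min_maf %||% 0.01
  config$filters$transversions_only <-
    config$filters$transversions_only %||% TRUE
  config$block_size <- config$block_size %||% 5e6
  config$analyses <- config$analyses %||% character(0)
  config$pca <- config$pca %||% list(k = 2)
  if (is.data.frame(config$simulation$tree$edges) ||
      is.list(config$simulation$tree$edges))
    config$simulation$tree$edges <-
      as.data.frame(config$simulation$tree$edges)
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_log <- function(con, event, ...) {
  rec <- c(list(event = event), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 10), con)
}

#' Run the full synthetic-study pipeline
#'
#' Executes simulation, genotyping and every toggled analysis in order,
#' writing per-stage TSV/JSON outputs, a combined JSON report and a
#' JSON-lines log that records seeds and the site count after each filter
#' stage. Identical configurations (including seeds) produce
#' byte-identical output bundles.
#'
#' @param config configuration list or YAML path (validated with
#'   [validate_pipeline_config()]).
#' @param out_dir output directory (created if needed; default: the
#'   config's `out_dir`, else a fresh temporary directory).
#' @return Invisibly, the report list (also written to `report.json`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- validate_pipeline_config(config)
  out_dir <- out_dir %||% config$out_dir %||%
    file.path(tempfile("adnakit_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "pipeline.log.jsonl"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  report <- list(seeds = config$seeds)
  sim <- config$simulation
  pipeline_log(log_con, "start", seeds = config$seeds)

  tree <- population_tree(sim$tree$edges, sim$tree$outgroup,
                          admixture = sim$tree$admixture)
  freqs <- simulate_frequencies(tree, sim$n_snps,
                                seed = config$seeds$frequencies)
  chrom_lengths <- unlist(sim$chrom_lengths %||% default_chrom_lengths())
  panel <- sample_diploids(freqs, unlist(sim$n_per_pop),
                           seed = config$seeds$diploids,
                           chrom_lengths = chrom_lengths)
  report$truth <- list(n_snps_ascertained = nrow(freqs),
                       populations = tree$leaves, outgroup = tree$outgroup)
  pipeline_log(log_con, "simulated", n_sites = nrow(freqs),
               n_individuals = nrow(panel$geno))

  truth_roh <- NULL
  if ("roh" %in% config$analyses && !is.null(sim$roh)) {
    segs <- as.data.frame(sim$roh$segments)
    segs$individual <- sim$roh$individual
    planted <- plant_roh(panel, segs, freqs,
                         seed = config$seeds$roh_plant)
    panel <- planted$panel
    truth_roh <- planted$segments
    report$truth$roh_segments <- truth_roh
  }

  # ancient samples: extra diploids from the source population, read
  # pileup, random-read pseudo-haploid calls
  src <- sim$ancient$source_pop
  anc_dip <- sample_diploids(
    freqs, stats::setNames(sim$ancient$n_ind, src),
    seed = config$seeds$diploids + 1L, chrom_lengths = chrom_lengths)
  anc_dip$variants <- panel$variants  # same coordinate system and alleles
  anc_dip$individuals$id <- sprintf("ancient_%02d",
                                    seq_len(sim$ancient$n_ind))
  anc_dip$individuals$population <- "Ancient"
  rownames(anc_dip$geno) <- anc_dip$individuals$id
  spec <- ancient_spec(sim$ancient$mean_depth, sim$ancient$damage_rate,
                       sim$ancient$error_rate, sim$ancient$missing_rate)
  pileup <- simulate_ancient_pileup(anc_dip, spec,
                                    seed = config$seeds$pileup)
  write_pileup_tsv(pileup, file.path(out_dir, "ancient_pileup.tsv"))
  ancient <- pseudo_haploidize_pileup(pileup, panel$variants,
                                      seed = config$seeds$haploidize)
  ancient$individuals$population <- "Ancient"

  # site filtering on the modern panel; transversion masking applies to
  # modern and ancient alike
  n0 <- ncol(panel$geno)
  keep <- rep(TRUE, n0)
  if (isTRUE(config$filters$transversions_only))
    keep <- keep & !mask_transitions(panel$variants)
  panel_f <- subset_panel(panel, sites = keep)
  panel_f <- filter_sites(panel_f, config$filters$max_missing,
                          config$filters$min_maf)
  site_key <- paste(panel_f$variants$chrom, panel_f$variants$pos)
  anc_idx <- match(site_key, paste(ancient$variants$chrom,
                                   ancient$variants$pos))
  ancient_f <- subset_panel(ancient, sites = anc_idx)
  pipeline_log(log_con, "filtered", n_sites_before = n0,
               n_sites_after_transversions = sum(keep),
               n_sites_after_filters = ncol(panel_f$geno))
  report$site_counts <- list(simulated = n0, transversions = sum(keep),
                             filtered = ncol(panel_f$geno))
  write_eigenstrat(panel_f, file.path(out_dir, "modern_panel"))

  blocks <- make_blocks(panel_f$variants, config$block_size)
  gf_mod <- group_allele_freqs(panel_f)
  gf_anc <- group_allele_freqs(ancient_f)
  gf <- list(freq = cbind(gf_mod$freq, gf_anc$freq),
             n_obs = cbind(gf_mod$n_obs, gf_anc$n_obs))

  if ("f3" %in% config$analyses) {
    pops <- setdiff(unique(panel_f$individuals$population), tree$outgroup)
    f3s <- lapply(pops, function(p)
      as.data.frame(f3_outgroup(gf, tree$outgroup, "Ancient", p, blocks)))
    f3s <- do.call(rbind, f3s)
    utils::write.table(f3s, file.path(out_dir, "f3.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$f3 <- f3s
    pipeline_log(log_con, "f3", n_stats = nrow(f3s))
  }

  if ("mismatch" %in% config$analyses) {
    pops <- setdiff(unique(panel_f$individuals$population), tree$outgroup)
    mm <- lapply(pops, function(p)
      as.data.frame(pairwise_mismatch(
        panel_f, p, blocks, transversions_only = FALSE,
        seed = config$seeds$mismatch)))
    mm <- do.call(rbind, mm)
    utils::write.table(mm, file.path(out_dir, "mismatch.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$mismatch <- mm
    pipeline_log(log_con, "mismatch", n_groups = nrow(mm))
  }

  if ("pca" %in% config$analyses) {
    mod_only <- subset_panel(
      panel_f, inds = panel_f$individuals$population != tree$outgroup)
    # the outgroup is excluded, so re-drop sites monomorphic among moderns
    poly <- site_summary(mod_only)$maf > 0
    poly[is.na(poly)] <- FALSE
    mod_only <- subset_panel(mod_only, sites = poly)
    model <- fit_pca(mod_only, k = config$pca$k)
    proj <- project_lsq(ancient_f$geno[, poly, drop = FALSE], model,
                        ploidy = "haploid")
    fit_scores <- model$scores
    colnames(fit_scores) <- paste0("PC", seq_len(config$pca$k))
    scores <- rbind(
      data.frame(id = model$individuals$id,
                 population = model$individuals$population,
                 fit_scores, check.names = FALSE),
      data.frame(id = ancient_f$individuals$id, population = "Ancient",
                 proj, check.names = FALSE))
    utils::write.table(scores, file.path(out_dir, "pca_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$pca <- list(pct_variance = model$pct_variance)
    pipeline_log(log_con, "pca",
                 pct_variance = round(model$pct_variance, 4))
  }

  if ("roh" %in% config$analyses && !is.null(truth_roh)) {
    segs <- call_roh(panel, sim$roh$individual, roh_params())
    utils::write.table(segs, file.path(out_dir, "roh_segments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$roh <- summarize_roh(segs, sum(chrom_lengths))
    pipeline_log(log_con, "roh", n_segments = nrow(segs))
  }

  if ("continuity" %in% config$analyses) {
    og_row <- which(panel_f$individuals$population == tree$outgroup)[1]
    og <- panel_f$geno[og_row, ]
    v <- panel_f$variants
    calls <- data.frame(
      chrom = v$chrom, pos = v$pos,
      allele_a = ifelse(og == 2L, v$allele1, v$allele0),
      allele_b = ifelse(og == 0L, v$allele0, v$allele1),
      stringsAsFactors = FALSE)[!is.na(og), ]
    v_pol <- polarize_by_outgroup(v, calls)
    modern_src <- subset_panel(
      panel_f, inds = panel_f$individuals$population == src)
    cd <- build_continuity_input(modern_src, ancient_f, v_pol)
    fit <- suppressWarnings(fit_continuity(cd))
    report$continuity <- list(t1 = fit$alt$t1, t2 = fit$alt$t2,
                              loglik_null = fit$null$loglik,
                              loglik_alt = fit$alt$loglik,
                              lrt = fit$lrt, p = fit$p,
                              n_sites = fit$n_sites)
    pipeline_log(log_con, "continuity", lrt = fit$lrt, p = fit$p)
  }

  if ("sexdet" %in% config$analyses && length(sim$sexes)) {
    sx <- lapply(seq_along(sim$sexes), function(i) {
      prof <- simulate_coverage_profile(
        sim$sexes[[i]], autosomal_depth = 1,
        chrom_lengths = chrom_lengths,
        seed = config$seeds$coverage + i)
      res <- sex_from_coverage(prof)
      data.frame(individual = names(sim$sexes)[i],
                 true_sex = sim$sexes[[i]], ratio = res$ratio,
                 call = res$call, stringsAsFactors = FALSE)
    })
    sx <- do.call(rbind, sx)
    utils::write.table(sx, file.path(out_dir, "sex_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$sexdet <- sx
    pipeline_log(log_con, "sexdet", n_calls = nrow(sx))
  }

  if ("insgeno" %in% config$analyses && length(sim$insertion_carriers)) {
    ig <- lapply(seq_along(sim$insertion_carriers), function(i) {
      reads <- simulate_insertion_reads(
        sim$insertion_carriers[[i]], n_reads = sim$n_insertion_reads,
        seed = config$seeds$insertion + i)
      res <- genotype_insertion(reads)
      data.frame(individual = names(sim$insertion_carriers)[i],
                 true_carrier = sim$insertion_carriers[[i]],
                 support_present = res$support_present,
                 support_absent = res$support_absent, call = res$call,
                 stringsAsFactors = FALSE)
    })
    ig <- do.call(rbind, ig)
    utils::write.table(ig, file.path(out_dir, "insertion_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$insgeno <- ig
    pipeline_log(log_con, "insgeno", n_calls = nrow(ig))
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "rows")
  pipeline_log(log_con, "done")
  invisible(report)
}

#' Hash every file of a pipeline output bundle
#'
#' Convenience for determinism checks: MD5 of every regular file under the
#' output directory, keyed by relative path.
#'
#' @param out_dir a [run_pipeline()] output directory.
#' @return Named character vector of MD5 hashes.
#' @export
hash_bundle <- function(out_dir) {
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  h <- tools::md5sum(files)
  names(h) <- substring(files, nchar(out_dir) + 2)
  h
}
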