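#' Configuration for an end-to-end pipeline run
#'
#' Collects every tunable parameter of the pipeline with its default. All
#' randomness flows from `seed` (stage seeds are derived by fixed offsets);
#' a fixed seed makes [run_pipeline()] fully reproducible. The default
#' problem size (four chromosomes x 5000 probes, 130 sibships of 2-3)
#' keeps a complete run at desk scale.
#'
#' @param seed master integer seed.
#' @param cohort a [cohort_config()].
#' @param landscape a [landscape_config()].
#' @param pheno a [pheno_config()].
#' @param thresholds named list of QC threshold overrides (see
#'   [qc_pipeline()]).
#' @param n_perms_state,n_perms_intensity permutation counts for the two
#'   association scans.
#' @param n_resamples one-per-sibship resampling draws for burden tests.
#' @param traits composite scores to scan ("PC1", "IQadjPC1").
#' @param burden_classes burden classes to compute.
#' @param jitter_sd,fp_rate call-emission noise (bp jitter SD; false calls
#'   per sample).
#' @param noise_sd LRR noise SD.
#' @param region_scheme_state,region_scheme_intensity numeric vectors
#'   (core_p, core_len, flank_p, flank_len).
#' @param candidates candidate region data.frame (`name`, `chrom`, `start`,
#'   `end`, `type`) or NULL to pick a few simulated genes.
#' @param gene_sets named list of gene sets or NULL to build random sets
#'   from the simulated gene models.
#' @param genome_build label carried into output headers.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            cohort = cohort_config(n_families = 130,
                                                   n_probes_per_chrom = 5000,
                                                   seed = seed),
                            landscape = landscape_config(),
                            pheno = pheno_config(),
                            thresholds = list(),
                            n_perms_state = 1999,
                            n_perms_intensity = 1999,
                            n_resamples = 100,
                            traits = c("PC1", "IQadjPC1"),
                            burden_classes = c("all", "gene", "exon", "rare",
                                               "short", "medium", "large"),
                            jitter_sd = 0, fp_rate = 0.5, noise_sd = 0.15,
                            region_scheme_state = c(0.005, 2, 0.05, 2),
                            region_scheme_intensity = c(0.001, 2, 0.05, 2),
                            candidates = NULL, gene_sets = NULL,
                            genome_build = "sim1") {
  structure(list(seed = as.integer(seed), cohort = cohort,
                 landscape = landscape, pheno = pheno,
                 thresholds = thresholds, n_perms_state = n_perms_state,
                 n_perms_intensity = n_perms_intensity,
                 n_resamples = n_resamples, traits = traits,
                 burden_classes = burden_classes, jitter_sd = jitter_sd,
                 fp_rate = fp_rate, noise_sd = noise_sd,
                 region_scheme_state = region_scheme_state,
                 region_scheme_intensity = region_scheme_intensity,
                 candidates = candidates, gene_sets = gene_sets,
                 genome_build = genome_build),
            class = "pipeline_config")
}

#' Run the complete CNV-trait analysis pipeline on synthetic data
#'
#' simulate -> phenotype -> QC -> burden -> CNV-state association ->
#' intensity association -> meta-analysis -> region detection ->
#' co-segregation -> enrichment, with per-stage record counts logged and,
#' when `out_dir` is given, every result table written as a TSV whose header
#' names the thresholds used.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed), or NULL to skip
#'   writing files.
#' @param verbose print per-stage progress (default FALSE).
#' @return list with all intermediate and final objects (`samples`,
#'   `genome`, `segments`, `calls`, `pheno`, `qc`, `burden`, `state`,
#'   `intensity`, `coseg`, `enrichment`, `summary`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_msg <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed

  # --- simulate -------------------------------------------------------
  cohort <- generate_cohort(config$cohort)
  samples <- cohort$samples
  genome <- generate_genome(config$cohort)
  probes <- genome$probes
  segments <- generate_cnv_landscape(samples, probes, config$landscape,
                                     seed = seed + 2L,
                                     reference_cnvs = genome$reference_cnvs)
  log_msg("simulate: %d samples, %d probes, %d true segments",
          nrow(samples), nrow(probes), nrow(segments))
  intens <- render_intensities(segments, samples, probes,
                               noise_sd = config$noise_sd, seed = seed + 3L)
  calls_raw <- emit_cnv_calls(segments, probes, jitter_sd = config$jitter_sd,
                              fp_rate = config$fp_rate, seed = seed + 4L)
  # carriers of the causal region = samples with any CNV overlapping it
  # (the CNV+ state the association model tests), not only planted segments
  carrier <- rep(FALSE, nrow(samples))
  if (any(segments$is_causal)) {
    civ <- segments[segments$is_causal, ][1, ]
    over <- segments$chrom == civ$chrom & segments$start <= civ$end &
      segments$end >= civ$start
    carrier <- samples$sample_id %in% segments$sample_id[over]
  }
  pheno_raw <- generate_phenotypes(samples, carrier, config$pheno,
                                   seed = seed + 5L)

  # --- phenotype ------------------------------------------------------
  pheno <- derive_phenotypes(pheno_raw, samples)
  log_msg("phenotype: %d cases, %d controls", sum(pheno$label == "case"),
          sum(pheno$label == "control"))

  # --- QC -------------------------------------------------------------
  lrr_sd <- apply(intens$lrr, 1, stats::sd)
  qc <- qc_pipeline(calls_raw, genome, lrr_sd, config$thresholds)
  kept <- samples$sample_id %in% qc$samples_kept
  samples_kept <- samples[kept, , drop = FALSE]
  log_msg("qc: %s", paste(names(qc$counts), qc$counts, sep = "=",
                          collapse = ", "))

  pheno_kept <- pheno[match(samples_kept$sample_id, pheno$sample_id), ]

  # cohorts with too few sibships cannot be resampled/permuted; skip them
  fam_counts <- tapply(samples_kept$family_id, samples_kept$cohort,
                       function(x) length(unique(x)))
  usable_cohorts <- names(fam_counts)[fam_counts >= 3]

  # --- burden ---------------------------------------------------------
  burden_rows <- list()
  for (cl in config$burden_classes) {
    b <- compute_burden(qc$calls, samples_kept$sample_id, cl)
    for (measure in c("n_events", "total_length_bp")) {
      for (tr in config$traits) {
        for (ch in usable_cohorts) {
          sel <- samples_kept$cohort == ch
          rc <- resampled_correlation(b[[measure]][sel],
                                      pheno_kept[[tr]][sel],
                                      samples_kept$family_id[sel],
                                      n_resamples = config$n_resamples,
                                      seed = seed + 10L)
          burden_rows[[length(burden_rows) + 1L]] <- data.frame(
            class = cl, measure = measure, trait = tr, cohort = ch,
            rho = rc$rho, p = rc$p, n = rc$n_per_draw,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  burden_tab <- do.call(rbind, burden_rows)
  b_all <- compute_burden(qc$calls, samples_kept$sample_id, "all")
  cc <- list(n_events = case_control_burden(b_all$n_events,
                                            pheno_kept$label,
                                            samples_kept$family_id,
                                            config$n_resamples,
                                            seed = seed + 11L),
             total_length_bp = case_control_burden(b_all$total_length_bp,
                                                   pheno_kept$label,
                                                   samples_kept$family_id,
                                                   config$n_resamples,
                                                   seed = seed + 12L))
  log_msg("burden: %d class/trait/cohort combinations", nrow(burden_tab))

  # --- CNV-state association -----------------------------------------
  state <- assign_probe_states(qc$calls, probes, samples_kept)
  autosomal_probes <- probes$probe_id[normalize_chrom(probes$chrom) != "X"]
  x_probes <- setdiff(probes$probe_id, autosomal_probes)
  sch <- config$region_scheme_state
  state_res <- list()
  x_res <- list()
  for (ch in usable_cohorts) {
    sel <- samples_kept$cohort == ch
    sub <- state[sel, , drop = FALSE]
    cov_auto <- intersect(restrict_to_covered(sub), autosomal_probes)
    for (tr in config$traits) {
      key <- paste(ch, tr, sep = ".")
      if (length(cov_auto) > 0) {
        state_res[[key]] <- state_association(
          sub, pheno_kept[[tr]][sel], samples_kept$family_id[sel],
          cov_auto, config$n_perms_state, seed + 20L)
      }
      xsub <- sub[, intersect(colnames(sub), x_probes), drop = FALSE]
      if (ncol(xsub) > 0 && sum(colSums(xsub) > 0) > 0) {
        x_res[[key]] <- x_association(xsub, pheno_kept[[tr]][sel],
                                      samples_kept$family_id[sel],
                                      samples_kept$sex[sel],
                                      config$n_perms_state, seed + 21L)
      }
    }
  }
  cohorts <- usable_cohorts
  state_meta <- list()
  state_regions <- list()
  for (tr in config$traits) {
    keys <- paste(cohorts, tr, sep = ".")
    if (length(cohorts) == 2 && all(keys %in% names(state_res))) {
      m <- meta_analyze(state_res[[keys[1]]], state_res[[keys[2]]],
                        n_perms = config$n_perms_state)
      state_meta[[tr]] <- m
      state_regions[[tr]] <- annotate_regions(
        detect_regions(m, probes, sch[1], sch[2], sch[3], sch[4],
                       p_col = "p_meta"),
        genome, state)
    }
  }
  log_msg("state: %d meta probes, %d region(s)",
          if (length(state_meta) > 0) nrow(state_meta[[1]]) else 0L,
          sum(vapply(state_regions, nrow, integer(1))))

  # --- intensity association -----------------------------------------
  lrr_kept <- intens$lrr[kept, , drop = FALSE]
  pca <- lrr_pca(lrr_kept, K = min(100L, nrow(lrr_kept) - 1L))
  outlier <- flag_lrr_outliers(pca)
  ok_samples <- !outlier
  isch <- config$region_scheme_intensity
  intensity_res <- list()
  for (ch in cohorts) {
    sel <- samples_kept$cohort == ch & ok_samples
    for (tr in config$traits) {
      key <- paste(ch, tr, sep = ".")
      intensity_res[[key]] <- intensity_association(
        lrr_kept[sel, autosomal_probes, drop = FALSE],
        pheno_kept[[tr]][sel], pca$scores[sel, 1:2, drop = FALSE],
        samples_kept$family_id[sel], autosomal_probes,
        config$n_perms_intensity, seed + 30L)
    }
  }
  intensity_meta <- list()
  intensity_regions <- list()
  intensity_cohort_regions <- list()
  for (tr in config$traits) {
    keys <- paste(cohorts, tr, sep = ".")
    if (length(cohorts) == 2 && all(keys %in% names(intensity_res))) {
      m <- meta_analyze(intensity_res[[keys[1]]], intensity_res[[keys[2]]],
                        n_perms = config$n_perms_intensity)
      intensity_meta[[tr]] <- m
      intensity_regions[[tr]] <- annotate_regions(
        detect_regions(m, probes, isch[1], isch[2], isch[3], isch[4],
                       p_col = "p_meta"),
        genome, state)
    }
    for (ch in cohorts) {    # cohort-level regions are reported as well
      key <- paste(ch, tr, sep = ".")
      if (!is.null(intensity_res[[key]])) {
        intensity_cohort_regions[[key]] <- annotate_regions(
          detect_regions(intensity_res[[key]], probes, isch[1], isch[2],
                         isch[3], isch[4]),
          genome, state)
      }
    }
  }
  log_msg("intensity: %d outliers flagged, %d meta region(s)", sum(outlier),
          sum(vapply(intensity_regions, nrow, integer(1))))

  # --- co-segregation -------------------------------------------------
  candidates <- config$candidates
  if (is.null(candidates)) {
    set.seed(seed + 40L)
    pick <- sort(sample.int(nrow(genome$genes), min(5, nrow(genome$genes))))
    candidates <- data.frame(name = genome$genes$gene[pick],
                             chrom = genome$genes$chrom[pick],
                             start = genome$genes$start[pick],
                             end = genome$genes$end[pick],
                             type = "gene", stringsAsFactors = FALSE)
  }
  coseg <- list(
    large = find_large_case_cnvs(qc$calls, pheno_kept, samples_kept),
    shared = find_shared_case_cnvs(qc$calls, pheno_kept, samples_kept),
    candidates = candidate_overlap(qc$calls, candidates, pheno_kept,
                                   samples_kept))
  log_msg("coseg: %d large, %d shared, %d candidate rows",
          nrow(coseg$large), nrow(coseg$shared), nrow(coseg$candidates))

  # --- enrichment -----------------------------------------------------
  gene_sets <- config$gene_sets
  if (is.null(gene_sets)) {
    set.seed(seed + 41L)
    gene_sets <- lapply(seq_len(10), function(i) {
      sample(genome$genes$gene, 15)
    })
    names(gene_sets) <- sprintf("SET%02d", seq_along(gene_sets))
  }
  case_ids <- pheno_kept$sample_id[pheno_kept$label == "case"]
  case_calls <- qc$calls[qc$calls$sample_id %in% case_ids, , drop = FALSE]
  covered <- restrict_to_covered(state)
  if (nrow(case_calls) > 0 && length(covered) > 0) {
    cov_probes <- probes[probes$probe_id %in% covered, , drop = FALSE]
    has_probe <- vapply(seq_len(nrow(case_calls)), function(i) {
      length(probes_in_interval(cov_probes, case_calls$chrom[i],
                                case_calls$start[i],
                                case_calls$end[i])) > 0
    }, logical(1))
    case_calls <- case_calls[has_probe, , drop = FALSE]
  }
  enrichment <- NULL
  if (nrow(case_calls) > 0 && length(covered) > 0) {
    enrichment <- target_enrichment(
      case_calls[, c("sample_id", "chrom", "start", "end")], gene_sets,
      genome$genes, probes, covered, n_perms = 999, seed = seed + 42L)
  }

  # --- summary & output ----------------------------------------------
  summary_tab <- data.frame(
    stage = c("samples", "probes", "true_segments", "raw_calls", "qc_calls",
              "samples_kept", "covered_probes", "meta_probes",
              "state_regions", "intensity_regions", "lrr_outliers"),
    count = c(nrow(samples), nrow(probes), nrow(segments), nrow(calls_raw),
              nrow(qc$calls), nrow(samples_kept), length(covered),
              if (length(state_meta) > 0) nrow(state_meta[[1]]) else 0L,
              sum(vapply(state_regions, nrow, integer(1))),
              sum(vapply(intensity_regions, nrow, integer(1))),
              sum(outlier)),
    stringsAsFactors = FALSE)

  result <- list(config = config, samples = samples,
                 samples_kept = samples_kept, genome = genome,
                 segments = segments, calls_raw = calls_raw, pheno = pheno,
                 pheno_kept = pheno_kept, qc = qc,
                 burden = list(table = burden_tab, case_control = cc),
                 state = list(results = state_res, x = x_res,
                              meta = state_meta, regions = state_regions,
                              matrix = state),
                 intensity = list(results = intensity_res,
                                  meta = intensity_meta,
                                  regions = intensity_regions,
                                  cohort_regions = intensity_cohort_regions,
                                  outliers = outlier, pca = pca),
                 coseg = coseg, enrichment = enrichment,
                 summary = summary_tab, lrr = intens$lrr)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# region annotation: genes overlapping the region interval and CNV+ frequency
annotate_regions <- function(regions, genome, state) {
  if (nrow(regions) == 0) {
    regions$genes <- character(0)
    regions$cnv_plus_pct <- numeric(0)
    return(regions)
  }
  ann <- annotate_genes(regions, genome$genes, NULL)
  regions$genes <- ann$genes
  regions$cnv_plus_pct <- vapply(seq_len(nrow(regions)), function(i) {
    ids <- strsplit(regions$probe_ids[i], ",")[[1]]
    cnv_plus_frequency(intersect(ids, colnames(state)), state)$percent
  }, numeric(1))
  regions$length_kb <- call_span_kb(regions$start, regions$end)
  regions
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- result$qc$thresholds
  cfg <- result$config
  audit <- c(th, list(seed = cfg$seed, n_perms_state = cfg$n_perms_state,
                      n_perms_intensity = cfg$n_perms_intensity,
                      n_resamples = cfg$n_resamples,
                      genome_build = cfg$genome_build))
  wp <- function(df, name) {
    write_tsv_audited(df, file.path(out_dir, name), audit)
  }
  utils::write.table(result$genome$probes, file.path(out_dir, "probes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_penncnv_calls(result$calls_raw, file.path(out_dir, "calls_raw.txt"))
  wp(result$qc$calls, "calls_qc.tsv")
  wp(result$pheno, "phenotypes.tsv")
  wp(result$samples, "pedigree.tsv")
  wp(result$burden$table, "burden.tsv")
  for (tr in names(result$state$meta)) {
    wp(result$state$meta[[tr]], sprintf("state_meta_%s.tsv", tr))
    wp(result$state$regions[[tr]], sprintf("state_regions_%s.tsv", tr))
  }
  for (tr in names(result$intensity$meta)) {
    wp(result$intensity$meta[[tr]], sprintf("intensity_meta_%s.tsv", tr))
    wp(result$intensity$regions[[tr]],
       sprintf("intensity_regions_%s.tsv", tr))
  }
  wp(result$coseg$large, "coseg_large.tsv")
  wp(result$coseg$shared, "coseg_shared.tsv")
  wp(result$coseg$candidates, "coseg_candidates.tsv")
  if (!is.null(result$enrichment)) wp(result$enrichment, "enrichment.tsv")
  wp(result$summary, "summary.tsv")
  invisible(out_dir)
}
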