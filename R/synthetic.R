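#' Configuration for a synthetic sibship cohort
#'
#' Defaults emulate a learning-disability twin/sibling study: 343 sibships
#' of 2-3 children (no parents genotyped), about 78% recruited through a
#' reading-disability proband ("RD" cohort) and the rest through an ADHD
#' proband ("ADHD" cohort), genotyped on a SNP array.
#'
#' @param n_families number of unrelated sibships.
#' @param sibship_size_range integer length-2 vector (min, max); sizes are
#'   drawn uniformly on that range.
#' @param cohort_split probability a family belongs to the "RD" cohort.
#' @param chromosomes chromosome labels; "X" receives sex-aware handling.
#' @param n_probes_per_chrom probes simulated per chromosome.
#' @param chrom_length length in bp of each simulated chromosome.
#' @param seed integer seed; fully determines all generator output.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_families = 343,
                          sibship_size_range = c(2, 3),
                          cohort_split = 0.78,
                          chromosomes = c("1", "2", "3", "X"),
                          n_probes_per_chrom = 2000,
                          chrom_length = 5e7,
                          seed = 1L) {
  if (n_families < 1) stop("n_families must be >= 1")
  if (length(sibship_size_range) != 2 ||
      sibship_size_range[1] > sibship_size_range[2] ||
      sibship_size_range[1] < 2) {
    stop("sibship_size_range must be (min, max) with min >= 2")
  }
  if (n_probes_per_chrom < 2) stop("need >= 2 probes per chromosome")
  structure(list(n_families = as.integer(n_families),
                 sibship_size_range = as.integer(sibship_size_range),
                 cohort_split = cohort_split,
                 chromosomes = normalize_chrom(chromosomes),
                 n_probes_per_chrom = as.integer(n_probes_per_chrom),
                 chrom_length = chrom_length,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate samples and families for a sibship cohort
#'
#' @param config a [cohort_config()].
#' @return list with `samples` (data.frame: `sample_id`, `family_id`, `sex`,
#'   `cohort`) and `families` (data.frame: `family_id`, `size`, `cohort`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  size_choices <- seq(config$sibship_size_range[1],
                      config$sibship_size_range[2])
  sizes <- if (length(size_choices) == 1) {
    rep(size_choices, config$n_families)
  } else {
    sample(size_choices, config$n_families, replace = TRUE)
  }
  cohorts <- ifelse(stats::runif(config$n_families) < config$cohort_split,
                    "RD", "ADHD")
  fam_ids <- sprintf("F%04d", seq_len(config$n_families))
  samples <- data.frame(
    sample_id = sprintf("%s_S%d", rep(fam_ids, sizes),
                        unlist(lapply(sizes, seq_len))),
    family_id = rep(fam_ids, sizes),
    sex = sample(c("M", "F"), sum(sizes), replace = TRUE),
    cohort = rep(cohorts, sizes),
    stringsAsFactors = FALSE)
  families <- data.frame(family_id = fam_ids, size = sizes, cohort = cohorts,
                         stringsAsFactors = FALSE)
  list(samples = samples, families = families)
}

#' Generate a synthetic genome: probes, gene models, exclusion and reference
#' CNV interval sets
#'
#' Probes are uniform over each chromosome (sorted, unique positions). Genes
#' carry exon sub-intervals within their spans. Exclusion regions mimic
#' centromeres/gaps. The reference CNV set stands in for a population CNV
#' database: loci each carry `count` independent reference events used by the
#' rarity classifier.
#'
#' @param config a [cohort_config()].
#' @param n_genes_per_chrom,n_ref_loci_per_chrom,n_exclusions_per_chrom
#'   counts per chromosome.
#' @return list with data.frames `probes` (`probe_id`, `chrom`, `pos`),
#'   `genes` (`gene`, `chrom`, `start`, `end`), `exons` (`gene`, `chrom`,
#'   `start`, `end`), `exclusion_regions`, and `reference_cnvs` (one row per
#'   reference event, with `locus` and `count` bookkeeping columns).
#' @export
generate_genome <- function(config, n_genes_per_chrom = 80,
                            n_ref_loci_per_chrom = 25,
                            n_exclusions_per_chrom = 2) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed + 1L)
  chroms <- config$chromosomes
  L <- config$chrom_length
  probes <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- sort(sample.int(L, config$n_probes_per_chrom))
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
  probes$probe_id <- sprintf("rs%s_%07d", probes$chrom,
                             seq_len(nrow(probes)))
  probes <- probes[, c("probe_id", "chrom", "pos")]

  genes <- do.call(rbind, lapply(chroms, function(ch) {
    start <- sort(sample.int(L - 300000L, n_genes_per_chrom))
    len <- sample(10000:250000, n_genes_per_chrom, replace = TRUE)
    data.frame(gene = sprintf("GENE%s_%02d", ch, seq_len(n_genes_per_chrom)),
               chrom = ch, start = start, end = start + len,
               stringsAsFactors = FALSE)
  }))
  exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    n_ex <- sample(2:8, 1)
    span <- g$end - g$start
    ex_start <- sort(g$start + sample.int(span - 500L, n_ex))
    ex_end <- pmin(ex_start + sample(100:2000, n_ex, replace = TRUE), g$end)
    data.frame(gene = g$gene, chrom = g$chrom, start = ex_start, end = ex_end,
               stringsAsFactors = FALSE)
  }))

  exclusion_regions <- do.call(rbind, lapply(chroms, function(ch) {
    start <- sample.int(L - 2e6, n_exclusions_per_chrom)
    data.frame(chrom = ch, start = start,
               end = start + sample(500000:2000000, n_exclusions_per_chrom,
                                    replace = TRUE),
               stringsAsFactors = FALSE)
  }))

  reference_cnvs <- do.call(rbind, lapply(chroms, function(ch) {
    start <- sample.int(L - 500000L, n_ref_loci_per_chrom)
    len <- sample(20000:250000, n_ref_loci_per_chrom, replace = TRUE)
    # mixture of common (>=5 events) and rare loci
    count <- ifelse(stats::runif(n_ref_loci_per_chrom) < 0.4,
                    sample(5:60, n_ref_loci_per_chrom, replace = TRUE),
                    sample(1:4, n_ref_loci_per_chrom, replace = TRUE))
    locus <- sprintf("REF%s_%02d", ch, seq_len(n_ref_loci_per_chrom))
    idx <- rep(seq_len(n_ref_loci_per_chrom), count)
    data.frame(chrom = ch, start = start[idx], end = (start + len)[idx],
               locus = locus[idx], count = count[idx],
               stringsAsFactors = FALSE)
  }))

  list(probes = probes, genes = genes, exons = exons,
       exclusion_regions = exclusion_regions,
       reference_cnvs = reference_cnvs)
}

#' Configuration of the simulated CNV landscape
#'
#' @param bg_rate mean number of background (non-causal) CNV events seeded
#'   per sample (Poisson).
#' @param bg_len_probes integer range of typical background event lengths in
#'   probes.
#' @param bg_long_frac fraction of background events drawn from the long
#'   tail (`bg_long_len_probes`), emulating the rare large CNVs of real
#'   cohorts.
#' @param bg_long_len_probes probe-length range of long-tail events.
#' @param bg_at_ref_frac fraction of background events placed at reference
#'   CNV loci (weighted by locus event count, so recurrent population
#'   polymorphisms are re-sampled more often — this is what makes the
#'   rarity classification informative on synthetic data). Requires
#'   `reference_cnvs` to be passed to [generate_cnv_landscape()].
#' @param bg_share_prob probability each sibling of a seeded carrier inherits
#'   a background event (enables co-segregation structure).
#' @param causal_region list(chrom, start, end) or NULL to auto-place a
#'   region spanning `causal_n_probes` probes mid-chromosome 1.
#' @param causal_n_probes probes spanned by the auto-placed causal region.
#' @param carrier_frac fraction of samples carrying the causal segment
#'   (independent Bernoulli per sample).
#' @param causal_share_prob probability a sibling of a causal carrier also
#'   carries it (0 keeps the marginal carrier fraction exact).
#' @param causal_cn copy number of the causal segment (default heterozygous
#'   deletion).
#' @return list of class `landscape_config`.
#' @export
landscape_config <- function(bg_rate = 6, bg_len_probes = c(10, 25),
                             bg_long_frac = 0.03,
                             bg_long_len_probes = c(40, 80),
                             bg_at_ref_frac = 0.5,
                             bg_share_prob = 0.25,
                             causal_region = NULL, causal_n_probes = 12,
                             carrier_frac = 0, causal_share_prob = 0,
                             causal_cn = 1L) {
  structure(list(bg_rate = bg_rate, bg_len_probes = as.integer(bg_len_probes),
                 bg_long_frac = bg_long_frac,
                 bg_long_len_probes = as.integer(bg_long_len_probes),
                 bg_at_ref_frac = bg_at_ref_frac,
                 bg_share_prob = bg_share_prob,
                 causal_region = causal_region,
                 causal_n_probes = as.integer(causal_n_probes),
                 carrier_frac = carrier_frac,
                 causal_share_prob = causal_share_prob,
                 causal_cn = as.integer(causal_cn)),
            class = "landscape_config")
}

# baseline copy number given chromosome and sex
baseline_cn <- function(chrom, sex) {
  ifelse(normalize_chrom(chrom) == "X" & sex == "M", 1L, 2L)
}

#' Generate ground-truth CNV segments for a cohort
#'
#' Background events are seeded per sample (Poisson rate), placed on probe
#' runs, and copied to siblings with probability `bg_share_prob`. A designated
#' causal region is carried by `carrier_frac` of samples. Copy numbers are
#' non-baseline by construction (deletions and duplications relative to the
#' sex-aware baseline).
#'
#' @param samples cohort samples data.frame.
#' @param probes probe manifest.
#' @param config a [landscape_config()].
#' @param seed integer seed.
#' @param reference_cnvs optional reference CNV event table (see
#'   [generate_genome()]); enables placement of recurrent background events
#'   at reference loci.
#' @return data.frame of segments: `sample_id`, `chrom`, `start`, `end`,
#'   `cn`, `is_causal`.
#' @export
generate_cnv_landscape <- function(samples, probes, config, seed = 1L,
                                   reference_cnvs = NULL) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(seed)
  n <- nrow(samples)
  probes <- probes[order(probes$chrom, probes$pos), ]
  by_chrom <- split(seq_len(nrow(probes)), probes$chrom)
  chrom_weights <- lengths(by_chrom) / nrow(probes)

  seg_rows <- list()
  add_seg <- function(sample_id, chrom, i0, i1, cn, causal = FALSE) {
    pos <- probes$pos[by_chrom[[chrom]]]
    list(sample_id = sample_id, chrom = chrom,
         start = pos[i0], end = pos[i1], cn = cn, is_causal = causal)
  }

  # unique reference loci (rows expanded per event; weight by count when
  # sampling so recurrent polymorphisms are re-drawn more often)
  ref_loci <- NULL
  if (!is.null(reference_cnvs) && nrow(reference_cnvs) > 0 &&
      config$bg_at_ref_frac > 0) {
    ref_loci <- reference_cnvs
  }

  # background events: seed per sample, share with sibs
  n_ev <- stats::rpois(n, config$bg_rate)
  fam_members <- split(samples$sample_id, samples$family_id)
  for (i in seq_len(n)) {
    if (n_ev[i] == 0) next
    for (k in seq_len(n_ev[i])) {
      placed <- FALSE
      if (!is.null(ref_loci) &&
          stats::runif(1) < config$bg_at_ref_frac) {
        r <- ref_loci[sample.int(nrow(ref_loci), 1), ]
        inside <- probes_in_interval(probes, r$chrom, r$start, r$end)
        if (length(inside) >= 1) {
          ch <- r$chrom
          rel <- match(inside, by_chrom[[ch]])
          i0 <- rel[1]
          len <- length(rel)
          placed <- TRUE
        }
      }
      if (!placed) {
        ch <- sample(names(by_chrom), 1, prob = chrom_weights)
        npr <- length(by_chrom[[ch]])
        rng <- if (stats::runif(1) < config$bg_long_frac) {
          config$bg_long_len_probes
        } else {
          config$bg_len_probes
        }
        len_choices <- seq(rng[1], rng[2])
        len <- min(if (length(len_choices) == 1) len_choices else
          sample(len_choices, 1), npr)
        i0 <- sample.int(npr - len + 1L, 1)
      }
      # non-baseline copy number for the carrier's sex on this chromosome
      delta <- sample(c(-2L, -1L, 1L, 2L), 1, prob = c(0.05, 0.5, 0.35, 0.1))
      carriers <- samples$sample_id[i]
      sibs <- setdiff(fam_members[[samples$family_id[i]]], carriers)
      if (length(sibs) > 0 && config$bg_share_prob > 0) {
        carriers <- c(carriers,
                      sibs[stats::runif(length(sibs)) < config$bg_share_prob])
      }
      for (sid in carriers) {
        sex <- samples$sex[match(sid, samples$sample_id)]
        base <- baseline_cn(ch, sex)
        cn <- max(0L, min(4L, base + delta))
        if (cn == base) next
        seg_rows[[length(seg_rows) + 1L]] <- add_seg(sid, ch, i0, i0 + len - 1L,
                                                     cn)
      }
    }
  }

  # causal region
  if (config$carrier_frac > 0) {
    cr <- config$causal_region
    if (is.null(cr)) {
      ch <- names(by_chrom)[1]
      npr <- length(by_chrom[[ch]])
      i0 <- floor(npr / 2)
      pos <- probes$pos[by_chrom[[ch]]]
      cr <- list(chrom = ch, start = pos[i0],
                 end = pos[i0 + config$causal_n_probes - 1L])
    }
    inside <- probes_in_interval(probes, cr$chrom, cr$start, cr$end)
    if (length(inside) == 0) stop("causal region contains no probes")
    carriers <- samples$sample_id[stats::runif(n) < config$carrier_frac]
    if (config$causal_share_prob > 0 && length(carriers) > 0) {
      fams <- samples$family_id[match(carriers, samples$sample_id)]
      extra <- unlist(lapply(unique(fams), function(f) {
        sibs <- setdiff(fam_members[[f]], carriers)
        sibs[stats::runif(length(sibs)) < config$causal_share_prob]
      }))
      carriers <- c(carriers, extra)
    }
    for (sid in carriers) {
      seg_rows[[length(seg_rows) + 1L]] <-
        list(sample_id = sid, chrom = cr$chrom, start = cr$start,
             end = cr$end, cn = config$causal_cn, is_causal = TRUE)
    }
  }

  if (length(seg_rows) == 0) {
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0), cn = integer(0),
                      is_causal = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(seg_rows, as.data.frame,
                               stringsAsFactors = FALSE))
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  rownames(out) <- NULL
  out
}

# LRR mean shift by absolute copy number relative to a diploid baseline;
# typical array behavior (the magnitudes are configurable, not estimated)
.default_lrr_shift <- c(`0` = -3.5, `1` = -0.66, `2` = 0, `3` = 0.40,
                        `4` = 0.68)

#' Render per-probe array intensities from ground-truth segments
#'
#' LRR at a probe is the copy-number shift plus Gaussian noise; diploid
#' (baseline) probes have mean 0. On the male X, copy numbers are mapped
#' relative to the haploid baseline before the shift lookup, so the baseline
#' state again has mean 0. BAF is drawn from cluster patterns consistent
#' with the copy number.
#'
#' @param segments ground-truth segments (see [generate_cnv_landscape()]).
#' @param samples cohort samples (for sex on X).
#' @param probes probe manifest.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed integer seed.
#' @param lrr_shift named numeric: LRR mean by copy number 0..4.
#' @param baf logical; also render a BAF matrix.
#' @return list with `lrr` (samples x probes matrix, dimnames set) and
#'   `baf` (same shape or NULL).
#' @export
render_intensities <- function(segments, samples, probes, noise_sd = 0.15,
                               seed = 1L, lrr_shift = .default_lrr_shift,
                               baf = FALSE) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  n <- nrow(samples)
  p <- nrow(probes)
  probes <- probes[order(probes$chrom, probes$pos), ]
  lrr <- matrix(stats::rnorm(n * p, 0, noise_sd), n, p,
                dimnames = list(samples$sample_id, probes$probe_id))
  cnmat <- NULL
  if (isTRUE(baf)) cnmat <- matrix(NA_integer_, n, p)
  if (nrow(segments) > 0) {
    for (i in seq_len(nrow(segments))) {
      s <- segments[i, ]
      cols <- probes_in_interval(probes, s$chrom, s$start, s$end)
      if (length(cols) == 0) next
      row <- match(s$sample_id, samples$sample_id)
      base <- baseline_cn(s$chrom, samples$sex[row])
      eff <- max(0L, min(4L, s$cn - base + 2L))
      lrr[row, cols] <- lrr[row, cols] + lrr_shift[as.character(eff)]
      if (isTRUE(baf)) cnmat[row, cols] <- s$cn
    }
  }
  baf_mat <- NULL
  if (isTRUE(baf)) {
    baf_mat <- render_baf(cnmat, n, p, dimnames(lrr))
  }
  list(lrr = lrr, baf = baf_mat)
}

render_baf <- function(cnmat, n, p, dn) {
  cluster <- function(cn) {
    switch(as.character(cn),
           `0` = stats::runif(1),                 # no signal: uniform noise
           `1` = sample(c(0, 1), 1),
           `3` = sample(c(0, 1/3, 2/3, 1), 1, prob = c(.3, .2, .2, .3)),
           `4` = sample(c(0, .25, .5, .75, 1), 1),
           sample(c(0, 0.5, 1), 1, prob = c(.25, .5, .25)))
  }
  baf <- matrix(sample(c(0, 0.5, 1), n * p, replace = TRUE,
                       prob = c(.25, .5, .25)), n, p, dimnames = dn)
  idx <- which(!is.na(cnmat))
  if (length(idx) > 0) {
    baf[idx] <- vapply(cnmat[idx], cluster, numeric(1))
  }
  pmin(1, pmax(0, baf + stats::rnorm(n * p, 0, 0.02)))
}

#' Emit PennCNV-style call records from ground-truth segments
#'
#' Each true segment yields one call with optionally jittered boundaries, a
#' confidence score, and the probe count recomputed from the manifest. False
#' positive calls can be added at a configurable per-sample rate. With
#' `jitter_sd = 0` and `fp_rate = 0`, calls are bijective with segments.
#'
#' @param segments ground-truth segments.
#' @param probes probe manifest.
#' @param jitter_sd SD (bp) of Gaussian boundary jitter.
#' @param fp_rate mean number of false-positive calls per existing sample.
#' @param conf_meanlog,conf_sdlog log-normal confidence score parameters.
#' @param conf_fixed if non-NULL, all confidences are set to this value.
#' @param seed integer seed.
#' @return calls data.frame (`sample_id`, `chrom`, `start`, `end`, `cn`,
#'   `n_snps`, `conf`, `is_causal`); calls left with no probe after jitter
#'   are dropped.
#' @export
emit_cnv_calls <- function(segments, probes, jitter_sd = 0, fp_rate = 0,
                           conf_meanlog = log(30), conf_sdlog = 0.6,
                           conf_fixed = NULL, seed = 1L) {
  set.seed(seed)
  probes <- probes[order(probes$chrom, probes$pos), ]
  calls <- segments
  names(calls)[names(calls) == "cn"] <- "cn"
  if (nrow(calls) > 0 && jitter_sd > 0) {
    calls$start <- as.integer(pmax(1, round(calls$start +
      stats::rnorm(nrow(calls), 0, jitter_sd))))
    calls$end <- as.integer(round(calls$end +
      stats::rnorm(nrow(calls), 0, jitter_sd)))
    swap <- calls$end < calls$start
    tmp <- calls$start[swap]
    calls$start[swap] <- calls$end[swap]
    calls$end[swap] <- tmp
  }
  if (fp_rate > 0) {
    sids <- unique(segments$sample_id)
    n_fp <- stats::rpois(length(sids), fp_rate)
    by_chrom <- split(seq_len(nrow(probes)), probes$chrom)
    # false calls are placed on autosomes only: their copy numbers are drawn
    # without knowledge of sex, which on the X could coincide with baseline
    by_chrom <- by_chrom[normalize_chrom(names(by_chrom)) != "X"]
    fp <- list()
    for (i in seq_along(sids)) {
      if (n_fp[i] == 0 || length(by_chrom) == 0) next
      for (k in seq_len(n_fp[i])) {
        ch <- sample(names(by_chrom), 1)
        idxs <- by_chrom[[ch]]
        len <- sample(3:15, 1)
        i0 <- sample.int(length(idxs) - len, 1)
        fp[[length(fp) + 1L]] <- data.frame(
          sample_id = sids[i], chrom = ch,
          start = probes$pos[idxs[i0]], end = probes$pos[idxs[i0 + len - 1L]],
          cn = sample(c(1L, 3L), 1), is_causal = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    if (length(fp) > 0) calls <- rbind(calls, do.call(rbind, fp))
  }
  if (nrow(calls) == 0) {
    out <- empty_calls()
    out$is_causal <- logical(0)
    return(out)
  }
  calls$n_snps <- vapply(seq_len(nrow(calls)), function(i) {
    length(probes_in_interval(probes, calls$chrom[i], calls$start[i],
                              calls$end[i]))
  }, integer(1))
  calls <- calls[calls$n_snps >= 1, , drop = FALSE]
  calls$conf <- if (!is.null(conf_fixed)) {
    rep(conf_fixed, nrow(calls))
  } else {
    stats::rlnorm(nrow(calls), conf_meanlog, conf_sdlog)
  }
  rownames(calls) <- NULL
  calls[, c("sample_id", "chrom", "start", "end", "cn", "n_snps", "conf",
            "is_causal")]
}

#' Configuration of the phenotype generator
#'
#' Traits load on a single latent reading/language factor F; the default
#' loadings follow the broad pattern observed for such test batteries (word
#' reading and phonological decoding loading highest, nonword repetition
#' lowest). Residual noise SDs are set so each trait has unit variance.
#'
#' @param loadings named numeric of per-trait loadings on F.
#' @param noise_sd per-trait residual SD; default `sqrt(1 - loadings^2)`.
#' @param family_icc within-sibship correlation of F (0 <= icc < 1).
#' @param causal_beta shift of F (in SD units) for causal-CNV carriers.
#' @param piq_factor_corr correlation of performance IQ with F.
#' @param viq_factor_corr correlation of verbal IQ with F.
#' @param discr_weights weights of the discriminant composite over
#'   (word reading, spelling, orthographic coding).
#' @param missing_rate per-trait probability of a missing value.
#' @return list of class `pheno_config`.
#' @export
pheno_config <- function(loadings = c(WRead = 0.918, WSpell = 0.813,
                                      PD = 0.895, PA = 0.801, OC = 0.764,
                                      NWR = 0.493),
                         noise_sd = NULL,
                         family_icc = 0.4,
                         causal_beta = 0,
                         piq_factor_corr = 0.3,
                         viq_factor_corr = 0.5,
                         discr_weights = c(WRead = 0.5, WSpell = 0.3,
                                           OC = 0.2),
                         missing_rate = 0.02) {
  if (any(abs(loadings) > 1)) stop("|loadings| must be <= 1")
  if (family_icc < 0 || family_icc >= 1) stop("family_icc must be in [0, 1)")
  if (is.null(noise_sd)) noise_sd <- sqrt(1 - loadings^2)
  structure(list(loadings = loadings, noise_sd = noise_sd,
                 family_icc = family_icc, causal_beta = causal_beta,
                 piq_factor_corr = piq_factor_corr,
                 viq_factor_corr = viq_factor_corr,
                 discr_weights = discr_weights,
                 missing_rate = missing_rate),
            class = "pheno_config")
}

#' Generate factor-structured phenotypes for a cohort
#'
#' F = family effect + individual effect (+ `causal_beta` for carriers);
#' trait_j = loading_j * F + noise_j. Performance and verbal IQ correlate
#' with F at configured levels; the discriminant score is a fixed weighted
#' composite of three traits, standardized.
#'
#' @param samples cohort samples data.frame.
#' @param carrier logical vector: causal-CNV carrier status per sample.
#' @param config a [pheno_config()].
#' @param seed integer seed.
#' @return data.frame with `sample_id`, trait columns, `VIQ`, `PIQ`,
#'   `IBGdiscr`; the latent factor is attached as attribute `"latent"`.
#' @export
generate_phenotypes <- function(samples, carrier, config = pheno_config(),
                                seed = 1L) {
  stopifnot(inherits(config, "pheno_config"),
            length(carrier) == nrow(samples))
  set.seed(seed)
  n <- nrow(samples)
  fam <- factor(samples$family_id)
  icc <- config$family_icc
  fam_eff <- stats::rnorm(nlevels(fam), 0, sqrt(icc))[as.integer(fam)]
  f <- fam_eff + stats::rnorm(n, 0, sqrt(1 - icc)) +
    config$causal_beta * as.numeric(carrier)
  traits <- sapply(names(config$loadings), function(tr) {
    config$loadings[[tr]] * f + stats::rnorm(n, 0, config$noise_sd[[tr]])
  })
  piq <- config$piq_factor_corr * f +
    stats::rnorm(n, 0, sqrt(1 - config$piq_factor_corr^2))
  viq <- config$viq_factor_corr * f +
    stats::rnorm(n, 0, sqrt(1 - config$viq_factor_corr^2))
  discr <- as.vector(traits[, names(config$discr_weights)] %*%
                       config$discr_weights)
  discr <- as.vector(scale(discr))
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * ncol(traits)) < config$missing_rate,
                   n, ncol(traits))
    traits[miss] <- NA_real_
  }
  out <- data.frame(sample_id = samples$sample_id, traits, VIQ = viq,
                    PIQ = piq, IBGdiscr = discr, stringsAsFactors = FALSE)
  attr(out, "latent") <- f
  out
}
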