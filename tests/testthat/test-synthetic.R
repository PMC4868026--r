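test_that("cohort generation is deterministic and respects the config", {
  cfg <- cohort_config(n_families = 10, sibship_size_range = c(2, 2),
                       seed = 11)
  a <- generate_cohort(cfg)
  expect_equal(nrow(a$samples), 20)
  expect_equal(length(unique(a$samples$family_id)), 10)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_true(all(a$samples$cohort %in% c("RD", "ADHD")))
  expect_true(all(a$samples$sex %in% c("M", "F")))
  expect_error(cohort_config(n_families = 0))
  expect_error(cohort_config(sibship_size_range = c(1, 2)))
})

test_that("family-size histogram matches the uniform sampling distribution", {
  cfg <- cohort_config(n_families = 300, sibship_size_range = c(2, 3),
                       seed = 5)
  fams <- generate_cohort(cfg)$families
  # oracle: direct multinomial simulation of uniform sizes on {2,3}
  set.seed(999)
  ref <- replicate(2000, sum(sample(2:3, 300, replace = TRUE) == 2))
  n2 <- sum(fams$size == 2)
  expect_true(n2 >= quantile(ref, 0.0005) && n2 <= quantile(ref, 0.9995))
})

test_that("genome generation yields sorted probes, contained exons, and
           reference loci with exact event counts", {
  cfg <- cohort_config(n_probes_per_chrom = 1000, chromosomes = c("1", "X"),
                       seed = 3)
  g <- generate_genome(cfg)
  for (ch in unique(g$probes$chrom)) {
    pos <- g$probes$pos[g$probes$chrom == ch]
    expect_true(all(diff(pos) > 0))
  }
  # exons lie within their gene's span
  m <- match(g$exons$gene, g$genes$gene)
  expect_true(all(g$exons$start >= g$genes$start[m]))
  expect_true(all(g$exons$end <= g$genes$end[m]))
  # rarity classifier sees exactly k overlaps for a call placed at a locus
  loci <- unique(g$reference_cnvs[, c("chrom", "start", "end", "locus",
                                      "count")])
  for (i in sample(nrow(loci), 5)) {
    call <- make_call(chrom = loci$chrom[i], start = loci$start[i],
                      end = loci$end[i])
    res <- classify_rarity(call, g$reference_cnvs)
    # brute-force interval scan: events covering >= 50% of the call
    w <- pmax(0, pmin(call$end, g$reference_cnvs$end) -
                pmax(call$start, g$reference_cnvs$start) + 1)
    ok <- g$reference_cnvs$chrom == call$chrom &
      w >= 0.5 * (call$end - call$start + 1)
    expect_equal(res$ref_overlaps, sum(ok))
    expect_gte(sum(ok), loci$count[i])
  }
})

test_that("causal-carrier assignment follows the configured fraction", {
  cfg <- cohort_config(n_families = 100, sibship_size_range = c(2, 2),
                       n_probes_per_chrom = 500, seed = 2)
  cohort <- generate_cohort(cfg)
  g <- generate_genome(cfg)
  # zero fraction -> nobody carries it
  seg0 <- generate_cnv_landscape(cohort$samples, g$probes,
                                 landscape_config(bg_rate = 0,
                                                  carrier_frac = 0),
                                 seed = 4)
  expect_equal(nrow(seg0), 0)
  # fraction 0.05, n = 400: carrier count within the binomial 99.9% interval
  cfg4 <- cohort_config(n_families = 200, sibship_size_range = c(2, 2),
                        n_probes_per_chrom = 500, seed = 8)
  cohort4 <- generate_cohort(cfg4)
  seg <- generate_cnv_landscape(cohort4$samples, generate_genome(cfg4)$probes,
                                landscape_config(bg_rate = 0,
                                                 carrier_frac = 0.05),
                                seed = 9)
  n_carriers <- length(unique(seg$sample_id))
  expect_true(n_carriers >= qbinom(0.0005, 400, 0.05) &&
                n_carriers <= qbinom(0.9995, 400, 0.05))
  expect_true(all(seg$is_causal))
  # sharing probability 1 -> every carrier's sibs carry it
  seg_share <- generate_cnv_landscape(
    cohort4$samples, generate_genome(cfg4)$probes,
    landscape_config(bg_rate = 0, carrier_frac = 0.05,
                     causal_share_prob = 1), seed = 10)
  carrier_fams <- unique(cohort4$samples$family_id[
    cohort4$samples$sample_id %in% seg_share$sample_id])
  fam_members <- split(cohort4$samples$sample_id, cohort4$samples$family_id)
  for (f in carrier_fams) {
    expect_true(all(fam_members[[f]] %in% seg_share$sample_id))
  }
})

test_that("rendered LRR shifts order with copy number", {
  samples <- make_samples(2, 2)
  probes <- make_probes(pos = seq(1e4, 5e5, by = 1e4))
  segs <- data.frame(sample_id = c("F001_S1", "F001_S2"), chrom = "1",
                     start = c(100000L, 100000L), end = c(200000L, 200000L),
                     cn = c(1L, 3L), is_causal = FALSE,
                     stringsAsFactors = FALSE)
  # zero noise, diploid everywhere -> identically 0
  quiet <- render_intensities(segs[0, ], samples, probes, noise_sd = 0,
                              seed = 1)
  expect_true(all(quiet$lrr == 0))
  # deletion probe mean strictly below duplication probe mean
  r <- render_intensities(segs, samples, probes, noise_sd = 0, seed = 1)
  del_probes <- probes_in_interval(probes, "1", 100000, 200000)
  expect_lt(mean(r$lrr[1, del_probes]), mean(r$lrr[2, del_probes]))
  expect_equal(unname(r$lrr[1, del_probes[1]]), -0.66)
  expect_equal(unname(r$lrr[2, del_probes[1]]), 0.40)
  # with noise, a long-deletion carrier's segment mean is below a
  # non-carrier's over the same probes
  rn <- render_intensities(segs[1, ], samples, probes, noise_sd = 0.1,
                           seed = 2)
  expect_lt(mean(rn$lrr[1, del_probes]), mean(rn$lrr[2, del_probes]))
  expect_error(render_intensities(segs, samples, probes, noise_sd = -1),
               "noise_sd")
  # BAF stays in [0, 1] and diploid probes cluster at {0, 1/2, 1}
  rb <- render_intensities(segs, samples, probes, noise_sd = 0.1, seed = 3,
                           baf = TRUE)
  expect_true(all(rb$baf >= 0 & rb$baf <= 1))
})

test_that("emitted calls are bijective with segments when noise-free and
           carry oracle probe counts", {
  samples <- make_samples(5, 2)
  probes <- make_probes(pos = seq(1e4, 1e6, by = 1e4))
  set.seed(20)
  segs <- generate_cnv_landscape(samples, probes,
                                 landscape_config(bg_rate = 3,
                                                  bg_at_ref_frac = 0),
                                 seed = 21)
  calls <- emit_cnv_calls(segs, probes, jitter_sd = 0, fp_rate = 0, seed = 22)
  expect_equal(nrow(calls), nrow(segs))
  expect_identical(calls[, c("sample_id", "chrom", "start", "end", "cn")],
                   segs[, c("sample_id", "chrom", "start", "end", "cn")])
  for (i in seq_len(nrow(calls))) {
    expect_equal(calls$n_snps[i],
                 brute_probe_count(probes, calls$chrom[i], calls$start[i],
                                   calls$end[i]))
  }
  # confidence fixed below 10 -> the QC filter retains zero calls
  low <- emit_cnv_calls(segs, probes, conf_fixed = 9.5, seed = 23)
  expect_equal(nrow(filter_calls(low)), 0)
})

test_that("generated phenotypes recover the configured factor structure", {
  cfg <- cohort_config(n_families = 300, sibship_size_range = c(2, 2),
                       seed = 30)
  samples <- generate_cohort(cfg)$samples
  # icc = 0, no causal effect -> between-sib trait correlation near 0
  p0 <- generate_phenotypes(samples, rep(FALSE, nrow(samples)),
                            pheno_config(family_icc = 0, missing_rate = 0),
                            seed = 31)
  sib1 <- seq(1, nrow(samples), by = 2)
  r_sib <- cor(p0$WRead[sib1], p0$WRead[sib1 + 1])
  expect_lt(abs(r_sib), 0.12)
  # positive icc -> sibs correlate
  p1 <- generate_phenotypes(samples, rep(FALSE, nrow(samples)),
                            pheno_config(family_icc = 0.5, missing_rate = 0),
                            seed = 31)
  expect_gt(cor(p1$WRead[sib1], p1$WRead[sib1 + 1]), 0.2)
  # causal_beta = -0.8, 5% carriers, n = 600: carrier/non-carrier latent
  # difference recovered within 2 SE
  carrier <- rep(FALSE, nrow(samples))
  carrier[sample(nrow(samples), 30)] <- TRUE
  p2 <- generate_phenotypes(samples, carrier,
                            pheno_config(causal_beta = -0.8,
                                         missing_rate = 0), seed = 32)
  f <- attr(p2, "latent")
  tt <- t.test(f[carrier], f[!carrier])
  expect_lt(abs((mean(f[carrier]) - mean(f[!carrier])) - (-0.8)),
            2 * tt$stderr)
  expect_lt(tt$p.value, 1e-4)
  # discriminant composite is standardized
  expect_equal(sd(p2$IBGdiscr), 1, tolerance = 1e-8)
})
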