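test_that("probe state coding is sex-aware and matches the interval scan
           oracle", {
  samples <- make_samples(4, 2)          # alternating M/F
  probes <- make_probes(chrom = rep(c("1", "X"), each = 50),
                        pos = rep(seq(1e4, 5e5, by = 1e4), 2))
  calls <- rbind(
    make_call(samples$sample_id[1], "1", 100000, 200000, cn = 3),  # dup
    make_call(samples$sample_id[2], "1", 150000, 250000, cn = 1),  # del
    make_call(samples$sample_id[1], "X", 100000, 200000, cn = 1),  # M: base
    make_call(samples$sample_id[2], "X", 100000, 200000, cn = 1),  # F: CNV+
    make_call(samples$sample_id[3], "X", 300000, 400000, cn = 2))  # M: CNV+
  st <- assign_probe_states(calls, probes, samples)
  # autosomal dup probes are CNV+
  p_auto <- probes$probe_id[probes$chrom == "1" & probes$pos == 150000]
  expect_equal(unname(st[samples$sample_id[1], p_auto]), 1L)
  # male X copy number 1 is baseline -> CNV-
  p_x <- probes$probe_id[probes$chrom == "X" & probes$pos == 150000]
  expect_equal(unname(st[samples$sample_id[1], p_x]), 0L)
  # female X copy number 1 -> CNV+
  expect_equal(unname(st[samples$sample_id[2], p_x]), 1L)
  # male X copy number 2 -> CNV+
  p_x2 <- probes$probe_id[probes$chrom == "X" & probes$pos == 350000]
  expect_equal(unname(st[samples$sample_id[3], p_x2]), 1L)
  # probe covered by no call -> CNV-
  expect_equal(unname(st[samples$sample_id[4], p_auto]), 0L)
  # column sums equal the brute-force per-probe carrier counts
  expect_equal(unname(colSums(st)), brute_state_counts(calls, probes,
                                                       samples))
  # unknown sex with an X call errors
  samples2 <- samples
  samples2$sex[2] <- NA
  expect_error(assign_probe_states(calls, probes, samples2), "unknown sex")
})

test_that("state matrix columns match brute force on random landscapes", {
  set.seed(88)
  samples <- make_samples(8, 2)
  probes <- make_probes(chrom = sample(c("1", "2"), 120, replace = TRUE),
                        pos = sample.int(2e6, 120))
  probes <- probes[order(probes$chrom, probes$pos), ]
  for (rep in 1:5) {
    n <- 25
    start <- sample.int(2e6, n)
    calls <- data.frame(
      sample_id = sample(samples$sample_id, n, replace = TRUE),
      chrom = sample(c("1", "2"), n, replace = TRUE),
      start = start, end = start + sample.int(3e5, n),
      cn = sample(c(0L, 1L, 3L, 4L), n, replace = TRUE),
      n_snps = 10L, conf = 20, stringsAsFactors = FALSE)
    st <- assign_probe_states(calls, probes, samples)
    expect_equal(unname(colSums(st)),
                 brute_state_counts(calls, probes, samples))
  }
  # covered-probe restriction: a single planted call spanning k probes
  one <- make_call(samples$sample_id[1], "1", 0, 3e6)
  one$start <- min(probes$pos[probes$chrom == "1"])
  one$end <- max(probes$pos[probes$chrom == "1"])
  st1 <- assign_probe_states(one, probes, samples)
  expect_equal(length(restrict_to_covered(st1)),
               sum(probes$chrom == "1"))
  expect_equal(length(restrict_to_covered(st1 * 0L)), 0)
})

test_that("the family permutation test attains the minimal p for a perfect
           association and p = 1 for monomorphic states", {
  fams <- sprintf("F%02d", 1:20)           # singletons
  state <- c(rep(1, 10), rep(0, 10))
  res <- family_permutation_test(state, state, fams, n_perms = 99, seed = 4,
                                 adaptive = FALSE)
  expect_equal(res$p, 1 / 100)
  expect_equal(res$direction, 1)
  mono <- family_permutation_test(rep(1, 20), rnorm(20), fams, 99, seed = 5)
  expect_equal(mono$p, 1)
  expect_equal(mono$direction, 0)
})

test_that("permutation p-values are calibrated under the family-structured
           null", {
  set.seed(90)
  fams <- rep(sprintf("F%02d", 1:30), each = 2)
  n <- length(fams)
  R <- 300
  rej <- 0
  for (r in seq_len(R)) {
    state <- as.numeric(runif(n) < 0.15)
    if (var(state) == 0) state[1] <- 1
    fam_eff <- rnorm(30)[rep(1:30, each = 2)]
    y <- fam_eff + rnorm(n)
    res <- family_permutation_test(state, y, fams, n_perms = 199,
                                   seed = 5000 + r, adaptive = FALSE)
    if (res$p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / R, 0.02)
  expect_lt(rej / R, 0.08)
})

test_that("power of the state test increases with the planted effect", {
  set.seed(91)
  fams <- rep(sprintf("F%03d", 1:100), each = 2)
  n <- length(fams)
  power_at <- function(beta, R = 40) {
    hits <- 0
    for (r in seq_len(R)) {
      state <- as.numeric(runif(n) < 0.1)
      if (var(state) == 0) state[1] <- 1
      y <- beta * state + rnorm(n)
      res <- family_permutation_test(state, y, fams, n_perms = 199,
                                     seed = 7000 + r, adaptive = FALSE)
      if (res$p < 0.05) hits <- hits + 1
    }
    hits / R
  }
  p_small <- power_at(0.2)
  p_large <- power_at(1.2)
  expect_gt(p_large, p_small)
  expect_gt(p_large, 0.9)
})

test_that("sex-stratified X association combines strata by sample-size
           weights", {
  set.seed(92)
  samples <- make_samples(40, 2)
  n <- nrow(samples)
  probes <- make_probes(chrom = "X", pos = seq(1e4, 2e5, by = 1e4))
  st <- matrix(0L, n, nrow(probes),
               dimnames = list(samples$sample_id, probes$probe_id))
  st[sample(n, 12), 3] <- 1L
  y <- rnorm(n) + 0.5 * st[, 3]
  res <- x_association(st, y, samples$family_id, samples$sex,
                       n_perms = 199, seed = 6)
  expect_true(!is.null(res$combined))
  # females monomorphic -> combined equals male stratum
  st2 <- st
  st2[samples$sex == "F", ] <- 0L
  males_plus <- sum(st2[samples$sex == "M", 3])
  if (males_plus > 0) {
    res2 <- x_association(st2, y, samples$family_id, samples$sex,
                          n_perms = 199, seed = 6)
    expect_equal(res2$combined$p_meta,
                 2 * pnorm(-abs(res2$combined$Z)))
    m <- res2$males
    z_m <- m$direction[m$probe_id == probes$probe_id[3]] *
      qnorm(1 - m$p[m$probe_id == probes$probe_id[3]] / 2)
    expect_equal(res2$combined$Z[res2$combined$probe_id ==
                                   probes$probe_id[3]], z_m,
                 tolerance = 1e-10)
  }
})

test_that("meta-analysis matches the weighted-z arithmetic oracle", {
  # equal z and N in both cohorts -> Z = z * sqrt(2)
  a <- data.frame(probe_id = "p1", p = 2 * pnorm(-1.96), direction = 1,
                  N = 500)
  b <- a
  m <- meta_analyze(a, b)
  expect_equal(m$Z, 1.96 * sqrt(2), tolerance = 1e-6)
  expect_equal(m$Z, 2.772, tolerance = 1e-3)
  # opposite directions cancel
  b2 <- a
  b2$direction <- -1
  expect_equal(meta_analyze(a, b2)$Z, 0)
  # single-cohort probes are excluded
  b3 <- data.frame(probe_id = "p2", p = 0.01, direction = 1, N = 300)
  expect_equal(nrow(meta_analyze(a, b3)), 0)
  # random (p, N) pairs against an independent arithmetic oracle
  set.seed(93)
  for (rep in 1:200) {
    pa <- runif(1)
    pb <- runif(1)
    da <- sample(c(-1, 1), 1)
    db <- sample(c(-1, 1), 1)
    Na <- sample(100:1000, 1)
    Nb <- sample(100:1000, 1)
    ra <- data.frame(probe_id = "q", p = pa, direction = da, N = Na)
    rb <- data.frame(probe_id = "q", p = pb, direction = db, N = Nb)
    got <- meta_analyze(ra, rb)$Z
    za <- da * qnorm(1 - pa / 2)
    zb <- db * qnorm(1 - pb / 2)
    oracle <- (sqrt(Na) * za + sqrt(Nb) * zb) / sqrt(Na + Nb)
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  # p = 0 clamped with warning
  z0 <- data.frame(probe_id = "p1", p = 0, direction = 1, N = 100)
  expect_warning(meta_analyze(z0, a), "clamped")
})

test_that("region detection equals exhaustive enumeration on random p
           vectors", {
  probes <- make_probes(pos = seq(1e4, 4e5, by = 1e4))
  # worked example: two core probes then two flank probes
  p <- c(0.004, 0.003, 0.03, 0.04, 0.5, rep(0.9, 35))
  res <- data.frame(probe_id = probes$probe_id, p = p)
  reg <- detect_regions(res, probes)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$n_probes, 4)
  expect_equal(reg$start, probes$pos[1])
  expect_equal(reg$end, probes$pos[4])
  # all null -> nothing
  expect_equal(nrow(detect_regions(
    data.frame(probe_id = probes$probe_id, p = rep(0.5, 40)), probes)), 0)
  # single core probe with flanks -> rejected (core needs 2 consecutive)
  p2 <- c(0.03, 0.001, 0.03, 0.04, rep(0.9, 36))
  expect_equal(nrow(detect_regions(
    data.frame(probe_id = probes$probe_id, p = p2), probes)), 0)
  # randomized oracle comparison
  set.seed(94)
  for (rep in 1:300) {
    pv <- runif(40)
    hot <- runif(40) < 0.25
    pv[hot] <- runif(sum(hot), 0, 0.06)
    veryhot <- runif(40) < 0.1
    pv[veryhot] <- runif(sum(veryhot), 0, 0.01)
    na_mask <- runif(40) < 0.1          # untested probes break runs
    pv[na_mask] <- NA
    res <- data.frame(probe_id = probes$probe_id[!na_mask],
                      p = pv[!na_mask])
    got <- detect_regions(res, probes)
    oracle <- brute_regions(pv)
    expect_equal(nrow(got), length(oracle))
    if (length(oracle) > 0) {
      expect_equal(got$start,
                   vapply(oracle, function(o) probes$pos[o["start"]],
                          numeric(1)))
      expect_equal(got$end,
                   vapply(oracle, function(o) probes$pos[o["end"]],
                          numeric(1)))
    }
  }
})

test_that("regions never span chromosome boundaries", {
  probes <- make_probes(chrom = rep(c("1", "2"), each = 4),
                        pos = rep(c(1e4, 2e4, 3e4, 4e4), 2))
  res <- data.frame(probe_id = probes$probe_id, p = rep(0.001, 8))
  reg <- detect_regions(res, probes)
  expect_equal(nrow(reg), 2)
  expect_equal(reg$chrom, c("1", "2"))
})

test_that("the Bonferroni threshold reproduces the two-trait scan alpha", {
  expect_equal(signif(bonferroni_alpha(0.05, 2, 5173), 2), 4.8e-6)
  expect_equal(bonferroni_alpha(0.05, 1, 1), 0.05)
  expect_equal(signif(bonferroni_alpha(0.05, 2, 704855), 2), 3.5e-8)
  expect_error(bonferroni_alpha(0.05, 0, 10), "positive")
})

test_that("regional CNV+ frequency counts samples CNV+ at any member
           probe", {
  st <- matrix(0L, 500, 5,
               dimnames = list(sprintf("S%03d", 1:500),
                               sprintf("p%d", 1:5)))
  st[1:9, 2:4] <- 1L
  f <- cnv_plus_frequency(c("p2", "p3"), st)
  expect_equal(f$percent, 1.8)
  expect_equal(cnv_plus_frequency("p5", st)$percent, 0)
  st2 <- st
  st2[, 1] <- 1L
  expect_equal(cnv_plus_frequency("p1", st2)$percent, 100)
})
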