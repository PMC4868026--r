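# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no binary fixtures.

make_probes <- function(chrom = "1", pos = seq(10000, 1000000, by = 10000)) {
  if (length(chrom) == 1) chrom <- rep(chrom, length(pos))
  data.frame(probe_id = sprintf("p%s_%04d", chrom, seq_along(pos)),
             chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

make_call <- function(sample_id = "S1", chrom = "1", start = 100000,
                      end = 200000, cn = 1L, n_snps = 15L, conf = 20) {
  data.frame(sample_id = sample_id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), cn = as.integer(cn),
             n_snps = as.integer(n_snps), conf = conf,
             stringsAsFactors = FALSE)
}

make_samples <- function(n_fam = 10, size = 2, cohort = "RD") {
  fams <- sprintf("F%03d", seq_len(n_fam))
  data.frame(
    sample_id = sprintf("%s_S%d", rep(fams, each = size), seq_len(size)),
    family_id = rep(fams, each = size),
    sex = rep(c("M", "F"), length.out = n_fam * size),
    cohort = cohort, stringsAsFactors = FALSE)
}

# brute-force count of probes inside an interval (oracle for interval scans)
brute_probe_count <- function(probes, chrom, start, end) {
  sum(probes$chrom == chrom & probes$pos >= start & probes$pos <= end)
}

# brute-force per-probe CNV+ carrier count from call intervals (oracle)
brute_state_counts <- function(calls, probes, samples) {
  counts <- integer(nrow(probes))
  for (j in seq_len(nrow(probes))) {
    plus <- character(0)
    for (i in seq_len(nrow(calls))) {
      if (calls$chrom[i] != probes$chrom[j]) next
      if (probes$pos[j] < calls$start[i] || probes$pos[j] > calls$end[i]) next
      sex <- samples$sex[match(calls$sample_id[i], samples$sample_id)]
      base <- if (calls$chrom[i] == "X" && sex == "M") 1L else 2L
      if (calls$cn[i] != base) plus <- c(plus, calls$sample_id[i])
    }
    counts[j] <- length(unique(plus))
  }
  counts
}

# exhaustive region enumeration oracle: all maximal runs of p < flank_p
# containing >= core_len consecutive p < core_p and >= flank_len extra probes
brute_regions <- function(p, core_p = 0.005, core_len = 2, flank_p = 0.05,
                          flank_len = 2) {
  n <- length(p)
  ok <- !is.na(p) & p < flank_p
  regions <- list()
  i <- 1
  while (i <= n) {
    if (!ok[i]) {
      i <- i + 1
      next
    }
    j <- i
    while (j < n && ok[j + 1]) j <- j + 1
    run <- i:j
    core_runs <- rle(p[run] < core_p)
    has_core <- any(core_runs$lengths[core_runs$values] >= core_len)
    if (has_core && length(run) >= core_len + flank_len) {
      regions[[length(regions) + 1L]] <- c(start = i, end = j)
    }
    i <- j + 1
  }
  regions
}
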