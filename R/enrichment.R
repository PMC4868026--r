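#' Interval-permutation gene-set enrichment test
#'
#' Tests whether a set of genomic intervals (typically case CNV calls)
#' overlaps a gene set's genes more often than probe-matched random
#' intervals do. The observed statistic per set is the number of intervals
#' hitting at least one set gene (gene spans extended by `flank_bp`). Each
#' permutation replaces every interval by a random run of the same number of
#' consecutive covered probes (uniform over feasible start positions within
#' a chromosome), where the covered probe set is all probes encompassed by
#' CNV calls; this matches the null intervals to the probe content of the
#' observed ones. `p_empirical = (1 + exceedances) / (1 + n_perms)`;
#' `p_corrected` is Bonferroni across tested sets.
#'
#' Before testing, overlapping intervals of one sample are merged and
#' duplicate intervals across samples are collapsed to one (the test assumes
#' independent intervals); disable with `collapse = FALSE`.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `sample_id`.
#' @param gene_sets named list of character vectors of gene symbols.
#' @param genes gene models (`gene`, `chrom`, `start`, `end`).
#' @param probes probe manifest.
#' @param covered_probes character vector of covered probe ids.
#' @param n_perms number of permutations.
#' @param seed integer seed.
#' @param flank_bp gene flank (default 50 kb).
#' @param collapse merge/deduplicate intervals first (default TRUE).
#' @return data.frame: `set`, `n_genes`, `observed`, `p_empirical`,
#'   `p_corrected`; attribute `"n_intervals"` records the tested interval
#'   count.
#' @export
target_enrichment <- function(intervals, gene_sets, genes, probes,
                              covered_probes, n_perms = 1000, seed = 1L,
                              flank_bp = 50000, collapse = TRUE) {
  set.seed(seed)
  probes <- probes[order(probes$chrom, probes$pos), ]
  cov_idx <- which(probes$probe_id %in% covered_probes)
  if (length(cov_idx) == 0) stop("no covered probes")
  cov <- probes[cov_idx, , drop = FALSE]

  if (collapse && nrow(intervals) > 0) {
    if (!is.null(intervals$sample_id)) {
      merged <- do.call(rbind, lapply(split(intervals, intervals$sample_id),
                                      merge_intervals))
    } else {
      merged <- intervals[, c("chrom", "start", "end")]
    }
    key <- paste(merged$chrom, merged$start, merged$end)
    intervals <- merged[!duplicated(key), , drop = FALSE]
  }
  n_int <- nrow(intervals)
  if (n_int == 0) stop("no intervals to test")

  # number of covered probes per interval (defines the matched null)
  probe_runs <- lapply(seq_len(n_int), function(i) {
    idx <- probes_in_interval(cov, intervals$chrom[i], intervals$start[i],
                              intervals$end[i])
    if (length(idx) == 0) {
      stop("interval with zero covered probes: ", intervals$chrom[i], ":",
           intervals$start[i], "-", intervals$end[i])
    }
    length(idx)
  })
  run_len <- unlist(probe_runs)

  # feasible start positions in the covered-probe list for a run of length L:
  # all L probes must sit on one chromosome (consecutive in the covered set)
  cov_chrom <- cov$chrom
  feasible_starts <- function(L) {
    n <- nrow(cov)
    if (L > n) stop("interval spans more covered probes than exist")
    ok <- cov_chrom[seq_len(n - L + 1)] == cov_chrom[seq_len(n - L + 1) + L - 1]
    which(ok)
  }
  starts_by_len <- lapply(sort(unique(run_len)), feasible_starts)
  names(starts_by_len) <- as.character(sort(unique(run_len)))

  # merged, flanked gene intervals per set and chromosome, for fast lookup
  set_lookup <- lapply(gene_sets, function(members) {
    g <- genes[genes$gene %in% members, , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    g$start <- pmax(1, g$start - flank_bp)
    g$end <- g$end + flank_bp
    merged <- merge_intervals(g)
    split(merged, merged$chrom)
  })

  # count intervals hitting >= 1 merged set interval; the merged set is
  # disjoint and sorted, so the only candidate is the last one starting at
  # or before the query end
  count_stat <- function(chroms, starts, ends, lookup) {
    total <- 0L
    for (ch in unique(chroms)) {
      iv <- lookup[[ch]]
      if (is.null(iv)) next
      sel <- chroms == ch
      k <- findInterval(ends[sel], iv$start)
      ok <- k >= 1
      ok[ok] <- iv$end[k[ok]] >= starts[sel][ok]
      total <- total + sum(ok)
    }
    total
  }

  results <- data.frame(set = names(gene_sets),
                        n_genes = vapply(gene_sets, length, integer(1)),
                        observed = NA_integer_, p_empirical = NA_real_,
                        stringsAsFactors = FALSE)
  skipped <- vapply(set_lookup, is.null, logical(1)) |
    lengths(gene_sets) == 0
  if (any(skipped)) {
    warning("skipping empty/unresolvable gene sets: ",
            paste(names(gene_sets)[skipped], collapse = ", "))
  }

  # pre-draw permutation intervals (shared across sets)
  perm_runs <- lapply(seq_len(n_perms), function(k) {
    st <- vapply(run_len, function(L) {
      fs <- starts_by_len[[as.character(L)]]
      fs[sample.int(length(fs), 1)]
    }, integer(1))
    en <- st + run_len - 1L
    data.frame(chrom = cov_chrom[st], start = cov$pos[st], end = cov$pos[en],
               stringsAsFactors = FALSE)
  })

  for (i in which(!skipped)) {
    lookup <- set_lookup[[i]]
    obs <- count_stat(intervals$chrom, intervals$start, intervals$end, lookup)
    exceed <- sum(vapply(perm_runs, function(pr) {
      count_stat(pr$chrom, pr$start, pr$end, lookup) >= obs
    }, logical(1)))
    results$observed[i] <- obs
    results$p_empirical[i] <- (1 + exceed) / (1 + n_perms)
  }
  n_tested <- sum(!skipped)
  results$p_corrected <- pmin(1, results$p_empirical * n_tested)
  attr(results, "n_intervals") <- n_int
  results
}

#' Assemble composite candidate gene sets by keyword
#'
#' Builds one composite set per keyword group by case-insensitive substring
#' match on set names in a flat term -> genes table, taking the union of the
#' member genes of all matching sets (the usual way candidate pathway
#' hypotheses such as "axon guidance", "neuron migration" or sex-hormone
#' terms are encoded over an ontology export).
#'
#' @param go_table named list of character vectors (set name -> genes), e.g.
#'   from [read_gmt()].
#' @param keywords named list of character vectors of keywords; each element
#'   yields one composite set.
#' @return named list of character vectors (composite gene sets); empty
#'   matches yield empty sets with a warning.
#' @export
build_candidate_sets <- function(go_table, keywords) {
  out <- lapply(keywords, function(kw) {
    hit <- rep(FALSE, length(go_table))
    for (k in kw) {
      hit <- hit | grepl(k, names(go_table), ignore.case = TRUE)
    }
    sort(unique(unlist(go_table[hit], use.names = FALSE)))
  })
  empty <- lengths(out) == 0
  if (any(empty)) {
    warning("keywords matched no sets: ",
            paste(names(keywords)[empty], collapse = ", "))
  }
  out
}
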