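#' Build the samples x probes binary CNV-state matrix
#'
#' A probe is CNV+ ("1") for a sample iff at least one QC-passing call of
#' that sample covers it and the call's copy number differs from the
#' baseline: 2 on autosomes and on the female X, 1 on the male X. Deletions
#' and duplications both map to the single CNV+ state.
#'
#' @param calls QC-passing calls.
#' @param probes probe manifest sorted by (chrom, pos).
#' @param samples samples data.frame with `sample_id` and `sex` (needed for
#'   X calls; an X call for a sample with missing sex is an error).
#' @return integer matrix (samples x probes) of 0/1 states, dimnames set.
#' @export
assign_probe_states <- function(calls, probes, samples) {
  probes <- probes[order(probes$chrom, probes$pos), ]
  state <- matrix(0L, nrow(samples), nrow(probes),
                  dimnames = list(samples$sample_id, probes$probe_id))
  if (nrow(calls) == 0) return(state)
  sex <- samples$sex[match(calls$sample_id, samples$sample_id)]
  on_x <- normalize_chrom(calls$chrom) == "X"
  if (any(on_x & (is.na(sex) | !sex %in% c("M", "F")))) {
    stop("X-chromosome call for a sample with unknown sex")
  }
  base <- ifelse(on_x & sex == "M", 1L, 2L)
  for (i in seq_len(nrow(calls))) {
    if (calls$cn[i] == base[i]) next
    cols <- probes_in_interval(probes, calls$chrom[i], calls$start[i],
                               calls$end[i])
    if (length(cols) == 0) next
    row <- match(calls$sample_id[i], samples$sample_id)
    state[row, cols] <- 1L
  }
  state
}

#' Restrict a state matrix to probes covered by at least one CNV
#'
#' Only probes where at least one sample is CNV+ enter association testing;
#' monomorphic CNV+ probes (every sample CNV+) are retained here and flagged
#' untestable by the association test itself.
#'
#' @param state 0/1 state matrix from [assign_probe_states()].
#' @return character vector of covered probe ids.
#' @export
restrict_to_covered <- function(state) {
  colnames(state)[colSums(state) > 0]
}

#' Probe-wise CNV-state association in one cohort
#'
#' Runs the sibship-preserving permutation scan of score on 0/1 state for
#' the requested probes, sharing one permutation set across probes.
#'
#' @param state state matrix (samples x probes) for the cohort's samples.
#' @param scores numeric score per sample (NA scores excluded with their
#'   samples).
#' @param family_ids family membership per sample.
#' @param probe_ids probes to test (default: covered probes).
#' @param n_perms permutations.
#' @param seed integer seed.
#' @return data.frame: `probe_id`, `p`, `direction`, `slope`,
#'   `n_informative`, `N`.
#' @export
state_association <- function(state, scores, family_ids,
                              probe_ids = restrict_to_covered(state),
                              n_perms = 1999, seed = 1L) {
  ok <- !is.na(scores)
  X <- state[ok, probe_ids, drop = FALSE]
  res <- permutation_scan(X, scores[ok], family_ids[ok], n_perms, seed)
  data.frame(probe_id = probe_ids, p = res$p, direction = res$direction,
             slope = res$slope, n_informative = res$n_informative,
             N = sum(ok), stringsAsFactors = FALSE)
}

#' Sex-stratified X-chromosome association
#'
#' X probes are tested separately within males and within females (CNV state
#' is sex-aware) and the two strata are combined with the same sample-size
#' weighted z-score scheme used for cross-cohort meta-analysis. A stratum
#' with no variation at a probe is excluded from the combination; probes
#' with both strata excluded are dropped.
#'
#' @param state state matrix over X probes (all samples).
#' @param scores numeric score per sample.
#' @param family_ids family membership per sample.
#' @param sexes "M"/"F" per sample.
#' @param n_perms,seed permutation parameters.
#' @return list with `males`, `females` (per-stratum results) and `combined`
#'   (meta-analyzed across strata).
#' @export
x_association <- function(state, scores, family_ids, sexes, n_perms = 1999,
                          seed = 1L) {
  run_stratum <- function(sel, sd_seed) {
    if (sum(sel & !is.na(scores)) < 4) return(NULL)
    if (length(unique(family_ids[sel & !is.na(scores)])) < 2) return(NULL)
    sub <- state[sel, , drop = FALSE]
    covered <- colnames(sub)[colSums(sub) > 0 &
                               colSums(sub) < sum(sel & !is.na(scores))]
    if (length(covered) == 0) return(NULL)
    state_association(sub, scores[sel], family_ids[sel], covered, n_perms,
                      sd_seed)
  }
  males <- run_stratum(sexes == "M", seed)
  females <- run_stratum(sexes == "F", seed + 1L)
  combined <- meta_analyze(males, females, n_perms = n_perms)
  # probes informative in a single stratum pass through with Z = z_i
  passthrough <- function(res, other) {
    if (is.null(res)) return(NULL)
    only <- if (is.null(other)) res else
      res[!res$probe_id %in% other$probe_id, , drop = FALSE]
    if (nrow(only) == 0) return(NULL)
    z <- ifelse(only$direction == 0, 0,
                only$direction * stats::qnorm(1 - only$p / 2))
    data.frame(probe_id = only$probe_id, Z = z,
               p_meta = 2 * stats::pnorm(-abs(z)), z_a = z, z_b = NA_real_,
               N_a = only$N, N_b = NA_integer_, stringsAsFactors = FALSE)
  }
  combined <- rbind(combined, passthrough(males, females),
                    passthrough(females, males))
  list(males = males, females = females, combined = combined)
}

#' Sample-size weighted meta-analysis of two association result sets
#'
#' Each per-cohort p is converted to a signed z (probit of the two-sided p,
#' signed by the effect direction); the combined statistic is
#' `Z = sum(sqrt(N_i) z_i) / sqrt(sum(N_i))` with a two-sided p. Only probes
#' present in both inputs are meta-analyzed; single-cohort probes stay in
#' the per-cohort outputs but are absent here. Input p of 0 is clamped to
#' `1 / (1 + n_perms)` with a warning.
#'
#' @param res_a,res_b data.frames with `probe_id`, `p`, `direction`, `N`
#'   (either may be NULL/empty -> empty result).
#' @param n_perms permutation count used to clamp p = 0 inputs.
#' @return data.frame: `probe_id`, `Z`, `p_meta`, `z_a`, `z_b`, `N_a`, `N_b`.
#' @export
meta_analyze <- function(res_a, res_b, n_perms = 1999) {
  empty <- data.frame(probe_id = character(0), Z = numeric(0),
                      p_meta = numeric(0), z_a = numeric(0), z_b = numeric(0),
                      N_a = integer(0), N_b = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(res_a) || is.null(res_b) || nrow(res_a) == 0 ||
      nrow(res_b) == 0) {
    return(empty)
  }
  shared <- intersect(res_a$probe_id, res_b$probe_id)
  if (length(shared) == 0) return(empty)
  a <- res_a[match(shared, res_a$probe_id), ]
  b <- res_b[match(shared, res_b$probe_id), ]
  signed_z <- function(p, direction) {
    if (any(p <= 0)) {
      warning("p = 0 input clamped to 1/(1 + n_perms)")
      p[p <= 0] <- 1 / (1 + n_perms)
    }
    ifelse(direction == 0, 0, direction * stats::qnorm(1 - p / 2))
  }
  za <- signed_z(a$p, a$direction)
  zb <- signed_z(b$p, b$direction)
  Z <- (sqrt(a$N) * za + sqrt(b$N) * zb) / sqrt(a$N + b$N)
  data.frame(probe_id = shared, Z = Z, p_meta = 2 * stats::pnorm(-abs(Z)),
             z_a = za, z_b = zb, N_a = a$N, N_b = b$N,
             stringsAsFactors = FALSE)
}

#' Two-tier consecutive-probe region detection
#'
#' A region is a maximal run of consecutive tested probes with
#' `p < flank_p` that (i) contains at least `core_len` consecutive probes
#' with `p < core_p` and (ii) has at least `flank_len` member probes beyond
#' such a core (i.e. run length >= core_len + flank_len). Probes absent from
#' `results` (untested/monomorphic) break runs: a region cannot jump over an
#' untested probe. The default scheme is the CNV-state criterion (two
#' consecutive p < 0.005 plus two or more contiguous p < 0.05); the
#' intensity analysis uses core_p = 0.001.
#'
#' @param results data.frame with `probe_id` and a p-value column.
#' @param probes full probe manifest (`probe_id`, `chrom`, `pos`), sorted.
#' @param core_p,core_len,flank_p,flank_len scheme parameters.
#' @param p_col name of the p-value column in `results`.
#' @return data.frame of regions: `chrom`, `start`, `end`, `n_probes`,
#'   `probe_ids` (comma-separated), `p_min`, `p_max`.
#' @export
detect_regions <- function(results, probes, core_p = 0.005, core_len = 2,
                           flank_p = 0.05, flank_len = 2, p_col = "p") {
  probes <- probes[order(probes$chrom, probes$pos), ]
  p <- results[[p_col]][match(probes$probe_id, results$probe_id)]
  in_run <- !is.na(p) & p < flank_p
  # break runs at chromosome boundaries
  chrom_break <- c(TRUE, probes$chrom[-1] != probes$chrom[-nrow(probes)])
  run_id <- cumsum(!in_run | chrom_break)
  regions <- list()
  for (rid in unique(run_id[in_run])) {
    idx <- which(run_id == rid & in_run)
    if (length(idx) < core_len + flank_len) next
    core <- p[idx] < core_p
    best <- max_run_length(core)
    if (best < core_len) next
    regions[[length(regions) + 1L]] <- data.frame(
      chrom = probes$chrom[idx[1]],
      start = probes$pos[idx[1]],
      end = probes$pos[idx[length(idx)]],
      n_probes = length(idx),
      probe_ids = paste(probes$probe_id[idx], collapse = ","),
      p_min = min(p[idx]), p_max = max(p[idx]),
      stringsAsFactors = FALSE)
  }
  if (length(regions) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      probe_ids = character(0), p_min = numeric(0),
                      p_max = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out
}

max_run_length <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Bonferroni-corrected significance threshold
#'
#' `base_alpha / (n_traits * n_probes)` — the genome-wide threshold for a
#' scan of `n_probes` probes and `n_traits` correlated traits tested.
#'
#' @param base_alpha nominal alpha (default 0.05).
#' @param n_traits,n_probes positive counts.
#' @return corrected alpha.
#' @export
bonferroni_alpha <- function(base_alpha = 0.05, n_traits = 1, n_probes = 1) {
  if (n_traits <= 0 || n_probes <= 0) stop("counts must be positive")
  base_alpha / (n_traits * n_probes)
}

#' CNV+ frequency of a region
#'
#' Percentage of samples that are CNV+ at one or more of the region's
#' probes, plus the per-probe frequency range.
#'
#' @param probe_ids character vector of the region's member probes.
#' @param state 0/1 state matrix (samples x probes).
#' @return list with `percent` (any-probe frequency, %), `per_probe_range`
#'   (min/max per-probe %, length 2).
#' @export
cnv_plus_frequency <- function(probe_ids, state) {
  sub <- state[, probe_ids, drop = FALSE]
  any_plus <- rowSums(sub) > 0
  per_probe <- 100 * colMeans(sub)
  list(percent = 100 * mean(any_plus),
       per_probe_range = range(per_probe))
}
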