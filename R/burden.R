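#' Per-sample CNV burden statistics
#'
#' Counts and summed spans of QC-passing calls per sample, overall or for a
#' class of calls: annotated to genes, annotated to exons, rare, or by length
#' class (short < 100 kb, medium 100-500 kb inclusive, large > 500 kb, on
#' the inclusive bp span). Samples with no qualifying call get (0, 0).
#'
#' @param calls annotated calls (columns `genes`, `exonic`, `rare` required
#'   for the corresponding classes).
#' @param sample_ids all sample ids to report (zero rows included).
#' @param class one of "all", "gene", "exon", "rare", "short", "medium",
#'   "large".
#' @param short_kb,large_kb length-class boundaries in kb.
#' @return data.frame with `sample_id`, `class`, `n_events`,
#'   `total_length_bp`.
#' @export
compute_burden <- function(calls, sample_ids, class = "all",
                           short_kb = 100, large_kb = 500) {
  span <- interval_span(calls$start, calls$end)
  keep <- switch(class,
                 all = rep(TRUE, nrow(calls)),
                 gene = calls$genes != "",
                 exon = calls$exonic,
                 rare = calls$rare,
                 short = span < short_kb * 1000,
                 medium = span >= short_kb * 1000 & span <= large_kb * 1000,
                 large = span > large_kb * 1000,
                 stop("unknown burden class: ", class))
  sub <- calls[keep, , drop = FALSE]
  f <- factor(sub$sample_id, levels = sample_ids)
  data.frame(sample_id = sample_ids, class = class,
             n_events = as.integer(table(f)),
             total_length_bp = as.numeric(tapply(
               as.numeric(interval_span(sub$start, sub$end)), f, sum,
               default = 0)),
             stringsAsFactors = FALSE)
}

resample_one_per_family <- function(family_ids) {
  idx <- unlist(lapply(split(seq_along(family_ids), family_ids),
                       function(i) if (length(i) == 1) i else sample(i, 1)),
                use.names = FALSE)
  sort(idx)
}

#' Burden-score correlation with one-per-sibship resampling
#'
#' For each of `n_resamples` draws, one individual is sampled uniformly from
#' every sibship and the rank correlation (Spearman rho by default) between
#' the burden measure and the score is computed on that unrelated subset;
#' the median rho and median p over draws are reported. This avoids bias
#' from sample relatedness and from non-normal burden distributions.
#'
#' @param burden numeric burden measure per sample.
#' @param scores numeric score per sample.
#' @param family_ids family membership per sample.
#' @param n_resamples number of resampling draws (default 100).
#' @param seed integer seed.
#' @param method "spearman" (default) or "pearson".
#' @return list with `rho` (median), `p` (median), `rho_draws`, `p_draws`,
#'   `n_resamples`, `n_per_draw`.
#' @export
resampled_correlation <- function(burden, scores, family_ids,
                                  n_resamples = 100, seed = 1L,
                                  method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(burden) == length(scores),
            length(family_ids) == length(scores))
  if (length(unique(family_ids)) < 3) stop("need >= 3 families")
  set.seed(seed)
  rho <- p <- numeric(n_resamples)
  npd <- integer(n_resamples)
  for (k in seq_len(n_resamples)) {
    idx <- resample_one_per_family(family_ids)
    ok <- idx[!is.na(burden[idx]) & !is.na(scores[idx])]
    npd[k] <- length(ok)
    if (length(ok) < 3 || stats::sd(burden[ok]) == 0 ||
        stats::sd(scores[ok]) == 0) {
      rho[k] <- 0
      p[k] <- 1
      next
    }
    ct <- suppressWarnings(stats::cor.test(burden[ok], scores[ok],
                                           method = method, exact = FALSE))
    rho[k] <- unname(ct$estimate)
    p[k] <- ct$p.value
  }
  list(rho = stats::median(rho), p = stats::median(p), rho_draws = rho,
       p_draws = p, n_resamples = n_resamples,
       n_per_draw = as.integer(stats::median(npd)))
}

#' Case/control burden association with one-per-sibship resampling
#'
#' Per draw, one individual per sibship is retained; draws without at least
#' one case and one control are redrawn (up to `max_retry` extra attempts).
#' Affection status (case = 1, control = 0; "neither" excluded) is regressed
#' on the burden measure by logistic regression; the median odds ratio and
#' median Wald p over draws are reported. Draws with complete separation or
#' non-converged fits are excluded and counted.
#'
#' @param burden numeric burden measure per sample.
#' @param labels character labels in {"case", "control", "neither"}.
#' @param family_ids family membership per sample.
#' @param n_resamples number of resampling draws.
#' @param seed integer seed.
#' @param max_retry redraw budget per draw.
#' @return list with `odds_ratio` (median), `p` (median), `n_excluded`
#'   (separated/failed draws), `n_resamples`.
#' @export
case_control_burden <- function(burden, labels, family_ids,
                                n_resamples = 100, seed = 1L,
                                max_retry = 50) {
  stopifnot(length(burden) == length(labels))
  set.seed(seed)
  or <- p <- rep(NA_real_, n_resamples)
  excluded <- 0L
  for (k in seq_len(n_resamples)) {
    for (try in seq_len(max_retry)) {
      idx <- resample_one_per_family(family_ids)
      idx <- idx[labels[idx] %in% c("case", "control") & !is.na(burden[idx])]
      y <- as.integer(labels[idx] == "case")
      if (length(unique(y)) == 2) break
    }
    if (length(unique(y)) < 2) {
      excluded <- excluded + 1L
      next
    }
    x <- burden[idx]
    if (stats::sd(x) == 0) {      # degenerate covariate
      or[k] <- 1
      p[k] <- 1
      next
    }
    x <- as.vector(scale(x))      # OR reported per SD of the burden measure
    fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
    co <- summary(fit)$coefficients
    separated <- !fit$converged || abs(co["x", "Estimate"]) > 15 ||
      co["x", "Std. Error"] > 1e3
    if (separated) {
      excluded <- excluded + 1L
      next
    }
    or[k] <- exp(co["x", "Estimate"])
    p[k] <- co["x", "Pr(>|z|)"]
  }
  list(odds_ratio = stats::median(or, na.rm = TRUE),
       p = stats::median(p, na.rm = TRUE), n_excluded = excluded,
       n_resamples = n_resamples)
}
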