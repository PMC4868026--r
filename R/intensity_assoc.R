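#' PCA of the LRR intensity matrix
#'
#' SVD-based principal components of the sample-centered LRR matrix (probes
#' with any missing value dropped). Component scores per sample are used
#' both as batch-effect covariates (first two, by default) and for outlier
#' screening.
#'
#' @param lrr samples x probes numeric matrix.
#' @param K number of components to extract (default `min(100, n - 1)`).
#' @return list with `scores` (samples x K), `sdev`,
#'   `variance_explained` (length K fractions).
#' @export
lrr_pca <- function(lrr, K = NULL) {
  n <- nrow(lrr)
  if (n < 3) stop("need >= 3 samples for LRR PCA")
  keep <- colSums(is.na(lrr)) == 0
  lrr <- lrr[, keep, drop = FALSE]
  if (is.null(K)) K <- min(100L, n - 1L)
  K <- min(K, n - 1L, ncol(lrr))
  pc <- stats::prcomp(lrr, center = TRUE, scale. = FALSE, rank. = K)
  ev <- pc$sdev^2
  list(scores = pc$x[, seq_len(K), drop = FALSE], sdev = pc$sdev,
       variance_explained = (ev / sum(ev))[seq_len(K)])
}

#' Flag LRR outlier samples
#'
#' Default rule: a sample is an outlier when its score on any of the first
#' `n_comp` components exceeds `n_mad` median-absolute-deviations (scaled)
#' from the component median.
#'
#' @param model result of [lrr_pca()].
#' @param n_mad MAD multiple (default 6).
#' @param n_comp number of leading components screened (default 2).
#' @return logical vector, one per sample.
#' @export
flag_lrr_outliers <- function(model, n_mad = 6, n_comp = 2) {
  sc <- model$scores[, seq_len(min(n_comp, ncol(model$scores))),
                     drop = FALSE]
  flags <- rep(FALSE, nrow(sc))
  for (j in seq_len(ncol(sc))) {
    m <- stats::mad(sc[, j])
    if (m == 0) next
    flags <- flags | abs(sc[, j] - stats::median(sc[, j])) > n_mad * m
  }
  flags
}

#' Probe-wise LRR intensity association in one cohort
#'
#' The dosage-sensitive complement of the binary state test: the score is
#' first residualized on the covariates (LRR principal components 1-2 by
#' default), then each probe's LRR column is tested against the residualized
#' score with the sibship-preserving permutation scan. The rank correlation
#' of LRR with the (unresidualized) score is reported as the effect
#' surrogate giving the direction of association. Zero-variance LRR probes
#' are untested (dropped from the output).
#'
#' @param lrr samples x probes matrix for the cohort (outliers already
#'   excluded).
#' @param scores numeric score per sample.
#' @param covariates matrix of covariates (e.g. LRR PCs), or NULL.
#' @param family_ids family membership per sample.
#' @param probe_ids probes to test (default: all columns).
#' @param n_perms,seed permutation parameters.
#' @return data.frame: `probe_id`, `p`, `rho_lrr`, `direction`, `N`.
#' @export
intensity_association <- function(lrr, scores, covariates = NULL, family_ids,
                                  probe_ids = colnames(lrr), n_perms = 1999,
                                  seed = 1L) {
  ok <- !is.na(scores)
  y <- scores[ok]
  X <- lrr[ok, probe_ids, drop = FALSE]
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)[ok, , drop = FALSE]
    y <- stats::lm.fit(cbind(1, cv), y)$residuals
  }
  sds <- apply(X, 2, stats::sd)
  testable <- sds > 0
  X <- X[, testable, drop = FALSE]
  res <- permutation_scan(X, y, family_ids[ok], n_perms, seed)
  rho <- suppressWarnings(
    as.vector(stats::cor(apply(X, 2, rank), rank(scores[ok]),
                         method = "pearson")))
  data.frame(probe_id = probe_ids[testable], p = res$p, rho_lrr = rho,
             direction = sign(rho), N = sum(ok), stringsAsFactors = FALSE)
}

#' Region detection for the intensity analysis
#'
#' Same engine as [detect_regions()] with the intensity scheme: pairs of
#' consecutive probes with p < 0.001, contiguous with two or more probes
#' with p < 0.05.
#'
#' @param results intensity association results (`probe_id`, `p`).
#' @param probes probe manifest.
#' @param p_col p-value column name.
#' @return regions data.frame (see [detect_regions()]).
#' @export
detect_intensity_regions <- function(results, probes, p_col = "p") {
  detect_regions(results, probes, core_p = 0.001, core_len = 2,
                 flank_p = 0.05, flank_len = 2, p_col = p_col)
}
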