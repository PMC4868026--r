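#' Derive the first principal component of reading/language traits
#'
#' PCA on the correlation matrix of the trait battery (traits enter
#' standardized), complete cases only — samples with any missing trait are
#' excluded and receive NA scores. Only the first component is used
#' downstream; its sign is oriented so the first trait's loading is positive
#' (principal components are sign-ambiguous). Scores are standardized to
#' unit variance. Loadings are reported on the correlation scale
#' (eigenvector times singular value), i.e. the correlation of each trait
#' with the component.
#'
#' @param traits data.frame or matrix of trait scores (samples x traits).
#' @param trait_cols columns to enter the PCA (default: all columns).
#' @return list with `scores` (length nrow(traits), NA for incomplete cases),
#'   `variance_explained` (fraction in (0, 1]), `loadings` (named numeric),
#'   `n_complete`.
#' @export
derive_pc1 <- function(traits, trait_cols = colnames(traits)) {
  x <- as.matrix(as.data.frame(traits)[, trait_cols, drop = FALSE])
  storage.mode(x) <- "double"
  complete <- stats::complete.cases(x)
  if (sum(complete) < 2) stop("need >= 2 complete-case samples for PCA")
  xc <- x[complete, , drop = FALSE]
  sds <- apply(xc, 2, stats::sd)
  constant <- sds == 0
  if (all(constant)) stop("all traits are constant")
  pc <- stats::prcomp(xc[, !constant, drop = FALSE], center = TRUE,
                      scale. = TRUE)
  ev <- pc$sdev^2
  scores1 <- pc$x[, 1]
  load1 <- pc$rotation[, 1] * pc$sdev[1]
  if (load1[1] < 0) {
    scores1 <- -scores1
    load1 <- -load1
  }
  s <- stats::sd(scores1)
  if (s > 0) scores1 <- scores1 / s
  out <- rep(NA_real_, nrow(x))
  out[complete] <- scores1
  loadings <- stats::setNames(rep(NA_real_, length(trait_cols)), trait_cols)
  loadings[names(load1)] <- load1
  list(scores = out, variance_explained = ev[1] / sum(ev),
       loadings = loadings, n_complete = sum(complete))
}

#' IQ-adjust a composite score
#'
#' Residuals of an ordinary least-squares regression of the score on
#' performance IQ (intercept included). Samples with either value missing get
#' NA. By OLS orthogonality the residuals are uncorrelated with PIQ, and the
#' adjustment is idempotent.
#'
#' @param pc1 numeric composite score.
#' @param piq numeric performance IQ, same length.
#' @return numeric vector of residuals (NA where input missing).
#' @export
adjust_for_iq <- function(pc1, piq) {
  stopifnot(length(pc1) == length(piq))
  ok <- !is.na(pc1) & !is.na(piq)
  if (sum(ok) < 3) stop("need >= 3 paired non-missing values")
  if (stats::sd(piq[ok]) == 0) stop("PIQ is constant; regression degenerate")
  fit <- stats::lm.fit(cbind(1, piq[ok]), pc1[ok])
  out <- rep(NA_real_, length(pc1))
  out[ok] <- fit$residuals
  out
}

#' Assign case/control labels from a discriminant score
#'
#' In `"decile"` mode, samples at or below the 10th percentile are labeled
#' "case" (poor performance) and at or above the 90th percentile "control"
#' (good performance); ties at the boundary are included in the extreme
#' group. In `"threshold"` mode fixed cutoffs are applied (score strictly
#' below the lower cutoff: case; strictly above the upper: control).
#' Degenerate distributions (both percentile boundaries equal) yield all
#' "neither".
#'
#' @param scores numeric discriminant scores (lower = poorer performance).
#' @param mode `"decile"` or `"threshold"`.
#' @param probs percentile pair for decile mode.
#' @param thresholds cutoff pair (lower, upper) for threshold mode.
#' @return character vector in {"case", "control", "neither"} (NA scores map
#'   to "neither").
#' @export
assign_case_control <- function(scores, mode = c("decile", "threshold"),
                                probs = c(0.1, 0.9),
                                thresholds = c(-1.4, 2.2)) {
  mode <- match.arg(mode)
  labels <- rep("neither", length(scores))
  if (mode == "decile") {
    if (sum(!is.na(scores)) < 10) stop("need >= 10 scores for decile mode")
    qs <- stats::quantile(scores, probs, na.rm = TRUE, names = FALSE)
    if (qs[1] >= qs[2]) return(labels)
    labels[!is.na(scores) & scores <= qs[1]] <- "case"
    labels[!is.na(scores) & scores >= qs[2]] <- "control"
  } else {
    labels[!is.na(scores) & scores < thresholds[1]] <- "case"
    labels[!is.na(scores) & scores > thresholds[2]] <- "control"
  }
  labels
}

#' Derive composite phenotypes per cohort
#'
#' Runs [derive_pc1()] separately within each cohort (trait correlation
#' structure may differ between recruitment arms), then [adjust_for_iq()],
#' and assigns case/control labels from the discriminant score over the whole
#' dataset.
#'
#' @param pheno phenotype table with trait columns, `PIQ`, `IBGdiscr`.
#' @param samples samples table with `sample_id`, `cohort`.
#' @param trait_cols trait columns entering the PCA.
#' @param case_mode passed to [assign_case_control()].
#' @return `pheno` with added columns `PC1`, `IQadjPC1`, `label`; per-cohort
#'   PCA summaries attached as attribute `"pca"`.
#' @export
derive_phenotypes <- function(pheno, samples,
                              trait_cols = c("WRead", "WSpell", "PD", "PA",
                                             "OC", "NWR"),
                              case_mode = "decile") {
  stopifnot(all(pheno$sample_id == samples$sample_id))
  pheno$PC1 <- NA_real_
  pca_info <- list()
  for (ch in unique(samples$cohort)) {
    idx <- which(samples$cohort == ch)
    res <- derive_pc1(pheno[idx, ], trait_cols)
    pheno$PC1[idx] <- res$scores
    pca_info[[ch]] <- res[c("variance_explained", "loadings", "n_complete")]
  }
  pheno$IQadjPC1 <- NA_real_
  for (ch in unique(samples$cohort)) {
    idx <- which(samples$cohort == ch)
    pheno$IQadjPC1[idx] <- adjust_for_iq(pheno$PC1[idx], pheno$PIQ[idx])
  }
  pheno$label <- assign_case_control(pheno$IBGdiscr, mode = case_mode)
  attr(pheno, "pca") <- pca_info
  pheno
}
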