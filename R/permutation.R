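#' Build sibship-preserving permutations
#'
#' Each permutation (a column of the returned index matrix) rearranges the
#' phenotype vector while preserving sibship structure: whole per-family
#' score blocks are shuffled across families of equal size, and member order
#' is shuffled within each family. Singleton families are permuted among
#' themselves. Applying a column `k` as `y[P[, k]]` yields one null score
#' vector.
#'
#' @param family_ids character/factor of family membership, one per sample.
#' @param n_perms number of permutations.
#' @param seed integer seed.
#' @return integer matrix (n_samples x n_perms) of permuted indices.
#' @export
make_family_permutations <- function(family_ids, n_perms, seed = 1L) {
  set.seed(seed)
  fam <- split(seq_along(family_ids), family_ids)
  if (length(fam) < 2) stop("need >= 2 families to permute")
  sizes <- lengths(fam)
  by_size <- split(fam, sizes)
  n <- length(family_ids)
  K <- as.integer(n_perms)
  P <- matrix(0L, n, K)
  # vectorized construction: uniform permutations are drawn by ordering
  # random keys within (perm) and (perm, family) strata
  for (grp in by_size) {
    m <- length(grp)
    s <- length(grp[[1]])
    G <- matrix(unlist(grp), s, m)
    # block order of families, one permutation of 1:m per column (perm)
    bo <- matrix(order(rep(seq_len(K), each = m), stats::runif(m * K)),
                 m, K) - (rep(seq_len(K), each = m) - 1L) * m
    # within-family member order, one permutation of 1:s per (perm, family)
    wo <- matrix(order(rep(seq_len(m * K), each = s),
                       stats::runif(s * m * K)),
                 s, m * K) - (rep(seq_len(m * K), each = s) - 1L) * s
    src <- G[cbind(as.vector(wo), rep(as.vector(bo), each = s))]
    P[as.vector(G), ] <- matrix(src, s * m, K)
  }
  P
}

#' Permutation association scan of many predictors against one score
#'
#' For each column of `X` (a binary CNV state or a continuous intensity),
#' the observed statistic is the OLS slope of `y` on that column; the null
#' distribution permutes `y` by sibship-preserving permutations (shared
#' across columns). Because permutation leaves `mean(y)` and the per-column
#' variance of `X` unchanged, slopes are compared through their centered
#' cross-products. The p-value is `(1 + #{|b_perm| >= |b_obs|}) / (1 +
#' n_perms)`.
#'
#' @param X numeric matrix (samples x predictors); zero-variance columns get
#'   p = 1 and direction 0.
#' @param y numeric score vector.
#' @param family_ids family membership per sample.
#' @param n_perms number of permutations.
#' @param seed integer seed.
#' @param perms optional pre-built permutation matrix (overrides
#'   `n_perms`/`seed`).
#' @param chunk predictors processed per block (memory control).
#' @return data.frame with one row per column of `X`: `slope`, `p`,
#'   `direction` (+1/-1/0), `n_informative`.
#' @export
permutation_scan <- function(X, y, family_ids, n_perms = 1000, seed = 1L,
                             perms = NULL, chunk = 2000L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), length(family_ids) == length(y))
  if (is.null(perms)) {
    perms <- make_family_permutations(family_ids, n_perms, seed)
  }
  n_perms <- ncol(perms)
  n <- length(y)
  Yp <- matrix(y[perms], nrow = n)
  my <- mean(y)
  p_out <- numeric(ncol(X))
  slope <- numeric(ncol(X))
  ninf <- integer(ncol(X))
  for (b in seq(1, ncol(X), by = chunk)) {
    cols <- b:min(b + chunk - 1L, ncol(X))
    Xb <- X[, cols, drop = FALSE]
    sx <- colSums(Xb)
    sxx <- colSums(Xb^2) - sx^2 / n
    num_obs <- as.vector(crossprod(Xb, y)) - sx * my
    num_perm <- crossprod(Xb, Yp) - sx * my      # column recycling over perms
    tol <- 1e-8 * (abs(num_obs) + 1)
    exceed <- rowSums(abs(num_perm) >= abs(num_obs) - tol)
    pvals <- (1 + exceed) / (1 + n_perms)
    mono <- sxx <= 0
    pvals[mono] <- 1
    slope[cols] <- ifelse(mono, 0, num_obs / pmax(sxx, .Machine$double.eps))
    p_out[cols] <- pvals
    ninf[cols] <- colSums(Xb != matrix(Xb[1, ], n, length(cols),
                                       byrow = TRUE)) + ifelse(mono, 0, 1)
  }
  direction <- sign(slope)
  direction[p_out == 1 & slope == 0] <- 0
  data.frame(slope = slope, p = p_out, direction = direction,
             n_informative = ninf)
}

#' Family-aware permutation test for a single probe
#'
#' Single-predictor interface over the same engine as [permutation_scan()],
#' with optional adaptive early stopping: permutations are drawn in batches
#' and the test stops once at least `min_exceed` null statistics have reached
#' the observed one (the p estimate is then already stable).
#'
#' @param state numeric vector (e.g. 0/1 CNV state).
#' @param scores numeric score vector.
#' @param family_ids family membership per sample.
#' @param n_perms maximum number of permutations.
#' @param seed integer seed.
#' @param adaptive logical; stop early once `min_exceed` exceedances.
#' @param min_exceed exceedance target for early stopping.
#' @return list with `p`, `slope`, `direction`, `n_perms_used`,
#'   `n_informative`, `N`.
#' @export
family_permutation_test <- function(state, scores, family_ids,
                                    n_perms = 10000, seed = 1L,
                                    adaptive = TRUE, min_exceed = 100) {
  stopifnot(length(state) == length(scores))
  n <- length(scores)
  if (stats::var(state) == 0) {
    return(list(p = 1, slope = 0, direction = 0, n_perms_used = 0L,
                n_informative = 0L, N = n))
  }
  sx <- sum(state)
  sxx <- sum(state^2) - sx^2 / n
  my <- mean(scores)
  num_obs <- sum(state * scores) - sx * my
  tol <- 1e-8 * (abs(num_obs) + 1)
  batch <- if (adaptive) 500L else n_perms
  done <- 0L
  exceed <- 0L
  k <- 0L
  while (done < n_perms) {
    nb <- min(batch, n_perms - done)
    P <- make_family_permutations(family_ids, nb, seed + k)
    num_perm <- as.vector(crossprod(matrix(state, ncol = 1),
                                    matrix(scores[P], nrow = n))) - sx * my
    exceed <- exceed + sum(abs(num_perm) >= abs(num_obs) - tol)
    done <- done + nb
    k <- k + 1L
    if (adaptive && exceed >= min_exceed) break
  }
  slope <- num_obs / sxx
  list(p = (1 + exceed) / (1 + done), slope = slope,
       direction = sign(slope), n_perms_used = done,
       n_informative = sum(state != state[1]) + 1L, N = n)
}
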