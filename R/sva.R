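#' Surrogate-variable batch correction
#'
#' Removes non-biological variation (e.g. batch effects) from a transformed
#' feature matrix with a two-step surrogate-variable estimate:
#'
#' 1. Each feature is residualised on the accession (group) means. The top
#'    right-singular vectors of the residual matrix are the surrogate
#'    variable candidates; because the residuals are orthogonal to the group
#'    design, so are the surrogates.
#' 2. The number of surrogates `k` is chosen by a permutation test on the
#'    singular values (each feature's residuals permuted independently,
#'    `B` permutations; components are kept while their singular value
#'    exceeds the permutation `1 - alpha` quantile, stopping at the first
#'    failure), or fixed via `n_sv`.
#'
#' Each feature is then regressed on accession plus surrogates and the
#' surrogate contribution is subtracted.
#'
#' @inheritParams feature_matrix
#' @param n_sv `"auto"` for the permutation test, or a fixed integer >= 0.
#' @param B Number of permutations for the automatic choice (default 100).
#' @param alpha Significance level of the permutation test (default 0.05).
#' @return The corrected feature tibble, with attributes `n_sv` (chosen k)
#'   and `surrogates` (samples x k matrix).
#' @export
sva_correct <- function(features, samples, n_sv = "auto", B = 100,
                        alpha = 0.05) {
  validate_feature_matrix(features, samples, transformed = TRUE)
  m <- intensity_matrix(features)
  acc <- samples$accession[match(colnames(m), samples$sample_id)]
  if (length(unique(acc)) < 2) stop("need at least 2 accessions")
  resid <- residualize_on_groups(m, acc)
  max_k <- ncol(m) - length(unique(acc))
  if (identical(n_sv, "auto")) {
    k <- choose_n_sv(resid, B = B, alpha = alpha)
  } else {
    k <- as.integer(n_sv)
  }
  if (k >= ncol(m) - length(unique(acc)) + 1 || k > max_k) {
    stop("n_sv must be smaller than n_samples - n_accessions")
  }
  if (k == 0) {
    out <- features
    attr(out, "n_sv") <- 0L
    attr(out, "surrogates") <- matrix(numeric(0), nrow = ncol(m), ncol = 0)
    return(out)
  }
  sv <- svd(resid, nu = 0, nv = k)$v  # samples x k, orthonormal, orth. to groups
  corrected <- m - (m %*% sv) %*% t(sv)
  out <- set_intensities(features, corrected)
  attr(out, "n_sv") <- k
  attr(out, "surrogates") <- sv
  out
}

# Subtract group means from each feature (row-wise residualisation on the
# one-way accession design).
residualize_on_groups <- function(m, groups) {
  g <- factor(groups)
  means <- t(apply(m, 1, function(x) tapply(x, g, mean)[as.character(g)]))
  m - means
}

# Permutation test on singular values of the residual matrix: permute each
# row independently, recompute singular values, keep leading components
# whose observed singular value beats the permutation (1 - alpha) quantile,
# stopping at the first non-significant component.
choose_n_sv <- function(resid, B = 100, alpha = 0.05) {
  d_obs <- svd(resid, nu = 0, nv = 0)$d
  n <- ncol(resid)
  perm_d <- matrix(0, nrow = B, ncol = length(d_obs))
  for (b in seq_len(B)) {
    perm <- t(apply(resid, 1, sample))
    perm_d[b, ] <- svd(perm, nu = 0, nv = 0)$d
  }
  thresh <- apply(perm_d, 2, stats::quantile, probs = 1 - alpha)
  sig <- d_obs > thresh
  k <- 0L
  for (i in seq_along(sig)) {
    if (!sig[i]) break
    k <- i
  }
  k
}
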