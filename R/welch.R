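#' Welch heteroscedastic one-way ANOVA
#'
#' The generalised Welch test for equality of group means under unequal
#' variances. With group sizes \eqn{n_i}, means \eqn{\bar x_i} and variances
#' \eqn{s_i^2}, let \eqn{w_i = n_i/s_i^2}, \eqn{W = \sum w_i},
#' \eqn{\bar x_w = \sum w_i \bar x_i / W} and
#' \eqn{\Lambda = \sum (1 - w_i/W)^2/(n_i - 1) / (k^2 - 1)}. The statistic is
#' \deqn{F^* = \frac{\sum w_i (\bar x_i - \bar x_w)^2 / (k-1)}
#'                  {1 + 2(k-2)\Lambda},}
#' referred to an F distribution with \eqn{k - 1} and \eqn{1/(3\Lambda)}
#' degrees of freedom. For \eqn{k = 2} the statistic equals the squared
#' two-sample Welch t statistic.
#'
#' @param data A data frame with one value column and one grouping column,
#'   or a list of numeric vectors (one per group).
#' @param value,group Column names (strings) when `data` is a data frame.
#' @return A one-row tibble with `statistic`, `df1`, `df2` and `p`.
#' @examples
#' welch_anova(list(a = c(1, 2, 3), b = c(2, 3, 5), c = c(9, 7, 8)))
#' @export
welch_anova <- function(data, value = "value", group = "group") {
  groups <- as_group_list(data, value, group)
  k <- length(groups)
  if (k < 2) stop("welch_anova needs at least 2 groups")
  n <- vapply(groups, base::length, integer(1))
  if (any(n < 2)) {
    stop("group(s) with fewer than 2 values: ",
         paste(names(groups)[n < 2], collapse = ", "))
  }
  s2 <- vapply(groups, stats::var, numeric(1))
  if (any(s2 <= 0)) {
    stop("group(s) with zero variance: ",
         paste(names(groups)[s2 <= 0], collapse = ", "))
  }
  xbar <- vapply(groups, mean, numeric(1))
  w <- n / s2
  W <- sum(w)
  xw <- sum(w * xbar) / W
  lambda <- sum((1 - w / W)^2 / (n - 1)) / (k^2 - 1)
  fstat <- (sum(w * (xbar - xw)^2) / (k - 1)) / (1 + 2 * (k - 2) * lambda)
  df1 <- k - 1
  df2 <- 1 / (3 * lambda)
  tibble::tibble(
    statistic = fstat, df1 = df1, df2 = df2,
    p = stats::pf(fstat, df1, df2, lower.tail = FALSE)
  )
}

#' Two-sample Welch t test
#'
#' Standard Welch t with Welch–Satterthwaite degrees of freedom and a
#' two-sided p-value; used as the post-hoc accession-vs-blank test.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return A one-row tibble with `statistic` (t), `df` and `p`.
#' @export
welch_two_sample <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("welch_two_sample needs at least 2 values per group")
  }
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  if (va + vb <= 0) {
    # both groups constant: no evidence of a difference unless means differ,
    # in which case the statistic is infinite
    tstat <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
    return(tibble::tibble(statistic = tstat, df = length(a) + length(b) - 2,
                          p = if (is.finite(tstat)) 1 else 0))
  }
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  tibble::tibble(statistic = tstat, df = df,
                 p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE))
}

#' Benjamini–Hochberg adjustment
#'
#' Step-up FDR adjustment; a thin validating wrapper around
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Welch-ANOVA screen for differential metabolites
#'
#' Runs the Welch heteroscedastic one-way test per feature (row) across
#' accessions, adjusts with Benjamini–Hochberg, and flags the significant
#' set. Intended for log-transformed, z-scaled peak areas.
#'
#' @inheritParams feature_matrix
#' @param alpha FDR level for the `significant` flag (default 0.05).
#' @param exclude_blanks Drop blank samples before testing (default TRUE).
#' @return A tibble with one row per feature: `feature_id`, `statistic`,
#'   `df1`, `df2`, `p`, `p_adj`, `significant`.
#' @export
differential_metabolites <- function(features, samples, alpha = 0.05,
                                     exclude_blanks = TRUE) {
  validate_feature_matrix(features, samples, transformed = TRUE)
  keep <- if (exclude_blanks) samples$sample_id[!samples$is_blank] else samples$sample_id
  m <- intensity_matrix(features)[, keep, drop = FALSE]
  acc <- samples$accession[match(keep, samples$sample_id)]
  res <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    welch_anova(split(m[i, ], acc))
  })
  res <- dplyr::mutate(res,
    feature_id = features$feature_id,
    p_adj = bh_adjust(.data$p),
    significant = .data$p_adj < alpha,
    .before = 1
  )
  res
}

# Screening-context Welch ANOVA returning only the p-value. Groups whose
# values are exactly constant (an artifact of half-minimum imputation, which
# fills every censored replicate of a group with the same number) get their
# zero variance floored at the smallest positive group variance so the
# statistic stays defined; with no positive variance anywhere the feature is
# fully degenerate (p = 1 when all means agree, 0 otherwise).
welch_anova_p <- function(values, groups) {
  xs <- split(values, groups)
  n <- vapply(xs, base::length, integer(1))
  xs <- xs[n >= 2]
  n <- n[n >= 2]
  k <- length(xs)
  if (k < 2) return(NA_real_)
  xbar <- vapply(xs, mean, numeric(1))
  s2 <- vapply(xs, stats::var, numeric(1))
  if (all(s2 <= 0)) return(if (max(xbar) - min(xbar) == 0) 1 else 0)
  s2[s2 <= 0] <- min(s2[s2 > 0])
  w <- n / s2
  W <- sum(w)
  xw <- sum(w * xbar) / W
  lambda <- sum((1 - w / W)^2 / (n - 1)) / (k^2 - 1)
  fstat <- (sum(w * (xbar - xw)^2) / (k - 1)) / (1 + 2 * (k - 2) * lambda)
  stats::pf(fstat, k - 1, 1 / (3 * lambda), lower.tail = FALSE)
}

# fast numeric-only two-sample Welch p (same degeneracy handling)
welch_t_p <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  if (va + vb <= 0) return(if (mean(a) == mean(b)) 1 else 0)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
}

# Coerce a data frame (value/group columns) or a list of vectors into a
# named list of numeric vectors, dropping NAs.
as_group_list <- function(data, value, group) {
  if (is.data.frame(data)) {
    groups <- split(data[[value]], data[[group]])
  } else if (is.list(data)) {
    groups <- data
    if (is.null(names(groups))) names(groups) <- seq_along(groups)
  } else {
    stop("data must be a data frame or a list of numeric vectors")
  }
  lapply(groups, function(x) x[!is.na(x)])
}
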