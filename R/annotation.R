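#' Isotope annotation of co-eluting features
#'
#' A simplified stand-in for full adduct/isotope annotation: features are
#' first grouped by retention time (single linkage, [group_coeluting()]),
#' then isotope relations are detected inside each group
#' ([detect_isotopes()]) from the characteristic 1.00336 Da spacing, an
#' intensity-ratio window and per-sample intensity correlation. The head of
#' a detected isotope series is the monoisotopic peak \[M\]; the
#' [monoisotopic_filter()] reduces a feature set to such heads (strict
#' policy) or to heads plus unrelated singletons (permissive).
#'
#' @name annotation
NULL

ISOTOPE_DELTA <- 1.00336  # Da, 13C - 12C spacing

#' Group features that co-elute
#'
#' Single-linkage grouping of features whose retention times differ by at
#' most `rt_tol`.
#'
#' @inheritParams feature_matrix
#' @param rt_tol Retention-time tolerance in minutes (default 0.05).
#' @return The feature tibble with an added integer `group_id` column
#'   (groups numbered in RT order).
#' @export
group_coeluting <- function(features, rt_tol = 0.05) {
  ord <- order(features$rt)
  rt <- features$rt[ord]
  gid <- integer(length(rt))
  g <- 0L
  for (i in seq_along(rt)) {
    if (i == 1 || rt[i] - rt[i - 1] > rt_tol) g <- g + 1L
    gid[i] <- g
  }
  out <- features
  out$group_id <- NA_integer_
  out$group_id[ord] <- gid
  out
}

#' Detect isotope relations within co-elution groups
#'
#' Within each group, feature B is the `k`-th isotope of A when
#' `mz(B) - mz(A)` is within `ppm_tol` of `k * 1.00336 / z` for a charge
#' `z <= max_charge`, the mean intensity ratio B/A lies in
#' `[min_ratio, max_ratio]`, and the per-sample intensity correlation is at
#' least `min_cor`. Chains extend greedily from each unclaimed head in
#' ascending m/z order; the head becomes `monoisotopic`, its partners
#' `isotope_k`, everything else `unassigned`.
#'
#' @inheritParams feature_matrix
#' @param rt_tol Retention-time tolerance passed to [group_coeluting()] when
#'   `group_id` is absent.
#' @param ppm_tol Mass tolerance in ppm (default 20).
#' @param max_charge Maximum charge state considered (default 2).
#' @param min_ratio,max_ratio Allowed mean intensity ratio of an isotope to
#'   its parent (defaults 0.02 and 0.8).
#' @param min_cor Minimum per-sample intensity correlation (default 0.8).
#' @return A tibble `feature_id`, `group_id`, `isotope_role`
#'   (`"monoisotopic"`, `"isotope_k"`, `"unassigned"`), `monoisotopic`
#'   (logical), `parent_id`.
#' @export
detect_isotopes <- function(features, rt_tol = 0.05, ppm_tol = 20,
                            max_charge = 2, min_ratio = 0.02, max_ratio = 0.8,
                            min_cor = 0.8) {
  if (!"group_id" %in% names(features)) {
    features <- group_coeluting(features, rt_tol = rt_tol)
  }
  m <- intensity_matrix(features)
  res <- purrr::map_dfr(split(seq_len(nrow(features)), features$group_id),
                        function(idx) {
    annotate_group(features[idx, , drop = FALSE], m[idx, , drop = FALSE],
                   ppm_tol = ppm_tol, max_charge = max_charge,
                   min_ratio = min_ratio, max_ratio = max_ratio,
                   min_cor = min_cor)
  })
  res[match(features$feature_id, res$feature_id), ]
}

annotate_group <- function(feats, m, ppm_tol, max_charge, min_ratio,
                           max_ratio, min_cor) {
  n <- nrow(feats)
  role <- rep("unassigned", n)
  parent <- rep(NA_character_, n)
  if (n >= 2) {
    ord <- order(feats$mz)
    mean_int <- rowMeans(m, na.rm = TRUE)
    claimed <- rep(FALSE, n)
    for (hi in ord) {
      if (claimed[hi]) next
      chain <- hi
      for (z in seq_len(max_charge)) {
        k <- 1L
        current <- hi
        repeat {
          target <- feats$mz[hi] + k * ISOTOPE_DELTA / z
          tol <- target * ppm_tol / 1e6
          cand <- which(!claimed & seq_len(n) != hi &
                          abs(feats$mz - target) <= tol)
          cand <- cand[vapply(cand, function(ci) {
            ratio <- mean_int[ci] / mean_int[current]
            ok_ratio <- is.finite(ratio) && ratio >= min_ratio &&
              ratio <= max_ratio
            ok_ratio && isotope_cor(m[current, ], m[ci, ]) >= min_cor
          }, logical(1))]
          if (length(cand) == 0) break
          ci <- cand[which.min(abs(feats$mz[cand] - target))]
          role[ci] <- paste0("isotope_", k)
          parent[ci] <- feats$feature_id[hi]
          claimed[ci] <- TRUE
          chain <- c(chain, ci)
          current <- ci
          k <- k + 1L
        }
        if (length(chain) > 1) break
      }
      if (length(chain) > 1) {
        role[hi] <- "monoisotopic"
        claimed[hi] <- TRUE
      }
    }
  }
  tibble::tibble(
    feature_id = feats$feature_id,
    group_id = feats$group_id,
    isotope_role = role,
    monoisotopic = role == "monoisotopic",
    parent_id = parent
  )
}

# correlation of paired observed intensities; requires >= 3 shared samples
isotope_cor <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(-1)
  stats::cor(a[ok], b[ok])
}

#' Monoisotopic feature filter
#'
#' Reduces an annotation to the features carrying a monoisotopic flag.
#' Under the default `"strict"` policy only detected isotope-series heads
#' pass (a restrictive filter); under `"permissive"`, unassigned singletons
#' pass as well.
#'
#' @param annotations Output of [detect_isotopes()].
#' @param policy `"strict"` or `"permissive"`.
#' @return The subset of `annotations` that passes, with `monoisotopic`
#'   set to `TRUE` for the policy used.
#' @export
monoisotopic_filter <- function(annotations, policy = c("strict", "permissive")) {
  policy <- match.arg(policy)
  keep <- if (policy == "strict") {
    annotations$isotope_role == "monoisotopic"
  } else {
    annotations$isotope_role %in% c("monoisotopic", "unassigned")
  }
  out <- annotations[keep, , drop = FALSE]
  out$monoisotopic <- TRUE
  out
}
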