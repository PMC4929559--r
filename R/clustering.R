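#' Pearson correlation distance between samples
#'
#' Distance `d(i, j) = 1 - r(i, j)` where `r` is the Pearson correlation
#' between the intensity profiles of samples `i` and `j` across features.
#'
#' @param features A wide feature tibble (see [feature_matrix]) or a plain
#'   numeric matrix with features in rows and samples in columns.
#' @return A [stats::dist] object over the samples.
#' @export
correlation_distance <- function(features) {
  m <- if (is.data.frame(features)) intensity_matrix(features) else as.matrix(features)
  if (nrow(m) < 2) stop("need at least 2 features to correlate samples")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant sample column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  stats::as.dist(1 - stats::cor(m))
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Standard UPGMA agglomeration with deterministic tie-breaking: among
#' minimum-distance pairs, the pair whose clusters contain the smallest
#' (then second-smallest) original leaf indices is merged first. The same
#' code path clusters metabolic correlation distances and genetic mismatch
#' distances.
#'
#' @param d A [stats::dist] object or a symmetric distance matrix with
#'   labels.
#' @return An object of class `hclust` (compatible with [stats::cutree()],
#'   [stats::cophenetic()], `as.dendrogram()` etc.).
#' @export
upgma <- function(d) {
  dm <- as.matrix(d)
  if (anyNA(dm)) stop("distance matrix contains NA")
  n <- nrow(dm)
  labels <- rownames(dm)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n < 2) stop("need at least 2 objects")

  # active cluster bookkeeping: hclust id (-leaf or +merge), size, smallest
  # original leaf index (for tie-breaking)
  id <- -seq_len(n)
  size <- rep(1L, n)
  rep_leaf <- seq_len(n)
  active <- rep(TRUE, n)
  D <- dm
  diag(D) <- Inf
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    act <- which(active)
    sub <- D[act, act, drop = FALSE]
    dmin <- min(sub)
    cand <- which(sub == dmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # tie-break on (min rep leaf, max rep leaf)
    pr <- cbind(pmin(rep_leaf[act[cand[, 1]]], rep_leaf[act[cand[, 2]]]),
                pmax(rep_leaf[act[cand[, 1]]], rep_leaf[act[cand[, 2]]]))
    pick <- order(pr[, 1], pr[, 2])[1]
    i <- act[cand[pick, 1]]
    j <- act[cand[pick, 2]]

    merge[step, ] <- sort_merge_pair(id[i], id[j])
    height[step] <- dmin

    # UPGMA update: distance of new cluster to k is the size-weighted mean
    newd <- (size[i] * D[i, ] + size[j] * D[j, ]) / (size[i] + size[j])
    D[i, ] <- newd
    D[, i] <- newd
    D[i, i] <- Inf
    active[j] <- FALSE
    D[j, ] <- Inf
    D[, j] <- Inf
    size[i] <- size[i] + size[j]
    rep_leaf[i] <- min(rep_leaf[i], rep_leaf[j])
    id[i] <- step
  }

  structure(
    list(merge = merge, height = height, order = hclust_order(merge),
         labels = labels, method = "average",
         call = match.call(), dist.method = attr(d, "method")),
    class = "hclust"
  )
}

# hclust convention: singletons (negative ids) before merges, otherwise
# ascending.
sort_merge_pair <- function(a, b) {
  if ((a < 0 && b < 0) || (a > 0 && b > 0)) c(min(a, b), max(a, b))
  else if (a < 0) c(a, b) else c(b, a)
}

# leaf order for plotting: expand the merge matrix recursively
hclust_order <- function(merge) {
  expand <- function(i) {
    if (i < 0) return(-i)
    c(expand(merge[i, 1]), expand(merge[i, 2]))
  }
  expand(nrow(merge))
}

#' Cut a correlation-distance dendrogram at a correlation threshold
#'
#' Cuts at height `1 - threshold`; connected subtrees below the cut are the
#' clusters.
#'
#' @param tree An `hclust` object built on correlation distances.
#' @param threshold Correlation threshold in (0, 1] (default 0.95, i.e. cut
#'   height 0.05).
#' @return A tibble with `label` and `cluster` (integer id).
#' @export
cut_at_correlation <- function(tree, threshold = 0.95) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  cl <- stats::cutree(tree, h = 1 - threshold)
  tibble::tibble(label = names(cl), cluster = unname(cl))
}

# leaf-set keys of every internal node of an hclust tree
cluster_keys <- function(tree) {
  n <- length(tree$labels)
  sets <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    members <- unlist(lapply(tree$merge[i, ], function(x) {
      if (x < 0) -x else sets[[x]]
    }))
    sets[[i]] <- sort(members)
  }
  list(
    sets = lapply(sets, function(s) tree$labels[s]),
    keys = vapply(sets, function(s) paste(tree$labels[s], collapse = "\r"),
                  character(1))
  )
}

#' Multiscale-bootstrap AU support for sample clusters
#'
#' Clusters samples by UPGMA on Pearson correlation distance, then assesses
#' every cluster of the observed dendrogram by multiscale bootstrap
#' resampling of the features: at each scale `r` it draws `B` bootstrap
#' samples of `ceiling(n * r)` features with replacement, reclusters, and
#' records the bootstrap probability `BP(r)` — the fraction of bootstrap
#' trees containing the cluster. BP values are clipped to
#' `[1/(B+1), 1 - 1/(B+1)]` and the model
#' `qnorm(1 - BP(r)) = v * sqrt(r) + c / sqrt(r)` is fitted by weighted
#' least squares (binomial variance weights); the approximately unbiased
#' support is `AU = 1 - pnorm(v - c)`. Scales at which the cluster appeared
#' in all or in none of the bootstrap trees carry no information about the
#' curvature and are excluded from the fit; if fewer than two informative
#' scales remain, AU falls back to the clipped BP (1-level or 0-level)
#' when the cluster was (almost) always or never recovered, and `NA`
#' otherwise.
#'
#' @inheritParams correlation_distance
#' @param scales Resampling scale grid (default `seq(0.5, 1.4, by = 0.1)`).
#' @param B Bootstrap replicates per scale (default 1000).
#' @param seed Optional integer seed for reproducible resampling.
#' @return A list with `tree` (the observed `hclust`) and `support`, a
#'   tibble with one row per internal node: `node`, `members` (list of leaf
#'   labels), `au`, `bp1` (BP at the scale nearest 1), `v`, `c`,
#'   `fit_quality` (weighted residual sum of squares), and `bp`, a list
#'   column of per-scale bootstrap probabilities.
#' @export
multiscale_bootstrap_au <- function(features, scales = seq(0.5, 1.4, by = 0.1),
                                    B = 1000, seed = NULL) {
  m <- if (is.data.frame(features)) intensity_matrix(features) else as.matrix(features)
  if (!is.null(seed)) set.seed(seed)
  if (length(scales) < 1) stop("need at least one scale")
  n_feat <- nrow(m)
  tree <- upgma(correlation_distance(m))
  obs <- cluster_keys(tree)
  n_cl <- length(obs$keys)

  counts <- matrix(0L, nrow = n_cl, ncol = length(scales))
  used_B <- integer(length(scales))
  for (si in seq_along(scales)) {
    n_r <- max(2L, ceiling(n_feat * scales[si]))
    for (b in seq_len(B)) {
      idx <- sample.int(n_feat, n_r, replace = TRUE)
      mb <- m[idx, , drop = FALSE]
      sds <- apply(mb, 2, stats::sd)
      if (any(sds == 0)) next  # degenerate resample carries no tree
      bt <- upgma(stats::as.dist(1 - stats::cor(mb)))
      bk <- cluster_keys(bt)$keys
      counts[, si] <- counts[, si] + (obs$keys %in% bk)
      used_B[si] <- used_B[si] + 1L
    }
    if (used_B[si] == 0L) stop("all bootstrap resamples degenerate at scale ",
                               scales[si])
  }

  support <- purrr::map_dfr(seq_len(n_cl), function(ci) {
    fit_au(counts[ci, ], used_B, scales)
  })
  support <- dplyr::mutate(support,
    node = seq_len(n_cl),
    members = obs$sets,
    .before = 1
  )
  list(tree = tree, support = support)
}

# Fit the signed-distance / curvature model for one cluster.
fit_au <- function(count, B, scales) {
  bp_raw <- count / B
  bp <- pmin(pmax(bp_raw, 1 / (B + 1)), 1 - 1 / (B + 1))
  near1 <- which.min(abs(scales - 1))
  interior <- count > 0 & count < B
  if (sum(interior) < 2) {
    au <- if (all(count == 0)) {
      1 / (mean(B) + 1)
    } else if (all(count == B)) {
      1 - 1 / (mean(B) + 1)
    } else if (mean(bp_raw) > 0.5 && sum(interior) == 0) {
      1 - 1 / (mean(B) + 1)
    } else {
      NA_real_
    }
    return(tibble::tibble(au = au, bp1 = bp_raw[near1], v = NA_real_,
                          c = NA_real_, fit_quality = NA_real_,
                          bp = list(stats::setNames(bp_raw, scales))))
  }
  r <- scales[interior]
  bpi <- bp[interior]
  Bi <- B[interior]
  psi <- stats::qnorm(1 - bpi)
  w <- (stats::dnorm(psi)^2 * Bi) / (bpi * (1 - bpi))
  X <- cbind(sqrt(r), 1 / sqrt(r))
  fit <- stats::lm.wfit(X, psi, w)
  v <- unname(fit$coefficients[1])
  cc <- unname(fit$coefficients[2])
  tibble::tibble(
    au = 1 - stats::pnorm(v - cc),
    bp1 = bp_raw[near1],
    v = v, c = cc,
    fit_quality = sum(w * fit$residuals^2),
    bp = list(stats::setNames(bp_raw, scales))
  )
}

#' Write a dendrogram in Newick format
#'
#' Branch lengths are merge-height differences between parent and child
#' nodes (leaf branches extend to height zero).
#'
#' @param tree An `hclust` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  n <- length(tree$labels)
  node_str <- character(n - 1)
  node_h <- tree$height
  part <- function(x, parent_h) {
    if (x < 0) {
      sprintf("%s:%.12g", tree$labels[-x], parent_h)
    } else {
      sprintf("(%s,%s):%.12g",
              part(tree$merge[x, 1], node_h[x]),
              part(tree$merge[x, 2], node_h[x]),
              parent_h - node_h[x])
    }
  }
  root <- nrow(tree$merge)
  txt <- sprintf("(%s,%s);",
                 part(tree$merge[root, 1], node_h[root]),
                 part(tree$merge[root, 2], node_h[root]))
  writeLines(txt, path)
  invisible(path)
}
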