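#' Pairwise between-species differential abundance
#'
#' Contrasts two species within one mating status on a subset of rows
#' of the normalized combined matrix (ejaculate divergence uses mated
#' channels; female tract divergence uses virgin channels, after
#' excluding ejaculate proteins). Calls use the standard thresholds.
#'
#' @param norm `mq_norm` object (or log2 matrix) over the combined table.
#' @param design sample design covering the matrix channels.
#' @param species_a,species_b the two species to contrast
#'   (`log2FC = A - B`).
#' @param status `"mated"` or `"virgin"` channels to use.
#' @param rows optional row keys (or logical/integer index) restricting
#'   the contrast to a protein set.
#' @param lfc_threshold,q_threshold calling thresholds.
#' @return The `mq_contrast` data frame with an extra `call` column;
#'   attribute `n_called` gives the number of non-`ns` rows.
#' @export
pairwise_divergence <- function(norm, design, species_a, species_b,
                                status = "mated", rows = NULL,
                                lfc_threshold = 1, q_threshold = 0.05) {
  mat <- if (inherits(norm, "mq_norm")) norm$log2 else as.matrix(norm)
  if (!is.null(rows)) {
    mat <- if (is.character(rows)) {
      i <- match(rows, rownames(mat))
      if (anyNA(i)) stop("unknown row keys in subset")
      mat[i, , drop = FALSE]
    } else {
      mat[rows, , drop = FALSE]
    }
  }
  if (nrow(mat) == 0) stop("empty row subset")
  cha <- design_channels(design, species_a, status)
  chb <- design_channels(design, species_b, status)
  if (length(cha) == 0) {
    stop("no ", status, " channels for species ", species_a)
  }
  if (length(chb) == 0) {
    stop("no ", status, " channels for species ", species_b)
  }
  res <- fit_moderated(mat, cha, chb)
  res$call <- call_differential(res, lfc_threshold, q_threshold)
  attr(res, "n_called") <- sum(res$call != "ns")
  attr(res, "contrast") <- paste0(species_a, "_vs_", species_b, ".", status)
  res
}

#' Median-centred group means
#'
#' Per-row arithmetic means of log2 values within each group, with the
#' per-row median across groups subtracted — the representation used
#' for abundance heatmaps and k-means clustering.
#'
#' @param norm `mq_norm` object or log2 matrix.
#' @param design sample design.
#' @param groups character vector naming the design columns that define
#'   groups (default `c("species", "status")`).
#' @return Matrix rows x groups of median-centred group means.
#' @export
replicate_average_center <- function(norm, design,
                                     groups = c("species", "status")) {
  mat <- if (inherits(norm, "mq_norm")) norm$log2 else as.matrix(norm)
  validate_design(design)
  g <- interaction(design[groups], drop = TRUE, sep = ".")
  means <- vapply(levels(g), function(lv) {
    ch <- design$channel[g == lv]
    i <- match(ch, colnames(mat))
    if (anyNA(i)) stop("design channels missing from matrix: ",
                       paste(ch[is.na(i)], collapse = ", "))
    if (length(i) == 0) stop("empty group: ", lv)
    rowMeans(mat[, i, drop = FALSE])
  }, numeric(nrow(mat)))
  if (nrow(mat) == 1L) means <- matrix(means, 1L,
                                       dimnames = list(rownames(mat),
                                                       levels(g)))
  med <- apply(means, 1, stats::median)
  sweep(means, 1, med, "-")
}

#' K-means clustering of abundance profiles
#'
#' Squared-Euclidean k-means with a fixed number of clusters (the
#' analysis fixes k, e.g. 7 for ejaculate and 4 for tract profiles) and
#' best-of-restarts labelling, deterministic given the seed.
#'
#' @param mat matrix of (centred) profiles, rows = proteins.
#' @param k number of clusters (>= 1).
#' @param seed RNG seed.
#' @param n_restarts number of random restarts.
#' @return List of class `mq_clusters`: `k`, `labels` (named by row),
#'   `centers`, `wss` (total within-cluster sum of squares), `seed`.
#' @export
kmeans_cluster <- function(mat, k, seed = 1, n_restarts = 100) {
  mat <- as.matrix(mat)
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1) {
    stop("k must be a single integer >= 1")
  }
  if (k > nrow(mat)) stop("k cannot exceed the number of rows")
  if (any(!is.finite(mat))) stop("matrix must be finite")
  set.seed(seed)
  km <- stats::kmeans(mat, centers = k, nstart = n_restarts,
                      iter.max = 100)
  labels <- km$cluster
  names(labels) <- rownames(mat)
  out <- list(k = as.integer(k), labels = labels, centers = km$centers,
              wss = km$tot.withinss, seed = seed)
  class(out) <- "mq_clusters"
  out
}

#' Two-sided Fisher association between set membership and a flag
#'
#' Tests whether an annotation flag (e.g. a predicted signal peptide)
#' is associated with membership in a protein set (e.g. the
#' species-divergent proteins) within a universe.
#'
#' @param set_members keys in the set.
#' @param flagged keys carrying the annotation flag.
#' @param universe all keys under consideration (must contain the set).
#' @return List: `table` (2x2), `p` (two-sided exact), `odds_ratio`.
#' @export
fisher_association <- function(set_members, flagged, universe) {
  if (length(universe) == 0) stop("universe must be nonempty")
  if (!all(set_members %in% universe)) {
    stop("set members must be contained in the universe")
  }
  in_set <- universe %in% set_members
  has_flag <- universe %in% flagged
  tab <- table(factor(in_set, levels = c(TRUE, FALSE)),
               factor(has_flag, levels = c(TRUE, FALSE)),
               dnn = c("in_set", "flagged"))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, p = ft$p.value,
       odds_ratio = unname(ft$estimate))
}

#' Monte-Carlo resampling test for gene-family representation
#'
#' Draws `B` samples of the observed set size without replacement from
#' the pool and compares the number of family-flagged keys drawn with
#' the observed count. Both tail probabilities are reported with the
#' add-one estimator `(1 + #{draws >= k_obs}) / (B + 1)` (and the
#' analogous lower tail), alongside closed-form hypergeometric tails.
#'
#' @param sample_keys keys of the observed set (e.g. ejaculate rows).
#' @param pool_keys keys of the pool (all quantified rows).
#' @param family_flags logical vector named by pool key, or a character
#'   vector of flagged keys.
#' @param B number of simulated draws (default 99999).
#' @param seed RNG seed.
#' @return List of class `mq_resampling`: `N`, `K`, `n`, `k_obs`, `B`,
#'   `p_upper`, `p_lower`, `p_hyper_upper`, `p_hyper_lower`, `seed`.
#' @export
family_resampling_test <- function(sample_keys, pool_keys, family_flags,
                                   B = 99999, seed = 1) {
  if (!all(sample_keys %in% pool_keys)) {
    stop("sample keys must be contained in the pool")
  }
  if (length(sample_keys) > length(pool_keys)) {
    stop("sample cannot be larger than the pool")
  }
  if (B < 1) stop("B must be >= 1")
  if (is.character(family_flags)) {
    flags <- pool_keys %in% family_flags
  } else {
    flags <- as.logical(family_flags[pool_keys])
    if (anyNA(flags)) stop("family_flags must cover every pool key")
  }
  N <- length(pool_keys)
  K <- sum(flags)
  n <- length(sample_keys)
  k_obs <- sum(pool_keys[flags] %in% sample_keys)

  set.seed(seed)
  draws <- vapply(seq_len(B), function(b) {
    sum(flags[sample.int(N, n)])
  }, integer(1))
  p_upper <- (1 + sum(draws >= k_obs)) / (B + 1)
  p_lower <- (1 + sum(draws <= k_obs)) / (B + 1)

  out <- list(
    N = N, K = K, n = n, k_obs = k_obs, B = as.integer(B),
    p_upper = p_upper, p_lower = p_lower,
    p_hyper_upper = stats::phyper(k_obs - 1, K, N - K, n,
                                  lower.tail = FALSE),
    p_hyper_lower = stats::phyper(k_obs, K, N - K, n),
    seed = seed
  )
  class(out) <- "mq_resampling"
  out
}
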