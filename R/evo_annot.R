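#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. The p-value is exact (from the
#' null permutation distribution of U) when n1 + n2 <= 12 and there are
#' no ties; otherwise a normal approximation with tie and continuity
#' correction is used. With all observations tied the two-sided p is 1.
#'
#' @param x,y numeric samples (nonempty).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (location
#'   of `x` relative to `y`).
#' @return List: `U` (statistic for `x`), `p`, `method`.
#' @export
mannwhitney_u <- function(x, y,
                          alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("samples must be nonempty")
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tie_sizes <- table(c(x, y))
  has_ties <- any(tie_sizes > 1)
  if (n1 + n2 <= 12 && !has_ties) {
    p <- switch(alternative,
      two.sided = {
        pl <- stats::pwilcox(U, n1, n2)
        pu <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
        min(1, 2 * min(pl, pu))
      },
      less = stats::pwilcox(U, n1, n2),
      greater = stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    )
    method <- "exact"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(tie_sizes^3 - tie_sizes)
    sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- U - mu
      corr <- switch(alternative,
                     two.sided = sign(z) * 0.5,
                     greater = 0.5,
                     less = -0.5)
      z <- (z - corr) / sqrt(sig2)
      p <- switch(alternative,
        two.sided = min(1, 2 * min(stats::pnorm(z),
                                   stats::pnorm(z, lower.tail = FALSE))),
        less = stats::pnorm(z),
        greater = stats::pnorm(z, lower.tail = FALSE)
      )
    }
    method <- "normal approximation (tie/continuity corrected)"
  }
  list(U = U, p = p, method = method)
}

#' Compare evolutionary rates (dN/dS) between protein groups
#'
#' Per species pair, summarises pairwise dN/dS for each named protein
#' group (n, mean, standard error) and runs Mann-Whitney tests for the
#' requested group comparisons. An optional genome-background table
#' contributes a `genome` group (the genome-average line).
#'
#' @param omega long data frame `protein_id`, `pair`, `omega`.
#' @param groups named list: group name -> character vector of protein
#'   IDs. Groups with no rate values in a pair are skipped with a
#'   warning.
#' @param comparisons list of length-2 character vectors of group names;
#'   default compares every pair of groups.
#' @param genome_omega optional data frame `pair`, `omega` of
#'   genome-background rates (added as group `"genome"`).
#' @param alternative passed to [mannwhitney_u()]; default two-sided.
#' @return List with `summary` (pair, group, n, mean_omega, se) and
#'   `tests` (pair, group_a, group_b, n_a, n_b, p).
#' @export
compare_rate_groups <- function(omega, groups, comparisons = NULL,
                                genome_omega = NULL,
                                alternative = "two.sided") {
  pairs <- sort(unique(c(omega$pair,
                         if (!is.null(genome_omega)) genome_omega$pair)))
  vals <- list()
  for (pr in pairs) {
    sub <- omega[omega$pair == pr, ]
    vals[[pr]] <- lapply(groups, function(ids) {
      v <- sub$omega[sub$protein_id %in% ids]
      v[is.finite(v)]
    })
    if (!is.null(genome_omega)) {
      vals[[pr]]$genome <-
        genome_omega$omega[genome_omega$pair == pr]
    }
  }
  gnames <- names(vals[[1]])
  if (is.null(comparisons)) {
    comparisons <- utils::combn(gnames, 2, simplify = FALSE)
  }
  summary <- do.call(rbind, lapply(pairs, function(pr) {
    do.call(rbind, lapply(gnames, function(g) {
      v <- vals[[pr]][[g]]
      data.frame(pair = pr, group = g, n = length(v),
                 mean_omega = if (length(v) > 0) mean(v) else NA_real_,
                 se = if (length(v) > 1) {
                   stats::sd(v) / sqrt(length(v))
                 } else {
                   NA_real_
                 },
                 stringsAsFactors = FALSE)
    }))
  }))
  tests <- list()
  for (pr in pairs) {
    for (cmp in comparisons) {
      va <- vals[[pr]][[cmp[1]]]
      vb <- vals[[pr]][[cmp[2]]]
      if (length(va) == 0 || length(vb) == 0) {
        warning("no rate values for comparison ", cmp[1], " vs ", cmp[2],
                " in pair ", pr, "; skipped")
        next
      }
      mw <- mannwhitney_u(va, vb, alternative = alternative)
      tests[[length(tests) + 1]] <- data.frame(
        pair = pr, group_a = cmp[1], group_b = cmp[2],
        n_a = length(va), n_b = length(vb), p = mw$p,
        stringsAsFactors = FALSE)
    }
  }
  tests <- if (length(tests) > 0) do.call(rbind, tests) else NULL
  rownames(summary) <- NULL
  if (!is.null(tests)) rownames(tests) <- NULL
  list(summary = summary, tests = tests)
}

#' GO term enrichment by one-sided Fisher test
#'
#' For every term annotated to at least `min_genes` background proteins,
#' tests enrichment of the term in the foreground against the
#' background universe (one-sided hypergeometric upper tail), with BH
#' adjustment across tested terms.
#'
#' @param foreground character vector of foreground keys (must be a
#'   subset of the background).
#' @param background character vector of universe keys.
#' @param go_annot data frame `protein_id`, `term`, `branch`
#'   (pre-propagated term sets).
#' @param min_genes minimum annotated background genes per tested term.
#' @return Data frame `term`, `branch`, `annotated`, `in_foreground`,
#'   `p`, `q`, sorted by p; empty for an empty foreground.
#' @export
go_enrichment <- function(foreground, background, go_annot,
                          min_genes = 15) {
  empty <- data.frame(term = character(0), branch = character(0),
                      annotated = integer(0), in_foreground = integer(0),
                      p = numeric(0), q = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(foreground) == 0) return(empty)
  if (!all(foreground %in% background)) {
    stop("foreground must be a subset of the background")
  }
  annot <- go_annot[go_annot$protein_id %in% background, , drop = FALSE]
  annot <- unique(annot[, c("protein_id", "term", "branch")])
  if (nrow(annot) == 0) return(empty)
  K <- table(annot$term)
  terms <- names(K)[K >= min_genes]
  if (length(terms) == 0) return(empty)
  N <- length(unique(background))
  n <- length(unique(foreground))
  fg_annot <- annot[annot$protein_id %in% foreground, , drop = FALSE]
  kf <- table(factor(fg_annot$term, levels = terms))
  res <- data.frame(
    term = terms,
    branch = annot$branch[match(terms, annot$term)],
    annotated = as.integer(K[terms]),
    in_foreground = as.integer(kf),
    stringsAsFactors = FALSE
  )
  res$p <- stats::phyper(res$in_foreground - 1, res$annotated,
                         N - res$annotated, n, lower.tail = FALSE)
  res$q <- bh_adjust(res$p)
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors (n >= 3, finite, nonconstant).
#' @return List: `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least three observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("values must be finite")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' PCA of samples on the most variable proteins
#'
#' Ranks proteins by abundance variance across channels, projects the
#' samples onto the principal axes of the selected sub-matrix after
#' per-protein mean-centering (no unit-variance scaling), and reports
#' the fraction of variance per component.
#'
#' @param norm `mq_norm` object or log2 matrix (proteins x channels).
#' @param n_top number of most-variable proteins to use (all rows, with
#'   a warning, if the matrix is smaller).
#' @return List of class `mq_pca`: `scores` (samples x components),
#'   `var_explained` (percent per component), `proteins` (selected row
#'   keys).
#' @export
pca_top_variable <- function(norm, n_top = 500) {
  mat <- if (inherits(norm, "mq_norm")) norm$log2 else as.matrix(norm)
  if (ncol(mat) < 2) stop("need at least two samples")
  if (nrow(mat) < n_top) {
    warning("matrix has fewer than ", n_top, " rows; using all ",
            nrow(mat))
    n_top <- nrow(mat)
  }
  v <- apply(mat, 1, stats::var)
  top <- order(v, decreasing = TRUE)[seq_len(n_top)]
  sub <- mat[top, , drop = FALSE]
  pr <- stats::prcomp(t(sub), center = TRUE, scale. = FALSE)
  var_explained <- 100 * pr$sdev^2 / sum(pr$sdev^2)
  out <- list(scores = pr$x, var_explained = var_explained,
              proteins = rownames(sub))
  class(out) <- "mq_pca"
  out
}
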