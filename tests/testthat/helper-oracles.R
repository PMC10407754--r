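# Independent brute-force oracles used by unit and acceptance tests.
# Deliberately coded in a different style from the package functions
# (sort/order-based trimming, direct enumeration) so they constitute an
# independent route to the same quantities.

# TMM scaling factors: plain loop, order-based double trimming
oracle_tmm <- function(mat, ref) {
  lib <- colSums(mat)
  fs <- vapply(seq_len(ncol(mat)), function(j) {
    x <- mat[, j]
    r <- mat[, ref]
    ok <- x > 0 & r > 0
    x <- x[ok]
    r <- r[ok]
    M <- log2(x / lib[j]) - log2(r / lib[ref])
    A <- 0.5 * (log2(x / lib[j]) + log2(r / lib[ref]))
    w <- 1 / ((lib[j] - x) / (lib[j] * x) + (lib[ref] - r) / (lib[ref] * r))
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    keep_m <- order(M)[(floor(n * 0.3) + 1):(n - floor(n * 0.3))]
    keep_a <- order(A)[(floor(n * 0.05) + 1):(n - floor(n * 0.05))]
    keep <- intersect(keep_m, keep_a)
    2^(sum((M * w)[keep]) / sum(w[keep]))
  }, numeric(1))
  fs / exp(mean(log(fs)))
}

# Benjamini-Hochberg step-up: q_(i) = min over j >= i of m p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  s <- sort(p, index.return = TRUE)
  val <- pmin(1, rev(cummin(rev(m * s$x / seq_len(m)))))
  out <- numeric(m)
  out[s$ix] <- val
  out
}

# two-sided Fisher p by exhaustive enumeration of tables with the
# observed margins, summing point probabilities <= that of the table
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Mann-Whitney exact p by full enumeration of group assignments
oracle_mw_exact <- function(x, y, alternative) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  p_less <- mean(us <= u_obs)
  p_greater <- mean(us >= u_obs)
  switch(alternative,
         less = p_less,
         greater = p_greater,
         two.sided = min(1, 2 * min(p_less, p_greater)))
}

# sample scores and variance fractions from an explicit spectral
# decomposition of the sample covariance matrix
oracle_pca <- function(mat_sub) {
  x <- t(mat_sub)
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(xc) / (nrow(x) - 1), symmetric = TRUE)
  list(scores = xc %*% ev$vectors,
       var_frac = 100 * ev$values / sum(ev$values))
}

# align signs of oracle score columns to a reference before comparison
align_signs <- function(scores, ref) {
  for (j in seq_len(ncol(scores))) {
    if (sum(scores[, j] * ref[, j]) < 0) scores[, j] <- -scores[, j]
  }
  scores
}
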