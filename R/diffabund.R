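#' Trimmed mean of M-values scaling factors
#'
#' Between-channel scaling factors from doubly trimmed, precision-
#' weighted mean log-ratios against a reference channel. For channel x
#' with library size Nx and reference r with size Nr, per-protein
#' M = log2((x/Nx)/(r/Nr)) and A = (log2(x/Nx) + log2(r/Nr))/2; rows
#' with a zero in either channel are excluded. M-values are trimmed by
#' rank (30% each tail) and A-values by 5% each tail; the factor is the
#' inverse-variance-weighted mean of the surviving M-values, with
#' asymptotic binomial weights 1/v, v = (Nx-x)/(Nx x) + (Nr-r)/(Nr r).
#' Factors are rescaled to geometric mean 1.
#'
#' @param mat nonnegative intensity matrix, proteins x channels.
#' @param ref_channel reference channel name or index; default is the
#'   channel whose total intensity is closest to the mean total.
#' @param logratio_trim,abs_trim trim fractions for M and A.
#' @return Named numeric vector of per-channel factors.
#' @export
tmm_factors <- function(mat, ref_channel = NULL, logratio_trim = 0.3,
                        abs_trim = 0.05) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least two channels")
  if (any(mat < 0)) stop("intensities must be nonnegative")
  if (is.null(colnames(mat))) colnames(mat) <- paste0("ch", seq_len(ncol(mat)))
  lib <- colSums(mat)
  if (any(lib == 0)) {
    stop("channel(s) with all-zero intensities: ",
         paste(colnames(mat)[lib == 0], collapse = ", "))
  }
  if (is.null(ref_channel)) {
    ref_channel <- which.min(abs(lib - mean(lib)))
  }
  if (is.character(ref_channel)) {
    ref_channel <- match(ref_channel, colnames(mat))
  }
  if (is.na(ref_channel) || ref_channel < 1 || ref_channel > ncol(mat)) {
    stop("invalid reference channel")
  }
  r <- mat[, ref_channel]
  nR <- lib[ref_channel]
  f <- vapply(seq_len(ncol(mat)), function(j) {
    tmm_pair_factor(mat[, j], r, lib[j], nR, logratio_trim, abs_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(mat)
  f
}

# one-pair TMM factor (no geometric-mean rescaling)
tmm_pair_factor <- function(obs, ref, nO, nR, logratio_trim, abs_trim) {
  M <- log2((obs / nO) / (ref / nR))
  A <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
  fin <- is.finite(M) & is.finite(A) & (A > -1e10)
  M <- M[fin]; A <- A[fin]; v <- v[fin]
  if (length(M) == 0 || max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1
  hiA <- n + 1 - loA
  keep <- (rank(M) >= loM & rank(M) <= hiM) &
    (rank(A) >= loA & rank(A) <= hiA)
  f <- sum(M[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' Normalized log2 abundance matrix
#'
#' `log2((x + pseudocount) / (library size x factor) * scale_constant)`:
#' a counts-per-million-style transform on the intensity scale, with the
#' TMM factor absorbing composition differences between channels.
#'
#' @param mat nonnegative intensity matrix.
#' @param factors per-channel factors from [tmm_factors()].
#' @param pseudocount positive offset added before the log (default 0.5).
#' @param scale_constant scale of the normalized values (default 1e6).
#' @return List of class `mq_norm`: `log2` (normalized matrix),
#'   `factors`, `lib_size`, `pseudocount`.
#' @export
normalize_log2 <- function(mat, factors = tmm_factors(mat),
                           pseudocount = 0.5, scale_constant = 1e6) {
  mat <- as.matrix(mat)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
      is.na(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be a single positive number")
  }
  if (length(factors) != ncol(mat)) {
    stop("length(factors) must equal the number of channels")
  }
  if (any(factors <= 0)) stop("factors must be positive")
  lib <- colSums(mat)
  eff <- lib * factors
  val <- log2(sweep(mat + pseudocount, 2, eff, "/") * scale_constant)
  out <- list(log2 = val, factors = factors, lib_size = lib,
              pseudocount = pseudocount)
  class(out) <- "mq_norm"
  out
}

#' Moderated two-group differential abundance fit
#'
#' Per-row two-group linear model on normalized log2 abundances with
#' empirical Bayes variance shrinkage. The pooled residual variance s2
#' (d = nA + nB - 2 df) is shrunk towards a prior s0^2 with prior
#' degrees of freedom d0 estimated by method of moments on log s2
#' (digamma/trigamma matching):
#' `s_tilde^2 = (d0 s0^2 + d s2) / (d0 + d)`,
#' `t = log2FC / (s_tilde sqrt(1/nA + 1/nB))`, p from a t distribution
#' on d0 + d df. Rows with s2 = 0 are excluded from moment estimation
#' and assigned `s_tilde^2 = s0^2`. Works at two replicates per group.
#'
#' @param norm an `mq_norm` object or a log2 matrix.
#' @param channels_a,channels_b channel names (or indices) of the two
#'   groups; `log2FC = mean(A) - mean(B)`.
#' @param d0_override optional fixed prior df; `0` gives the ordinary
#'   pooled two-sample t-test.
#' @return Data frame of class `mq_contrast` with `row_key`, `log2fc`,
#'   `t_mod`, `df_total`, `p`, `q` (BH within this contrast); attributes
#'   `d0` and `s02` carry the prior.
#' @export
fit_moderated <- function(norm, channels_a, channels_b,
                          d0_override = NULL) {
  mat <- if (inherits(norm, "mq_norm")) norm$log2 else as.matrix(norm)
  ia <- resolve_channels(mat, channels_a)
  ib <- resolve_channels(mat, channels_b)
  nA <- length(ia); nB <- length(ib)
  if (nA < 2 || nB < 2) {
    stop("each group needs at least two replicate channels")
  }
  if (length(intersect(ia, ib)) > 0) stop("groups share channels")
  A <- mat[, ia, drop = FALSE]
  B <- mat[, ib, drop = FALSE]
  mA <- rowMeans(A); mB <- rowMeans(B)
  lfc <- mA - mB
  d <- nA + nB - 2
  s2 <- (rowSums((A - mA)^2) + rowSums((B - mB)^2)) / d

  if (!is.null(d0_override) && d0_override == 0) {
    d0 <- 0
    s02 <- NA_real_
    s_tilde2 <- s2
  } else {
    pos <- s2 > 0
    if (sum(pos) < 2) stop("too few rows with positive variance")
    z <- log(s2[pos])
    if (is.null(d0_override)) {
      excess <- stats::var(z) - trigamma(d / 2)
      if (excess > 0) {
        d0 <- 2 * trigamma_inverse(excess)
      } else {
        d0 <- Inf
      }
    } else {
      d0 <- d0_override
    }
    if (is.finite(d0)) {
      s02 <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                   digamma(d0 / 2) - log(d0 / 2))
      s_tilde2 <- (d0 * s02 + d * s2) / (d0 + d)
      s_tilde2[!pos] <- s02
    } else {
      s02 <- exp(mean(z) - digamma(d / 2) + log(d / 2))
      s_tilde2 <- rep(s02, length(s2))
    }
  }
  se <- sqrt(s_tilde2 * (1 / nA + 1 / nB))
  t_mod <- lfc / se
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p[se == 0] <- 1  # degenerate rows: no evidence either way
  res <- data.frame(
    row_key = if (!is.null(rownames(mat))) rownames(mat) else
      as.character(seq_len(nrow(mat))),
    log2fc = lfc,
    t_mod = t_mod,
    df_total = df_total,
    p = p,
    q = bh_adjust(p),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "d0") <- d0
  attr(res, "s02") <- s02
  attr(res, "n_a") <- nA
  attr(res, "n_b") <- nB
  class(res) <- c("mq_contrast", "data.frame")
  res
}

resolve_channels <- function(mat, channels) {
  if (is.character(channels)) {
    i <- match(channels, colnames(mat))
    if (anyNA(i)) {
      stop("unknown channel(s): ",
           paste(channels[is.na(i)], collapse = ", "))
    }
    i
  } else {
    as.integer(channels)
  }
}

# Newton inversion of the trigamma function (y = trigamma(x), solve x)
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < 1e-10) break
  }
  x
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`; `NA`/`NaN`
#'   inputs are an error.
#' @return Adjusted q-values (monotone in sorted order, capped at 1).
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues)) stop("p-values must not contain NA/NaN")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
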