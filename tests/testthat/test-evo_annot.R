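test_that("Mann-Whitney U matches enumeration, identities and wilcox.test", {
  mw <- mannwhitney_u(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(mw$p, 1 / choose(4, 2))
  expect_equal(mw$U, 0)
  # complete ties: two-sided p is 1
  expect_equal(mannwhitney_u(rep(2, 5), rep(2, 4))$p, 1)

  set.seed(91)
  for (i in 1:10) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    x <- rnorm(n1)
    y <- rnorm(n2)
    alt <- sample(c("two.sided", "less", "greater"), 1)
    mw <- mannwhitney_u(x, y, alt)
    expect_equal(mw$p, oracle_mw_exact(x, y, alt))
    # U_x + U_y = n1 * n2
    uy <- mannwhitney_u(y, x, alt)$U
    expect_equal(mw$U + uy, n1 * n2)
  }
  # large samples with ties: agree with wilcox.test's corrected normal
  set.seed(92)
  x <- sample(1:10, 60, replace = TRUE)
  y <- sample(2:11, 45, replace = TRUE)
  for (alt in c("two.sided", "less", "greater")) {
    got <- mannwhitney_u(x, y, alt)
    ref <- suppressWarnings(wilcox.test(x, y, alternative = alt))
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(mannwhitney_u(numeric(0), 1:3), "nonempty")
})

test_that("rate-group comparisons detect shifts and report the genome line", {
  set.seed(93)
  ids_a <- sprintf("a%03d", 1:100)
  ids_b <- sprintf("b%03d", 1:100)
  omega <- rbind(
    data.frame(protein_id = ids_a, pair = "p1",
               omega = rgamma(100, 2, scale = 0.09)),
    data.frame(protein_id = ids_b, pair = "p1",
               omega = rgamma(100, 2, scale = 0.09) + 0.2)
  )
  genome <- data.frame(pair = "p1", omega = rgamma(500, 2, scale = 0.09))
  out <- compare_rate_groups(omega, list(ga = ids_a, gb = ids_b),
                             genome_omega = genome)
  expect_setequal(out$summary$group, c("ga", "gb", "genome"))
  shift_test <- out$tests[out$tests$group_a == "ga" &
                            out$tests$group_b == "gb", ]
  expect_lt(shift_test$p, 0.01)
  gb_mean <- out$summary$mean_omega[out$summary$group == "gb"]
  ga_mean <- out$summary$mean_omega[out$summary$group == "ga"]
  expect_gt(gb_mean, ga_mean)

  # two identical groups: p = 1 under complete ties
  same <- compare_rate_groups(
    rbind(omega[1:100, ], transform(omega[1:100, ],
                                    protein_id = ids_b)),
    list(ga = ids_a, gb = ids_b))
  expect_equal(same$tests$p, 1)

  # row order invariance
  out2 <- compare_rate_groups(omega[sample(nrow(omega)), ],
                              list(ga = ids_a, gb = ids_b),
                              genome_omega = genome)
  expect_equal(out2$summary[order(out2$summary$group), ],
               out$summary[order(out$summary$group), ],
               ignore_attr = TRUE)

  # empty group is skipped with a warning
  expect_warning(
    compare_rate_groups(omega, list(ga = ids_a, empty = "nope")),
    "skipped")
})

test_that("GO enrichment equals the hypergeometric/Fisher closed form", {
  set.seed(94)
  bg <- sprintf("p%03d", 1:200)
  annot <- do.call(rbind, lapply(sprintf("T%02d", 1:8), function(tt) {
    data.frame(protein_id = sample(bg, sample(10:60, 1)), term = tt,
               branch = sample(c("BP", "CC", "MF"), 1),
               stringsAsFactors = FALSE)
  }))
  fg <- sample(bg, 40)
  res <- go_enrichment(fg, bg, annot, min_genes = 15)
  expect_true(all(res$annotated >= 15))
  for (i in seq_len(nrow(res))) {
    K <- res$annotated[i]
    k <- res$in_foreground[i]
    tab <- matrix(c(k, K - k, 40 - k, 200 - K - 40 + k), 2, 2)
    ref <- fisher.test(tab, alternative = "greater")$p.value
    expect_equal(res$p[i], ref, tolerance = 1e-12)
  }
  # a 14-gene term is never tested
  small <- data.frame(protein_id = bg[1:14], term = "SMALL", branch = "BP")
  res2 <- go_enrichment(fg, bg, rbind(annot, small), min_genes = 15)
  expect_false("SMALL" %in% res2$term)
  # foreground = background -> nothing enriched
  res3 <- go_enrichment(bg, bg, annot)
  expect_true(all(res3$q >= 0.99))
  expect_equal(nrow(go_enrichment(character(0), bg, annot)), 0)
  # a term filling the whole foreground and nothing else: point mass
  hot <- data.frame(protein_id = fg[1:20], term = "HOT", branch = "MF")
  res4 <- go_enrichment(fg[1:20], bg, rbind(annot, hot), min_genes = 15)
  expect_equal(res4$p[res4$term == "HOT"],
               1 / choose(200, 20) * choose(20, 20) * choose(180, 0))
})

test_that("Pearson correlation covers exact and random cases", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  set.seed(95)
  a <- rnorm(50)
  b <- 0.5 * a + rnorm(50)
  got <- pearson_r(a, b)
  # formula oracle
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  tstat <- r * sqrt(48 / (1 - r^2))
  expect_equal(got$r, r)
  expect_equal(got$p, 2 * pt(-abs(tstat), 48))
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_r(1:2, 1:2), "three")
})

test_that("PCA matches a spectral-decomposition oracle up to sign", {
  m <- log2(seeded_matrix(80, 10, seed = 96))
  pca <- suppressWarnings(pca_top_variable(m, n_top = 40))
  v <- apply(m, 1, var)
  sub <- m[order(v, decreasing = TRUE)[1:40], ]
  ora <- oracle_pca(sub)
  k <- sum(ora$var_frac > 1e-8)
  sc <- align_signs(ora$scores[, 1:k], pca$scores[, 1:k])
  expect_equal(unname(pca$scores[, 1:k]), unname(sc), tolerance = 1e-8)
  expect_equal(pca$var_explained[1:k], ora$var_frac[1:k],
               tolerance = 1e-8)
  expect_equal(sum(pca$var_explained), 100, tolerance = 1e-8)

  # collinear samples: PC1 carries all the variance
  base <- rnorm(30)
  mm <- outer(base, seq(1, 3, length.out = 5))
  rownames(mm) <- sprintf("r%02d", 1:30)
  p1 <- pca_top_variable(mm, n_top = 30)
  expect_equal(p1$var_explained[1], 100, tolerance = 1e-8)
  expect_warning(pca_top_variable(mm, n_top = 100), "fewer")
  expect_error(pca_top_variable(mm[, 1, drop = FALSE]), "two samples")
})
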