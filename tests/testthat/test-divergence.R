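test_that("pairwise divergence is antisymmetric in species order", {
  m <- log2(seeded_matrix(150, 8, seed = 81))
  d <- mini_design()
  a <- pairwise_divergence(m, d, "americana", "virilis", status = "mated")
  b <- pairwise_divergence(m, d, "virilis", "americana", status = "mated")
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$p, b$p)
  expect_equal(sum(a$call == "up"), sum(b$call == "down"))
  expect_equal(attr(a, "n_called"), attr(b, "n_called"))
})

test_that("identical species profiles produce zero divergence calls", {
  set.seed(82)
  half <- matrix(rnorm(100 * 4), 100, 4)
  m <- cbind(half, half)  # virilis channels copy americana exactly
  colnames(m) <- sprintf("ch%02d", 1:8)
  rownames(m) <- sprintf("r%03d", 1:100)
  res <- pairwise_divergence(m, mini_design(), "americana", "virilis",
                             status = "mated")
  expect_equal(attr(res, "n_called"), 0)
  expect_equal(res$log2fc, rep(0, 100))
})

test_that("divergence respects row subsets and missing-status errors", {
  m <- log2(seeded_matrix(50, 8, seed = 83))
  d <- mini_design()
  keys <- rownames(m)[1:10]
  res <- pairwise_divergence(m, d, "americana", "virilis", rows = keys)
  expect_equal(res$row_key, keys)
  expect_error(pairwise_divergence(m, d, "americana", "virilis",
                                   rows = "nope"), "unknown row")
  d2 <- d[d$status == "mated", ]
  expect_error(pairwise_divergence(m, d2, "americana", "virilis",
                                   status = "virgin"), "virgin")
})

test_that("replicate averaging and median centering match hand values", {
  d <- mini_design()
  m <- matrix(0, 2, 8, dimnames = list(c("r1", "r2"), d$channel))
  # r1: group means americana.mated=1, americana.virgin=2,
  #     virilis.mated=3, virilis.virgin=4
  m[1, ] <- c(1, 1, 2, 2, 3, 3, 4, 4)
  m[2, ] <- c(5, 7, 0, 0, 0, 0, 0, 0)  # americana.mated mean 6, rest 0
  cc <- replicate_average_center(m, d)
  # r1 group means (1,2,3,4), median 2.5 -> (-1.5,-0.5,0.5,1.5)
  expect_setequal(unname(cc[1, ]), c(-1.5, -0.5, 0.5, 1.5))
  expect_equal(sort(unname(cc[2, ])), c(0, 0, 0, 6))
  # a single group centers to all zeros
  d1 <- d[1:2, ]
  m1 <- m[, 1:2, drop = FALSE]
  z <- replicate_average_center(m1, d1)
  expect_true(all(z == 0))
  # three group means (1,2,3) -> (-1,0,1)
  d3 <- data.frame(channel = c("ch01", "ch02", "ch03"),
                   species = c("a", "b", "c"), status = "mated",
                   replicate = 1)
  m3 <- matrix(c(1, 2, 3), 1, 3, dimnames = list("r", d3$channel))
  expect_equal(unname(replicate_average_center(m3, d3)[1, ]),
               c(-1, 0, 1))
})

test_that("k-means clustering satisfies its structural contracts", {
  set.seed(84)
  centers <- matrix(c(0, 0, 10, 10, -10, 5), 3, 2, byrow = TRUE)
  m <- centers[rep(1:3, each = 20), ] + matrix(rnorm(120, sd = 0.01), 60, 2)
  rownames(m) <- sprintf("r%02d", 1:60)
  cl <- kmeans_cluster(m, 3, seed = 2)
  expect_lt(cl$wss, 1)
  expect_equal(length(unique(cl$labels)), 3)
  # duplicated identical rows share a label
  dup <- rbind(m, m[1, , drop = FALSE])
  rownames(dup) <- c(rownames(m), "copy")
  cld <- kmeans_cluster(dup, 3, seed = 2)
  expect_equal(unname(cld$labels["copy"]), unname(cld$labels["r01"]))
  # deterministic given the seed
  expect_identical(kmeans_cluster(m, 3, seed = 5),
                   kmeans_cluster(m, 3, seed = 5))
  # objective beats random labelings
  set.seed(85)
  rand_wss <- replicate(100, {
    lab <- sample(1:3, nrow(m), replace = TRUE)
    sum(vapply(1:3, function(k) {
      x <- m[lab == k, , drop = FALSE]
      if (nrow(x) == 0) 0 else sum(sweep(x, 2, colMeans(x))^2)
    }, numeric(1)))
  })
  expect_true(all(cl$wss <= rand_wss))
  expect_error(kmeans_cluster(m, 0), "k must")
  expect_error(kmeans_cluster(m, 100), "exceed")
})

test_that("Fisher association handles balanced, extreme and random tables", {
  u <- sprintf("p%02d", 1:20)
  # perfectly balanced 2x2: [[5,5],[5,5]]
  res <- fisher_association(u[1:10], c(u[1:5], u[11:15]), u)
  expect_equal(res$p, 1)
  # complete separation: [[10,0],[0,10]] -> p = 2 / C(20,10)
  res2 <- fisher_association(u[1:10], u[1:10], u)
  expect_equal(res2$p, 2 / choose(20, 10), tolerance = 1e-12)
  # symmetry under swapping set and flag
  res3 <- fisher_association(u[1:10], u[6:17], u)
  res4 <- fisher_association(u[6:17], u[1:10], u)
  expect_equal(res3$p, res4$p)
  expect_error(fisher_association("a", "a", character(0)), "nonempty")
  expect_error(fisher_association("zz", "a", u), "contained")
})

test_that("resampling test agrees with hypergeometric tails", {
  pool <- sprintf("p%03d", 1:50)
  flags <- setNames(c(rep(TRUE, 20), rep(FALSE, 30)), pool)
  set.seed(86)
  samp <- sample(pool, 10)
  rs <- family_resampling_test(samp, pool, flags, B = 9999, seed = 3)
  expect_equal(rs$N, 50)
  expect_equal(rs$K, 20)
  expect_equal(rs$n, 10)
  se_u <- sqrt(rs$p_hyper_upper * (1 - rs$p_hyper_upper) / rs$B)
  se_l <- sqrt(rs$p_hyper_lower * (1 - rs$p_hyper_lower) / rs$B)
  expect_lt(abs(rs$p_upper - rs$p_hyper_upper), 3 * se_u + 2 / rs$B)
  expect_lt(abs(rs$p_lower - rs$p_hyper_lower), 3 * se_l + 2 / rs$B)
  expect_gte(rs$p_upper + rs$p_lower, 1)
})

test_that("resampling degenerate cases behave", {
  pool <- sprintf("p%02d", 1:12)
  flags <- setNames(rep(c(TRUE, FALSE), 6), pool)
  # sample = pool: both tails are 1
  rs <- family_resampling_test(pool, pool, flags, B = 99, seed = 1)
  expect_equal(rs$p_upper, 1)
  expect_equal(rs$p_lower, 1)
  # no flagged key in the sample: the upper tail is 1
  rs0 <- family_resampling_test(pool[c(2, 4, 6)], pool, flags, B = 99,
                                seed = 1)
  expect_equal(rs0$k_obs, 0)
  expect_equal(rs0$p_upper, 1)
  expect_error(family_resampling_test(c(pool, "x"), pool, flags),
               "contained")
})
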