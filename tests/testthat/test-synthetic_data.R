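test_that("parameter validation rejects invalid fractions and scales", {
  expect_error(sim_params(frac_multicopy = 1.2), "\\[0, 1\\]")
  expect_error(sim_params(frac_ejaculate = -0.1), "\\[0, 1\\]")
  expect_error(sim_params(baseline_log2_sd = 0), "> 0")
  expect_error(sim_params(peptides_per_protein = list(lambda = 0.5)),
               "lambda")
})

test_that("generator is deterministic under a fixed seed", {
  p <- sim_params(n_orthogroups = 100, seed = 5)
  a <- generate_proteome(p)
  b <- generate_proteome(p)
  expect_identical(a$orthomap, b$orthomap)
  expect_identical(a$truth, b$truth)
  expect_identical(a$annotations, b$annotations)
  pa <- simulate_experiment(a, default_design(), p)
  pb <- simulate_experiment(b, default_design(), p)
  expect_identical(pa, pb)
})

test_that("frac_multicopy = 0 yields only 1:1:1 orthogroups", {
  p <- sim_params(n_orthogroups = 150, frac_multicopy = 0, seed = 2)
  pr <- generate_proteome(p)
  cnt <- table(pr$truth$orthogroup, pr$truth$species)
  expect_true(all(cnt == 1))
  expect_false(any(pr$truth$is_family_member))
})

test_that("multicopy orthogroup count lies in the binomial 99% band", {
  p <- sim_params(n_orthogroups = 2000, frac_multicopy = 0.05, seed = 3)
  pr <- generate_proteome(p)
  n_multi <- length(unique(pr$truth$orthogroup[pr$truth$is_family_member]))
  band <- qbinom(c(0.005, 0.995), 2000, 0.05)
  expect_gte(n_multi, band[1])
  expect_lte(n_multi, band[2])
})

test_that("noise-free mated/virgin ratio equals 2^shift for ejaculate proteins", {
  p <- sim_params(n_orthogroups = 60, channel_noise_sd = 0,
                  ejaculate_log2_shift = 3, frac_ejaculate = 0.3,
                  n_postmating_response = 0, seed = 4)
  ds <- simulate_dataset(p)
  tb <- aggregate_to_protein(ds$peptides$americana)
  truth <- ds$proteome$truth
  ej <- truth$protein_id[truth$is_ejaculate & truth$species == "americana"]
  mated <- design_channels(ds$design, "americana", "mated")[1]
  virgin <- design_channels(ds$design, "americana", "virgin")[1]
  sel <- tb$protein_id %in% ej
  expect_true(any(sel))
  ratio <- tb[[mated]][sel] / tb[[virgin]][sel]
  expect_equal(ratio, rep(8, sum(sel)), tolerance = 1e-9)
  # non-ejaculate proteins are flat between the same channels
  other <- !sel
  expect_equal(tb[[mated]][other] / tb[[virgin]][other],
               rep(1, sum(other)), tolerance = 1e-9)
})

test_that("planted divergence effects are recovered within noise", {
  p <- sim_params(n_orthogroups = 500, seed = 6)
  ds <- simulate_dataset(p)
  tb <- aggregate_to_protein(ds$peptides$americana)
  truth <- ds$proteome$truth
  amer <- truth[truth$species == "americana", ]
  i <- match(tb$protein_id, amer$protein_id)
  eff <- amer$effect_americana_virilis[i]
  cha <- design_channels(ds$design, "americana", "mated")
  chb <- design_channels(ds$design, "virilis", "mated")
  lfc <- rowMeans(log2(as.matrix(tb[, cha]))) -
    rowMeans(log2(as.matrix(tb[, chb])))
  div <- !is.na(eff) & eff != 0
  expect_gt(sum(div), 30)
  # estimated log2 differences track the planted +/-2 effects
  expect_equal(mean(lfc[div] - eff[div]), 0, tolerance = 0.1)
  expect_lt(sd(lfc[div] - eff[div]), 0.5)
  expect_equal(mean(lfc[!div]), 0, tolerance = 0.1)
})

test_that("mRNA-protein coupling hits the target correlation", {
  p <- sim_params(n_orthogroups = 2000, seed = 8)
  pr <- generate_proteome(p)
  truth <- pr$truth
  mrna <- pr$annotations$mrna
  sec_ej <- truth$is_ejaculate & truth$has_signal_peptide
  for (s in c("americana", "virilis")) {
    x <- truth$base_log2 + truth$member_offset +
      truth[[paste0("offset_", s)]]
    m <- mrna[mrna$species == s & mrna$tissue == "accessory_gland", ]
    mv <- m$log2_expr[match(truth$protein_id, m$protein_id)]
    n <- sum(sec_ej)
    expect_gte(n, 200)
    r <- cor(x[sec_ej], mv[sec_ej])
    expect_lt(abs(r - p$mrna_protein_r_target), 0.1)
    # non-secretory tissue couples much more weakly
    mc <- mrna[mrna$species == s & mrna$tissue == "carcass", ]
    mcv <- mc$log2_expr[match(truth$protein_id, mc$protein_id)]
    expect_lt(cor(x[sec_ej], mcv[sec_ej]), 0.3)
  }
})

test_that("ejaculate proteins are less abundant than the tract proteome", {
  p <- sim_params(n_orthogroups = 800, seed = 9)
  ds <- simulate_dataset(p)
  truth <- ds$proteome$truth
  for (s in mq_species()) {
    tb <- aggregate_to_protein(ds$peptides[[s]])
    st <- truth[match(tb$protein_id, truth$protein_id), ]
    ab <- rowMeans(log2(intensity_matrix(tb)))
    mw <- mannwhitney_u(ab[st$is_ejaculate], ab[!st$is_ejaculate],
                        alternative = "less")
    expect_lt(mw$p, 0.05)
  }
})

test_that("design/species mismatch is a configuration error", {
  p <- sim_params(n_orthogroups = 20, seed = 1)
  pr <- generate_proteome(p)
  d <- default_design()
  d$species[1] <- "melanogaster"
  expect_error(simulate_experiment(pr, d, p), "species")
})

test_that("written synthetic dataset round-trips through the readers", {
  p <- sim_params(n_orthogroups = 40, seed = 10)
  ds <- simulate_dataset(p)
  dir <- withr::local_tempdir()
  write_synthetic(ds, dir)
  pep <- read_peptide_table(file.path(dir, "peptides_virilis.tsv"))
  expect_equal(pep$protein_id, ds$peptides$virilis$protein_id)
  expect_equal(as.matrix(pep[, chan_cols(pep)]),
               as.matrix(ds$peptides$virilis[,
                 chan_cols(ds$peptides$virilis)]),
               tolerance = 1e-12, ignore_attr = TRUE)
  om <- read_orthomap(file.path(dir, "orthomap.tsv"))
  expect_equal(om, ds$proteome$orthomap)
  expect_true(file.exists(file.path(dir, "manifest.json")))
})
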