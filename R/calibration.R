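#' Null calibration of the mated-vs-virgin differential test
#'
#' Simulates datasets with no planted effects (no ejaculate proteins,
#' no species divergence, no gene families, no postmating-response
#' proteins) and measures the false discovery proportion of
#' mated-vs-virgin calls at the standard thresholds on the combined
#' table, for one species contrast (three mated vs two virgin
#' replicates by default — the design's hardest case). Under the global
#' null every call is false, so the per-dataset false discovery
#' proportion is V / max(R, 1) and the empirical FDR is its mean.
#'
#' @param n_datasets number of simulated null datasets.
#' @param n_orthogroups orthogroups per dataset (rows in the combined
#'   table are about three times this).
#' @param seed base seed; dataset i uses `seed + i`.
#' @param species which species' mated-vs-virgin contrast to score.
#' @param lfc_threshold,q_threshold calling thresholds.
#' @param design sample design.
#' @return List: `fdp` (per-dataset false discovery proportion),
#'   `n_calls` (per-dataset call count), `empirical_fdr`, `mc_se`
#'   (Monte-Carlo standard error of the mean), `pvalues` (moderated
#'   test p-values from the first dataset, for uniformity checks).
#' @export
null_calibration <- function(n_datasets = 200, n_orthogroups = 667,
                             seed = 1, species = "americana",
                             lfc_threshold = 1, q_threshold = 0.05,
                             design = default_design()) {
  fdp <- numeric(n_datasets)
  n_calls <- integer(n_datasets)
  pvalues <- NULL
  cha <- design_channels(design, species, "mated")
  chb <- design_channels(design, species, "virgin")
  for (i in seq_len(n_datasets)) {
    params <- sim_params(
      n_orthogroups = n_orthogroups,
      frac_multicopy = 0, frac_ejaculate = 0,
      frac_species_divergent = 0, n_postmating_response = 0,
      frac_unassigned = 0, seed = seed + i
    )
    ds <- simulate_dataset(params, design)
    tables <- lapply(ds$peptides, function(pt) {
      suppressMessages(filter_min_unique(aggregate_to_protein(pt)))
    })
    combined <- suppressMessages(
      merge_by_orthogroup(tables, ds$proteome$orthomap))
    norm <- normalize_log2(intensity_matrix(combined))
    res <- fit_moderated(norm, cha, chb)
    calls <- call_differential(res, lfc_threshold, q_threshold)
    R <- sum(calls != "ns")
    n_calls[i] <- R
    fdp[i] <- R / max(R, 1)  # every call is false under the null
    if (i == 1) pvalues <- res$p
  }
  list(
    fdp = fdp,
    n_calls = n_calls,
    empirical_fdr = mean(fdp),
    mc_se = stats::sd(fdp) / sqrt(n_datasets),
    pvalues = pvalues
  )
}
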