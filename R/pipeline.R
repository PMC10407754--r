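#' Pipeline configuration
#'
#' Collects every tunable the end-to-end analysis uses: the synthetic
#' generator parameters (or an input directory of previously written
#' tables), thresholds, cluster counts, resampling draws and seeds.
#'
#' @param params [sim_params()] object used when simulating.
#' @param design sample design data frame.
#' @param input_dir optional directory of tables written by
#'   [write_synthetic()]; when given, tables are read instead of
#'   simulated.
#' @param lfc_threshold,q_threshold differential-abundance calling
#'   thresholds.
#' @param min_unique minimum unique peptides per protein.
#' @param min_genes minimum annotated genes per tested GO term.
#' @param k_ejaculate,k_frt k-means cluster counts for the ejaculate
#'   and tract heatmaps.
#' @param resampling_b Monte-Carlo draws for the gene-family test.
#' @param n_top_pca number of most-variable proteins for the PCA.
#' @param seed seed for clustering and resampling (the generator has
#'   its own seed inside `params`).
#' @return List of class `mq_config`.
#' @export
pipeline_config <- function(params = sim_params(),
                            design = default_design(),
                            input_dir = NULL,
                            lfc_threshold = 1,
                            q_threshold = 0.05,
                            min_unique = 2,
                            min_genes = 15,
                            k_ejaculate = 7,
                            k_frt = 4,
                            resampling_b = 99999,
                            n_top_pca = 500,
                            seed = 1L) {
  if (lfc_threshold <= 0 || q_threshold <= 0) {
    stop("thresholds must be positive")
  }
  if (min_unique < 1) stop("min_unique must be >= 1")
  cfg <- list(params = params, design = design, input_dir = input_dir,
              lfc_threshold = lfc_threshold, q_threshold = q_threshold,
              min_unique = min_unique, min_genes = min_genes,
              k_ejaculate = k_ejaculate, k_frt = k_frt,
              resampling_b = resampling_b, n_top_pca = n_top_pca,
              seed = as.integer(seed))
  class(cfg) <- "mq_config"
  cfg
}

read_synthetic_inputs <- function(dir, design) {
  peptides <- lapply(unique(design$species), function(s) {
    read_peptide_table(file.path(dir, sprintf("peptides_%s.tsv", s)))
  })
  names(peptides) <- unique(design$species)
  list(
    peptides = peptides,
    orthomap = read_orthomap(file.path(dir, "orthomap.tsv")),
    annotations = list(
      proteins = utils::read.delim(
        file.path(dir, "annotations_proteins.tsv"),
        stringsAsFactors = FALSE),
      go = utils::read.delim(file.path(dir, "annotations_go.tsv"),
                             stringsAsFactors = FALSE),
      omega = utils::read.delim(file.path(dir, "annotations_omega.tsv"),
                                stringsAsFactors = FALSE),
      genome_omega = utils::read.delim(
        file.path(dir, "annotations_genome_omega.tsv"),
        stringsAsFactors = FALSE),
      mrna = utils::read.delim(file.path(dir, "annotations_mrna.tsv"),
                               stringsAsFactors = FALSE)
    ),
    exclusion_list = readLines(file.path(dir, "exclusion_list.txt")),
    truth = NULL
  )
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest, peptide-to-protein aggregation, the
#' unique-peptide filter, orthogroup merging, TMM normalization,
#' per-species mated-vs-virgin contrasts, ejaculate classification,
#' between-species divergence for the ejaculate and tract sets, k-means
#' clustering, signal-peptide association tests, the gene-family
#' resampling test, evolutionary-rate comparisons, GO enrichment,
#' mRNA-protein correlations and PCA. Every stage logs row counts via
#' [message()]. Deterministic under fixed seeds.
#'
#' @param config an [pipeline_config()] object.
#' @param out_dir optional output directory; when given, all stage
#'   tables and a `summary.json` are written.
#' @return List of class `mq_pipeline_result` with all stage outputs
#'   and a `summary` list of headline counts.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (!inherits(config, "mq_config")) {
    stop("config must be created by pipeline_config()")
  }
  design <- config$design
  sp <- unique(design$species)
  pairs <- utils::combn(sort(sp), 2, simplify = FALSE)

  # --- simulate or ingest -------------------------------------------------
  if (is.null(config$input_dir)) {
    message("stage simulate: generating synthetic dataset")
    ds <- simulate_dataset(config$params, design)
    peptides <- ds$peptides
    orthomap <- ds$proteome$orthomap
    annotations <- ds$proteome$annotations
    exclusion_list <- ds$proteome$exclusion_list
    truth <- ds$proteome$truth
  } else {
    message("stage ingest: reading tables from ", config$input_dir)
    inp <- read_synthetic_inputs(config$input_dir, design)
    peptides <- inp$peptides
    orthomap <- inp$orthomap
    annotations <- inp$annotations
    exclusion_list <- inp$exclusion_list
    truth <- inp$truth
  }

  # --- aggregate + filter per species ------------------------------------
  per_species <- lapply(sp, function(s) {
    tb <- aggregate_to_protein(peptides[[s]])
    message(sprintf("stage aggregate: %s: %d peptides -> %d proteins",
                    s, nrow(peptides[[s]]), nrow(tb)))
    filt <- filter_min_unique(tb, config$min_unique)
    list(all = tb, filtered = filt)
  })
  names(per_species) <- sp

  # per-species mated-vs-virgin contrast (includes orthology-unassigned
  # proteins, which only exist in within-species analyses)
  species_level <- lapply(sp, function(s) {
    tb <- per_species[[s]]$filtered
    mat <- intensity_matrix(tb)
    nn <- normalize_log2(mat)
    res <- fit_moderated(nn, design_channels(design, s, "mated"),
                         design_channels(design, s, "virgin"))
    res$call <- call_differential(res, config$lfc_threshold,
                                  config$q_threshold)
    cand <- res$row_key[res$call == "up"]
    uniq <- setdiff(cand, orthomap$protein_id)
    message(sprintf(
      "stage diffexp: %s: %d candidates (%d without orthogroup)",
      s, length(cand), length(uniq)))
    list(table = tb, contrast = res, candidates = cand,
         candidates_unique = uniq)
  })
  names(species_level) <- sp

  # --- merge + normalize the combined table ------------------------------
  combined <- merge_by_orthogroup(
    lapply(species_level, function(x) x$table), orthomap)
  message(sprintf("stage merge: combined table has %d rows (%d orthogroups)",
                  nrow(combined), length(unique(combined$orthogroup))))
  cmat <- intensity_matrix(combined)
  norm <- normalize_log2(cmat)

  # --- classify ejaculate vs tract ---------------------------------------
  calls <- vapply(sp, function(s) {
    res <- fit_moderated(norm, design_channels(design, s, "mated"),
                         design_channels(design, s, "virgin"))
    call_differential(res, config$lfc_threshold, config$q_threshold)
  }, character(nrow(combined)))
  classification <- classify_ejaculate(calls, combined$row_key,
                                       combined$protein_id,
                                       exclusion_list)
  n_by_class <- table(classification$class)
  message("stage classify: ",
          paste(names(n_by_class), as.integer(n_by_class),
                sep = "=", collapse = ", "))

  sig_df <- annotations$proteins[, c("protein_id", "has_signal_peptide")]
  sig_fraction <- signal_peptide_fraction(classification, sig_df)

  ej_rows <- classification$row_key[classification$class == "ejaculate"]
  frt_rows <- classification$row_key[classification$class %in%
                                       c("FRT", "virgin-biased")]

  # --- divergence contrasts ----------------------------------------------
  run_pairs <- function(rows, status) {
    out <- lapply(pairs, function(ab) {
      pairwise_divergence(norm, design, ab[1], ab[2], status = status,
                          rows = rows,
                          lfc_threshold = config$lfc_threshold,
                          q_threshold = config$q_threshold)
    })
    names(out) <- vapply(pairs, paste, collapse = "_", character(1))
    out
  }
  ej_divergence <- if (length(ej_rows) >= 2) {
    run_pairs(ej_rows, "mated")
  } else {
    NULL
  }
  frt_divergence <- if (length(frt_rows) >= 2) {
    run_pairs(frt_rows, "virgin")
  } else {
    NULL
  }
  for (nm in names(ej_divergence)) {
    message(sprintf("stage diverge: ejaculate %s: %d differentially abundant",
                    nm, attr(ej_divergence[[nm]], "n_called")))
  }
  for (nm in names(frt_divergence)) {
    message(sprintf("stage diverge: tract %s: %d differentially abundant",
                    nm, attr(frt_divergence[[nm]], "n_called")))
  }

  # --- clustering ---------------------------------------------------------
  centered <- replicate_average_center(norm, design)
  ej_clusters <- if (length(ej_rows) >= config$k_ejaculate) {
    kmeans_cluster(centered[ej_rows, , drop = FALSE], config$k_ejaculate,
                   seed = config$seed)
  } else NULL
  frt_clusters <- if (length(frt_rows) >= config$k_frt) {
    kmeans_cluster(centered[frt_rows, , drop = FALSE], config$k_frt,
                   seed = config$seed)
  } else NULL

  # --- signal peptide x divergence association ---------------------------
  fam_df <- annotations$proteins[, c("protein_id", "has_signal_peptide")]
  sig_ids <- fam_df$protein_id[fam_df$has_signal_peptide]
  sig_assoc <- list()
  for (nm in names(ej_divergence)) {
    res <- ej_divergence[[nm]]
    div_keys <- res$row_key[res$call != "ns"]
    ids <- combined$protein_id[match(res$row_key, combined$row_key)]
    div_ids <- combined$protein_id[match(div_keys, combined$row_key)]
    sig_assoc[[paste0("ejaculate.", nm)]] <-
      fisher_association(div_ids, sig_ids, ids)
  }
  for (nm in names(frt_divergence)) {
    res <- frt_divergence[[nm]]
    div_keys <- res$row_key[res$call != "ns"]
    ids <- combined$protein_id[match(res$row_key, combined$row_key)]
    div_ids <- combined$protein_id[match(div_keys, combined$row_key)]
    sig_assoc[[paste0("frt.", nm)]] <-
      fisher_association(div_ids, sig_ids, ids)
  }

  # --- gene-family resampling test ---------------------------------------
  fam_flags <- combined$is_family_member
  names(fam_flags) <- combined$row_key
  resampling <- if (length(ej_rows) > 0) {
    family_resampling_test(ej_rows, combined$row_key, fam_flags,
                           B = config$resampling_b,
                           seed = config$seed + 1L)
  } else NULL

  # --- evolutionary rates -------------------------------------------------
  ann <- annotations$proteins
  quantified <- unique(combined$protein_id)
  cls_of <- classification$class[match(ann$protein_id,
                                       classification$protein_id)]
  is_ej <- !is.na(cls_of) & cls_of == "ejaculate"
  is_frt <- !is.na(cls_of) & cls_of %in% c("FRT", "virgin-biased")
  groups <- list(
    ejaculate_sec = ann$protein_id[is_ej & ann$has_signal_peptide],
    ejaculate_nonsec = ann$protein_id[is_ej & !ann$has_signal_peptide],
    frt_step_sec = ann$protein_id[is_frt & ann$serine_type_endopeptidase],
    frt_sec = ann$protein_id[is_frt & ann$has_signal_peptide &
                               !ann$serine_type_endopeptidase],
    frt_nonsec = ann$protein_id[is_frt & !ann$has_signal_peptide]
  )
  rate_comparisons <- list(
    c("ejaculate_sec", "ejaculate_nonsec"),
    c("ejaculate_sec", "genome"),
    c("ejaculate_nonsec", "genome"),
    c("frt_sec", "frt_nonsec"),
    c("frt_sec", "genome"),
    c("frt_step_sec", "frt_sec"),
    c("frt_step_sec", "ejaculate_sec"),
    c("frt_step_sec", "genome")
  )
  rates <- compare_rate_groups(annotations$omega, groups,
                               comparisons = rate_comparisons,
                               genome_omega = annotations$genome_omega)

  # --- GO enrichment ------------------------------------------------------
  ej_ids <- unique(classification$protein_id[classification$class ==
                                               "ejaculate"])
  enrichment <- go_enrichment(ej_ids, quantified, annotations$go,
                              min_genes = config$min_genes)

  # --- mRNA-protein correlation ------------------------------------------
  mrna_cor <- mrna_protein_correlation(norm, design, combined,
                                       classification, ann,
                                       annotations$mrna)

  # --- PCA ----------------------------------------------------------------
  pca <- pca_top_variable(norm, config$n_top_pca)
  message(sprintf("stage pca: PC1 explains %.1f%% of variance",
                  pca$var_explained[1]))

  summary <- pipeline_summary(sp, per_species, species_level, combined,
                              classification, ej_divergence,
                              frt_divergence, resampling, pca,
                              sig_fraction)

  result <- list(
    design = design, peptides = peptides, orthomap = orthomap,
    annotations = annotations, exclusion_list = exclusion_list,
    truth = truth, per_species = species_level, combined = combined,
    norm = norm, classification = classification,
    sig_fraction = sig_fraction, ej_divergence = ej_divergence,
    frt_divergence = frt_divergence, ej_clusters = ej_clusters,
    frt_clusters = frt_clusters, sig_assoc = sig_assoc,
    resampling = resampling, rates = rates, enrichment = enrichment,
    mrna_cor = mrna_cor, pca = pca, summary = summary, config = config
  )
  class(result) <- "mq_pipeline_result"
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

mrna_protein_correlation <- function(norm, design, combined,
                                     classification, ann, mrna) {
  sec_ej <- classification$protein_id[
    classification$class == "ejaculate" &
      ann$has_signal_peptide[match(classification$protein_id,
                                   ann$protein_id)]]
  out <- list()
  for (s in unique(design$species)) {
    ch <- design_channels(design, s, "mated")
    keys <- combined$row_key[combined$species == s &
                               combined$protein_id %in% sec_ej]
    if (length(keys) < 3) next
    prot <- rowMeans(norm$log2[keys, ch, drop = FALSE])
    ids <- combined$protein_id[match(keys, combined$row_key)]
    for (ti in unique(mrna$tissue)) {
      m <- mrna[mrna$species == s & mrna$tissue == ti, ]
      mv <- m$log2_expr[match(ids, m$protein_id)]
      ok <- !is.na(mv)
      if (sum(ok) < 3) next
      pc <- pearson_r(mv[ok], prot[ok])
      out[[length(out) + 1]] <- data.frame(
        species = s, tissue = ti, class = "ejaculate_sec",
        n = pc$n, r = pc$r, p = pc$p, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

pipeline_summary <- function(sp, per_species, species_level, combined,
                             classification, ej_divergence,
                             frt_divergence, resampling, pca,
                             sig_fraction) {
  n_by_class <- function(cc) {
    sum(classification$class == cc)
  }
  og_of <- function(cc) {
    length(unique(combined$orthogroup[classification$class == cc]))
  }
  div_counts <- function(dv) {
    if (is.null(dv)) return(NULL)
    lapply(dv, function(res) {
      list(n = nrow(res), n_differential = attr(res, "n_called"))
    })
  }
  sigf <- function(cc) {
    i <- match(cc, sig_fraction$class)
    if (is.na(i)) NULL else sig_fraction$fraction[i]
  }
  list(
    species = lapply(stats::setNames(sp, sp), function(s) {
      list(
        total_proteins = nrow(per_species[[s]]$all),
        two_unique_peptides = nrow(per_species[[s]]$filtered),
        ejaculate_candidates = length(species_level[[s]]$candidates),
        ejaculate_candidates_unique =
          length(species_level[[s]]$candidates_unique)
      )
    }),
    combined = list(
      rows = nrow(combined),
      orthogroups = length(unique(combined$orthogroup)),
      ejaculate_proteins = n_by_class("ejaculate"),
      ejaculate_orthogroups = og_of("ejaculate"),
      ejaculate_shared_all_species =
        sum(classification$shared_across_species &
              classification$class == "ejaculate"),
      frt_proteins = n_by_class("FRT") + n_by_class("virgin-biased"),
      frt_orthogroups = length(unique(
        combined$orthogroup[classification$class %in%
                              c("FRT", "virgin-biased")])),
      virgin_biased = n_by_class("virgin-biased"),
      excluded = n_by_class("excluded")
    ),
    signal_peptide_fraction = list(
      ejaculate = sigf("ejaculate"),
      frt = sigf("FRT")
    ),
    ejaculate_divergence = div_counts(ej_divergence),
    frt_divergence = div_counts(frt_divergence),
    family_resampling = if (!is.null(resampling)) {
      resampling[c("N", "K", "n", "k_obs", "B", "p_upper", "p_lower",
                   "p_hyper_upper", "p_hyper_lower")]
    } else NULL,
    pca_variance_pct = round(pca$var_explained[1:3], 1)
  )
}

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tsv <- function(x, f) {
    utils::write.table(x, file.path(out_dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(result$combined, "combined.tsv")
  tsv(as.data.frame(result$classification), "classification.tsv")
  tsv(result$sig_fraction, "signal_peptide_fraction.tsv")
  for (nm in names(result$ej_divergence)) {
    tsv(as.data.frame(result$ej_divergence[[nm]]),
        sprintf("divergence_ejaculate_%s.tsv", nm))
  }
  for (nm in names(result$frt_divergence)) {
    tsv(as.data.frame(result$frt_divergence[[nm]]),
        sprintf("divergence_frt_%s.tsv", nm))
  }
  if (!is.null(result$ej_clusters)) {
    tsv(data.frame(row_key = names(result$ej_clusters$labels),
                   cluster = unname(result$ej_clusters$labels)),
        "clusters_ejaculate.tsv")
  }
  if (!is.null(result$frt_clusters)) {
    tsv(data.frame(row_key = names(result$frt_clusters$labels),
                   cluster = unname(result$frt_clusters$labels)),
        "clusters_frt.tsv")
  }
  if (!is.null(result$resampling)) {
    jsonlite::write_json(
      result$resampling[c("N", "K", "n", "k_obs", "B", "p_upper",
                          "p_lower", "p_hyper_upper", "p_hyper_lower",
                          "seed")],
      file.path(out_dir, "resampling.json"), auto_unbox = TRUE,
      digits = NA)
  }
  tsv(result$rates$summary, "rates_summary.tsv")
  if (!is.null(result$rates$tests)) tsv(result$rates$tests, "rates_tests.tsv")
  tsv(result$enrichment, "enrichment.tsv")
  if (!is.null(result$mrna_cor)) tsv(result$mrna_cor, "mrna_correlation.tsv")
  jsonlite::write_json(
    list(var_explained_pct = result$pca$var_explained,
         scores = as.data.frame(result$pca$scores)),
    file.path(out_dir, "pca.json"), digits = NA)
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Recovery of the planted ejaculate set against ground truth
#'
#' Sensitivity and false discovery rate of the classified ejaculate set
#' relative to the planted truth, restricted to proteins present in the
#' combined table (the classifier cannot recover filtered-out rows).
#'
#' @param classification `mq_classification` from the pipeline.
#' @param truth generator truth table (needs `protein_id`,
#'   `is_ejaculate`).
#' @return List: `sensitivity`, `fdr`, `n_called`, `n_true_present`.
#' @export
recovery_metrics <- function(classification, truth) {
  called <- unique(classification$protein_id[
    classification$class == "ejaculate"])
  present <- unique(classification$protein_id)
  true_ej <- unique(truth$protein_id[truth$is_ejaculate])
  true_present <- intersect(true_ej, present)
  tp <- length(intersect(called, true_present))
  fp <- length(setdiff(called, true_ej))
  list(
    sensitivity = if (length(true_present) > 0) {
      tp / length(true_present)
    } else NA_real_,
    fdr = if (length(called) > 0) fp / length(called) else 0,
    n_called = length(called),
    n_true_present = length(true_present)
  )
}

#' Recovery of planted between-species divergence
#'
#' Compares per-row divergence calls against the planted per-pair truth
#' effects; sensitivity over rows with a nonzero planted effect, FDR
#' over called rows.
#'
#' @param divergence named list of per-pair `mq_contrast` results (as
#'   produced inside [run_pipeline()]), names `speciesA_speciesB`.
#' @param combined combined table (maps row keys to protein IDs).
#' @param truth generator truth table with `effect_<pair>` columns.
#' @return List: `sensitivity`, `fdr`, `n_true`, `n_called`.
#' @export
divergence_recovery <- function(divergence, combined, truth) {
  tp <- 0L; fp <- 0L; n_true <- 0L; n_called <- 0L
  for (nm in names(divergence)) {
    res <- divergence[[nm]]
    ids <- combined$protein_id[match(res$row_key, combined$row_key)]
    eff <- truth[[paste0("effect_", nm)]][match(ids, truth$protein_id)]
    truly <- !is.na(eff) & eff != 0
    called <- res$call != "ns"
    tp <- tp + sum(truly & called)
    fp <- fp + sum(!truly & called)
    n_true <- n_true + sum(truly)
    n_called <- n_called + sum(called)
  }
  list(
    sensitivity = if (n_true > 0) tp / n_true else NA_real_,
    fdr = if (n_called > 0) fp / n_called else 0,
    n_true = n_true, n_called = n_called
  )
}
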