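#' Simulation parameters for the synthetic proteomics generator
#'
#' Bundles every quantity the generator needs to fabricate peptide-level
#' reporter-intensity tables, orthology maps and annotations with the
#' statistical structure the downstream analysis assumes. Defaults encode
#' the study conditions: a 16-plex design over three species, ~5%
#' one-to-many orthogroups, ~10% transferred ejaculate proteins planted at
#' lower baseline abundance with a +3 log2 mating shift, between-species
#' divergence effects of 2 log2 units, signal-peptide probabilities of
#' 0.52 (ejaculate) and 0.41 (female reproductive tract), elevated dN/dS
#' for secreted ejaculate proteins and female serine-type endopeptidases,
#' and a target mRNA-protein correlation of 0.45 for secreted ejaculate
#' proteins in male secretory tissues.
#'
#' @param n_orthogroups number of orthogroups to simulate.
#' @param frac_multicopy fraction of orthogroups carrying a duplicated
#'   member in one species (gene families).
#' @param frac_ejaculate fraction of orthogroups that are transferred
#'   male ejaculate proteins.
#' @param ejaculate_log2_shift log2 abundance increase of ejaculate
#'   proteins in mated channels.
#' @param frac_species_divergent fraction of orthogroups with a planted
#'   between-species abundance difference (gene-family orthogroups are
#'   always planted divergent, on top of this fraction).
#' @param divergent_log2_effect absolute log2 effect of planted
#'   species divergence.
#' @param peptides_per_protein list with `lambda` (mean peptide count of
#'   the shifted Poisson, minimum 1), `frac_single` (fraction of proteins
#'   forced to exactly one unique peptide, exercising the >=2 filter).
#' @param peptide_offset_sd log2 SD of the per-peptide ionization offset
#'   (drawn once per peptide, shared across channels).
#' @param channel_noise_sd log2 SD of per-peptide, per-channel
#'   measurement noise.
#' @param baseline_log2_mean,baseline_log2_sd log2-intensity scale of
#'   protein baselines.
#' @param ejaculate_baseline_offset log2 offset (negative) applied to
#'   ejaculate protein baselines; transferred proteins are less abundant
#'   than the resident tract proteome.
#' @param member_offset_sd log2 SD of the per-protein offset around the
#'   orthogroup baseline (orthologs/paralogs differ slightly).
#' @param sig_peptide_prob_by_class named vector of signal-peptide
#'   probabilities for classes `ejaculate` and `frt`.
#' @param frac_frt_step fraction of female reproductive tract proteins
#'   annotated as secreted serine-type endopeptidases.
#' @param omega_params_by_class named list of `c(shape, scale)` gamma
#'   parameters of pairwise dN/dS by rate class (`ejaculate_sec`,
#'   `ejaculate_nonsec`, `frt_step_sec`, `frt_sec`, `frt_nonsec`,
#'   `background`).
#' @param mrna_protein_r_target target Pearson correlation between log
#'   mRNA abundance in male secretory tissues and log2 protein abundance
#'   for secreted ejaculate proteins.
#' @param n_postmating_response number of planted female postmating-
#'   response proteins (mating-responsive but not male-derived); these
#'   form the curated exclusion list.
#' @param frac_unassigned fraction of proteins left out of the orthology
#'   map (species-unique candidates).
#' @param n_genome_background number of genome-background genes for which
#'   pairwise dN/dS is emitted (genome-average reference).
#' @param peptide_dropout optional probability of dropping a peptide row
#'   (robustness tests only; default 0, isobaric data are near-complete).
#' @param seed integer seed; a fixed seed makes every generator output
#'   byte-identical across runs.
#'
#' @return An object of class `mq_sim_params` (a validated list).
#' @export
sim_params <- function(n_orthogroups = 2000,
                       frac_multicopy = 0.05,
                       frac_ejaculate = 0.10,
                       ejaculate_log2_shift = 3,
                       frac_species_divergent = 0.25,
                       divergent_log2_effect = 2,
                       peptides_per_protein = list(lambda = 3, frac_single = 0.05),
                       peptide_offset_sd = 0.8,
                       channel_noise_sd = 0.5,
                       baseline_log2_mean = 20,
                       baseline_log2_sd = 2,
                       ejaculate_baseline_offset = -2,
                       member_offset_sd = 0.25,
                       sig_peptide_prob_by_class = c(ejaculate = 0.52, frt = 0.41),
                       frac_frt_step = 0.05,
                       omega_params_by_class = list(
                         ejaculate_sec = c(shape = 2, scale = 0.15),
                         ejaculate_nonsec = c(shape = 2, scale = 0.09),
                         frt_step_sec = c(shape = 2, scale = 0.14),
                         frt_sec = c(shape = 2, scale = 0.06),
                         frt_nonsec = c(shape = 2, scale = 0.04),
                         background = c(shape = 2, scale = 0.09)),
                       mrna_protein_r_target = 0.45,
                       n_postmating_response = 12,
                       frac_unassigned = 0.03,
                       n_genome_background = 4000,
                       peptide_dropout = 0,
                       seed = 1L) {
  p <- list(
    n_orthogroups = as.integer(n_orthogroups),
    frac_multicopy = frac_multicopy,
    frac_ejaculate = frac_ejaculate,
    ejaculate_log2_shift = ejaculate_log2_shift,
    frac_species_divergent = frac_species_divergent,
    divergent_log2_effect = divergent_log2_effect,
    peptides_per_protein = peptides_per_protein,
    peptide_offset_sd = peptide_offset_sd,
    channel_noise_sd = channel_noise_sd,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    ejaculate_baseline_offset = ejaculate_baseline_offset,
    member_offset_sd = member_offset_sd,
    sig_peptide_prob_by_class = sig_peptide_prob_by_class,
    frac_frt_step = frac_frt_step,
    omega_params_by_class = omega_params_by_class,
    mrna_protein_r_target = mrna_protein_r_target,
    n_postmating_response = as.integer(n_postmating_response),
    frac_unassigned = frac_unassigned,
    n_genome_background = as.integer(n_genome_background),
    peptide_dropout = peptide_dropout,
    seed = as.integer(seed)
  )
  fracs <- c("frac_multicopy", "frac_ejaculate", "frac_species_divergent",
             "frac_frt_step", "frac_unassigned", "peptide_dropout",
             "mrna_protein_r_target")
  for (f in fracs) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("parameter '", f, "' must be a single value in [0, 1]")
    }
  }
  if (any(p$sig_peptide_prob_by_class < 0 | p$sig_peptide_prob_by_class > 1)) {
    stop("sig_peptide_prob_by_class probabilities must lie in [0, 1]")
  }
  sds <- c("peptide_offset_sd", "baseline_log2_sd")
  for (f in sds) {
    if (p[[f]] <= 0) stop("parameter '", f, "' must be > 0")
  }
  if (p$channel_noise_sd < 0) stop("channel_noise_sd must be >= 0")
  if (p$member_offset_sd < 0) stop("member_offset_sd must be >= 0")
  if (p$n_orthogroups < 1) stop("n_orthogroups must be >= 1")
  if (is.null(p$peptides_per_protein$lambda) ||
      p$peptides_per_protein$lambda < 1) {
    stop("peptides_per_protein$lambda must be >= 1")
  }
  class(p) <- "mq_sim_params"
  p
}

og_pairs <- function() {
  c("americana_novamexicana", "americana_virilis", "novamexicana_virilis")
}

#' Generate a synthetic three-species proteome with ground truth
#'
#' Draws orthogroups (mostly 1:1:1, a configurable fraction with a
#' duplicated member in one species), assigns ejaculate / female tract
#' classes, between-species divergence offsets, signal peptides,
#' serine-type endopeptidase flags, pairwise dN/dS by rate class, GO
#' terms, and tissue mRNA abundances coupled to protein baselines at a
#' target correlation.
#'
#' @param params an [sim_params()] object.
#' @return A list of class `mq_proteome` with components:
#'   \describe{
#'     \item{orthomap}{data frame `protein_id`, `species`, `orthogroup`
#'       (proteins sampled as unassigned are absent, mirroring orthology
#'       pipelines that leave some proteins unplaced).}
#'     \item{annotations}{list of data frames: `proteins` (flags),
#'       `go` (protein_id, term, branch), `omega` (protein_id, pair,
#'       omega), `genome_omega` (gene_id, pair, omega), `mrna`
#'       (protein_id, species, tissue, log2_expr).}
#'     \item{truth}{per-protein planted truth: class labels, per-pair
#'       divergence flags and true log2 effects, baselines.}
#'     \item{exclusion_list}{protein IDs of planted female
#'       postmating-response proteins.}
#'     \item{params}{the parameters used.}
#'   }
#' @export
generate_proteome <- function(params) {
  if (!inherits(params, "mq_sim_params")) {
    stop("params must be created by sim_params()")
  }
  set.seed(params$seed)
  sp <- mq_species()
  short <- mq_species_short()
  n <- params$n_orthogroups
  og <- sprintf("OG%05d", seq_len(n))

  multicopy <- stats::runif(n) < params$frac_multicopy
  is_ejac <- stats::runif(n) < params$frac_ejaculate
  pmr <- rep(FALSE, n)
  idx_frt <- which(!is_ejac)
  n_pmr <- min(params$n_postmating_response, length(idx_frt))
  if (n_pmr > 0) pmr[sample(idx_frt, n_pmr)] <- TRUE

  divergent <- stats::runif(n) < params$frac_species_divergent
  divergent[multicopy] <- TRUE  # gene families are planted divergent
  div_sp <- sample(sp, n, replace = TRUE)
  div_sign <- sample(c(-1, 1), n, replace = TRUE)
  div_off <- matrix(0, n, 3, dimnames = list(og, sp))
  if (any(divergent)) {
    div_off[cbind(which(divergent), match(div_sp[divergent], sp))] <-
      (div_sign * params$divergent_log2_effect)[divergent]
  }

  base <- stats::rnorm(
    n,
    params$baseline_log2_mean +
      ifelse(is_ejac, params$ejaculate_baseline_offset, 0),
    params$baseline_log2_sd
  )

  # copy counts per orthogroup x species; duplicates land in one species
  copies <- matrix(1L, n, 3, dimnames = list(og, sp))
  extra_sp <- sample(sp, n, replace = TRUE)
  if (any(multicopy)) {
    copies[cbind(which(multicopy), match(extra_sp[multicopy], sp))] <- 2L
  }

  tab <- do.call(rbind, lapply(seq_along(sp), function(j) {
    k <- copies[, j]
    data.frame(
      orthogroup = rep(og, k),
      species = sp[j],
      copy = sequence(k),
      stringsAsFactors = FALSE
    )
  }))
  tab$protein_id <- sprintf("%s_%s_p%d", short[tab$species],
                            tab$orthogroup, tab$copy)
  rownames(tab) <- NULL
  i <- match(tab$orthogroup, og)

  tab$is_ejaculate <- is_ejac[i]
  tab$is_pmr <- pmr[i]
  tab$is_family_member <- multicopy[i]
  tab$base_log2 <- base[i]
  tab$member_offset <- stats::rnorm(nrow(tab), 0, params$member_offset_sd)
  for (s in sp) tab[[paste0("offset_", s)]] <- div_off[i, s]

  pairs <- og_pairs()
  for (pr in pairs) {
    ab <- strsplit(pr, "_", fixed = TRUE)[[1]]
    eff <- div_off[i, ab[1]] - div_off[i, ab[2]]
    tab[[paste0("effect_", pr)]] <- eff
    tab[[paste0("divergent_", pr)]] <- eff != 0
  }

  cls <- ifelse(tab$is_ejaculate, "ejaculate", "frt")
  tab$has_signal_peptide <- stats::runif(nrow(tab)) <
    params$sig_peptide_prob_by_class[cls]
  tab$is_step <- !tab$is_ejaculate &
    stats::runif(nrow(tab)) < params$frac_frt_step
  tab$has_signal_peptide[tab$is_step] <- TRUE  # STEP class is secreted

  tab$rate_class <- ifelse(
    tab$is_ejaculate,
    ifelse(tab$has_signal_peptide, "ejaculate_sec", "ejaculate_nonsec"),
    ifelse(tab$is_step, "frt_step_sec",
           ifelse(tab$has_signal_peptide, "frt_sec", "frt_nonsec"))
  )

  # proteins left out of the orthology map (species-unique candidates)
  tab$orthology_assigned <- stats::runif(nrow(tab)) >= params$frac_unassigned

  # pairwise dN/dS drawn per rate class
  om <- params$omega_params_by_class
  omega <- do.call(rbind, lapply(pairs, function(pr) {
    pars <- do.call(rbind, om[tab$rate_class])
    data.frame(
      protein_id = tab$protein_id,
      pair = pr,
      omega = stats::rgamma(nrow(tab), shape = pars[, "shape"],
                            scale = pars[, "scale"]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(omega) <- NULL

  genome_omega <- do.call(rbind, lapply(pairs, function(pr) {
    data.frame(
      gene_id = sprintf("BG%05d", seq_len(params$n_genome_background)),
      pair = pr,
      omega = stats::rgamma(params$n_genome_background,
                            shape = om$background["shape"],
                            scale = om$background["scale"]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(genome_omega) <- NULL

  go <- synth_go_terms(tab)
  mrna <- synth_mrna(tab, params)

  annotations <- list(
    proteins = tab[, c("protein_id", "species", "orthogroup",
                       "has_signal_peptide", "is_step",
                       "is_family_member")],
    go = go,
    omega = omega,
    genome_omega = genome_omega,
    mrna = mrna
  )
  names(annotations$proteins)[names(annotations$proteins) == "is_step"] <-
    "serine_type_endopeptidase"

  orthomap <- tab[tab$orthology_assigned,
                  c("protein_id", "species", "orthogroup")]
  rownames(orthomap) <- NULL

  out <- list(
    orthomap = orthomap,
    annotations = annotations,
    truth = tab,
    exclusion_list = tab$protein_id[tab$is_pmr],
    params = params
  )
  class(out) <- "mq_proteome"
  out
}

# GO catalogue: generic terms plus a few reproduction terms planted to be
# enriched among ejaculate proteins
synth_go_terms <- function(tab) {
  branches <- c(rep("BP", 20), rep("CC", 10), rep("MF", 10))
  terms <- sprintf("GO:%07d", seq_along(branches))
  planted <- terms[1:5]  # sperm/seminal-fluid-like BP terms
  n <- nrow(tab)
  base_k <- 1 + stats::rpois(n, 2)
  rows <- vector("list", n)
  pick <- lapply(seq_len(n), function(j) {
    sample(terms, min(base_k[j], length(terms)))
  })
  ej <- tab$is_ejaculate
  planted_hits <- matrix(stats::runif(n * length(planted)), n) <
    ifelse(ej, 0.25, 0.02)
  for (j in seq_len(n)) {
    tj <- unique(c(pick[[j]], planted[planted_hits[j, ]]))
    rows[[j]] <- data.frame(protein_id = tab$protein_id[j], term = tj,
                            stringsAsFactors = FALSE)
  }
  go <- do.call(rbind, rows)
  go$branch <- branches[match(go$term, terms)]
  rownames(go) <- NULL
  go
}

# mRNA abundances per male tissue, coupled to the protein log2 baseline.
# For a target correlation r, mrna = r * z(protein) + sqrt(1 - r^2) * e,
# so the sample correlation within a class approaches r.
synth_mrna <- function(tab, params) {
  tissues <- c("accessory_gland", "ejaculatory_bulb", "testis", "carcass")
  sp <- mq_species()
  r_target <- params$mrna_protein_r_target
  sec_ej <- tab$is_ejaculate & tab$has_signal_peptide
  out <- vector("list", length(sp) * length(tissues))
  k <- 0
  for (s in sp) {
    x <- tab$base_log2 + tab$member_offset + tab[[paste0("offset_", s)]]
    z <- (x - mean(x)) / stats::sd(x)
    for (ti in tissues) {
      r <- if (ti %in% c("accessory_gland", "ejaculatory_bulb")) {
        ifelse(sec_ej, r_target, 0.15)
      } else {
        rep(0.1, nrow(tab))
      }
      m <- r * z + sqrt(1 - r^2) * stats::rnorm(nrow(tab))
      k <- k + 1
      out[[k]] <- data.frame(
        protein_id = tab$protein_id, species = s, tissue = ti,
        log2_expr = 6 + 2 * m, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate the 16-plex labeling experiment at the peptide level
#'
#' Each protein row tracks its orthogroup's abundance across all
#' channels: peptide intensities are `2^(protein log2 + peptide offset +
#' channel noise)`, where the protein's channel log2 value is its
#' baseline plus the species-divergence offset of the channel's species,
#' plus the mating shift in mated channels for ejaculate (and planted
#' postmating-response) proteins. Conserved peptides report every sample
#' in the multiplexed mixture, so the mating shift applies in mated
#' channels of every species (conspecific matings throughout).
#'
#' @param proteome an `mq_proteome` from [generate_proteome()].
#' @param design a sample design (see [default_design()]).
#' @param params the same [sim_params()] used for the proteome.
#' @return Named list (one element per species) of peptide-level
#'   data frames with columns `peptide`, `protein_id`, `is_unique`,
#'   and one intensity column per design channel.
#' @export
simulate_experiment <- function(proteome, design = default_design(),
                                params = proteome$params) {
  if (!inherits(proteome, "mq_proteome")) {
    stop("proteome must be created by generate_proteome()")
  }
  validate_design(design)
  truth <- proteome$truth
  if (!all(design$species %in% unique(truth$species))) {
    stop("design refers to species absent from the simulated proteome")
  }
  set.seed(params$seed + 1L)
  sp <- mq_species()
  nch <- nrow(design)
  lambda <- params$peptides_per_protein$lambda
  frac_single <- params$peptides_per_protein$frac_single
  if (is.null(frac_single)) frac_single <- 0

  out <- lapply(sp, function(s) {
    rows <- truth[truth$species == s, , drop = FALSE]
    np <- nrow(rows)

    # per-channel protein log2 abundance
    off <- vapply(design$species,
                  function(cs) rows[[paste0("offset_", cs)]],
                  numeric(np))
    if (np == 1L) off <- matrix(off, 1L, nch)
    shift <- outer(rows$is_ejaculate | rows$is_pmr,
                   design$status == "mated") * params$ejaculate_log2_shift
    prot_log2 <- rows$base_log2 + rows$member_offset + off + shift

    npep <- 1L + stats::rpois(np, lambda - 1)
    npep[stats::runif(np) < frac_single] <- 1L
    idx <- rep(seq_len(np), npep)
    pep_off <- stats::rnorm(length(idx), 0, params$peptide_offset_sd)
    noise <- matrix(stats::rnorm(length(idx) * nch, 0,
                                 params$channel_noise_sd),
                    length(idx), nch)
    ints <- 2^(prot_log2[idx, , drop = FALSE] + pep_off + noise)
    colnames(ints) <- design$channel

    pep_rank <- sequence(npep)
    tbl <- data.frame(
      peptide = sprintf("%s_pep%02d", rows$protein_id[idx], pep_rank),
      protein_id = rows$protein_id[idx],
      is_unique = TRUE,
      stringsAsFactors = FALSE
    )
    tbl <- cbind(tbl, as.data.frame(ints))
    if (params$peptide_dropout > 0) {
      drop <- stats::runif(nrow(tbl)) < params$peptide_dropout
      drop[pep_rank == 1L] <- FALSE  # keep at least one peptide
      tbl <- tbl[!drop, , drop = FALSE]
    }
    rownames(tbl) <- NULL
    tbl
  })
  names(out) <- sp
  out
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: [generate_proteome()] plus
#' [simulate_experiment()] under one parameter set.
#'
#' @inheritParams simulate_experiment
#' @param params an [sim_params()] object.
#' @return A list of class `mq_dataset` with `proteome`, `design` and
#'   `peptides` (per-species peptide tables).
#' @export
simulate_dataset <- function(params = sim_params(),
                             design = default_design()) {
  proteome <- generate_proteome(params)
  peptides <- simulate_experiment(proteome, design, params)
  out <- list(proteome = proteome, design = design, peptides = peptides)
  class(out) <- "mq_dataset"
  out
}

#' Write a synthetic dataset to disk
#'
#' Emits the TSV dialects consumed by the reading functions
#' (`peptides_<species>.tsv`, `design.tsv`, `orthomap.tsv`, `truth.tsv`,
#' annotation tables) plus a `manifest.json` recording parameters and
#' seed.
#'
#' @param dataset an `mq_dataset` from [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(dataset, dir) {
  if (!inherits(dataset, "mq_dataset")) {
    stop("dataset must be created by simulate_dataset()")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(x, f) {
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  for (s in names(dataset$peptides)) {
    tsv(dataset$peptides[[s]], sprintf("peptides_%s.tsv", s))
  }
  write_design(dataset$design, file.path(dir, "design.tsv"))
  pr <- dataset$proteome
  tsv(pr$orthomap, "orthomap.tsv")
  tsv(pr$truth, "truth.tsv")
  tsv(pr$annotations$proteins, "annotations_proteins.tsv")
  tsv(pr$annotations$go, "annotations_go.tsv")
  tsv(pr$annotations$omega, "annotations_omega.tsv")
  tsv(pr$annotations$genome_omega, "annotations_genome_omega.tsv")
  tsv(pr$annotations$mrna, "annotations_mrna.tsv")
  writeLines(pr$exclusion_list, file.path(dir, "exclusion_list.txt"))
  manifest <- unclass(pr$params)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
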