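#' Call differential abundance from a contrast result
#'
#' `up` when log2FC exceeds the fold-change threshold and the BH q-value
#' is below the FDR threshold; `down` symmetrically; otherwise `ns`.
#' Defaults are the standard |log2FC| > 1, FDR < 0.05 calling surface.
#'
#' @param result an `mq_contrast` data frame (needs `log2fc` and `q`).
#' @param lfc_threshold positive log2 fold-change threshold.
#' @param q_threshold positive FDR threshold.
#' @return Character vector of calls (`"up"`, `"down"`, `"ns"`).
#' @export
call_differential <- function(result, lfc_threshold = 1,
                              q_threshold = 0.05) {
  if (!is.numeric(lfc_threshold) || lfc_threshold <= 0) {
    stop("lfc_threshold must be > 0")
  }
  if (!is.numeric(q_threshold) || q_threshold <= 0) {
    stop("q_threshold must be > 0")
  }
  out <- rep("ns", nrow(result))
  out[result$log2fc > lfc_threshold & result$q < q_threshold] <- "up"
  out[result$log2fc < -lfc_threshold & result$q < q_threshold] <- "down"
  out
}

#' Classify proteins as ejaculate, tract-resident, or virgin-biased
#'
#' The ejaculate set is the union over species of mated-biased calls on
#' the combined table, minus a curated exclusion list of known female
#' postmating-response proteins (mating-responsive but not
#' male-derived); those land in class `excluded`. Remaining rows with a
#' virgin-biased call in any species form `virgin-biased`; everything
#' else quantified is the female reproductive tract (`FRT`) proteome.
#' The four classes partition the table.
#'
#' @param calls data frame or matrix of per-species calls
#'   (`"up"`/`"down"`/`"ns"`), one column per species, rows aligned with
#'   `row_keys`.
#' @param row_keys row keys of the combined table.
#' @param protein_ids protein IDs aligned with `row_keys` (exclusion
#'   list matching).
#' @param exclusion_list character vector of protein IDs to exclude
#'   from the ejaculate set; IDs absent from the table raise a warning.
#' @return Data frame of class `mq_classification`: `row_key`,
#'   `protein_id`, `class`, one `mated_<species>` flag per species, and
#'   `shared_across_species` (mated-biased in every species).
#' @export
classify_ejaculate <- function(calls, row_keys, protein_ids,
                               exclusion_list = character(0)) {
  calls <- as.matrix(calls)
  if (nrow(calls) != length(row_keys) ||
      length(protein_ids) != length(row_keys)) {
    stop("calls, row_keys and protein_ids must have matching lengths")
  }
  if (is.null(colnames(calls))) {
    stop("calls must have species column names")
  }
  missing_ids <- setdiff(exclusion_list, protein_ids)
  if (length(missing_ids) > 0) {
    warning("exclusion list IDs absent from table: ",
            paste(utils::head(missing_ids, 5), collapse = ", "),
            if (length(missing_ids) > 5) ", ...")
  }
  up <- calls == "up"
  down <- calls == "down"
  mated_any <- rowSums(up) > 0
  virgin_any <- rowSums(down) > 0
  on_list <- protein_ids %in% exclusion_list

  cls <- rep("FRT", length(row_keys))
  cls[virgin_any] <- "virgin-biased"
  cls[mated_any] <- "ejaculate"
  cls[mated_any & on_list] <- "excluded"

  out <- data.frame(row_key = row_keys, protein_id = protein_ids,
                    class = cls, stringsAsFactors = FALSE)
  for (s in colnames(calls)) out[[paste0("mated_", s)]] <- up[, s]
  out$shared_across_species <- rowSums(up) == ncol(calls)
  rownames(out) <- NULL
  class(out) <- c("mq_classification", "data.frame")
  out
}

#' Signal-peptide fraction per protein class
#'
#' Fraction of proteins carrying a predicted signal peptide (a proxy
#' for secretion) in each class, with an exact binomial confidence
#' interval.
#'
#' @param classification an `mq_classification` data frame.
#' @param sig_flags logical vector named by protein ID, or a data frame
#'   with `protein_id` and `has_signal_peptide`.
#' @param conf confidence level for the interval.
#' @return Data frame `class`, `n`, `n_signal`, `fraction`, `ci_lower`,
#'   `ci_upper`.
#' @export
signal_peptide_fraction <- function(classification, sig_flags,
                                    conf = 0.99) {
  if (is.data.frame(sig_flags)) {
    flags <- sig_flags$has_signal_peptide
    names(flags) <- sig_flags$protein_id
  } else {
    flags <- sig_flags
  }
  f <- flags[classification$protein_id]
  if (anyNA(f)) stop("sig_flags must cover every classified protein")
  cl <- unique(classification$class)
  res <- lapply(cl, function(cc) {
    sel <- classification$class == cc
    n <- sum(sel)
    k <- sum(f[sel])
    ci <- if (n > 0) {
      stats::binom.test(k, n, conf.level = conf)$conf.int
    } else {
      c(NA_real_, NA_real_)
    }
    data.frame(class = cc, n = n, n_signal = k,
               fraction = if (n > 0) k / n else NA_real_,
               ci_lower = ci[1], ci_upper = ci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
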