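#' Read a peptide-level quantitation table
#'
#' Tab-separated dialect with header
#' `peptide  protein_id  is_unique  ch01 ... ch16` (any number of
#' channel columns matching `^ch[0-9]+$` is accepted). Reporter
#' intensities must be nonnegative; offending rows are reported with
#' their line numbers.
#'
#' @param path file path.
#' @return Data frame of validated peptide records.
#' @export
read_peptide_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("peptide", "protein_id", "is_unique")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("peptide table is missing column(s): ", paste(miss, collapse = ", "))
  }
  ch <- channel_cols(x)
  if (length(ch) == 0) stop("peptide table has no channel columns (ch01...)")
  x$is_unique <- as.logical(x$is_unique)
  if (nrow(x) > 0) {
    if (any(!nzchar(x$protein_id) | is.na(x$protein_id))) {
      bad <- which(!nzchar(x$protein_id) | is.na(x$protein_id))
      stop("empty protein_id at line(s): ",
           paste(utils::head(bad + 1L, 10), collapse = ", "))
    }
    ints <- as.matrix(x[, ch, drop = FALSE])
    if (anyNA(ints)) {
      bad <- which(rowSums(is.na(ints)) > 0)
      stop("missing intensity at line(s): ",
           paste(utils::head(bad + 1L, 10), collapse = ", "))
    }
    if (any(ints < 0)) {
      bad <- which(rowSums(ints < 0) > 0)
      stop("negative intensity at line(s): ",
           paste(utils::head(bad + 1L, 10), collapse = ", "))
    }
  }
  x
}

#' @rdname read_peptide_table
#' @param records peptide record data frame to write.
#' @export
write_peptide_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

channel_cols <- function(x) grep("^ch[0-9]+$", names(x), value = TRUE)

#' Aggregate peptide records to protein-level quantitation
#'
#' Protein abundance per channel is the sum of intensities of all
#' peptides assigned to the protein. Shared (non-unique) peptides
#' contribute intensity to every protein they are assigned to, but only
#' distinct peptide sequences flagged unique count towards
#' `n_unique_peptides`.
#'
#' @param records peptide record data frame (see [read_peptide_table()]).
#' @return Data frame with `protein_id`, `n_unique_peptides`, and one
#'   summed-intensity column per channel, sorted by `protein_id`.
#' @export
aggregate_to_protein <- function(records) {
  ch <- channel_cols(records)
  if (length(ch) == 0) stop("records have no channel columns")
  if (nrow(records) == 0) {
    out <- data.frame(protein_id = character(0),
                      n_unique_peptides = integer(0))
    for (cc in ch) out[[cc]] <- numeric(0)
    return(out)
  }
  sums <- rowsum(as.matrix(records[, ch, drop = FALSE]),
                 group = records$protein_id)
  uni <- records[records$is_unique, c("protein_id", "peptide")]
  uni <- unique(uni)
  n_uni <- table(factor(uni$protein_id, levels = rownames(sums)))
  out <- data.frame(protein_id = rownames(sums),
                    n_unique_peptides = as.integer(n_uni),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(sums, row.names = NULL))
  rownames(out) <- NULL
  out
}

#' Filter proteins by minimum unique-peptide support
#'
#' Retains proteins identified by at least `k` unique peptides (default
#' 2, the standard identification filter for quantitative comparisons).
#' Idempotent.
#'
#' @param table protein quantitation table from [aggregate_to_protein()].
#' @param k minimum number of unique peptides (>= 1).
#' @return The filtered table; retention counts are reported via
#'   [message()].
#' @export
filter_min_unique <- function(table, k = 2) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1) {
    stop("k must be a single integer >= 1")
  }
  if (is.null(table$n_unique_peptides)) {
    stop("table has no n_unique_peptides column; aggregate first")
  }
  keep <- table$n_unique_peptides >= k
  message(sprintf("filter_min_unique: retained %d/%d proteins (k = %d)",
                  sum(keep), nrow(table), as.integer(k)))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write a protein quantitation table
#'
#' TSV with header `protein_id  n_unique_peptides  ch01 ...`, optionally
#' an `orthogroup` column.
#'
#' @param path file path.
#' @export
read_protein_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(x$protein_id)) stop("protein table is missing 'protein_id'")
  x
}

#' @rdname read_protein_table
#' @param table protein table to write.
#' @export
write_protein_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
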