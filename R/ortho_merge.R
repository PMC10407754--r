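#' Read / write an orthology map
#'
#' TSV with header `protein_id  species  orthogroup`. A protein maps to
#' at most one orthogroup; proteins without an assignment are simply
#' absent from the map.
#'
#' @param path file path.
#' @export
read_orthomap <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("protein_id", "species", "orthogroup")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("orthology map is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(x$protein_id)) {
    stop("orthology map assigns some protein more than one orthogroup")
  }
  x
}

#' @rdname read_orthomap
#' @param map orthology map data frame.
#' @export
write_orthomap <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Gene-family membership flags
#'
#' A protein is a gene-family member when its orthogroup has more than
#' one member in at least one species (one-to-many or many-to-one
#' orthology).
#'
#' @param map orthology map (`protein_id`, `species`, `orthogroup`).
#' @return Data frame `protein_id`, `orthogroup`, `is_family_member`.
#' @export
family_membership <- function(map) {
  cnt <- stats::aggregate(list(n = map$protein_id),
                          by = list(orthogroup = map$orthogroup,
                                    species = map$species),
                          FUN = length)
  fam_og <- unique(cnt$orthogroup[cnt$n > 1])
  data.frame(protein_id = map$protein_id,
             orthogroup = map$orthogroup,
             is_family_member = map$orthogroup %in% fam_og,
             stringsAsFactors = FALSE)
}

#' Merge per-species protein tables into a combined orthogroup table
#'
#' Rows are keyed `orthogroup:protein_id`; one-to-many orthology yields
#' one row per member protein so duplicated genes can be analysed
#' separately. Proteins with no orthogroup assignment are set aside (see
#' attribute `unassigned`) — they are excluded from cross-species
#' contrasts but remain available for within-species analyses.
#'
#' @param tables named list of filtered protein tables, one per species.
#' @param map orthology map covering (a subset of) the proteins.
#' @return Combined data frame with columns `row_key`, `orthogroup`,
#'   `protein_id`, `species`, `is_family_member`, `n_unique_peptides`
#'   and the channel columns; attribute `unassigned` holds the left-out
#'   rows (with their species).
#' @export
merge_by_orthogroup <- function(tables, map) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("tables must be a named list (names = species)")
  }
  fam <- family_membership(map)
  parts <- list()
  un <- list()
  for (s in names(tables)) {
    tb <- tables[[s]]
    if (anyDuplicated(tb$protein_id)) {
      stop("duplicate protein IDs within species '", s, "'")
    }
    j <- match(tb$protein_id, map$protein_id)
    assigned <- !is.na(j)
    message(sprintf(
      "merge_by_orthogroup: %s: %d/%d proteins assigned to orthogroups",
      s, sum(assigned), nrow(tb)))
    if (any(!assigned)) {
      u <- tb[!assigned, , drop = FALSE]
      u$species <- s
      un[[s]] <- u
    }
    if (any(assigned)) {
      a <- tb[assigned, , drop = FALSE]
      a$orthogroup <- map$orthogroup[j[assigned]]
      a$species <- s
      a$is_family_member <-
        fam$is_family_member[match(a$protein_id, fam$protein_id)]
      parts[[s]] <- a
    }
  }
  if (length(parts) == 0) stop("no proteins could be assigned to orthogroups")
  combined <- do.call(rbind, parts)
  ch <- channel_cols(combined)
  combined$row_key <- paste0(combined$orthogroup, ":", combined$protein_id)
  combined <- combined[, c("row_key", "orthogroup", "protein_id", "species",
                           "is_family_member", "n_unique_peptides", ch)]
  rownames(combined) <- NULL
  attr(combined, "unassigned") <-
    if (length(un) > 0) {
      u <- do.call(rbind, un)
      rownames(u) <- NULL
      u
    } else {
      NULL
    }
  combined
}

#' Split a combined table back into per-species protein tables
#'
#' Inverse of [merge_by_orthogroup()]: per-species tables (including
#' any unassigned rows carried in the `unassigned` attribute) are
#' recovered exactly.
#'
#' @param combined combined table from [merge_by_orthogroup()].
#' @return Named list of per-species protein tables.
#' @export
split_by_species <- function(combined) {
  ch <- channel_cols(combined)
  keep <- c("protein_id", "n_unique_peptides", ch)
  out <- lapply(split(combined, combined$species), function(x) {
    y <- x[, keep, drop = FALSE]
    rownames(y) <- NULL
    y
  })
  un <- attr(combined, "unassigned")
  if (!is.null(un)) {
    for (s in unique(un$species)) {
      u <- un[un$species == s, keep, drop = FALSE]
      y <- rbind(out[[s]], u)
      y <- y[order(y$protein_id), , drop = FALSE]
      rownames(y) <- NULL
      out[[s]] <- y
    }
  }
  out
}

#' Extract the channel intensity matrix from a table
#'
#' @param table any table carrying channel columns; row names of the
#'   result are `row_key` if present, else `protein_id`.
#' @return Numeric matrix, proteins x channels.
#' @export
intensity_matrix <- function(table) {
  ch <- channel_cols(table)
  if (length(ch) == 0) stop("table has no channel columns")
  m <- as.matrix(table[, ch, drop = FALSE])
  rownames(m) <- if (!is.null(table$row_key)) table$row_key else
    table$protein_id
  m
}
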