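#' Species analysed by the pipeline
#'
#' The three *Drosophila virilis*-group species quantified in one 16-plex
#' run: *D. americana*, *D. novamexicana* and *D. virilis*.
#'
#' @return Character vector of species identifiers.
#' @export
mq_species <- function() c("americana", "novamexicana", "virilis")

# short codes used in protein identifiers
mq_species_short <- function() {
  c(americana = "amer", novamexicana = "nova", virilis = "vir")
}

#' Default 16-channel sample design
#'
#' One TMTpro 16-plex run: three mated replicates per species, three
#' virgin replicates for *D. virilis* and two each for *D. americana*
#' and *D. novamexicana*. Virgin replication is unbalanced by design:
#' the virilis lineage is the outgroup and its virgin proteome is
#' expected to have diverged most.
#'
#' @return A data frame with columns `channel`, `species`, `status`
#'   (`"mated"` or `"virgin"`) and `replicate`.
#' @export
default_design <- function() {
  sp <- mq_species()
  data.frame(
    channel = sprintf("ch%02d", 1:16),
    species = c(rep(sp, each = 3), rep(sp, times = c(2, 2, 3))),
    status = c(rep("mated", 9), rep("virgin", 7)),
    replicate = c(rep(1:3, 3), 1:2, 1:2, 1:3),
    stringsAsFactors = FALSE
  )
}

validate_design <- function(design) {
  need <- c("channel", "species", "status", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss) > 0) {
    stop("design is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(design$channel)) {
    stop("design channel labels must be unique")
  }
  bad <- setdiff(unique(design$status), c("virgin", "mated"))
  if (length(bad) > 0) {
    stop("design status must be 'virgin' or 'mated', found: ",
         paste(bad, collapse = ", "))
  }
  invisible(design)
}

#' Channels belonging to one species/status group
#'
#' @param design sample design data frame.
#' @param species species identifier, or `NULL` for all.
#' @param status `"mated"`, `"virgin"` or `NULL` for both.
#' @return Character vector of channel labels.
#' @export
design_channels <- function(design, species = NULL, status = NULL) {
  validate_design(design)
  keep <- rep(TRUE, nrow(design))
  if (!is.null(species)) keep <- keep & design$species %in% species
  if (!is.null(status)) keep <- keep & design$status %in% status
  design$channel[keep]
}

#' Read / write a sample design table
#'
#' Tab-separated dialect with header `channel  species  status  replicate`.
#'
#' @param path file path.
#' @return `read_design` returns the validated design data frame.
#' @export
read_design <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_design(x)
  x$replicate <- as.integer(x$replicate)
  x
}

#' @rdname read_design
#' @param design design data frame to write.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
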