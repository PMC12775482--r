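#' Construct a substrate library
#'
#' A substrate library is a plain tibble with one row per peptide: columns
#' `id`, `sequence`, optional `group` (provenance label), and one numeric
#' column per panel protease holding that protease's normalised cleavage
#' Z-score for the peptide. All package functions accept this shape and
#' infer the panel from the non-reserved numeric columns (or take an explicit
#' `proteases` argument).
#'
#' @param sequences Character vector of peptides.
#' @param Z Optional numeric matrix or data frame of cleavage scores, one
#'   column per protease (column names are the panel).
#' @param id Optional ids; defaults to `pep00001`-style labels. Must be
#'   unique.
#' @param group Optional provenance label per peptide.
#' @return A tibble (`id`, `sequence`, `group`, one column per protease).
#' @export
#' @examples
#' peptide_library(c("PLGLAGAAAA", "AAAAAAAAAA"),
#'                 Z = cbind(MMP1 = c(2.1, -0.3), MMP2 = c(0.4, 0.1)))
peptide_library <- function(sequences, Z = NULL, id = NULL, group = NULL) {
  sequences <- validate_peptides(sequences)
  n <- length(sequences)
  if (is.null(id)) id <- sprintf("pep%05d", seq_len(n))
  if (anyDuplicated(id)) stop("peptide ids must be unique", call. = FALSE)
  out <- tibble(id = as.character(id), sequence = sequences)
  if (!is.null(group)) out$group <- as.character(group)
  if (!is.null(Z)) {
    Z <- as.data.frame(Z)
    if (nrow(Z) != n) stop("`Z` must have one row per sequence", call. = FALSE)
    if (is.null(names(Z)) || any(names(Z) == ""))
      stop("`Z` columns must be named by protease", call. = FALSE)
    for (p in names(Z)) {
      if (!is.numeric(Z[[p]]))
        stop(sprintf("Z column '%s' is not numeric", p), call. = FALSE)
      out[[p]] <- Z[[p]]
    }
  }
  out
}

#' Extract the cleavage-score matrix of a library
#'
#' @param lib A library tibble (see [peptide_library()]).
#' @param proteases Panel columns; inferred when `NULL`.
#' @return Numeric matrix (peptides x proteases) with ids as row names.
#' @export
zscore_matrix <- function(lib, proteases = NULL) {
  proteases <- infer_proteases(lib, proteases)
  m <- as.matrix(lib[proteases])
  rownames(m) <- lib[["id"]]
  m
}

#' Read / write substrate libraries
#'
#' CSV libraries are UTF-8 with a header; the peptide column is named
#' `sequence`, an optional `id` and `group` column are recognised, and every
#' other column is a per-protease Z-score column named by the protease. FASTA
#' files carry sequences only (empty panel). A write -> read round trip
#' preserves sequences, panel order and scores to full precision.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"fasta"`.
#' @return A library tibble.
#' @export
read_library <- function(path, format = c("auto", "csv", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE))
      "fasta" else "csv"
  }
  if (format == "fasta") {
    aa <- Biostrings::readAAStringSet(path)
    if (length(aa) == 0) stop("no FASTA records in ", path, call. = FALSE)
    ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1)
    lib <- peptide_library(unname(as.character(aa)), id = ids)
    log_inform("read %d peptides from %s (fasta)", nrow(lib), path)
    return(lib)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"sequence" %in% names(raw))
    stop("library CSV must have a 'sequence' column: ", path, call. = FALSE)
  zcols <- setdiff(names(raw), c("id", "sequence", "group"))
  Z <- NULL
  if (length(zcols)) {
    Z <- lapply(zcols, function(p) {
      v <- suppressWarnings(as.numeric(raw[[p]]))
      bad <- which(is.na(v) & !is.na(raw[[p]]) & raw[[p]] != "NA")
      if (length(bad))
        stop(sprintf("non-numeric value '%s' in Z column '%s' at row %d",
                     raw[[p]][bad[1]], p, bad[1]), call. = FALSE)
      v
    })
    names(Z) <- zcols
    Z <- as.data.frame(Z, check.names = FALSE)
  }
  if (!is.null(raw[["id"]]) && anyDuplicated(raw[["id"]]))
    stop("duplicate peptide ids in ", path, call. = FALSE)
  lib <- peptide_library(raw$sequence, Z = Z, id = raw[["id"]],
                         group = raw[["group"]])
  log_inform("read %d peptides x %d proteases from %s", nrow(lib), length(zcols), path)
  lib
}

#' @rdname read_library
#' @param lib Library tibble to write.
#' @export
write_library <- function(lib, path, format = c("auto", "csv", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE))
      "fasta" else "csv"
  }
  if (format == "fasta") {
    ids <- lib[["id"]] %||% sprintf("pep%05d", seq_len(nrow(lib)))
    aa <- Biostrings::AAStringSet(setNames(lib$sequence, ids))
    Biostrings::writeXStringSet(aa, path)
  } else {
    readr::write_csv(lib, path, progress = FALSE)
  }
  log_inform("wrote %d peptides to %s (%s)", nrow(lib), path, format)
  invisible(path)
}
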