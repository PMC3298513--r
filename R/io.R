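# Protein-record container and readers/writers for FASTA and the
# sequence-to-species map.

#' Construct a protein-record table
#'
#' The container used throughout: one row per protein with a unique id, the
#' amino-acid sequence (20 standard residues plus 'X'; '-' only when
#' aligned), an optional species and an optional taxon lineage.
#'
#' @param id Character vector of unique, non-empty identifiers.
#' @param sequence Character vector of sequences.
#' @param species Character vector (recycled) of species names.
#' @param lineage List of character vectors of taxon names, or `NULL`.
#' @param aligned Whether gap characters are permitted.
#' @return A data frame of class `protein_records`.
#' @export
protein_records <- function(id, sequence, species = NA_character_,
                            lineage = NULL, aligned = FALSE) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence)) stopf("id and sequence lengths differ")
  if (any(!nzchar(id))) stopf("empty record id")
  dup <- unique(id[duplicated(id)])
  if (length(dup)) stopf("duplicate record id(s): %s", paste(dup, collapse = ", "))
  if (any(nchar(sequence) < 1L)) {
    bad <- id[nchar(sequence) < 1L]
    stopf("empty sequence for record(s): %s", paste(bad, collapse = ", "))
  }
  legal <- .legal_chars(aligned)
  for (i in seq_along(sequence)) {
    ch <- seq_chars(sequence[i])
    bad <- which(!(ch %in% legal))
    if (length(bad)) {
      stopf("illegal character '%s' in record '%s' at position %d",
            ch[bad[1L]], id[i], bad[1L])
    }
  }
  if (is.null(lineage)) lineage <- rep(list(character(0)), length(id))
  out <- data.frame(id = id, species = rep_len(as.character(species), length(id)),
                    sequence = sequence, stringsAsFactors = FALSE)
  out$lineage <- lineage
  class(out) <- c("protein_records", "data.frame")
  out
}

#' Read protein sequences from FASTA
#'
#' Record ids are the first whitespace-delimited token of each header and
#' must be unique. Characters outside the 20 standard residues plus 'X'
#' (and '-' for alignments) are rejected with the offending record and
#' position. Gap characters in unaligned input are stripped with a warning,
#' so curated alignments can be fed directly to the scanning stages.
#'
#' @param path FASTA file.
#' @param aligned If `TRUE`, gaps are retained and all records must have
#'   equal aligned length.
#' @return A [protein_records()] data frame, input order preserved.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stopf("duplicate record id(s) in %s: %s", path,
                         paste(dup, collapse = ", "))
  if (aligned) {
    if (length(unique(nchar(seqs))) > 1L)
      stopf("ragged aligned FASTA %s: record lengths %s", path,
            paste(range(nchar(seqs)), collapse = ".."))
  } else if (any(grepl("-", seqs, fixed = TRUE))) {
    warnf("gap characters stripped from unaligned input %s", path)
    seqs <- gsub("-", "", seqs, fixed = TRUE)
  }
  protein_records(ids, seqs, aligned = aligned)
}

#' Write protein records to FASTA
#'
#' @param records A [protein_records()] data frame.
#' @param path Output file.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  set <- Biostrings::BStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a sequence-to-species map
#'
#' Tab-separated, no header: id, species, optional semicolon-joined
#' lineage. Every id must appear exactly once.
#'
#' @param path TSV file.
#' @param records Optional [protein_records()]; map ids absent from the
#'   records trigger a warning.
#' @return Data frame with `id`, `species` and a `lineage` list column.
#' @export
read_species_map <- function(path, records = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stopf("species map %s needs >= 2 columns (id, species)", path)
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stopf("duplicate id rows in species map: %s",
                         paste(dup, collapse = ", "))
  lineage <- if (ncol(df) >= 3L) {
    lapply(df[[3L]], function(x) {
      if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1L]]
    })
  } else rep(list(character(0)), nrow(df))
  if (!is.null(records)) {
    missing <- setdiff(ids, records$id)
    if (length(missing))
      warnf("species map ids absent from sequence set: %s",
            paste(missing, collapse = ", "))
  }
  out <- data.frame(id = ids, species = df[[2L]], stringsAsFactors = FALSE)
  out$lineage <- lineage
  out
}

#' Write a sequence-to-species map
#'
#' @param map Data frame with `id`, `species` and optionally a `lineage`
#'   list column.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_species_map <- function(map, path) {
  lineage <- if (!is.null(map$lineage))
    vapply(map$lineage, paste, "", collapse = ";") else ""
  utils::write.table(data.frame(map$id, map$species, lineage),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach species (and lineage) from a map to protein records
#'
#' @param records A [protein_records()] data frame.
#' @param map Result of [read_species_map()].
#' @return The records with `species`/`lineage` filled in.
#' @export
assign_species <- function(records, map) {
  i <- match(records$id, map$id)
  hit <- !is.na(i)
  records$species[hit] <- map$species[i[hit]]
  if (!is.null(map$lineage)) records$lineage[hit] <- map$lineage[i[hit]]
  records
}
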