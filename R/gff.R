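# GFF3-style writer for domain calls.

.gff_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  x
}

#' Write domain calls as GFF3
#'
#' One feature line per call: seqid, source `waspfam`, type = domain kind,
#' 1-based inclusive coordinates, score, and an `evidence` attribute.
#' Output is deterministically ordered by (seqid, start, kind), so
#' identical input yields a byte-identical file.
#'
#' @param records A [protein_records()] data frame; every call must
#'   reference one of its ids and lie within the sequence.
#' @param calls Domain-call data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_domain_annotations <- function(records, calls, path) {
  unknown <- setdiff(calls$id, records$id)
  if (length(unknown)) stopf("calls reference unknown record id(s): %s",
                             paste(unique(unknown), collapse = ", "))
  if (nrow(calls)) {
    len <- nchar(records$sequence)[match(calls$id, records$id)]
    bad <- which(calls$start < 1L | calls$end > len | calls$start > calls$end)
    if (length(bad)) {
      stopf("call coordinates outside sequence for '%s' (%s %d..%d, length %d)",
            calls$id[bad[1L]], calls$kind[bad[1L]],
            calls$start[bad[1L]], calls$end[bad[1L]], len[bad[1L]])
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(calls)) {
    ord <- order(calls$id, calls$start, calls$kind, calls$end)
    calls <- calls[ord, , drop = FALSE]
    lines <- sprintf("%s\twaspfam\t%s\t%d\t%d\t%s\t.\t.\tevidence=%s",
                     calls$id, calls$kind, calls$start, calls$end,
                     formatC(calls$score, format = "g", digits = 6),
                     .gff_escape(calls$evidence))
    writeLines(lines, con)
  }
  invisible(path)
}
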