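# Accessors for the bundled printed dataset statistics.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "waspfam")
  if (!nzchar(path)) stopf("bundled data file not found: %s", file)
  path
}

#' Printed per-family dataset statistics
#'
#' The per-family sequence counts of the curated dataset (totals,
#' WGS-derived counts, completeness classes, species counts) as printed in
#' the original data-statistics table.
#'
#' @return Data frame, one row per family.
#' @export
wasp_table1 <- function() {
  utils::read.delim(.extdata("table1_counts.tsv"), stringsAsFactors = FALSE)
}

#' Printed whole-dataset statistics
#'
#' @return Named numeric vector: total sequences (1021), total organisms
#'   (408) and WH2 domain sequences underlying the family logos (1080).
#' @export
wasp_dataset_stats <- function() {
  df <- utils::read.delim(.extdata("dataset_stats.tsv"), stringsAsFactors = FALSE)
  stats::setNames(df$value, df$key)
}

#' Printed per-logo WH2 sequence counts
#'
#' Sequence counts behind the eight family WH2 logos.
#'
#' @return Data frame with `logo` and `n`.
#' @export
wh2_logo_counts <- function() {
  utils::read.delim(.extdata("wh2_logo_counts.tsv"), stringsAsFactors = FALSE)
}

#' Printed per-logo central-domain sequence counts
#'
#' @return Data frame with `logo` and `n`.
#' @export
c_logo_counts <- function() {
  utils::read.delim(.extdata("c_logo_counts.tsv"), stringsAsFactors = FALSE)
}
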