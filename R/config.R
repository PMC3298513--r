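# Run configuration: compiled-in defaults for every detector threshold and
# classifier rule, serializable to a flat sectioned key/value file.

#' Default run configuration
#'
#' Nested named list with one block per module. Every parameter has a
#' documented default here; [read_config()] refuses unknown keys.
#'
#' Sections:
#' \describe{
#'   \item{detectors}{Pattern gap ranges, composition windows/thresholds,
#'     acidic-terminus and coiled-coil parameters.}
#'   \item{profiles}{Pseudocount, column occupancy, score threshold as a
#'     fraction of the consensus score, and the maximum unconstrained gap
#'     between the two halves of the split WMD model.}
#'   \item{classifier}{VCA grouping span, charged-region length for the
#'     WAWH type-III rule, completeness policy and pseudogene threshold.}
#'   \item{profiler}{Whether pseudogenes count towards presence.}
#' }
#'
#' @return Nested named list of parameter blocks.
#' @export
waspfam_config <- function() {
  list(
    detectors = list(
      wh2_gap_min = 6L, wh2_gap_max = 14L,
      c_spacer_max = 6L,
      basic_window = 8L, basic_fraction = 0.40,
      ppr_window = 10L, ppr_fraction = 0.40,
      ser_window = 10L, ser_fraction = 0.40,
      chg_window = 200L, chg_fraction = 0.80,
      acidic_tail = 60L, acidic_window = 8L, acidic_fraction = 0.50,
      acidic_end_slack = 10L, acidic_aromatic_window = 5L,
      cc_window = 28L, cc_threshold = 0.60
    ),
    profiles = list(
      pseudocount = 1.0,
      min_column_occupancy = 0.5,
      score_threshold_frac = 0.6,
      wmd_max_gap = 200L
    ),
    classifier = list(
      vca_span = 200L,
      chg_min_length = 400L,
      cxxc_region = 40L,
      partial_max_missing = 0.05,
      complete_tolerance = 0.01,
      pseudogene_min_disablements = 2L
    ),
    profiler = list(
      include_pseudogenes = FALSE
    )
  )
}

#' Serialize a configuration to a flat sectioned key/value file
#'
#' @param config Nested list as returned by [waspfam_config()].
#' @param path Output file (or a connection).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  con <- if (inherits(path, "connection")) path else file(path, "w")
  if (!inherits(path, "connection")) on.exit(close(con))
  for (section in names(config)) {
    writeLines(sprintf("[%s]", section), con)
    blk <- config[[section]]
    for (key in names(blk)) {
      writeLines(sprintf("%s = %s", key, format(blk[[key]], scientific = FALSE)), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read a configuration file over the compiled-in defaults
#'
#' Flat key/value text with `[section]` headers; `#` starts a comment.
#' Unknown sections or keys are an error; values are coerced to the type of
#' the corresponding default.
#'
#' @param path Config file.
#' @param defaults Base configuration to override.
#' @return Nested named list.
#' @export
read_config <- function(path, defaults = waspfam_config()) {
  if (!file.exists(path)) stopf("no such config file: %s", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  config <- defaults
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!section %in% names(config)) stopf("unknown config section: [%s]", section)
      next
    }
    if (is.null(section)) stopf("config entry before any [section]: '%s'", ln)
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stopf("malformed config line: '%s'", ln)
    key <- trimws(kv[1L])
    val <- trimws(kv[2L])
    if (!key %in% names(config[[section]]))
      stopf("unknown config key: %s.%s", section, key)
    old <- config[[section]][[key]]
    config[[section]][[key]] <- if (is.integer(old)) as.integer(val)
      else if (is.numeric(old)) as.numeric(val)
      else if (is.logical(old)) as.logical(val)
      else val
    if (is.na(config[[section]][[key]]))
      stopf("cannot parse value for %s.%s: '%s'", section, key, val)
  }
  config
}
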