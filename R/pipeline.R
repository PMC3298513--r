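# End-to-end scanning and classification over whole protein sets.

#' Run every detector over one sequence
#'
#' Pattern scanners (WH2, C, CRIB), composition scanners (basic,
#' poly-proline, serine-rich, charged), the acidic-terminus detector, the
#' coiled-coil heuristic and any supplied profile models.
#'
#' @param sequence Amino-acid string.
#' @param id Record identifier.
#' @param profiles Named list of `profile_model`s (may be empty).
#' @param config Run configuration ([waspfam_config()]).
#' @return Domain-call data frame sorted by start.
#' @export
scan_sequence <- function(sequence, id = NA_character_, profiles = list(),
                          config = waspfam_config()) {
  d <- config$detectors
  out <- list(
    scan_pattern(sequence, wh2_pattern(d$wh2_gap_min, d$wh2_gap_max), id),
    scan_c_domain(sequence, id, d$c_spacer_max),
    scan_crib(sequence, id),
    scan_composition(sequence, composition_spec("B", c("K", "R"),
                                                d$basic_window, d$basic_fraction), id),
    scan_composition(sequence, composition_spec("PPR", "P",
                                                d$ppr_window, d$ppr_fraction), id),
    scan_composition(sequence, composition_spec("SER", "S",
                                                d$ser_window, d$ser_fraction), id),
    scan_composition(sequence, composition_spec("CHG", c("E", "R", "K"),
                                                d$chg_window, d$chg_fraction), id),
    scan_acidic_terminus(sequence, id, d$acidic_tail, d$acidic_window,
                         d$acidic_fraction, d$acidic_end_slack,
                         d$acidic_aromatic_window)$call,
    scan_coiled_coil(sequence, id, d$cc_window, d$cc_threshold))
  for (m in profiles) out[[length(out) + 1L]] <- scan_profile(sequence, m, id = id)
  calls <- rbind_calls(out)
  # A basic-region call inside a long charged region is redundant evidence
  # (the charged region is itself K/R-rich); keep the larger feature.
  chg <- calls[calls$kind == "CHG", , drop = FALSE]
  if (nrow(chg)) {
    contained <- calls$kind == "B" &
      vapply(seq_len(nrow(calls)), function(i)
        any(calls$start[i] >= chg$start & calls$end[i] <= chg$end), TRUE)
    calls <- calls[!contained, , drop = FALSE]
  }
  calls[order(calls$start, calls$end, calls$kind), , drop = FALSE]
}

#' Scan a whole protein set
#'
#' @param records A [protein_records()] data frame.
#' @param profiles Named list of `profile_model`s.
#' @param config Run configuration.
#' @return Domain-call data frame over all records. Output for each record
#'   is independent of every other record.
#' @export
scan_proteome <- function(records, profiles = list(), config = waspfam_config()) {
  rbind_calls(lapply(seq_len(nrow(records)), function(i) {
    scan_sequence(records$sequence[i], records$id[i], profiles, config)
  }))
}

#' Classify a whole protein set
#'
#' Scans, resolves architectures, assigns family/subtype, and derives the
#' completeness class from per-family expected lengths (given, or the
#' median length of classified members of each family).
#'
#' @param records A [protein_records()] data frame.
#' @param profiles Named list of `profile_model`s (e.g. [build_profiles()]).
#' @param config Run configuration.
#' @param species_map Optional map from [read_species_map()].
#' @param cds Optional named character vector of coding sequences (by
#'   record id) for pseudogene flagging.
#' @param expected_lengths Optional named numeric vector family -> expected
#'   full length.
#' @return Data frame: id, species, family, subtype, completeness,
#'   pseudogene, architecture, rationale.
#' @export
classify_proteome <- function(records, profiles = list(),
                              config = waspfam_config(), species_map = NULL,
                              cds = NULL, expected_lengths = NULL) {
  if (!is.null(species_map)) records <- assign_species(records, species_map)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    calls <- scan_sequence(records$sequence[i], records$id[i], profiles, config)
    arch <- resolve_architecture(records$id[i], calls,
                                 nchar(records$sequence[i]))
    cls <- classify_architecture(arch, records$sequence[i], config)
    data.frame(id = records$id[i], species = records$species[i],
               family = cls$family, subtype = cls$subtype,
               completeness = NA_character_, pseudogene = FALSE,
               architecture = arch$architecture, rationale = cls$rationale,
               length = nchar(records$sequence[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)

  cc <- config$classifier
  if (is.null(expected_lengths)) {
    expected_lengths <- tapply(out$length[out$family != "unclassified"],
                               out$family[out$family != "unclassified"],
                               stats::median)
  }
  for (i in seq_len(nrow(out))) {
    if (out$family[i] == "unclassified") next
    exp_len <- expected_lengths[[out$family[i]]]
    out$completeness[i] <- assess_completeness(
      out$length[i], if (is.null(exp_len)) NA_real_ else exp_len,
      cc$partial_max_missing, cc$complete_tolerance)
  }
  if (!is.null(cds)) {
    hit <- out$id %in% names(cds)
    out$pseudogene[hit] <- vapply(out$id[hit], function(id) {
      flag_pseudogene(cds[[id]],
                      min_disablements = cc$pseudogene_min_disablements)$pseudogene
    }, TRUE)
  }
  out$length <- NULL
  rownames(out) <- NULL
  out
}

#' Write a classification table to TSV
#'
#' @param assignments Result of [classify_proteome()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_classifications <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
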