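# Resolution of overlapping domain calls into one ordered architecture per
# protein, and rule-based assignment of family, subtype, completeness and
# pseudogene status.

#' Resolve overlapping domain calls into an ordered architecture
#'
#' Greedy selection by (score descending, start ascending, length
#' descending); overlapping lower-priority calls are dropped. The
#' architecture string joins the kinds of the surviving calls N- to
#' C-terminally.
#'
#' @param id Record identifier.
#' @param calls Domain-call data frame for this record.
#' @param seq_length Optional sequence length for coordinate validation.
#' @return An `architecture` object: list with `id`, `calls` (sorted by
#'   start, mutually non-overlapping) and `architecture` (string).
#' @export
resolve_architecture <- function(id, calls, seq_length = NULL) {
  if (is.null(calls) || nrow(calls) == 0L) {
    return(structure(list(id = id, calls = empty_calls(), architecture = ""),
                     class = "architecture"))
  }
  stopifnot(all(is.na(calls$id) | calls$id == id))
  if (!is.null(seq_length) &&
      any(calls$start < 1L | calls$end > seq_length | calls$start > calls$end))
    stopf("call coordinates outside sequence for record '%s'", id)
  len <- calls$end - calls$start + 1L
  ord <- order(-calls$score, calls$start, -len)
  kept <- logical(nrow(calls))
  ks <- integer(0)
  ke <- integer(0)
  for (i in ord) {
    if (!any(calls$start[i] <= ke & calls$end[i] >= ks)) {
      kept[i] <- TRUE
      ks <- c(ks, calls$start[i])
      ke <- c(ke, calls$end[i])
    }
  }
  res <- calls[kept, , drop = FALSE]
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  structure(list(id = id, calls = res,
                 architecture = paste(res$kind, collapse = "-")),
            class = "architecture")
}

#' @export
print.architecture <- function(x, ...) {
  cat(sprintf("<architecture %s> %s (%d calls)\n", x$id,
              if (nzchar(x$architecture)) x$architecture else "(empty)",
              nrow(x$calls)))
  invisible(x)
}

#' Identify VCA groups in a resolved architecture
#'
#' A VCA group is one or more WH2 calls followed by a C call and then an A
#' call, in order, with the whole group spanning at most `span` residues.
#'
#' @param calls Resolved (non-overlapping, start-sorted) domain calls.
#' @param span Maximum group span in residues.
#' @return List of groups; each a list with `wh2`, `c`, `a` (row indices
#'   into `calls`).
#' @export
vca_groups <- function(calls, span = 200L) {
  groups <- list()
  pending <- integer(0)
  c_idx <- NA_integer_
  for (i in seq_len(NROW(calls))) {
    k <- calls$kind[i]
    if (k == "WH2") {
      if (!is.na(c_idx)) {
        pending <- i
        c_idx <- NA_integer_
      } else pending <- c(pending, i)
    } else if (k == "C") {
      if (length(pending)) c_idx <- i
    } else if (k == "A") {
      if (!is.na(c_idx)) {
        while (length(pending) &&
               calls$end[i] - calls$start[pending[1L]] + 1L > span) {
          pending <- pending[-1L]
        }
        if (length(pending)) {
          groups[[length(groups) + 1L]] <-
            list(wh2 = pending, c = c_idx, a = i)
        }
        pending <- integer(0)
        c_idx <- NA_integer_
      }
    }
  }
  groups
}

# Count in-order (WH2+, C) units; two or more followed by a terminal A is
# the tandem-VCA form. (The acidic-terminus detector is anchored at the
# C-terminus, so interior acidic segments are not individual A calls.)
.count_vc_units <- function(calls) {
  n <- 0L
  state <- 0L
  for (i in seq_len(NROW(calls))) {
    k <- calls$kind[i]
    if (k == "WH2") state <- 1L
    else if (k == "C" && state == 1L) { n <- n + 1L; state <- 0L }
  }
  n
}

# Count in-order PPR -> WH2 -> C repeats (the Trichomonas tandem form).
.count_ppr_vc_repeats <- function(calls) {
  n <- 0L
  state <- 0L
  for (i in seq_len(NROW(calls))) {
    k <- calls$kind[i]
    if (k == "PPR") state <- 1L
    else if (k == "WH2" && state >= 1L) state <- 2L
    else if (k == "C" && state == 2L) { n <- n + 1L; state <- 0L }
  }
  n
}

# Does the architecture contain a usable WMD? Either a plain WMD call, or
# an N-half followed by a C-half within max_gap residues (the split model
# for the low-complexity insertion of the class-2 form).
.has_wmd <- function(calls, max_gap = 200L) {
  w <- which(calls$kind == "WMD")
  if (length(w) == 0L) return(FALSE)
  has_n <- grepl("half=N", calls$evidence[w])
  has_c <- grepl("half=C", calls$evidence[w])
  if (any(has_n == has_c)) return(TRUE)   # untagged or both: a full WMD call
  for (i in w[has_n]) {
    for (j in w[has_c]) {
      gap <- calls$start[j] - calls$end[i] - 1L
      if (gap >= 0L && gap <= max_gap) return(TRUE)
    }
  }
  FALSE
}

# >= 2 CxxC motifs within the first `region` residues.
.has_cxxc_pair <- function(sequence, region = 40L) {
  if (is.null(sequence)) return(TRUE)   # no sequence: predicate not applied
  head <- substr(sequence, 1L, min(nchar(sequence), region))
  m <- gregexpr("(?=C..C)", head, perl = TRUE)[[1L]]
  sum(m > 0L) >= 2L
}

#' Assign family and subtype from a resolved architecture
#'
#' Family is keyed on the N-terminal family domain (WH1 = WASP, WHD = WAVE,
#' WAHD = WASH, WMD = WHAMM, IMD = WAML); proteins with a GTPase-binding
#' region (CRIB and/or WAID) but no family N-terminal domain are WAWH.
#' Subtypes refine the family from the VCA region and central features:
#' S-WASP (GBD present, central+acidic absent), tandem-PPR-VC (two or more
#' PPR-WH2-C repeats without an acidic domain), tandem-VCA (two VCA groups),
#' no-WH2 (CA without WH2), WAML-short (IMD+WAID without VCA), and the
#' three WAWH types (III: long charged region; II: N-terminal CxxC pair,
#' serine-rich region and coiled-coil; I: basic region before the CRIB).
#' WAWH subtype precedence is III, II, I (most specific evidence first).
#'
#' @param arch An [resolve_architecture()] result.
#' @param sequence Optional raw sequence; enables the CxxC predicate of the
#'   WAWH type-II rule.
#' @param config Run configuration ([waspfam_config()]).
#' @return List with `id`, `family`, `subtype` and `rationale` (matched-rule
#'   trace; non-empty for classified records).
#' @export
classify_architecture <- function(arch, sequence = NULL,
                                  config = waspfam_config()) {
  stopifnot(inherits(arch, "architecture"))
  calls <- arch$calls
  cc <- config$classifier
  has <- function(k) any(calls$kind == k)
  first_start <- function(k) {
    i <- which(calls$kind == k)
    if (length(i)) calls$start[min(i)] else NA_integer_
  }
  res <- function(family, subtype, rationale) {
    list(id = arch$id, family = family, subtype = subtype,
         rationale = rationale)
  }

  groups <- vca_groups(calls, cc$vca_span)
  nvca <- length(groups)
  kind_score <- function(k) sum(calls$score[calls$kind == k])
  nterm <- c(WH1 = has("WH1"), WHD = has("WHD"), WAHD = has("WAHD"),
             WMD = .has_wmd(calls, config$profiles$wmd_max_gap),
             IMD = has("IMD"))
  note <- ""
  if (sum(nterm) > 1L) {
    present <- names(nterm)[nterm]
    sc <- vapply(present, kind_score, 0)
    pick <- present[which.max(sc)]
    note <- sprintf("; multiple N-terminal domains (%s), chose %s by score",
                    paste(present, collapse = ","), pick)
    nterm[] <- FALSE
    nterm[pick] <- TRUE
  }

  if (nterm[["WH1"]]) {
    if (.count_ppr_vc_repeats(calls) >= 2L && !has("A"))
      return(res("WASP", "tandem-PPR-VC",
                 paste0("WH1 with tandem PPR-WH2-C repeats and no acidic domain", note)))
    if (nvca >= 1L)
      return(res("WASP", "canonical", paste0("WH1 with VCA group", note)))
    if ((has("CRIB") || has("WAID")) && !(has("C") && has("A")))
      return(res("WASP", "S-WASP",
                 paste0("WH1 with CRIB/WAID but central+acidic domains absent", note)))
    return(res("WASP", "canonical",
               paste0("WH1 present; VCA degraded or incomplete", note)))
  }
  if (nterm[["WHD"]])
    return(res("WAVE", "canonical", paste0("WHD N-terminal domain", note)))
  if (nterm[["WAHD"]]) {
    if ((nvca >= 2L || .count_vc_units(calls) >= 2L) && has("A"))
      return(res("WASH", "tandem-VCA", paste0("WAHD with two VCA groups in tandem", note)))
    if (!has("WH2") && has("C") && has("A"))
      return(res("WASH", "no-WH2", paste0("WAHD with CA but no WH2 domain", note)))
    return(res("WASH", "canonical", paste0("WAHD N-terminal domain", note)))
  }
  if (nterm[["WMD"]])
    return(res("WHAMM", "canonical", paste0("WMD N-terminal domain", note)))
  if (nterm[["IMD"]]) {
    if (nvca >= 1L)
      return(res("WAML", "canonical", paste0("IMD with WAID and VCA group", note)))
    if (!(has("C") && has("A")))
      return(res("WAML", "WAML-short",
                 paste0("IMD with WAID but VCA region absent", note)))
    return(res("WAML", "canonical", paste0("IMD with CA evidence", note)))
  }

  if (has("CRIB") || has("WAID")) {
    gbd_start <- min(first_start("CRIB"), first_start("WAID"), na.rm = TRUE)
    chg <- which(calls$kind == "CHG" &
                 calls$end - calls$start + 1L >= cc$chg_min_length)
    if (length(chg))
      return(res("WAWH", "WAWH-III",
                 sprintf("GBD without WH1; charged region of %d residues (type III)%s",
                         max(calls$end[chg] - calls$start[chg] + 1L), note)))
    ser_before <- any(calls$kind == "SER" & calls$start < gbd_start)
    cc_after <- any(calls$kind == "CC" & calls$start > gbd_start)
    if (ser_before && cc_after && .has_cxxc_pair(sequence, cc$cxxc_region))
      return(res("WAWH", "WAWH-II",
                 paste0("GBD without WH1; N-terminal CxxC pair, serine-rich region ",
                        "and coiled-coil (type II)", note)))
    b_before <- any(calls$kind == "B" & calls$start < gbd_start)
    return(res("WAWH", "WAWH-I",
               paste0("GBD without WH1",
                      if (b_before) "; basic region before CRIB (type I)"
                      else "; type I by default", note)))
  }

  res("unclassified", "none", "no family-defining domain evidence")
}

#' Assign a completeness class from observed and expected length
#'
#' The missing fraction is `m = max(0, 1 - observed/expected)`. Within the
#' completeness tolerance the protein is Complete; up to 5 % missing it is
#' a Partial; beyond that a Fragment.
#'
#' @param observed_length Observed sequence length.
#' @param expected_length Expected full-length size for the family; `NA`
#'   yields "Complete" with a warning.
#' @param partial_max_missing Partial/Fragment boundary (default 0.05).
#' @param complete_tolerance Length jitter treated as complete (default 0.01).
#' @return One of "Complete", "Partial", "Fragment".
#' @export
assess_completeness <- function(observed_length, expected_length,
                                partial_max_missing = 0.05,
                                complete_tolerance = 0.01) {
  stopifnot(partial_max_missing > 0, partial_max_missing < 1)
  if (is.na(expected_length)) {
    warnf("no expected length available; reporting Complete")
    return("Complete")
  }
  m <- max(0, 1 - observed_length / expected_length)
  if (m <= complete_tolerance) "Complete"
  else if (m <= partial_max_missing) "Partial"
  else "Fragment"
}

#' Count coding disablements and flag pseudogenes
#'
#' Disablements counted on the coding sequence: internal in-frame stop
#' codons, missing initial ATG, missing terminal stop codon, and a length
#' not divisible by three (frame-shift proxy). A gene is flagged when the
#' count reaches `min_disablements` — more damage than is attributable to
#' sequencing or assembly error.
#'
#' @param cds Nucleotide string over A, C, G, T, N.
#' @param frame 0-based reading-frame offset.
#' @param min_disablements Flagging threshold (default 2).
#' @return List with `pseudogene` (flag), `n_disablements` and
#'   `disablements` (labels).
#' @export
flag_pseudogene <- function(cds, frame = 0L, min_disablements = 2L) {
  if (is.null(cds) || !nzchar(cds)) stopf("empty coding sequence")
  cds <- toupper(cds)
  ch <- seq_chars(cds)
  if (!all(ch %in% c("A", "C", "G", "T", "N")))
    stopf("coding sequence must be over A, C, G, T, N")
  body <- substr(cds, frame + 1L, nchar(cds))
  n <- nchar(body)
  found <- character(0)
  if (n %% 3L != 0L) found <- c(found, "length_not_multiple_of_3")
  ncod <- n %/% 3L
  codons <- if (ncod > 0L)
    substring(body, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod)) else character(0)
  stops <- c("TAA", "TAG", "TGA")
  if (ncod < 1L || codons[1L] != "ATG") found <- c(found, "missing_start_ATG")
  if (ncod < 1L || !codons[ncod] %in% stops) found <- c(found, "missing_terminal_stop")
  internal <- if (ncod > 2L) which(codons[2:(ncod - 1L)] %in% stops) else integer(0)
  found <- c(found, rep("internal_stop", length(internal)))
  list(pseudogene = length(found) >= min_disablements,
       n_disablements = length(found),
       disablements = found)
}
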