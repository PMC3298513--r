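# Degenerate residue-class motif patterns and the scanner that locates them.
#
# A pattern is an ordered list of residue-class sets with bounded runs of
# unconstrained residues ("gaps") between consecutive fixed positions. This
# is the formalism behind the WH2 consensus
# [VILM]-[LM]-[ASED]-[ASDEQ]-[IL]-[KRQ]-x(gap)-[L]-[KR]-[KR]-[VTA],
# the central (C) domain pattern and the CRIB motif.

#' Construct a degenerate motif pattern
#'
#' @param name Pattern name; becomes the `kind` of every resulting call.
#' @param positions List of character vectors, one residue-class set per
#'   fixed position, each a non-empty subset of [aa_alphabet()].
#' @param gaps List of length `length(positions) - 1`; element `j` is an
#'   integer pair `c(min, max)` bounding the unconstrained run between fixed
#'   positions `j` and `j + 1` (`c(0, 0)` for adjacent positions).
#' @return A `motif_pattern` object.
#' @export
motif_pattern <- function(name, positions, gaps = NULL) {
  if (is.null(gaps)) gaps <- rep(list(c(0L, 0L)), max(0L, length(positions) - 1L))
  if (length(positions) < 1L) stopf("pattern '%s': needs at least one position", name)
  if (length(gaps) != length(positions) - 1L)
    stopf("pattern '%s': %d positions need %d gap slots, got %d",
          name, length(positions), length(positions) - 1L, length(gaps))
  for (p in positions) {
    if (length(p) == 0L || !all(p %in% aa_alphabet()))
      stopf("pattern '%s': residue classes must be non-empty subsets of the 20-letter alphabet", name)
  }
  for (g in gaps) {
    if (length(g) != 2L || g[1] < 0L || g[1] > g[2])
      stopf("pattern '%s': gap slots must be c(min, max) with 0 <= min <= max", name)
  }
  structure(list(name = name,
                 positions = lapply(positions, unique),
                 gaps = lapply(gaps, as.integer)),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  parts <- character(0)
  for (j in seq_along(x$positions)) {
    parts <- c(parts, paste0("[", paste(x$positions[[j]], collapse = ""), "]"))
    if (j < length(x$positions)) {
      g <- x$gaps[[j]]
      if (g[2] > 0L)
        parts <- c(parts, if (g[1] == g[2]) sprintf("x%d", g[1]) else sprintf("x(%d,%d)", g[1], g[2]))
    }
  }
  cat(sprintf("<motif_pattern %s> %s\n", x$name, paste(parts, collapse = "-")))
  invisible(x)
}

#' Built-in WH2 domain pattern
#'
#' The WH2 consensus derived from the family-wide alignment: an N-terminal
#' amphipathic-helix block \code{[VILM][LM][ASED][ASDEQ][IL][KRQ]}, a
#' variable unconstrained run, and the conserved \code{L[KR][KR][VTA]}
#' (LKKT/LKKV) anchor. The printed consensus shows a run of ten, but linker
#' lengths vary between subfamilies (four to five in most, seven to eight in
#' fungal WASPs, ten in WASH), so the run is exposed as a configurable
#' range; the default (6, 14) brackets the printed ten.
#'
#' @param gap_min,gap_max Bounds on the unconstrained run between the helix
#'   block and the LKK anchor.
#' @return A `motif_pattern` named "WH2".
#' @export
wh2_pattern <- function(gap_min = 6, gap_max = 14) {
  motif_pattern(
    "WH2",
    positions = list(c("V", "I", "L", "M"), c("L", "M"),
                     c("A", "S", "E", "D"), c("A", "S", "D", "E", "Q"),
                     c("I", "L"), c("K", "R", "Q"),
                     "L", c("K", "R"), c("K", "R"), c("V", "T", "A")),
    gaps = c(rep(list(c(0L, 0L)), 5L), list(c(gap_min, gap_max)),
             rep(list(c(0L, 0L)), 3L)))
}

#' Built-in central (C) domain pattern
#'
#' Three large hydrophobic residues (VILM), each separated by three
#' residues, followed by a basic doublet or triplet (K/R) and terminated by
#' another large hydrophobic residue (VILMY). The spacings around the basic
#' run are not fixed by the consensus and default to 0..6.
#'
#' @param n_basic 2 or 3 basic residues.
#' @param spacer_max Maximum unconstrained run on either side of the basic run.
#' @return A `motif_pattern` named "C".
#' @export
c_pattern <- function(n_basic = 2, spacer_max = 6) {
  h <- c("V", "I", "L", "M")
  b <- c("K", "R")
  motif_pattern(
    "C",
    positions = c(list(h, h, h), rep(list(b), n_basic),
                  list(c("V", "I", "L", "M", "Y"))),
    gaps = c(list(c(3L, 3L), c(3L, 3L), c(0L, spacer_max)),
             rep(list(c(0L, 0L)), n_basic - 1L),
             list(c(0L, spacer_max))))
}

#' Built-in CRIB motif pattern
#'
#' The Cdc42/Rac interactive binding consensus
#' I-S-x-P-x(2..4)-F-x-H-x-x-H-V-G with each fixed class widened by
#' conservative substitutions. The consensus is literature-standard (it is
#' not defined by the family alignment itself) and can be overridden through
#' the configuration.
#'
#' @return A `motif_pattern` named "CRIB".
#' @export
crib_pattern <- function() {
  motif_pattern(
    "CRIB",
    positions = list(c("I", "V"), c("S", "T"), "P", c("F", "Y", "W"),
                     "H", "H", c("V", "I"), c("G", "A")),
    gaps = list(c(1L, 1L), c(0L, 0L), c(2L, 4L), c(1L, 1L),
                c(2L, 2L), c(0L, 0L), c(0L, 0L)))
}

# Fixed-position offsets (0-based, relative to match start) for one
# assignment of gap lengths, plus the total match length.
.pattern_offsets <- function(pattern, gap_lengths) {
  k <- length(pattern$positions)
  off <- integer(k)
  for (j in seq_len(k - 1L)) off[j + 1L] <- off[j] + 1L + gap_lengths[j]
  list(off = off, len = off[k] + 1L)
}

#' Scan a sequence with a degenerate motif pattern
#'
#' Reports every distinct placement (start, end) at which the pattern
#' matches, enumerating all admissible gap lengths. Overlapping matches are
#' all reported; resolving them is the classifier's job. The score is the
#' number of matched fixed positions plus a bonus of 1 if any unconstrained
#' (gap) residue is V, I or F — the hydrophobic linker residue that docks
#' into a hydrophobic pocket on actin.
#'
#' 'X' residues never satisfy a residue-class position.
#'
#' @param sequence Amino-acid string.
#' @param pattern A [motif_pattern()].
#' @param id Record identifier stored in the result.
#' @return A domain-call data frame (id, kind, start, end, score, evidence),
#'   sorted by start; zero rows if there is no match.
#' @export
scan_pattern <- function(sequence, pattern, id = NA_character_) {
  stopifnot(inherits(pattern, "motif_pattern"))
  chars <- seq_chars(sequence)
  n <- length(chars)
  k <- length(pattern$positions)

  # Membership mask per distinct residue class.
  keys <- vapply(pattern$positions, function(p) paste(sort(p), collapse = ""), "")
  masks <- lapply(unique(keys), function(key) {
    chars %in% pattern$positions[[match(key, keys)]]
  })
  names(masks) <- unique(keys)

  # All gap-length assignments (cross product over variable slots).
  ranges <- lapply(pattern$gaps, function(g) seq.int(g[1], g[2]))
  combos <- if (length(ranges)) as.matrix(expand.grid(ranges, KEEP.OUT.ATTRS = FALSE)) else
    matrix(integer(0), nrow = 1L, ncol = 0L)

  hits <- vector("list", nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    geom <- .pattern_offsets(pattern, combos[ci, ])
    if (geom$len > n) next
    ns <- n - geom$len + 1L
    m <- rep(TRUE, ns)
    for (j in seq_len(k)) {
      m <- m & masks[[keys[j]]][seq_len(ns) + geom$off[j]]
      if (!any(m)) break
    }
    starts <- which(m)
    if (length(starts) == 0L) next
    ends <- starts + geom$len - 1L
    gap_off <- setdiff(seq_len(geom$len) - 1L, geom$off)
    bonus <- vapply(starts, function(s) {
      as.integer(length(gap_off) > 0L && any(chars[s + gap_off] %in% c("V", "I", "F")))
    }, 1L)
    hits[[ci]] <- data.frame(start = starts, end = ends,
                             score = k + bonus, stringsAsFactors = FALSE)
  }
  hits <- hits[!vapply(hits, is.null, TRUE)]
  if (length(hits) == 0L) return(empty_calls())
  all <- do.call(rbind, hits)
  # One row per distinct (start, end); keep the best score.
  ord <- order(all$start, all$end, -all$score)
  all <- all[ord, , drop = FALSE]
  all <- all[!duplicated(all[c("start", "end")]), , drop = FALSE]
  make_calls(id, pattern$name, all$start, all$end, all$score,
             vapply(seq_len(nrow(all)),
                    function(i) substr(sequence, all$start[i], all$end[i]), ""))
}

#' Scan a sequence for the central (C) domain
#'
#' Runs both the basic-doublet and basic-triplet forms of [c_pattern()] and
#' merges placements, keeping the better score where both forms match the
#' same span.
#'
#' @inheritParams scan_pattern
#' @param spacer_max Passed to [c_pattern()].
#' @return A domain-call data frame sorted by start.
#' @export
scan_c_domain <- function(sequence, id = NA_character_, spacer_max = 6) {
  calls <- rbind_calls(list(scan_pattern(sequence, c_pattern(2, spacer_max), id),
                            scan_pattern(sequence, c_pattern(3, spacer_max), id)))
  if (nrow(calls) == 0L) return(calls)
  ord <- order(calls$start, calls$end, -calls$score)
  calls <- calls[ord, , drop = FALSE]
  calls <- calls[!duplicated(calls[c("start", "end")]), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Scan a sequence for the CRIB motif
#'
#' @inheritParams scan_pattern
#' @param pattern CRIB pattern; defaults to [crib_pattern()].
#' @return A domain-call data frame sorted by start.
#' @export
scan_crib <- function(sequence, id = NA_character_, pattern = crib_pattern()) {
  scan_pattern(sequence, pattern, id)
}
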