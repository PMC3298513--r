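# Composition-biased (low-complexity) region detectors: basic, poly-proline,
# serine-rich and long charged regions, and the acidic C-terminal (A) domain.

#' Construct a composition-window specification
#'
#' A region is reported where every sliding window of `window` residues has
#' at least `min_fraction` of its residues in `targets`. Runs of passing
#' windows are trimmed to the outermost target residues, and trimmed runs
#' separated by at most `merge_gap` residues are merged. 'X' residues never
#' count towards the target numerator.
#'
#' @param kind Call kind (e.g. "B", "PPR", "SER", "CHG").
#' @param targets Character vector of target residues.
#' @param window Window length in residues (>= 4).
#' @param min_fraction Minimum target fraction per window (0 < f <= 1).
#' @param merge_gap Merge runs separated by at most this many residues.
#' @return A `composition_spec` object.
#' @export
composition_spec <- function(kind, targets, window, min_fraction,
                             merge_gap = max(2L, window %/% 2L)) {
  if (window < 4L) stopf("composition spec '%s': window must be >= 4", kind)
  if (min_fraction <= 0 || min_fraction > 1)
    stopf("composition spec '%s': min_fraction must be in (0, 1]", kind)
  if (!all(targets %in% aa_alphabet()))
    stopf("composition spec '%s': targets must be standard residues", kind)
  structure(list(kind = kind, targets = unique(targets),
                 window = as.integer(window), min_fraction = min_fraction,
                 merge_gap = as.integer(merge_gap)),
            class = "composition_spec")
}

#' Built-in composition specifications
#'
#' Defaults: basic region K/R >= 0.40 over window 8; poly-proline P >= 0.40
#' over window 10; serine-rich S >= 0.40 over window 10; long charged region
#' E/R/K >= 0.80 over window 200 (the Entamoeba-type region is described as
#' about 90 % E/R/K over about 800 residues; the lower detection threshold
#' tolerates divergence).
#'
#' @name composition_presets
#' @return A `composition_spec`.
NULL

#' @rdname composition_presets
#' @export
basic_region_spec <- function() composition_spec("B", c("K", "R"), 8L, 0.40)

#' @rdname composition_presets
#' @export
ppr_spec <- function() composition_spec("PPR", "P", 10L, 0.40)

#' @rdname composition_presets
#' @export
serine_rich_spec <- function() composition_spec("SER", "S", 10L, 0.40)

#' @rdname composition_presets
#' @export
charged_region_spec <- function() composition_spec("CHG", c("E", "R", "K"), 200L, 0.80)

#' Scan a sequence for composition-biased regions
#'
#' @param sequence Amino-acid string.
#' @param spec A [composition_spec()].
#' @param id Record identifier stored in the result.
#' @return Domain-call data frame; the score is the overall target fraction
#'   of each merged, trimmed run. Empty if the sequence is shorter than the
#'   window.
#' @export
scan_composition <- function(sequence, spec, id = NA_character_) {
  stopifnot(inherits(spec, "composition_spec"))
  chars <- seq_chars(sequence)
  n <- length(chars)
  w <- spec$window
  if (n < w) return(empty_calls())
  is_target <- chars %in% spec$targets
  cs <- cumsum(c(0L, is_target))
  counts <- cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]
  need <- ceiling(w * spec$min_fraction - 1e-9)
  pass <- counts >= need
  if (!any(pass)) return(empty_calls())

  # Maximal stretches of consecutive passing window starts.
  r <- rle(pass)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  runs <- data.frame(s = starts[r$values], e = stops[r$values] + w - 1L)

  # Trim to outermost target residues.
  for (i in seq_len(nrow(runs))) {
    s0 <- runs$s[i]
    idx <- which(is_target[s0:runs$e[i]])
    runs$s[i] <- s0 + idx[1L] - 1L
    runs$e[i] <- s0 + idx[length(idx)] - 1L
  }

  # Merge runs closer than the merge gap.
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      last <- nrow(merged)
      if (runs$s[i] - merged$e[last] - 1L <= spec$merge_gap) {
        merged$e[last] <- max(merged$e[last], runs$e[i])
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }

  frac <- vapply(seq_len(nrow(merged)), function(i) {
    span <- merged$s[i]:merged$e[i]
    sum(is_target[span]) / length(span)
  }, 0)
  make_calls(id, spec$kind, merged$s, merged$e, frac,
             sprintf("fraction=%.3f;window=%d;targets=%s",
                     frac, w, paste(spec$targets, collapse = "")))
}

#' Locate the acidic C-terminal (A) domain and classify its aromatics
#'
#' Searches the C-terminal tail for a D/E-rich segment ending close to the
#' terminus. Most A domains end in a tryptophan at or near the last residue;
#' some lineages substitute phenylalanine/tyrosine, and some (e.g.
#' kinetoplastid WASH) have no aromatic at all. Aromatic residues directly
#' following the acidic segment (within `aromatic_window` residues) are
#' absorbed into the call.
#'
#' @param sequence Amino-acid string.
#' @param id Record identifier.
#' @param tail_length Length of the C-terminal tail searched (default 60).
#' @param window,min_fraction D/E composition window and threshold.
#' @param end_slack Maximum distance between segment end and the terminus.
#' @param aromatic_window Trailing residues inspected for W/F/Y.
#' @return A list with `call` (a domain-call data frame with zero or one
#'   row of kind "A") and `aromatic_class` (one of "W", "F_or_Y",
#'   "W_plus_F_or_Y", "none", or `NA` when no A domain is found).
#' @export
scan_acidic_terminus <- function(sequence, id = NA_character_,
                                 tail_length = 60L, window = 8L,
                                 min_fraction = 0.5, end_slack = 10L,
                                 aromatic_window = 5L) {
  chars <- seq_chars(sequence)
  n <- length(chars)
  none <- list(call = empty_calls(), aromatic_class = NA_character_)
  if (n < window) return(none)
  tail_start <- max(1L, n - as.integer(tail_length) + 1L)
  tail_seq <- substr(sequence, tail_start, n)
  spec <- composition_spec("A", c("D", "E"), window, min_fraction)
  runs <- scan_composition(tail_seq, spec, id)
  if (nrow(runs) == 0L) return(none)
  runs$start <- runs$start + tail_start - 1L
  runs$end <- runs$end + tail_start - 1L
  runs <- runs[n - runs$end <= end_slack, , drop = FALSE]
  if (nrow(runs) == 0L) return(none)
  run <- runs[which.max(runs$end - runs$start), , drop = FALSE]

  # Absorb trailing aromatics into the call.
  trail <- seq.int(run$end + 1L, min(n, run$end + aromatic_window))
  trail <- trail[trail <= n & trail > run$end]
  aro_trail <- trail[chars[trail] %in% c("W", "F", "Y")]
  end <- if (length(aro_trail)) max(aro_trail) else run$end
  span <- run$start:end
  look <- seq.int(run$start, min(n, end + aromatic_window))
  has_w <- any(chars[look] == "W")
  has_fy <- any(chars[look] %in% c("F", "Y"))
  cls <- if (has_w && has_fy) "W_plus_F_or_Y" else if (has_w) "W" else
    if (has_fy) "F_or_Y" else "none"
  frac <- sum(chars[span] %in% c("D", "E")) / length(span)
  call <- make_calls(id, "A", run$start, end, frac,
                     sprintf("fraction=%.3f;aromatic_class=%s", frac, cls))
  list(call = call, aromatic_class = cls)
}
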