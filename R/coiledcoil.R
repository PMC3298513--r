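# Heptad-repeat coiled-coil heuristic.

#' Scan a sequence for coiled-coil regions
#'
#' Slides a window over the sequence and, in each of the seven heptad
#' frames, measures the fraction of hydrophobic residues (V, I, L, M, F, A)
#' at the core `a`/`d` positions. A window passes when its best frame
#' reaches `threshold`; consecutive passing windows are merged and the
#' merged span is trimmed to the outermost hydrophobic `a`/`d` position of
#' its best frame, anchoring the call on the heptad core.
#'
#' @param sequence Amino-acid string.
#' @param id Record identifier.
#' @param window Window length, a multiple of 7 (default 28, four heptads).
#' @param threshold Minimum best-frame a/d hydrophobic fraction (default 0.6).
#' @return Domain-call data frame of kind "CC"; empty if the sequence is
#'   shorter than the window.
#' @export
scan_coiled_coil <- function(sequence, id = NA_character_,
                             window = 28L, threshold = 0.6) {
  window <- as.integer(window)
  if (window %% 7L != 0L) stopf("coiled-coil window must be a multiple of 7")
  chars <- seq_chars(sequence)
  n <- length(chars)
  if (n < window) return(empty_calls())
  hyd <- chars %in% c("V", "I", "L", "M", "F", "A")
  n_ad <- 2L * window %/% 7L

  # Per frame: windowed count of hydrophobic residues at a/d positions.
  frame_counts <- matrix(0L, nrow = n - window + 1L, ncol = 7L)
  for (f in 0:6) {
    ad <- hyd & (((seq_len(n) - 1L - f) %% 7L) %in% c(0L, 3L))
    cs <- cumsum(c(0L, ad))
    frame_counts[, f + 1L] <- cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]
  }
  best <- apply(frame_counts, 1L, max)
  need <- ceiling(n_ad * threshold - 1e-9)
  pass <- best >= need
  if (!any(pass)) return(empty_calls())

  r <- rle(pass)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  spans <- data.frame(s = starts[r$values], e = stops[r$values] + window - 1L)

  out <- vector("list", nrow(spans))
  for (i in seq_len(nrow(spans))) {
    span <- spans$s[i]:spans$e[i]
    # Best frame over the whole span.
    fr_frac <- vapply(0:6, function(f) {
      ad <- span[((span - 1L - f) %% 7L) %in% c(0L, 3L)]
      if (length(ad) == 0L) return(0)
      sum(hyd[ad]) / length(ad)
    }, 0)
    f <- which.max(fr_frac) - 1L
    ad <- span[((span - 1L - f) %% 7L) %in% c(0L, 3L)]
    core <- ad[hyd[ad]]
    if (length(core) == 0L) next
    # Trim terminal core positions until the core a/d fraction reaches the
    # threshold (stray hydrophobics far from the heptad core are shed).
    frac <- 0
    while (length(core) >= 2L) {
      ad_in <- ad[ad >= core[1L] & ad <= core[length(core)]]
      frac <- sum(hyd[ad_in]) / length(ad_in)
      if (frac >= threshold) break
      gap_l <- core[2L] - core[1L]
      gap_r <- core[length(core)] - core[length(core) - 1L]
      core <- if (gap_l >= gap_r) core[-1L] else core[-length(core)]
    }
    if (length(core) < 2L || frac < threshold) next
    out[[i]] <- make_calls(id, "CC", core[1L], core[length(core)], frac,
                           sprintf("frame=%d;ad_fraction=%.3f", f, frac))
  }
  rbind_calls(out)
}
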