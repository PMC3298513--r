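# Column-frequency scoring models (ungapped PSSMs) for the alignment-defined
# family domains (WH1, WHD, WAHD, WMD, IMD, WAID, WAM1-4, WASH motifs), and
# sequence-logo information content.

.seq_strings <- function(records) {
  if (is.data.frame(records) && "sequence" %in% names(records)) records$sequence
  else if (is.character(records)) records
  else stopf("expected a protein-records data frame or a character vector of sequences")
}

#' Build an ungapped column-frequency scoring model from a seed alignment
#'
#' Columns whose gap fraction exceeds `1 - min_column_occupancy` are
#' dropped. Per-column residue frequencies are computed over non-gap,
#' non-'X' residues with a background-proportional pseudocount
#' (`freq = (count + pseudocount * background) / (n + pseudocount)`), so
#' every frequency is strictly positive. Scores are `log2(freq /
#' background)` bits; the background defaults to uniform 1/20.
#'
#' @param records Aligned sequences (protein-records data frame or
#'   character vector); all of equal length, at least 2.
#' @param name Model name.
#' @param kind Call kind emitted by [scan_profile()] (defaults to `name`).
#' @param pseudocount Total pseudocount mass (default 1, Laplace-style).
#' @param min_column_occupancy Minimum non-gap fraction per retained column.
#' @param background Length-20 background frequency vector (order of
#'   [aa_alphabet()]); defaults to uniform.
#' @param evidence_tag Optional string prefixed to call evidence (used to
#'   label the two halves of the split WMD model).
#' @return A `profile_model` with frequency and score matrices (20 x width),
#'   the consensus (maximum attainable) score and a default threshold of
#'   60 % of the consensus score.
#' @export
build_profile <- function(records, name, kind = name, pseudocount = 1,
                          min_column_occupancy = 0.5, background = NULL,
                          evidence_tag = NULL) {
  seqs <- .seq_strings(records)
  if (length(seqs) < 2L) stopf("profile '%s': need at least 2 aligned sequences", name)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stopf("profile '%s': ragged alignment (widths %s)", name,
          paste(unique(widths), collapse = ", "))
  aa <- aa_alphabet()
  if (is.null(background)) background <- rep(1 / 20, 20L)
  if (length(background) != 20L || any(background <= 0))
    stopf("background must be 20 positive frequencies")
  background <- background / sum(background)

  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-")
  keep <- gap_frac <= 1 - min_column_occupancy
  if (!any(keep)) stopf("profile '%s': all columns dropped by occupancy filter", name)
  mat <- mat[, keep, drop = FALSE]
  w <- ncol(mat)

  freq <- matrix(0, nrow = 20L, ncol = w, dimnames = list(aa, NULL))
  for (j in seq_len(w)) {
    col <- mat[, j]
    col <- col[col %in% aa]
    counts <- tabulate(match(col, aa), nbins = 20L)
    freq[, j] <- (counts + pseudocount * background) / (length(col) + pseudocount)
  }
  score <- log2(freq / background)
  consensus <- sum(apply(score, 2L, max))
  structure(list(name = name, kind = kind, alphabet = aa,
                 columns = freq, background = background, score = score,
                 width = w, consensus_score = consensus,
                 threshold = 0.6 * consensus,
                 pseudocount = pseudocount,
                 min_column_occupancy = min_column_occupancy,
                 evidence_tag = evidence_tag,
                 n_seq = length(seqs)),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("<profile_model %s> kind=%s width=%d n=%d consensus=%.1f bits threshold=%.1f bits\n",
              x$name, x$kind, x$width, x$n_seq, x$consensus_score, x$threshold))
  invisible(x)
}

#' Consensus sequence of a profile model
#'
#' @param model A `profile_model`.
#' @return The modal residue of each column, as a string.
#' @export
profile_consensus <- function(model) {
  paste(model$alphabet[apply(model$score, 2L, which.max)], collapse = "")
}

#' Scan a sequence with a profile model
#'
#' Scores every ungapped placement of the model (total log-odds in bits;
#' 'X' and other non-standard residues contribute 0) and reports
#' placements at or above the threshold, greedily selecting
#' non-overlapping calls by score (ties: leftmost).
#'
#' @param sequence Amino-acid string.
#' @param model A [build_profile()] model.
#' @param score_threshold Minimum total score in bits; defaults to the
#'   model's stored threshold (60 % of the consensus score).
#' @param id Record identifier.
#' @return Domain-call data frame; empty if the sequence is shorter than
#'   the model.
#' @export
scan_profile <- function(sequence, model, score_threshold = NULL,
                         id = NA_character_) {
  stopifnot(inherits(model, "profile_model"))
  if (is.null(score_threshold)) score_threshold <- model$threshold
  chars <- seq_chars(sequence)
  n <- length(chars)
  w <- model$width
  if (n < w) return(empty_calls())
  idx <- match(chars, model$alphabet)
  noff <- n - w + 1L
  scores <- numeric(noff)
  for (j in seq_len(w)) {
    colv <- model$score[, j]
    v <- colv[idx[seq_len(noff) + j - 1L]]
    v[is.na(v)] <- 0
    scores <- scores + v
  }
  cand <- which(scores >= score_threshold)
  if (length(cand) == 0L) return(empty_calls())
  cand <- cand[order(-scores[cand], cand)]
  kept <- integer(0)
  for (s in cand) {
    if (!any(abs(kept - s) < w)) kept <- c(kept, s)
  }
  kept <- sort(kept)
  tag <- if (is.null(model$evidence_tag)) "" else paste0(model$evidence_tag, ";")
  make_calls(id, model$kind, kept, kept + w - 1L, scores[kept],
             sprintf("%sbits=%.2f;model=%s", tag, scores[kept], model$name))
}

#' Per-column frequencies and information content of an alignment
#'
#' Frequencies are computed over non-gap (and non-'X') residues. The
#' information content of a column is `log2(20) - H` bits, where `H` is the
#' Shannon entropy of the observed frequencies; with the small-sample
#' correction enabled, `(20 - 1) / (2 * ln(2) * n)` is subtracted and the
#' result floored at 0. Columns with no observed residues get `NA`.
#'
#' @param records Aligned sequences (protein-records data frame or
#'   character vector), at least one.
#' @param small_sample_correction Apply the small-sample correction.
#' @return Data frame with `position`, `n` (non-gap count), `ic` (bits) and
#'   one frequency column per residue.
#' @export
compute_logo <- function(records, small_sample_correction = FALSE) {
  seqs <- .seq_strings(records)
  if (length(seqs) < 1L) stopf("logo: empty alignment")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) stopf("logo: ragged alignment")
  aa <- aa_alphabet()
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  w <- ncol(mat)
  out <- data.frame(position = seq_len(w), n = integer(w), ic = numeric(w))
  freq <- matrix(0, nrow = w, ncol = 20L, dimnames = list(NULL, aa))
  for (j in seq_len(w)) {
    col <- mat[, j]
    col <- col[col %in% aa]
    nj <- length(col)
    out$n[j] <- nj
    if (nj == 0L) {
      out$ic[j] <- NA_real_
      next
    }
    f <- tabulate(match(col, aa), nbins = 20L) / nj
    freq[j, ] <- f
    h <- -sum(ifelse(f > 0, f * log2(f), 0))
    ic <- log2(20) - h
    if (small_sample_correction) ic <- ic - (20 - 1) / (2 * log(2) * nj)
    out$ic[j] <- max(0, min(log2(20), ic))
  }
  cbind(out, as.data.frame(freq))
}

#' Write a logo table to TSV
#'
#' The header records whether the small-sample correction was applied.
#'
#' @param logo Result of [compute_logo()].
#' @param path Output file.
#' @param small_sample_correction Mode flag recorded in the file header.
#' @return `path`, invisibly.
#' @export
write_logo_tsv <- function(logo, path, small_sample_correction = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# waspfam sequence logo; small_sample_correction=%s",
                     tolower(as.character(small_sample_correction))), con)
  utils::write.table(logo, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a profile model's frequency matrix to TSV
#'
#' @param model A `profile_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# waspfam profile %s kind=%s pseudocount=%g n=%d",
                     model$name, model$kind, model$pseudocount, model$n_seq), con)
  df <- data.frame(residue = model$alphabet, model$columns, check.names = FALSE)
  colnames(df) <- c("residue", sprintf("pos%d", seq_len(model$width)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
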