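# Shared constants and small internal helpers.

#' The 20-letter amino-acid alphabet
#'
#' Order used throughout for frequency vectors and profile matrices.
#' @return Character vector of the 20 standard residues.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Legal residue characters in unaligned sequences ('X' = ambiguous).
.legal_chars <- function(aligned = FALSE) {
  c(aa_alphabet(), "X", if (aligned) "-")
}

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic package code goes through
# this so that a seed fully determines the output.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Split a sequence string into a character vector of residues.
seq_chars <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

# Empty domain-call table; every detector returns this shape.
empty_calls <- function() {
  data.frame(id = character(), kind = character(),
             start = integer(), end = integer(),
             score = numeric(), evidence = character(),
             stringsAsFactors = FALSE)
}

# Build a one-row (or n-row) domain-call table.
make_calls <- function(id, kind, start, end, score, evidence) {
  if (length(start) == 0L) return(empty_calls())
  data.frame(id = id, kind = kind,
             start = as.integer(start), end = as.integer(end),
             score = as.numeric(score), evidence = as.character(evidence),
             stringsAsFactors = FALSE)
}

rbind_calls <- function(lst) {
  lst <- lst[vapply(lst, NROW, 1L) > 0L]
  if (length(lst) == 0L) return(empty_calls())
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
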