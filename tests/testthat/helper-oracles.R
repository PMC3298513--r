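# Independent oracles and small fixtures shared across the test files.

random_seq <- function(n, alphabet = aa_alphabet()) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --------------------------------------------------------------------------
# Pattern-scanner oracle: per-gap-length PCRE enumeration with a lookahead
# so overlapping matches at different starts are all found. Independent of
# the shifted-mask implementation.

.class_regex <- function(set) {
  if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
}

oracle_scan_pattern <- function(sequence, pattern) {
  k <- length(pattern$positions)
  ranges <- lapply(pattern$gaps, function(g) seq.int(g[1], g[2]))
  combos <- if (length(ranges)) expand.grid(ranges, KEEP.OUT.ATTRS = FALSE) else
    data.frame(row.names = 1)
  hits <- list()
  for (ci in seq_len(nrow(combos))) {
    gaps <- as.integer(combos[ci, ])
    rx <- character(0)
    for (j in seq_len(k)) {
      rx <- c(rx, .class_regex(pattern$positions[[j]]))
      if (j < k && gaps[j] > 0L) rx <- c(rx, sprintf(".{%d}", gaps[j]))
    }
    len <- k + sum(gaps)
    m <- gregexpr(sprintf("(?=%s)", paste(rx, collapse = "")), sequence,
                  perl = TRUE)[[1L]]
    starts <- m[m > 0L]
    for (s in starts)
      hits[[length(hits) + 1L]] <- c(start = s, end = s + len - 1L)
  }
  if (length(hits) == 0L)
    return(data.frame(start = integer(), end = integer()))
  df <- unique(as.data.frame(do.call(rbind, hits)))
  df[order(df$start, df$end), , drop = FALSE]
}

expect_pattern_matches_oracle <- function(sequence, pattern) {
  got <- scan_pattern(sequence, pattern)
  want <- oracle_scan_pattern(sequence, pattern)
  expect_equal(nrow(got), nrow(want))
  if (nrow(want)) {
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
}

# --------------------------------------------------------------------------
# Profile-scanner oracle: direct per-offset column-lookup scoring.

oracle_profile_scores <- function(sequence, model) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  w <- model$width
  if (n < w) return(numeric(0))
  vapply(seq_len(n - w + 1L), function(s) {
    total <- 0
    for (j in seq_len(w)) {
      a <- ch[s + j - 1L]
      total <- total + if (a %in% model$alphabet) model$score[a, j] else 0
    }
    total
  }, 0)
}

# --------------------------------------------------------------------------
# Dollo oracle: enumerate every admissible gain edge and search loss-edge
# subsets of increasing size until the implied leaf states reproduce the
# matrix. Returns the minimal (gain, losses) labelling as node labels.

oracle_dollo <- function(tree, presence) {
  # presence: named logical over all tips
  tree <- waspfam:::.label_nodes(tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  ch <- waspfam:::.children(tree)
  tips_under <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    unlist(lapply(ch[[v]], tips_under))
  }
  subtree_tips <- lapply(seq_len(nnode), tips_under)
  pres_tips <- names(presence)[presence]
  if (length(pres_tips) == 0L) return(NULL)

  label_of <- function(v) {
    if (v <= ntip) tree$tip.label[v] else tree$node.label[v - ntip]
  }
  best <- NULL
  for (gain in seq_len(nnode)) {
    if (!all(pres_tips %in% subtree_tips[[gain]])) next
    inside <- which(vapply(seq_len(nnode), function(v)
      v != gain && all(subtree_tips[[v]] %in% subtree_tips[[gain]]), TRUE))
    found <- NULL
    for (k in 0:length(inside)) {
      if (!is.null(best) && k >= length(best$losses)) break
      combs <- if (k == 0L) list(integer(0)) else
        utils::combn(inside, k, simplify = FALSE)
      for (losses in combs) {
        lost <- unique(unlist(subtree_tips[losses]))
        implied <- setdiff(subtree_tips[[gain]], lost)
        states <- names(presence) %in% implied
        if (identical(states, unname(presence))) {
          found <- losses
          break
        }
      }
      if (!is.null(found)) break
    }
    if (!is.null(found) &&
        (is.null(best) || length(found) < length(best$losses))) {
      best <- list(gain = label_of(gain),
                   losses = sort(vapply(found, label_of, "")))
    }
  }
  best
}

# --------------------------------------------------------------------------
# Small generation helpers

tiny_sim <- function(seed, archs, n_each = 1L, noise = 0) {
  plan <- data.frame(species = paste0("sp_", archs), architecture = archs,
                     n = n_each, stringsAsFactors = FALSE)
  generate_proteome(generator_config(seed = seed, plan = plan, noise = noise))
}

empty_calls_df <- function() waspfam:::empty_calls()

# Minimal boundary error of each planted element against detected calls of
# the same kind on the same record (Inf when a planted element is missed).
boundary_errors <- function(truth_calls, calls) {
  vapply(seq_len(nrow(truth_calls)), function(i) {
    t <- truth_calls[i, ]
    cand <- calls[calls$id == t$id & calls$kind == t$kind &
                    calls$start <= t$end & calls$end >= t$start, , drop = FALSE]
    if (nrow(cand) == 0L) return(Inf)
    min(pmax(abs(cand$start - t$start), abs(cand$end - t$end)))
  }, 0)
}

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
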