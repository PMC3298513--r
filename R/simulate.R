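# Seeded generator of synthetic proteomes with full ground truth.
#
# Each synthetic protein is an N-to-C concatenation of sampled domain
# instances following one of the family architectures, joined by background
# linkers. The generator is designed so that planted ground truth is
# unambiguous: linkers are rejection-sampled to be free of WH2/C/CRIB
# pattern matches, composition-defined blocks receive short non-target
# guard flanks sized to the windowing slack of the detectors, and
# architectures defined by the ABSENCE of an element (S-WASP, WAML-short,
# the tandem PPR-VC form, the WASH no-WH2 form) are verified against the
# corresponding detector and resampled if a chance match appears.

# ---------------------------------------------------------------------------
# Architecture catalogue

#' The synthetic architecture catalogue
#'
#' The ordered element lists of the family domain organisations emulated by
#' the generator: the canonical and variant forms of WASP (including
#' S-WASP and the tandem PPR-VC form), WAVE (including the coiled-coil and
#' plant forms), WASH (canonical, WH2-less, tandem-VCA), WHAMM (with and
#' without the low-complexity WMD insertion), the three WAWH types, and
#' WAML (canonical and short).
#'
#' @return Named list; each entry has `family`, `subtype` and `elements`.
#'   Element tokens are domain kinds plus `WMDN`/`WMDC` (the two halves of
#'   the WMD), `A:W`/`A:F`/`A:none` (acidic domain by aromatic class),
#'   `CXXC` (N-terminal CxxC motif pair) and `LC` (low-complexity
#'   insertion).
#' @export
wasp_architectures <- function() {
  list(
    WASP_canonical_2V = list(family = "WASP", subtype = "canonical",
      elements = c("WH1", "B", "CRIB", "WAID", "PPR", "WH2", "WH2", "C", "A:W")),
    WASP_canonical_1V = list(family = "WASP", subtype = "canonical",
      elements = c("WH1", "B", "CRIB", "WAID", "PPR", "WH2", "C", "A:F")),
    WASP_fungal_waid = list(family = "WASP", subtype = "canonical",
      elements = c("WH1", "B", "WAID", "PPR", "WH2", "C", "A:W")),
    WASP_yeast = list(family = "WASP", subtype = "canonical",
      elements = c("WH1", "B", "PPR", "WH2", "C", "A:W")),
    SWASP_basidio = list(family = "WASP", subtype = "S-WASP",
      elements = c("WH1", "CRIB", "WAID")),
    SWASP_fish = list(family = "WASP", subtype = "S-WASP",
      elements = c("WH1", "CRIB", "WAID", "PPR", "WH2")),
    WASP_tandem2 = list(family = "WASP", subtype = "tandem-PPR-VC",
      elements = c("WH1", "B", "CRIB", "WAID", "PPR", "WH2", "C", "PPR", "WH2", "C")),
    WASP_tandem3 = list(family = "WASP", subtype = "tandem-PPR-VC",
      elements = c("WH1", "B", "CRIB", "WAID", "PPR", "WH2", "C", "PPR", "WH2", "C",
                   "PPR", "WH2", "C")),
    WAVE_canonical = list(family = "WAVE", subtype = "canonical",
      elements = c("WHD", "B", "PPR", "WH2", "C", "A:W")),
    WAVE_two_wh2 = list(family = "WAVE", subtype = "canonical",
      elements = c("WHD", "B", "PPR", "WH2", "WH2", "C", "A:W")),
    WAVE_coiled = list(family = "WAVE", subtype = "canonical",
      elements = c("WHD", "CC", "PPR", "WH2", "WH2", "C", "A:W")),
    WAVE_plant = list(family = "WAVE", subtype = "canonical",
      elements = c("WHD", "B", "WAM1", "WAM2", "WAM3", "WAM4", "WH2", "C", "A:W")),
    WASH_canonical = list(family = "WASH", subtype = "canonical",
      elements = c("WAHD", "WASHM1", "WASHM2", "PPR", "WH2", "C", "A:W")),
    WASH_no_wh2 = list(family = "WASH", subtype = "no-WH2",
      elements = c("WAHD", "WASHM1", "WASHM2", "PPR", "C", "A:none")),
    WASH_tandem_vca = list(family = "WASH", subtype = "tandem-VCA",
      elements = c("WAHD", "WASHM1", "WASHM2", "PPR", "WH2", "C", "A:W",
                   "WH2", "C", "A:W")),
    WHAMM_compact = list(family = "WHAMM", subtype = "canonical",
      elements = c("WMDN", "WMDC", "CC", "PPR", "WH2", "WH2", "C", "A:W")),
    WHAMM_insertion = list(family = "WHAMM", subtype = "canonical",
      elements = c("WMDN", "LC", "WMDC", "CC", "PPR", "WH2", "WH2", "C", "A:W")),
    WAWH_I = list(family = "WAWH", subtype = "WAWH-I",
      elements = c("B", "CRIB", "WAID", "PPR", "WH2", "C", "A:W")),
    WAWH_II = list(family = "WAWH", subtype = "WAWH-II",
      elements = c("CXXC", "SER", "CRIB", "WAID", "CC", "PPR", "WH2", "C", "A:W")),
    WAWH_III = list(family = "WAWH", subtype = "WAWH-III",
      elements = c("CRIB", "WAID", "CHG", "PPR", "WH2", "C", "A:W")),
    WAML_canonical = list(family = "WAML", subtype = "canonical",
      elements = c("IMD", "WAID", "PPR", "WH2", "C", "A:W")),
    WAML_short = list(family = "WAML", subtype = "WAML-short",
      elements = c("IMD", "WAID"))
  )
}

# Profile-domain consensus lengths.
.profile_domain_lengths <- c(
  WH1 = 100L, WHD = 90L, WAHD = 90L, WMDN = 60L, WMDC = 110L, IMD = 150L,
  WAID = 50L, WAM1 = 20L, WAM3 = 15L, WAM4 = 180L,
  WASHM1 = 15L, WASHM2 = 15L)

# ---------------------------------------------------------------------------
# Generator configuration

#' Generator configuration
#'
#' @param seed Mandatory integer seed; a seed fully determines all outputs.
#' @param plan Data frame with columns `species`, `architecture`, `n`
#'   (copies); defaults to [default_plan()].
#' @param noise Per-motif point-mutation rate in [0, 1]: each residue of
#'   each planted element is substituted with this probability.
#' @param p_partial,p_fragment Truncation probabilities: a Partial loses up
#'   to 5 % of its length, a Fragment 10-50 %.
#' @param linker_min,linker_max Background linker length range (residues).
#' @param seed_n,seed_divergence Seed-alignment depth and per-position
#'   substitution rate for the synthetic family-domain alignments.
#' @param chg_length Length of the planted charged region (WAWH type III).
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed, plan = NULL, noise = 0,
                             p_partial = 0, p_fragment = 0,
                             linker_min = 10L, linker_max = 60L,
                             seed_n = 20L, seed_divergence = 0.05,
                             chg_length = 800L) {
  if (missing(seed) || is.null(seed)) stopf("generator seed is mandatory")
  stopifnot(noise >= 0, noise <= 1, p_partial >= 0, p_fragment >= 0,
            p_partial + p_fragment <= 1)
  structure(list(seed = as.integer(seed), plan = plan, noise = noise,
                 p_partial = p_partial, p_fragment = p_fragment,
                 linker_min = as.integer(linker_min),
                 linker_max = as.integer(linker_max),
                 seed_n = as.integer(seed_n),
                 seed_divergence = seed_divergence,
                 chg_length = as.integer(chg_length)),
            class = "generator_config")
}

#' Default generation plan
#'
#' Distributes `n_total` proteins round-robin over the full architecture
#' catalogue, one synthetic species per architecture.
#'
#' @param n_total Total number of proteins (default 200).
#' @return Data frame with `species`, `architecture`, `n`.
#' @export
default_plan <- function(n_total = 200L) {
  archs <- names(wasp_architectures())
  base <- n_total %/% length(archs)
  extra <- n_total %% length(archs)
  n <- rep(base, length(archs)) + c(rep(1L, extra), rep(0L, length(archs) - extra))
  data.frame(species = paste0("sp_", archs), architecture = archs, n = n,
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Element emitters (all assume an active RNG stream)

.sample_aa <- function(n, exclude = NULL) {
  pool <- setdiff(aa_alphabet(), exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

.sample_class <- function(class) sample(class, 1L)

# Guard specification for composition-defined neighbours: linker residues
# adjacent to such a block must avoid the block's target residues over the
# windowing slack, so detected boundaries coincide with planted ones.
.guard_spec <- function(token) {
  if (is.null(token)) return(NULL)
  kind <- sub(":.*$", "", token)
  hyd <- c("V", "I", "L", "M", "F", "A")  # keep coiled-coil windows out too
  switch(kind,
    B = list(len = 6L, exclude = c("K", "R", hyd)),
    PPR = list(len = 8L, exclude = c("P", hyd)),
    SER = list(len = 8L, exclude = c("S", hyd)),
    CHG = list(len = 45L, exclude = c("E", "R", "K", hyd)),
    A = list(len = 8L, exclude = c("D", "E", hyd)),
    CC = list(len = 28L, exclude = hyd),
    NULL)
}

# Pattern-free check used for linkers and consensus draws.
.has_motif_match <- function(sequence) {
  nrow(scan_pattern(sequence, wh2_pattern())) > 0L ||
    nrow(scan_c_domain(sequence)) > 0L ||
    nrow(scan_crib(sequence)) > 0L
}

.sample_motif_free <- function(n, exclude = NULL, tries = 100L) {
  for (i in seq_len(tries)) {
    s <- .sample_aa(n, exclude)
    if (!.has_motif_match(s)) return(s)
  }
  stopf("failed to sample a motif-free segment of length %d", n)
}

# A background linker between two elements, with guard flanks.
.emit_linker <- function(len_range, left_token = NULL, right_token = NULL) {
  gl <- .guard_spec(left_token)
  gr <- .guard_spec(right_token)
  body_len <- sample(seq.int(len_range[1L], len_range[2L]), 1L)
  left <- if (!is.null(gl)) .sample_aa(gl$len, gl$exclude) else ""
  right <- if (!is.null(gr)) .sample_aa(gr$len, gr$exclude) else ""
  body <- .sample_aa(body_len)
  s <- paste0(left, body, right)
  for (i in seq_len(50L)) {
    if (!.has_motif_match(s)) return(s)
    body <- .sample_aa(body_len)
    s <- paste0(left, body, right)
  }
  stopf("failed to sample a motif-free linker")
}

# Sample an instance of a class/gap pattern; returns the string. The
# instance is self-checked against the pattern before emission.
.emit_pattern_instance <- function(pattern, gap_exclude = NULL) {
  k <- length(pattern$positions)
  parts <- character(0)
  for (j in seq_len(k)) {
    parts <- c(parts, .sample_class(pattern$positions[[j]]))
    if (j < k) {
      g <- pattern$gaps[[j]]
      glen <- if (g[1] == g[2]) g[1] else sample(seq.int(g[1], g[2]), 1L)
      if (glen > 0L) parts <- c(parts, .sample_aa(glen, gap_exclude))
    }
  }
  s <- paste(parts, collapse = "")
  calls <- scan_pattern(s, pattern)
  if (!any(calls$start == 1L & calls$end == nchar(s)))
    stopf("emitted instance does not match its pattern (internal error)")
  s
}

# Composition block: `frac` of positions are target residues; both edges
# forced to targets; non-target fill avoids confounding residues — in
# particular hydrophobics, so neither the coiled-coil heuristic nor the
# hydrophobic-anchored patterns can fire inside the block.
.emit_composition_block <- function(len, targets, frac = 0.9,
                                    fill_exclude = c(targets, "V", "I", "L",
                                                     "M", "F", "A")) {
  # Rejection keeps the realised composition close to the nominal rate, so
  # short blocks cannot drift into the detector's uncertain regime.
  repeat {
    is_t <- stats::runif(len) < frac
    is_t[c(1L, len)] <- TRUE
    if (mean(is_t) >= frac - 0.05) break
  }
  ch <- character(len)
  ch[is_t] <- sample(targets, sum(is_t), replace = TRUE)
  if (any(!is_t)) ch[!is_t] <- strsplit(.sample_aa(sum(!is_t), fill_exclude),
                                        "", fixed = TRUE)[[1L]]
  paste(ch, collapse = "")
}

# Coiled coil: perfect heptads with hydrophobic a/d core. Returns the
# string and the core span (first..last core residue), which is the planted
# truth the detector anchors on.
.emit_coiled_coil <- function(n_heptads = 8L) {
  out <- character(0)
  for (i in seq_len(n_heptads)) {
    h <- strsplit(.sample_aa(7L, exclude = c("V", "I", "L", "M", "F", "A")),
                  "", fixed = TRUE)[[1L]]
    h[1L] <- sample(c("L", "I", "V"), 1L)
    h[4L] <- sample(c("L", "I", "V"), 1L)
    out <- c(out, h)
  }
  list(seq = paste(out, collapse = ""),
       core_start = 1L, core_end = 7L * (n_heptads - 1L) + 4L)
}

.emit_acidic <- function(aromatic = c("W", "F", "none")) {
  aromatic <- match.arg(aromatic)
  len <- sample(12:20, 1L)
  block <- .emit_composition_block(len, c("D", "E"), frac = 0.95,
                                   fill_exclude = c("D", "E", "W", "F", "Y",
                                                    "V", "I", "L", "M", "A"))
  suffix <- switch(aromatic, W = "W", F = "F", none = "")
  list(seq = paste0(block, suffix), aromatic = aromatic)
}

# ---------------------------------------------------------------------------
# Family-domain models (synthetic seed alignments)

# Draw motif-free consensus strings for every profile-defined domain, plus
# the structured WAM2 consensus (prolines separated by leucines, closed by
# a QWR triplet).
.draw_domain_models <- function(config) {
  lens <- .profile_domain_lengths
  consensus <- list()
  for (kind in names(lens))
    consensus[[kind]] <- .sample_motif_free(lens[[kind]])
  consensus$WAM2 <- paste0(paste(rep("PPL", 6L), collapse = ""), "PQWR")
  seeds <- list()
  for (kind in names(consensus)) {
    cons <- seq_chars(consensus[[kind]])
    seqs <- vapply(seq_len(config$seed_n), function(i) {
      ch <- cons
      mut <- stats::runif(length(ch)) < config$seed_divergence
      if (any(mut)) {
        ch[mut] <- vapply(ch[mut], function(a)
          sample(setdiff(aa_alphabet(), a), 1L), "")
      }
      paste(ch, collapse = "")
    }, "")
    seeds[[kind]] <- seqs
  }
  list(consensus = consensus, seeds = seeds)
}

#' Build profile models from seed alignments
#'
#' The `WMDN`/`WMDC` seed alignments become the two halves of the split WMD
#' model (both emit calls of kind `WMD`, tagged `half=N` / `half=C`); every
#' other alignment becomes a model whose kind is its own name.
#'
#' @param seeds Named list of aligned sequence sets (character vectors or
#'   protein-record data frames), e.g. from [generate_seed_alignments()].
#' @param config Run configuration ([waspfam_config()]).
#' @return Named list of `profile_model`s.
#' @export
build_profiles <- function(seeds, config = waspfam_config()) {
  pc <- config$profiles
  out <- list()
  for (kind in names(seeds)) {
    name <- kind
    call_kind <- kind
    tag <- NULL
    if (kind == "WMDN") { name <- "WMD-N"; call_kind <- "WMD"; tag <- "half=N" }
    if (kind == "WMDC") { name <- "WMD-C"; call_kind <- "WMD"; tag <- "half=C" }
    m <- build_profile(seeds[[kind]], name = name, kind = call_kind,
                       pseudocount = pc$pseudocount,
                       min_column_occupancy = pc$min_column_occupancy,
                       evidence_tag = tag)
    m$threshold <- pc$score_threshold_frac * m$consensus_score
    out[[kind]] <- m
  }
  out
}

#' Generate the synthetic seed alignments
#'
#' @param config A [generator_config()].
#' @return Named list of [protein_records()], one aligned set per
#'   profile-defined domain (WH1, WHD, WAHD, WMDN, WMDC, IMD, WAID,
#'   WAM1-4, WASHM1-2).
#' @export
generate_seed_alignments <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  models <- with_seed(config$seed, .draw_domain_models(config))
  out <- list()
  for (kind in names(models$seeds)) {
    out[[kind]] <- protein_records(
      sprintf("%s_seed_%02d", kind, seq_along(models$seeds[[kind]])),
      models$seeds[[kind]], aligned = TRUE)
  }
  out
}

# ---------------------------------------------------------------------------
# Protein assembly

# Emit one protein for an architecture; returns seq + truth calls. Assumes
# active RNG stream.
.emit_protein <- function(arch_name, arch, models, config) {
  elements <- arch$elements
  has_c <- any(elements == "C")
  has_a <- any(startsWith(elements, "A:"))
  has_wh2 <- any(elements == "WH2")

  for (attempt in seq_len(50L)) {
    parts <- "M"
    pos <- 1L
    truth <- list()
    add <- function(s) {
      parts[[length(parts) + 1L]] <<- s
      start <- pos + 1L
      pos <<- pos + nchar(s)
      start
    }
    intra_vca <- function(tok) sub(":.*$", "", tok) %in% c("WH2", "C", "A")

    lead <- .emit_linker(c(2L, 8L), right_token = elements[1L])
    add(lead)
    for (i in seq_along(elements)) {
      tok <- elements[i]
      kind <- sub(":.*$", "", tok)
      if (kind %in% names(models$consensus) || kind == "WAM2") {
        s <- models$consensus[[kind]]
        start <- add(s)
        truth_kind <- if (kind %in% c("WMDN", "WMDC")) "WMD" else kind
        truth[[length(truth) + 1L]] <- list(kind = truth_kind, start = start,
                                            end = pos)
      } else if (kind == "WH2") {
        s <- .emit_pattern_instance(wh2_pattern())
        start <- add(s)
        truth[[length(truth) + 1L]] <- list(kind = "WH2", start = start, end = pos)
      } else if (kind == "C") {
        s <- .emit_pattern_instance(c_pattern(sample(2:3, 1L)))
        start <- add(s)
        truth[[length(truth) + 1L]] <- list(kind = "C", start = start, end = pos)
      } else if (kind == "CRIB") {
        s <- .emit_pattern_instance(crib_pattern())
        start <- add(s)
        truth[[length(truth) + 1L]] <- list(kind = "CRIB", start = start, end = pos)
      } else if (kind == "B") {
        s <- .emit_composition_block(sample(10:16, 1L), c("K", "R"))
        start <- add(s)
        truth[[length(truth) + 1L]] <- list(kind = "B", start = start, end = pos)
      } else if (kind == "PPR") {
        s <- .emit_composition_block(sample(14:30, 1L), "P")
        start <- add(s)
        truth[[length(truth) + 1L]] <- list(kind = "PPR", start = start, end = pos)
      } else if (kind == "SER") {
        s <- .emit_composition_block(sample(14:20, 1L), "S")
        start <- add(s)
        truth[[length(truth) + 1L]] <- list(kind = "SER", start = start, end = pos)
      } else if (kind == "CHG") {
        s <- .emit_composition_block(config$chg_length, c("E", "R", "K"))
        start <- add(s)
        truth[[length(truth) + 1L]] <- list(kind = "CHG", start = start, end = pos)
      } else if (kind == "CC") {
        cc <- .emit_coiled_coil(8L)
        start <- add(cc$seq)
        truth[[length(truth) + 1L]] <- list(kind = "CC",
                                            start = start + cc$core_start - 1L,
                                            end = start + cc$core_end - 1L)
      } else if (kind == "A") {
        aro <- sub("^A:", "", tok)
        a <- .emit_acidic(aro)
        start <- add(a$seq)
        # Only the terminal acidic domain is recoverable truth: the A
        # detector is anchored at the C-terminus, so the interior acidic
        # segment of a tandem VCA is planted but not claimed as a call.
        if (i == length(elements))
          truth[[length(truth) + 1L]] <- list(kind = "A", start = start, end = pos)
      } else if (kind == "CXXC") {
        x1 <- .sample_aa(2L, exclude = "C")
        x2 <- .sample_aa(2L, exclude = "C")
        sp <- .sample_aa(3L, exclude = "C")
        add(paste0("C", x1, "C", sp, "C", x2, "C"))
      } else if (kind == "LC") {
        add(paste(sample(c("G", "S", "A", "Q", "N"), 120L, replace = TRUE),
                  collapse = ""))
      } else {
        stopf("unknown architecture element '%s' in %s", tok, arch_name)
      }
      if (i < length(elements)) {
        # The low-complexity insertion sits inside the WMD domain and
        # abuts both halves directly.
        if (elements[i] == "LC" || elements[i + 1L] == "LC") next
        rng <- if (intra_vca(elements[i]) && intra_vca(elements[i + 1L]))
          c(3L, 8L) else c(config$linker_min, config$linker_max)
        add(.emit_linker(rng, left_token = elements[i],
                         right_token = elements[i + 1L]))
      }
    }
    # Architectures without an acidic domain get a D/E-free tail so that
    # no chance acidic segment ends near the terminus.
    if (!has_a) add(.sample_motif_free(sample(12:18, 1L), exclude = c("D", "E")))
    seqs <- paste(parts, collapse = "")

    # Absence self-check: architectures defined by a missing element must
    # not contain a chance match for it.
    ok <- TRUE
    if (!has_c && nrow(scan_c_domain(seqs)) > 0L) ok <- FALSE
    if (ok && !has_a && nrow(scan_acidic_terminus(seqs)$call) > 0L) ok <- FALSE
    if (ok && !has_wh2 && nrow(scan_pattern(seqs, wh2_pattern())) > 0L) ok <- FALSE
    if (ok) {
      truth_df <- do.call(rbind, lapply(truth, function(t)
        data.frame(kind = t$kind, start = t$start, end = t$end,
                   stringsAsFactors = FALSE)))
      return(list(sequence = seqs, truth = truth_df))
    }
  }
  stopf("could not assemble an unambiguous %s protein in 50 attempts", arch_name)
}

# Apply per-motif point mutations; returns mutated sequence.
.apply_motif_noise <- function(sequence, truth, rate) {
  if (rate <= 0 || is.null(truth) || nrow(truth) == 0L) return(sequence)
  ch <- seq_chars(sequence)
  for (i in seq_len(nrow(truth))) {
    span <- truth$start[i]:truth$end[i]
    mut <- span[stats::runif(length(span)) < rate]
    for (p in mut) ch[p] <- sample(setdiff(aa_alphabet(), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic proteome with ground truth
#'
#' @param config A [generator_config()].
#' @return List with `records` ([protein_records()] with species),
#'   `truth` (per-record table: id, species, architecture, family, subtype,
#'   completeness, pseudogene), `truth_calls` (planted elements: id, kind,
#'   start, end), `species_map`, `seeds` (the synthetic seed alignments)
#'   and `config`.
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  archs <- wasp_architectures()
  plan <- if (is.null(config$plan)) default_plan() else config$plan
  bad <- setdiff(plan$architecture, names(archs))
  if (length(bad)) stopf("plan references unknown architecture(s): %s",
                         paste(bad, collapse = ", "))

  with_seed(config$seed, {
    models <- .draw_domain_models(config)
    ids <- character(0)
    seqs <- character(0)
    species <- character(0)
    truth_rows <- list()
    call_rows <- list()
    serial <- 0L
    for (r in seq_len(nrow(plan))) {
      arch_name <- plan$architecture[r]
      arch <- archs[[arch_name]]
      for (copy in seq_len(plan$n[r])) {
        serial <- serial + 1L
        id <- sprintf("syn%04d_%s", serial, arch_name)
        p <- .emit_protein(arch_name, arch, models, config)
        sq <- .apply_motif_noise(p$sequence, p$truth, config$noise)

        completeness <- "Complete"
        u <- stats::runif(1L)
        if (u < config$p_fragment) completeness <- "Fragment"
        else if (u < config$p_fragment + config$p_partial) completeness <- "Partial"
        if (completeness != "Complete") {
          frac <- if (completeness == "Partial") stats::runif(1L, 0.01, 0.05)
            else stats::runif(1L, 0.10, 0.50)
          cut <- max(1L, floor(nchar(sq) * frac))
          from_n <- stats::runif(1L) < 0.5
          if (from_n) {
            sq <- substr(sq, cut + 1L, nchar(sq))
            p$truth$start <- p$truth$start - cut
            p$truth$end <- p$truth$end - cut
          } else {
            sq <- substr(sq, 1L, nchar(sq) - cut)
          }
          keep <- p$truth$start >= 1L & p$truth$end <= nchar(sq)
          p$truth <- p$truth[keep, , drop = FALSE]
        }

        ids <- c(ids, id)
        seqs <- c(seqs, sq)
        species <- c(species, plan$species[r])
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          id = id, species = plan$species[r], architecture = arch_name,
          family = arch$family, subtype = arch$subtype,
          completeness = completeness, pseudogene = FALSE,
          stringsAsFactors = FALSE)
        if (nrow(p$truth))
          call_rows[[length(call_rows) + 1L]] <- data.frame(
            id = id, p$truth, stringsAsFactors = FALSE)
      }
    }
    records <- protein_records(ids, seqs, species = species)
    seeds <- list()
    for (kind in names(models$seeds)) {
      seeds[[kind]] <- protein_records(
        sprintf("%s_seed_%02d", kind, seq_along(models$seeds[[kind]])),
        models$seeds[[kind]], aligned = TRUE)
    }
    list(records = records,
         truth = do.call(rbind, truth_rows),
         truth_calls = do.call(rbind, call_rows),
         species_map = data.frame(id = ids, species = species,
                                  stringsAsFactors = FALSE),
         seeds = seeds,
         config = config)
  })
}

# ---------------------------------------------------------------------------
# Taxonomy scenarios

#' Derive a per-species generation plan from planted gain/loss events
#'
#' Propagates one gain edge and any number of loss edges per family down a
#' rooted species tree to leaf inventories, yielding a generation plan (one
#' canonical protein per present family per species) plus the event truth.
#'
#' @param tree Rooted `phylo` tree (or a newick string).
#' @param gains Named character vector: family -> child-node label of the
#'   gain edge. Families default to gain at the root.
#' @param losses Data frame with `family`, `edge` (child-node label).
#' @param families Families simulated (default WASP, WAVE, WASH).
#' @return List with `plan` (species, architecture, n), `events`
#'   (family, edge, event) and the labelled `tree`.
#' @export
generate_scenario <- function(tree, gains = NULL, losses = NULL,
                              families = c("WASP", "WAVE", "WASH")) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stopf("scenario tree must be rooted")
  tree <- .label_nodes(tree)
  ntip <- length(tree$tip.label)
  root_label <- tree$node.label[1L]
  all_labels <- c(tree$tip.label, tree$node.label)

  if (is.null(gains)) gains <- stats::setNames(rep(root_label, length(families)),
                                               families)
  if (anyDuplicated(names(gains))) stopf("more than one gain for a family")
  if (is.null(losses)) losses <- data.frame(family = character(),
                                            edge = character(),
                                            stringsAsFactors = FALSE)
  bad <- setdiff(c(gains, losses$edge), all_labels)
  if (length(bad)) stopf("unknown tree edge(s): %s", paste(bad, collapse = ", "))

  node_of <- function(label) match(label, all_labels)
  ch <- .children(tree)
  tips_under <- function(v) {
    if (v <= ntip) return(v)
    unlist(lapply(ch[[v]], tips_under))
  }

  canon <- c(WASP = "WASP_canonical_2V", WAVE = "WAVE_canonical",
             WASH = "WASH_canonical", WHAMM = "WHAMM_compact",
             WAWH = "WAWH_I", WAML = "WAML_canonical")
  present <- matrix(FALSE, nrow = ntip, ncol = length(families),
                    dimnames = list(tree$tip.label, families))
  ev <- list()
  for (fam in families) {
    g <- gains[[fam]]
    under_gain <- tree$tip.label[tips_under(node_of(g))]
    lost <- unique(unlist(lapply(losses$edge[losses$family == fam], function(e)
      tree$tip.label[tips_under(node_of(e))])))
    present[, fam] <- tree$tip.label %in% setdiff(under_gain, lost)
    ev[[fam]] <- data.frame(
      family = fam, edge = c(g, losses$edge[losses$family == fam]),
      event = c("gain", rep("loss", sum(losses$family == fam))),
      stringsAsFactors = FALSE)
  }
  plan <- do.call(rbind, lapply(tree$tip.label, function(sp) {
    fams <- families[present[sp, ]]
    if (length(fams) == 0L) return(NULL)
    data.frame(species = sp, architecture = unname(canon[fams]), n = 1L,
               stringsAsFactors = FALSE)
  }))
  rownames(plan) <- NULL
  events <- do.call(rbind, ev)
  rownames(events) <- NULL
  list(plan = plan, events = events, tree = tree)
}

# ---------------------------------------------------------------------------
# Coding sequences and pseudogene injection

.human_codons <- c(
  A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC", G = "GGC",
  H = "CAC", I = "ATC", K = "AAG", L = "CTG", M = "ATG", N = "AAC",
  P = "CCC", Q = "CAG", R = "AGG", S = "AGC", T = "ACC", V = "GTG",
  W = "TGG", Y = "TAC", X = "NNN")

#' Reverse-translate a protein and optionally inject disablements
#'
#' Uses the most frequent human codon for each residue and appends a TAA
#' stop. Requested disablements are injected deterministically: an internal
#' stop replaces the middle codon, `remove_start` mutates the initial ATG,
#' `remove_stop` replaces the terminal stop, `indel` deletes one
#' nucleotide after the second codon.
#'
#' @param sequence Protein sequence (or a one-row [protein_records()]).
#' @param disablements Character vector drawn from `internal_stop`,
#'   `remove_start`, `remove_stop`, `indel` (repeats allowed for
#'   `internal_stop`).
#' @return Nucleotide string.
#' @export
generate_cds <- function(sequence, disablements = character()) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1L]
  ch <- seq_chars(sequence)
  codons <- unname(.human_codons[ch])
  if (anyNA(codons)) stopf("cannot reverse-translate residue(s): %s",
                           paste(unique(ch[is.na(codons)]), collapse = ", "))
  codons <- c(codons, "TAA")
  n_internal <- sum(disablements == "internal_stop")
  if (n_internal > 0L) {
    k <- length(codons)
    targets <- unique(pmin(pmax(2L, floor(k * seq_len(n_internal) / (n_internal + 1L))),
                           k - 1L))
    codons[targets] <- "TAA"
  }
  if ("remove_start" %in% disablements) codons[1L] <- "ATC"
  if ("remove_stop" %in% disablements) codons[length(codons)] <- "GCC"
  cds <- paste(codons, collapse = "")
  if ("indel" %in% disablements) {
    pos <- 7L
    cds <- paste0(substr(cds, 1L, pos - 1L), substr(cds, pos + 1L, nchar(cds)))
  }
  cds
}

# ---------------------------------------------------------------------------
# Synthetic supplementary alignments

#' Write synthetic stand-ins for the per-family supplementary alignments
#'
#' The curated per-family alignment archive distributed with the original
#' dataset is not bundled; this writes synthetic aligned FASTAs (clearly
#' labelled `synthetic_` in the filename) with the per-family record counts
#' taken from the printed dataset statistics, so counting-based checks can
#' run without network access.
#'
#' @param dir Output directory (created if needed).
#' @param counts Named integer vector family -> record count; defaults to
#'   the bundled Table-1 totals (see [wasp_table1()]).
#' @param seed RNG seed.
#' @param width Aligned length of the synthetic rows.
#' @return Named character vector of file paths.
#' @export
write_synthetic_supplementary <- function(dir, counts = NULL, seed = 1L,
                                          width = 120L) {
  if (is.null(counts)) {
    t1 <- wasp_table1()
    counts <- stats::setNames(t1$total, t1$family)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  with_seed(seed, {
    for (fam in names(counts)) {
      cons <- seq_chars(.sample_aa(width))
      seqs <- vapply(seq_len(counts[[fam]]), function(i) {
        ch <- cons
        mut <- stats::runif(width) < 0.1
        if (any(mut)) ch[mut] <- vapply(ch[mut], function(a)
          sample(setdiff(aa_alphabet(), a), 1L), "")
        paste(ch, collapse = "")
      }, "")
      rec <- protein_records(sprintf("%s_%04d", fam, seq_len(counts[[fam]])),
                             seqs, aligned = TRUE)
      path <- file.path(dir, sprintf("synthetic_alignment_%s.fasta", fam))
      write_fasta(rec, path)
      paths[fam] <- path
    }
  })
  paths
}
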