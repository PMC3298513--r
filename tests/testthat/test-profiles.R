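# Profile models, profile scanning and sequence-logo information content.

test_that("profile frequencies follow the pseudocount closed form", {
  m <- build_profile(rep("MLKV", 10L), "toy")
  expect_equal(m$width, 4L)
  modal <- (10 + 1 * (1 / 20)) / (10 + 1)
  expect_equal(unname(m$columns["M", 1L]), modal)
  expect_equal(unname(m$columns["L", 2L]), modal)
  expect_true(all(abs(colSums(m$columns) - 1) < 1e-9))
  expect_true(all(m$columns > 0))
})

test_that("all-gap columns are dropped; fully-gapped alignments error", {
  m <- build_profile(c("M-KV", "M-LV", "M-KV"), "gappy")
  expect_equal(m$width, 3L)
  expect_error(build_profile(c("--", "--"), "void"), "all columns dropped")
  expect_error(build_profile(c("ML", "MLK"), "ragged"), "ragged")
  expect_error(build_profile("ML", "single"), "at least 2")
})

test_that("profile building is permutation-invariant", {
  set.seed(31)
  seqs <- vapply(1:8, function(i) random_seq(25), "")
  m1 <- build_profile(seqs, "p")
  m2 <- build_profile(rev(seqs), "p")
  expect_equal(m1$columns, m2$columns)
})

test_that("scanning the consensus scores the consensus score at its offset", {
  set.seed(32)
  seqs <- vapply(1:10, function(i) random_seq(20), "")
  m <- build_profile(seqs, "p")
  cons <- profile_consensus(m)
  s <- paste0(random_seq(50), cons, random_seq(50))
  calls <- scan_profile(s, m, score_threshold = m$consensus_score - 1e-9)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 51L)
  expect_equal(calls$score, m$consensus_score, tolerance = 1e-12)
})

test_that("profile scan agrees with the all-offset oracle scorer", {
  set.seed(33)
  seqs <- vapply(1:10, function(i) random_seq(15), "")
  m <- build_profile(seqs, "p")
  for (i in 1:5) {
    s <- random_seq(300)
    want <- oracle_profile_scores(s, m)
    thr <- stats::quantile(want, 0.9)  # force some hits
    calls <- scan_profile(s, m, score_threshold = thr)
    # every reported score matches the oracle at that offset
    expect_equal(calls$score, want[calls$start], tolerance = 1e-9)
    # non-overlapping, and no above-threshold offset outside a reported
    # call's exclusion zone is missed
    if (nrow(calls) > 1L)
      expect_true(all(diff(calls$start) >= m$width))
    hits <- which(want >= thr)
    uncovered <- hits[!vapply(hits, function(h)
      any(abs(calls$start - h) < m$width), TRUE)]
    expect_length(uncovered, 0L)
  }
})

test_that("sequences with X scan neutrally and short sequences are empty", {
  m <- build_profile(rep("MLKVMLKV", 5L), "p")
  expect_equal(nrow(scan_profile("MLK", m)), 0L)
  sx <- gsub("M", "X", profile_consensus(m))
  sc <- oracle_profile_scores(sx, m)
  expect_equal(scan_profile(sx, m, score_threshold = sc[1L])$score[1L], sc[1L])
})

test_that("logo information content matches the closed forms", {
  ic <- function(seqs) compute_logo(seqs)$ic
  expect_equal(ic(rep("L", 20L)), log2(20), tolerance = 1e-9)
  expect_equal(ic(aa_alphabet()), 0, tolerance = 1e-9)
  expect_equal(ic(c(rep("L", 10L), rep("K", 10L))), log2(20) - 1,
               tolerance = 1e-9)
})

test_that("small-sample correction subtracts (19)/(2 ln2 n)", {
  seqs <- rep("L", 20L)
  corr <- compute_logo(seqs, small_sample_correction = TRUE)$ic
  expect_equal(corr, log2(20) - 19 / (2 * log(2) * 20), tolerance = 1e-9)
})

test_that("IC bounds hold on fuzzed alignments; empty alignment errors", {
  set.seed(34)
  for (i in 1:20) {
    n <- sample(1:30, 1L)
    w <- sample(1:15, 1L)
    seqs <- vapply(seq_len(n), function(j)
      random_seq(w, alphabet = c(aa_alphabet(), "-")), "")
    logo <- compute_logo(seqs)
    ok <- !is.na(logo$ic)
    expect_true(all(logo$ic[ok] >= 0 & logo$ic[ok] <= log2(20) + 1e-12))
    expect_equal(logo$n, colSums(do.call(rbind, strsplit(seqs, "")) != "-"),
                 ignore_attr = TRUE)
  }
  expect_error(compute_logo(character(0)), "empty")
})

test_that("logo and profile TSV writers produce readable tables", {
  logo <- compute_logo(c("MLKV", "MLKV", "MLRV"))
  p <- tempfile(fileext = ".tsv")
  write_logo_tsv(logo, p, small_sample_correction = FALSE)
  lines <- readLines(p)
  expect_match(lines[1L], "small_sample_correction=false")
  back <- utils::read.delim(p, comment.char = "#")
  expect_equal(nrow(back), 4L)

  m <- build_profile(c("MLKV", "MLKV"), "toy")
  write_profile_tsv(m, p)
  tab <- utils::read.delim(p, comment.char = "#")
  expect_equal(dim(tab), c(20L, 5L))
})
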