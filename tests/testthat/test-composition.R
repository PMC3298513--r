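# Composition-window detectors and the acidic C-terminus.

test_that("basic-region spec finds the trimmed K/R run", {
  calls <- scan_composition("AAKRKRKRKRKRAA", basic_region_spec())
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 3L)
  expect_equal(calls$end, 12L)
  expect_equal(calls$score, 1.0)
})

test_that("composition scan is empty on non-target and short sequences", {
  expect_equal(nrow(scan_composition("MMMMMMMM", ppr_spec())), 0L)
  expect_equal(nrow(scan_composition("KR", basic_region_spec())), 0L)
})

test_that("a planted charged block is recovered almost entirely", {
  set.seed(77)
  block <- waspfam:::.emit_composition_block(800L, c("E", "R", "K"))
  seqs <- paste0(random_seq(60, alphabet = setdiff(aa_alphabet(), c("E", "R", "K"))),
                 block,
                 random_seq(60, alphabet = setdiff(aa_alphabet(), c("E", "R", "K"))))
  calls <- scan_composition(seqs, charged_region_spec())
  expect_equal(nrow(calls), 1L)
  covered <- min(calls$end, 60 + 800) - max(calls$start, 61) + 1
  expect_gte(covered / 800, 0.95)
  expect_gte(calls$score, 0.80)
})

test_that("merged composition calls never overlap and respect the threshold", {
  set.seed(88)
  spec <- basic_region_spec()
  slack <- (spec$window - ceiling(spec$window * spec$min_fraction)) / spec$window
  for (i in 1:25) {
    s <- random_seq(400, alphabet = c(aa_alphabet(), rep(c("K", "R"), 3)))
    calls <- scan_composition(s, spec)
    if (nrow(calls) > 1L) {
      expect_true(all(calls$start[-1L] > calls$end[-nrow(calls)]))
    }
    # overall fraction of a merged run >= threshold - windowing slack
    expect_true(all(calls$score >= spec$min_fraction - slack))
  }
})

test_that("acidic terminus is detected with its aromatic class", {
  base <- strrep("G", 40)
  w <- scan_acidic_terminus(paste0(base, "DDEEDDEEW"))
  expect_equal(nrow(w$call), 1L)
  expect_equal(w$aromatic_class, "W")
  expect_equal(w$call$end, 49L)  # the trailing tryptophan is absorbed

  f <- scan_acidic_terminus(paste0(base, "DDEEDDEEF"))
  expect_equal(f$aromatic_class, "F_or_Y")

  none <- scan_acidic_terminus(paste0(base, "DDEEDDEEDD"))
  expect_equal(nrow(none$call), 1L)
  expect_equal(none$aromatic_class, "none")

  both <- scan_acidic_terminus(paste0(base, "DDEEWDDEEF"))
  expect_equal(both$aromatic_class, "W_plus_F_or_Y")
})

test_that("an acidic run far from the terminus is not an A domain", {
  s <- paste0(strrep("G", 10), "DDEEDDEE", strrep("G", 30))
  expect_equal(nrow(scan_acidic_terminus(s)$call), 0L)
})
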