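# Architecture resolution and family/subtype/completeness/pseudogene rules.

# Build a resolved architecture from an ordered kind list, with scores on
# the scales the detectors use (profiles >> patterns >> compositions).
arch_from_kinds <- function(kinds, id = "rec") {
  score_of <- function(k) switch(k,
    WH1 = , WHD = , WAHD = , WMD = , IMD = , WAID = , WAM1 = , WAM2 = ,
    WAM3 = , WAM4 = , WASHM1 = , WASHM2 = 150,
    WH2 = 10, C = 6, CRIB = 8,
    1)
  width_of <- function(k) switch(k, WH1 = , WHD = , WAHD = , IMD = 90,
                                 WMD = 60, WAID = 50, CHG = 450, 15)
  pos <- 1L
  rows <- lapply(kinds, function(k) {
    w <- width_of(k)
    r <- data.frame(id = id, kind = k, start = pos, end = pos + w - 1L,
                    score = score_of(k),
                    evidence = if (k == "WMD") "half=N;half=C" else "",
                    stringsAsFactors = FALSE)
    pos <<- pos + w + 5L
    r
  })
  resolve_architecture(id, do.call(rbind, rows))
}

test_that("overlap resolution keeps the higher-scoring call", {
  calls <- data.frame(id = "r", kind = "WH2",
                      start = c(10L, 12L), end = c(29L, 31L),
                      score = c(11, 9), evidence = "", stringsAsFactors = FALSE)
  arch <- resolve_architecture("r", calls)
  expect_equal(nrow(arch$calls), 1L)
  expect_equal(arch$calls$start, 10L)
})

test_that("resolution is greedy-score-maximal and non-overlapping", {
  set.seed(61)
  for (i in 1:30) {
    n <- sample(1:12, 1L)
    calls <- data.frame(id = "r", kind = sample(c("WH2", "C", "B"), n, TRUE),
                        start = sample(1:80, n, TRUE), score = round(runif(n), 3),
                        evidence = "", stringsAsFactors = FALSE)
    calls$end <- calls$start + sample(5:20, n, TRUE)
    arch <- resolve_architecture("r", calls)
    kept <- arch$calls
    if (nrow(kept) > 1L)
      expect_true(all(kept$start[-1L] > kept$end[-nrow(kept)]))
    # direct recomputation of the greedy rule
    ord <- order(-calls$score, calls$start, -(calls$end - calls$start + 1L))
    want <- calls[0, ]
    for (j in ord) {
      if (!any(calls$start[j] <= want$end & calls$end[j] >= want$start))
        want <- rbind(want, calls[j, ])
    }
    expect_equal(nrow(kept), nrow(want))
    expect_setequal(paste(kept$start, kept$end), paste(want$start, want$end))
  }
})

test_that("a VCA group is recognised within the span", {
  calls <- data.frame(id = "r", kind = c("WH2", "C", "A"),
                      start = c(100L, 125L, 150L), end = c(119L, 140L, 170L),
                      score = c(10, 6, 1), evidence = "",
                      stringsAsFactors = FALSE)
  expect_length(vca_groups(calls), 1L)
  # out of span: no group
  calls$start <- c(100L, 400L, 700L)
  calls$end <- c(119L, 415L, 720L)
  expect_length(vca_groups(calls, span = 200L), 0L)
})

test_that("family rules match the domain-organisation catalogue", {
  cases <- list(
    list(c("WH1", "B", "CRIB", "WAID", "PPR", "WH2", "C", "A"), "WASP", "canonical"),
    list(c("WH1", "B", "PPR", "WH2", "C", "A"), "WASP", "canonical"),
    list(c("WHD", "B", "PPR", "WH2", "C", "A"), "WAVE", "canonical"),
    list(c("WAHD", "PPR", "WH2", "C", "A", "WH2", "C", "A"), "WASH", "tandem-VCA"),
    list(c("WAHD", "PPR", "WH2", "C", "A"), "WASH", "canonical"),
    list(c("WAHD", "PPR", "C", "A"), "WASH", "no-WH2"),
    list(c("WMD", "PPR", "WH2", "C", "A"), "WHAMM", "canonical"),
    list(c("IMD", "WAID", "PPR", "WH2", "C", "A"), "WAML", "canonical"),
    list(c("IMD", "WAID"), "WAML", "WAML-short"),
    list(c("B", "CRIB", "WAID", "PPR", "WH2", "C", "A"), "WAWH", "WAWH-I"),
    list(c("WH1", "CRIB", "WAID"), "WASP", "S-WASP"),
    list(c("WH1", "B", "CRIB", "WAID", "PPR", "WH2", "C", "PPR", "WH2", "C"),
         "WASP", "tandem-PPR-VC"))
  for (cs in cases) {
    got <- classify_architecture(arch_from_kinds(cs[[1L]]))
    expect_equal(got$family, cs[[2L]], info = paste(cs[[1L]], collapse = "-"))
    expect_equal(got$subtype, cs[[3L]], info = paste(cs[[1L]], collapse = "-"))
    expect_true(nzchar(got$rationale))
  }
  empty <- classify_architecture(resolve_architecture("r", NULL))
  expect_equal(empty$family, "unclassified")
  expect_equal(empty$subtype, "none")
})

test_that("classification is a pure function of the architecture", {
  arch <- arch_from_kinds(c("WHD", "B", "PPR", "WH2", "C", "A"))
  expect_identical(classify_architecture(arch), classify_architecture(arch))
})

test_that("S-WASP and WAML-short are never assigned when C and A co-occur", {
  pool <- c("WH1", "IMD", "CRIB", "WAID", "C", "A", "WH2", "PPR", "B")
  set.seed(62)
  for (i in 1:60) {
    kinds <- sample(pool, sample(2:7, 1L))
    got <- classify_architecture(arch_from_kinds(kinds))
    if (all(c("C", "A") %in% kinds))
      expect_false(got$subtype %in% c("S-WASP", "WAML-short"),
                   info = paste(kinds, collapse = "-"))
  }
})

test_that("WAWH subtype rules use charged region, CxxC/Ser/coil, basic", {
  a3 <- arch_from_kinds(c("CRIB", "WAID", "CHG", "PPR", "WH2", "C", "A"))
  expect_equal(classify_architecture(a3)$subtype, "WAWH-III")
  a2 <- arch_from_kinds(c("SER", "CRIB", "WAID", "CC", "PPR", "WH2", "C", "A"))
  seq2 <- paste0("MCAAC", "GCDDC", strrep("G", 400))
  expect_equal(classify_architecture(a2, sequence = seq2)$subtype, "WAWH-II")
  # without the CxxC pair the type-II rule does not fire
  expect_equal(classify_architecture(a2, sequence = strrep("G", 400))$subtype,
               "WAWH-I")
})

test_that("completeness follows the 5 % missing rule", {
  expect_equal(assess_completeness(500, 500), "Complete")
  expect_equal(assess_completeness(480, 500), "Partial")   # 4 % missing
  expect_equal(assess_completeness(350, 500), "Fragment")  # 30 % missing
  expect_equal(assess_completeness(497, 500), "Complete")  # within tolerance
  expect_warning(got <- assess_completeness(500, NA), "expected length")
  expect_equal(got, "Complete")
})

test_that("pseudogene disablements are counted as specified", {
  clean <- flag_pseudogene("ATGAAATAA")
  expect_equal(clean$n_disablements, 0L)
  expect_false(clean$pseudogene)

  one <- flag_pseudogene("ATGTAAAAATAA")
  expect_gte(one$n_disablements, 1L)
  expect_false(one$pseudogene)   # below the default threshold of 2

  four <- flag_pseudogene("AAATAAAAAA")
  expect_equal(four$n_disablements, 4L)
  expect_true(four$pseudogene)

  expect_error(flag_pseudogene(""), "empty")
  expect_error(flag_pseudogene("ATGU"), "A, C, G, T, N")
})
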