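# Synthetic-proteome generator: determinism, planted-truth recovery,
# taxonomy scenarios and CDS disablement injection.

test_that("the generator is deterministic given the seed", {
  s1 <- tiny_sim(13, c("WASP_canonical_2V", "WAWH_II"), n_each = 2L)
  s2 <- tiny_sim(13, c("WASP_canonical_2V", "WAWH_II"), n_each = 2L)
  expect_identical(s1$records$sequence, s2$records$sequence)
  expect_identical(s1$truth_calls, s2$truth_calls)
  s3 <- tiny_sim(14, c("WASP_canonical_2V", "WAWH_II"), n_each = 2L)
  expect_false(identical(s1$records$sequence, s3$records$sequence))
})

test_that("planted truth coordinates are valid and the seed is mandatory", {
  sim <- tiny_sim(15, c("WHAMM_insertion", "WASH_tandem_vca"))
  len <- nchar(sim$records$sequence[match(sim$truth_calls$id, sim$records$id)])
  expect_true(all(sim$truth_calls$start >= 1L))
  expect_true(all(sim$truth_calls$end <= len))
  expect_error(generator_config(), "seed")
  expect_error(generate_proteome(
    generator_config(1, plan = data.frame(species = "s", architecture = "nope",
                                          n = 1L))), "unknown architecture")
})

test_that("planted motif instances satisfy their patterns", {
  sim <- tiny_sim(16, c("WASP_canonical_2V", "WAWH_I"), n_each = 2L)
  for (i in which(sim$truth_calls$kind %in% c("WH2", "CRIB"))) {
    t <- sim$truth_calls[i, ]
    s <- substr(sim$records$sequence[match(t$id, sim$records$id)], t$start, t$end)
    p <- if (t$kind == "WH2") wh2_pattern() else crib_pattern()
    hits <- scan_pattern(s, p)
    expect_true(any(hits$start == 1L & hits$end == nchar(s)))
  }
})

test_that("at noise 0 every planted element is recovered within 2 residues", {
  sim <- tiny_sim(17, names(wasp_architectures()))
  profiles <- build_profiles(sim$seeds)
  calls <- scan_proteome(sim$records, profiles)
  err <- boundary_errors(sim$truth_calls, calls)
  expect_true(all(err <= 2))
})

test_that("the planted charged block satisfies its own specification", {
  sim <- tiny_sim(18, "WAWH_III")
  chg <- sim$truth_calls[sim$truth_calls$kind == "CHG", ]
  expect_gte(chg$end - chg$start + 1L, 400L)
  s <- substr(sim$records$sequence[match(chg$id, sim$records$id)],
              chg$start, chg$end)
  frac <- mean(strsplit(s, "")[[1L]] %in% c("E", "R", "K"))
  expect_gte(frac, 0.80)
})

test_that("scenario events propagate to leaf inventories", {
  tree <- ape::read.tree(text = "((human,fly)meta,(yeast1,yeast2)fungi)root;")
  sc <- generate_scenario(tree,
                          losses = data.frame(family = "WASH", edge = "fungi",
                                              stringsAsFactors = FALSE))
  plan <- sc$plan
  expect_false(any(plan$species %in% c("yeast1", "yeast2") &
                     plan$architecture == "WASH_canonical"))
  expect_true(any(plan$species == "human" & plan$architecture == "WASH_canonical"))
  # no events: all species get all families
  sc0 <- generate_scenario(tree)
  expect_equal(nrow(sc0$plan), 4L * 3L)
  expect_error(generate_scenario(tree, gains = c(WASP = "root", WASP = "meta")),
               "more than one gain")
})

test_that("the full loop recovers planted gain/loss events exactly", {
  tree <- ape::read.tree(text = "((human,fly)meta,((yeast1,yeast2)fungi,amoeba)opi)root;")
  losses <- data.frame(family = c("WASH", "WAVE"), edge = c("fungi", "fly"),
                       stringsAsFactors = FALSE)
  sc <- generate_scenario(tree, losses = losses)
  plan <- sc$plan
  plan$n <- 1L
  sim <- generate_proteome(generator_config(seed = 19, plan = plan))
  profiles <- build_profiles(sim$seeds)
  cls <- classify_proteome(sim$records, profiles, species_map = sim$species_map)
  mat <- build_presence_matrix(cls)
  rec <- dollo_reconstruct(sc$tree, mat)
  got <- rec$events[order(rec$events$family, rec$events$event, rec$events$edge), ]
  want <- sc$events[order(sc$events$family, sc$events$event, sc$events$edge), ]
  expect_equal(got$family, want$family)
  expect_equal(got$event, want$event)
  expect_equal(got$edge, want$edge)
})

test_that("clean CDS reverse-translation has zero disablements", {
  sim <- tiny_sim(20, "WASP_yeast")
  cds <- generate_cds(sim$records$sequence[1L])
  expect_equal(flag_pseudogene(cds)$n_disablements, 0L)
})

test_that("injected disablements are counted and flagged", {
  seqs <- "MLKVAAPG"
  two <- generate_cds(seqs, c("internal_stop", "internal_stop"))
  res <- flag_pseudogene(two)
  expect_gte(res$n_disablements, 2L)
  expect_true(res$pseudogene)

  indel <- generate_cds(seqs, "indel")
  expect_true("length_not_multiple_of_3" %in% flag_pseudogene(indel)$disablements)

  no_start <- generate_cds(seqs, "remove_start")
  expect_true("missing_start_ATG" %in% flag_pseudogene(no_start)$disablements)
})

test_that("truncation produces Partials and Fragments with adjusted truth", {
  cfg <- generator_config(seed = 23,
                          plan = data.frame(species = "s",
                                            architecture = "WASP_canonical_2V",
                                            n = 30L),
                          p_partial = 0.3, p_fragment = 0.3)
  sim <- generate_proteome(cfg)
  expect_setequal(unique(sim$truth$completeness),
                  c("Complete", "Partial", "Fragment"))
  len <- nchar(sim$records$sequence[match(sim$truth_calls$id, sim$records$id)])
  expect_true(all(sim$truth_calls$end <= len))
  expect_true(all(sim$truth_calls$start >= 1L))
})

test_that("synthetic supplementary alignments carry the printed counts", {
  dir <- tempfile()
  paths <- write_synthetic_supplementary(dir, counts = c(WASP = 7L, WAML = 3L),
                                         seed = 3L)
  expect_equal(nrow(read_fasta(paths[["WASP"]], aligned = TRUE)), 7L)
  expect_equal(nrow(read_fasta(paths[["WAML"]], aligned = TRUE)), 3L)
  expect_match(basename(paths[["WASP"]]), "^synthetic_")
})
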