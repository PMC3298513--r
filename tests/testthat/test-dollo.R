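# Presence matrices and Dollo gain/loss reconstruction.

test_that("presence matrix counts per species and family", {
  asg <- data.frame(
    id = c("a", "b", "c", "d"),
    species = c("X", "X", "X", "Y"),
    family = c("WASP", "WASP", "WAVE", "WASH"),
    pseudogene = c(FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  m <- build_presence_matrix(asg)
  expect_equal(unname(m["X", c("WASP", "WAVE", "WASH")]), c(2L, 1L, 0L))
  expect_equal(unname(m["Y", "WASH"]), 1L)
  # permuting the rows leaves the matrix unchanged
  expect_identical(m, build_presence_matrix(asg[sample(4), ]))
})

test_that("pseudogenes are excluded from presence by default", {
  asg <- data.frame(id = "a", species = "X", family = "WAVE",
                    pseudogene = TRUE, stringsAsFactors = FALSE)
  expect_equal(unname(build_presence_matrix(asg)["X", "WAVE"]), 0L)
  expect_equal(unname(build_presence_matrix(asg, include_pseudogenes = TRUE)["X", "WAVE"]),
               1L)
})

test_that("unclassified records and unknown species are handled", {
  asg <- data.frame(id = c("a", "b"), species = c("X", NA),
                    family = c("unclassified", "WASP"),
                    pseudogene = FALSE, stringsAsFactors = FALSE)
  expect_error(build_presence_matrix(asg), "species missing.*b")
  asg$species <- c("X", "Y")
  m <- build_presence_matrix(asg)
  expect_equal(sum(m), 1L)  # the unclassified record is not counted
})

test_that("gain above the MRCA, one loss on the absent tip", {
  tree <- ape::read.tree(text = "((A,B),C);")
  m <- matrix(c(1L, 0L, 1L), ncol = 1L, dimnames = list(c("A", "B", "C"), "WASP"))
  rec <- dollo_reconstruct(tree, m)
  ev <- rec$events
  expect_equal(ev$event, c("gain", "loss"))
  expect_equal(ev$edge[2L], "B")
  # gain on the root edge (MRCA of A and C is the root)
  root_label <- rec$tree$node.label[1L]
  expect_equal(ev$edge[1L], root_label)
  # implied leaf states reproduce the matrix
  expect_equal(unname(rec$states[c("A", "B", "C"), "WASP"]), c(TRUE, FALSE, TRUE))
})

test_that("all-present family gains at the root with zero losses", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  m <- matrix(1L, nrow = 4L, ncol = 1L,
              dimnames = list(c("A", "B", "C", "D"), "WASH"))
  ev <- dollo_reconstruct(tree, m)$events
  expect_equal(ev$event, "gain")
})

test_that("a family absent everywhere yields no events", {
  tree <- ape::read.tree(text = "((A,B),C);")
  m <- matrix(0L, nrow = 3L, ncol = 1L, dimnames = list(c("A", "B", "C"), "WAML"))
  rec <- dollo_reconstruct(tree, m)
  expect_equal(nrow(rec$events), 0L)
  expect_equal(rec$absent_families, "WAML")
})

test_that("reconstruction equals the brute-force minimal labelling", {
  set.seed(71)
  for (i in 1:60) {
    ntip <- sample(3:8, 1L)
    tree <- ape::rtree(ntip, tip.label = paste0("t", seq_len(ntip)))
    pres <- stats::setNames(sample(c(TRUE, FALSE), ntip, replace = TRUE),
                            tree$tip.label)
    if (!any(pres)) pres[1L] <- TRUE
    m <- matrix(as.integer(pres), ncol = 1L,
                dimnames = list(tree$tip.label, "WASP"))
    rec <- dollo_reconstruct(tree, m)
    want <- oracle_dollo(tree, pres)
    got_gain <- rec$events$edge[rec$events$event == "gain"]
    got_losses <- sort(rec$events$edge[rec$events$event == "loss"])
    expect_equal(length(got_losses), length(want$losses))
    expect_equal(got_losses, want$losses)
    expect_equal(got_gain, want$gain)
    # leaf states always reproduce the matrix
    expect_equal(unname(rec$states[tree$tip.label, "WASP"]), unname(pres))
  }
})

test_that("species absent from the matrix are no-data, not losses", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  m <- matrix(c(1L, 1L, 1L), ncol = 1L,
              dimnames = list(c("A", "B", "C"), "WASP"))  # D unsequenced
  ev <- dollo_reconstruct(tree, m)$events
  expect_equal(ev$event, "gain")  # no loss inferred for D
})

test_that("adding a presence-only species never decreases inferred events", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  m1 <- matrix(c(1L, 0L, 1L), ncol = 1L,
               dimnames = list(c("A", "B", "C"), "WASP"))
  m2 <- rbind(m1, D = 1L)
  n1 <- nrow(dollo_reconstruct(tree, m1)$events)
  n2 <- nrow(dollo_reconstruct(tree, m2)$events)
  expect_gte(n2, n1)
})

test_that("unrooted trees are rooted with a warning", {
  tree <- ape::unroot(ape::read.tree(text = "((A,B),(C,D));"))
  m <- matrix(1L, nrow = 4L, ncol = 1L,
              dimnames = list(c("A", "B", "C", "D"), "WASP"))
  expect_warning(dollo_reconstruct(tree, m, outgroup = "A"), "rooted at outgroup")
})

test_that("inventory summary collapses uniform clades", {
  tree <- ape::read.tree(text = "((A,B),C);")
  m <- matrix(c(1L, 1L, 0L, 1L, 1L, 1L), nrow = 3L,
              dimnames = list(c("A", "B", "C"), c("WASP", "WAVE")))
  inv <- summarize_inventory(m, tree)$inventory
  # A and B share (1,1) and collapse into one clade row; C stands alone
  expect_equal(nrow(inv), 2L)
  expect_equal(sort(inv$n_species), c(1L, 2L))
  # single-species tree: one row equal to the matrix row
  t1 <- ape::read.tree(text = "(A);")
  inv1 <- summarize_inventory(m["A", , drop = FALSE], t1)$inventory
  expect_equal(inv1$n_species, 1L)
  expect_equal(inv1$WASP, 1L)
})
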