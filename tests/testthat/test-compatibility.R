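test_that("column encoding applies the gap-mode rules", {
  aln <- aln_from_strings(c("AA", "A-", "--", "CC"))
  g <- classify_gaps(aln)
  # column 2: internal gap for t2 (flanked by A... actually end) -- build a
  # clearer case: gap flanked by nucleotides
  aln2 <- aln_from_strings(c("AAA", "A-A", "---", "CCC"))
  g2 <- classify_gaps(aln2)
  enc <- encode_column(aln2, g2, 2, fifth_state = TRUE)
  expect_identical(unname(enc[1:4]), c("A", "GAP", NA, "C"))
  enc0 <- encode_column(aln2, g2, 2, fifth_state = FALSE)
  expect_identical(unname(enc0[1:4]), c("A", NA, NA, "C"))
  # terminal gaps are missing regardless of gap mode
  expect_true(is.na(encode_column(aln, g, 1, TRUE)[3]))
  # invariant column
  expect_identical(unname(encode_column(aln2, g2, 3, TRUE)[c(1, 2, 4)]),
                   c("A", "A", "C"))
  expect_error(encode_column(aln2, g2, 4), "out of range")
})

test_that("state-pair graphs collect distinct doubly-observed combinations", {
  gr <- build_state_pair_graph(c("T", "T", "A", "A"), c("A", "T", "A", "T"))
  expect_identical(nrow(gr$edges), 4L)
  expect_setequal(gr$left, c("T", "A"))
  expect_setequal(gr$right, c("A", "T"))

  gr2 <- build_state_pair_graph(c("A", NA), c("C", "G"))
  expect_identical(unname(gr2$edges[1, ]), c("A", "C"))
  expect_identical(nrow(gr2$edges), 1L)

  gr3 <- build_state_pair_graph(c("A", "C", "G"), c("T", "T", "T"))
  expect_identical(nrow(gr3$edges), 3L)
  expect_identical(unname(gr3$right), "T")

  expect_error(build_state_pair_graph(c("A", "C"), c("A", "C", "G")), "taxon counts")
})

test_that("the cycle test reproduces the four-gamete rule and known cases", {
  # all four combinations present: incompatible
  expect_true(are_incompatible(c("T", "T", "A", "A"), c("A", "T", "A", "T")))
  # any column against an invariant column: star graph, compatible
  expect_false(are_incompatible(c("A", "C", "G", "T"), rep("A", 4)))
  # a column against itself: perfect matching, compatible
  col <- c("A", "C", "G", "T", "GAP")
  expect_false(are_incompatible(col, col))
  # path graph (edges T-C, A-G, A-C): compatible, confirmed by the oracle
  ci <- c(rep("T", 4), rep("A", 4))
  cj <- c(rep("C", 4), rep("G", 3), "C")
  expect_false(are_incompatible(ci, cj))
  expect_true(brute_force_compatible(ci, cj))
})

test_that("the cycle test is symmetric and trivial columns never conflict", {
  set.seed(11)
  for (k in 1:200) {
    n <- sample(4:8, 1)
    ci <- rand_col(n); cj <- rand_col(n)
    expect_identical(are_incompatible(ci, cj), are_incompatible(cj, ci))
  }
  # fewer than 2 distinct non-missing states: compatible with anything
  for (k in 1:50) {
    n <- sample(4:8, 1)
    const <- rep(sample(c("A", "C", "G", "T", "GAP"), 1), n)
    const[seq_len(sample(0:(n - 2), 1))] <- NA
    expect_false(are_incompatible(const, rand_col(n)))
  }
})

test_that("removing taxa never creates incompatibility", {
  set.seed(13)
  for (k in 1:500) {
    n <- sample(5:10, 1)
    ci <- rand_col(n); cj <- rand_col(n)
    if (!are_incompatible(ci, cj)) {
      keep <- sample(n, sample(2:(n - 1), 1))
      expect_false(are_incompatible(ci[keep], cj[keep]))
    }
  }
})

test_that("the verdict is invariant to relabelling state identities", {
  set.seed(17)
  states <- c("A", "C", "G", "T", "GAP")
  for (k in 1:200) {
    n <- sample(4:8, 1)
    ci <- rand_col(n); cj <- rand_col(n)
    perm <- setNames(sample(states), states)
    expect_identical(are_incompatible(ci, cj),
                     are_incompatible(unname(perm[ci]), unname(perm[cj])))
  }
})

test_that("the brute-force oracle handles the canonical cases", {
  # invariant columns need no changes on any tree
  expect_true(brute_force_compatible(rep("A", 6), rand_col(6)))
  # four-gamete case fails on all 3 unrooted 4-taxon topologies
  expect_false(brute_force_compatible(c("T", "T", "A", "A"), c("A", "T", "A", "T")))
  # three or fewer doubly-observed taxa are always compatible
  expect_true(brute_force_compatible(c("A", "C", "G", NA, NA),
                                     c("T", "G", "A", "C", "C")))
  expect_error(brute_force_compatible(rand_col(9, 0), rand_col(9, 0)), "limited to 8")
})

test_that("oracle and cycle test agree on random column pairs", {
  set.seed(19)
  for (k in 1:2000) {
    n <- sample(4:6, 1)
    ci <- rand_col(n); cj <- rand_col(n)
    expect_identical(!are_incompatible(ci, cj), brute_force_compatible(ci, cj))
  }
})

test_that("the oracle's Fitch lengths match an independent parsimony program", {
  set.seed(23)
  lv <- c("A", "C", "G", "T", "GAP")
  for (k in 1:25) {
    n <- sample(4:6, 1)
    col <- rand_col(n, p_missing = 0)
    trees <- phangorn::allTrees(n, rooted = FALSE)
    dat <- phangorn::phyDat(matrix(col, ncol = 1,
                                   dimnames = list(trees[[1]]$tip.label, NULL)),
                            type = "USER", levels = lv)
    for (i in sample(seq_along(trees), min(5, length(trees)))) {
      edges <- ape::reorder.phylo(trees[[i]], "postorder")$edge
      mine <- phyin:::.fitch_length(match(col, lv), edges, n)
      expect_identical(mine, as.integer(phangorn::parsimony(trees[[i]], dat)))
    }
  }
})
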