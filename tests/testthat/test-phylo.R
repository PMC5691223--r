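aln <- function(...) {
  seqs <- c(...)
  tibble::tibble(id = paste0("t", seq_along(seqs)), sequence = seqs)
}

test_that("p-distance counts mismatches over compared columns", {
  d <- p_distance(aln("AAAA", "AAAT"))
  expect_equal(d["t1", "t2"], 0.25)
  expect_equal(diag(d), c(t1 = 0, t2 = 0))

  expect_equal(p_distance(aln("AAAA", "AAAA"))["t1", "t2"], 0)

  # pairwise deletion: the gapped column is dropped for that pair only
  d2 <- p_distance(aln("A-AA", "AAAA"))
  expect_equal(d2["t1", "t2"], 0)
  # complete deletion drops the column for everyone
  d3 <- p_distance(
    aln("A-AT", "AAAA", "AAAA"), "complete_deletion"
  )
  expect_equal(d3["t1", "t2"], 1 / 3)

  expect_error(
    p_distance(aln("A---", "-AAA", "AAAA")), "comparable.*t1.*t2"
  )
})

test_that("three taxa resolve by the closed-form three-point formulas", {
  dm <- matrix(
    c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0),
    3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c"))
  )
  tr <- nj_tree(dm)
  # b_a = (d_ab + d_ac - d_bc)/2 etc.
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["a"]], 0.1)
  expect_equal(lens[["b"]], 0.2)
  expect_equal(lens[["c"]], 0.4)
  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")
  asym <- dm
  asym[1, 2] <- 0.9
  expect_error(nj_tree(asym), "symmetric")
})

test_that("NJ recovers additive trees exactly", {
  set.seed(404)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    case <- random_additive_case(n)
    est <- nj_tree(case$dm)
    expect_setequal(
      tree_bipartitions(est)$split, tree_bipartitions(case$tree)$split
    )
    d_est <- ape::cophenetic.phylo(est)[
      rownames(case$dm), colnames(case$dm)
    ]
    expect_lt(max(abs(d_est - case$dm)), 1e-6)
  }
})

test_that("4-taxon NJ agrees with the exhaustive least-squares oracle", {
  set.seed(405)
  for (rep in 1:25) {
    case <- random_additive_case(4)
    est <- nj_tree(case$dm)
    expect_equal(tree_bipartitions(est)$split, ls_best_quartet(case$dm))
  }
})

test_that("equidistant taxa resolve deterministically by the tie rule", {
  labs <- c("a", "b", "c", "d")
  dm <- matrix(1, 4, 4, dimnames = list(labs, labs))
  diag(dm) <- 0
  t1 <- nj_tree(dm)
  t2 <- nj_tree(dm)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  # lowest-index pair joined first
  expect_true(is_monophyletic(t1, c("a", "b")))
})

test_that("bootstrap gives full support to a clean split, reproducibly", {
  block <- tibble::tibble(
    id = c("a1", "a2", "b1", "b2"),
    sequence = c(strrep("A", 40), strrep("A", 40),
      strrep("W", 40), strrep("W", 40))
  )
  bt <- bootstrap_support(block, n_reps = 100, seed = 11)
  sup <- suppressWarnings(as.integer(bt$node.label))
  expect_true(100 %in% sup)

  bt2 <- bootstrap_support(block, n_reps = 100, seed = 11)
  expect_equal(bt$node.label, bt2$node.label)

  # supports are invariant to taxon order
  bt3 <- bootstrap_support(block[c(3, 1, 4, 2), ], n_reps = 100, seed = 11)
  support_by_split <- function(tree) {
    bip <- tree_bipartitions(tree)
    setNames(
      tree$node.label[bip$node - length(tree$tip.label)], bip$split
    )
  }
  expect_mapequal(support_by_split(bt), support_by_split(bt3))

  # a single replicate can only give 0 or 100
  b1 <- bootstrap_support(block, n_reps = 1, seed = 2)
  sup1 <- suppressWarnings(as.integer(b1$node.label))
  expect_true(all(sup1[!is.na(sup1)] %in% c(0L, 100L)))
})

test_that("monophyly is an exact bipartition query", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,e:1);")
  expect_true(is_monophyletic(tr, c("a", "b")))
  expect_true(is_monophyletic(tr, c("c", "d")))
  expect_false(is_monophyletic(tr, c("a", "c")))
  expect_true(is_monophyletic(tr, "a"))
  expect_true(is_monophyletic(tr, c("a", "b", "c", "d", "e")))
  expect_error(is_monophyletic(tr, "zz"), "not in tree")
})
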