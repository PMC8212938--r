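test_that("alignment distances: p-distance, Poisson and pairwise deletion", {
  m <- rbind(a = strsplit("AAAA", "")[[1]], b = strsplit("AAAT", "")[[1]])
  d <- distance_from_alignment(m)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "a"], 0)

  ident <- rbind(a = strsplit("WRKY", "")[[1]], b = strsplit("WRKY", "")[[1]])
  expect_equal(distance_from_alignment(ident)["a", "b"], 0)
  expect_equal(distance_from_alignment(ident, "poisson")["a", "b"], 0)

  # gapped columns are dropped per pair
  g <- rbind(a = strsplit("A-CD", "")[[1]], b = strsplit("AEC-", "")[[1]])
  expect_equal(distance_from_alignment(g)["a", "b"], 0)  # only cols 1,3 compare

  # poisson correction
  p <- distance_from_alignment(m, "poisson")
  expect_equal(p["a", "b"], -log(1 - 0.25))

  # zero comparable columns names the pair
  z <- rbind(x = strsplit("A--", "")[[1]], y = strsplit("-AA", "")[[1]],
             w = strsplit("AAA", "")[[1]])
  expect_error(distance_from_alignment(z), "'x' and 'y'")
})

test_that("three-taxon neighbor joining matches the closed-form solution", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  expect_equal(length(tr$tip.label), 3)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], 0.5)
  expect_equal(bl[["b"]], 1.5)
  expect_equal(bl[["c"]], 2.5)
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("NJ is exact on additive matrices and rejects malformed input", {
  set.seed(31)
  for (k in 1:10) {
    gen <- random_additive(sample(4:8, 1))
    tr <- neighbor_joining(gen$d)
    got <- ape::cophenetic.phylo(tr)[rownames(gen$d), colnames(gen$d)]
    expect_equal(got, gen$d, tolerance = 1e-9)
    # independent implementation recovers the same tree
    ref <- ape::nj(gen$d)
    expect_equal(ape::dist.topo(ape::unroot(ref), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
  }
  bad <- matrix(c(0, 1, 2, 9, 0, 3, 2, 3, 0), 3, 3)
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("each NJ join attains the exhaustive Q-criterion minimum", {
  set.seed(32)
  for (k in 1:10) {
    gen <- random_additive(sample(5:8, 1))
    tr <- neighbor_joining(gen$d, trace = TRUE)
    steps <- attr(tr, "join_trace")
    for (s in steps) {
      if (nrow(s$d) <= 3) next
      orc <- oracle_q(s$d)
      tol <- 1e-9 * max(1, abs(orc$min))
      expect_lte(orc$q(s$pair[1], s$pair[2]), orc$min + tol)
    }
  }
})

test_that("exact Q ties break to the smallest index pair", {
  # all distances equal: every Q is identical in exact arithmetic
  d <- matrix(2, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(d) <- 0
  tr <- neighbor_joining(d, trace = TRUE)
  steps <- attr(tr, "join_trace")
  expect_equal(unname(steps[[1]]$pair), c(1L, 2L))
  expect_equal(unname(steps[[2]]$pair), c(1L, 2L))
})

test_that("bipartition extraction finds the expected splits", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,e:1);")
  bp <- tree_bipartitions(tr)
  expect_setequal(unname(bp), c("c|d|e", "c|d"))
})

test_that("bootstrap supports: clean separation, single replicate, determinism", {
  seqs <- two_clade_sequences(seed = 41)
  for (seed in c(1, 2, 99)) {
    tr <- bootstrap_support(seqs, n_reps = 100, seed = seed)
    expect_equal(split_support(tr, c("a1", "a2", "a3")), 100L)
  }
  one <- bootstrap_support(seqs, n_reps = 1, seed = 5)
  sup <- suppressWarnings(as.integer(one$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0L, 100L)))

  t1 <- bootstrap_support(seqs, n_reps = 25, seed = 7)
  t2 <- bootstrap_support(seqs, n_reps = 25, seed = 7)
  expect_identical(t1$node.label, t2$node.label)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})
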