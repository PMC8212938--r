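records_for <- function(ids) {
  r <- parse_protein_id(ids)
  r$sequence <- "A"
  r$start <- seq_along(ids) * 100L
  r$end <- r$start + 10L
  r
}

test_that("clade-based grouping: triads, singletons, duplicate subgenomes", {
  # a tight triad clade plus two distant singletons
  tr <- ape::read.tree(text = paste0(
    "((g1_c4A:0.05,(g1_c4B:0.05,g1_c4D:0.05):0.02):0.5,",
    "g2_c1D:0.6,g3_c1A:0.7);"))
  rec <- records_for(c("g1_c4A.1", "g1_c4B.1", "g1_c4D.1", "g2_c1D.1", "g3_c1A.1"))
  rec$gene_id <- sub("\\.1$", "", rec$record_id)
  g <- infer_groups(tr, rec)
  expect_equal(nrow(g$groups), 3)
  expect_setequal(g$groups$homeolog_type, c("A:B:D", "D", "A"))
  triad <- g$groups[g$groups$homeolog_type == "A:B:D", ]
  expect_equal(triad$complement, 4L)
  expect_equal(triad$n_members, 3L)
  # partition: every copy in exactly one group
  expect_equal(sort(g$copies$gene_id), sort(rec$gene_id))
  expect_false(anyNA(g$copies$group_id))

  # two same-subgenome copies in a tight clade must not merge
  tr2 <- ape::read.tree(text = "((g1_c4A:0.05,g2_c4A:0.05):0.5,g3_c1B:0.6,g4_c2D:0.7);")
  rec2 <- records_for(c("g1_c4A.1", "g2_c4A.1", "g3_c1B.1", "g4_c2D.1"))
  rec2$gene_id <- sub("\\.1$", "", rec2$record_id)
  g2 <- infer_groups(tr2, rec2)
  expect_equal(nrow(g2$groups), 4)

  # cross-complement tight clade must also split
  tr3 <- ape::read.tree(text = "((g1_c4A:0.05,g2_c5B:0.05):0.5,g3_c1B:0.6,g4_c2D:0.7);")
  rec3 <- records_for(c("g1_c4A.1", "g2_c5B.1", "g3_c1B.1", "g4_c2D.1"))
  rec3$gene_id <- sub("\\.1$", "", rec3$record_id)
  expect_equal(nrow(infer_groups(tr3, rec3)$groups), 4)

  # a leaf without a placed complement becomes a singleton with NA type info
  tr4 <- ape::read.tree(text = "((g1_c4A:0.05,scaffoldgene:0.05):0.5,g3_c1B:0.6,g4_c2D:0.7);")
  rec4 <- records_for(c("g1_c4A.1", "scaffoldgene.1", "g3_c1B.1", "g4_c2D.1"))
  rec4$gene_id <- sub("\\.1$", "", rec4$record_id)
  g4 <- infer_groups(tr4, rec4)
  expect_equal(nrow(g4$groups), 4)
  lone <- g4$copies[g4$copies$gene_id == "scaffoldgene", ]
  expect_equal(g4$groups$n_members[g4$groups$group_id == lone$group_id], 1L)
})

test_that("compactness guard: distant same-complement singletons stay apart", {
  txt <- "((g1_c4A:0.45,g2_c4D:0.45):0.2,g3_c1B:0.6,g4_c2D:0.7);"
  tr <- ape::read.tree(text = txt)
  rec <- records_for(c("g1_c4A.1", "g2_c4D.1", "g3_c1B.1", "g4_c2D.1"))
  rec$gene_id <- sub("\\.1$", "", rec$record_id)
  expect_equal(nrow(infer_groups(tr, rec)$groups), 4)          # 0.9 apart: split
  expect_equal(nrow(infer_groups(tr, rec, Inf)$groups), 3)     # guard off: merged
})

test_that("homeolog typing and percentage arithmetic", {
  g <- homeolog_groups(table1_copies())
  tg <- type_groups(g)
  expect_equal(tg$copies, c(225L, 2L, 24L, 14L, 10L, 4L, 15L))
  expect_equal(tg$genes, c(75L, 1L, 12L, 7L, 10L, 4L, 15L))
  expect_equal(attr(tg, "total_copies"), 294L)
  expect_equal(attr(tg, "total_genes"), 124L)
  expect_equal(tg$pct_genes[tg$homeolog_type == "A:B:D"], 60.48)

  empty <- homeolog_groups(table1_copies()[0, ])
  tg0 <- type_groups(empty)
  expect_true(all(tg0$copies == 0) && all(tg0$genes == 0) && all(tg0$pct_genes == 0))
})

test_that("naming follows complement order and the reference-subgenome rule", {
  # one triad on complement 1
  cp <- data.frame(gene_id = c("x_c1A", "x_c1B", "x_c1D"),
                   subgenome = c("A", "B", "D"), complement = 1L,
                   start = c(100L, 90L, 120L), group_id = "G1",
                   stringsAsFactors = FALSE)
  nm <- assign_names(homeolog_groups(cp), prefix = "TaWRKY")
  expect_equal(sort(nm$copies$name), c("TaWRKY1-A", "TaWRKY1-B", "TaWRKY1-D"))

  # two complement-1 triads, reference subgenome A, ordered by A-copy start
  cp2 <- do.call(rbind, lapply(1:2, function(i) {
    data.frame(gene_id = paste0("g", i, "_c1", c("A", "B", "D")),
               subgenome = c("A", "B", "D"), complement = 1L,
               start = c(c(500L, 100L)[i], 10L, 10L),
               group_id = paste0("G", i), stringsAsFactors = FALSE)
  }))
  nm2 <- assign_names(homeolog_groups(cp2))
  g2 <- nm2$groups
  expect_equal(g2$serial[g2$group_id == "G1"], 2L)
  expect_equal(g2$serial[g2$group_id == "G2"], 1L)

  # reference subgenome = most copies in the complement (here A: 4 copies);
  # groups lacking an A copy are ordered after, then complement 2 follows
  cp3 <- rbind(cp2,
               data.frame(gene_id = c("g3_c1B", "g3_c1D"),
                          subgenome = c("B", "D"), complement = 1L,
                          start = c(1L, 1L), group_id = "G3",
                          stringsAsFactors = FALSE),
               data.frame(gene_id = c("g4_c1A", "g5_c2A"),
                          subgenome = "A", complement = c(1L, 2L),
                          start = c(50L, 1L), group_id = c("G4", "G5"),
                          stringsAsFactors = FALSE))
  nm3 <- assign_names(homeolog_groups(cp3))
  g3 <- setNames(nm3$groups$serial, nm3$groups$group_id)
  expect_equal(unname(g3[c("G4", "G2", "G1")]), c(1L, 2L, 3L))  # by A-copy start
  expect_equal(unname(g3[["G3"]]), 4L)  # no A copy: last within complement 1
  expect_equal(unname(g3[["G5"]]), 5L)  # complement 2 after all of complement 1
})

test_that("naming is a bijection, stable under row permutation", {
  cp <- table1_copies()
  g <- assign_names(homeolog_groups(cp))
  expect_setequal(g$groups$serial, seq_len(nrow(g$groups)))

  set.seed(51)
  cp_shuffled <- cp[sample.int(nrow(cp)), ]
  g2 <- assign_names(homeolog_groups(cp_shuffled))
  n1 <- setNames(g$copies$name, g$copies$gene_id)
  n2 <- setNames(g2$copies$name, g2$copies$gene_id)
  expect_equal(n2[names(n1)], n1)
})

test_that("summary statistics reproduce the subgenome and complement closed forms", {
  st <- summary_stats(homeolog_groups(table1_copies()),
                      comparators = c(rice = 103, maize = 119))
  # A = 75+1+12+10, B = 75+1+7+4, D = 75+12+7+15
  expect_equal(st$subgenome$copies, c(98L, 87L, 109L))
  expect_equal(st$subgenome$pct_copies, c(33.33, 29.59, 37.07))
  expect_equal(st$complements$genes, c(24L, 19L, 19L, 19L, 19L, 5L, 19L))
  expect_equal(unname(st$fold_vs_comparators), c(2.85, 2.47))
  expect_equal(st$totals$copies, 294L)
  # linear identities
  expect_equal(sum(st$types$copies), st$totals$copies)
  expect_equal(sum(st$types$genes), st$totals$genes)
  expect_equal(sum(st$subgenome$copies), st$totals$copies)
})
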