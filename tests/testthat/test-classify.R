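hit_row <- function(start, zf) {
  data.frame(heptapeptide = "WRKYGQK", hepta_start = start, zf_type = zf,
             zf_start = ifelse(zf == "none", NA_integer_, start + 10L),
             zf_end = ifelse(zf == "none", NA_integer_, start + 40L),
             stringsAsFactors = FALSE)
}

test_that("major-group rule table: domain count and zinc-finger type", {
  expect_equal(call_major_group(rbind(hit_row(10, "C2H2"), hit_row(100, "C2H2")))$group, "I")
  expect_equal(call_major_group(hit_row(10, "C2HC"))$group, "III")
  expect_equal(call_major_group(hit_row(10, "C2H2"))$group, "II")

  # one domain, no zinc finger: group II, unresolved, flagged
  none <- call_major_group(hit_row(10, "none"))
  expect_equal(none$group, "II")
  expect_true(none$subgroup_unresolved)
  expect_true(none$missing_zf)

  expect_error(call_major_group(hit_row(10, "C2H2")[0, ]), "not a family member")
})

test_that("the C-terminal domain decides on conflicting zinc-finger types", {
  hits <- rbind(hit_row(100, "C2HC"), hit_row(10, "C2H2"))
  call <- call_major_group(hits)          # order must not matter
  expect_equal(call$group, "I")
  expect_equal(call$zf_type, "C2HC")
  call_rev <- call_major_group(hits[2:1, ])
  expect_equal(call_rev$zf_type, "C2HC")
})

test_that("subgroup resolution picks the nearest reference, ties to IIa", {
  txt <- paste0("((copy:0.1,refA:0.1):0.5,(refB:0.2,refC:0.2):0.5,",
                "(refD:0.3,refE:0.3):0.6);")
  tr <- ape::read.tree(text = txt)
  labels <- c(refA = "IIa", refB = "IIb", refC = "IIc", refD = "IId", refE = "IIe")
  call <- resolve_subgroup("copy", tr, labels)
  expect_equal(call$group, "IIa")
  expect_equal(call$nearest_reference, "refA")

  # exact equidistance: alphabetical subgroup order wins
  tie <- ape::read.tree(text = "((refX:0.1,refY:0.1):0.2,copy:0.1,(refB:1,(refC:1,(refD:1,refE:1):1):1):1);")
  tie_labels <- c(refX = "IIb", refY = "IIa", refB = "IIb", refC = "IIc",
                  refD = "IId", refE = "IIe")
  expect_equal(resolve_subgroup("copy", tie, tie_labels)$group, "IIa")

  expect_error(resolve_subgroup("copy", tr, labels[c("refA", "refB")]),
               "IIc.*IId.*IIe")
  expect_error(resolve_subgroup("missing", tr, labels), "not in the tree")
})

test_that("classification of planted catalogs recovers the planted labels", {
  sim <- simulate_proteome(small_sim(seed = 13))
  scan <- scan_proteome(sim$records)
  copies <- collapse_isoforms(scan)
  calls <- classify_copies(copies, scan)
  truth <- sim$truth$grouping
  got <- setNames(calls$group, calls$gene_id)
  expect_equal(unname(got[truth$gene_id]), truth$group_label)
  expect_equal(sum(calls$group == "I"), 4L)
  expect_equal(sum(calls$group == "III"), 6L)
})
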