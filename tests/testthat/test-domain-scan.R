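c2h2_zf <- function() paste0("C", "AAAA", "C", strrep("A", 22), "H", "A", "H")
c2hc_zf <- function() paste0("C", strrep("A", 7), "C", strrep("A", 23), "H", "A", "C")

test_that("planted heptapeptide + zinc finger cassettes are detected and typed", {
  s <- paste0(strrep("M", 10), "WRKYGQK", "NNN", c2h2_zf(), "LLLL")
  h <- find_wrky_domains(s)
  expect_equal(nrow(h), 1)
  expect_equal(h$heptapeptide, "WRKYGQK")
  expect_equal(h$hepta_start, 11L)
  expect_equal(h$zf_type, "C2H2")
  expect_equal(h$zf_start, 21L)
  expect_true(h$zf_start > h$hepta_start)

  s3 <- paste0(strrep("M", 5), "WRKYGQK", "NN", c2hc_zf())
  expect_equal(find_wrky_domains(s3)$zf_type, "C2HC")

  # no tryptophan -> no hits; short sequence -> no hits
  expect_equal(nrow(find_wrky_domains(strrep("ACDEF", 20))), 0)
  expect_equal(nrow(find_wrky_domains("ACD")), 0)

  # two cassettes -> two hits in left-to-right order
  s2 <- paste0("MM", "WRKYGQK", "AA", c2h2_zf(), strrep("G", 8),
               "WRKYGKK", "AA", c2hc_zf(), "EE")
  h2 <- find_wrky_domains(s2)
  expect_equal(nrow(h2), 2)
  expect_true(h2$hepta_start[1] < h2$hepta_start[2])
  expect_equal(h2$zf_type, c("C2H2", "C2HC"))
  expect_equal(h2$heptapeptide, c("WRKYGQK", "WRKYGKK"))

  # strict mode drops variant heptapeptides
  expect_equal(nrow(find_wrky_domains(s2, wrky_heptapeptides(strict = TRUE))), 1)
})

test_that("zinc finger search respects max_zf_gap and the nearest-cysteine rule", {
  far <- paste0("WRKYGQK", strrep("A", 61), c2h2_zf())
  expect_equal(find_wrky_domains(far)$zf_type, "none")
  expect_true(is.na(find_wrky_domains(far)$zf_start))
  expect_equal(find_wrky_domains(far, max_zf_gap = 80)$zf_type, "C2H2")

  # a C2HC pattern strictly nearer the heptapeptide beats a later C2H2
  near_hc <- paste0("WRKYGQK", "AA", c2hc_zf(), "AAAA", c2h2_zf())
  expect_equal(find_wrky_domains(near_hc)$zf_type, "C2HC")
})

test_that("hit count is invariant under appending non-matching residues", {
  set.seed(5)
  for (k in 1:20) {
    core <- paste0(random_peptide(sample(5:30, 1)), "WRKYGQK",
                   random_peptide(3), c2h2_zf())
    n0 <- nrow(find_wrky_domains(core))
    tail <- paste(sample(setdiff(AA, "W"), sample(1:40, 1), replace = TRUE),
                  collapse = "")
    expect_equal(nrow(find_wrky_domains(paste0(core, tail))), n0)
  }
})

test_that("proteome scan keeps exactly the records with domains", {
  set.seed(9)
  bg <- vapply(1:5, function(i)
    paste(sample(setdiff(AA, "W"), 120, replace = TRUE), collapse = ""),
    character(1))
  fam <- vapply(1:2, function(i)
    paste0(random_peptide(20), "WRKYGQK", "AAA", c2h2_zf(), random_peptide(15)),
    character(1))
  rec <- parse_protein_id(c(paste0("bg", 1:5), "g1_c1A.1", "g2_c2B.1"))
  rec$sequence <- c(bg, fam)
  sc <- scan_proteome(rec)
  expect_equal(nrow(sc$candidates), 2)
  expect_setequal(sc$candidates$record_id, c("g1_c1A.1", "g2_c2B.1"))
  expect_named(sc$hits, sc$candidates$record_id)

  expect_equal(nrow(scan_proteome(rec[0, ])$candidates), 0)
})

test_that("isoform collapse keeps the first isoform, sorts, and is idempotent", {
  rec <- parse_protein_id(c("g1_c1A.2", "g1_c1A.1", "g1_c1A.3", "g2_c1B.1",
                            "g3_c2A.1", "unplaced.1"))
  rec$sequence <- "A"
  rec$start <- c(10L, 10L, 10L, 5L, 7L, NA)
  rec$end <- rec$start
  out <- collapse_isoforms(rec)
  expect_equal(out$record_id, c("g1_c1A.1", "g2_c1B.1", "g3_c2A.1", "unplaced.1"))
  expect_equal(out$isoform_index, rep(1L, 4))
  # one record per distinct gene id
  expect_equal(nrow(out), length(unique(rec$gene_id)))
  # idempotent
  expect_identical(collapse_isoforms(out), out)
  # single-isoform input -> identity (up to ordering)
  single <- rec[rec$isoform_index == 1, ]
  expect_setequal(collapse_isoforms(single)$record_id, single$record_id)

  dup <- rbind(rec, rec[2, ])
  expect_error(collapse_isoforms(dup), "duplicate")
})
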