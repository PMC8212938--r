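test_that("emitted counts match the configuration exactly", {
  cfg <- small_sim(seed = 3)
  sim <- simulate_proteome(cfg)
  tg <- sim$truth$grouping
  expect_equal(nrow(tg), 18)                                    # 4*3 + 2*2 + 2
  expect_equal(length(unique(tg$truth_gene)), 8)
  expect_equal(nrow(sim$records), 18 + 4 + 20)                  # + extra isoforms + background
  expect_equal(sum(sim$truth$isoforms$n_isoforms >= 2), 3)
  expect_equal(sum(sim$truth$isoforms$n_isoforms - 1), 4)  # extras total
  expect_equal(table(tg$group_label)[c("I", "II", "III")],
               table(factor(c(rep("I", 4), rep("II", 8), rep("III", 6)))),
               ignore_attr = TRUE)
  # per-complement gene counts
  per_comp <- table(tapply(tg$complement, tg$truth_gene, unique))
  expect_equal(as.integer(per_comp[as.character(1:7)]), c(2, 1, 1, 1, 1, 1, 1))
  # coordinates strictly increase along each chromosome
  co <- sim$coordinates
  for (chr in unique(co$chromosome)) {
    s <- co$start[co$chromosome == chr]
    expect_true(all(diff(sort(s)) > 0))
    expect_true(all(!duplicated(s)))
  }
  expect_true(all(co$start <= co$end))
})

test_that("simulation is byte-identical for a fixed seed", {
  s1 <- simulate_proteome(small_sim(seed = 8))
  s2 <- simulate_proteome(small_sim(seed = 8))
  expect_identical(s1$records, s2$records)
  expect_identical(s1$coordinates, s2$coordinates)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_protein_fasta(s1$records, f1)
  write_protein_fasta(s2$records, f2)
  expect_identical(readLines(f1), readLines(f2))

  s3 <- simulate_proteome(small_sim(seed = 9))
  expect_false(identical(s1$records$sequence, s3$records$sequence))
})

test_that("mutation never touches motif cassettes: scanner recall is total", {
  sim <- simulate_proteome(small_sim(seed = 12))
  fam <- sim$records[!grepl("^bg", sim$records$gene_id), ]
  hits_per <- vapply(fam$sequence, function(s) nrow(find_wrky_domains(s)),
                     integer(1))
  expect_true(all(hits_per >= 1))
  tg <- sim$truth$grouping
  planted <- setNames(tg$group_label, tg$gene_id)
  expect_equal(unname(hits_per) >= 2,
               unname(planted[fam$gene_id] == "I"))
  # background proteins never carry a heptapeptide
  bg <- sim$records[grepl("^bg", sim$records$gene_id), ]
  expect_true(all(vapply(bg$sequence, function(s)
    nrow(find_wrky_domains(s)) == 0, logical(1))))
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_multi_isoform = 5, extra_isoforms_total = 3),
               "extra_isoforms_total")
  expect_error(sim_config(type_counts = c("A:B:D" = 2),
                          per_complement_counts = c("1" = 1, "2" = 1, "3" = 0,
                                                    "4" = 0, "5" = 0, "6" = 0,
                                                    "7" = 0),
                          group_plan = c(I = 5, II = 0, III = 0),
                          n_multi_isoform = 0, extra_isoforms_total = 0),
               "group_plan sums")
  expect_error(sim_config(within_triad_divergence = 0.8,
                          between_gene_divergence = 0.7),
               "within_triad_divergence")
  # group plan that cannot be met by whole genes
  cfg <- sim_config(type_counts = c("A:B:D" = 2),
                    per_complement_counts = c("1" = 2, "2" = 0, "3" = 0,
                                              "4" = 0, "5" = 0, "6" = 0, "7" = 0),
                    group_plan = c(I = 5, II = 1, III = 0),
                    n_multi_isoform = 0, extra_isoforms_total = 0,
                    n_background = 0)
  expect_error(simulate_proteome(cfg), "infeasible group plan")
})

test_that("recovery scoring: perfect, shuffled and empty catalogs", {
  catalog <- run_pipeline(list(simulate = TRUE, sim = small_sim(seed = 3)))
  truth <- catalog$simulation$truth
  r <- score_recovery(truth, catalog)
  expect_equal(unlist(r), c(isoform_collapse = 1, grouping = 1,
                            homeolog_types = 1, group_labels = 1))

  shuffled <- catalog
  set.seed(4)
  shuffled$groups$copies$group_id <- sample(shuffled$groups$copies$group_id)
  expect_lt(score_recovery(truth, shuffled)$grouping, 1)

  empty <- catalog
  empty$groups$copies <- empty$groups$copies[0, ]
  expect_equal(unlist(score_recovery(truth, empty)),
               c(isoform_collapse = 0, grouping = 0, homeolog_types = 0,
                 group_labels = 0))

  bad <- catalog
  bad$groups$copies$gene_id[1] <- "not_a_real_copy"
  expect_error(score_recovery(truth, bad), "leaf-set mismatch")
})
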