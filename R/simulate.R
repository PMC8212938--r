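AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
# Non-cassette filler for family proteins excludes W, C and H so no spurious
# heptapeptide or zinc-finger pattern can arise by chance or by mutation.
FILLER17 <- setdiff(AA20, c("W", "C", "H"))

#' Configuration for the allohexaploid proteome simulator
#'
#' The defaults emulate the architecture of the wheat WRKY family as
#' catalogued from the IWGSC RefSeq annotation: 124 genes in 294 subgenome
#' copies (75 full A:B:D triads, 1 A:B, 12 A:D, 7 B:D pairs and 10/4/15
#' A/B/D singletons), 24 genes on chromosome complement 1 and 5 on
#' complement 6, a group plan of 52 group-I, 148 group-II and 94 group-III
#' copies, 47 copies carrying extra splice isoforms for 353 family records
#' in total, and 500 motif-free background proteins.
#'
#' @param seed integer RNG seed; the whole simulation is reproducible from
#'   it.
#' @param type_counts named integer vector of genes per homeolog type.
#' @param per_complement_counts named integer vector (names `"1"`..`"7"`)
#'   of genes per chromosome complement; must sum to the gene total.
#' @param group_plan named integer vector of gene copies per WRKY group.
#'   Keys `I`, `II`, `III`; `IIa`..`IIe` are accepted and summed into `II`
#'   (subgroups of independent gene ancestors carry no phylogenetic
#'   signal, so planting happens at the major-group level). Must sum to the
#'   copy total implied by `type_counts`.
#' @param n_multi_isoform number of gene copies that carry two or more
#'   splice isoforms.
#' @param extra_isoforms_total total number of extra isoform records; must
#'   be at least `n_multi_isoform`.
#' @param n_background number of motif-free background proteins.
#' @param within_triad_divergence per-copy substitution rate
#'   (substitutions/site) from the gene's ancestral protein; pairwise
#'   divergence within a triad is about twice this.
#' @param between_gene_divergence nominal divergence between distinct genes
#'   (substitutions/site); ancestors are drawn independently, so realised
#'   between-gene divergence is near saturation, and this value acts as the
#'   declared lower bound that must exceed the within-triad rate.
#' @param protein_length_range integer (min, max) ancestral protein length.
#' @param indel_rate per-copy probability of one short (1-3 residue)
#'   insertion or deletion in a non-cassette region; 0 (the default) keeps
#'   all copies of a gene the same length.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       type_counts = c("A:B:D" = 75, "A:B" = 1, "A:D" = 12,
                                       "B:D" = 7, "A" = 10, "B" = 4, "D" = 15),
                       per_complement_counts = c("1" = 24, "2" = 19, "3" = 19,
                                                 "4" = 19, "5" = 19, "6" = 5,
                                                 "7" = 19),
                       group_plan = c(I = 52, II = 148, III = 94),
                       n_multi_isoform = 47,
                       extra_isoforms_total = 59,
                       n_background = 500,
                       within_triad_divergence = 0.15,
                       between_gene_divergence = 0.75,
                       protein_length_range = c(120, 300),
                       indel_rate = 0) {
  type_counts <- unlist(type_counts)                 # accept YAML-style lists
  per_complement_counts <- unlist(per_complement_counts)
  group_plan <- unlist(group_plan)
  protein_length_range <- unlist(protein_length_range)
  bad_types <- setdiff(names(type_counts), HOMEOLOG_TYPES)
  if (length(bad_types)) stop("unknown homeolog type(s): ", paste(bad_types, collapse = ", "))
  n_genes <- sum(type_counts)
  copies_per_type <- vapply(names(type_counts), function(ty)
    length(strsplit(ty, ":")[[1]]), integer(1))
  n_copies <- sum(type_counts * copies_per_type)

  if (!setequal(names(per_complement_counts), as.character(1:7))) {
    stop("per_complement_counts must be named '1'..'7'")
  }
  per_complement_counts <- per_complement_counts[as.character(1:7)]
  if (sum(per_complement_counts) != n_genes) {
    stop("per_complement_counts sums to ", sum(per_complement_counts),
         " but type_counts implies ", n_genes, " genes")
  }

  plan <- group_plan
  subs <- intersect(names(plan), II_SUBGROUPS)
  if (length(subs)) {
    ii <- sum(plan[subs]) + (if ("II" %in% names(plan)) plan[["II"]] else 0)
    plan <- plan[setdiff(names(plan), c(II_SUBGROUPS, "II"))]
    plan <- c(plan, II = unname(ii))
  }
  bad_groups <- setdiff(names(plan), c("I", "II", "III"))
  if (length(bad_groups)) stop("unknown group(s) in group_plan: ", paste(bad_groups, collapse = ", "))
  plan <- vapply(c("I", "II", "III"), function(g)
    if (g %in% names(plan)) as.integer(plan[[g]]) else 0L, integer(1))
  names(plan) <- c("I", "II", "III")
  if (sum(plan) != n_copies) {
    stop("group_plan sums to ", sum(plan), " copies but type_counts implies ", n_copies)
  }

  if (extra_isoforms_total < n_multi_isoform) {
    stop("extra_isoforms_total (", extra_isoforms_total,
         ") must be at least n_multi_isoform (", n_multi_isoform, ")")
  }
  if (n_multi_isoform > n_copies) {
    stop("n_multi_isoform exceeds the number of gene copies")
  }
  if (within_triad_divergence >= between_gene_divergence) {
    stop("within_triad_divergence must be below between_gene_divergence")
  }
  if (length(protein_length_range) != 2 || protein_length_range[1] > protein_length_range[2] ||
      protein_length_range[1] < 115) {
    stop("protein_length_range must be (min, max) with min >= 115 (room for two motif cassettes)")
  }
  structure(list(seed = as.integer(seed), type_counts = type_counts,
                 per_complement_counts = per_complement_counts,
                 group_plan = plan, group_plan_input = group_plan,
                 n_genes = n_genes, n_copies = n_copies,
                 n_multi_isoform = as.integer(n_multi_isoform),
                 extra_isoforms_total = as.integer(extra_isoforms_total),
                 n_background = as.integer(n_background),
                 within_triad_divergence = within_triad_divergence,
                 between_gene_divergence = between_gene_divergence,
                 protein_length_range = as.integer(protein_length_range),
                 indel_rate = indel_rate),
            class = "sim_config")
}

# Partition genes (with 3, 2 or 1 copies each) over group labels so the
# per-group copy sums match the plan exactly. Greedy triads-first with a
# small backtrack per label.
allocate_groups <- function(copies_per_gene, plan) {
  pools <- list(`3` = which(copies_per_gene == 3),
                `2` = which(copies_per_gene == 2),
                `1` = which(copies_per_gene == 1))
  out <- character(length(copies_per_gene))
  for (lab in names(plan)) {
    need <- plan[[lab]]
    pick <- NULL
    for (t3 in rev(0:min(length(pools$`3`), need %/% 3))) {
      r <- need - 3 * t3
      for (t2 in rev(0:min(length(pools$`2`), r %/% 2))) {
        t1 <- r - 2 * t2
        if (t1 <= length(pools$`1`)) {
          pick <- c(t3, t2, t1)
          break
        }
      }
      if (!is.null(pick)) break
    }
    if (is.null(pick)) {
      stop("infeasible group plan: cannot reach ", need, " copies for group ", lab)
    }
    take <- c(pools$`3`[seq_len(pick[1])], pools$`2`[seq_len(pick[2])],
              pools$`1`[seq_len(pick[3])])
    out[take] <- lab
    if (pick[1] > 0) pools$`3` <- pools$`3`[-seq_len(pick[1])]
    if (pick[2] > 0) pools$`2` <- pools$`2`[-seq_len(pick[2])]
    if (pick[3] > 0) pools$`1` <- pools$`1`[-seq_len(pick[3])]
  }
  out
}

rand_filler <- function(n) {
  if (n <= 0) "" else paste(sample(FILLER17, n, replace = TRUE), collapse = "")
}

# One WRKY motif cassette: heptapeptide + spacer + zinc finger. Spacer and
# zinc-finger internals are filler (no W/C/H), so the only C/H residues are
# the pattern-defining ones.
make_cassette <- function(zf_type, spacer = 10) {
  zf <- if (zf_type == "C2H2") {
    paste0("C", rand_filler(4), "C", rand_filler(22), "H", rand_filler(1), "H")
  } else {
    paste0("C", rand_filler(7), "C", rand_filler(23), "H", rand_filler(1), "C")
  }
  paste0("WRKYGQK", rand_filler(spacer), zf)
}

# Ancestral protein for one gene: filler with one cassette (two for group I),
# plus a logical mask of immutable (cassette) positions.
ancestral_protein <- function(group, L) {
  zf <- if (group == "III") "C2HC" else "C2H2"
  if (group == "I") {
    cas1 <- make_cassette("C2H2")
    cas2 <- make_cassette(zf)
    lead <- sample(5:15, 1)
    mid <- sample(8:20, 1)
    tail_len <- max(5L, L - lead - nchar(cas1) - mid - nchar(cas2))
    parts <- c(rand_filler(lead), cas1, rand_filler(mid), cas2, rand_filler(tail_len))
    lens <- c(lead, nchar(cas1), mid, nchar(cas2), tail_len)
    immut_block <- c(FALSE, TRUE, FALSE, TRUE, FALSE)
  } else {
    cas <- make_cassette(zf)
    lead <- sample(8:40, 1)
    tail_len <- max(5L, L - lead - nchar(cas))
    parts <- c(rand_filler(lead), cas, rand_filler(tail_len))
    lens <- c(lead, nchar(cas), tail_len)
    immut_block <- c(FALSE, TRUE, FALSE)
  }
  list(chars = strsplit(paste(parts, collapse = ""), "")[[1]],
       immutable = rep(immut_block, lens))
}

mutate_copy <- function(chars, immutable, rate, indel_rate) {
  mutable <- which(!immutable)
  k <- round(rate * length(mutable))
  if (k > 0) {
    pos <- sample(mutable, k)
    repl <- sample(FILLER17, k, replace = TRUE)
    clash <- repl == chars[pos]
    while (any(clash)) {
      repl[clash] <- sample(FILLER17, sum(clash), replace = TRUE)
      clash <- repl == chars[pos]
    }
    chars[pos] <- repl
  }
  if (indel_rate > 0 && stats::runif(1) < indel_rate && length(mutable) > 10) {
    at <- sample(mutable, 1)
    len <- sample(1:3, 1)
    if (stats::runif(1) < 0.5) {
      chars <- append(chars, strsplit(rand_filler(len), "")[[1]], after = at)
    } else {
      drop <- intersect(at:(at + len - 1), mutable)
      if (length(drop)) chars <- chars[-drop]
    }
  }
  chars
}

#' Simulate an allohexaploid proteome with a planted WRKY family
#'
#' For every planned gene an ancestral protein is drawn (filler residues
#' around one motif cassette, or two for group I; C2HC zinc finger for
#' group III, C2H2 otherwise), then one diverged copy is emitted per
#' subgenome of its homeolog type by substituting non-cassette residues at
#' the configured rate - motif cassettes are never touched, so scanner
#' recall is perfect by construction. Copies receive synthetic accessions
#' `g<N>_c<K><S>.1` and strictly increasing coordinates on their
#' chromosome; selected copies gain extra identical-sequence isoforms
#' (`.2`, `.3`, ...); background proteins are uniform over the 20 amino
#' acids with any accidental heptapeptide rejected and resampled. Fully
#' reproducible for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return An object of class `wrky_simulation`: list with `records` (all
#'   family isoforms plus background, shuffled), `coordinates` (per-copy
#'   gene coordinate table) and `truth` (planted grouping, homeolog types,
#'   per-copy group labels, isoform map).
#' @export
simulate_proteome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  genes <- data.frame(
    gene = seq_len(config$n_genes),
    type = rep(names(config$type_counts), config$type_counts),
    stringsAsFactors = FALSE)
  genes$n_copies <- vapply(strsplit(genes$type, ":"), length, integer(1))
  genes$group <- allocate_groups(genes$n_copies, as.list(config$group_plan))
  genes <- genes[sample.int(nrow(genes)), , drop = FALSE]
  genes$gene <- seq_len(nrow(genes))
  genes$complement <- rep(1:7, config$per_complement_counts)
  row.names(genes) <- NULL

  lr <- config$protein_length_range
  copy_rows <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    L <- sample(lr[1]:lr[2], 1)
    anc <- ancestral_protein(genes$group[g], L)
    sgs <- strsplit(genes$type[g], ":")[[1]]
    rows <- lapply(sgs, function(sg) {
      ch <- mutate_copy(anc$chars, anc$immutable, config$within_triad_divergence,
                        config$indel_rate)
      data.frame(gene = genes$gene[g], subgenome = sg,
                 complement = genes$complement[g],
                 gene_id = sprintf("g%d_c%d%s", genes$gene[g],
                                   genes$complement[g], sg),
                 sequence = paste(ch, collapse = ""),
                 group = genes$group[g], homeolog_type = genes$type[g],
                 stringsAsFactors = FALSE)
    })
    copy_rows[[g]] <- do.call(rbind, rows)
  }
  copies <- do.call(rbind, copy_rows)

  # strictly increasing coordinates per chromosome, ordered by gene index
  copies$chromosome <- paste0(copies$complement, copies$subgenome)
  copies$start <- NA_integer_
  copies$end <- NA_integer_
  for (chr in unique(copies$chromosome)) {
    rows <- which(copies$chromosome == chr)
    rows <- rows[order(copies$gene[rows])]
    starts <- 100000L * seq_along(rows)
    copies$start[rows] <- starts
    copies$end[rows] <- starts + 3L * nchar(copies$sequence[rows]) + 200L
  }

  # splice isoforms: identical sequence, incremented suffix
  n_iso <- rep(1L, nrow(copies))
  sel <- sample.int(nrow(copies), config$n_multi_isoform)
  n_iso[sel] <- 2L
  extra_left <- config$extra_isoforms_total - config$n_multi_isoform
  while (extra_left > 0) {
    i <- sel[sample.int(length(sel), 1)]
    n_iso[i] <- n_iso[i] + 1L
    extra_left <- extra_left - 1L
  }
  fam <- copies[rep(seq_len(nrow(copies)), n_iso), , drop = FALSE]
  iso_index <- unlist(lapply(n_iso, seq_len))
  fam$isoform_index <- iso_index
  fam$record_id <- paste0(fam$gene_id, ".", fam$isoform_index)

  bg_len <- sample(lr[1]:lr[2], config$n_background, replace = TRUE)
  heptas <- wrky_heptapeptides()
  bg_seq <- vapply(bg_len, function(L) {
    repeat {
      s <- paste(sample(AA20, L, replace = TRUE), collapse = "")
      if (!any(vapply(heptas, function(h) grepl(h, s, fixed = TRUE), logical(1)))) {
        return(s)
      }
    }
  }, character(1))
  bg <- data.frame(record_id = sprintf("bg%04d.1", seq_len(config$n_background)),
                   gene_id = sprintf("bg%04d", seq_len(config$n_background)),
                   isoform_index = 1L, chromosome = "U",
                   complement = NA_integer_, subgenome = NA_character_,
                   sequence = bg_seq, start = NA_integer_, end = NA_integer_,
                   stringsAsFactors = FALSE)

  records <- rbind(
    data.frame(record_id = fam$record_id, gene_id = fam$gene_id,
               isoform_index = fam$isoform_index, chromosome = fam$chromosome,
               complement = fam$complement, subgenome = fam$subgenome,
               sequence = fam$sequence, start = fam$start, end = fam$end,
               stringsAsFactors = FALSE),
    bg)
  records <- records[sample.int(nrow(records)), , drop = FALSE]
  row.names(records) <- NULL

  coordinates <- data.frame(gene_id = copies$gene_id,
                            chromosome = copies$chromosome,
                            start = copies$start, end = copies$end,
                            stringsAsFactors = FALSE)

  truth <- list(
    grouping = data.frame(gene_id = copies$gene_id, truth_gene = copies$gene,
                          subgenome = copies$subgenome,
                          complement = copies$complement,
                          homeolog_type = copies$homeolog_type,
                          group_label = copies$group,
                          first_record = paste0(copies$gene_id, ".1"),
                          stringsAsFactors = FALSE),
    isoforms = data.frame(gene_id = copies$gene_id, n_isoforms = n_iso,
                          stringsAsFactors = FALSE),
    config = config)
  structure(list(records = records, coordinates = coordinates, truth = truth),
            class = "wrky_simulation")
}

#' @export
print.wrky_simulation <- function(x, ...) {
  cat("synthetic allohexaploid proteome:", nrow(x$records), "records (",
      nrow(x$truth$grouping), "family copies over",
      length(unique(x$truth$grouping$truth_gene)), "genes +",
      sum(grepl("^bg", x$records$gene_id)), "background )\n")
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits the proteome FASTA, the gene-coordinate TSV and the ground truth
#' as JSON.
#'
#' @param sim a `wrky_simulation`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "wrky_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "proteome.fasta")
  coords <- file.path(dir, "coordinates.tsv")
  truth <- file.path(dir, "truth.json")
  write_protein_fasta(sim$records, fasta)
  write.table(sim$coordinates, coords, sep = "\t", quote = FALSE,
              row.names = FALSE)
  tr <- sim$truth
  tr$config <- unclass(tr$config)
  jsonlite::write_json(tr, truth, dataframe = "columns", auto_unbox = TRUE)
  invisible(c(fasta = fasta, coordinates = coords, truth = truth))
}

#' Score pipeline recovery of the planted ground truth
#'
#' Exact-match rates for four axes: isoform collapse (each planted copy is
#' represented by its first isoform), grouping (each planted gene's copy
#' set is exactly one inferred group), homeolog types (matched groups carry
#' the planted type) and per-copy major group labels. All rates are 1 on
#' default generator settings; an empty catalog scores 0 everywhere.
#'
#' @param truth the `truth` element of a `wrky_simulation`.
#' @param catalog a `family_catalog` from [run_pipeline()].
#' @return A list of class `recovery_report` with elements
#'   `isoform_collapse`, `grouping`, `homeolog_types`, `group_labels`.
#' @export
score_recovery <- function(truth, catalog) {
  stopifnot(inherits(catalog, "family_catalog"))
  tg <- truth$grouping
  cp <- catalog$groups$copies
  if (nrow(cp) == 0) {
    return(structure(list(isoform_collapse = 0, grouping = 0,
                          homeolog_types = 0, group_labels = 0),
                     class = "recovery_report"))
  }
  if (!setequal(cp$gene_id, tg$gene_id)) {
    stop("leaf-set mismatch between catalog and ground truth")
  }
  iso_rate <- mean(cp$record_id[match(tg$gene_id, cp$gene_id)] == tg$first_record)

  truth_parts <- vapply(split(tg$gene_id, tg$truth_gene),
                        function(v) paste(sort(v), collapse = "|"), character(1))
  cat_parts <- vapply(split(cp$gene_id, cp$group_id),
                      function(v) paste(sort(v), collapse = "|"), character(1))
  matched <- truth_parts %in% cat_parts
  group_rate <- mean(matched)

  cat_type <- setNames(catalog$groups$groups$homeolog_type,
                       cat_parts[match(catalog$groups$groups$group_id, names(cat_parts))])
  truth_type <- vapply(split(tg$homeolog_type, tg$truth_gene), `[`, character(1), 1)
  type_rate <- mean(matched & truth_type == cat_type[truth_parts])

  major <- function(x) ifelse(grepl("^II[a-e]$", x), "II", x)
  call_group <- catalog$calls$group[match(tg$gene_id, catalog$calls$gene_id)]
  label_rate <- mean(major(call_group) == major(tg$group_label), na.rm = FALSE)

  structure(list(isoform_collapse = iso_rate, grouping = group_rate,
                 homeolog_types = unname(type_rate), group_labels = label_rate),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery rates: isoform collapse", x$isoform_collapse,
      "| grouping", x$grouping, "| homeolog types", x$homeolog_types,
      "| group labels", x$group_labels, "\n")
  invisible(x)
}
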