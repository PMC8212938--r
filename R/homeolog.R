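HOMEOLOG_TYPES <- c("A:B:D", "A:B", "A:D", "B:D", "A", "B", "D")
SUBGENOMES <- c("A", "B", "D")

#' Construct a homeolog grouping from a per-copy table
#'
#' A homeolog group is one gene: 1-3 copies, at most one per subgenome, all
#' on the same chromosome complement (groups without a placed complement
#' must be singletons). The homeolog type is the sorted set of member
#' subgenomes, e.g. `A:B:D` for a full triad.
#'
#' @param copies data frame with one row per gene copy and columns
#'   `gene_id`, `subgenome`, `complement`, `group_id` (plus optionally
#'   `record_id`, `chromosome`, `start`, `end`, which are carried through).
#' @return An object of class `homeolog_groups`: list with `copies` and a
#'   per-group table `groups` (`group_id`, `complement`, `homeolog_type`,
#'   `n_members`).
#' @export
homeolog_groups <- function(copies) {
  need <- c("gene_id", "subgenome", "complement", "group_id")
  miss <- setdiff(need, names(copies))
  if (length(miss)) stop("copies table lacks column(s): ", paste(miss, collapse = ", "))
  for (col in c("record_id", "chromosome", "start", "end", "name")) {
    if (!col %in% names(copies)) copies[[col]] <- rep(NA, nrow(copies))
  }
  split_idx <- split(seq_len(nrow(copies)), copies$group_id)
  gid <- names(split_idx)
  comp <- integer(length(gid))
  type <- character(length(gid))
  nmem <- integer(length(gid))
  for (k in seq_along(split_idx)) {
    rows <- split_idx[[k]]
    sg <- copies$subgenome[rows]
    cc <- unique(copies$complement[rows])
    if (any(duplicated(sg[!is.na(sg)]))) {
      stop("group ", gid[k], " has two copies on the same subgenome")
    }
    if (length(cc) > 1) {
      stop("group ", gid[k], " spans more than one chromosome complement")
    }
    if (is.na(cc) && length(rows) > 1) {
      stop("group ", gid[k], " has multiple members but no complement")
    }
    comp[k] <- cc
    nmem[k] <- length(rows)
    sg <- sg[!is.na(sg)]
    type[k] <- if (length(sg)) {
      paste(SUBGENOMES[sort(match(sg, SUBGENOMES))], collapse = ":")
    } else NA_character_
  }
  groups <- data.frame(group_id = gid, complement = comp, homeolog_type = type,
                       n_members = nmem, stringsAsFactors = FALSE,
                       row.names = NULL)
  structure(list(copies = copies, groups = groups), class = "homeolog_groups")
}

#' @export
print.homeolog_groups <- function(x, ...) {
  cat("homeolog grouping:", nrow(x$groups), "gene(s),", nrow(x$copies),
      "copy/copies\n")
  tt <- table(factor(x$groups$homeolog_type, levels = HOMEOLOG_TYPES))
  print(tt)
  invisible(x)
}

#' Infer homeologous gene groups from a phylogeny
#'
#' Greedy maximal-clade partition of the (unrooted) tree. A candidate group
#' is the leaf set on either side of a tree edge - taking both sides makes
#' the partition independent of where the trifurcating root happens to sit -
#' and it qualifies exactly when all its leaves share one chromosome
#' complement and no subgenome appears twice (so a group holds at most one
#' A, one B and one D copy). Candidates are accepted largest-first; every
#' leaf lands in exactly one group, and leaves in no accepted multi-leaf
#' candidate - including leaves without a placed complement - become
#' singleton groups.
#'
#' Because neighbor joining gives every leaf a cherry partner, two unrelated
#' same-complement singleton genes can form a topologically qualifying
#' clade. A qualifying clade is therefore additionally required to be
#' compact: the largest patristic (path-length) distance between its leaves
#' must not exceed `max_within_distance`. The default of 0.45
#' substitutions/site sits midway between the within-triad (<= 0.3) and
#' between-gene (>= 0.6) divergence regimes under which grouping is
#' well-posed; use `Inf` to disable the check (it is skipped automatically
#' for trees without branch lengths).
#'
#' @param tree a `phylo` whose tips correspond one-to-one to `records` rows
#'   (matched on `gene_id`, falling back to `record_id`).
#' @param records protein record data frame carrying `subgenome` and
#'   `complement`.
#' @param max_within_distance largest allowed leaf-to-leaf path distance
#'   inside one group.
#' @return A `homeolog_groups` object.
#' @export
infer_groups <- function(tree, records, max_within_distance = 0.45) {
  tips <- tree$tip.label
  idx <- match(tips, records$gene_id)
  if (anyNA(idx)) idx <- match(tips, records$record_id)
  if (anyNA(idx) || anyDuplicated(idx)) {
    stop("tree leaves do not correspond one-to-one to records")
  }
  rec <- records[idx, , drop = FALSE]   # aligned with tip numbering
  ntip <- length(tips)
  nnode <- tree$Nnode
  kids <- split(tree$edge[, 2], tree$edge[, 1])

  pd <- if (!is.null(tree$edge.length) && is.finite(max_within_distance)) {
    ape::cophenetic.phylo(tree)[tips, tips]
  } else NULL

  leaves_below <- vector("list", ntip + nnode)
  for (t in seq_len(ntip)) leaves_below[[t]] <- t
  po <- stats::reorder(tree, "postorder")
  for (parent in unique(po$edge[, 1])) {
    leaves_below[[parent]] <- unlist(leaves_below[kids[[as.character(parent)]]])
  }

  # candidate groups: both sides of every edge, deduplicated, capped at 3 leaves
  candidates <- list()
  for (node in seq_len(ntip + nnode)) {
    if (node == ntip + 1L) next
    lv <- leaves_below[[node]]
    if (length(lv) <= 3) candidates[[length(candidates) + 1L]] <- sort(lv)
    if (ntip - length(lv) <= 3 && ntip - length(lv) >= 1) {
      candidates[[length(candidates) + 1L]] <- setdiff(seq_len(ntip), lv)
    }
  }
  candidates <- unique(candidates)
  qualifies <- function(lv) {
    if (length(lv) == 1) return(TRUE)
    comp <- rec$complement[lv]
    sg <- rec$subgenome[lv]
    !anyNA(comp) && length(unique(comp)) == 1 &&
      !anyNA(sg) && !any(duplicated(sg)) &&
      (is.null(pd) || max(pd[lv, lv]) <= max_within_distance)
  }
  sizes <- lengths(candidates)
  firsts <- vapply(candidates, `[`, integer(1), 1)
  ord <- order(-sizes, firsts)

  group_of <- rep(NA_integer_, ntip)
  next_id <- 0L
  for (k in ord) {
    lv <- candidates[[k]]
    if (all(is.na(group_of[lv])) && qualifies(lv)) {
      next_id <- next_id + 1L
      group_of[lv] <- next_id
    }
  }
  for (t in which(is.na(group_of))) {
    next_id <- next_id + 1L
    group_of[t] <- next_id
  }

  copies <- rec
  copies$group_id <- sprintf("G%03d", group_of)
  row.names(copies) <- NULL
  homeolog_groups(copies)
}

#' Homeolog-type breakdown of a catalog
#'
#' Counts gene copies and genes per homeolog type (`A:B:D`, `A:B`, `A:D`,
#' `B:D`, `A`, `B`, `D`) and the percentage of genes in each type, rounded
#' half-up to two decimals.
#'
#' @param groups a `homeolog_groups` object.
#' @return Data frame with columns `homeolog_type`, `copies`, `genes`,
#'   `pct_genes`; total genes and copies are attached as attributes
#'   `total_genes` / `total_copies`.
#' @export
type_groups <- function(groups) {
  stopifnot(inherits(groups, "homeolog_groups"))
  g <- groups$groups
  f <- factor(g$homeolog_type, levels = HOMEOLOG_TYPES)
  genes <- as.integer(table(f))
  copies <- vapply(HOMEOLOG_TYPES, function(ty)
    sum(g$n_members[!is.na(g$homeolog_type) & g$homeolog_type == ty]),
    integer(1))
  total_genes <- nrow(g)
  pct <- if (total_genes > 0) round_half_up(100 * genes / total_genes, 2) else rep(0, length(genes))
  out <- data.frame(homeolog_type = HOMEOLOG_TYPES, copies = unname(copies),
                    genes = genes, pct_genes = pct, stringsAsFactors = FALSE)
  attr(out, "total_genes") <- total_genes
  attr(out, "total_copies") <- nrow(groups$copies)
  out
}

#' Assign systematic names to homeolog groups
#'
#' Serial numbers run 1..G over chromosome complements 1 to 7. Within a
#' complement: (i) the reference subgenome is the one carrying the most
#' family copies in that complement (ties broken A > B > D); (ii) groups
#' with a copy on the reference subgenome come first, ordered by that copy's
#' start coordinate; (iii) the remaining groups follow, ordered by their
#' highest-priority subgenome (A > B > D) and that copy's start. Groups with
#' no placed complement are numbered last, ordered by gene id. Each member
#' is named `prefix + serial + "-" + subgenome` (e.g. `TaWRKY75-A`).
#'
#' @param groups a `homeolog_groups` object with member start coordinates.
#' @param prefix name prefix, default `"TaWRKY"`.
#' @return The `homeolog_groups` object with `serial` and `base_name` added
#'   to `groups` and `name` filled in on `copies`.
#' @export
assign_names <- function(groups, prefix = "TaWRKY") {
  stopifnot(inherits(groups, "homeolog_groups"))
  g <- groups$groups
  cp <- groups$copies
  ordered_ids <- character(0)
  for (comp in sort(unique(g$complement[!is.na(g$complement)]))) {
    gid <- g$group_id[!is.na(g$complement) & g$complement == comp]
    cc <- cp[cp$group_id %in% gid & !is.na(cp$subgenome), , drop = FALSE]
    counts <- table(factor(cc$subgenome, levels = SUBGENOMES))
    ref <- SUBGENOMES[which.max(counts)]  # which.max: first max, so A > B > D
    ref_start <- function(id) {
      r <- cc[cc$group_id == id & cc$subgenome == ref, , drop = FALSE]
      if (nrow(r)) as.numeric(r$start[1]) else NA_real_
    }
    has_ref <- vapply(gid, function(id) !is.na(ref_start(id)), logical(1))
    first <- gid[has_ref]
    first <- first[order(vapply(first, ref_start, numeric(1)), first)]
    rest <- gid[!has_ref]
    if (length(rest)) {
      key <- t(vapply(rest, function(id) {
        r <- cc[cc$group_id == id, , drop = FALSE]
        pri <- min(match(r$subgenome, SUBGENOMES))
        st <- r$start[match(SUBGENOMES[pri], r$subgenome)]
        c(pri, if (is.na(st)) Inf else st)
      }, numeric(2)))
      rest <- rest[order(key[, 1], key[, 2], rest)]
    }
    ordered_ids <- c(ordered_ids, first, rest)
  }
  unplaced <- g$group_id[is.na(g$complement)]
  if (length(unplaced)) {
    first_gene <- vapply(unplaced, function(id)
      min(cp$gene_id[cp$group_id == id]), character(1))
    ordered_ids <- c(ordered_ids, unplaced[order(first_gene)])
  }
  serial <- match(g$group_id, ordered_ids)
  g$serial <- serial
  g$base_name <- paste0(prefix, serial)
  cp$name <- paste0(g$base_name[match(cp$group_id, g$group_id)],
                    ifelse(is.na(cp$subgenome), "", paste0("-", cp$subgenome)))
  groups$groups <- g
  groups$copies <- cp
  groups
}

#' Catalog summary statistics
#'
#' Copy counts and percentages per subgenome, gene counts per chromosome
#' complement, the homeolog-type breakdown of [type_groups()], totals, and
#' (optionally) fold ratios of the total copy count against comparator
#' family sizes from other species. Percentages are rounded half-up to two
#' decimals.
#'
#' @param groups a `homeolog_groups` object.
#' @param comparators optional named integer vector of comparator family
#'   sizes (e.g. `c(rice = 103, maize = 119)`).
#' @return An object of class `catalog_stats`.
#' @export
summary_stats <- function(groups, comparators = NULL) {
  stopifnot(inherits(groups, "homeolog_groups"))
  cp <- groups$copies
  g <- groups$groups
  types <- type_groups(groups)
  total_copies <- nrow(cp)
  total_genes <- nrow(g)
  sub_counts <- as.integer(table(factor(cp$subgenome, levels = SUBGENOMES)))
  sub_pct <- if (total_copies > 0) round_half_up(100 * sub_counts / total_copies, 2) else rep(0, 3)
  subgenome <- data.frame(subgenome = SUBGENOMES, copies = sub_counts,
                          pct_copies = sub_pct, stringsAsFactors = FALSE)
  comp_counts <- as.integer(table(factor(g$complement, levels = 1:7)))
  complements <- data.frame(complement = 1:7, genes = comp_counts)
  fold <- if (!is.null(comparators)) round_half_up(total_copies / comparators, 2) else NULL
  structure(list(types = types,
                 totals = list(genes = total_genes, copies = total_copies,
                               unplaced_genes = sum(is.na(g$complement))),
                 subgenome = subgenome, complements = complements,
                 fold_vs_comparators = fold),
            class = "catalog_stats")
}

#' @export
print.catalog_stats <- function(x, ...) {
  cat("Family catalog:", x$totals$genes, "genes,", x$totals$copies, "gene copies\n")
  cat("\nHomeolog types:\n")
  print(x$types, row.names = FALSE)
  cat("\nCopies per subgenome:\n")
  print(x$subgenome, row.names = FALSE)
  cat("\nGenes per chromosome complement:\n")
  print(x$complements, row.names = FALSE)
  if (!is.null(x$fold_vs_comparators)) {
    cat("\nCopy-count fold ratio vs comparators:\n")
    print(x$fold_vs_comparators)
  }
  invisible(x)
}
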