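WRKY_GROUPS <- c("I", "IIa", "IIb", "IIc", "IId", "IIe", "III")
II_SUBGROUPS <- c("IIa", "IIb", "IIc", "IId", "IIe")

#' Call the major WRKY group from domain hits
#'
#' Structural rule table: two or more WRKY domains is group I; one domain
#' with a C2HC (CCHC) zinc finger is group III; one domain with a C2H2 zinc
#' finger is group II (subgroup unresolved here; see [resolve_subgroup()]).
#' When hits disagree on zinc-finger type, the C-terminal domain decides -
#' the classifying domain of two-domain proteins is the C-terminal one. A
#' single domain with no detectable zinc finger is kept in group II with a
#' `missing_zf` flag rather than dropped, since the scan already admitted
#' the protein as a family member.
#'
#' @param hits data frame of domain hits from [find_wrky_domains()] (>= 1
#'   row).
#' @return A list (class `group_call`): `group` (`"I"`, `"II"` or `"III"`),
#'   `n_domains`, `zf_type` (of the C-terminal domain),
#'   `subgroup_unresolved`, `missing_zf`, `nearest_reference` (`NA` until
#'   resolved).
#' @export
call_major_group <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) {
    stop("no WRKY domain hits: not a family member")
  }
  hits <- hits[order(hits$hepta_start), , drop = FALSE]
  n <- nrow(hits)
  zf <- hits$zf_type[n]
  group <- if (n >= 2) "I" else if (zf == "C2HC") "III" else "II"
  structure(list(group = group, n_domains = n, zf_type = zf,
                 subgroup_unresolved = group == "II",
                 missing_zf = zf == "none",
                 nearest_reference = NA_character_),
            class = "group_call")
}

#' @export
print.group_call <- function(x, ...) {
  cat("WRKY group", x$group, "(", x$n_domains, "domain(s), zinc finger",
      x$zf_type, ")\n")
  invisible(x)
}

#' Resolve a group II subgroup by nearest labelled reference
#'
#' The subgroup (IIa-IIe) of a gene copy is the label of the reference leaf
#' with minimum patristic (path-length) distance in a tree that contains
#' both the copy and labelled reference proteins; exact ties are broken by
#' alphabetical subgroup order. This is a deterministic stand-in for visual
#' clade assignment against a reference panel.
#'
#' @param copy_id tip label of the gene copy.
#' @param tree_with_references `phylo` containing the copy and the
#'   reference leaves.
#' @param reference_labels named character vector mapping reference tip
#'   labels to subgroups; every subgroup IIa-IIe must be represented.
#' @return A `group_call` with `group` set to the subgroup and
#'   `nearest_reference` filled in.
#' @export
resolve_subgroup <- function(copy_id, tree_with_references, reference_labels) {
  tips <- tree_with_references$tip.label
  if (!copy_id %in% tips) stop("copy '", copy_id, "' is not in the tree")
  refs <- reference_labels[names(reference_labels) %in% tips]
  missing <- setdiff(II_SUBGROUPS, unique(refs))
  if (length(missing)) {
    stop("missing reference(s) for subgroup(s): ", paste(missing, collapse = ", "))
  }
  pd <- ape::cophenetic.phylo(tree_with_references)
  d <- pd[copy_id, names(refs)]
  best <- d <= min(d) + 1e-12
  cand <- sort(unname(refs[best]))  # alphabetical subgroup order breaks ties
  sub <- cand[1]
  nearest <- names(refs)[best & refs == sub][1]
  structure(list(group = sub, n_domains = 1L, zf_type = "C2H2",
                 subgroup_unresolved = FALSE, missing_zf = FALSE,
                 nearest_reference = nearest),
            class = "group_call")
}

#' Classify every collapsed gene copy of a scan
#'
#' Applies [call_major_group()] to the hits of each copy's representative
#' record.
#'
#' @param copies collapsed record data frame (see [collapse_isoforms()]).
#' @param scan the `wrky_scan` the copies came from.
#' @return Data frame with columns `gene_id`, `record_id`, `group`,
#'   `n_domains`, `zf_type`.
#' @export
classify_copies <- function(copies, scan) {
  stopifnot(inherits(scan, "wrky_scan"))
  calls <- lapply(copies$record_id, function(id) call_major_group(scan$hits[[id]]))
  data.frame(gene_id = copies$gene_id, record_id = copies$record_id,
             group = vapply(calls, `[[`, character(1), "group"),
             n_domains = vapply(calls, `[[`, integer(1), "n_domains"),
             zf_type = vapply(calls, `[[`, character(1), "zf_type"),
             stringsAsFactors = FALSE)
}
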