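#' Parse protein accessions into gene, isoform and subgenome components
#'
#' Understands three identifier grammars and falls back gracefully:
#'
#' * IWGSC RefSeq style: `TraesCS` + chromosome complement digit (1-7) +
#'   subgenome letter (A/B/D) + `02G` + six digits + optional `.isoform`
#'   (e.g. `TraesCS4A02G123456.2`); unplaced scaffolds use `TraesCSU02G...`.
#' * Synthetic style emitted by [simulate_proteome()]: `g<N>_c<K><S>.<i>`
#'   (gene N, complement K, subgenome S, isoform i), e.g. `g12_c3A.1`.
#' * Generic: `gene_id[.isoform]`; anything before a final `.digits` suffix
#'   is the gene identifier.
#'
#' Parsing is total: identifiers that match no location-bearing grammar get
#' `NA` chromosome, complement and subgenome rather than a guess. Records
#' without a dot suffix are isoform 1 by convention.
#'
#' @param ids character vector of accessions.
#' @return A data frame with columns `record_id`, `gene_id`, `isoform_index`,
#'   `chromosome`, `complement`, `subgenome`.
#' @examples
#' parse_protein_id(c("TraesCS4A02G000100.1", "g3_c2D.2", "geneX"))
#' @export
parse_protein_id <- function(ids) {
  stopifnot(is.character(ids))
  if (any(!nzchar(ids))) stop("malformed header: empty accession")

  has_iso <- grepl("\\.[0-9]+$", ids)
  gene_id <- ifelse(has_iso, sub("\\.[0-9]+$", "", ids), ids)
  isoform <- rep(1L, length(ids))
  isoform[has_iso] <- as.integer(sub("^.*\\.([0-9]+)$", "\\1", ids[has_iso]))

  chrom <- rep(NA_character_, length(ids))
  iwgsc <- grepl("^TraesCS([1-7][ABD]|U)02G[0-9]{6}(\\.[0-9]+)?$", ids)
  chrom[iwgsc] <- sub("^TraesCS([1-7][ABD]|U)02G.*$", "\\1", ids[iwgsc])
  synth <- grepl("^g[0-9]+_c[1-7][ABD](\\.[0-9]+)?$", ids)
  chrom[synth] <- sub("^g[0-9]+_c([1-7][ABD]).*$", "\\1", ids[synth])

  loc <- chromosome_parts(chrom)
  data.frame(record_id = ids, gene_id = gene_id,
             isoform_index = as.integer(isoform), chromosome = chrom,
             complement = loc$complement, subgenome = loc$subgenome,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Split chromosome labels like "4A" into complement 4 / subgenome "A".
# "U" (unplaced) and unrecognised labels give NA for both, keeping the
# invariant that complement and subgenome are both present or both absent.
chromosome_parts <- function(chrom) {
  ok <- !is.na(chrom) & grepl("^[1-7][ABD]$", chrom)
  complement <- rep(NA_integer_, length(chrom))
  subgenome <- rep(NA_character_, length(chrom))
  complement[ok] <- as.integer(substr(chrom[ok], 1L, 1L))
  subgenome[ok] <- substr(chrom[ok], 2L, 2L)
  list(complement = complement, subgenome = subgenome)
}

#' Read a protein FASTA file into a record table
#'
#' Headers are whitespace-delimited; the first token is the accession and is
#' parsed with [parse_protein_id()]. Sequences are uppercased and a trailing
#' stop symbol `*` is stripped. Residues other than the 20 standard amino
#' acids and `X` are rejected with the offending record named.
#'
#' @param path path to a FASTA file of protein sequences.
#' @return A data frame of protein records: the columns of
#'   [parse_protein_id()] plus `sequence`, `start`, `end` (coordinates are
#'   `NA` until supplied with [apply_coordinates()]).
#' @seealso [write_protein_fasta()], [read_coordinates()]
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) return(empty_records())
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) return(empty_records())
  acc <- vapply(strsplit(names(ss), "[[:space:]]+"),
                function(x) if (length(x)) x[[1L]] else "", character(1))
  if (any(!nzchar(acc))) stop("malformed header: empty accession")
  seqs <- sub("\\*$", "", toupper(as.character(ss)))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
  if (any(bad)) {
    stop("non-amino-acid characters in record(s): ",
         paste(utils::head(acc[bad], 5), collapse = ", "))
  }
  rec <- parse_protein_id(unname(acc))
  rec$sequence <- unname(seqs)
  rec$start <- NA_integer_
  rec$end <- NA_integer_
  rec
}

empty_records <- function() {
  data.frame(record_id = character(0), gene_id = character(0),
             isoform_index = integer(0), chromosome = character(0),
             complement = integer(0), subgenome = character(0),
             sequence = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records a protein record data frame with `record_id` and
#'   `sequence` columns.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  ss <- Biostrings::BStringSet(setNames(records$sequence, records$record_id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a gene-coordinate table
#'
#' Tab-separated with header columns `gene_id`, `chromosome`, `start`, `end`;
#' coordinates are 1-based inclusive (GFF3 convention). Duplicated gene ids
#' and inverted intervals are format errors.
#'
#' @param path path to the TSV file.
#' @return A data frame with columns `gene_id`, `chromosome`, `start`, `end`.
#' @export
read_coordinates <- function(path) {
  if (!file.exists(path)) stop("coordinate table not found: ", path)
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "chromosome", "start", "end")
  if (!all(need %in% names(df))) {
    stop("coordinate table must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[need]
  df$gene_id <- as.character(df$gene_id)
  df$chromosome <- as.character(df$chromosome)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  dup <- duplicated(df$gene_id)
  if (any(dup)) {
    stop("duplicate gene_id in coordinate table: ",
         paste(unique(df$gene_id[dup]), collapse = ", "))
  }
  bad <- !is.na(df$start) & !is.na(df$end) & df$start > df$end
  if (any(bad)) {
    stop("start > end for gene(s): ", paste(df$gene_id[bad], collapse = ", "))
  }
  df
}

#' Attach coordinates from a gene-coordinate table to protein records
#'
#' Coordinates (and the chromosome label, hence complement and subgenome)
#' from the table override anything parsed from the FASTA headers.
#'
#' @param records a protein record data frame.
#' @param coordinates a data frame from [read_coordinates()].
#' @return The record data frame with `chromosome`, `complement`,
#'   `subgenome`, `start`, `end` updated for matched genes.
#' @export
apply_coordinates <- function(records, coordinates) {
  i <- match(records$gene_id, coordinates$gene_id)
  hit <- !is.na(i)
  records$chromosome[hit] <- coordinates$chromosome[i[hit]]
  records$start[hit] <- coordinates$start[i[hit]]
  records$end[hit] <- coordinates$end[i[hit]]
  loc <- chromosome_parts(records$chromosome)
  records$complement <- loc$complement
  records$subgenome <- loc$subgenome
  records
}

#' Write a phylogenetic tree in newick format
#'
#' Branch lengths are printed with six decimals and internal node labels
#' (integer bootstrap supports, when present) are carried along.
#'
#' @param tree a `phylo` object.
#' @param path output path.
#' @return The path, invisibly.
#' @seealso [read_newick()]
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  writeLines(newick_string(tree), path)
  invisible(path)
}

#' Read a newick tree
#'
#' @param path path to a newick file.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

newick_string <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  blen <- tree$edge.length
  eidx <- setNames(seq_len(nrow(tree$edge)), tree$edge[, 2])
  fmt <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    lab <- ""
    if (!is.null(tree$node.label)) {
      l <- tree$node.label[node - ntip]
      if (!is.na(l) && nzchar(l)) lab <- l
    }
    parts <- vapply(kids[[as.character(node)]], function(ch) {
      len <- if (is.null(blen)) NULL else blen[eidx[[as.character(ch)]]]
      if (is.null(len)) fmt(ch) else sprintf("%s:%.6f", fmt(ch), len)
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  paste0(fmt(ntip + 1L), ";")
}

#' Write a family catalog as a TSV report
#'
#' One row per gene copy with its assigned name, identifiers, subgenome,
#' complement, homeolog type, WRKY group and coordinates. An empty catalog
#' yields a header-only file.
#'
#' @param catalog a `family_catalog` from [run_pipeline()], or a data frame
#'   already shaped like the report.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  df <- if (inherits(catalog, "family_catalog")) catalog_table(catalog) else catalog
  need <- c("name", "gene_id", "record_id", "subgenome", "complement",
            "homeolog_type", "group", "chromosome", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("catalog table lacks column(s): ", paste(miss, collapse = ", "))
  write.table(df[need], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flatten a family catalog into its per-copy report table
#'
#' @param catalog a `family_catalog`.
#' @return A data frame with one row per gene copy.
#' @export
catalog_table <- function(catalog) {
  stopifnot(inherits(catalog, "family_catalog"))
  cp <- catalog$groups$copies
  g <- catalog$groups$groups
  gi <- match(cp$group_id, g$group_id)
  ci <- match(cp$gene_id, catalog$calls$gene_id)
  out <- data.frame(
    name = if ("name" %in% names(cp)) cp$name else NA_character_,
    gene_id = cp$gene_id, record_id = cp$record_id,
    subgenome = cp$subgenome, complement = cp$complement,
    homeolog_type = g$homeolog_type[gi],
    group = catalog$calls$group[ci],
    chromosome = cp$chromosome, start = cp$start, end = cp$end,
    stringsAsFactors = FALSE)
  out[order(is.na(out$complement), out$complement, out$subgenome, out$start,
            out$gene_id), , drop = FALSE]
}
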