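#' Allowed WRKY heptapeptides
#'
#' The canonical DNA-binding domain opens with WRKYGQK; WRKYGKK and WRKYGEK
#' are the common natural variants. Strict mode restricts matching to the
#' canonical heptapeptide only.
#'
#' @param strict if `TRUE`, return only `WRKYGQK`.
#' @return Character vector of 7-mers.
#' @export
wrky_heptapeptides <- function(strict = FALSE) {
  if (strict) "WRKYGQK" else c("WRKYGQK", "WRKYGKK", "WRKYGEK")
}

# Zinc-finger patterns: C2H2 is C-x(4,5)-C-x(22,23)-H-x-H, C2HC is
# C-x(7)-C-x(23)-H-x-C. Matched with leftmost-first regular expressions so
# the reported first cysteine is the nearest one downstream.
ZF_PATTERNS <- c(C2H2 = "C[A-Z]{4,5}C[A-Z]{22,23}H[A-Z]H",
                 C2HC = "C[A-Z]{7}C[A-Z]{23}H[A-Z]C")
ZF_MAX_LEN <- 35L

#' Locate WRKY domains in one protein sequence
#'
#' Scans left to right for non-overlapping occurrences of any allowed
#' heptapeptide. For each occurrence the nearest downstream zinc finger whose
#' first cysteine lies within `max_zf_gap` residues of the heptapeptide end
#' is attached: C2H2 (C-x(4,5)-C-x(22,23)-H-x-H) or C2HC
#' (C-x(7)-C-x(23)-H-x-C). If both patterns match, the one starting nearer
#' the heptapeptide wins; ties go to C2H2. A heptapeptide with no zinc
#' finger in range is still reported with `zf_type = "none"`.
#'
#' @param seq one amino-acid string.
#' @param allowed_heptapeptides set of admissible 7-mers
#'   (default [wrky_heptapeptides()]).
#' @param max_zf_gap maximum number of residues between the heptapeptide end
#'   and the zinc finger's first cysteine (default 60, roughly the span of
#'   the ~60-residue WRKY domain).
#' @return A data frame with one row per hit: `heptapeptide`, `hepta_start`
#'   (1-based), `zf_type` (`"C2H2"`, `"C2HC"` or `"none"`), `zf_start`,
#'   `zf_end` (1-based inclusive, `NA` when no finger was found).
#' @examples
#' s <- paste0("MAAAAAAAAA", "WRKYGQK", "NNN",
#'             "CAAAAC", strrep("A", 22), "HAH", "LLLL")
#' find_wrky_domains(s)
#' @export
find_wrky_domains <- function(seq, allowed_heptapeptides = wrky_heptapeptides(),
                              max_zf_gap = 60) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  empty <- data.frame(heptapeptide = character(0), hepta_start = integer(0),
                      zf_type = character(0), zf_start = integer(0),
                      zf_end = integer(0), stringsAsFactors = FALSE)
  if (nchar(seq) < 7) return(empty)

  starts <- integer(0)
  heptas <- character(0)
  for (h in allowed_heptapeptides) {
    m <- gregexpr(h, seq, fixed = TRUE)[[1]]
    if (m[1] != -1) {
      starts <- c(starts, as.integer(m))
      heptas <- c(heptas, rep(h, length(m)))
    }
  }
  if (!length(starts)) return(empty)
  o <- order(starts)
  starts <- starts[o]
  heptas <- heptas[o]
  keep <- logical(length(starts))
  last_end <- 0L
  for (k in seq_along(starts)) {
    if (starts[k] > last_end) {
      keep[k] <- TRUE
      last_end <- starts[k] + 6L
    }
  }
  starts <- starts[keep]
  heptas <- heptas[keep]

  n <- length(starts)
  zf_type <- rep("none", n)
  zf_start <- rep(NA_integer_, n)
  zf_end <- rep(NA_integer_, n)
  for (k in seq_len(n)) {
    he <- starts[k] + 6L
    window <- substr(seq, he + 1L, min(nchar(seq), he + max_zf_gap + ZF_MAX_LEN))
    best_off <- NA_integer_
    best_len <- NA_integer_
    best_type <- "none"
    for (ty in names(ZF_PATTERNS)) {
      m <- regexpr(ZF_PATTERNS[[ty]], window)
      if (m != -1 && m <= max_zf_gap) {
        off <- as.integer(m)
        if (is.na(best_off) || off < best_off) {
          best_off <- off
          best_len <- attr(m, "match.length")
          best_type <- ty
        }
        # equal offsets: first pattern tried (C2H2) already stored, tie kept
      }
    }
    if (best_type != "none") {
      zf_type[k] <- best_type
      zf_start[k] <- he + best_off
      zf_end[k] <- he + best_off + best_len - 1L
    }
  }
  data.frame(heptapeptide = heptas, hepta_start = starts, zf_type = zf_type,
             zf_start = zf_start, zf_end = zf_end, stringsAsFactors = FALSE)
}

#' Scan a proteome for WRKY family candidates
#'
#' Runs [find_wrky_domains()] over every record and keeps those with at
#' least one hit. The result is deterministic for a fixed input.
#'
#' @param records a protein record data frame (see [read_protein_fasta()]).
#' @param allowed_heptapeptides,max_zf_gap passed to [find_wrky_domains()].
#' @return An object of class `wrky_scan`: a list with `candidates` (the
#'   record rows that carry a domain) and `hits` (a list of hit tables named
#'   by `record_id`, each sorted by position).
#' @export
scan_proteome <- function(records, allowed_heptapeptides = wrky_heptapeptides(),
                          max_zf_gap = 60) {
  hits <- lapply(records$sequence, find_wrky_domains,
                 allowed_heptapeptides = allowed_heptapeptides,
                 max_zf_gap = max_zf_gap)
  has <- vapply(hits, nrow, integer(1)) > 0
  hits <- hits[has]
  candidates <- records[has, , drop = FALSE]
  row.names(candidates) <- NULL
  names(hits) <- candidates$record_id
  structure(list(candidates = candidates, hits = hits), class = "wrky_scan")
}

#' @export
print.wrky_scan <- function(x, ...) {
  cat("WRKY proteome scan:", nrow(x$candidates), "candidate record(s),",
      length(unique(x$candidates$gene_id)), "distinct gene id(s)\n")
  invisible(x)
}

#' Collapse splice isoforms to one record per gene
#'
#' Keeps, for every gene identifier, the record with the smallest isoform
#' index (the "first" isoform). Output is sorted by chromosome complement,
#' subgenome and start coordinate; records without a placed chromosome sort
#' last.
#'
#' @param candidates a `wrky_scan` or a protein record data frame.
#' @return A protein record data frame with exactly one row per `gene_id`.
#' @export
collapse_isoforms <- function(candidates) {
  rec <- if (inherits(candidates, "wrky_scan")) candidates$candidates else candidates
  if (!nrow(rec)) return(rec)
  key <- paste(rec$gene_id, rec$isoform_index, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (gene_id, isoform_index) in input: ",
         paste(utils::head(rec$record_id[dup], 5), collapse = ", "))
  }
  o <- order(rec$gene_id, rec$isoform_index)
  rec <- rec[o, , drop = FALSE]
  rec <- rec[!duplicated(rec$gene_id), , drop = FALSE]
  rec <- rec[order(is.na(rec$complement), rec$complement, rec$subgenome,
                   rec$start, rec$gene_id), , drop = FALSE]
  row.names(rec) <- NULL
  rec
}
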