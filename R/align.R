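#' The BLOSUM62 substitution matrix
#'
#' Convenience accessor for the BLOSUM62 matrix shipped with Biostrings,
#' the default scoring model for all alignment operations here.
#'
#' @return A symmetric integer matrix with amino-acid dimnames.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

encode_chars <- function(chars, alphabet) {
  i <- match(chars, alphabet)
  if (anyNA(i)) {
    stop("residue(s) absent from substitution matrix: ",
         paste(unique(chars[is.na(i)]), collapse = ", "))
  }
  i
}

moves_to_indices <- function(moves) {
  ia <- cumsum(moves != 3L)
  ib <- cumsum(moves != 2L)
  ia[moves == 3L] <- 0L
  ib[moves == 2L] <- 0L
  list(a = ia, b = ib)
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch/Gotoh optimal global alignment. A gap of length L costs
#' `gap_open + (L - 1) * gap_extend`. The traceback is deterministic: on
#' ties it prefers the diagonal move, then the vertical (gap in `b`), then
#' the horizontal (gap in `a`).
#'
#' @param a,b amino-acid strings.
#' @param sub_matrix substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend gap penalties (negative; defaults -10 / -1).
#' @return `list(score, alignment)` where `alignment` is the pair of gapped
#'   strings.
#' @examples
#' pairwise_global_align("WRKY", "WRKY")$score # 11 + 5 + 5 + 7 = 28
#' @export
pairwise_global_align <- function(a, b, sub_matrix = blosum62(),
                                  gap_open = -10, gap_extend = -1) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  a <- toupper(a)
  b <- toupper(b)
  na <- nchar(a)
  nb <- nchar(b)
  if (na == 0 && nb == 0) return(list(score = 0, alignment = c("", "")))
  if (na == 0 || nb == 0) {
    len <- max(na, nb)
    gaps <- strrep("-", len)
    score <- gap_open + gap_extend * (len - 1)
    al <- if (na == 0) c(gaps, b) else c(a, gaps)
    return(list(score = score, alignment = al))
  }
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  S <- sub_matrix[encode_chars(ca, rownames(sub_matrix)),
                  encode_chars(cb, colnames(sub_matrix)), drop = FALSE]
  r <- nw_affine_cpp(unname(S) + 0.0, gap_open, gap_extend)
  idx <- moves_to_indices(r$moves)
  aa <- ifelse(idx$a > 0, ca[pmax(idx$a, 1L)], "-")
  bb <- ifelse(idx$b > 0, cb[pmax(idx$b, 1L)], "-")
  list(score = r$score,
       alignment = c(paste(aa, collapse = ""), paste(bb, collapse = "")))
}

# 3-mer cosine distances used for the guide tree. Sequences too short to
# carry a 3-mer get an empty profile and distance 1 to everything (0 to an
# identical string), which is all the guide tree needs.
kmer_cosine_dist <- function(sequences, k = 3) {
  n <- length(sequences)
  km <- lapply(sequences, function(s) {
    L <- nchar(s)
    if (L < k) character(0) else substring(s, 1:(L - k + 1), k:L)
  })
  keys <- unique(unlist(km))
  M <- matrix(0, n, max(1L, length(keys)))
  for (i in seq_len(n)) {
    if (length(km[[i]])) {
      t <- table(factor(km[[i]], levels = keys))
      M[i, seq_along(keys)] <- as.numeric(t)
    }
  }
  nr <- sqrt(rowSums(M^2))
  Mn <- M / ifelse(nr > 0, nr, 1)
  D <- 1 - tcrossprod(Mn)
  D[D < 0] <- 0
  same <- outer(sequences, sequences, "==")
  D[same] <- 0
  diag(D) <- 0
  D
}

pad_submatrix <- function(sub_matrix) {
  # numeric copy used for profile products; gap mass is simply absent from
  # the frequency vectors, so no explicit gap row is needed
  m <- unname(sub_matrix) + 0.0
  m
}

#' Progressive multiple sequence alignment
#'
#' Guide-tree progressive alignment in the ClustalW tradition: the guide
#' tree is UPGMA (average linkage) on 3-mer cosine distances, and clusters
#' are merged by profile-profile global alignment where a column pair is
#' scored by the mean of all residue-pair substitution scores (gap pairs
#' score 0), with the same affine gap penalties as
#' [pairwise_global_align()].
#'
#' @param sequences named character vector (or list) of amino-acid strings;
#'   unnamed input gets `seq1..seqN`.
#' @param sub_matrix,gap_open,gap_extend scoring parameters.
#' @return An object of class `protein_msa`: list with `names`, `rows`
#'   (equal-length gapped strings in input order) and `n_columns`.
#' @export
progressive_msa <- function(sequences, sub_matrix = blosum62(),
                            gap_open = -10, gap_extend = -1) {
  sequences <- toupper(unlist(sequences))
  n <- length(sequences)
  if (n == 0) stop("no sequences to align")
  nm <- names(sequences) %||% paste0("seq", seq_len(n))
  if (is.null(names(sequences))) names(sequences) <- nm
  if (any(!nzchar(sequences))) stop("empty sequence cannot be aligned")
  if (n == 1) {
    return(structure(list(names = nm, rows = unname(sequences),
                          n_columns = nchar(sequences[[1]])),
                     class = "protein_msa"))
  }

  alphabet <- rownames(sub_matrix)
  K <- length(alphabet)
  S <- pad_submatrix(sub_matrix)
  enc <- lapply(sequences, function(s)
    matrix(encode_chars(strsplit(s, "")[[1]], alphabet), nrow = 1))

  hc <- hclust(as.dist(kmer_cosine_dist(unname(sequences))), method = "average")
  clusters <- vector("list", n)          # alignment matrices (codes, 0 = gap)
  members <- vector("list", n)           # original sequence indices per row
  merged <- vector("list", nrow(hc$merge))
  merged_members <- vector("list", nrow(hc$merge))
  get_cl <- function(id) if (id < 0) enc[[-id]] else merged[[id]]
  get_mb <- function(id) if (id < 0) -id else merged_members[[id]]

  for (r in seq_len(nrow(hc$merge))) {
    A <- get_cl(hc$merge[r, 1])
    B <- get_cl(hc$merge[r, 2])
    FA <- profile_freq_cpp(A, K)
    FB <- profile_freq_cpp(B, K)
    colscore <- (FA %*% S) %*% t(FB)
    mv <- nw_affine_cpp(colscore, gap_open, gap_extend)$moves
    idx <- moves_to_indices(mv)
    L <- length(mv)
    A2 <- matrix(0L, nrow(A), L)
    A2[, idx$a > 0] <- A[, idx$a[idx$a > 0], drop = FALSE]
    B2 <- matrix(0L, nrow(B), L)
    B2[, idx$b > 0] <- B[, idx$b[idx$b > 0], drop = FALSE]
    merged[[r]] <- rbind(A2, B2)
    merged_members[[r]] <- c(get_mb(hc$merge[r, 1]), get_mb(hc$merge[r, 2]))
  }
  final <- merged[[nrow(hc$merge)]]
  ord <- merged_members[[nrow(hc$merge)]]
  final <- final[order(ord), , drop = FALSE]

  rows <- apply(final, 1, function(v)
    paste(ifelse(v > 0, alphabet[pmax(v, 1L)], "-"), collapse = ""))
  structure(list(names = nm, rows = unname(rows), n_columns = ncol(final)),
            class = "protein_msa")
}

#' @export
print.protein_msa <- function(x, ...) {
  cat("protein MSA:", length(x$rows), "sequences x", x$n_columns, "columns\n")
  invisible(x)
}

#' @export
as.matrix.protein_msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$rows, ""))
  rownames(m) <- x$names
  m
}

#' Remove gaps from alignment rows
#'
#' @param aln a `protein_msa`.
#' @return Character vector of ungapped sequences, named.
#' @export
degap <- function(aln) {
  setNames(gsub("-", "", aln$rows, fixed = TRUE), aln$names)
}
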