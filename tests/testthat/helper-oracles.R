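# Independent oracles and fixture builders used across the suite.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptide <- function(len) paste(sample(AA, len, replace = TRUE), collapse = "")

# Exhaustive affine-gap global alignment score by recursive enumeration of
# every monotone alignment path (pure R; practical only for short sequences).
oracle_align_score <- function(a, b, sub = blosum62(), go = -10, ge = -1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca)
  nb <- length(cb)
  rec <- function(i, j, last) {
    if (i > na && j > nb) return(0)
    best <- -Inf
    if (i <= na && j <= nb) {
      best <- max(best, sub[ca[i], cb[j]] + rec(i + 1L, j + 1L, 0L))
    }
    if (i <= na) best <- max(best, (if (last == 1L) ge else go) + rec(i + 1L, j, 1L))
    if (j <= nb) best <- max(best, (if (last == 2L) ge else go) + rec(i, j + 1L, 2L))
    best
  }
  rec(1L, 1L, 0L)
}

# Fast exhaustive enumerator (compiled); validated against the pure-R
# recursion in test-align.R before being used at criterion scale.
enum_align_score <- function(a, b, sub = blosum62(), go = -10, ge = -1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  S <- sub[ca, cb, drop = FALSE]
  wrkycatalog:::enum_align_score_cpp(unname(S) + 0.0, go, ge)
}

# Random unrooted tree with positive branch lengths and its (additive)
# path-length matrix.
random_additive <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# Exhaustive scan of the NJ join criterion Q(i,j) = (n-2) d(i,j) - R_i - R_j
# by scalar double loops. Returns the minimum and a per-pair evaluator so a
# chosen pair can be checked against the minimum (mathematically tied pairs -
# both cherries of an additive 4-taxon matrix, say - differ only in floating
# point noise between evaluation orders, so argmin identity is asserted up to
# tolerance and exact tie-breaking is exercised on integer matrices).
oracle_q <- function(d) {
  k <- nrow(d)
  R <- rowSums(d)
  qij <- function(i, j) (k - 2) * d[i, j] - R[i] - R[j]
  qmin <- Inf
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) qmin <- min(qmin, qij(i, j))
  }
  list(min = qmin, q = qij)
}

# Per-copy table realising the catalogued wheat family architecture:
# 75 A:B:D triads, 1 A:B, 12 A:D, 7 B:D, 10 A, 4 B, 15 D singletons over
# chromosome complements (24, 19, 19, 19, 19, 5, 19).
table1_copies <- function() {
  type_counts <- c("A:B:D" = 75, "A:B" = 1, "A:D" = 12, "B:D" = 7,
                   "A" = 10, "B" = 4, "D" = 15)
  complements <- rep(1:7, c(24, 19, 19, 19, 19, 5, 19))
  types <- rep(names(type_counts), type_counts)
  rows <- lapply(seq_along(types), function(k) {
    sgs <- strsplit(types[k], ":")[[1]]
    data.frame(gene_id = sprintf("g%d_c%d%s", k, complements[k], sgs),
               record_id = sprintf("g%d_c%d%s.1", k, complements[k], sgs),
               subgenome = sgs, complement = complements[k],
               chromosome = paste0(complements[k], sgs),
               start = 1000L * k, end = 1000L * k + 500L,
               group_id = sprintf("G%03d", k), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# A compact simulation configuration for fast unit tests.
small_sim <- function(seed = 3) {
  sim_config(seed = seed,
             type_counts = c("A:B:D" = 4, "A:D" = 2, "B" = 2),
             per_complement_counts = c("1" = 2, "2" = 1, "3" = 1, "4" = 1,
                                       "5" = 1, "6" = 1, "7" = 1),
             group_plan = c(I = 4, II = 8, III = 6),
             n_multi_isoform = 3, extra_isoforms_total = 4, n_background = 20)
}

# Two well-separated clades of near-identical sequences.
two_clade_sequences <- function(seed = 11, per_clade = 3, len = 80) {
  set.seed(seed)
  base1 <- random_peptide(len)
  base2 <- random_peptide(len)
  jitter <- function(s) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), 2)
    ch[pos] <- sample(AA, 2, replace = TRUE)
    paste(ch, collapse = "")
  }
  out <- c(vapply(seq_len(per_clade), function(i) jitter(base1), character(1)),
           vapply(seq_len(per_clade), function(i) jitter(base2), character(1)))
  names(out) <- c(paste0("a", seq_len(per_clade)), paste0("b", seq_len(per_clade)))
  out
}
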