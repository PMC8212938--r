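#' Pairwise distances from a multiple alignment
#'
#' p-distance is the fraction of mismatching residues over comparable
#' columns, comparing each pair under pairwise deletion (columns where
#' either row is gapped are skipped for that pair). The Poisson-corrected
#' distance is `-ln(1 - p)`.
#'
#' @param aln a `protein_msa` (or a character matrix of gapped rows with
#'   `-` as gap).
#' @param model `"p_distance"` (default) or `"poisson"`.
#' @param on_empty what to do when a pair shares no comparable column:
#'   `"error"` (default, naming the pair) or `"max"` (distance 1, used
#'   internally by bootstrap resampling where a pathological resample must
#'   not abort the replicate).
#' @return A symmetric numeric matrix with zero diagonal and sequence names
#'   as dimnames.
#' @export
distance_from_alignment <- function(aln, model = c("p_distance", "poisson"),
                                    on_empty = c("error", "max")) {
  model <- match.arg(model)
  on_empty <- match.arg(on_empty)
  m <- if (inherits(aln, "protein_msa")) as.matrix(aln) else aln
  stopifnot(is.matrix(m), nrow(m) >= 2)
  nm <- rownames(m) %||% paste0("seq", seq_len(nrow(m)))
  codes <- matrix(match(m, sort(unique(as.vector(m)))), nrow = nrow(m))
  codes[m == "-"] <- 0L
  storage.mode(codes) <- "integer"
  r <- aln_pdist_cpp(codes)
  comp <- r$comparable
  diag(comp) <- 1L
  if (any(comp == 0)) {
    if (on_empty == "error") {
      ij <- which(comp == 0, arr.ind = TRUE)[1, ]
      stop("no comparable alignment columns between '", nm[min(ij)], "' and '",
           nm[max(ij)], "'")
    }
    p <- ifelse(comp == 0, 1, r$mismatches / comp)
  } else {
    p <- r$mismatches / comp
  }
  d <- switch(model,
              p_distance = p,
              poisson = {
                if (any(p >= 1)) stop("saturated p-distance (p >= 1); Poisson correction undefined")
                -log(1 - p)
              })
  diag(d) <- 0
  dimnames(d) <- list(nm, nm)
  validate_distance_matrix(d)
  d
}

validate_distance_matrix <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (any(is.na(d))) stop("distance matrix contains NA")
  if (any(d < 0)) stop("distance matrix has negative entries")
  if (any(abs(d - t(d)) > 1e-8)) stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal is not zero")
  invisible(d)
}

#' Neighbor-joining tree construction
#'
#' Standard neighbor joining: at each step join the pair minimising
#' `Q(i, j) = (n - 2) d(i, j) - R_i - R_j` with `R_i = sum_k d(i, k)`;
#' branch lengths follow the two-point formulas, with negative lengths
#' clamped to zero and the deficit transferred to the sister branch so the
#' joined pair's path length is preserved. Ties on Q are broken by the
#' smallest (i, j) index pair in the current matrix. The last three nodes
#' are joined into a trifurcation, giving the usual unrooted-tree
#' representation.
#'
#' @param dm symmetric distance matrix (zero diagonal) with unique labels,
#'   n >= 3; a `dist` object is also accepted.
#' @param trace if `TRUE`, attach the per-step distance matrices and chosen
#'   pairs as attribute `"join_trace"` (used for oracle testing).
#' @return A `phylo` object with a trifurcating root.
#' @export
neighbor_joining <- function(dm, trace = FALSE) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  validate_distance_matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("neighbor joining requires at least 3 taxa")
  labels <- rownames(dm) %||% paste0("t", seq_len(n))
  if (anyDuplicated(labels)) stop("duplicate taxon labels")
  if (any(grepl("[(),:;]", labels))) stop("taxon labels may not contain newick metacharacters")

  frag <- labels
  d <- unname(dm)
  steps <- list()
  while (nrow(d) > 3) {
    k <- nrow(d)
    R <- rowSums(d)
    Q <- (k - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 0, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]
    j <- cand[1, 2]
    if (trace) steps[[length(steps) + 1L]] <- list(d = d, pair = c(i, j))
    bi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (k - 2))
    bj <- d[i, j] - bi
    if (bi < 0) { bi <- 0; bj <- d[i, j] }
    if (bj < 0) { bj <- 0; bi <- d[i, j] }
    newfrag <- sprintf("(%s:%.17g,%s:%.17g)", frag[i], bi, frag[j], bj)
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    d[i, ] <- dk
    d[, i] <- dk
    d[i, i] <- 0
    frag[i] <- newfrag
    d <- d[-j, -j, drop = FALSE]
    frag <- frag[-j]
  }
  if (trace) steps[[length(steps) + 1L]] <- list(d = d, pair = c(1L, 2L))
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  b1 <- max(b1, 0); b2 <- max(b2, 0); b3 <- max(b3, 0)
  txt <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);", frag[1], b1, frag[2], b2,
                 frag[3], b3)
  tree <- ape::read.tree(text = txt)
  if (trace) attr(tree, "join_trace") <- steps
  tree
}

#' Canonical leaf bipartitions of an unrooted tree
#'
#' Each internal edge splits the leaves in two; the split is reported as the
#' sorted side not containing the alphabetically first label, so the same
#' bipartition always yields the same string regardless of rooting.
#'
#' @param phy a `phylo` object.
#' @return Named character vector: names are internal node numbers (as
#'   character), values the canonical split strings. The root node is
#'   omitted (its "edge" is not a real edge).
#' @export
tree_bipartitions <- function(phy) {
  ntip <- length(phy$tip.label)
  anchor <- sort(phy$tip.label)[1]
  parts <- ape::prop.part(phy)
  out <- character(0)
  for (k in seq_along(parts)) {
    node <- ntip + k
    if (node == ntip + 1L) next  # root
    tips <- phy$tip.label[parts[[k]]]
    side <- if (anchor %in% tips) setdiff(phy$tip.label, tips) else tips
    if (length(side) < 2 || length(side) > ntip - 2) next  # trivial split
    out[[as.character(node)]] <- paste(sort(side), collapse = "|")
  }
  out
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Aligns the sequences, builds the NJ tree, then resamples alignment
#' columns with replacement `n_reps` times; the support of an internal edge
#' is the percentage of replicate trees containing the same leaf
#' bipartition. Supports are stored as integer node labels (the root label
#' is empty). Reproducible for a fixed `seed`.
#'
#' @param sequences named amino-acid strings (>= 3).
#' @param n_reps number of bootstrap replicates (>= 1; 100 at desk scale,
#'   1000 to mirror large published analyses).
#' @param seed integer seed governing the resampling.
#' @param model distance model, see [distance_from_alignment()].
#' @param sub_matrix,gap_open,gap_extend alignment scoring parameters.
#' @return A `phylo` object whose `node.label` holds bootstrap percentages.
#' @export
bootstrap_support <- function(sequences, n_reps = 100, seed = 1,
                              model = "p_distance", sub_matrix = blosum62(),
                              gap_open = -10, gap_extend = -1) {
  stopifnot(n_reps >= 1)
  aln <- progressive_msa(sequences, sub_matrix = sub_matrix,
                         gap_open = gap_open, gap_extend = gap_extend)
  tree <- neighbor_joining(distance_from_alignment(aln, model))
  attach_bootstrap(aln, tree, n_reps = n_reps, seed = seed, model = model)
}

# Shared by bootstrap_support() and the pipeline (which already has the MSA).
attach_bootstrap <- function(aln, tree, n_reps, seed, model = "p_distance") {
  m <- as.matrix(aln)
  L <- ncol(m)
  target <- tree_bipartitions(tree)
  counts <- setNames(integer(length(target)), names(target))
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    mb <- m[, cols, drop = FALSE]
    db <- distance_from_alignment(mb, model, on_empty = "max")
    tb <- neighbor_joining(db)
    got <- tree_bipartitions(tb)
    counts <- counts + as.integer(target %in% got)
  }
  ntip <- length(tree$tip.label)
  labs <- rep("", tree$Nnode)
  idx <- as.integer(names(target)) - ntip
  labs[idx] <- as.character(as.integer(round(100 * counts / n_reps)))
  tree$node.label <- labs
  tree
}

#' Bootstrap support for a specific leaf bipartition
#'
#' @param phy a tree with bootstrap node labels (see [bootstrap_support()]).
#' @param tips character vector of tip labels forming one side of the split.
#' @return The integer support, or `NA` if the tree does not contain the
#'   bipartition.
#' @export
split_support <- function(phy, tips) {
  anchor <- sort(phy$tip.label)[1]
  side <- if (anchor %in% tips) setdiff(phy$tip.label, tips) else tips
  key <- paste(sort(side), collapse = "|")
  bp <- tree_bipartitions(phy)
  hit <- names(bp)[bp == key]
  if (!length(hit)) return(NA_integer_)
  ntip <- length(phy$tip.label)
  as.integer(phy$node.label[as.integer(hit[1]) - ntip])
}
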