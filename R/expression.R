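STRESSES <- c("cold", "drought", "heat", "PEG")

#' Build a qPCR Ct record
#'
#' Cycle-threshold measurements for one gene in one sample. Replicate
#' cycles may be supplied as vectors; they are averaged (arithmetic mean of
#' cycles) before any delta-Ct arithmetic.
#'
#' @param gene gene identifier.
#' @param sample sample label.
#' @param ct_target Ct value(s) of the target gene.
#' @param ct_reference Ct value(s) of the endogenous reference gene.
#' @return A list of class `ct_record`.
#' @export
ct_record <- function(gene, sample, ct_target, ct_reference) {
  stopifnot(is.numeric(ct_target), is.numeric(ct_reference))
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)) ||
      any(ct_target <= 0) || any(ct_reference <= 0)) {
    stop("Ct values must be finite and positive")
  }
  structure(list(gene = gene, sample = sample,
                 ct_target = ct_target, ct_reference = ct_reference),
            class = "ct_record")
}

#' Relative expression by the 2^-ddCt (Livak) method
#'
#' `dCt = Ct(target) - Ct(reference)` within each sample, `ddCt =
#' dCt(treated) - dCt(control)`, and the fold change is `2^-ddCt`; 1 means
#' no change. Replicates are averaged before the subtraction.
#'
#' @param treated,control `ct_record`s (or plain lists with the same
#'   fields) for the same gene.
#' @return Fold change (numeric scalar).
#' @examples
#' trt <- ct_record("g1", "stress", 24, 20)
#' ctl <- ct_record("g1", "mock", 26, 20)
#' relative_expression(trt, ctl) # ddCt = -2 -> 4
#' @export
relative_expression <- function(treated, control) {
  if (!identical(treated$gene, control$gene)) {
    stop("treated and control records are for different genes: ",
         treated$gene, " vs ", control$gene)
  }
  dct_t <- mean(treated$ct_target) - mean(treated$ct_reference)
  dct_c <- mean(control$ct_target) - mean(control$ct_reference)
  2^(-(dct_t - dct_c))
}

#' Log2-transform a TPM expression matrix
#'
#' @param m nonnegative numeric matrix of TPM values (genes x conditions).
#' @param pseudocount positive offset added before the log (default 1).
#' @return `log2(m + pseudocount)`, same shape.
#' @export
log2_transform <- function(m, pseudocount = 1) {
  stopifnot(is.numeric(m))
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (any(m < 0, na.rm = TRUE)) stop("negative TPM values are not allowed")
  log2(m + pseudocount)
}

#' Multi-stress responsiveness filter
#'
#' A gene detected (TPM at or above `detect_threshold`) under at most one of
#' the four abiotic stresses - cold, drought, heat, PEG - is classed
#' `non_responsive`; a gene detected under two or more is `multi_stress`
#' (it responds to at least two types of stress).
#'
#' @param m TPM matrix with genes as rows; columns must include `cold`,
#'   `drought`, `heat`, `PEG` (extra columns are ignored).
#' @param detect_threshold detection cutoff in TPM units (default 0.5).
#' @return Named character vector of classes, one per gene.
#' @export
stress_response_filter <- function(m, detect_threshold = 0.5) {
  stopifnot(is.matrix(m) || is.data.frame(m))
  m <- as.matrix(m)
  missing <- setdiff(STRESSES, colnames(m))
  if (length(missing)) {
    stop("missing stress column(s): ", paste(missing, collapse = ", "))
  }
  if (any(m < 0, na.rm = TRUE)) stop("negative TPM values are not allowed")
  detected <- m[, STRESSES, drop = FALSE] >= detect_threshold
  n <- rowSums(detected)
  out <- ifelse(n >= 2, "multi_stress", "non_responsive")
  names(out) <- rownames(m) %||% as.character(seq_len(nrow(m)))
  out
}
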