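# Global quality score: the mean of valid per-residue predictions, an
# optional coverage pre-factor that mimics lDDT's penalty for incomplete
# models, and a length-windowed expected-error estimate derived from a
# reference set of (model length, |predicted - actual global lDDT|) pairs.

#' Global score from per-residue predictions
#'
#' @param per_residue numeric predictions in [0,1], NA = invalid.
#' @return arithmetic mean of the valid values.
#' @export
global_from_local <- function(per_residue) {
  ok <- !is.na(per_residue)
  if (!any(ok)) stop("no valid per-residue predictions")
  mean(per_residue[ok])
}

#' Coverage-normalized global score
#'
#' Multiplies the global score by the fraction of target-sequence residues
#' covered by the model. Coverage counts model residues that align to the
#' target sequence (sequence match), not the raw residue count.
#'
#' @param global global score in [0,1].
#' @param model a `structure3d`.
#' @param target_sequence the full target sequence (one-letter string).
#' @return coverage x global.
#' @export
coverage_normalize <- function(global, model, target_sequence) {
  if (nchar(target_sequence) == 0) stop("empty target sequence")
  if (n_residues(model) == 0) stop("empty model")
  cov <- model_coverage(model, target_sequence)
  cov * global
}

#' Fraction of the target sequence covered by a model
#' @inheritParams coverage_normalize
#' @export
model_coverage <- function(model, target_sequence) {
  tseq <- strsplit(target_sequence, "")[[1]]
  mseq <- model$aa
  # greedy order-preserving subsequence match: counts exactly the model
  # residues that can be aligned to the target in sequence order
  ti <- 1L
  n_mapped <- 0L
  for (a in mseq) {
    while (ti <= length(tseq) && tseq[ti] != a) ti <- ti + 1L
    if (ti > length(tseq)) break
    n_mapped <- n_mapped + 1L
    ti <- ti + 1L
  }
  min(1, n_mapped / length(tseq))
}

#' Expected-error model
#'
#' @param model_length integer vector of reference model lengths.
#' @param abs_error numeric vector |predicted - actual global lDDT|.
#' @param half_width window half-width in residues (default 40).
#' @return object of class `error_model`.
#' @export
error_model <- function(model_length, abs_error, half_width = 40) {
  stopifnot(length(model_length) == length(abs_error),
            length(abs_error) >= 1, all(abs_error >= 0))
  structure(list(length = as.integer(model_length),
                 err = as.numeric(abs_error),
                 half_width = half_width), class = "error_model")
}

#' Expected global-score error for a model length
#'
#' Root-mean-square of the reference absolute errors from models of
#' length within l +/- half_width. An empty window widens to the 30
#' nearest reference points (or all, if fewer exist).
#'
#' @param em an [error_model()].
#' @param model_length query length l.
#' @return expected error (lDDT units).
#' @export
expected_error <- function(em, model_length) {
  sel <- abs(em$length - model_length) <= em$half_width
  if (!any(sel)) {
    k <- min(30, length(em$err))
    sel <- order(abs(em$length - model_length))[seq_len(k)]
  }
  sqrt(mean(em$err[sel]^2))
}
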