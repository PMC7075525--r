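#' lDDT parameters
#'
#' The local Distance Difference Test counts, over all reference atom pairs
#' within an inclusion radius, how often the model reproduces the reference
#' distance within a set of deviation thresholds. Defaults follow the
#' standard parametrization: 15 A inclusion radius and thresholds
#' 0.5, 1, 2, 4 A.
#'
#' @param inclusion_radius inclusion radius in Angstrom.
#' @param thresholds strictly increasing deviation thresholds in Angstrom.
#' @return list of class `lddt_params`.
#' @export
lddt_params <- function(inclusion_radius = 15, thresholds = c(0.5, 1, 2, 4)) {
  stopifnot(all(diff(thresholds) > 0), all(thresholds > 0),
            inclusion_radius > max(thresholds))
  structure(list(inclusion_radius = inclusion_radius,
                 thresholds = thresholds),
            class = "lddt_params")
}

# atom table of a structure restricted for lDDT: for residues whose
# amino-acid identity differs between model and reference, side-chain atoms
# beyond CB are ignored.
.lddt_ref_atoms <- function(reference, keep_full) {
  at <- reference$atoms
  bb <- at$name %in% c("N", "CA", "C", "O", "CB")
  at[keep_full[at$res] | bb, , drop = FALSE]
}

#' Compute per-residue and global lDDT
#'
#' Superposition-free comparison of a model against a reference structure.
#' Every reference heavy-atom pair from different residues with distance
#' below the inclusion radius contributes one check per threshold; a check
#' is conserved iff both atoms exist in the model and the model distance
#' deviates from the reference distance by less than the threshold. Atoms
#' missing from the model fail their checks; atoms present only in the
#' model are ignored.
#'
#' @param model,reference `structure3d` objects.
#' @param mapping integer vector, one entry per model residue, giving the
#'   matching reference residue index (NA = unmapped). Default: identity
#'   (requires equal lengths).
#' @param params an [lddt_params()].
#' @return list of class `lddt_result` with `per_residue` (model-indexed,
#'   NA where the residue has no reference contacts or no mapping),
#'   `global_score` (pooled conserved / pooled total, not a mean of
#'   per-residue values), and `conserved` / `total` counts per model residue.
#' @export
compute_lddt <- function(model, reference, mapping = NULL,
                         params = lddt_params()) {
  nm <- n_residues(model)
  nr <- n_residues(reference)
  if (is.null(mapping)) {
    if (nm != nr)
      stop("default identity mapping requires equal residue counts")
    mapping <- seq_len(nm)
  }
  stopifnot(length(mapping) == nm)
  if (all(is.na(mapping))) stop("empty model-to-reference mapping")
  if (nrow(reference$atoms) == 0) stop("reference has no coordinates")

  # reference residue -> model residue (inverse of mapping)
  inv <- rep(NA_integer_, nr)
  inv[mapping[!is.na(mapping)]] <- which(!is.na(mapping))

  keep_full <- rep(FALSE, nr)
  mapped <- which(!is.na(inv))
  keep_full[mapped] <- model$aa[inv[mapped]] == reference$aa[mapped]
  rat <- .lddt_ref_atoms(reference, keep_full)

  rxyz <- as.matrix(rat[, c("x", "y", "z")])
  rres <- rat$res
  # model coordinates for each reference atom (NA when absent)
  mkey <- paste(model$atoms$res, model$atoms$name)
  rkey <- paste(inv[rres], rat$name)
  mi <- match(rkey, mkey)
  mxyz <- matrix(NA_real_, nrow(rat), 3)
  got <- !is.na(mi)
  mxyz[got, ] <- as.matrix(model$atoms[mi[got], c("x", "y", "z")])

  dr <- cross_dist(rxyz, rxyz)
  pair <- which(upper.tri(dr) & dr < params$inclusion_radius &
                  outer(rres, rres, "!="), arr.ind = TRUE)
  nth <- length(params$thresholds)
  n <- n_residues(model)
  cons <- tot <- rep(0, n)
  if (nrow(pair) > 0) {
    a <- pair[, 1]; b <- pair[, 2]
    dref <- dr[pair]
    dmod <- sqrt(rowSums((mxyz[a, , drop = FALSE] -
                            mxyz[b, , drop = FALSE])^2))
    dev <- abs(dmod - dref)           # NA when an atom is missing
    nc <- rowSums(outer(dev, params$thresholds, "<"))
    nc[is.na(dmod)] <- 0
    # accumulate per *model* residue (via reference residue mapping)
    for (side in list(a, b)) {
      mres <- inv[rres[side]]
      ok <- !is.na(mres)
      f <- factor(mres[ok], levels = seq_len(n))
      tot <- tot + as.numeric(tapply(rep(nth, sum(ok)), f, sum, default = 0))
      cons <- cons + as.numeric(tapply(nc[ok], f, sum, default = 0))
    }
    global <- sum(nc) / (nth * nrow(pair))
  } else {
    global <- NA_real_
  }
  per <- ifelse(tot > 0, cons / tot, NA_real_)
  structure(list(per_residue = per, global_score = global,
                 conserved = cons, total = tot),
            class = "lddt_result")
}

#' Binary correctness labels from per-residue scores
#'
#' Residues with score strictly above `cut` are labelled correctly
#' modelled (1), others 0; invalid scores stay NA (excluded downstream).
#'
#' @param per_residue numeric scores in [0,1] or NA.
#' @param cut classification cut (default 0.6).
#' @return integer vector of 0/1/NA.
#' @export
classify_correct <- function(per_residue, cut = 0.6) {
  stopifnot(all(per_residue >= 0 & per_residue <= 1, na.rm = TRUE))
  out <- ifelse(per_residue > cut, 1L, 0L)
  out[is.na(per_residue)] <- NA_integer_
  out
}
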