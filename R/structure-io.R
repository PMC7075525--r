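#' Structure container
#'
#' A parsed single-chain polymer structure. Residues are indexed 1..n in
#' chain order; author numbering is kept as metadata only. Atom records live
#' in a single data frame, one row per (residue, atom name).
#'
#' @param id structure identifier.
#' @param aa character vector of one-letter amino-acid codes ('X' for
#'   non-standard residues).
#' @param resno integer vector of author residue numbers.
#' @param inscode character vector of insertion codes ("" if none).
#' @param atoms data frame with columns `res` (1-based residue index),
#'   `name` (canonical atom name, e.g. "CA"), `el` (element symbol) and
#'   `x`, `y`, `z` (Angstrom).
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(id, aa, resno = seq_along(aa),
                        inscode = rep("", length(aa)), atoms) {
  stopifnot(is.character(aa), length(aa) >= 1,
            all(atoms$res >= 1), all(atoms$res <= length(aa)),
            all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
  s <- list(id = as.character(id), aa = aa, resno = as.integer(resno),
            inscode = as.character(inscode),
            atoms = as.data.frame(atoms, stringsAsFactors = FALSE))
  class(s) <- "structure3d"
  s
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d '%s': %d residues, %d atoms\n",
              x$id, n_residues(x), nrow(x$atoms)))
  invisible(x)
}

#' Number of residues in a structure
#' @param s a `structure3d`.
#' @export
n_residues <- function(s) length(s$aa)

# Coordinate matrix (n x 3, NA rows where absent) of one named atom per
# residue. The workhorse accessor for CA/N/C/O/CB positions.
atom_matrix <- function(s, name) {
  n <- n_residues(s)
  m <- matrix(NA_real_, n, 3)
  sel <- s$atoms$name == name
  m[s$atoms$res[sel], ] <- as.matrix(s$atoms[sel, c("x", "y", "z")])
  m
}

# TRUE where N, CA and C are all present.
backbone_complete <- function(s) {
  has <- function(nm) !is.na(atom_matrix(s, nm)[, 1])
  has("N") & has("CA") & has("C")
}

.STD_AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
              MSE = "M")

#' Read a single chain from a PDB file
#'
#' Parses ATOM records of the selected (default: first) chain into a
#' [structure3d()]. Waters, HETATM records and hydrogens are dropped; when
#' alternate locations are present, the highest-occupancy altloc is kept
#' (ties resolved in favour of the altloc that sorts first). Non-standard
#' residues get the one-letter code 'X' (selenomethionine maps to 'M').
#'
#' @param path PDB file path.
#' @param chain optional one-character chain identifier.
#' @return A [structure3d()].
#' @export
read_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$elesy %in% c("H", "D")) &
             !grepl("^[0-9]*H", at$elety), , drop = FALSE]
  if (is.null(chain)) {
    chains <- unique(at$chain)
    chain <- chains[1]
  }
  at <- at[at$chain %in% chain, , drop = FALSE]
  known <- at$resid %in% names(.STD_AA3)
  at <- at[known, , drop = FALSE]
  if (nrow(at) == 0)
    stop("no amino-acid residues found in '", path, "'",
         if (!is.null(chain)) paste0(" (chain ", chain, ")"))

  ins <- ifelse(is.na(at$insert), "", at$insert)
  rkey <- paste(at$resno, ins, sep = "|")
  ridx <- match(rkey, unique(rkey))

  # altloc resolution: per residue+atom name keep highest occupancy
  at$o[is.na(at$o)] <- 1
  alt <- ifelse(is.na(at$alt), "", at$alt)
  ord <- order(ridx, at$elety, -at$o, alt)
  at <- at[ord, , drop = FALSE]
  ridx <- ridx[ord]
  keep <- !duplicated(paste(ridx, at$elety))
  at <- at[keep, , drop = FALSE]
  ridx <- ridx[keep]

  first <- !duplicated(ridx)
  aa <- unname(.STD_AA3[at$resid[first]])
  aa[is.na(aa)] <- "X"
  structure3d(
    id = sub("\\.pdb$", "", basename(path)),
    aa = aa,
    resno = at$resno[first],
    inscode = ifelse(is.na(at$insert[first]), "", at$insert[first]),
    atoms = data.frame(res = ridx, name = at$elety,
                       el = at$elesy, x = at$x, y = at$y, z = at$z,
                       stringsAsFactors = FALSE))
}

#' One-letter sequence of a structure
#' @param s a `structure3d`.
#' @return A single string, residues in index order.
#' @export
extract_sequence <- function(s) {
  if (n_residues(s) == 0) stop("empty structure")
  paste(s$aa, collapse = "")
}

#' Sparse C-alpha distance map
#'
#' All unordered residue pairs i < j whose C-alpha atoms are both present
#' and closer than `cutoff` (strict).
#'
#' @param s a `structure3d`.
#' @param cutoff distance cutoff in Angstrom (> 0).
#' @return data frame with columns `i`, `j`, `d`.
#' @export
ca_distance_map <- function(s, cutoff) {
  stopifnot(cutoff > 0)
  ca <- atom_matrix(s, "CA")
  ok <- which(!is.na(ca[, 1]))
  if (length(ok) < 2)
    return(data.frame(i = integer(), j = integer(), d = numeric()))
  d <- cross_dist(ca[ok, , drop = FALSE], ca[ok, , drop = FALSE])
  idx <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  out <- data.frame(i = ok[idx[, 1]], j = ok[idx[, 2]],
                    d = d[idx])
  out[order(out$i, out$j), , drop = FALSE]
}

# Ideal tetrahedral C-beta construction from backbone geometry. Used for
# glycine and any residue whose CB is missing.
.cb_from_backbone <- function(n, ca, c) {
  # standard tetrahedral construction for an L-amino acid; direction from
  # the backbone frame, re-scaled to the ideal 1.53 A CA-CB bond
  b <- ca - n
  cc <- c - ca
  a <- vcross(b, cc)
  dir <- -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc
  ca + 1.53 * unitv(dir)
}

#' C-beta representative positions
#'
#' Per residue: the actual CB coordinate when present, otherwise an ideal
#' tetrahedral CB inferred from the N, CA and C backbone positions (bond
#' length 1.53 A). Residues with incomplete backbones and no CB are invalid.
#'
#' @param s a `structure3d`.
#' @return list with `xyz` (n x 3 matrix) and `valid` (logical vector).
#' @export
cb_coords <- function(s) {
  cb <- atom_matrix(s, "CB")
  nmat <- atom_matrix(s, "N"); camat <- atom_matrix(s, "CA")
  cmat <- atom_matrix(s, "C")
  valid <- !is.na(cb[, 1])
  for (i in which(!valid)) {
    if (!any(is.na(c(nmat[i, ], camat[i, ], cmat[i, ])))) {
      cb[i, ] <- .cb_from_backbone(nmat[i, ], camat[i, ], cmat[i, ])
      valid[i] <- TRUE
    }
  }
  list(xyz = cb, valid = valid)
}

#' Write a structure with per-residue scores in the B-factor column
#'
#' Scores in [0, 1] are written as score x 100 for every atom of the
#' residue; invalid scores (NA) use the sentinel 99.99.
#'
#' @param s a `structure3d`.
#' @param scores numeric vector, one per residue, values in [0,1] or NA.
#' @param path output file path.
#' @export
write_scored_pdb <- function(s, scores, path) {
  if (length(scores) != n_residues(s))
    stop("need exactly one score per residue")
  if (any(!is.na(scores) & (scores < 0 | scores > 1)))
    stop("scores must lie in [0, 1] or be NA")
  b <- ifelse(is.na(scores), 99.99, round(scores * 100, 2))
  at <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = s$resno[at$res],
                   resid = vapply(s$aa[at$res], function(a) {
                     hit <- names(.STD_AA3)[match(a, .STD_AA3)]
                     if (is.na(hit)) "UNK" else hit
                   }, ""),
                   elety = at$name,
                   chain = rep("A", nrow(at)),
                   o = rep(1, nrow(at)),
                   b = b[at$res])
  invisible(path)
}

#' Read a FASTA file (first record)
#' @param path FASTA file.
#' @return Named character: the sequence, name = record id.
#' @export
read_fasta_seq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no FASTA record in ", path)
  id <- sub("^>\\s*(\\S+).*", "\\1", lines[heads[1]])
  to <- if (length(heads) > 1) heads[2] - 1 else length(lines)
  seq <- paste(lines[(heads[1] + 1):to], collapse = "")
  stats::setNames(gsub("\\s", "", seq), id)
}
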