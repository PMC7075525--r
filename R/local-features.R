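# Non-potential single-model terms: a DSSP-equivalent 8-state secondary
# structure assignment with Shrake-Rupley solvent accessibility, agreement
# scores against sequence-based predictions (PSIPRED-style 3-state +
# confidence, ACCpro-style 2-state burial), a SCWRL3-style hard-sphere
# clash score, the local residue count N, and Gaussian spherical smoothing.

# ---- DSSP-equivalent assignment ------------------------------------------

# Kabsch-Sander electrostatic H-bond energy; donor NH(i), acceptor C=O(j).
# H is placed 1.0 A from N along the bisector of (N - C_prev) and (N - CA).
.hbond_energies <- function(nmat, camat, cmat, omat) {
  n <- nrow(nmat)
  h <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    if (anyNA(c(nmat[i, ], camat[i, ], cmat[i - 1, ]))) next
    d1 <- nmat[i, ] - cmat[i - 1, ]
    d2 <- nmat[i, ] - camat[i, ]
    if (vnorm(d1) < 1e-6 || vnorm(d2) < 1e-6) next
    h[i, ] <- nmat[i, ] + unitv(unitv(d1) + unitv(d2))
  }
  q <- 0.42 * 0.20 * 332
  E <- matrix(Inf, n, n)            # E[i, j]: donor i, acceptor j
  for (i in 2:n) {
    if (anyNA(h[i, ])) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2) next      # no bond to self or direct neighbour
      if (anyNA(c(omat[j, ], cmat[j, ]))) next
      rON <- vnorm(nmat[i, ] - omat[j, ])
      if (rON > 5.2) next           # beyond any plausible H-bond
      rCH <- vnorm(h[i, ] - cmat[j, ])
      rOH <- vnorm(h[i, ] - omat[j, ])
      rCN <- vnorm(nmat[i, ] - cmat[j, ])
      if (min(rON, rCH, rOH, rCN) < 0.5) { E[i, j] <- -9.9; next }
      E[i, j] <- q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    }
  }
  E
}

# 8-state assignment from the H-bond pattern (states G,H,I,E,B,T,S,C).
# Helices from consecutive n-turns, strands/bridges from parallel and
# antiparallel bridge patterns, T for turn membership, S for bends.
.dssp_states <- function(s) {
  n <- n_residues(s)
  nmat <- atom_matrix(s, "N"); camat <- atom_matrix(s, "CA")
  cmat <- atom_matrix(s, "C"); omat <- atom_matrix(s, "O")
  state <- rep("C", n)
  if (n < 3) return(state)
  E <- .hbond_energies(nmat, camat, cmat, omat)
  hb <- E < -0.5                     # hb[donor, acceptor]
  turn <- function(k) {              # k-turn at i: CO(i) accepts NH(i+k)
    t <- rep(FALSE, n)
    idx <- seq_len(n - k)
    t[idx] <- hb[cbind(idx + k, idx)]
    t
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)

  # bridges
  para <- anti <- matrix(FALSE, n, n)
  for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
    if (abs(i - j) < 3) next
    if ((hb[i, j - 1] && hb[j + 1, i]) || (hb[j, i - 1] && hb[i + 1, j]))
      para[i, j] <- TRUE
    if ((hb[i, j] && hb[j, i]) || (hb[i + 1, j - 1] && hb[j + 1, i - 1]))
      anti[i, j] <- TRUE
  }
  bridge <- para | anti
  has_bridge <- apply(bridge, 1, any)
  # extended: bridge residue adjacent (in sequence) to another bridge
  ext <- has_bridge &
    (c(FALSE, has_bridge[-n]) | c(has_bridge[-1], FALSE))

  # helices: two consecutive k-turns put k residues in a helix
  mark_helix <- function(tk, k) {
    m <- rep(FALSE, n)
    for (i in 2:(n - k)) if (tk[i - 1] && tk[i]) m[i:(i + k - 1)] <- TRUE
    m
  }
  h4 <- mark_helix(t4, 4)
  h3 <- mark_helix(t3, 3)
  h5 <- mark_helix(t5, 5)

  # bends: CA direction change > 70 degrees
  bend <- rep(FALSE, n)
  for (i in 3:(n - 2)) {
    if (anyNA(c(camat[i - 2, ], camat[i, ], camat[i + 2, ]))) next
    u <- camat[i, ] - camat[i - 2, ]
    v <- camat[i + 2, ] - camat[i, ]
    a <- acos(max(-1, min(1, sum(unitv(u) * unitv(v))))) * 180 / pi
    bend[i] <- a > 70
  }
  in_turn <- rep(FALSE, n)
  for (k in 3:5) {
    tk <- list(t3, t4, t5)[[k - 2]]
    for (i in which(tk)) in_turn[pmin(n, (i + 1):(i + k - 1))] <- TRUE
  }

  state[bend] <- "S"
  state[in_turn] <- "T"
  state[h5] <- "I"
  state[h3] <- "G"
  state[has_bridge & !ext] <- "B"
  state[ext] <- "E"
  state[h4] <- "H"
  state
}

# ---- Shrake-Rupley solvent accessibility ---------------------------------

.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# deterministic unit sphere points (golden-section spiral)
.sphere_points <- function(m) {
  k <- seq_len(m) - 0.5
  phi <- acos(1 - 2 * k / m)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# per-atom solvent-accessible surface area, probe 1.4 A
.sasa_atoms <- function(xyz, el, probe = 1.4, n_points = 92) {
  r <- .VDW[el]
  r[is.na(r)] <- 1.7
  r <- r + probe
  n <- nrow(xyz)
  pts <- .sphere_points(n_points)
  d <- cross_dist(xyz, xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < r[i] + r & seq_len(n) != i)
    p <- pts * r[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    if (length(nb) > 0) {
      dd <- cross_dist(p, xyz[nb, , drop = FALSE])
      free <- rowSums(dd < rep(r[nb], each = n_points)) == 0
    } else free <- rep(TRUE, n_points)
    area[i] <- 4 * pi * r[i]^2 * sum(free) / n_points
  }
  area
}

# Tien et al. theoretical maximum accessible surface areas (A^2)
.MAX_ASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225,
              E = 223, G = 104, H = 224, I = 197, L = 201, K = 236,
              M = 224, F = 240, P = 159, S = 155, T = 172, W = 285,
              Y = 263, V = 174)

#' Secondary structure and solvent accessibility of a model
#'
#' Assigns 8-state secondary structure with a DSSP-equivalent hydrogen-bond
#' rule set (Kabsch-Sander electrostatic energy, bond below -0.5 kcal/mol)
#' and computes per-residue Shrake-Rupley solvent-accessible surface
#' (probe 1.4 A). Both are computed internally; no external binary is
#' invoked.
#'
#' @param model a `structure3d`.
#' @return list with `state` (character, one of G,H,I,E,B,T,S,C),
#'   `acc` (accessibility in A^2), and `rel_acc` (accessibility scaled by
#'   the residue type's theoretical maximum, clamped to [0,1]; NA for
#'   unknown residue types).
#' @export
assign_ss_and_acc <- function(model) {
  state <- .dssp_states(model)
  at <- model$atoms
  area <- .sasa_atoms(as.matrix(at[, c("x", "y", "z")]), at$el)
  acc <- as.numeric(tapply(area, factor(at$res,
                                        levels = seq_len(n_residues(model))),
                           sum, default = 0))
  mx <- .MAX_ASA[model$aa]
  list(state = state, acc = acc,
       rel_acc = ifelse(is.na(mx), NA_real_, pmin(1, acc / mx)))
}

# ---- secondary-structure agreement table ---------------------------------

.DSSP8 <- c("G", "H", "I", "E", "B", "T", "S", "C")
.PRED3 <- c("H", "E", "C")

#' Train the secondary-structure agreement table
#'
#' Log-odds score S(d, p, c) = log[p(d,p,c) / (p(d) p(p,c))] relating an
#' observed DSSP state d to a predicted 3-state p with confidence c
#' (0..9). Trained from paired observations with a Laplace pseudo-count.
#'
#' @param dssp character vector of observed 8-state labels.
#' @param pred character vector of predicted states (H/E/C).
#' @param conf integer vector of prediction confidences 0..9.
#' @param pseudo Laplace pseudo-count per cell.
#' @return object of class `ss_agreement_table`.
#' @export
train_ss_agreement <- function(dssp, pred, conf, pseudo = 1) {
  stopifnot(length(dssp) == length(pred), length(pred) == length(conf),
            all(dssp %in% .DSSP8), all(pred %in% .PRED3),
            all(conf %in% 0:9))
  cnt <- array(pseudo, dim = c(8, 3, 10),
               dimnames = list(.DSSP8, .PRED3, 0:9))
  for (k in seq_along(dssp))
    cnt[dssp[k], pred[k], conf[k] + 1] <- cnt[dssp[k], pred[k], conf[k] + 1] + 1
  total <- sum(cnt)
  p_joint <- cnt / total
  p_d <- apply(p_joint, 1, sum)
  p_pc <- apply(p_joint, c(2, 3), sum)
  S <- array(0, dim = dim(cnt), dimnames = dimnames(cnt))
  for (d in 1:8) S[d, , ] <- log(p_joint[d, , ] / (p_d[d] * p_pc))
  structure(list(S = S, n = length(dssp), pseudo = pseudo),
            class = "ss_agreement_table")
}

#' Secondary-structure agreement score
#' @param table an `ss_agreement_table`.
#' @param dssp_state observed 8-state label(s).
#' @param pred_state predicted state(s) (H/E/C).
#' @param conf confidence(s) 0..9.
#' @return numeric log-odds score(s).
#' @export
ss_agreement <- function(table, dssp_state, pred_state, conf) {
  table$S[cbind(match(dssp_state, .DSSP8), match(pred_state, .PRED3),
                conf + 1)]
}

#' Solvent-accessibility agreement
#'
#' A residue is classed buried iff its relative accessibility is strictly
#' below 25% of the residue type's theoretical maximum; the feature is 1
#' when that class matches the two-state prediction, else 0.
#'
#' @param acc accessibility in A^2.
#' @param aa one-letter residue code.
#' @param pred_state predicted class, `"b"` (buried) or `"e"` (exposed).
#' @param cut relative-accessibility burial cut (default 0.25).
#' @return 0/1, NA for residue types without a reference maximum.
#' @export
acc_agreement <- function(acc, aa, pred_state, cut = 0.25) {
  mx <- .MAX_ASA[aa]
  obs <- ifelse(acc / mx < cut, "b", "e")
  out <- as.integer(obs == pred_state)
  out[is.na(mx)] <- NA_integer_
  out
}

# ---- clash score ---------------------------------------------------------

.CLASH_R <- c(C = 1.6, N = 1.3, O = 1.3, S = 1.7)
.CLASH_FLOOR <- 0.8254

#' SCWRL3-style hard-sphere clash score
#'
#' For atom pairs from residues at least two positions apart in sequence
#' (contacts of adjacent residues are governed by covalent geometry and are
#' skipped): penalty 0 when the distance d >= R_ij (sum of hard-sphere
#' radii: C 1.6, N 1.3, O 1.3, S 1.7 A), 10 when d <= 0.8254 R_ij, and
#' linear in between. Per residue: the sum over its atoms' penalties,
#' sign-flipped so that higher = better (0 = clash-free).
#'
#' @param model a `structure3d`.
#' @return per-residue numeric vector (<= 0).
#' @export
clash_score <- function(model) {
  at <- model$atoms
  n <- n_residues(model)
  r <- .CLASH_R[at$el]
  r[is.na(r)] <- 1.6
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d <- cross_dist(xyz, xyz)
  rsum <- outer(r, r, "+")
  sep <- abs(outer(at$res, at$res, "-"))
  sel <- which(upper.tri(d) & sep >= 2 & d < rsum, arr.ind = TRUE)
  pen <- numeric(n)
  if (nrow(sel) > 0) {
    dd <- d[sel]
    rr <- rsum[sel]
    p <- pmin(10, 10 * (rr - dd) / (rr * (1 - .CLASH_FLOOR)))
    f1 <- factor(at$res[sel[, 1]], levels = seq_len(n))
    f2 <- factor(at$res[sel[, 2]], levels = seq_len(n))
    pen <- as.numeric(tapply(p, f1, sum, default = 0)) +
      as.numeric(tapply(p, f2, sum, default = 0))
  }
  -pen
}

#' Local residue count N
#'
#' Number of other residues whose C-alpha lies strictly within `radius` of
#' the residue's own C-alpha.
#'
#' @param model a `structure3d`.
#' @param radius count radius in Angstrom (default 15).
#' @return per-residue integer vector, NA where CA is missing.
#' @export
residue_count_n <- function(model, radius = 15) {
  ca <- atom_matrix(model, "CA")
  ok <- !is.na(ca[, 1])
  out <- rep(NA_integer_, n_residues(model))
  idx <- which(ok)
  if (length(idx) >= 1) {
    d <- cross_dist(ca[idx, , drop = FALSE], ca[idx, , drop = FALSE])
    out[idx] <- as.integer(rowSums(d < radius) - 1L)
  }
  out
}

#' Gaussian spherical smoothing of per-residue values
#'
#' smoothed_i = sum_j w_ij v_j / sum_j w_ij with w_ij =
#' exp(-d_ij^2 / (2 sigma^2)) over valid residues j (including j = i with
#' weight 1), using C-alpha distances. Residues with no valid contributor
#' stay invalid. Constant fields are preserved exactly.
#'
#' @param values per-residue numeric vector, NA = invalid.
#' @param model a `structure3d`.
#' @param sigma Gaussian width in Angstrom (default 5).
#' @return smoothed numeric vector, same length.
#' @export
spherical_smooth <- function(values, model, sigma = 5) {
  n <- n_residues(model)
  stopifnot(length(values) == n)
  ca <- atom_matrix(model, "CA")
  valid <- !is.na(values) & !is.na(ca[, 1])
  out <- rep(NA_real_, n)
  if (!any(valid)) return(out)
  vi <- which(valid)
  for (i in seq_len(n)) {
    if (is.na(ca[i, 1])) { out[i] <- values[i]; next }
    d2 <- rowSums(sweep(ca[vi, , drop = FALSE], 2, ca[i, ])^2)
    w <- exp(-d2 / (2 * sigma^2))
    if (sum(w) > 0) out[i] <- sum(w * values[vi]) / sum(w)
  }
  out
}

# ---- predictor-file readers ----------------------------------------------

#' Read a PSIPRED vertical-format (.ss2) prediction
#'
#' Tolerates header/comment lines. Returns per-residue state (H/E/C) and a
#' 0..9 confidence derived from the probability column of the stated
#' class: conf = min(9, floor(10 * p_state)).
#'
#' @param path file path.
#' @return list with `aa`, `state`, `conf`.
#' @export
read_psipred <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !grepl("^#", lines)]
  parts <- strsplit(lines, "\\s+")
  keep <- vapply(parts, function(p)
    length(p) >= 6 && p[3] %in% .PRED3 && !is.na(suppressWarnings(
      as.numeric(p[4]))), TRUE)
  parts <- parts[keep]
  if (length(parts) == 0) stop("no prediction rows in ", path)
  aa <- vapply(parts, `[`, "", 2)
  state <- vapply(parts, `[`, "", 3)
  pc <- vapply(parts, function(p) as.numeric(p[4]), 0)  # coil prob
  ph <- vapply(parts, function(p) as.numeric(p[5]), 0)
  pe <- vapply(parts, function(p) as.numeric(p[6]), 0)
  pstate <- ifelse(state == "C", pc, ifelse(state == "H", ph, pe))
  list(aa = aa, state = state,
       conf = pmin(9L, as.integer(floor(10 * pstate))))
}

#' Read an ACCpro-style two-state accessibility prediction
#'
#' FASTA-like: optional `>` header, then a string of `e` (exposed) and
#' `-`/`b` (buried) characters.
#'
#' @param path file path.
#' @return character vector of `"b"`/`"e"` per residue.
#' @export
read_accpro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !grepl("^[>#]", lines)]
  if (length(lines) == 0) stop("no prediction in ", path)
  ch <- strsplit(paste(lines, collapse = ""), "")[[1]]
  out <- ifelse(ch %in% c("e", "E"), "e", "b")
  out
}
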