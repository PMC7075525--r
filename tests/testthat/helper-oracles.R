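# Independent brute-force oracles and small structure builders used across
# the suite. The oracles are deliberately written as straight-line loop
# code, independent of the package's vectorized implementations.

# a structure from an explicit atom table
mk_struct <- function(aa, atoms, id = "toy") {
  structure3d(id = id, aa = aa, atoms = atoms)
}

# random compact "structure" of n residues with backbone-ish atoms at
# random coordinates (not physically sensible; good for oracle checks)
random_structure <- function(n, atoms_per_res = c("N", "CA", "C", "O"),
                             spread = 8) {
  rows <- list()
  for (i in seq_len(n)) {
    base <- runif(3, 0, spread)
    for (nm in atoms_per_res) {
      rows[[length(rows) + 1]] <- data.frame(
        res = i, name = nm, el = substr(nm, 1, 1),
        x = base[1] + rnorm(1, 0, 0.8), y = base[2] + rnorm(1, 0, 0.8),
        z = base[3] + rnorm(1, 0, 0.8), stringsAsFactors = FALSE)
    }
  }
  mk_struct(sample(discoqa:::.AA20, n, replace = TRUE),
            do.call(rbind, rows))
}

# rigid-body copy
transform_structure <- function(s, rot, shift) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  s$atoms[, c("x", "y", "z")] <- xyz %*% t(rot) +
    matrix(shift, nrow(xyz), 3, byrow = TRUE)
  s
}

random_rot <- function() discoqa:::random_rotation()

# ---- lDDT oracle ---------------------------------------------------------
# O(pairs) recount with explicit loops; reference-defined contacts,
# missing model atoms fail their checks.
lddt_oracle <- function(model, reference, radius = 15,
                        thresholds = c(0.5, 1, 2, 4)) {
  rat <- reference$atoms
  mat <- model$atoms
  n <- n_residues(model)
  cons <- tot <- rep(0, n)
  gcons <- gtot <- 0
  mkey <- paste(mat$res, mat$name)
  for (a in seq_len(nrow(rat) - 1)) {
    for (b in (a + 1):nrow(rat)) {
      if (rat$res[a] == rat$res[b]) next
      dref <- sqrt(sum((rat[a, c("x", "y", "z")] -
                          rat[b, c("x", "y", "z")])^2))
      if (dref >= radius) next
      ia <- match(paste(rat$res[a], rat$name[a]), mkey)
      ib <- match(paste(rat$res[b], rat$name[b]), mkey)
      for (t in thresholds) {
        ok <- FALSE
        if (!is.na(ia) && !is.na(ib)) {
          dmod <- sqrt(sum((mat[ia, c("x", "y", "z")] -
                              mat[ib, c("x", "y", "z")])^2))
          ok <- abs(dmod - dref) < t
        }
        gtot <- gtot + 1
        gcons <- gcons + ok
        for (r in unique(c(rat$res[a], rat$res[b]))) {
          tot[r] <- tot[r] + 1
          cons[r] <- cons[r] + ok
        }
      }
    }
  }
  list(per_residue = ifelse(tot > 0, cons / tot, NA_real_),
       global_score = if (gtot > 0) gcons / gtot else NA_real_)
}

# ---- DisCo oracle --------------------------------------------------------
# literal re-implementation of the four defining equations, scoring model
# residue i against clusters of template constraints
disco_oracle <- function(ensemble, model) {
  n <- n_residues(model)
  ca <- discoqa:::atom_matrix(model, "CA")
  con <- ensemble$constraints
  score <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    vals <- c()
    for (j in seq_len(n)) {
      if (j == i || is.na(ca[i, 1]) || is.na(ca[j, 1])) next
      d <- sqrt(sum((ca[i, ] - ca[j, ])^2))
      if (d >= ensemble$max_dist) next
      lo <- min(i, j); hi <- max(i, j)
      rows <- which(con$i == lo & con$j == hi)
      if (length(rows) == 0) next
      cls <- unique(con$cluster[rows])
      w <- exp(ensemble$gamma * ensemble$ss_c[cls])
      w <- w / sum(w)
      s_ij <- 0
      for (k in seq_along(cls)) {
        mus <- con$mu[rows][con$cluster[rows] == cls[k]]
        h <- mean(exp(-0.5 * (d - mus)^2))
        s_ij <- s_ij + w[k] * h
      }
      vals <- c(vals, s_ij)
    }
    if (length(vals) > 0) score[i] <- mean(vals)
  }
  score
}

# ---- AUC oracle ----------------------------------------------------------
# concordant-pair enumeration with half-credit for ties
auc_oracle <- function(pred, lab) {
  pos <- pred[lab == 1]; neg <- pred[lab == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# hand-written 3-residue PDB (GLY-ALA-GLY with full backbone, ALA has CB)
write_tiny_pdb <- function(path, altloc = FALSE) {
  fmt <- function(serial, name, alt, res, resno, x, y, z, occ) {
    sprintf("ATOM  %5d  %-3s%1s%3s A%4d    %8.3f%8.3f%8.3f%6.2f  0.00          %2s",
            serial, name, alt, res, resno, x, y, z, occ,
            substr(name, 1, 1))
  }
  lines <- c(
    fmt(1, "N", " ", "GLY", 1, 0.0, 0.0, 0.0, 1.0),
    fmt(2, "CA", " ", "GLY", 1, 1.458, 0.0, 0.0, 1.0),
    fmt(3, "C", " ", "GLY", 1, 2.009, 1.420, 0.0, 1.0),
    fmt(4, "O", " ", "GLY", 1, 1.251, 2.390, 0.0, 1.0),
    fmt(5, "N", " ", "ALA", 2, 3.332, 1.536, 0.0, 1.0),
    fmt(6, "CA", " ", "ALA", 2, 3.988, 2.839, 0.0, 1.0),
    fmt(7, "C", " ", "ALA", 2, 5.502, 2.710, 0.0, 1.0),
    fmt(8, "O", " ", "ALA", 2, 6.102, 1.640, 0.0, 1.0))
  if (altloc) {
    lines <- c(lines,
               fmt(9, "CB", "A", "ALA", 2, 3.508, 3.602, 1.240, 0.6),
               fmt(10, "CB", "B", "ALA", 2, 3.600, 3.700, 1.300, 0.4))
  } else {
    lines <- c(lines, fmt(9, "CB", " ", "ALA", 2, 3.508, 3.602, 1.240, 1.0))
  }
  lines <- c(lines,
             fmt(11, "N", " ", "GLY", 3, 6.139, 3.877, 0.0, 1.0),
             fmt(12, "CA", " ", "GLY", 3, 7.590, 3.900, 0.0, 1.0),
             fmt(13, "C", " ", "GLY", 3, 8.150, 5.310, 0.0, 1.0),
             fmt(14, "O", " ", "GLY", 3, 7.400, 6.280, 0.0, 1.0),
             "END")
  writeLines(lines, path)
  path
}

# single-atom-per-residue helper: residues are lone atoms at given coords
point_structure <- function(coords, aa = NULL, name = "CA", el = NULL) {
  n <- nrow(coords)
  if (is.null(aa)) aa <- rep("A", n)
  if (is.null(el)) el <- substr(name, 1, 1)
  mk_struct(aa, data.frame(res = seq_len(n), name = name, el = el,
                           x = coords[, 1], y = coords[, 2],
                           z = coords[, 3], stringsAsFactors = FALSE))
}
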