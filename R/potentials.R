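# Knowledge-based statistical potentials of mean force. Six terms share one
# inverse-Boltzmann trainer: observed type-conditional distributions are
# contrasted against a type-pooled reference distribution with an additive
# pseudo-count weight sigma (Sippl-style sparse-data handling):
#   e(bin | type) = -log[(f_obs(bin|type) + sigma * f_ref(bin)) /
#                        ((1 + sigma) * f_ref(bin))]
# Types never observed in the corpus fall back to the reference (energy 0).
# On output all energies are sign-flipped so that, like every other feature,
# higher means better.

# The standard alphabet of chemically distinguishable heavy atoms:
# 4 backbone atoms plus the side-chain atoms of each residue type (167).
atom_type_alphabet <- function() {
  unlist(lapply(.AA20, function(a)
    paste(a, c("N", "CA", "C", "O", .SIDECHAIN[[a]]), sep = ":")),
    use.names = FALSE)
}

# map structure atoms to type indices (NA for atoms outside the alphabet,
# e.g. atoms of 'X' residues)
.atom_types <- function(s, alphabet) {
  match(paste(s$aa[s$atoms$res], s$atoms$name, sep = ":"), alphabet)
}

#' Default configuration of the statistical-potential terms
#'
#' Distance histograms use 0.5 A bins on [0, 20) A for the all-atom and
#' C-beta interaction terms; the reduced term bins (distance, direction
#' angle) on [0, 15) A x [0, 180] deg with 1 A x 30 deg cells. Packing
#' terms count neighbours within 10 A into count bins 0..32 (clamped).
#' Torsion uses 30 x 30 deg phi/psi cells keyed by a 5-group identity
#' triplet (GLY | PRO | pre-PRO | hydrophobic | polar). Interaction terms
#' apply a sequence-separation threshold |i-j| >= 5 to focus on long-range
#' contacts.
#'
#' @param sigma pseudo-count weight.
#' @param s_min minimum sequence separation for interaction terms.
#' @param d_max_pair,d_max_reduced,bin_pair distance limits / bin width (A).
#' @param pack_radius,pack_max packing count radius (A) and count clamp.
#' @param torsion_bin phi/psi bin width in degrees.
#' @return list of class `potential_config`.
#' @export
potential_config <- function(sigma = 0.02, s_min = 5,
                             d_max_pair = 20, d_max_reduced = 15,
                             bin_pair = 0.5, pack_radius = 10, pack_max = 32,
                             torsion_bin = 30) {
  structure(as.list(environment()), class = "potential_config")
}

.TORSION_GROUPS <- c("GLY", "PRO", "PREPRO", "HPHOB", "POLAR")
.HPHOB <- c("A", "V", "L", "I", "M", "F", "W", "Y", "C")

# identity grouping for the torsion term; `next_aa` feeds the pre-proline
# class
torsion_group <- function(aa, next_aa) {
  ifelse(aa == "G", "GLY",
    ifelse(aa == "P", "PRO",
      ifelse(!is.na(next_aa) & next_aa == "P", "PREPRO",
        ifelse(aa %in% .HPHOB, "HPHOB", "POLAR"))))
}

# ---- shared table plumbing ----------------------------------------------

.new_table <- function(term, labels, nbins, config, bin_info) {
  structure(list(term = term, labels = labels, nbins = nbins,
                 config = config, bin_info = bin_info,
                 counts = matrix(0, length(labels), nbins,
                                 dimnames = list(labels, NULL)),
                 energies = NULL, meta = list(corpus_size = 0L)),
            class = "potential_table")
}

#' @export
print.potential_table <- function(x, ...) {
  cat(sprintf("potential_table '%s': %d types x %d bins (corpus: %d)\n",
              x$term, length(x$labels), x$nbins, x$meta$corpus_size))
  invisible(x)
}

.finalize_table <- function(tab) {
  cnt <- tab$counts
  sigma <- tab$config$sigma
  total <- sum(cnt)
  if (total == 0) stop("empty corpus: no counts collected")
  f_ref <- colSums(cnt) / total
  rs <- rowSums(cnt)
  e <- matrix(0, nrow(cnt), ncol(cnt), dimnames = dimnames(cnt))
  live <- which(rs > 0)
  pos <- which(f_ref > 0)
  for (t in live) {
    f_obs <- cnt[t, pos] / rs[t]
    e[t, pos] <- -log((f_obs + sigma * f_ref[pos]) /
                        ((1 + sigma) * f_ref[pos]))
  }
  tab$energies <- e
  tab
}

# unordered pair-type key over a label alphabet of size T
.pair_key <- function(t1, t2, T) {
  lo <- pmin(t1, t2); hi <- pmax(t1, t2)
  (lo - 1L) * T + hi
}

.pair_labels <- function(labels) {
  T <- length(labels)
  idx <- which(upper.tri(matrix(0, T, T), diag = TRUE), arr.ind = TRUE)
  keys <- (idx[, 1] - 1L) * T + idx[, 2]   # row <= col
  stats::setNames(paste(labels[idx[, 1]], labels[idx[, 2]], sep = "|"), keys)
}

# ---- per-term event extraction -------------------------------------------
# Every term reduces a structure to (type label, bin index) events; the
# same extraction feeds both training (counting) and scoring (lookup).

.events_interaction <- function(s, term, config) {
  if (term == "all_atom") {
    alphabet <- atom_type_alphabet()
    ty <- .atom_types(s, alphabet)
    ok <- !is.na(ty)
    xyz <- as.matrix(s$atoms[ok, c("x", "y", "z")])
    res <- s$atoms$res[ok]
    ty <- ty[ok]
  } else {
    cb <- cb_coords(s)
    ok <- cb$valid & s$aa %in% .AA20
    xyz <- cb$xyz[ok, , drop = FALSE]
    res <- which(ok)
    ty <- match(s$aa[ok], .AA20)
    alphabet <- .AA20
  }
  if (length(res) < 2)
    return(list(type = integer(), bin = integer(), res1 = integer(),
                res2 = integer(), T = length(alphabet)))
  d <- cross_dist(xyz, xyz)
  sel <- which(upper.tri(d) & d < config$d_max_pair &
                 abs(outer(res, res, "-")) >= config$s_min, arr.ind = TRUE)
  a <- sel[, 1]; b <- sel[, 2]
  list(type = .pair_key(ty[a], ty[b], length(alphabet)),
       bin = pmin(floor(d[sel] / config$bin_pair) + 1L,
                  ceiling(config$d_max_pair / config$bin_pair)),
       res1 = res[a], res2 = res[b], atom1 = a, atom2 = b,
       T = length(alphabet))
}

# reduced representation: CA position + unit direction from the backbone
# frame (the side-chain direction), pair geometry = (distance, angle
# between the two direction vectors)
.reduced_frames <- function(s) {
  nmat <- atom_matrix(s, "N"); ca <- atom_matrix(s, "CA")
  cmat <- atom_matrix(s, "C")
  ok <- backbone_complete(s) & s$aa %in% .AA20
  dirs <- matrix(NA_real_, n_residues(s), 3)
  for (i in which(ok)) {
    u <- unitv(nmat[i, ] - ca[i, ]) + unitv(cmat[i, ] - ca[i, ])
    dirs[i, ] <- -unitv(u)
  }
  list(ca = ca, dir = dirs, ok = ok)
}

.events_reduced <- function(s, config) {
  fr <- .reduced_frames(s)
  res <- which(fr$ok)
  nb_d <- ceiling(config$d_max_reduced / 1)       # 1 A distance bins
  nb_a <- 180 %/% 30                              # 30 deg angle bins
  if (length(res) < 2)
    return(list(type = integer(), bin = integer(), res1 = integer(),
                res2 = integer(), T = length(.AA20), nbins = nb_d * nb_a))
  ca <- fr$ca[res, , drop = FALSE]
  d <- cross_dist(ca, ca)
  sel <- which(upper.tri(d) & d < config$d_max_reduced &
                 abs(outer(res, res, "-")) >= config$s_min, arr.ind = TRUE)
  a <- sel[, 1]; b <- sel[, 2]
  cosang <- rowSums(fr$dir[res[a], , drop = FALSE] *
                      fr$dir[res[b], , drop = FALSE])
  ang <- acos(pmax(-1, pmin(1, cosang))) * 180 / pi
  dbin <- pmin(floor(d[sel]) + 1L, nb_d)
  abin <- pmin(floor(ang / 30) + 1L, nb_a)
  ty <- match(s$aa, .AA20)
  list(type = .pair_key(ty[res[a]], ty[res[b]], length(.AA20)),
       bin = (dbin - 1L) * nb_a + abin,
       res1 = res[a], res2 = res[b], T = length(.AA20),
       nbins = nb_d * nb_a)
}

.events_packing <- function(s, term, config) {
  if (term == "packing") {
    alphabet <- atom_type_alphabet()
    ty <- .atom_types(s, alphabet)
    ok <- !is.na(ty)
    xyz <- as.matrix(s$atoms[ok, c("x", "y", "z")])
    res <- s$atoms$res[ok]
    ty <- ty[ok]
  } else {
    cb <- cb_coords(s)
    ok <- cb$valid & s$aa %in% .AA20
    xyz <- cb$xyz[ok, , drop = FALSE]
    res <- which(ok)
    ty <- match(s$aa[ok], .AA20)
    alphabet <- .AA20
  }
  if (length(res) == 0)
    return(list(type = integer(), bin = integer(), res = integer(),
                T = length(alphabet)))
  d <- cross_dist(xyz, xyz)
  other <- outer(res, res, "!=")
  counts <- rowSums(d < config$pack_radius & other)
  list(type = ty, bin = pmin(counts, config$pack_max) + 1L,
       res = res, T = length(alphabet))
}

# phi/psi dihedrals; NA at chain termini / incomplete backbones
phi_psi <- function(s) {
  n <- n_residues(s)
  nmat <- atom_matrix(s, "N"); ca <- atom_matrix(s, "CA")
  cmat <- atom_matrix(s, "C")
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1 &&
        !anyNA(c(cmat[i - 1, ], nmat[i, ], ca[i, ], cmat[i, ])))
      phi[i] <- dihedral_angle(cmat[i - 1, ], nmat[i, ], ca[i, ], cmat[i, ])
    if (i < n &&
        !anyNA(c(nmat[i, ], ca[i, ], cmat[i, ], nmat[i + 1, ])))
      psi[i] <- dihedral_angle(nmat[i, ], ca[i, ], cmat[i, ], nmat[i + 1, ])
  }
  cbind(phi = phi, psi = psi)
}

.events_torsion <- function(s, config) {
  n <- n_residues(s)
  pp <- phi_psi(s)
  nb <- 360 %/% config$torsion_bin
  aa <- s$aa
  nxt <- c(aa[-1], NA)
  grp <- match(torsion_group(aa, nxt), .TORSION_GROUPS)
  valid <- !is.na(pp[, 1]) & !is.na(pp[, 2]) & !is.na(grp)
  # require both sequence neighbours with assignable groups
  valid <- valid & c(FALSE, !is.na(grp[-n])) & c(!is.na(grp[-1]), FALSE)
  res <- which(valid)
  if (length(res) == 0)
    return(list(type = integer(), bin = integer(), res = integer(),
                T = length(.TORSION_GROUPS)^3, nbins = nb * nb))
  G <- length(.TORSION_GROUPS)
  key <- (grp[res - 1] - 1L) * G * G + (grp[res] - 1L) * G + grp[res + 1]
  pbin <- function(x) pmin(floor((x + 180) / config$torsion_bin) + 1L, nb)
  list(type = key, bin = (pbin(pp[res, 1]) - 1L) * nb + pbin(pp[res, 2]),
       res = res, T = G^3, nbins = nb * nb)
}

.term_events <- function(term, s, config) {
  switch(term,
         all_atom = ,
         cb_interaction = .events_interaction(s, term, config),
         reduced = .events_reduced(s, config),
         packing = ,
         cb_packing = .events_packing(s, term, config),
         torsion = .events_torsion(s, config),
         stop("unknown potential term: ", term))
}

.term_table_shape <- function(term, config) {
  switch(term,
    all_atom = {
      lab <- .pair_labels(atom_type_alphabet())
      list(labels = lab,
           nbins = ceiling(config$d_max_pair / config$bin_pair))
    },
    cb_interaction = list(labels = .pair_labels(.AA20),
                          nbins = ceiling(config$d_max_pair /
                                            config$bin_pair)),
    reduced = list(labels = .pair_labels(.AA20),
                   nbins = ceiling(config$d_max_reduced) * 6L),
    packing = list(labels = stats::setNames(atom_type_alphabet(),
                                            seq_along(atom_type_alphabet())),
                   nbins = config$pack_max + 1L),
    cb_packing = list(labels = stats::setNames(.AA20, seq_along(.AA20)),
                      nbins = config$pack_max + 1L),
    torsion = {
      G <- length(.TORSION_GROUPS)
      keys <- seq_len(G^3)
      grid <- expand.grid(k3 = .TORSION_GROUPS, k2 = .TORSION_GROUPS,
                          k1 = .TORSION_GROUPS)[, 3:1]
      list(labels = stats::setNames(
        paste(grid$k1, grid$k2, grid$k3, sep = "|"), keys),
        nbins = (360 %/% config$torsion_bin)^2)
    })
}

#' Train one statistical-potential term
#'
#' Counts term-specific events over a corpus of structures and converts
#' them to inverse-Boltzmann pseudo-energies. Counting is order-independent,
#' so shuffled corpora yield identical tables.
#'
#' @param term one of `"all_atom"`, `"cb_interaction"`, `"reduced"`,
#'   `"packing"`, `"cb_packing"`, `"torsion"`.
#' @param corpus list of `structure3d` objects.
#' @param config a [potential_config()].
#' @return A `potential_table`.
#' @export
train_potential <- function(term, corpus, config = potential_config()) {
  stopifnot(length(corpus) > 0)
  shape <- .term_table_shape(term, config)
  tab <- .new_table(term, shape$labels, shape$nbins, config,
                    bin_info = NULL)
  keyidx <- as.integer(names(shape$labels))
  lookup <- rep(NA_integer_, max(keyidx))
  lookup[keyidx] <- seq_along(keyidx)
  for (s in corpus) {
    ev <- .term_events(term, s, config)
    if (length(ev$type) == 0) next
    row <- lookup[ev$type]
    idx <- (ev$bin - 1L) * nrow(tab$counts) + row
    tb <- tabulate(idx, nbins = nrow(tab$counts) * tab$nbins)
    tab$counts <- tab$counts + matrix(tb, nrow(tab$counts), tab$nbins)
  }
  tab$meta$corpus_size <- length(corpus)
  .finalize_table(tab)
}

# shared scoring core: map events to energies, average per residue,
# sign-flip so higher = better
.score_events <- function(tab, ev, n, per_atom = FALSE) {
  keyidx <- as.integer(names(tab$labels))
  lookup <- rep(NA_integer_, max(keyidx))
  lookup[keyidx] <- seq_along(keyidx)
  if (length(ev$type) == 0) return(rep(NA_real_, n))
  e <- tab$energies[cbind(lookup[ev$type], ev$bin)]
  if (!is.null(ev$res)) {                     # one event per residue/atom
    f <- factor(ev$res, levels = seq_len(n))
    sums <- as.numeric(tapply(e, f, sum, default = NA))
    cnts <- as.numeric(tapply(rep(1, length(e)), f, sum, default = 0))
    return(ifelse(cnts > 0, -sums / cnts, NA_real_))
  }
  # pair events: contribute to both residues
  if (per_atom && !is.null(ev$atom1)) {
    # average per atom first, then per residue (full-atomic convention)
    fa <- factor(c(ev$atom1, ev$atom2))
    ae <- as.numeric(tapply(c(e, e), fa, mean))
    ares <- c(ev$res1, ev$res2)[match(as.integer(levels(fa)),
                                      c(ev$atom1, ev$atom2))]
    f <- factor(ares, levels = seq_len(n))
    sums <- as.numeric(tapply(ae, f, sum, default = NA))
    cnts <- as.numeric(tapply(rep(1, length(ae)), f, sum, default = 0))
    return(ifelse(cnts > 0, -sums / cnts, NA_real_))
  }
  f <- factor(c(ev$res1, ev$res2), levels = seq_len(n))
  ee <- c(e, e)
  sums <- as.numeric(tapply(ee, f, sum, default = NA))
  cnts <- as.numeric(tapply(rep(1, length(ee)), f, sum, default = 0))
  ifelse(cnts > 0, -sums / cnts, NA_real_)
}

#' Score pairwise-interaction terms on a model
#'
#' @param table a trained `potential_table` with term `all_atom`,
#'   `cb_interaction` or `reduced`.
#' @param model a `structure3d`.
#' @return per-residue numeric vector (higher = better; NA where the
#'   residue has no contributing pairs).
#' @export
score_interaction <- function(table, model) {
  if (!table$term %in% c("all_atom", "cb_interaction", "reduced"))
    stop("score_interaction expects an interaction-term table, got '",
         table$term, "'")
  ev <- .term_events(table$term, model, table$config)
  .score_events(table, ev, n_residues(model),
                per_atom = table$term == "all_atom")
}

#' Score packing terms on a model
#' @inheritParams score_interaction
#' @export
score_packing <- function(table, model) {
  if (!table$term %in% c("packing", "cb_packing"))
    stop("score_packing expects a packing-term table, got '",
         table$term, "'")
  ev <- .term_events(table$term, model, table$config)
  .score_events(table, ev, n_residues(model))
}

#' Score the torsion term on a model
#' @inheritParams score_interaction
#' @export
score_torsion <- function(table, model) {
  if (table$term != "torsion")
    stop("score_torsion expects a torsion table, got '", table$term, "'")
  ev <- .term_events(table$term, model, table$config)
  .score_events(table, ev, n_residues(model))
}

#' Score any potential term
#' @inheritParams score_interaction
#' @export
score_potential <- function(table, model) {
  switch(table$term,
         all_atom = , cb_interaction = , reduced =
           score_interaction(table, model),
         packing = , cb_packing = score_packing(table, model),
         torsion = score_torsion(table, model))
}

#' Serialize / restore potential tables
#'
#' Tables round-trip bit-exactly through a versioned JSON container.
#'
#' @param tables named list of `potential_table`s.
#' @param path file path.
#' @export
write_potentials <- function(tables, path) {
  payload <- list(format = "discoqa-potentials", version = 1L,
                  tables = lapply(tables, function(t)
                    list(term = t$term, labels = as.list(t$labels),
                         keys = names(t$labels), nbins = t$nbins,
                         config = unclass(t$config),
                         energies = .enc_num(t$energies),
                         meta = t$meta)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_potentials
#' @export
read_potentials <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "discoqa-potentials"))
    stop("not a potentials container: ", path)
  tabs <- lapply(payload$tables, function(tl) {
    cfg <- structure(lapply(tl$config, function(v) v),
                     class = "potential_config")
    labels <- stats::setNames(unlist(tl$labels), unlist(tl$keys))
    t <- .new_table(tl$term, labels, as.integer(tl$nbins), cfg, NULL)
    t$energies <- matrix(.dec_num(tl$energies), length(labels),
                         as.integer(tl$nbins),
                         dimnames = list(labels, NULL))
    t$counts <- NULL
    t$meta <- tl$meta
    t
  })
  names(tabs) <- vapply(tabs, function(t) t$term, "")
  tabs
}
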