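# Oracle helpers local to this file ---------------------------------------

# brute-force interaction score: loop over all atom/position pairs,
# re-binning and re-averaging independently of the package's event path
interaction_oracle <- function(tab, s) {
  cfg <- tab$config
  n <- n_residues(s)
  if (tab$term == "cb_interaction") {
    cb <- cb_coords(s)
    pos <- cb$xyz; ok <- cb$valid
    per <- rep(NA_real_, n)
    acc <- cnt <- rep(0, n)
    for (i in which(ok)) for (j in which(ok)) {
      if (j <= i || abs(i - j) < cfg$s_min) next
      d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (d >= cfg$d_max_pair) next
      t1 <- match(s$aa[i], discoqa:::.AA20)
      t2 <- match(s$aa[j], discoqa:::.AA20)
      key <- (min(t1, t2) - 1) * 20 + max(t1, t2)
      bin <- floor(d / cfg$bin_pair) + 1
      e <- tab$energies[match(key, as.integer(names(tab$labels))), bin]
      for (r in c(i, j)) { acc[r] <- acc[r] + e; cnt[r] <- cnt[r] + 1 }
    }
    ifelse(cnt > 0, -acc / cnt, NA_real_)
  } else stop("oracle supports cb_interaction only")
}

packing_oracle <- function(tab, s) {
  cfg <- tab$config
  n <- n_residues(s)
  at <- s$atoms
  alphabet <- discoqa:::atom_type_alphabet()
  acc <- cnt <- rep(0, n)
  for (a in seq_len(nrow(at))) {
    ty <- match(paste(s$aa[at$res[a]], at$name[a], sep = ":"), alphabet)
    if (is.na(ty)) next
    ct <- 0
    for (b in seq_len(nrow(at))) {
      if (at$res[b] == at$res[a]) next
      d <- sqrt(sum((at[a, c("x", "y", "z")] - at[b, c("x", "y", "z")])^2))
      if (d < cfg$pack_radius) ct <- ct + 1
    }
    bin <- min(ct, cfg$pack_max) + 1
    e <- tab$energies[ty, bin]
    r <- at$res[a]
    acc[r] <- acc[r] + e; cnt[r] <- cnt[r] + 1
  }
  ifelse(cnt > 0, -acc / cnt, NA_real_)
}

# corpus with two pair types at sequence separation 5: an A|A pair with
# CB-CB distance ~ N(mu_a, sd) and a G|G pair drawn uniformly on the
# binned range (a flat reference), far apart
gaussian_pair_corpus <- function(n_struct, mu_a = 8, mu_g = 12, sd = 0.4,
                                 uniform_g = FALSE) {
  lapply(seq_len(n_struct), function(k) {
    da <- max(0.5, rnorm(1, mu_a, sd))
    dg <- if (uniform_g) runif(1, 0.01, 19.99) else
      max(0.5, rnorm(1, mu_g, sd))
    aa <- c("A", "G", "A", "A", "A", "A", "G")
    atoms <- data.frame(res = c(1L, 2L, 6L, 7L), name = "CB", el = "C",
                        x = c(0, 500, da, 500 + dg), y = 0, z = 0,
                        stringsAsFactors = FALSE)
    mk_struct(aa, atoms)
  })
}

test_that("a uniform corpus trains to zero energies", {
  # both pair types share one degenerate geometry: every type-conditional
  # distribution equals the pooled reference, so log(1) = 0 throughout
  corpus <- gaussian_pair_corpus(30, mu_a = 8, mu_g = 8, sd = 0)
  tab <- train_potential("cb_interaction", corpus)
  expect_true(all(abs(tab$energies) < 1e-12))
})

test_that("training finds the Gaussian minimum and sigma -> inf flattens", {
  set.seed(501)
  corpus <- gaussian_pair_corpus(800, mu_a = 8.25, sd = 0.4,
                                 uniform_g = TRUE)
  tab <- train_potential("cb_interaction", corpus)
  aidx <- match("A", discoqa:::.AA20)
  gidx <- match("G", discoqa:::.AA20)
  rowA <- match((aidx - 1) * 20 + aidx, as.integer(names(tab$labels)))
  rowG <- match((gidx - 1) * 20 + gidx, as.integer(names(tab$labels)))

  # count-and-log oracle on the same corpus: tabulate the drawn distances
  # and apply the inverse-Boltzmann formula directly
  da <- vapply(corpus, function(s) s$atoms$x[3] - s$atoms$x[1], 0)
  dg <- vapply(corpus, function(s) s$atoms$x[4] - 500, 0)
  cA <- tabulate(floor(da / 0.5) + 1, 40)
  cG <- tabulate(floor(dg / 0.5) + 1, 40)
  f_ref <- (cA + cG) / sum(cA + cG)
  sig <- tab$config$sigma
  eA <- ifelse(f_ref > 0,
               -log((cA / sum(cA) + sig * f_ref) / ((1 + sig) * f_ref)), 0)
  expect_equal(unname(tab$energies[rowA, ]), eA, tolerance = 1e-12)

  # against the flat reference, the energy minimum sits in the bin
  # containing the Gaussian mean
  expect_equal(which.min(tab$energies[rowA, ]), floor(8.25 / 0.5) + 1)
  # pseudo-count limit: sigma -> inf gives zero energies
  tab2 <- train_potential("cb_interaction", corpus,
                          potential_config(sigma = 1e9))
  expect_true(all(abs(tab2$energies) < 1e-6))
})

test_that("training is deterministic and order-independent", {
  set.seed(502)
  corpus <- lapply(1:12, function(k) make_native(18, seed = 600 + k))
  t1 <- train_potential("torsion", corpus)
  t2 <- train_potential("torsion", corpus[sample(length(corpus))])
  expect_identical(t1$energies, t2$energies)
  t3 <- train_potential("all_atom", corpus)
  t4 <- train_potential("all_atom", rev(corpus))
  expect_identical(t3$energies, t4$energies)
})

test_that("interaction scoring matches hand cases and the oracle", {
  set.seed(503)
  corpus <- lapply(1:10, function(k) make_native(20, seed = 700 + k))
  tab <- train_potential("cb_interaction", corpus)

  # all pairwise distances beyond d_max -> all residues invalid
  far <- point_structure(diag(3) * 1000, aa = c("A", "A", "A"),
                         name = "CB", el = "C")
  expect_true(all(is.na(score_interaction(tab, far))))

  # a single in-range pair scores both residues identically
  toy <- gaussian_pair_corpus(1, sd = 0)[[1]]
  sc <- score_interaction(tab, toy)
  expect_equal(sc[1], sc[6])
  expect_equal(sc[2], sc[7])
  expect_true(all(is.na(sc[3:5])))

  # helix vs. brute-force pair enumeration
  helix <- make_native(20, layout = rep("H", 20), seed = 504)
  expect_equal(score_interaction(tab, helix),
               interaction_oracle(tab, helix), tolerance = 1e-9)

  # term mismatch is a contract error
  expect_error(score_interaction(train_potential("packing", corpus), helix),
               "interaction-term")
})

test_that("packing scoring clamps counts and matches a brute-force recount", {
  set.seed(505)
  corpus <- lapply(1:10, function(k) make_native(20, seed = 800 + k))
  tab <- train_potential("packing", corpus)

  # an isolated residue sees the zero-count bin for every atom
  iso <- point_structure(matrix(c(0, 0, 0), 1), aa = "A",
                         name = "CB", el = "C")
  alphabet <- discoqa:::atom_type_alphabet()
  e0 <- unname(tab$energies[match("A:CB", alphabet), 1])
  expect_equal(score_packing(tab, iso), -e0)

  # counts past the clamp all land in the last bin
  many <- point_structure(rbind(c(0, 0, 0),
                                matrix(rnorm(3 * 40, 0, 2), ncol = 3)),
                          aa = rep("A", 41), name = "CB", el = "C")
  ev <- discoqa:::.events_packing(many, "packing", tab$config)
  expect_true(all(ev$bin <= tab$config$pack_max + 1))
  expect_equal(unname(ev$bin[1]), tab$config$pack_max + 1)

  coil <- make_native(30, seed = 506)
  expect_equal(score_packing(tab, coil), packing_oracle(tab, coil),
               tolerance = 1e-9)
})

test_that("torsion scoring handles termini, helix bins and grouping", {
  set.seed(507)
  corpus <- lapply(1:15, function(k) make_native(24, seed = 900 + k))
  tab <- train_potential("torsion", corpus)
  helix <- make_native(14, layout = rep("H", 14), seed = 508)
  sc <- score_torsion(tab, helix)
  expect_true(is.na(sc[1]) && is.na(sc[14]))
  expect_true(all(!is.na(sc[2:13])))

  # interior helix residues fall in the phi/psi cell containing (-57,-47):
  # identical group triplets with dihedrals in the same cell must agree
  pp <- discoqa:::phi_psi(helix)
  expect_true(all(abs(pp[3:12, 1] + 57) < 15))
  grp <- discoqa:::torsion_group(helix$aa, c(helix$aa[-1], NA))
  same <- which(grp[2:13] == grp[2]) + 1
  bins <- floor((pp[, 1] + 180) / 30) * 12 + floor((pp[, 2] + 180) / 30)
  twin <- same[duplicated(paste(grp[same - 1], grp[same], grp[same + 1],
                                bins[same])) |
                 duplicated(paste(grp[same - 1], grp[same], grp[same + 1],
                                  bins[same]), fromLast = TRUE)]
  if (length(twin) >= 2) expect_equal(sc[twin[1]], sc[twin[2]])
})

test_that("all six terms are rigid-motion invariant", {
  set.seed(509)
  corpus <- lapply(1:8, function(k) make_native(20, seed = 1000 + k))
  tabs <- train_all_potentials(corpus)
  s <- make_native(18, seed = 510)
  s2 <- transform_structure(s, random_rot(), runif(3, -50, 50))
  for (term in names(tabs)) {
    expect_equal(score_potential(tabs[[term]], s),
                 score_potential(tabs[[term]], s2), tolerance = 1e-9,
                 info = term)
  }
})

test_that("potential tables serialize and restore bit-exactly", {
  set.seed(511)
  corpus <- lapply(1:6, function(k) make_native(16, seed = 1100 + k))
  tabs <- train_all_potentials(corpus)
  path <- tempfile(fileext = ".json")
  write_potentials(tabs, path)
  back <- read_potentials(path)
  for (term in names(tabs)) {
    expect_identical(back[[term]]$energies, tabs[[term]]$energies,
                     info = term)
    s <- make_native(15, seed = 512)
    expect_identical(score_potential(back[[term]], s),
                     score_potential(tabs[[term]], s))
  }
})
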