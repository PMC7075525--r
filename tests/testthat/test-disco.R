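# builds an in-memory ensemble from explicit constraint rows; used by the
# closed-form and fuzzing checks
mk_ensemble <- function(L, ss_c, rows, gamma = 70, id_c = ss_c) {
  structure(list(target_length = as.integer(L), gamma = gamma,
                 max_dist = 15, ss_c = ss_c, id_c = id_c,
                 constraints = rows), class = "constraint_ensemble")
}

test_that("A3M parsing: self-alignment, insertions and terminal gaps", {
  dir <- tempfile(); dir.create(dir)
  nat <- make_native(8, seed = 701, id = "tq")
  tdir <- file.path(dir, "t"); dir.create(tdir)
  write_scored_pdb(nat, rep(0, 8), file.path(tdir, "self.pdb"))
  a3m <- file.path(dir, "a.a3m")
  tseq <- extract_sequence(nat)
  writeLines(c(">q", tseq, ">self", tseq), a3m)
  tm <- load_alignments(a3m, tdir)
  expect_length(tm, 1)
  expect_equal(unname(tm[[1]]$mapping), 1:8)
  expect_equal(tm[[1]]$seq_identity, 1)
  expect_equal(tm[[1]]$seq_similarity, 1)

  # a lowercase insertion consumes template positions without mapping
  ins <- paste0(substr(tseq, 1, 3), "ggg", substr(tseq, 4, 8))
  nat2 <- nat
  nat2$aa <- c(nat$aa[1:3], "G", "G", "G", nat$aa[4:8])
  # build an 11-residue template structure: 3 matched, 3 inserted, 5 matched
  at <- nat$atoms
  extra <- do.call(rbind, lapply(1:3, function(k) {
    a <- at[at$res == 3, ]; a$res <- 3 + k
    a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] + 30 + k; a
  }))
  at2 <- rbind(at[at$res <= 3, ], extra, transform(at[at$res >= 4, ],
                                                   res = res + 3))
  tmpl2 <- structure3d("ins", nat2$aa, atoms = at2)
  write_scored_pdb(tmpl2, rep(0, 11), file.path(tdir, "ins.pdb"))
  writeLines(c(">q", tseq, ">ins", ins), a3m)
  tm2 <- load_alignments(a3m, tdir)
  # target 4..8 map to template 7..11; the insertion is absent
  expect_equal(tm2[[1]]$mapping,
               setNames(c(1:3, 7:11), as.character(1:8)))

  # terminal gaps leave terminal positions unmapped
  gap <- paste0("--", substr(tseq, 3, 6), "--")
  tmpl3 <- structure3d("gap", nat$aa[3:6],
                       atoms = transform(at[at$res %in% 3:6, ],
                                         res = res - 2))
  write_scored_pdb(tmpl3, rep(0, 4), file.path(tdir, "gap.pdb"))
  writeLines(c(">q", tseq, ">gap", gap), a3m)
  tm3 <- load_alignments(a3m, tdir)
  expect_equal(names(tm3[[1]]$mapping), as.character(3:6))
})

test_that("clustering: singletons, duplicates and dissimilar templates", {
  nat <- make_native(12, seed = 702)
  dir <- tempfile()
  tt <- make_templates_and_alignments(nat, dir, n_templates = 1,
                                      noise = 0.2, identity = 0.9,
                                      seed = 703)
  tm <- load_alignments(tt$a3m, tt$template_dir)
  cl <- cluster_templates(tm)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$ss_c, tm[[1]]$seq_similarity)

  # two identical templates cluster together
  tm2 <- list(tm[[1]], tm[[1]])
  tm2[[2]]$template_id <- "copy"
  expect_length(cluster_templates(tm2), 1)

  # force dissimilar sequences below the threshold -> two clusters
  tm3 <- tm2
  tm3[[2]]$template_sequence <- paste(rep("W", 12), collapse = "")
  expect_length(cluster_templates(tm3, similarity_threshold = 0.95), 2)
})

test_that("ensemble construction applies the strict 15 A rule and keeps
           per-cluster counts", {
  nat <- make_native(10, seed = 704)
  # synthetic template whose CA pair sits exactly at 15.0: excluded
  ca <- matrix(0, 3, 3); ca[2, 1] <- 15; ca[3, 1] <- 5
  tm <- list(structure(list(template_id = "x",
                            mapping = setNames(1:3, 1:3),
                            template_sequence = "AAA", ca = ca,
                            seq_similarity = 0.8, seq_identity = 0.8),
                       class = "aligned_template"))
  ens <- build_ensemble(cluster_templates(tm), 3)
  expect_false(any(ens$constraints$i == 1 & ens$constraints$j == 2))
  expect_true(any(ens$constraints$i == 1 & ens$constraints$j == 3))
  # one pair, mu = 5, n = 1
  row <- ens$constraints[ens$constraints$i == 1 & ens$constraints$j == 3, ]
  expect_equal(row$mu, 5)
  expect_equal(nrow(row), 1)
})

test_that("evaluate_pair reproduces the closed-form Gaussians", {
  rows <- data.frame(i = 1L, j = 2L, cluster = 1L, mu = 7.0)
  ens <- mk_ensemble(2, ss_c = 0.9, rows = rows)
  expect_equal(evaluate_pair(ens, 1, 2, 7.0), 1.0)
  expect_equal(evaluate_pair(ens, 2, 1, 8.0), exp(-0.5), tolerance = 1e-12)
  expect_true(is.na(evaluate_pair(ens, 1, 3, 5)))

  # two clusters: weighted mean of per-cluster Gaussian means
  rows2 <- data.frame(i = 1L, j = 2L, cluster = c(1L, 1L, 2L),
                      mu = c(6, 8, 10))
  ens2 <- mk_ensemble(2, ss_c = c(0.5, 0.3), rows = rows2, gamma = 10)
  w <- exp(10 * c(0.5, 0.3)); w <- w / sum(w)
  h1 <- mean(exp(-0.5 * (7 - c(6, 8))^2)); h2 <- exp(-0.5 * (7 - 10)^2)
  expect_equal(evaluate_pair(ens2, 1, 2, 7), sum(w * c(h1, h2)),
               tolerance = 1e-12)
})

test_that("two near-identical cluster similarities yield the closed-form
           logistic weight at gamma 70", {
  rows <- data.frame(i = 1L, j = 2L, cluster = c(1L, 2L), mu = c(7, 9))
  ens <- mk_ensemble(2, ss_c = c(0.276, 0.273), rows = rows, gamma = 70)
  w_raw <- exp(70 * c(0.276, 0.273))
  w1 <- 1 / (1 + exp(-70 * (0.276 - 0.273)))
  expect_equal(w_raw[1] / sum(w_raw), w1, tolerance = 1e-12)
  # and the evaluated score uses exactly these weights
  g1 <- exp(-0.5 * (8 - 7)^2); g2 <- exp(-0.5 * (8 - 9)^2)
  expect_equal(evaluate_pair(ens, 1, 2, 8),
               w1 * g1 + (1 - w1) * g2, tolerance = 1e-12)
})

test_that("scoring a model equal to its single template gives 1 everywhere
           and uncovered residues stay invalid", {
  nat <- make_native(20, seed = 705, id = "cov")
  dir <- tempfile()
  tt <- make_templates_and_alignments(nat, dir, n_templates = 1, noise = 0,
                                      coverage = 0.5, identity = 1,
                                      seed = 706)
  tm <- load_alignments(tt$a3m, tt$template_dir)
  ens <- build_ensemble(cluster_templates(tm), 20)
  # score the template's own coordinates (as written/read): covered
  # residues all hit their Gaussian means exactly
  covered <- as.integer(names(tm[[1]]$mapping))
  model <- nat
  tmpl_s <- read_pdb(file.path(tt$template_dir, "tmpl01.pdb"))
  for (k in seq_along(covered)) {
    sel <- model$atoms$res == covered[k]
    tsel <- tmpl_s$atoms$res == k
    model$atoms[sel & model$atoms$name == "CA", c("x", "y", "z")] <-
      tmpl_s$atoms[tsel & tmpl_s$atoms$name == "CA", c("x", "y", "z")]
  }
  dr <- disco_score(ens, model)
  expect_true(all(abs(dr$score[covered] - 1) < 1e-12))
  expect_true(all(is.na(dr$score[setdiff(1:20, covered)])))
  expect_true(all(dr$features$fraction_evaluated[
    setdiff(1:20, covered)] == 0))
})

test_that("disco_score matches the straight-line oracle on noisy ensembles", {
  set.seed(707)
  for (rep in 1:20) {
    L <- sample(10:15, 1)
    nat <- make_native(L, seed = 7000 + rep)
    dir <- tempfile()
    tt <- make_templates_and_alignments(
      nat, dir, n_templates = 3, noise = c(0.3, 0.8, 1.5),
      coverage = c(1, 0.8, 0.7), identity = c(0.95, 0.7, 0.5),
      seed = 7100 + rep)
    tm <- load_alignments(tt$a3m, tt$template_dir)
    ens <- build_ensemble(cluster_templates(tm), L)
    model <- make_models(nat, runif(1, 0, 2), seed = 7200 + rep)[[1]]
    got <- disco_score(ens, model)
    expect_equal(got$score, disco_oracle(ens, model), tolerance = 1e-9)
    expect_true(all(got$score >= 0 & got$score <= 1, na.rm = TRUE))
    unlink(dir, recursive = TRUE)
  }
})

test_that("cluster weights sum to one and s_ij stays within [0,1] under
           fuzzing", {
  set.seed(708)
  for (rep in 1:30) {
    ncl <- sample(1:4, 1)
    rows <- do.call(rbind, lapply(seq_len(ncl), function(cc)
      data.frame(i = 1L, j = 2L, cluster = cc,
                 mu = runif(sample(1:5, 1), 1, 14.9))))
    ss <- runif(ncl)
    ens <- mk_ensemble(2, ss_c = ss, rows = rows,
                       gamma = sample(c(1, 10, 70, 300), 1))
    w <- exp(ens$gamma * ss); w <- w / sum(w)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    d <- runif(1, 0, 25)
    s <- evaluate_pair(ens, 1, 2, d)
    expect_true(s >= 0 && s <= 1)
  }
})

test_that("gamma controls cluster dominance monotonically, with the
           best-cluster limit at gamma -> inf", {
  rows <- data.frame(i = 1L, j = 2L, cluster = c(1L, 2L), mu = c(6, 9))
  ss <- c(0.8, 0.6)
  wbest <- function(g) {
    w <- exp(g * ss)
    (w / sum(w))[1]
  }
  gs <- c(0, 1, 10, 70, 300)
  expect_true(all(diff(sapply(gs, wbest)) >= 0))
  ens_inf <- mk_ensemble(2, ss_c = ss, rows = rows, gamma = 1e6)
  # at gamma = 1e6 the evaluation equals h of the best cluster alone
  d <- 6.7
  expect_equal(evaluate_pair(ens_inf, 1, 2, d), exp(-0.5 * (d - 6)^2),
               tolerance = 1e-12)
})

test_that("mean DisCo decreases with model perturbation amplitude", {
  nat <- make_native(18, seed = 709)
  dir <- tempfile()
  tt <- make_templates_and_alignments(nat, dir, n_templates = 2,
                                      noise = 0.3, identity = 0.9,
                                      seed = 710)
  ens <- build_ensemble(
    cluster_templates(load_alignments(tt$a3m, tt$template_dir)), 18)
  amps <- seq(0, 3, length.out = 8)
  set.seed(711)
  means <- sapply(amps, function(a)
    mean(replicate(20, {
      m <- make_models(nat, a)[[1]]
      mean(disco_score(ens, m)$score, na.rm = TRUE)
    })))
  expect_lt(cor(amps, means, method = "spearman"), 0)
  expect_true(all(diff(means) < 0.05))   # essentially monotone decline
})
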