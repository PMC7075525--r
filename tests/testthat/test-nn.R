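# a quick feature set around a small model with all optional inputs
small_feature_set <- function(seed = 801, n_corpus = 6, L = 16) {
  corpus <- lapply(seq_len(n_corpus), function(k)
    make_native(L, seed = seed + k))
  pots <- train_all_potentials(corpus)
  nat <- corpus[[1]]
  pred <- discoqa:::make_predictor_inputs(nat, 0.1, seed = seed + 50)
  ss_table <- train_ss_agreement(pred$ss_acc$state, pred$ss_state,
                                 pred$ss_conf)
  dir <- tempfile()
  tt <- make_templates_and_alignments(nat, dir, seed = seed + 60)
  ens <- build_ensemble(
    cluster_templates(load_alignments(tt$a3m, tt$template_dir)), L)
  fs <- compute_model_features(
    nat, pots, ss_table,
    sspred = list(state = pred$ss_state, conf = pred$ss_conf),
    accpred = pred$acc_state, ensemble = ens)
  unlink(dir, recursive = TRUE)
  list(fs = fs, model = nat)
}

test_that("assembled vectors have 47 dimensions, a unit one-hot and the
           documented block structure", {
  sf <- small_feature_set()
  fs <- sf$fs
  expect_equal(ncol(fs$X), 47)
  expect_equal(colnames(fs$X), feature_layout())
  onehot <- fs$X[, paste0("aa_", discoqa:::.AA20)]
  expect_true(all(rowSums(onehot) == 1))
  # interior residues with all inputs valid carry the full-vector group
  n <- nrow(fs$X)
  expect_true(all(fs$mask[2:(n - 1)] == 15L))
  # chain-terminal residues lose exactly the torsion block
  expect_equal(fs$mask[1], 15L - 1L)
  expect_equal(fs$mask[n], 15L - 1L)
  expect_true(all(is.na(fs$X[1, "torsion"])))
})

test_that("a target with no templates leaves the DisCo block invalid", {
  corpus <- lapply(1:4, function(k) make_native(14, seed = 820 + k))
  pots <- train_all_potentials(corpus)
  fs <- compute_model_features(corpus[[1]], pots)
  expect_true(all(bitwAnd(fs$mask, 8L) == 0))
  expect_true(all(is.na(fs$X[, "disco"])))
})

test_that("validity masks map bijectively onto the 16 feature groups", {
  set.seed(802)
  mask <- sample(0:15, 400, replace = TRUE)
  # group membership: a residue trains/dispatches group g iff its mask
  # covers g; its own group is exactly its mask
  for (g in 0:15) {
    cols <- discoqa:::.group_columns(g)
    expect_true(all(discoqa:::.FEAT_MANDATORY %in% cols))
    nblocks <- sum(bitwAnd(g, c(1L, 2L, 4L, 8L)) > 0)
    expect_equal(length(cols),
                 length(discoqa:::.FEAT_MANDATORY) +
                   sum(unlist(lapply(names(discoqa:::.BLOCK_BITS), function(b)
                     if (bitwAnd(g, discoqa:::.BLOCK_BITS[[b]]) > 0)
                       length(discoqa:::.FEAT_BLOCKS[[b]]) else 0))))
  }
  expect_equal(sort(unique(mask)), 0:15)
  expect_equal(length(unique(lapply(0:15, discoqa:::.group_columns))), 16)
})

test_that("hand-set weights reproduce a manual forward pass", {
  net <- list(W = list(matrix(c(1, 0, 0, -1), 2, 2),
                       matrix(c(0.5, -0.25), 2, 1)),
              b = list(c(0.1, 0.2), 0.05), sizes = c(2, 2, 1))
  X <- rbind(c(1, 2), c(-3, 0.5))
  # manual: h = relu(X W1 + b1); y = h W2 + b2
  h <- pmax(X %*% net$W[[1]] + rep(1, 2) %o% c(0.1, 0.2), 0)
  want <- h %*% net$W[[2]] + 0.05
  expect_equal(discoqa:::.mlp_forward(net, X), want, tolerance = 1e-12)
})

test_that("training is deterministic given the seed and recovers a
           constructed mapping", {
  set.seed(803)
  n <- 6000
  X <- matrix(rnorm(n * 47), n, 47, dimnames = list(NULL, feature_layout()))
  y <- pmin(1, pmax(0, (X[, 1] + X[, 2] + X[, "torsion"]) / 6 + 0.5))
  mask <- rep(1L, n)      # torsion block valid; ss/acc/disco absent
  cfg <- nn_config()
  tr <- sample(n, 4800)
  s1 <- train_nnscorer(X[tr, ], mask[tr], y[tr], cfg, seed = 9)
  s2 <- train_nnscorer(X[tr, ], mask[tr], y[tr], cfg, seed = 9)
  p1 <- predict_nnscorer(s1, X[-tr, ], mask[-tr])
  expect_identical(p1, predict_nnscorer(s2, X[-tr, ], mask[-tr]))
  expect_true(all(p1 >= 0 & p1 <= 1))
  # held-out MSE on the recoverable mapping
  expect_lt(mean((p1 - y[-tr])^2), 0.01)
})

test_that("under-populated groups fall back to a trained sub-group", {
  set.seed(804)
  n <- 1200
  X <- matrix(rnorm(n * 47), n, 47, dimnames = list(NULL, feature_layout()))
  y <- runif(n)
  mask <- rep(c(0L, 1L), c(600, 600))  # no rows ever have ss/acc/disco
  sc <- train_nnscorer(X, mask, y, nn_config(epochs = 5), seed = 1)
  expect_null(sc$nets[[16]])           # group 15 cannot be trained
  expect_true(sc$fallback[16] %in% c(0L, 1L))
  # prediction dispatch still total: any mask scores
  p <- predict_nnscorer(sc, X[1:5, ], rep(15L, 5))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(train_nnscorer(X[0, , drop = FALSE], integer(0), numeric(0),
                              nn_config()), "no training rows")
})

test_that("cross-validation partitions targets without leakage", {
  set.seed(805)
  n <- 1000
  ds <- list(features = matrix(rnorm(n * 47), n, 47,
                               dimnames = list(NULL, feature_layout())),
             mask = rep(15L, n),
             y = runif(n),
             target = rep(sprintf("t%02d", 1:10), each = 100),
             model = rep(sprintf("m%03d", 1:50), each = 20))
  cv <- cross_validate(ds, k = 5, nn_config(epochs = 2), seed = 3)
  # each fold holds exactly two targets' rows
  expect_equal(unname(table(cv$fold_of)), rep(2L, 5) , ignore_attr = TRUE)
  for (f in 1:5) {
    va_targets <- unique(ds$target[cv$fold == f])
    tr_targets <- unique(ds$target[cv$fold != f])
    expect_length(intersect(va_targets, tr_targets), 0)
  }
  expect_true(all(!is.na(cv$predictions)))
  expect_error(cross_validate(list(target = c("a", "b"), y = 1:2), k = 5),
               "at least 5")
})

test_that("dataset blending keeps the requested row counts", {
  mk <- function(n, tag) list(
    features = matrix(0, n, 47, dimnames = list(NULL, feature_layout())),
    mask = rep(15L, n), y = runif(n),
    target = rep(tag, n), model = rep(tag, n))
  a <- mk(100, "a"); b <- mk(60, "b")
  ab <- blend_datasets(a, b, fraction = 0.5, seed = 4)
  expect_equal(length(ab$y), 50 + 30)
  expect_equal(sum(ab$target == "a"), 50)
  # same seed, same blend
  ab2 <- blend_datasets(a, b, fraction = 0.5, seed = 4)
  expect_identical(ab$y, ab2$y)
})

test_that("scorer serialization round-trips predictions bit-exactly", {
  set.seed(806)
  n <- 900
  X <- matrix(rnorm(n * 47), n, 47, dimnames = list(NULL, feature_layout()))
  mask <- sample(c(7L, 15L), n, replace = TRUE)
  sc <- train_nnscorer(X, mask, runif(n), nn_config(epochs = 3), seed = 2)
  path <- tempfile(fileext = ".json")
  write_nnscorer(sc, path)
  sc2 <- read_nnscorer(path)
  expect_identical(predict_nnscorer(sc, X, mask),
                   predict_nnscorer(sc2, X, mask))
})
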