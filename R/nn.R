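# Feed-forward scorer fusing all per-residue terms into a predicted lDDT.
# Residues differ in which feature blocks are available (terminal residues
# have no torsion; targets without templates have no DisCo; predictor files
# may be absent), so one scorer holds 16 small networks - one per subset of
# the four optional blocks - and dispatches each residue to the network
# matching its validity mask. Networks are plain ReLU MLPs trained with
# RMSprop on mean squared error against per-residue lDDT.

# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

# ---- feature vector layout ----------------------------------------------

.FEAT_MANDATORY <- c("all_atom", "cb_interaction", "reduced", "packing",
                     "cb_packing", "rel_acc", "clash", "n_count",
                     "avg_all_atom", "avg_cb_interaction", "avg_reduced",
                     "avg_packing", "avg_cb_packing", "avg_torsion",
                     paste0("aa_", .AA20))
.FEAT_BLOCKS <- list(
  torsion = "torsion",
  ss = c("ss_agree", "avg_ss_agree"),
  acc = c("acc_agree", "avg_acc_agree"),
  disco = c("disco", "avg_n_clusters", "avg_max_seq_similarity",
            "avg_max_seq_identity", "avg_variance", "n_evaluated_pairs",
            "n_total_pairs", "fraction_evaluated"))

#' Feature-vector layout
#'
#' Column names of the full 47-dimensional per-residue feature vector:
#' 26 mandatory slots (5 interaction/packing potentials, scaled
#' accessibility, clash, local residue count N, 6 full-model averages and
#' the 20-dimensional amino-acid one-hot) plus 4 optional blocks (torsion;
#' secondary-structure agreement; accessibility agreement; DisCo score with
#' its 7 reliability features).
#'
#' @return character vector of 47 column names.
#' @export
feature_layout <- function() {
  c(.FEAT_MANDATORY, unlist(.FEAT_BLOCKS, use.names = FALSE))
}

.BLOCK_BITS <- c(torsion = 1L, ss = 2L, acc = 4L, disco = 8L)

#' Assemble per-residue feature vectors
#'
#' Applies spherical smoothing (sigma 5 A) to every per-residue term
#' except the residue count N and the DisCo block, computes full-model
#' averages over valid residues, and attaches the amino-acid one-hot.
#' Optional blocks (torsion, secondary-structure agreement, accessibility
#' agreement, DisCo) are flagged invalid per residue where the underlying
#' value is unavailable; the resulting validity mask (integer 0..15)
#' selects which of the 16 networks scores the residue.
#'
#' @param model a `structure3d`.
#' @param potentials named list of 6 per-residue potential score vectors
#'   (`all_atom`, `cb_interaction`, `reduced`, `packing`, `cb_packing`,
#'   `torsion`).
#' @param rel_acc,clash,n_count per-residue vectors from the local-feature
#'   terms.
#' @param ss_agree,acc_agree per-residue agreement vectors or NULL when
#'   the corresponding prediction input is missing.
#' @param disco a `disco_result` or NULL.
#' @param smooth_sigma smoothing width in Angstrom.
#' @return list of class `feature_set`: `X` (n x 47 matrix, NA in invalid
#'   optional slots), `mask` (integer validity mask per residue),
#'   `layout` (column names).
#' @export
assemble_features <- function(model, potentials, rel_acc, clash, n_count,
                              ss_agree = NULL, acc_agree = NULL,
                              disco = NULL, smooth_sigma = 5) {
  n <- n_residues(model)
  need <- c("all_atom", "cb_interaction", "reduced", "packing",
            "cb_packing", "torsion")
  stopifnot(all(need %in% names(potentials)))
  lens <- c(vapply(potentials[need], length, 0L), length(rel_acc),
            length(clash), length(n_count))
  if (any(lens != n)) stop("feature inputs must have one value per residue")

  sm <- function(v) spherical_smooth(v, model, smooth_sigma)
  torsion_valid <- !is.na(potentials$torsion)
  p <- lapply(potentials[need], sm)
  rel_acc_s <- sm(rel_acc)
  clash_s <- sm(clash)
  ss_s <- if (!is.null(ss_agree)) sm(ss_agree)
  acc_s <- if (!is.null(acc_agree)) sm(acc_agree)

  avg <- function(v) if (all(is.na(v))) 0 else mean(v, na.rm = TRUE)
  X <- matrix(NA_real_, n, length(feature_layout()),
              dimnames = list(NULL, feature_layout()))
  fill0 <- function(v) ifelse(is.na(v), 0, v)
  X[, "all_atom"] <- fill0(p$all_atom)
  X[, "cb_interaction"] <- fill0(p$cb_interaction)
  X[, "reduced"] <- fill0(p$reduced)
  X[, "packing"] <- fill0(p$packing)
  X[, "cb_packing"] <- fill0(p$cb_packing)
  X[, "rel_acc"] <- fill0(rel_acc_s)
  X[, "clash"] <- fill0(clash_s)
  X[, "n_count"] <- fill0(n_count)
  X[, "avg_all_atom"] <- avg(p$all_atom)
  X[, "avg_cb_interaction"] <- avg(p$cb_interaction)
  X[, "avg_reduced"] <- avg(p$reduced)
  X[, "avg_packing"] <- avg(p$packing)
  X[, "avg_cb_packing"] <- avg(p$cb_packing)
  X[, "avg_torsion"] <- avg(p$torsion)
  onehot <- matrix(0, n, 20)
  hit <- match(model$aa, .AA20)
  onehot[cbind(which(!is.na(hit)), hit[!is.na(hit)])] <- 1
  X[, paste0("aa_", .AA20)] <- onehot

  mask <- rep(0L, n)
  tv <- torsion_valid & !is.na(p$torsion)
  X[tv, "torsion"] <- p$torsion[tv]
  mask <- mask + .BLOCK_BITS["torsion"] * tv
  if (!is.null(ss_agree)) {
    sv <- !is.na(ss_s)
    X[sv, "ss_agree"] <- ss_s[sv]
    X[sv, "avg_ss_agree"] <- avg(ss_s)
    mask <- mask + .BLOCK_BITS["ss"] * sv
  }
  if (!is.null(acc_agree)) {
    av <- !is.na(acc_s)
    X[av, "acc_agree"] <- acc_s[av]
    X[av, "avg_acc_agree"] <- avg(acc_s)
    mask <- mask + .BLOCK_BITS["acc"] * av
  }
  if (!is.null(disco)) {
    dv <- !is.na(disco$score)
    X[dv, "disco"] <- disco$score[dv]
    fcols <- c("avg_n_clusters", "avg_max_seq_similarity",
               "avg_max_seq_identity", "avg_variance",
               "n_evaluated_pairs", "n_total_pairs", "fraction_evaluated")
    for (fc in fcols) X[dv, fc] <- fill0(disco$features[[fc]])[dv]
    mask <- mask + .BLOCK_BITS["disco"] * dv
  }
  structure(list(X = X, mask = as.integer(mask), layout = feature_layout()),
            class = "feature_set")
}

# columns used by feature group g (bitmask over the 4 optional blocks)
.group_columns <- function(g) {
  cols <- .FEAT_MANDATORY
  for (b in names(.BLOCK_BITS))
    if (bitwAnd(g, .BLOCK_BITS[[b]]) > 0) cols <- c(cols, .FEAT_BLOCKS[[b]])
  cols
}

#' NN training configuration
#'
#' Defaults are the production choice: mse loss, RMSprop, 100 epochs,
#' batch size 400, hidden topology 20-20-20 with ReLU, linear output
#' clamped to [0,1] at prediction time.
#'
#' @param hidden hidden layer sizes.
#' @param epochs,batch training schedule.
#' @param lr,rho,eps RMSprop parameters.
#' @param optimizer `"rmsprop"` (default) or `"sgd"`.
#' @param loss `"mse"` (default) or `"absolute"`.
#' @return list of class `nn_config`.
#' @export
nn_config <- function(hidden = c(20, 20, 20), epochs = 100, batch = 400,
                      lr = 1e-3, rho = 0.9, eps = 1e-8,
                      optimizer = "rmsprop", loss = "mse") {
  structure(as.list(environment()), class = "nn_config")
}

# ---- minimal MLP ---------------------------------------------------------

.mlp_init <- function(sizes) {
  L <- length(sizes) - 1
  W <- b <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- sqrt(6 / sizes[l])            # He-uniform
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b, sizes = sizes)
}

.mlp_forward <- function(net, X, keep = FALSE) {
  L <- length(net$W)
  A <- list(X)
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    A[[l + 1]] <- if (l < L) pmax(Z, 0) else Z
  }
  if (keep) A else A[[L + 1]]
}

.mlp_train <- function(net, X, y, cfg) {
  n <- nrow(X)
  L <- length(net$W)
  cW <- lapply(net$W, function(w) w * 0)
  cb <- lapply(net$b, function(b) b * 0)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = cfg$batch)
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch - 1, n)]
      A <- .mlp_forward(net, X[idx, , drop = FALSE], keep = TRUE)
      yhat <- A[[L + 1]][, 1]
      m <- length(idx)
      delta <- if (cfg$loss == "absolute")
        matrix(sign(yhat - y[idx]) / m, ncol = 1)
      else matrix(2 * (yhat - y[idx]) / m, ncol = 1)
      for (l in L:1) {
        gW <- crossprod(A[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) delta <- (delta %*% t(net$W[[l]])) * (A[[l]] > 0)
        if (cfg$optimizer == "rmsprop") {
          cW[[l]] <- cfg$rho * cW[[l]] + (1 - cfg$rho) * gW^2
          cb[[l]] <- cfg$rho * cb[[l]] + (1 - cfg$rho) * gb^2
          net$W[[l]] <- net$W[[l]] - cfg$lr * gW / sqrt(cW[[l]] + cfg$eps)
          net$b[[l]] <- net$b[[l]] - cfg$lr * gb / sqrt(cb[[l]] + cfg$eps)
        } else {
          net$W[[l]] <- net$W[[l]] - cfg$lr * gW
          net$b[[l]] <- net$b[[l]] - cfg$lr * gb
        }
      }
    }
  }
  net
}

# ---- NNScorer ------------------------------------------------------------

#' Train an NNScorer
#'
#' Trains one network per feature group. Group g's network sees the
#' mandatory features plus the blocks in g; its training rows are all
#' residues whose validity mask covers g (richer residues participate with
#' the subset of their features). Features are z-scored per group with the
#' standardization parameters stored. Groups with fewer rows than one
#' batch are not trained; they fall back to the best-populated sub-group's
#' network, ultimately the mandatory-only network, which is always trained.
#'
#' @param features a `feature_set` or a matrix laid out as
#'   [feature_layout()].
#' @param mask integer validity mask per row (0..15).
#' @param y per-residue lDDT targets in [0,1].
#' @param config an [nn_config()].
#' @param seed integer seed; training is bit-reproducible given the seed.
#' @return object of class `nn_scorer`.
#' @export
train_nnscorer <- function(features, mask, y, config = nn_config(),
                           seed = 1) {
  if (inherits(features, "feature_set")) {
    mask <- features$mask
    features <- features$X
  }
  stopifnot(nrow(features) == length(mask), length(mask) == length(y),
            all(y >= 0 & y <= 1))
  nets <- vector("list", 16)
  scal <- vector("list", 16)
  nrows <- integer(16)
  for (g in 0:15) {
    rows <- which(bitwAnd(mask, g) == g)
    nrows[g + 1] <- length(rows)
  }
  if (nrows[1] == 0) stop("no training rows available")
  for (g in 0:15) {
    rows <- which(bitwAnd(mask, g) == g)
    if (g > 0 && length(rows) < config$batch) next   # fallback later
    cols <- .group_columns(g)
    X <- features[rows, cols, drop = FALSE]
    mu <- colMeans(X)
    sd <- apply(X, 2, stats::sd)
    sd[sd < 1e-9] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sd, "/")
    net <- with_seed(seed + g, {
      net0 <- .mlp_init(c(length(cols), config$hidden, 1))
      .mlp_train(net0, Xs, y[rows], config)
    })
    nets[[g + 1]] <- net
    scal[[g + 1]] <- list(mu = mu, sd = sd, cols = cols)
  }
  # resolve fallbacks: untrained group -> trained sub-group with most rows
  fallback <- integer(16)
  for (g in 0:15) {
    if (!is.null(nets[[g + 1]])) { fallback[g + 1] <- g; next }
    subs <- Filter(function(h) bitwAnd(h, g) == h && !is.null(nets[[h + 1]]),
                   0:15)
    best <- subs[which.max(nrows[subs + 1])]
    fallback[g + 1] <- best
  }
  structure(list(nets = nets, scaling = scal, fallback = fallback,
                 n_rows = nrows, config = config, seed = seed,
                 layout = feature_layout()), class = "nn_scorer")
}

#' @export
print.nn_scorer <- function(x, ...) {
  trained <- sum(!vapply(x$nets, is.null, TRUE))
  cat(sprintf("nn_scorer: %d/16 group networks trained (seed %d)\n",
              trained, x$seed))
  invisible(x)
}

#' Predict per-residue lDDT with an NNScorer
#'
#' Each residue is dispatched to the network of its validity mask (or that
#' group's fallback); outputs are clamped to [0,1].
#'
#' @param scorer a trained `nn_scorer`.
#' @param features a `feature_set` or feature matrix.
#' @param mask integer validity mask per row; when NULL and `features` is
#'   a `feature_set`, taken from it. Masks can be overridden to ablate
#'   blocks (e.g. clear the DisCo bit).
#' @return numeric vector of predictions in [0,1].
#' @export
predict_nnscorer <- function(scorer, features, mask = NULL) {
  if (inherits(features, "feature_set")) {
    if (is.null(mask)) mask <- features$mask
    features <- features$X
  }
  stopifnot(!is.null(mask), nrow(features) == length(mask))
  out <- rep(NA_real_, nrow(features))
  for (g in unique(mask)) {
    use <- scorer$fallback[g + 1]
    net <- scorer$nets[[use + 1]]
    sc <- scorer$scaling[[use + 1]]
    rows <- which(mask == g)
    X <- features[rows, sc$cols, drop = FALSE]
    X[is.na(X)] <- 0   # cannot occur for valid blocks; belt and braces
    Xs <- sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")
    out[rows] <- pmin(1, pmax(0, .mlp_forward(net, Xs)[, 1]))
  }
  out
}

#' Target-level k-fold cross-validation
#'
#' Folds partition modelling targets (never residues or models): every
#' residue of every model of a target lands in the same fold. Returns
#' pooled out-of-fold predictions plus per-fold overall AUCs.
#'
#' @param dataset list with `features` (matrix), `mask`, `y`, `target`
#'   (target id per row), `model` (model id per row).
#' @param k number of folds.
#' @param config an [nn_config()].
#' @param seed seed for fold assignment and training.
#' @param cut classification cut for the per-fold AUC diagnostic.
#' @return list with `predictions` (pooled, row order of `dataset`),
#'   `fold` (fold id per row), `fold_auc`, and `scorers` (one per fold).
#' @export
cross_validate <- function(dataset, k = 5, config = nn_config(), seed = 1,
                           cut = 0.6) {
  targets <- sort(unique(dataset$target))
  if (length(targets) < k)
    stop("need at least ", k, " distinct targets for ", k, "-fold CV")
  fold_of <- with_seed(seed, {
    stats::setNames(rep(seq_len(k), length.out = length(targets))[
      sample.int(length(targets))], targets)
  })
  rowfold <- fold_of[dataset$target]
  preds <- rep(NA_real_, length(dataset$y))
  scorers <- vector("list", k)
  fold_auc <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    tr <- rowfold != f
    scorer <- train_nnscorer(dataset$features[tr, , drop = FALSE],
                             dataset$mask[tr], dataset$y[tr],
                             config, seed = seed + 1000 * f)
    scorers[[f]] <- scorer
    va <- which(!tr)
    preds[va] <- predict_nnscorer(scorer,
                                  dataset$features[va, , drop = FALSE],
                                  dataset$mask[va])
    lab <- classify_correct(dataset$y[va], cut)
    fold_auc[f] <- roc_auc(preds[va], lab)
  }
  list(predictions = preds, fold = unname(rowfold), fold_of = fold_of,
       fold_auc = fold_auc, scorers = scorers)
}

#' Blend two datasets
#'
#' Randomly selects a fraction of the rows of each dataset (sampling on
#' data points) and concatenates them, e.g. to build a mixed training set.
#'
#' @param a,b datasets as in [cross_validate()].
#' @param fraction fraction of rows kept from each.
#' @param seed RNG seed.
#' @return a dataset of the same shape.
#' @export
blend_datasets <- function(a, b, fraction = 0.5, seed = 1) {
  pick <- function(d, idx) list(features = d$features[idx, , drop = FALSE],
                                mask = d$mask[idx], y = d$y[idx],
                                target = d$target[idx], model = d$model[idx])
  with_seed(seed, {
    ia <- sort(sample.int(length(a$y), round(fraction * length(a$y))))
    ib <- sort(sample.int(length(b$y), round(fraction * length(b$y))))
    da <- pick(a, ia); db <- pick(b, ib)
    list(features = rbind(da$features, db$features),
         mask = c(da$mask, db$mask), y = c(da$y, db$y),
         target = c(da$target, db$target), model = c(da$model, db$model))
  })
}

#' Serialize / restore an NNScorer
#' @param scorer a trained `nn_scorer`.
#' @param path file path (JSON container with format version).
#' @export
write_nnscorer <- function(scorer, path) {
  enc_net <- function(net) if (is.null(net)) NULL else
    list(sizes = net$sizes,
         W = lapply(net$W, .enc_num),
         b = lapply(net$b, .enc_num))
  payload <- list(format = "discoqa-nnscorer", version = 1L,
                  layout = scorer$layout, seed = scorer$seed,
                  fallback = scorer$fallback, n_rows = scorer$n_rows,
                  config = unclass(scorer$config),
                  nets = lapply(scorer$nets, enc_net),
                  scaling = lapply(scorer$scaling, function(s)
                    if (is.null(s)) NULL else
                      list(mu = .enc_num(s$mu), sd = .enc_num(s$sd),
                           cols = s$cols)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_nnscorer
#' @export
read_nnscorer <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$format, "discoqa-nnscorer"))
    stop("not an nn_scorer container: ", path)
  dec_net <- function(nl) {
    if (is.null(nl)) return(NULL)
    sizes <- unlist(nl$sizes)
    W <- lapply(seq_along(nl$W), function(l)
      matrix(.dec_num(nl$W[[l]]), sizes[l], sizes[l + 1]))
    list(W = W, b = lapply(nl$b, .dec_num), sizes = sizes)
  }
  cfg <- structure(p$config, class = "nn_config")
  cfg$hidden <- unlist(cfg$hidden)
  structure(list(
    nets = lapply(p$nets, dec_net),
    scaling = lapply(p$scaling, function(s) if (is.null(s)) NULL else
      list(mu = stats::setNames(.dec_num(s$mu), unlist(s$cols)),
           sd = stats::setNames(.dec_num(s$sd), unlist(s$cols)),
           cols = unlist(s$cols))),
    fallback = unlist(p$fallback), n_rows = unlist(p$n_rows),
    config = cfg, seed = p$seed, layout = unlist(p$layout)),
    class = "nn_scorer")
}
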