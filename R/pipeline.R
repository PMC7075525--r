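# End-to-end orchestration: compute all per-residue terms for one model,
# train the reference checkpoints (potential tables, secondary-structure
# agreement table, NNScorer, error model) from synthetic corpora, and
# score models with graceful degradation when optional inputs are absent.

.POT_TERMS <- c("all_atom", "cb_interaction", "reduced", "packing",
                "cb_packing", "torsion")

#' Train the six potential tables on a corpus
#'
#' @param corpus list of `structure3d` objects.
#' @param config a [potential_config()].
#' @return named list of `potential_table`s.
#' @export
train_all_potentials <- function(corpus, config = potential_config()) {
  stats::setNames(lapply(.POT_TERMS, train_potential, corpus = corpus,
                         config = config), .POT_TERMS)
}

#' Compute the full per-residue feature set for one model
#'
#' Runs the six potential terms, the DSSP-equivalent secondary structure
#' and accessibility, the agreement terms (when predictions are given),
#' clash, local residue count, DisCo (when an ensemble is given), applies
#' spherical smoothing and assembles the feature vectors. Missing optional
#' inputs simply leave the corresponding feature block invalid.
#'
#' @param model a `structure3d`.
#' @param potentials named list of the six trained `potential_table`s.
#' @param ss_table an `ss_agreement_table` (needed only when `sspred`
#'   is given).
#' @param sspred list with `state` and `conf` (e.g. from
#'   [read_psipred()]) or NULL.
#' @param accpred character vector of `"b"`/`"e"` (e.g. from
#'   [read_accpro()]) or NULL.
#' @param ensemble a `constraint_ensemble` or NULL; ignored (with a
#'   warning) when its target length does not match the model.
#' @return a `feature_set` (see [assemble_features()]); the DisCo result,
#'   when computed, is attached as attribute `"disco"`.
#' @export
compute_model_features <- function(model, potentials, ss_table = NULL,
                                   sspred = NULL, accpred = NULL,
                                   ensemble = NULL) {
  stopifnot(all(.POT_TERMS %in% names(potentials)))
  pots <- lapply(potentials[.POT_TERMS], score_potential, model = model)
  sa <- assign_ss_and_acc(model)
  n <- n_residues(model)

  ss_agree_v <- NULL
  if (!is.null(sspred)) {
    if (is.null(ss_table)) stop("secondary-structure prediction given ",
                                "but no agreement table")
    if (length(sspred$state) != n)
      stop("secondary-structure prediction length mismatch")
    ss_agree_v <- ss_agreement(ss_table, sa$state, sspred$state,
                               sspred$conf)
  }
  acc_agree_v <- NULL
  if (!is.null(accpred)) {
    if (length(accpred) != n) stop("accessibility prediction length mismatch")
    acc_agree_v <- acc_agreement(sa$acc, model$aa, accpred)
  }
  disco <- NULL
  if (!is.null(ensemble)) {
    if (ensemble$target_length != n) {
      warning("constraint ensemble ignored: target length ",
              ensemble$target_length, " vs model length ", n)
    } else {
      disco <- disco_score(ensemble, model)
    }
  }
  fs <- assemble_features(model, pots, rel_acc = sa$rel_acc,
                          clash = clash_score(model),
                          n_count = residue_count_n(model),
                          ss_agree = ss_agree_v, acc_agree = acc_agree_v,
                          disco = disco)
  attr(fs, "disco") <- disco
  attr(fs, "ss_acc") <- sa
  fs
}

#' Build a synthetic training/evaluation dataset
#'
#' The standard study corpus: `n_targets` idealized natives, each with
#' `models_per_target` perturbed models whose noise amplitudes span 0 to
#' `noise_max` Angstrom, templates (noisy, partially covering, mutated)
#' with a consistent alignment, and mock predictor files. Per residue of
#' every model: the assembled feature vector, its validity mask and the
#' true lDDT against the native.
#'
#' @param potentials,ss_table trained checkpoints used to featurize.
#' @param n_targets,models_per_target,noise_max corpus dimensions.
#' @param length_range residue-count range, sampled per target.
#' @param n_templates,template_noise,template_coverage,template_identity
#'   template generation controls (recycled per template).
#' @param predictor_error corruption rate of the mock predictions.
#' @param seed RNG seed governing the whole corpus.
#' @return dataset list: `features`, `mask`, `y`, `target`, `model`,
#'   `global` (data frame of per-model global lDDT and mean prediction
#'   inputs), usable with [cross_validate()].
#' @export
build_quality_dataset <- function(potentials, ss_table,
                                  n_targets = 30, models_per_target = 8,
                                  noise_max = 3,
                                  length_range = c(30, 42),
                                  n_templates = 4,
                                  template_noise = c(0.3, 0.6, 1, 1.5),
                                  template_coverage = c(1, 1, 0.8, 0.6),
                                  template_identity = c(0.95, 0.85, 0.7, 0.6),
                                  predictor_error = 0.15,
                                  seed = 7) {
  rows_X <- list(); rows_meta <- list()
  glob <- list()
  for (t in seq_len(n_targets)) {
    tid <- sprintf("t%03d", t)
    tseed <- seed + 1009 * t
    L <- with_seed(tseed, sample(length_range[1]:length_range[2], 1))
    native <- make_native(L, seed = tseed + 1, id = tid)
    tdir <- file.path(tempdir(), sprintf("discoqa_tmpl_%s_%d", tid, seed))
    tt <- make_templates_and_alignments(
      native, tdir, n_templates = n_templates, noise = template_noise,
      coverage = template_coverage, identity = template_identity,
      seed = tseed + 2)
    templates <- load_alignments(tt$a3m, tt$template_dir)
    ens <- build_ensemble(cluster_templates(templates), L)
    pred <- make_predictor_inputs(native, predictor_error,
                                  seed = tseed + 3)
    models <- make_models(native,
                          seq(0, noise_max,
                              length.out = models_per_target),
                          seed = tseed + 4)
    unlink(tdir, recursive = TRUE)
    for (m in models) {
      fs <- compute_model_features(
        m, potentials, ss_table,
        sspred = list(state = pred$ss_state, conf = pred$ss_conf),
        accpred = pred$acc_state, ensemble = ens)
      ld <- compute_lddt(m, native)
      keep <- !is.na(ld$per_residue)
      rows_X[[length(rows_X) + 1]] <- fs$X[keep, , drop = FALSE]
      rows_meta[[length(rows_meta) + 1]] <- data.frame(
        mask = fs$mask[keep], y = ld$per_residue[keep],
        target = tid, model = m$id, stringsAsFactors = FALSE)
      glob[[length(glob) + 1]] <- data.frame(
        target = tid, model = m$id, n_res = n_residues(m),
        global_lddt = ld$global_score, stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, rows_meta)
  list(features = do.call(rbind, rows_X), mask = meta$mask, y = meta$y,
       target = meta$target, model = meta$model,
       global = do.call(rbind, glob))
}

#' Train the full set of scoring checkpoints
#'
#' From scratch, on synthetic corpora: the six potential tables (trained
#' on idealized natives), the secondary-structure agreement table, the
#' NNScorer (trained on a perturbation corpus via
#' [build_quality_dataset()]) and the length-windowed expected-error
#' model derived from held-out global predictions.
#'
#' @param seed master seed.
#' @param n_potential_corpus natives used to train the potentials.
#' @param nn_args list of overrides passed to [build_quality_dataset()].
#' @param config an [nn_config()].
#' @return list of class `checkpoints`: `potentials`, `ss_table`,
#'   `scorer`, `error_model`, `dataset` (the training corpus), `cv`
#'   (cross-validation output).
#' @export
train_checkpoints <- function(seed = 7, n_potential_corpus = 200,
                              nn_args = list(), config = nn_config()) {
  corpus <- lapply(seq_len(n_potential_corpus), function(k)
    with_seed(seed + 31 * k,
              make_native(sample(30:42, 1),
                          id = sprintf("train%03d", k))))
  potentials <- train_all_potentials(corpus)

  # agreement table from uncorrupted + corrupted predictor pairs
  ss_d <- character(0); ss_p <- character(0); ss_c <- integer(0)
  for (k in seq_len(min(40, n_potential_corpus))) {
    pred <- make_predictor_inputs(corpus[[k]], error_rate = 0.15,
                                  seed = seed + 7000 + k)
    ss_d <- c(ss_d, pred$ss_acc$state)
    ss_p <- c(ss_p, pred$ss_state)
    ss_c <- c(ss_c, pred$ss_conf)
  }
  ss_table <- train_ss_agreement(ss_d, ss_p, ss_c)

  dataset <- do.call(build_quality_dataset,
                     c(list(potentials = potentials, ss_table = ss_table,
                            seed = seed), nn_args))
  cv <- cross_validate(dataset, k = 5, config = config, seed = seed)
  scorer <- train_nnscorer(dataset$features, dataset$mask, dataset$y,
                           config, seed = seed)

  # expected-error reference from the out-of-fold global predictions
  pg <- tapply(cv$predictions, dataset$model, mean, na.rm = TRUE)
  gl <- dataset$global
  err <- abs(as.numeric(pg[gl$model]) - gl$global_lddt)
  em <- error_model(gl$n_res, err)

  structure(list(potentials = potentials, ss_table = ss_table,
                 scorer = scorer, error_model = em,
                 dataset = dataset, cv = cv, seed = seed),
            class = "checkpoints")
}

#' Score a protein model end to end
#'
#' Computes all single-model terms, DisCo (when alignments and template
#' coordinates are available), dispatches every residue to the matching
#' feature-group network and returns per-residue predicted lDDT plus the
#' global score, its coverage-normalized variant and the length-dependent
#' expected error. Missing optional inputs (predictions, templates)
#' degrade gracefully to the corresponding feature group.
#'
#' @param model a `structure3d` or path to a PDB file.
#' @param checkpoints a `checkpoints` object (see [train_checkpoints()]).
#' @param target_sequence target sequence string or FASTA path; defaults
#'   to the model's own sequence.
#' @param a3m,template_dir alignment file + template coordinate directory
#'   (both or neither).
#' @param sspred path to a PSIPRED .ss2 file, or a list as returned by
#'   [read_psipred()], or NULL.
#' @param accpred path to an ACCpro two-state file, or a character
#'   vector, or NULL.
#' @param reference optional reference `structure3d`/PDB path; when given,
#'   true lDDT values are included for comparison.
#' @param gamma DisCo cluster-weighting constant.
#' @return object of class `quality_result`.
#' @export
qe_score <- function(model, checkpoints, target_sequence = NULL,
                     a3m = NULL, template_dir = NULL,
                     sspred = NULL, accpred = NULL, reference = NULL,
                     gamma = 70) {
  if (is.character(model)) model <- read_pdb(model)
  if (!is.null(target_sequence) && file.exists(target_sequence))
    target_sequence <- unname(read_fasta_seq(target_sequence))
  if (is.null(target_sequence)) target_sequence <- extract_sequence(model)
  if (is.character(sspred)) sspred <- read_psipred(sspred)
  if (is.character(accpred) && length(accpred) == 1 &&
      file.exists(accpred)) accpred <- read_accpro(accpred)

  ensemble <- NULL
  if (!is.null(a3m)) {
    if (is.null(template_dir)) stop("a3m given without template_dir")
    templates <- load_alignments(a3m, template_dir)
    ensemble <- build_ensemble(cluster_templates(templates),
                               nchar(target_sequence), gamma = gamma)
    if (ensemble$target_length != n_residues(model)) {
      warning("model covers ", n_residues(model), " of ",
              ensemble$target_length,
              " target residues; DisCo disabled for this model")
      ensemble <- NULL
    }
  }
  # predictions index the target sequence; apply only on full coverage
  n <- n_residues(model)
  if (!is.null(sspred) && length(sspred$state) != n) {
    warning("secondary-structure prediction length mismatch; ignored")
    sspred <- NULL
  }
  if (!is.null(accpred) && length(accpred) != n) {
    warning("accessibility prediction length mismatch; ignored")
    accpred <- NULL
  }
  fs <- compute_model_features(model, checkpoints$potentials,
                               checkpoints$ss_table, sspred = sspred,
                               accpred = accpred, ensemble = ensemble)
  pred <- predict_nnscorer(checkpoints$scorer, fs)
  glob <- global_from_local(pred)
  cov <- model_coverage(model, target_sequence)
  res <- list(
    model_id = model$id,
    per_residue = pred,
    residue_aa = model$aa,
    global_score = glob,
    coverage = cov,
    normalized_score = cov * glob,
    expected_error = expected_error(checkpoints$error_model, n),
    model_length = n,
    mode = if (is.null(ensemble)) "single-model" else "disco",
    feature_mask = fs$mask)
  if (!is.null(reference)) {
    if (is.character(reference)) reference <- read_pdb(reference)
    ld <- compute_lddt(model, reference)
    res$reference_lddt <- ld$per_residue
    res$reference_global_lddt <- ld$global_score
  }
  structure(res, class = "quality_result")
}

#' @export
print.quality_result <- function(x, ...) {
  cat(sprintf(
    "quality_result '%s' (%s mode): global %.3f (normalized %.3f, coverage %.2f), expected error %.3f\n",
    x$model_id, x$mode, x$global_score, x$normalized_score, x$coverage,
    x$expected_error))
  invisible(x)
}

#' Write a quality result as JSON / TSV
#' @param result a `quality_result`.
#' @param path output file.
#' @export
write_quality_json <- function(result, path) {
  jsonlite::write_json(
    list(model_id = result$model_id, mode = result$mode,
         global_score = result$global_score,
         normalized_score = result$normalized_score,
         coverage = result$coverage,
         expected_error = result$expected_error,
         model_length = result$model_length,
         per_residue = result$per_residue,
         reference_lddt = result$reference_lddt),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_quality_json
#' @export
write_quality_tsv <- function(result, path) {
  df <- data.frame(index = seq_along(result$per_residue),
                   aa = result$residue_aa,
                   predicted_lddt = round(result$per_residue, 4))
  if (!is.null(result$reference_lddt))
    df$reference_lddt <- round(result$reference_lddt, 4)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a full checkpoint set
#' @param cp a `checkpoints` object.
#' @param dir directory for the container files.
#' @export
write_checkpoints <- function(cp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_potentials(cp$potentials, file.path(dir, "potentials.json"))
  write_nnscorer(cp$scorer, file.path(dir, "nnscorer.json"))
  jsonlite::write_json(
    list(format = "discoqa-aux", version = 1L,
         ss_S = .enc_num(cp$ss_table$S), ss_n = cp$ss_table$n,
         ss_pseudo = cp$ss_table$pseudo,
         err_length = cp$error_model$length,
         err_values = .enc_num(cp$error_model$err),
         err_half_width = cp$error_model$half_width,
         seed = cp$seed),
    file.path(dir, "aux.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_checkpoints
#' @export
read_checkpoints <- function(dir) {
  aux <- jsonlite::read_json(file.path(dir, "aux.json"),
                             simplifyVector = FALSE)
  S <- array(.dec_num(aux$ss_S), dim = c(8, 3, 10),
             dimnames = list(.DSSP8, .PRED3, 0:9))
  structure(list(
    potentials = read_potentials(file.path(dir, "potentials.json")),
    scorer = read_nnscorer(file.path(dir, "nnscorer.json")),
    ss_table = structure(list(S = S, n = aux$ss_n,
                              pseudo = aux$ss_pseudo),
                         class = "ss_agreement_table"),
    error_model = error_model(unlist(aux$err_length),
                              .dec_num(aux$err_values),
                              aux$err_half_width),
    seed = aux$seed), class = "checkpoints")
}
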