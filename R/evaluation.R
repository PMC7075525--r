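# ROC-based evaluation of per-residue quality predictions: pooled overall
# AUC plus the mean per-model AUC (the expected AUC when looking at one
# particular model), with the exclusion rule for models on which an AUC is
# undefined.

#' Rank-based ROC AUC
#'
#' Mann-Whitney statistic with midrank tie correction; exact and
#' deterministic, no binning. Rows with NA prediction or label are
#' dropped.
#'
#' @param predictions numeric scores (higher = more likely positive).
#' @param labels binary 0/1 labels.
#' @return AUC in [0,1], or NA when only one class is present.
#' @export
roc_auc <- function(predictions, labels) {
  ok <- !is.na(predictions) & !is.na(labels)
  p <- predictions[ok]; l <- labels[ok]
  n1 <- sum(l == 1); n0 <- sum(l == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p)
  (sum(r[l == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate per-residue predictions
#'
#' Computes the pooled overall AUC over all residues and the mean
#' per-model AUC for the `score > cut` correctness classification.
#' Models on which the AUC is undefined - all residues labelled equally,
#' or constant predictions - are excluded from the per-model mean (they
#' still contribute to the pooled AUC).
#'
#' @param predictions numeric per-residue predictions.
#' @param lddt per-residue reference lDDT values in [0,1] (NA excluded).
#' @param model character/factor model id per residue.
#' @param cut correctness classification cut (default 0.6, strict >).
#' @return list of class `evaluation_report`: `overall_auc`,
#'   `per_model` (data frame: model, auc, excluded), `mean_per_model_auc`,
#'   `n_excluded_models`, `cut`.
#' @export
evaluate_predictions <- function(predictions, lddt, model, cut = 0.6) {
  stopifnot(length(predictions) == length(lddt),
            length(lddt) == length(model))
  labels <- classify_correct(lddt, cut)
  overall <- roc_auc(predictions, labels)
  ids <- unique(as.character(model))
  auc <- vapply(ids, function(m) {
    sel <- model == m
    p <- predictions[sel]
    ok <- !is.na(p) & !is.na(labels[sel])
    if (sum(ok) > 0 && stats::sd(p[ok]) == 0) return(NA_real_)
    roc_auc(p, labels[sel])
  }, 0)
  per_model <- data.frame(model = ids, auc = unname(auc),
                          excluded = is.na(auc))
  if (all(per_model$excluded)) {
    if (is.na(overall)) stop("no valid models to evaluate")
    mean_auc <- NA_real_
  } else {
    mean_auc <- mean(per_model$auc[!per_model$excluded])
  }
  structure(list(overall_auc = overall, per_model = per_model,
                 mean_per_model_auc = mean_auc,
                 n_excluded_models = sum(per_model$excluded), cut = cut),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("overall AUC %.4f | mean per-model AUC %s | %d/%d models excluded (cut %.2f)\n",
              x$overall_auc,
              ifelse(is.na(x$mean_per_model_auc), "NA",
                     sprintf("%.4f", x$mean_per_model_auc)),
              x$n_excluded_models, nrow(x$per_model), x$cut))
  invisible(x)
}

#' Naive per-residue predictor
#'
#' Blindly assigns each model's global score to every one of its
#' residues. By construction it cannot discriminate residues within one
#' model (its per-model AUCs are all excluded), yet its pooled AUC
#' benefits from between-model quality differences.
#'
#' @param global_scores named numeric vector, one global score per model.
#' @param residues_per_model named integer vector, residues per model
#'   (names matching `global_scores`).
#' @return list with `predictions` and `model` vectors, residue-expanded.
#' @export
naive_predictor <- function(global_scores, residues_per_model) {
  stopifnot(setequal(names(global_scores), names(residues_per_model)))
  ids <- names(global_scores)
  list(predictions = rep(unname(global_scores[ids]),
                         unname(residues_per_model[ids])),
       model = rep(ids, unname(residues_per_model[ids])))
}
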