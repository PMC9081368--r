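#' Confusion counts from truth/prediction pairs
#'
#' @param truth Integer 0/1 true labels (1 = MHC).
#' @param pred Integer 0/1 predicted labels.
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  if (!all(truth %in% c(0L, 1L)) || !all(pred %in% c(0L, 1L))) {
    abort("labels and predictions must be 0/1")
  }
  tibble(
    tp = sum(truth == 1L & pred == 1L),
    fp = sum(truth == 0L & pred == 1L),
    tn = sum(truth == 0L & pred == 0L),
    fn = sum(truth == 1L & pred == 0L)
  )
}

#' Sensitivity, specificity, accuracy and Matthews correlation
#'
#' Derives the four standard binary-classification metrics from confusion
#' counts:
#' \deqn{SE = TP/(TP+FN), \quad SP = TN/(TN+FP),}
#' \deqn{ACC = (TP+TN)/(TP+FP+TN+FN),}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}.}
#'
#' A zero denominator makes SE or SP undefined: the value is reported as
#' `NA` with the corresponding flag set. A zero MCC denominator yields
#' MCC = 0 with `mcc_zero_denom = TRUE` (the conventional guard against
#' silent NaN propagation).
#'
#' @param counts A one-row data frame with columns `tp`, `fp`, `tn`, `fn`
#'   (e.g. from [confusion_counts()]), or a numeric vector with those
#'   names.
#' @return A one-row tibble: the four counts, `se`, `sp`, `acc`, `mcc`,
#'   and the flags `se_undefined`, `sp_undefined`, `mcc_zero_denom`.
#' @export
#' @examples
#' compute_metrics(c(tp = 90, fn = 10, tn = 80, fp = 20))
compute_metrics <- function(counts) {
  if (is.numeric(counts)) {
    counts <- as.list(counts)
  }
  tp <- as.numeric(counts$tp)
  fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn)
  fn <- as.numeric(counts$fn)
  if (any(c(tp, fp, tn, fn) < 0)) {
    abort("confusion counts must be non-negative")
  }
  total <- tp + fp + tn + fn
  if (total == 0) {
    abort("cannot compute metrics from zero evaluated examples")
  }
  se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / total
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / sqrt(mcc_den) else 0
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    se = se, sp = sp, acc = acc, mcc = mcc,
    se_undefined = tp + fn == 0,
    sp_undefined = tn + fp == 0,
    mcc_zero_denom = mcc_den == 0
  )
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Encodes the dataset once, then for each fold fits the voting ensemble
#' on the out-of-fold sequences (the feature standardizer is re-fitted on
#' each training fold, so no information leaks from held-out data) and
#' predicts the held-out fold. The primary report pools the held-out
#' predictions of all folds into a single confusion table; per-fold
#' metrics are retained alongside.
#'
#' @param data A labeled tibble (`id`, `residues`, `label`), e.g. from
#'   [load_labeled()] or [generate_synthetic()].
#' @param config An [encoder_config()].
#' @param n_folds Number of folds (default 10).
#' @param seed Master seed: controls the fold shuffle and fans out to the
#'   base learners.
#' @param specs Learner specifications (default [default_learner_specs()]
#'   with this `seed`).
#' @param standardize Passed to [fit_ensemble()].
#' @return An object of class `mhc_cv`: list with `pooled` (one-row
#'   metrics tibble), `per_fold` (metrics tibble with a `fold` column),
#'   `predictions` (id, fold, label, pred and member votes), `config`,
#'   `n_folds`, `seed`.
#' @export
cross_validate <- function(data, config = encoder_config(), n_folds = 10,
                           seed = 1, specs = default_learner_specs(seed),
                           standardize = TRUE) {
  folded <- stratified_kfold(data, n_folds, seed)
  encoded <- encode_dataset(data, config)
  x <- feature_matrix(encoded)

  preds <- lapply(seq_len(n_folds), function(k) {
    tr <- folded$fold != k
    te <- !tr
    fit <- tryCatch(
      fit_ensemble(x[tr, , drop = FALSE], data$label[tr], specs = specs,
                   standardize = standardize, config = config),
      error = function(e) {
        abort(sprintf("fold %d: %s", k, conditionMessage(e)))
      })
    p <- predict_vote(fit, x[te, , drop = FALSE])
    dplyr::bind_cols(
      tibble(id = data$id[te], fold = k, label = data$label[te]),
      p[setdiff(names(p), "id")]
    )
  })
  preds <- dplyr::bind_rows(preds)

  per_fold <- dplyr::bind_rows(lapply(seq_len(n_folds), function(k) {
    rows <- preds[preds$fold == k, ]
    dplyr::bind_cols(tibble(fold = k),
                     compute_metrics(confusion_counts(rows$label, rows$pred)))
  }))
  pooled <- compute_metrics(confusion_counts(preds$label, preds$pred))

  structure(
    list(pooled = pooled, per_fold = per_fold, predictions = preds,
         config = config, n_folds = n_folds, seed = seed),
    class = "mhc_cv"
  )
}

#' Train on one dataset, evaluate on a disjoint hold-out
#'
#' Fits the ensemble once on the training set (standardizer from training
#' data only) and computes metrics on the test set. Train and test IDs
#' must be disjoint unless `allow_overlap = TRUE` is given explicitly
#' (a leakage guard; overlapping evaluation is only ever meaningful for
#' resubstitution checks).
#'
#' @param train,test Labeled tibbles (`id`, `residues`, `label`).
#' @param config An [encoder_config()].
#' @param seed Master seed for the base learners.
#' @param specs Learner specifications.
#' @param standardize Passed to [fit_ensemble()].
#' @param allow_overlap Permit train/test ID overlap (default FALSE).
#' @return An object of class `mhc_holdout`: list with `metrics` (one-row
#'   tibble), `predictions`, `model`, `config`, `seed`.
#' @export
evaluate_holdout <- function(train, test, config = encoder_config(),
                             seed = 1, specs = default_learner_specs(seed),
                             standardize = TRUE, allow_overlap = FALSE) {
  if (nrow(test) == 0) {
    abort("test set is empty")
  }
  overlap <- intersect(train$id, test$id)
  if (length(overlap) > 0 && !allow_overlap) {
    abort(sprintf("train and test sets share %d ID(s): %s",
                  length(overlap), paste(head(overlap, 5), collapse = ", ")))
  }
  fit <- fit_ensemble(encode_dataset(train, config), specs = specs,
                      standardize = standardize, config = config)
  p <- predict_vote(fit, encode_dataset(test, config))
  preds <- dplyr::bind_cols(tibble(label = test$label), p)
  metrics <- compute_metrics(confusion_counts(preds$label, preds$pred))
  structure(
    list(metrics = metrics, predictions = preds, model = fit,
         config = config, seed = seed),
    class = "mhc_holdout"
  )
}

#' @export
print.mhc_cv <- function(x, ...) {
  cat(sprintf("<mhc_cv> %d-fold stratified cross-validation (seed %d)\n",
              x$n_folds, x$seed))
  m <- x$pooled
  cat(sprintf("  pooled: ACC %.4f  MCC %.4f  SE %.4f  SP %.4f\n",
              m$acc, m$mcc, m$se, m$sp))
  invisible(x)
}

#' @export
print.mhc_holdout <- function(x, ...) {
  m <- x$metrics
  cat("<mhc_holdout> independent-test evaluation\n")
  cat(sprintf("  ACC %.4f  MCC %.4f  SE %.4f  SP %.4f\n",
              m$acc, m$mcc, m$se, m$sp))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' Writes confusion counts, the four metrics, per-fold breakdown (for
#' cross-validation results), the encoder configuration and the seed.
#'
#' @param result An `mhc_cv` or `mhc_holdout` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(result, path) {
  cfg <- result$config
  payload <- list(
    config = cfg[setdiff(names(cfg), character(0))],
    seed = result$seed
  )
  if (inherits(result, "mhc_cv")) {
    payload$protocol <- "cross_validation"
    payload$n_folds <- result$n_folds
    payload$pooled <- as.list(result$pooled)
    payload$per_fold <- result$per_fold
  } else {
    payload$protocol <- "holdout"
    payload$metrics <- as.list(result$metrics)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
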