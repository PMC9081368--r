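#' Default base-learner specifications
#'
#' The voting ensemble has exactly three members: a random forest, an
#' SMO-trained support vector machine with a linear kernel, and an
#' SGD-trained linear classifier with hinge loss and L2 regularization.
#' A single master seed fans out deterministically to the members
#' (`seed + 1`, `seed + 2`, `seed + 3` for the forest, the SVM and the
#' SGD learner respectively).
#'
#' @param seed Master integer seed.
#' @param rf_trees Number of trees in the random forest.
#' @param svm_cost Soft-margin cost C of the linear SVM.
#' @param sgd_reg L2 regularization strength of the SGD learner.
#' @param sgd_epochs Number of passes over the training data.
#' @return A named list of three learner specs (`random_forest`,
#'   `smo_svm`, `sgd_linear`).
#' @export
default_learner_specs <- function(seed = 1, rf_trees = 100, svm_cost = 1,
                                  sgd_reg = 1e-4, sgd_epochs = 25) {
  list(
    random_forest = list(kind = "random_forest", ntree = rf_trees,
                         seed = seed + 1L),
    smo_svm = list(kind = "smo_svm", cost = svm_cost, seed = seed + 2L),
    sgd_linear = list(kind = "sgd_linear", reg = sgd_reg,
                      epochs = sgd_epochs, seed = seed + 3L)
  )
}

## Pegasos-style SGD for the hinge-loss L2-regularized linear classifier.
## y in {0,1}; learns (w, b) with b unregularized.
fit_sgd_linear <- function(x, y, reg = 1e-4, epochs = 25, seed = 1) {
  ys <- ifelse(y == 1L, 1, -1)
  n <- nrow(x)
  p <- ncol(x)
  w <- numeric(p)
  b <- 0
  t <- 0
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      for (i in sample.int(n)) {
        t <- t + 1
        eta <- 1 / (reg * t)
        margin <- ys[i] * (sum(w * x[i, ]) + b)
        w <- (1 - eta * reg) * w
        if (margin < 1) {
          w <- w + eta * ys[i] * x[i, ]
          b <- b + eta * ys[i]
        }
      }
    }
  })
  list(w = w, b = b)
}

predict_sgd_linear <- function(fit, x) {
  as.integer(drop(x %*% fit$w) + fit$b > 0)
}

#' Fit the three-member voting ensemble
#'
#' Optionally standardizes the feature matrix (per-feature zero mean, unit
#' variance, fitted on the training data only — constant features are left
#' unscaled), then fits the random forest, the SMO-trained linear SVM and
#' the SGD linear classifier, each with its own seed. Deterministic for
#' fixed seeds and inputs.
#'
#' @param x An encoded dataset tibble (from [encode_dataset()]) or a
#'   numeric feature matrix.
#' @param y Binary labels (0 = non-MHC, 1 = MHC); taken from `x$label`
#'   when `x` is an encoded tibble and `y` is missing.
#' @param specs Learner specifications, see [default_learner_specs()].
#' @param standardize Standardize features before fitting (default TRUE;
#'   the SVM and SGD members are scale-sensitive).
#' @param config Optional [encoder_config()] snapshot stored with the
#'   model, recording how its training features were produced.
#' @return An object of class `mhc_ensemble`.
#' @export
#' @examples
#' \donttest{
#' ds <- generate_synthetic(n_pos = 15, n_neg = 15, delta = 0.8, seed = 7)
#' enc <- encode_dataset(ds, encoder_config(lambda_apaac = 4, lambda_paac = 4))
#' fit <- fit_ensemble(enc)
#' predict(fit, enc)
#' }
fit_ensemble <- function(x, y = NULL, specs = default_learner_specs(),
                         standardize = TRUE, config = NULL) {
  if (is.data.frame(x)) {
    if (is.null(y) && "label" %in% names(x)) {
      y <- x$label
    }
    x <- feature_matrix(x)
  }
  y <- as.integer(y)
  if (is.null(y) || length(y) != nrow(x)) {
    abort("y must supply one 0/1 label per row of x")
  }
  if (length(unique(y)) < 2) {
    abort("training labels contain a single class; need both 0 and 1")
  }
  bad <- which(!apply(is.finite(x), 2, all))
  if (length(bad) > 0) {
    abort(sprintf("non-finite feature values in column(s): %s",
                  paste(head(colnames(x)[bad], 5), collapse = ", ")))
  }
  kinds <- vapply(specs, `[[`, character(1), "kind")
  if (!setequal(kinds, c("random_forest", "smo_svm", "sgd_linear"))) {
    abort("specs must contain exactly one spec per learner kind")
  }
  specs <- specs[match(c("random_forest", "smo_svm", "sgd_linear"), kinds)]

  scaler <- NULL
  xs <- x
  if (standardize) {
    mu <- colMeans(x)
    sig <- apply(x, 2, sd)
    sig[sig == 0 | !is.finite(sig)] <- 1
    scaler <- list(center = mu, scale = sig)
    xs <- sweep(sweep(x, 2, mu, "-"), 2, sig, "/")
  }

  yf <- factor(y, levels = c(0L, 1L))
  rf_spec <- specs[[1]]
  svm_spec <- specs[[2]]
  sgd_spec <- specs[[3]]
  rf <- withr::with_seed(rf_spec$seed,
    randomForest::randomForest(x = xs, y = yf, ntree = rf_spec$ntree))
  svm <- withr::with_seed(svm_spec$seed,
    kernlab::ksvm(x = xs, y = yf, kernel = kernlab::vanilladot(),
                  C = svm_spec$cost, scaled = FALSE))
  sgd <- fit_sgd_linear(xs, y, reg = sgd_spec$reg,
                        epochs = sgd_spec$epochs, seed = sgd_spec$seed)

  structure(
    list(
      members = list(random_forest = rf, smo_svm = svm, sgd_linear = sgd),
      specs = specs,
      config = config,
      scaler = scaler,
      feature_labels = colnames(x),
      n_train = nrow(x),
      class_counts = table(factor(y, levels = c(0L, 1L))),
      version = as.character(packageVersion("mhcvote"))
    ),
    class = "mhc_ensemble"
  )
}

#' Majority vote over member predictions
#'
#' The ensemble label is the mode of the three members' hard 0/1 votes;
#' with three voters and two classes no tie is possible.
#'
#' @param votes An n x 3 matrix of 0/1 member votes.
#' @return Integer vector of n majority labels.
#' @export
vote_majority <- function(votes) {
  stopifnot(ncol(votes) == 3)
  as.integer(rowSums(votes) >= 2)
}

#' Predict with the voting ensemble
#'
#' Each member emits a hard 0/1 vote on every row; the ensemble label is
#' the 2-of-3 majority. The per-member votes are returned for audit.
#'
#' @param model A fitted [fit_ensemble()] object.
#' @param x An encoded dataset tibble or numeric matrix whose columns match
#'   the model's feature labels (same names, same order).
#' @return A tibble with columns `id` (when available), `pred`, and the
#'   member votes `vote_rf`, `vote_smo`, `vote_sgd`.
#' @export
predict_vote <- function(model, x) {
  stopifnot(inherits(model, "mhc_ensemble"))
  ids <- NULL
  if (is.data.frame(x)) {
    ids <- x[["id"]]
    x <- feature_matrix(x)
  } else {
    ids <- rownames(x)
  }
  if (ncol(x) != length(model$feature_labels) ||
      !identical(colnames(x), model$feature_labels)) {
    abort(sprintf(
      "feature mismatch: model expects %d columns (%s, ...), received %d (%s, ...)",
      length(model$feature_labels),
      paste(head(model$feature_labels, 2), collapse = ", "),
      ncol(x),
      paste(head(colnames(x), 2), collapse = ", ")))
  }
  if (!is.null(model$scaler)) {
    x <- sweep(sweep(x, 2, model$scaler$center, "-"), 2, model$scaler$scale, "/")
  }
  v_rf <- as.integer(as.character(predict(model$members$random_forest, x)))
  v_svm <- as.integer(as.character(kernlab::predict(model$members$smo_svm, x)))
  v_sgd <- predict_sgd_linear(model$members$sgd_linear, x)
  votes <- cbind(v_rf, v_svm, v_sgd)
  out <- tibble(
    pred = vote_majority(votes),
    vote_rf = v_rf, vote_smo = v_svm, vote_sgd = v_sgd
  )
  if (!is.null(ids)) {
    out <- dplyr::bind_cols(tibble(id = ids), out)
  }
  out
}

#' @export
predict.mhc_ensemble <- function(object, newdata, ...) {
  predict_vote(object, newdata)
}

#' @export
print.mhc_ensemble <- function(x, ...) {
  cat("<mhc_ensemble> hard-voting ensemble (random forest + SMO SVM + SGD linear)\n")
  cat(sprintf("  trained on %d sequences (%d non-MHC / %d MHC), %d features\n",
              x$n_train, x$class_counts[["0"]], x$class_counts[["1"]],
              length(x$feature_labels)))
  cat(sprintf("  standardized: %s\n", !is.null(x$scaler)))
  invisible(x)
}

#' Save / load a trained ensemble
#'
#' The model file embeds the fitted members, the feature-label contract,
#' the scaler, the learner specs and the package version; loading a file
#' written by a different package version is an error naming both
#' versions. Round-tripping preserves predictions exactly.
#'
#' @param model A fitted [fit_ensemble()] object.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `mhc_ensemble`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mhc_ensemble"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e) {
    abort(sprintf("cannot load model from '%s': %s", path, conditionMessage(e)))
  })
  if (!inherits(model, "mhc_ensemble")) {
    abort(sprintf("'%s' is not a saved mhc_ensemble model", path))
  }
  current <- as.character(packageVersion("mhcvote"))
  if (!identical(model$version, current)) {
    abort(sprintf("model was saved by mhcvote %s but %s is installed",
                  model$version, current))
  }
  model
}
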