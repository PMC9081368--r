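#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation result
#'
#' One row per fold with the four metrics and confusion counts.
#'
#' @param x An `mhc_cv` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mhc_cv <- function(x, ...) {
  x$per_fold
}

#' Summarize a cross-validation result in one row
#'
#' Pooled metrics across all held-out folds, plus fold count and seed.
#'
#' @inheritParams tidy.mhc_cv
#' @return A one-row tibble.
#' @export
glance.mhc_cv <- function(x, ...) {
  dplyr::bind_cols(x$pooled, tibble(n_folds = x$n_folds, seed = x$seed))
}

#' @export
tidy.mhc_holdout <- function(x, ...) {
  x$metrics
}

#' @export
glance.mhc_holdout <- function(x, ...) {
  dplyr::bind_cols(x$metrics, tibble(seed = x$seed))
}

#' Tidy a fitted voting ensemble
#'
#' One row per base learner with its kind and seed.
#'
#' @param x An `mhc_ensemble` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mhc_ensemble <- function(x, ...) {
  tibble(
    member = names(x$specs),
    kind = unname(vapply(x$specs, `[[`, character(1), "kind")),
    seed = unname(vapply(x$specs, function(s) as.integer(s$seed), integer(1)))
  )
}

#' @export
glance.mhc_ensemble <- function(x, ...) {
  tibble(
    n_train = x$n_train,
    n_features = length(x$feature_labels),
    standardized = !is.null(x$scaler),
    version = x$version
  )
}

#' Plot per-fold cross-validation metrics
#'
#' Dot plot of SE, SP, ACC and MCC across folds, with the pooled value
#' marked by a horizontal line per metric panel.
#'
#' @param object An `mhc_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mhc_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_fold[c("fold", "se", "sp", "acc", "mcc")],
    cols = c("se", "sp", "acc", "mcc"),
    names_to = "metric", values_to = "value"
  )
  pooled <- tidyr::pivot_longer(
    object$pooled[c("se", "sp", "acc", "mcc")],
    cols = dplyr::everything(),
    names_to = "metric", values_to = "value"
  )
  long$metric <- toupper(long$metric)
  pooled$metric <- toupper(pooled$metric)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fold, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(data = pooled,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = unique(long$fold)) +
    ggplot2::labs(x = "fold", y = NULL,
                  title = "Per-fold held-out metrics (dashed: pooled)") +
    ggplot2::theme_minimal()
}

#' Plot the amino-acid composition block of encoded sequences
#'
#' Column means of the 20 composition features per class — a quick visual
#' check of class separation at the composition level.
#'
#' @param encoded An encoded tibble from [encode_dataset()] containing a
#'   `label` column and the `d188.AAC.*` features.
#' @return A ggplot object.
#' @export
plot_composition <- function(encoded) {
  aac_cols <- grep("^d188\\.AAC\\.", names(encoded), value = TRUE)
  if (length(aac_cols) == 0) {
    abort("no d188.AAC.* columns found; encode with the d188 block enabled")
  }
  stopifnot("label" %in% names(encoded))
  long <- tidyr::pivot_longer(encoded[c("label", aac_cols)],
                              cols = dplyr::all_of(aac_cols),
                              names_to = "residue", values_to = "freq")
  long$residue <- sub("^d188\\.AAC\\.", "", long$residue)
  long$class <- ifelse(long$label == 1L, "MHC (positive)", "non-MHC (negative)")
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$residue, .data$class),
    freq = mean(.data$freq), .groups = "drop"
  )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$residue, y = .data$freq,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "residue", y = "mean frequency", fill = NULL) +
    ggplot2::theme_minimal()
}
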