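# ---- broom-style tidiers ----------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a confusion report
#'
#' @param x A [confusion_report()].
#' @param ... Unused.
#' @return Tibble with per-grade `n`, `correct` and `accuracy_pct`.
#' @export
tidy.confusion_report <- function(x, ...) {
  tibble(grade = x$grade, n = x$n, correct = x$correct,
         accuracy_pct = ifelse(x$n > 0, 100 * x$correct / x$n, NA_real_))
}

#' One-row summary of a confusion report
#'
#' @param x A [confusion_report()].
#' @param ... Unused.
#' @return Tibble with `n`, `correct` and overall `accuracy_pct`.
#' @export
glance.confusion_report <- function(x, ...) {
  tibble(n = sum(x$n), correct = sum(x$correct),
         accuracy_pct = overall_accuracy(x))
}

#' Tidy a fitted freshness model
#'
#' @param x A [fit_freshness_model()] result.
#' @param ... Unused.
#' @return Tibble of the stored per-feature min-max normalization
#'   parameters (the model's preprocessing contract).
#' @export
tidy.freshness_model <- function(x, ...) {
  as_tibble(x$norm_params)
}

#' One-row summary of a fitted freshness model
#'
#' @param x A [fit_freshness_model()] result.
#' @param ... Unused.
#' @return Tibble with the model type, feature and training-row counts and
#'   the grade levels.
#' @export
glance.freshness_model <- function(x, ...) {
  tibble(model = x$config$model, n_features = length(x$feature_names),
         n_train = x$n_train, grades = paste(x$levels, collapse = "/"))
}
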