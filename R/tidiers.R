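#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a gated comparison result
#'
#' @param x a `comparison_result`.
#' @param ... unused.
#' @return One-row tibble with `test`, `statistic`, `p_value`, `n`,
#'   `normality_used`, `flags`.
#' @export
tidy.comparison_result <- function(x, ...) {
  tibble::tibble(test = x$test_name, statistic = x$statistic,
                 p_value = x$p_value, n = paste(x$n, collapse = "/"),
                 normality_used = x$normality_used,
                 flags = paste(x$flags, collapse = "; "))
}

#' Tidy an ICC result
#' @param x an `icc_result`.
#' @param ... unused.
#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(icc = x$icc, model = x$model_tag,
                 n_subjects = x$n_subjects, n_raters = x$n_raters,
                 consistency = x$consistency_band)
}

#' Tidy chain measurements into a long tibble
#' @param x an `ossicle_measurements`.
#' @param ... unused.
#' @export
tidy.ossicle_measurements <- function(x, ...) {
  m <- x$measurements
  tibble::tibble(
    ear_id = m$ear_id,
    parameter = measurement_names,
    value = vapply(measurement_names, function(nm) m[[nm]], numeric(1)),
    available = vapply(measurement_names,
                       function(nm) m[[paste0(nm, "_available")]], logical(1)),
    unit = ifelse(grepl("angle", measurement_names), "deg",
                  ifelse(grepl("volume", measurement_names), "mm^3", "mm")))
}

#' One-row overview of chain measurements
#' @param x an `ossicle_measurements`.
#' @param ... unused.
#' @export
glance.ossicle_measurements <- function(x, ...) {
  tibble::tibble(ear_id = x$measurements$ear_id,
                 n_available = sum(vapply(measurement_names, function(nm)
                   isTRUE(x$measurements[[paste0(nm, "_available")]]), logical(1))),
                 stapes_available = x$stapes_available,
                 n_warnings = length(x$qc$warnings))
}

#' Plot recovery errors by parameter and noise level
#'
#' @param object a `recovery_report` from [evaluate_recovery()].
#' @param ... unused.
#' @return A ggplot object (box plots of signed recovery error).
#' @export
autoplot.recovery_report <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$error),
                      !grepl("volume", .data$parameter))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter, y = .data$error,
                                   fill = factor(.data$noise))) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "recovery error (mm or degrees)",
                  fill = "boundary flip\nprobability") +
    ggplot2::theme_minimal()
}

#' Plot measured parameters of one ear
#'
#' @param object an `ossicle_measurements`.
#' @param ... unused.
#' @export
autoplot.ossicle_measurements <- function(object, ...) {
  df <- tidy.ossicle_measurements(object)
  df <- dplyr::filter(df, .data$available)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~unit, scales = "free") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "measured value") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
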