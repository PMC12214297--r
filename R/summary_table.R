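#' Measurement tables and formatted summary reports
#'
#' A measurement table is a long tibble with one row per observation:
#' columns `ear_id`, `parameter`, `method` (`"manual"` or `"automated"`),
#' `replicate`, `value`, and optional grouping columns `sex`, `side`,
#' `age_group`. Replicates are averaged per ear/parameter/method before any
#' comparison, mirroring the convention that the final manual measurement is
#' the average of three repeats.
#'
#' @name summary_table
NULL

required_cols <- c("ear_id", "parameter", "method", "replicate", "value")

validate_measurement_table <- function(tbl) {
  missing <- setdiff(required_cols, names(tbl))
  if (length(missing))
    stop("measurement table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(tbl$value)))
    stop("measurement table contains non-finite values", call. = FALSE)
  dup <- duplicated(tbl[, c("ear_id", "parameter", "method", "replicate")])
  if (any(dup))
    stop("duplicate (ear_id, parameter, method, replicate) rows", call. = FALSE)
  invisible(tbl)
}

#' Format a percentage the way the demographic table prints it
#' @param count,total integers; returns e.g. "53.6" for 75 of 140.
#' @export
pct_string <- function(count, total) sprintf("%.1f", 100 * count / total)

mean_sd_string <- function(x) sprintf("%.2f ± %.2f", mean(x), stats::sd(x))

#' Summary report of a measurement table
#'
#' For `grouping = "method"`, compares manual vs automated per parameter
#' (paired, normality-gated) and reports the between-method ICC; for
#' `grouping` in `sex`/`side`/`age_group`, compares automated measurements
#' across the groups (two groups: normality-gated t / Mann-Whitney;
#' three or more: gated ANOVA / Kruskal-Wallis). Cells are "mean ± SD"
#' strings at two decimals.
#'
#' @param tbl a measurement table (see [summary_table]).
#' @param grouping one of `"method"`, `"sex"`, `"side"`, `"age_group"`.
#' @param comparisons if FALSE, only descriptive columns are emitted.
#' @param alpha significance level passed to the gated tests.
#' @return A tibble with one row per parameter.
#' @export
summarize_measurements <- function(tbl, grouping = "method", comparisons = TRUE,
                                   alpha = 0.05) {
  validate_measurement_table(tbl)
  if (!grouping %in% c("method", "sex", "side", "age_group"))
    stop("unsupported grouping: '", grouping, "'", call. = FALSE)
  if (grouping != "method" && !grouping %in% names(tbl))
    stop("grouping column '", grouping, "' absent from table", call. = FALSE)
  avg <- tbl |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("ear_id", "parameter", "method", "sex", "side", "age_group")))) |>
    dplyr::summarize(value = mean(.data$value), .groups = "drop")

  params <- unique(avg$parameter)
  rows <- lapply(params, function(pm) {
    sub <- dplyr::filter(avg, .data$parameter == pm)
    if (grouping == "method") {
      wide <- tidyr::pivot_wider(sub[, c("ear_id", "method", "value")],
                                 names_from = "method", values_from = "value")
      row <- tibble::tibble(parameter = pm)
      for (m in setdiff(names(wide), "ear_id"))
        row[[m]] <- mean_sd_string(wide[[m]])
      if (comparisons && all(c("manual", "automated") %in% names(wide))) {
        cmp <- paired_comparison(wide$manual, wide$automated, alpha)
        icc <- icc_consistency(as.matrix(wide[, c("manual", "automated")]))
        row$test <- cmp$test_name
        row$statistic <- round(cmp$statistic, 3)
        row$p_value <- round(cmp$p_value, 3)
        row$icc <- round(icc$icc, 3)
      }
      row
    } else {
      sub <- dplyr::filter(sub, .data$method == "automated")
      groups <- split(sub$value, sub[[grouping]])
      groups <- groups[lengths(groups) > 0]
      row <- tibble::tibble(parameter = pm)
      for (g in names(groups)) row[[g]] <- mean_sd_string(groups[[g]])
      if (comparisons) {
        if (length(groups) < 2) {
          warning("grouping '", grouping, "' has a single level for ", pm,
                  "; comparison reported as NA", call. = FALSE)
          row$test <- NA_character_; row$statistic <- NA_real_; row$p_value <- NA_real_
        } else if (length(groups) == 2) {
          cmp <- group_comparison(groups[[1]], groups[[2]], alpha)
          row$test <- cmp$test_name
          row$statistic <- round(cmp$statistic, 3)
          row$p_value <- round(cmp$p_value, 3)
        } else {
          cmp <- multi_group_comparison(groups, alpha)
          row$test <- cmp$test_name
          row$statistic <- round(cmp$statistic, 3)
          row$p_value <- round(cmp$p_value, 3)
        }
      }
      row
    }
  })
  dplyr::bind_rows(rows)
}

#' Render a summary tibble as Markdown
#' @param df a tibble from [summarize_measurements()].
#' @export
summary_markdown <- function(df) {
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(hdr, sep, body), collapse = "\n")
}

#' Convert pipeline measurements to the long table format
#'
#' @param measurements a tibble of one-row-per-ear results from
#'   [measure_chain()] (bound together), or a single `ossicle_measurements`.
#' @param method method label for the rows.
#' @export
measurements_to_table <- function(measurements, method = "automated") {
  if (inherits(measurements, "ossicle_measurements"))
    measurements <- measurements$measurements
  keep <- intersect(measurement_names, names(measurements))
  measurements |>
    dplyr::select(dplyr::any_of(c("ear_id", "sex", "side", "age_group", keep))) |>
    tidyr::pivot_longer(dplyr::all_of(keep), names_to = "parameter",
                        values_to = "value") |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::mutate(method = method, replicate = 1L)
}
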