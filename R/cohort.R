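#' Nonparametric test battery for a donor-blocked cohort
#'
#' Runs, per culture system and day, a Friedman test across all conditions
#' and Wilcoxon signed-rank post-hoc tests of every condition against the
#' control; and, per culture system and condition, a Wilcoxon test of day
#' 1 against day 3. Donors with missing values in a comparison are dropped
#' listwise. Significance is two-sided at `alpha` with no multiple-testing
#' correction by default (mirroring common practice for these designs); an
#' optional Holm adjustment is applied within each comparison family.
#'
#' @param cohort Tidy tibble with `donor`, `culture_system`, `condition`,
#'   `day` and the value column.
#' @param value_col Name of the value column (default `"value"`).
#' @param control Control condition label.
#' @param alpha Two-sided significance level (default 0.05).
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return Tibble with one row per test: `culture_system`, `day`,
#'   `comparison`, `group_a`, `group_b`, `test`, `statistic`, `p_value`,
#'   `significant`.
#' @export
cohort_tests <- function(cohort, value_col = "value", control = "control",
                         alpha = 0.05, p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  need <- c("donor", "culture_system", "condition", "day", value_col)
  if (!all(need %in% names(cohort)))
    stop("cohort needs columns: ", paste(need, collapse = ", "))
  if (all(is.na(cohort[[value_col]])))
    stop("the value column '", value_col, "' is empty")
  res <- list()
  paired_vals <- function(df, keys, key_col) {
    wide <- tapply(df[[value_col]], list(df$donor, df[[key_col]]), mean)
    wide[, keys, drop = FALSE]
  }
  for (sys in unique(cohort$culture_system)) {
    for (dy in sort(unique(cohort$day))) {
      sub <- cohort[cohort$culture_system == sys & cohort$day == dy, ]
      conds <- unique(sub$condition)
      if (length(conds) >= 3) {
        wide <- paired_vals(sub, conds, "condition")
        fr <- tryCatch(suppressWarnings(friedman_rm(wide)),
                       error = function(e) NULL)
        if (!is.null(fr))
          res[[length(res) + 1]] <- tibble::tibble(
            culture_system = sys, day = dy, comparison = "conditions",
            group_a = "all", group_b = "all", test = "friedman",
            statistic = fr$statistic, p_value = fr$p_value)
      }
      if (control %in% conds) {
        for (cd in setdiff(conds, control)) {
          wide <- paired_vals(sub, c(control, cd), "condition")
          ok <- complete.cases(wide)
          if (sum(ok) < 3) next
          wt <- wilcoxon_signed_rank(wide[ok, 1], wide[ok, 2])
          res[[length(res) + 1]] <- tibble::tibble(
            culture_system = sys, day = dy, comparison = "vs_control",
            group_a = control, group_b = cd, test = "wilcoxon",
            statistic = wt$statistic, p_value = wt$p_value)
        }
      }
    }
    days <- sort(unique(cohort$day[cohort$culture_system == sys]))
    if (length(days) == 2) {
      for (cd in unique(cohort$condition[cohort$culture_system == sys])) {
        sub <- cohort[cohort$culture_system == sys & cohort$condition == cd, ]
        wide <- paired_vals(sub, as.character(days), "day")
        ok <- complete.cases(wide)
        if (sum(ok) < 3) next
        wt <- wilcoxon_signed_rank(wide[ok, 1], wide[ok, 2])
        res[[length(res) + 1]] <- tibble::tibble(
          culture_system = sys, day = NA_real_, comparison = "day1_vs_day3",
          group_a = cd, group_b = cd, test = "wilcoxon",
          statistic = wt$statistic, p_value = wt$p_value)
      }
    }
  }
  out <- dplyr::bind_rows(res)
  if (!nrow(out)) return(out)
  if (p_adjust == "holm")
    out <- out |>
      dplyr::group_by(.data$culture_system, .data$comparison) |>
      dplyr::mutate(p_value = stats::p.adjust(.data$p_value, "holm")) |>
      dplyr::ungroup()
  out$significant <- out$p_value < alpha
  out
}

#' Blank extreme outliers for display
#'
#' The boxplot-display rule: values beyond three interquartile ranges from
#' the quartiles are extreme outliers, shown as missing in graphics while
#' always remaining in the statistics.
#'
#' @param x Numeric vector.
#' @param k IQR multiplier (default 3).
#' @return `x` with extreme outliers replaced by `NA`.
#' @export
drop_extreme_outliers <- function(x, k = 3) {
  q <- quantile(x, c(0.25, 0.75), na.rm = TRUE)
  iqr <- q[2] - q[1]
  x[x < q[1] - k * iqr | x > q[2] + k * iqr] <- NA
  x
}

#' Cohort boxplots with plot-only extreme-outlier exclusion
#'
#' Boxplots of the metric by condition, faceted by culture system and day.
#' Extreme outliers (beyond 3 IQR from the quartiles, computed per
#' condition within each facet) are excluded from the display only — tests
#' always run on the full data.
#'
#' @param cohort Tidy cohort tibble (see [cohort_tests()]).
#' @param value_col Name of the value column.
#' @return A ggplot object.
#' @export
plot_cohort_boxplots <- function(cohort, value_col = "value") {
  plotted <- cohort |>
    dplyr::group_by(.data$culture_system, .data$condition, .data$day) |>
    dplyr::mutate(.display = drop_extreme_outliers(.data[[value_col]])) |>
    dplyr::ungroup()
  ggplot2::ggplot(plotted,
                  ggplot2::aes(x = .data$condition, y = .data$.display)) +
    ggplot2::geom_boxplot(outlier.size = 0.8, na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$culture_system),
                        cols = ggplot2::vars(.data$day)) +
    ggplot2::labs(x = NULL, y = value_col) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
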