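#' Histogram of a subject's rescaled centrality scores
#'
#' The distribution view of a profile: max-rescaled nAC0 and nAC1 on
#' `[0, 1]` with the default 0.05-wide bins. An optional reference
#' proportion vector (e.g. from [matched_reference()]) is overlaid as a
#' step line.
#'
#' @param profile A [compute_profile()] tibble.
#' @param measure `"nac0"`, `"nac1"`, or `"both"`.
#' @param reference Optional bin-proportion vector matching `breaks`.
#' @param breaks Bin edges, default width 0.05.
#' @return A ggplot object.
#' @export
plot_nac_distribution <- function(profile, measure = c("both", "nac0", "nac1"),
                                  reference = NULL,
                                  breaks = seq(0, 1, by = 0.05)) {
  measure <- match.arg(measure)
  cols <- if (measure == "both") c("nac0_rescaled", "nac1_rescaled")
          else paste0(measure, "_rescaled")
  long <- tidyr::pivot_longer(profile[, c("region_id", cols)],
                              cols = dplyr::all_of(cols),
                              names_to = "measure", values_to = "score")
  long$measure <- sub("_rescaled$", "", long$measure)
  binned <- dplyr::reframe(
    dplyr::group_by(long, .data$measure),
    x = utils::head(breaks, -1) + diff(breaks) / 2,
    prop = {
      cnt <- bin_counts(.data$score[!is.na(.data$score)], breaks)
      cnt / sum(cnt)
    }
  )
  p <- ggplot2::ggplot(binned, ggplot2::aes(x = .data$x, y = .data$prop)) +
    ggplot2::geom_col(width = diff(breaks)[1], fill = "grey40",
                      colour = "white", linewidth = 0.2) +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = "max-rescaled nAC", y = "proportion of regions") +
    ggplot2::theme_minimal()
  if (!is.null(reference)) {
    ref <- tibble(
      x = utils::head(breaks, -1) + diff(breaks) / 2,
      prop = reference
    )
    p <- p + ggplot2::geom_step(
      data = ref, ggplot2::aes(x = .data$x, y = .data$prop),
      colour = "firebrick", direction = "mid"
    )
  }
  p
}

#' Normative band for one region
#'
#' Mean line and mean + 2 SD abnormality bound over the fitted age range,
#' optionally with the control points the model was fit on.
#'
#' @param object A [fit_normative()] model.
#' @param region 0-based region id.
#' @param sex `"F"` or `"M"`.
#' @param measure `"nac0"` or `"nac1"`.
#' @param controls Optional tibble with `age` and `score` columns to
#'   overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.normative_model <- function(object, region = 0, sex = "F",
                                     measure = "nac0", controls = NULL, ...) {
  row <- object[object$region_id == region & object$sex == sex &
                  object$measure == measure, ]
  if (nrow(row) != 1) abort("region/sex/measure not in the model")
  ages <- seq(row$age_min, row$age_max, length.out = 50)
  sd_line <- pmax(row$sd_intercept + row$sd_slope * ages, row$sd_floor)
  d <- tibble(
    age = ages,
    mean = row$mean_intercept + row$mean_slope * ages,
    upper = row$mean_intercept + row$mean_slope * ages + 2 * sd_line
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper), colour = "firebrick",
                       linetype = "dashed") +
    ggplot2::labs(
      x = "age (years)", y = measure,
      title = sprintf("region %d (%s): normative mean and +2 SD bound",
                      region, sex)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(controls)) {
    p <- p + ggplot2::geom_point(
      data = controls, ggplot2::aes(x = .data$age, y = .data$score),
      alpha = 0.4, size = 0.8
    )
  }
  p
}

#' Abnormal-region counts by group
#'
#' Jittered per-subject aR0/aR1 counts split by group, the cohort-level
#' contrast behind the patient-vs-control rank-sum comparison.
#'
#' @param reports A bound [assemble_report()] tibble with a `group` column.
#' @return A ggplot object.
#' @export
plot_ar_counts <- function(reports) {
  long <- tidyr::pivot_longer(reports[, c("subject_id", "group",
                                          "n_ar0", "n_ar1")],
                              cols = c("n_ar0", "n_ar1"),
                              names_to = "measure", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$count)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.9) +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = NULL, y = "abnormal regions per subject") +
    ggplot2::theme_minimal()
}
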