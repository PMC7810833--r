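#' Fit the age- and sex-resolved normative model
#'
#' For every region, sex, and centrality measure (`nac0`, `nac1`) the
#' control scores are regressed on age by ordinary least squares, giving the
#' normative mean line. The age trend of the dispersion is estimated by
#' regressing the absolute residuals, scaled by `sqrt(pi/2)` (which makes
#' `E|e| * sqrt(pi/2) = sigma` for Gaussian residuals), on age
#' (`sd_mode = "age_regressed"`, the default) or by the single pooled
#' residual SD (`sd_mode = "pooled"`). Predicted SDs are floored at 10% of
#' the pooled residual SD so near-deterministic fixtures cannot produce
#' zero-width normal ranges.
#'
#' Profiles must be on the canonical sum-to-1 scale; mixed or rescaled
#' inputs are rejected, because mean + 2 SD thresholds are only comparable
#' across subjects on a common scale.
#'
#' @param profiles Control profiles: a tibble with columns `subject_id`,
#'   `region_id`, `nac0`, `nac1` (rows from [compute_profile()] bound
#'   together).
#' @param metadata Tibble with columns `id`, `age`, `sex` covering every
#'   profiled subject; needs both sexes, at least 10 subjects and 2 distinct
#'   ages per sex.
#' @param sd_mode `"age_regressed"` or `"pooled"`.
#' @return A `normative_model` tibble: one row per region x sex x measure
#'   with `mean_intercept`, `mean_slope`, `sd_intercept`, `sd_slope`,
#'   `sd_floor`, `n`, `age_min`, `age_max`.
#' @export
fit_normative <- function(profiles, metadata,
                          sd_mode = c("age_regressed", "pooled")) {
  sd_mode <- match.arg(sd_mode)
  scale_sums <- assert_common_scale(profiles)
  meta <- dplyr::distinct(metadata[, c("id", "age", "sex")])
  ids <- unique(profiles$subject_id)
  meta <- meta[match(ids, meta$id), ]
  if (anyNA(meta$id)) abort("metadata missing for some profiled subjects")
  sexes <- sort(unique(meta$sex))
  if (length(sexes) < 2) {
    abort("single-sex cohort: the normative model is fit per sex")
  }

  pieces <- list()
  for (sx in sexes) {
    sub_ids <- meta$id[meta$sex == sx]
    ages <- meta$age[meta$sex == sx]
    if (length(sub_ids) < 10) {
      abort(sprintf("need at least 10 controls of sex %s (got %d)",
                    sx, length(sub_ids)))
    }
    if (length(unique(ages)) < 2) {
      abort(sprintf("degenerate ages for sex %s", sx))
    }
    for (measure in c("nac0", "nac1")) {
      wide <- score_matrix(profiles, sub_ids, measure)
      keep <- stats::complete.cases(wide)
      if (!all(keep)) {
        warn(sprintf("dropping %d subject(s) with undefined %s scores",
                     sum(!keep), measure))
      }
      y <- wide[keep, , drop = FALSE]
      age <- ages[keep]
      n <- nrow(y)
      x <- cbind(1, age)
      fit <- stats::lm.fit(x, y)
      co <- fit$coefficients
      res <- y - x %*% co
      pooled_sd <- sqrt(colSums(res^2) / max(n - 2, 1))
      abs_res <- abs(res) * sqrt(pi / 2)
      if (sd_mode == "age_regressed") {
        sd_co <- stats::lm.fit(x, abs_res)$coefficients
      } else {
        sd_co <- rbind(colMeans(abs_res) * 0 + pooled_sd, 0)
      }
      pieces[[length(pieces) + 1]] <- tibble(
        region_id = seq_len(ncol(y)) - 1L,
        sex = sx,
        measure = measure,
        mean_intercept = unname(co[1, ]),
        mean_slope = unname(co[2, ]),
        sd_intercept = unname(sd_co[1, ]),
        sd_slope = unname(sd_co[2, ]),
        sd_floor = unname(pmax(0.1 * pooled_sd, .Machine$double.eps)),
        n = n,
        age_min = min(age),
        age_max = max(age)
      )
    }
  }
  out <- dplyr::bind_rows(pieces)
  structure(out, sd_mode = sd_mode,
            score_scale = c(nac0 = stats::median(scale_sums$s0, na.rm = TRUE),
                            nac1 = stats::median(scale_sums$s1, na.rm = TRUE)),
            class = c("normative_model", class(out)))
}

# subjects x regions matrix of one measure, rows in sub_ids order
score_matrix <- function(profiles, sub_ids, measure) {
  p <- profiles[profiles$subject_id %in% sub_ids,
                c("subject_id", "region_id", measure)]
  wide <- tidyr::pivot_wider(p, names_from = "region_id",
                             values_from = dplyr::all_of(measure))
  wide <- wide[match(sub_ids, wide$subject_id), ]
  m <- as.matrix(wide[, -1])
  m[, order(as.integer(colnames(m))), drop = FALSE]
}

# Thresholding at mean + 2 SD is not scale-free: all subjects must sit on
# one common scale (canonically, sum-to-1 profiles). A subject whose total
# score departs from the cohort median total by more than 50% indicates
# mixed canonical / max-rescaled input and is rejected.
assert_common_scale <- function(profiles) {
  sums <- dplyr::summarise(
    dplyr::group_by(profiles, .data$subject_id),
    s0 = sum(.data$nac0), s1 = sum(.data$nac1), .groups = "drop"
  )
  for (col in c("s0", "s1")) {
    v <- sums[[col]][!is.na(sums[[col]])]
    if (length(v) < 2) next
    m <- stats::median(v)
    if (any(v > 1.5 * m | v < m / 1.5)) {
      abort(paste0("profiles are not on a common scale; mixing canonical ",
                   "(sum-to-1) and max-rescaled scores is not allowed — ",
                   "refit from compute_profile() output"))
    }
  }
  invisible(sums)
}

#' @exportS3Method generics::tidy
tidy.normative_model <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @exportS3Method generics::glance
glance.normative_model <- function(x, ...) {
  one_measure <- x[x$measure == x$measure[1], ]
  tibble(
    n_regions = length(unique(x$region_id)),
    n_sexes = length(unique(x$sex)),
    n_controls = sum(one_measure$n[!duplicated(one_measure$sex)]),
    sd_mode = attr(x, "sd_mode"),
    age_min = min(x$age_min),
    age_max = max(x$age_max)
  )
}

#' Normative upper threshold at an age
#'
#' `mean(age) + 2 * SD(age)` from the fitted lines, the bound above which a
#' region's score is called abnormal. Ages outside the fitted range are
#' extrapolated and flagged.
#'
#' @param model A [fit_normative()] result.
#' @param region 0-based region id(s).
#' @param sex `"F"` or `"M"`.
#' @param measure `"nac0"` or `"nac1"`.
#' @param age Age in years.
#' @return Numeric threshold(s) with logical attribute `extrapolated`.
#' @export
threshold_at <- function(model, region, sex, measure, age) {
  rows <- model[model$region_id %in% region & model$sex == sex &
                  model$measure == measure, ]
  rows <- rows[match(region, rows$region_id), ]
  if (anyNA(rows$region_id)) abort("region/sex/measure not in the model")
  extrap <- age < rows$age_min | age > rows$age_max
  if (any(extrap)) {
    warn(sprintf("age %.1f outside fitted range [%.1f, %.1f]; extrapolating",
                 age, rows$age_min[1], rows$age_max[1]))
  }
  m <- rows$mean_intercept + rows$mean_slope * age
  s <- pmax(rows$sd_intercept + rows$sd_slope * age, rows$sd_floor)
  structure(m + 2 * s, extrapolated = extrap)
}

# All thresholds for one sex/age as a long tibble (no warnings; the
# extrapolation flag is a column).
normative_thresholds <- function(model, sex, age) {
  rows <- model[model$sex == sex, ]
  if (nrow(rows) == 0) abort(sprintf("model does not cover sex %s", sex))
  s <- pmax(rows$sd_intercept + rows$sd_slope * age, rows$sd_floor)
  tibble(
    region_id = rows$region_id,
    measure = rows$measure,
    threshold = rows$mean_intercept + rows$mean_slope * age + 2 * s,
    extrapolated = age < rows$age_min | age > rows$age_max
  )
}

#' Flag a subject's abnormal regions
#'
#' A region is abnormal on a measure when its canonical score strictly
#' exceeds the normative `mean + 2 SD` at the subject's age and sex. The
#' same rule applies to controls (used for null-rate checks) and patients.
#' Abnormal regions on `nac0` form the set aR0; on `nac1`, aR1.
#'
#' @param profile A [compute_profile()] tibble for one subject (canonical
#'   scale).
#' @param record One-row metadata with `id`, `age`, `sex`.
#' @param model A [fit_normative()] result covering the subject's sex.
#' @return An `abnormal_regions` tibble: `subject_id`, `region_id`,
#'   `measure`, `score`, `threshold`, `abnormal`, `extrapolated`.
#'   Use [abnormal_sets()] for the plain aR0/aR1 id sets.
#' @export
detect_abnormal <- function(profile, record, model) {
  ref_scale <- attr(model, "score_scale")
  if (!is.null(ref_scale)) {
    for (ms in c("nac0", "nac1")) {
      s <- sum(profile[[ms]])
      if (!is.na(s) && !is.na(ref_scale[[ms]]) &&
          (s > 1.5 * ref_scale[[ms]] || s < ref_scale[[ms]] / 1.5)) {
        abort(sprintf(
          "profile %s total (%.3g) is on a different scale than the model (%.3g); canonical-scale profiles are required",
          ms, s, ref_scale[[ms]]
        ))
      }
    }
  }
  thr <- normative_thresholds(model, record$sex, record$age)
  long <- tidyr::pivot_longer(
    profile[, c("subject_id", "region_id", "nac0", "nac1")],
    cols = c("nac0", "nac1"), names_to = "measure", values_to = "score"
  )
  out <- dplyr::left_join(long, thr, by = c("region_id", "measure"))
  out$abnormal <- !is.na(out$score) & !is.na(out$threshold) &
    out$score > out$threshold
  structure(out, class = c("abnormal_regions", class(out)))
}

#' Extract aR0/aR1 region-id sets
#'
#' @param abnormal A [detect_abnormal()] result.
#' @return List with integer vectors `ar0` and `ar1` (0-based region ids).
#' @export
abnormal_sets <- function(abnormal) {
  list(
    ar0 = sort(abnormal$region_id[abnormal$abnormal &
                                    abnormal$measure == "nac0"]),
    ar1 = sort(abnormal$region_id[abnormal$abnormal &
                                    abnormal$measure == "nac1"])
  )
}

#' Draw region scores from a fitted normative model
#'
#' Samples one synthetic subject's scores per region and measure from the
#' fitted Gaussian model `N(mean(age), max(SD(age), floor)^2)` — the null
#' under which the abnormal-flag rate should equal the one-sided 2 SD tail,
#' about 2.28% per region.
#'
#' @param model A [fit_normative()] result.
#' @param sex,age Subject covariates.
#' @return Tibble `region_id`, `measure`, `score`.
#' @export
simulate_model_scores <- function(model, sex, age) {
  rows <- model[model$sex == sex, ]
  if (nrow(rows) == 0) abort(sprintf("model does not cover sex %s", sex))
  s <- pmax(rows$sd_intercept + rows$sd_slope * age, rows$sd_floor)
  tibble(
    region_id = rows$region_id,
    measure = rows$measure,
    score = rows$mean_intercept + rows$mean_slope * age + rnorm(nrow(rows), 0, s)
  )
}
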