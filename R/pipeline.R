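#' Pipeline configuration
#'
#' Collects every analysis constant in one validated object. The defaults
#' reproduce the reference analysis: adjacency threshold Z > 1.96, series
#' order n = 20, abnormality bound mean + 2 SD, band pass 0.01-0.1 Hz,
#' motion limits 2 mm / 0.02 rad, 0.05-wide distribution bins, and a
#' +/- 5 year age-matching window.
#'
#' @param threshold_z Strict Z threshold for an edge.
#' @param order_n Alpha-centrality series order.
#' @param ess_mode Effective-sample-size variant, `"lag1"` or `"full"`.
#' @param sd_mode Normative dispersion model, `"age_regressed"` or
#'   `"pooled"`.
#' @param bin_width Distribution histogram bin width on the rescaled scale.
#' @param match_window_years Age half-window for matched references.
#' @param low_hz,high_hz Band-pass limits.
#' @param trans_limit_mm,rot_limit_rad Motion QC limits.
#' @param discard_volumes Leading volumes to drop per session (0 for
#'   analysis-ready series).
#' @param seed Seed recorded in the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(threshold_z = 1.96, order_n = 20,
                            ess_mode = c("lag1", "full"),
                            sd_mode = c("age_regressed", "pooled"),
                            bin_width = 0.05, match_window_years = 5,
                            low_hz = 0.01, high_hz = 0.1,
                            trans_limit_mm = 2, rot_limit_rad = 0.02,
                            discard_volumes = 0, seed = 1L) {
  stopifnot(threshold_z > 0, order_n >= 1, bin_width > 0, bin_width <= 1,
            match_window_years >= 0, discard_volumes >= 0)
  structure(
    list(threshold_z = threshold_z, order_n = as.integer(order_n),
         ess_mode = match.arg(ess_mode), sd_mode = match.arg(sd_mode),
         bin_width = bin_width, match_window_years = match_window_years,
         low_hz = low_hz, high_hz = high_hz,
         trans_limit_mm = trans_limit_mm, rot_limit_rad = rot_limit_rad,
         discard_volumes = as.integer(discard_volumes),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis on an in-memory cohort
#'
#' The end-to-end chain per subject: motion QC, band-pass filtering,
#' per-session Z matrices, session averaging, binarization, centrality
#' profiles; then the normative model is fit on the usable controls, every
#' usable subject's abnormal regions are flagged against it, distribution
#' chi-squares are computed against matched-control references, and the
#' cohort statistics (edge-count ANCOVA, patient-vs-control rank-sum on
#' abnormal counts, clinical correlations) are assembled.
#'
#' @param cohort A [generate_cohort()] or [read_cohort()] result.
#' @param config A [pipeline_config()].
#' @param keep_adjacency Keep each subject's adjacency matrix in the result
#'   (memory-heavy at full atlas size), default `FALSE`.
#' @return A `cohort_analysis` list: `profiles`, `model`, `abnormal`,
#'   `reports`, `clinical`, `group_stats`, `exclusions`, `flags`,
#'   `manifest` (and `adjacency` when kept).
#' @export
run_cohort_analysis <- function(cohort, config = pipeline_config(),
                                keep_adjacency = FALSE) {
  subjects <- cohort$subjects
  metadata <- cohort$metadata
  atlas <- cohort$atlas

  profiles <- list()
  reports_base <- list()
  adjacency_kept <- if (keep_adjacency) list() else NULL
  subj_adj <- list()
  exclusions <- list()
  flags <- list()

  for (id in names(subjects)) {
    s <- subjects[[id]]
    sessions <- s$sessions
    if (config$discard_volumes > 0) {
      sessions <- lapply(sessions, discard_initial_volumes,
                         k = config$discard_volumes)
    }
    conn <- subject_z_matrix(
      sessions, s$motion,
      low_hz = config$low_hz, high_hz = config$high_hz,
      ess_mode = config$ess_mode,
      trans_limit_mm = config$trans_limit_mm,
      rot_limit_rad = config$rot_limit_rad
    )
    if (conn$n_sessions_used == 0) {
      exclusions[[id]] <- tibble(id = id, reason = conn$reason)
      next
    }
    adj <- binarize(conn$z, config$threshold_z)
    prof <- compute_profile(adj, order_n = config$order_n, subject_id = id)
    if (attr(prof, "lambda_max") == 0) {
      flags[[length(flags) + 1]] <- tibble(id = id, flag = "lambda_zero")
    } else if (!attr(prof, "connected")) {
      flags[[length(flags) + 1]] <- tibble(id = id, flag = "disconnected_graph")
    }
    profiles[[id]] <- prof
    subj_adj[[id]] <- list(n_edges = adj$n_edges,
                           n_sessions_used = conn$n_sessions_used)
    if (keep_adjacency) adjacency_kept[[id]] <- adj
    # hold a sparse copy for report assembly; dense copies of every
    # subject's 388 x 388 matrix would dominate memory at cohort scale
    reports_base[[id]] <- structure(
      list(a = Matrix::Matrix(adj$a != 0, sparse = TRUE),
           n_edges = adj$n_edges),
      class = "adjacency"
    )
  }

  usable <- names(profiles)
  if (length(usable) == 0) abort("no usable subjects after QC")
  profile_tbl <- dplyr::bind_rows(lapply(profiles, as_tibble))
  meta_usable <- metadata[metadata$id %in% usable, ]

  control_ids <- meta_usable$id[meta_usable$group == "control"]
  control_profiles <- profile_tbl[profile_tbl$subject_id %in% control_ids, ]
  model <- fit_normative(control_profiles, meta_usable,
                         sd_mode = config$sd_mode)

  breaks <- seq(0, 1, by = config$bin_width)
  abnormal_list <- list()
  report_rows <- list()
  for (id in usable) {
    rec <- meta_usable[meta_usable$id == id, ]
    ab <- detect_abnormal(profiles[[id]], rec, model)
    abnormal_list[[id]] <- ab
    dist_p <- lapply(c(nac0 = "nac0", nac1 = "nac1"), function(ms) {
      ref <- matched_reference(
        control_profiles, meta_usable[meta_usable$group == "control", ],
        sex = rec$sex, age = rec$age, measure = ms, breaks = breaks,
        window_years = config$match_window_years
      )
      scores <- profiles[[id]][[paste0(ms, "_rescaled")]]
      distribution_chisq(scores, ref, breaks)
    })
    report_rows[[id]] <- assemble_report(id, reports_base[[id]], ab, atlas,
                                         dist_p = dist_p)
  }
  abnormal_tbl <- dplyr::bind_rows(lapply(abnormal_list, as_tibble))
  reports <- dplyr::bind_rows(report_rows)
  reports <- dplyr::left_join(
    reports, meta_usable[, c("id", "group", "age", "sex")],
    by = c(subject_id = "id")
  )

  pat <- reports[reports$group == "patient", ]
  ctl <- reports[reports$group == "control", ]
  group_stats <- list(
    edges_ancova = if (nrow(pat) > 0 && nrow(ctl) > 0 && nrow(reports) >= 6) {
      edges_ancova(reports$n_edges, reports$group, reports$age)
    },
    ar0_comparison = if (nrow(pat) > 0 && nrow(ctl) > 0) {
      count_comparison(pat$n_ar0, ctl$n_ar0)
    },
    ar1_comparison = if (nrow(pat) > 0 && nrow(ctl) > 0) {
      count_comparison(pat$n_ar1, ctl$n_ar1)
    },
    ar0_ar1_correlation = if (nrow(pat) >= 5) {
      tryCatch(spearman(pat$n_ar0, pat$n_ar1), error = function(e) NULL)
    }
  )

  clinical <- if (nrow(pat) >= 5) {
    correlate_clinical(pat, metadata)
  }

  manifest <- list(
    package = "nacnorm",
    version = as.character(utils::packageVersion("nacnorm")),
    config = unclass(config),
    n_subjects = length(subjects),
    n_usable = length(usable),
    n_regions = nrow(atlas),
    design_flags = list(
      motion_reference = "displacement relative to first volume",
      filter = "projection on complement of trend + out-of-band Fourier modes",
      ess_formula = config$ess_mode,
      sd_regression = config$sd_mode,
      score_reduction = "row sums of the normalized centrality matrix",
      alpha_one = "alpha = 1/lambda exactly; order 20 partial sums"
    )
  )

  structure(
    list(profiles = profile_tbl, model = model, abnormal = abnormal_tbl,
         reports = reports, clinical = clinical, group_stats = group_stats,
         exclusions = dplyr::bind_rows(exclusions),
         flags = dplyr::bind_rows(flags),
         subject_meta = subj_adj,
         adjacency = adjacency_kept,
         manifest = manifest),
    class = "cohort_analysis"
  )
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf(
    "<cohort_analysis> %d usable subjects, %d regions; %d excluded\n",
    x$manifest$n_usable, x$manifest$n_regions,
    nrow(x$exclusions %||% tibble())
  ))
  invisible(x)
}

#' Run the pipeline on an on-disk cohort and write all outputs
#'
#' Reads a cohort directory (see [write_cohort()] for the layout), runs
#' [run_cohort_analysis()], and writes `profiles.tsv`, `model.tsv`,
#' `abnormal.tsv`, `reports.tsv`, `clinical.tsv`, `exclusions.tsv`,
#' `report.json` (per-subject reports plus group statistics) and
#' `manifest.json` into the output directory. Repeated runs on the same
#' inputs produce byte-identical files.
#'
#' @param cohort_dir Input cohort directory.
#' @param output_dir Output directory (created if missing).
#' @param config A [pipeline_config()].
#' @param tr_seconds Sampling interval of the stored series.
#' @return The `cohort_analysis`, invisibly.
#' @export
run_pipeline <- function(cohort_dir, output_dir,
                         config = pipeline_config(), tr_seconds = 3) {
  cohort <- read_cohort(cohort_dir, tr_seconds = tr_seconds)
  res <- run_cohort_analysis(cohort, config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(res$profiles, file.path(output_dir, "profiles.tsv"),
                   progress = FALSE)
  write_model_tsv(res$model, file.path(output_dir, "model.tsv"))
  readr::write_tsv(res$abnormal, file.path(output_dir, "abnormal.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$reports, file.path(output_dir, "reports.tsv"),
                   progress = FALSE)
  if (!is.null(res$clinical)) {
    readr::write_tsv(res$clinical, file.path(output_dir, "clinical.tsv"),
                     progress = FALSE)
  }
  if (nrow(res$exclusions %||% tibble()) > 0) {
    readr::write_tsv(res$exclusions, file.path(output_dir, "exclusions.tsv"),
                     progress = FALSE)
  }
  jsonlite::write_json(
    list(reports = res$reports, group_stats = res$group_stats,
         flags = res$flags),
    file.path(output_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  jsonlite::write_json(res$manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
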