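#' Per-subject abnormality report
#'
#' Condenses one subject's analysis into a single row: abnormal-region
#' counts, how densely the aR0 regions interconnect
#' ([connection_percentage()]), agreement between the aR0 and aR1 labelings
#' ([cohen_kappa()]), DMN enrichment of each set, and (when supplied) the
#' distribution chi-square p-values against the matched-control reference.
#'
#' @param subject_id Identifier.
#' @param adjacency The subject's [binarize()] result.
#' @param abnormal The subject's [detect_abnormal()] result.
#' @param atlas Atlas tibble (`region_id`, `is_dmn`).
#' @param dist_p Optional named list with elements `nac0`/`nac1`, each a
#'   [distribution_chisq()] row.
#' @return One-row tibble of the report fields.
#' @export
assemble_report <- function(subject_id, adjacency, abnormal, atlas,
                            dist_p = NULL) {
  sets <- abnormal_sets(abnormal)
  n_regions <- nrow(atlas)
  lab0 <- (atlas$region_id %in% sets$ar0)
  lab1 <- (atlas$region_id %in% sets$ar1)

  enr <- lapply(sets, function(s) {
    if (length(s) >= 1) dmn_enrichment(s, atlas)
    else tibble(n = 0L, n_dmn = 0L, observed_pct = NA_real_,
                expected_pct = 100 * sum(atlas$is_dmn) / n_regions,
                statistic = NA_real_, p_value = NA_real_)
  })

  tibble(
    subject_id = subject_id,
    n_edges = adjacency$n_edges,
    n_ar0 = length(sets$ar0),
    n_ar1 = length(sets$ar1),
    connection_percentage = connection_percentage(adjacency, sets$ar0),
    kappa = cohen_kappa(lab0, lab1),
    dmn_count_ar0 = enr$ar0$n_dmn,
    dmn_pct_ar0 = enr$ar0$observed_pct,
    dmn_chisq_p_ar0 = enr$ar0$p_value,
    dmn_count_ar1 = enr$ar1$n_dmn,
    dmn_pct_ar1 = enr$ar1$observed_pct,
    dmn_chisq_p_ar1 = enr$ar1$p_value,
    dist_chisq_p_nac0 = if (is.null(dist_p)) NA_real_ else dist_p$nac0$p_value,
    dist_chisq_p_nac1 = if (is.null(dist_p)) NA_real_ else dist_p$nac1$p_value
  )
}

#' Cohort-level clinical correlation table
#'
#' Correlates each abnormality summary (`n_ar0`, `n_ar1`,
#' `connection_percentage`) with each clinical covariate across patients.
#' Duration of illness uses partial Spearman with age as nuisance covariate
#' (duration and age are confounded); AED count, QOLIE-31 and LSSS use plain
#' Spearman. Correlations are computed on complete cases and unadjusted for
#' multiple testing; `n_tests` is attached as an attribute.
#'
#' @param reports Row-bound [assemble_report()] tibble for the patients.
#' @param metadata Metadata with `id`, `age`, `duration_years`, `n_aeds`,
#'   `qolie31`, `lsss`.
#' @return Tibble: `outcome`, `clinical`, `method`, `r`, `p_value`, `n`.
#' @export
correlate_clinical <- function(reports, metadata) {
  outcomes <- c("n_ar0", "n_ar1", "connection_percentage")
  clinicals <- c("duration_years", "n_aeds", "qolie31", "lsss")
  d <- dplyr::inner_join(
    reports[, c("subject_id", outcomes)],
    metadata[, c("id", "age", clinicals)],
    by = c(subject_id = "id")
  )
  rows <- list()
  for (oc in outcomes) {
    for (cl in clinicals) {
      partial <- cl == "duration_years"
      res <- tryCatch({
        if (partial) spearman_partial(d[[oc]], d[[cl]], d$age)
        else spearman(d[[oc]], d[[cl]])
      }, error = function(e) tibble(r = NA_real_, p_value = NA_real_,
                                    n = sum(stats::complete.cases(d[[oc]], d[[cl]]))))
      rows[[length(rows) + 1]] <- tibble(
        outcome = oc, clinical = cl,
        method = if (partial) "spearman_partial_age" else "spearman",
        r = res$r, p_value = res$p_value, n = res$n
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_tests") <- nrow(out)
  out
}
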