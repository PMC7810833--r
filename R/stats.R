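#' Chi-square comparison of a subject's score distribution to a reference
#'
#' Bins the subject's max-rescaled scores on `[0, 1]`, takes expected counts
#' from the matched-control reference proportions, merges adjacent bins
#' until every expected count is at least 5 (the usual chi-square validity
#' rule), and computes the Pearson statistic with `df = bins - 1`.
#'
#' @param subject_scores Numeric vector of max-rescaled scores in `[0, 1]`
#'   (one per region).
#' @param reference_props Reference bin proportions (summing to 1), one per
#'   bin of `breaks` — e.g. from [matched_reference()].
#' @param breaks Bin edges partitioning `[0, 1]`; default width 0.05.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n_bins` (after
#'   merging), `n`.
#' @export
distribution_chisq <- function(subject_scores,
                               reference_props,
                               breaks = seq(0, 1, by = 0.05)) {
  stopifnot(length(reference_props) == length(breaks) - 1)
  if (abs(sum(reference_props) - 1) > 1e-8) {
    abort("reference proportions must sum to 1")
  }
  scores <- subject_scores[!is.na(subject_scores)]
  if (any(scores < breaks[1] | scores > breaks[length(breaks)])) {
    abort("scores outside the binning range")
  }
  obs <- bin_counts(scores, breaks)
  n <- sum(obs)
  exp_counts <- reference_props * n
  m <- merge_sparse_bins(obs, exp_counts, min_expected = 5)
  if (length(m$observed) < 2) abort("fewer than 2 bins after merging")
  stat <- sum((m$observed - m$expected)^2 / m$expected)
  df <- length(m$observed) - 1
  tibble(statistic = stat, df = df,
         p_value = stats::pchisq(stat, df, lower.tail = FALSE),
         n_bins = length(m$observed), n = n)
}

bin_counts <- function(x, breaks) {
  # left-closed bins, last bin closed on both sides
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  tabulate(idx, nbins = length(breaks) - 1)
}

# Greedy merge: repeatedly fold the bin with the smallest expected count
# into its smaller neighbour until all expected >= min_expected (never
# below 2 bins). Deterministic.
merge_sparse_bins <- function(observed, expected, min_expected = 5) {
  while (length(expected) > 2 && min(expected) < min_expected) {
    i <- which.min(expected)
    j <- if (i == 1) 2
    else if (i == length(expected)) i - 1
    else if (expected[i - 1] <= expected[i + 1]) i - 1
    else i + 1
    keep <- min(i, j)
    drop <- max(i, j)
    observed[keep] <- observed[keep] + observed[drop]
    expected[keep] <- expected[keep] + expected[drop]
    observed <- observed[-drop]
    expected <- expected[-drop]
  }
  list(observed = observed, expected = expected)
}

#' Matched-control reference distribution
#'
#' Mean bin proportions of the max-rescaled scores of same-sex controls
#' within `window_years` of the subject's age. When fewer than
#' `min_matches` controls match, falls back to the regression-predicted
#' distribution: each bin's proportion is OLS-regressed on age over all
#' same-sex controls, predicted at the subject's age, clipped at zero and
#' renormalized.
#'
#' @param profiles Control profiles tibble with `subject_id`, `region_id`,
#'   and the `*_rescaled` columns.
#' @param metadata Control metadata (`id`, `age`, `sex`).
#' @param sex,age Subject covariates to match on.
#' @param measure `"nac0"` or `"nac1"`.
#' @param breaks Bin edges, default width 0.05 on `[0, 1]`.
#' @param window_years Age-matching half-window, default 5.
#' @param min_matches Minimum matched controls before the regression
#'   fallback, default 10.
#' @return Numeric vector of bin proportions summing to 1, with attribute
#'   `n_matched`.
#' @export
matched_reference <- function(profiles, metadata, sex, age,
                              measure = c("nac0", "nac1"),
                              breaks = seq(0, 1, by = 0.05),
                              window_years = 5, min_matches = 10) {
  measure <- match.arg(measure)
  col <- paste0(measure, "_rescaled")
  meta <- metadata[metadata$sex == sex, ]
  if (nrow(meta) == 0) abort(sprintf("no controls of sex %s", sex))
  props_of <- function(ids) {
    m <- vapply(ids, function(i) {
      s <- profiles[[col]][profiles$subject_id == i]
      p <- bin_counts(s[!is.na(s)], breaks)
      p / sum(p)
    }, numeric(length(breaks) - 1))
    rowMeans(m)
  }
  matched <- meta$id[abs(meta$age - age) <= window_years]
  if (length(matched) >= min_matches) {
    out <- props_of(matched)
    return(structure(out / sum(out), n_matched = length(matched)))
  }
  # regression fallback over all same-sex controls
  per_subject <- vapply(meta$id, function(i) {
    s <- profiles[[col]][profiles$subject_id == i]
    p <- bin_counts(s[!is.na(s)], breaks)
    p / sum(p)
  }, numeric(length(breaks) - 1))
  x <- cbind(1, meta$age)
  co <- stats::lm.fit(x, t(per_subject))$coefficients
  pred <- pmax(co[1, ] + co[2, ] * age, 0)
  if (sum(pred) == 0) abort("degenerate reference distribution")
  structure(pred / sum(pred), n_matched = length(matched))
}

#' Wilcoxon rank-sum comparison of two count samples
#'
#' Mann-Whitney/Wilcoxon rank-sum test via the tie-corrected normal
#' approximation without continuity correction. Positive `z` means the
#' first sample ranks higher.
#'
#' @param x,y Numeric samples (e.g. patients' and controls' abnormal-region
#'   counts).
#' @return One-row tibble: `z`, `p_value`, `median_x`, `median_y`, `n_x`,
#'   `n_y`.
#' @export
count_comparison <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  n1 <- length(x)
  n2 <- length(y)
  all_v <- c(x, y)
  r <- rank(all_v)
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n1 + n2 + 1) / 2
  ties <- table(all_v)
  nn <- n1 + n2
  tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
  if (sigma2 <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- (w - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  tibble(z = z, p_value = p, median_x = stats::median(x),
         median_y = stats::median(y), n_x = n1, n_y = n2)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks with the t approximation for the
#' p-value (`df = n - 2`). Ties are allowed.
#'
#' @param x,y Numeric vectors of equal length, at least 5.
#' @return One-row tibble: `r`, `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 5) abort("need at least 5 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    abort("constant input")
  }
  r <- stats::cor(rank(x), rank(y))
  tibble(r = r, p_value = t_test_p(r, n - 2), n = n)
}

t_test_p <- function(r, df) {
  if (abs(r) >= 1) return(0)
  t_stat <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(t_stat), df)
}

#' Partial Spearman correlation with one covariate
#'
#' Rank-transforms all three variables, then partials the covariate out of
#' the Pearson correlation of the ranks:
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, with a
#' t-test on `df = n - 3`.
#'
#' @param x,y Variables of interest.
#' @param covar Nuisance covariate (e.g. age).
#' @return One-row tibble: `r`, `p_value`, `n`.
#' @export
spearman_partial <- function(x, y, covar) {
  keep <- stats::complete.cases(x, y, covar)
  x <- x[keep]
  y <- y[keep]
  covar <- covar[keep]
  n <- length(x)
  if (n < 5) abort("need at least 5 complete triples")
  if (length(unique(x)) < 2 || length(unique(y)) < 2 ||
      length(unique(covar)) < 2) {
    abort("constant input")
  }
  rx <- rank(x)
  ry <- rank(y)
  rz <- rank(covar)
  r_xy <- stats::cor(rx, ry)
  r_xz <- stats::cor(rx, rz)
  r_yz <- stats::cor(ry, rz)
  denom <- sqrt((1 - r_xz^2) * (1 - r_yz^2))
  if (denom == 0) abort("covariate perfectly correlated with an input")
  r <- (r_xy - r_xz * r_yz) / denom
  tibble(r = r, p_value = t_test_p(r, n - 3), n = n)
}

#' Percentage of realised connections among a region set
#'
#' `100 * edges within the set / C(n, 2)`: how densely a subject's abnormal
#' regions are functionally connected to each other.
#'
#' @param a Adjacency matrix (or [binarize()] result).
#' @param regions 0-based region ids, at least 2 (fewer returns `NA`).
#' @return Percentage in `[0, 100]`, or `NA_real_` when `|regions| < 2`.
#' @export
connection_percentage <- function(a, regions) {
  a <- adjacency_matrix(a)
  regions <- unique(as.integer(regions))
  n <- length(regions)
  if (n < 2) return(NA_real_)
  idx <- regions + 1L
  sub <- a[idx, idx, drop = FALSE]
  100 * (sum(sub) / 2) / choose(n, 2)
}

#' Cohen's kappa for two binary labelings
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement `p_e` from the marginal products. Two identical
#' constant labelings (where `p_e = 1`) are defined as perfect agreement.
#'
#' @param labels_a,labels_b Logical or 0/1 vectors of equal length >= 2.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  a <- as.integer(as.logical(labels_a))
  b <- as.integer(as.logical(labels_b))
  if (length(a) != length(b) || length(a) < 2) {
    abort("labelings must have equal length >= 2")
  }
  po <- mean(a == b)
  pa <- mean(a)
  pb <- mean(b)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  if (pe >= 1) return(if (po == 1) 1 else (po - pe))
  (po - pe) / (1 - pe)
}

#' Default-mode-network enrichment of a region set
#'
#' Compares the observed percentage of a subject's abnormal regions inside
#' the DMN with the atlas expectation (`n_dmn / n_regions`, 100/388 = 25.8%
#' at the default atlas) by a one-sample goodness-of-fit chi-square on the
#' in/out split, `df = 1`.
#'
#' @param regions 0-based region ids (non-empty).
#' @param atlas Atlas tibble with `region_id` and `is_dmn`.
#' @return One-row tibble: `n`, `n_dmn`, `observed_pct`, `expected_pct`,
#'   `statistic`, `p_value`.
#' @export
dmn_enrichment <- function(regions, atlas) {
  regions <- unique(as.integer(regions))
  n <- length(regions)
  if (n < 1) abort("need at least one region")
  dmn_ids <- atlas$region_id[atlas$is_dmn == 1]
  p0 <- length(dmn_ids) / nrow(atlas)
  in_dmn <- sum(regions %in% dmn_ids)
  obs <- c(in_dmn, n - in_dmn)
  expd <- c(n * p0, n * (1 - p0))
  stat <- sum((obs - expd)^2 / expd)
  tibble(
    n = n, n_dmn = in_dmn,
    observed_pct = 100 * in_dmn / n,
    expected_pct = 100 * p0,
    statistic = stat,
    p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE)
  )
}

#' Edge-count ANCOVA: group effect and group-by-age interaction
#'
#' Fits `edges ~ group + age` and `edges ~ group * age`; reports the partial
#' F-test for the group main effect (given age, in the additive model) and
#' for the interaction term.
#'
#' @param edge_counts Per-subject edge counts.
#' @param group Two-level group labels.
#' @param age Ages (nuisance covariate).
#' @return Tibble with rows `group` and `group:age`: `df`, `F`, `p_value`.
#' @export
edges_ancova <- function(edge_counts, group, age) {
  d <- data.frame(edges = edge_counts, group = factor(group), age = age)
  if (nlevels(d$group) != 2) abort("need exactly two groups")
  if (nrow(d) < 6) abort("need at least 6 subjects")
  fit_age <- stats::lm(edges ~ age, data = d)
  fit_add <- stats::lm(edges ~ age + group, data = d)
  fit_int <- stats::lm(edges ~ age * group, data = d)
  if (any(is.na(coef(fit_int)))) abort("rank-deficient design")
  a_group <- stats::anova(fit_age, fit_add)
  a_int <- stats::anova(fit_add, fit_int)
  tibble(
    term = c("group", "group:age"),
    df = c(a_group$Df[2], a_int$Df[2]),
    F = c(a_group$F[2], a_int$F[2]),
    p_value = c(a_group$`Pr(>F)`[2], a_int$`Pr(>F)`[2])
  )
}
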