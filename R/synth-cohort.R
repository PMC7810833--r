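#' Configure a synthetic resting-state cohort
#'
#' Bundles every knob of the synthetic-cohort generator into a validated
#' configuration object. The defaults emulate the acquisition geometry and
#' cohort structure the analysis was designed around: 388 brain regions
#' (368 cerebral + 20 cerebellar), of which 100 belong to the default mode
#' network, three runs of 101 volumes at TR = 3 s, and healthy controls
#' spanning ages 18-84 of both sexes.
#'
#' The latent signal model is a community-structured correlation matrix:
#' regions fall into `n_communities` contiguous blocks, pairs within a block
#' correlate at `base_within_corr` (drifting with age at `age_slope` per year
#' and shifted by `sex_shift` for males) and pairs across blocks at
#' `base_between_corr`. Each session is a stationary AR(1) process with
#' coefficient `ar1_coeff` whose innovations carry that covariance. Patient
#' subjects additionally receive `n_hubs` randomly placed hub regions whose
#' correlation with every other region is boosted by `hub_corr_boost` —
#' regions that should surface downstream as abnormally central.
#'
#' @param n_controls,n_patients Cohort sizes.
#' @param n_regions Number of atlas regions (nodes of the graph).
#' @param n_dmn Number of regions labelled as default-mode-network members;
#'   defaults to the 100-of-388 atlas proportion scaled to `n_regions`.
#' @param n_sessions Resting-state runs per subject.
#' @param n_volumes Analysis-ready volumes per run.
#' @param tr_seconds Sampling interval (repetition time), seconds.
#' @param age_range Two-element numeric, inclusive age span of controls.
#' @param sex_ratio Fraction of female subjects.
#' @param ar1_coeff Temporal autocorrelation of the AR(1) signal, in `[0, 1)`.
#' @param n_communities Number of latent correlation blocks.
#' @param base_within_corr,base_between_corr Latent correlation levels within
#'   and between communities, each in `[0, 0.95]`.
#' @param age_slope Additive change in within-community correlation per year
#'   of age, centred on the middle of `age_range`.
#' @param sex_shift Additive shift in within-community correlation for males.
#' @param n_hubs Hub regions injected per patient.
#' @param hub_corr_boost Correlation added from a hub to every other region.
#' @param seed Integer seed; all randomness in [generate_cohort()] flows
#'   from it.
#'
#' @return A `cohort_config` list.
#' @export
#' @examples
#' cfg <- cohort_config(n_controls = 30, n_patients = 2, n_regions = 40)
#' cfg$n_regions
cohort_config <- function(n_controls = 300,
                          n_patients = 10,
                          n_regions = 388,
                          n_dmn = NULL,
                          n_sessions = 3,
                          n_volumes = 101,
                          tr_seconds = 3,
                          age_range = c(18, 84),
                          sex_ratio = 0.62,
                          ar1_coeff = 0.3,
                          n_communities = 8,
                          base_within_corr = 0.30,
                          base_between_corr = 0.05,
                          age_slope = -0.001,
                          sex_shift = 0.02,
                          n_hubs = 5,
                          hub_corr_boost = 0.3,
                          seed = 1L) {
  if (is.null(n_dmn)) {
    # the 100-of-388 atlas proportion, scaled to the configured graph size
    n_dmn <- max(1L, as.integer(round(n_regions * 100 / 388)))
  }
  cfg <- list(
    n_controls = as.integer(n_controls), n_patients = as.integer(n_patients),
    n_regions = as.integer(n_regions), n_dmn = as.integer(n_dmn),
    n_sessions = as.integer(n_sessions), n_volumes = as.integer(n_volumes),
    tr_seconds = as.numeric(tr_seconds), age_range = as.numeric(age_range),
    sex_ratio = as.numeric(sex_ratio), ar1_coeff = as.numeric(ar1_coeff),
    n_communities = as.integer(n_communities),
    base_within_corr = as.numeric(base_within_corr),
    base_between_corr = as.numeric(base_between_corr),
    age_slope = as.numeric(age_slope), sex_shift = as.numeric(sex_shift),
    n_hubs = as.integer(n_hubs), hub_corr_boost = as.numeric(hub_corr_boost),
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(
    cfg$n_regions >= 2, cfg$n_dmn >= 0, cfg$n_dmn <= cfg$n_regions,
    cfg$n_sessions >= 1, cfg$n_volumes >= 8, cfg$tr_seconds > 0,
    length(cfg$age_range) == 2, cfg$age_range[1] < cfg$age_range[2],
    cfg$sex_ratio >= 0, cfg$sex_ratio <= 1,
    cfg$n_communities >= 1, cfg$n_communities <= cfg$n_regions,
    cfg$n_hubs >= 0, cfg$hub_corr_boost >= 0
  )
  if (cfg$ar1_coeff < 0 || cfg$ar1_coeff >= 1) {
    abort("`ar1_coeff` must lie in [0, 1).")
  }
  for (nm in c("base_within_corr", "base_between_corr")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 0.95) {
      abort(sprintf("`%s` must lie in [0, 0.95].", nm))
    }
  }
  invisible(cfg)
}

#' Community membership of each region
#'
#' Contiguous near-equal blocks; region ids are 0-based throughout.
#' @param config A [cohort_config()].
#' @return Integer vector of community labels, one per region.
#' @export
region_communities <- function(config) {
  sort(rep_len(seq_len(config$n_communities), config$n_regions))
}

#' Build the latent region-by-region correlation matrix
#'
#' Constructs the correlation matrix the synthetic BOLD innovations are drawn
#' from: `base_between_corr` everywhere, `base_within_corr +
#' age_slope * (age - midpoint) (+ sex_shift for males)` within communities,
#' unit diagonal. Rows and columns of hub regions are boosted by
#' `hub_corr_boost` (clipped at 0.95). If the result is not positive
#' definite it is repaired by clipping eigenvalues below `1e-8` and
#' rescaling to unit diagonal; an irreparable matrix is an error.
#'
#' @param config A [cohort_config()].
#' @param age Subject age in years.
#' @param hubs Integer vector of 0-based hub region ids (empty for controls).
#' @param sex `"F"` or `"M"`.
#' @return A symmetric positive-definite matrix with unit diagonal.
#' @export
build_latent_covariance <- function(config, age, hubs = integer(), sex = "F") {
  n <- config$n_regions
  if (length(hubs) && (min(hubs) < 0 || max(hubs) > n - 1)) {
    abort("`hubs` must be 0-based region ids below `n_regions`.")
  }
  midpoint <- mean(config$age_range)
  within <- config$base_within_corr + config$age_slope * (age - midpoint) +
    if (identical(sex, "M")) config$sex_shift else 0
  within <- min(max(within, 0), 0.95)

  comm <- region_communities(config)
  same <- outer(comm, comm, "==")
  m <- matrix(config$base_between_corr, n, n)
  m[same] <- within
  if (length(hubs)) {
    idx <- hubs + 1L
    m[idx, ] <- pmin(m[idx, , drop = FALSE] + config$hub_corr_boost, 0.95)
    m[, idx] <- pmin(m[, idx, drop = FALSE] + config$hub_corr_boost, 0.95)
    m[idx, idx] <- pmin(
      m[idx, idx, drop = FALSE], 0.95
    )
  }
  diag(m) <- 1
  m <- (m + t(m)) / 2

  if (!is_positive_definite(m)) {
    m <- nearest_pd(m)
    if (!is_positive_definite(m)) {
      abort(sprintf(
        paste0("latent covariance not positive definite after repair ",
               "(within = %.3f, between = %.3f, boost = %.3f, %d hubs)"),
        within, config$base_between_corr, config$hub_corr_boost, length(hubs)
      ))
    }
  }
  m
}

is_positive_definite <- function(m) {
  !inherits(try(chol(m), silent = TRUE), "try-error")
}

# Clip eigenvalues below eps, reconstruct, restore unit diagonal.
nearest_pd <- function(m, eps = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  r <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(r))
  r <- r / tcrossprod(d)
  (r + t(r)) / 2
}

#' Simulate one subject's sessions and motion traces
#'
#' Each session is a stationary multivariate AR(1) process: `x_t = phi *
#' x_(t-1) + e_t` with innovations `e_t ~ N(0, (1 - phi^2) * Sigma)` so the
#' marginal covariance equals the latent `Sigma` from
#' [build_latent_covariance()]. Sessions are independent given the subject.
#' Motion traces are small Gaussian random walks starting at zero (the
#' reference volume); `inject_motion_violation` pushes one translation past
#' the 2 mm exclusion limit in the given session for QC testing.
#'
#' @param config A [cohort_config()].
#' @param record One-row subject metadata (needs `id`, `age`, `sex`, `group`).
#' @param hubs 0-based hub region ids (empty for controls).
#' @param seed Integer seed; identical seed gives bit-identical output.
#' @param inject_motion_violation Session index to contaminate, or `NULL`.
#' @return A `synthetic_subject`: list with `record`, `sessions` (list of
#'   [session_series()]), `motion` (list of T x 6 matrices, columns
#'   tx/ty/tz in mm then rx/ry/rz in radians), and `ground_truth_hubs`.
#' @export
simulate_subject <- function(config, record, hubs = integer(), seed,
                             inject_motion_violation = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (record$age < config$age_range[1] || record$age > config$age_range[2]) {
    warn(sprintf("age %.1f of subject %s outside configured range",
                 record$age, record$id))
  }
  sigma <- build_latent_covariance(config, record$age, hubs, record$sex)
  with_preserved_seed(seed, {
    u <- chol(sigma)
    phi <- config$ar1_coeff
    n <- config$n_regions
    tt <- config$n_volumes
    sessions <- vector("list", config$n_sessions)
    motion <- vector("list", config$n_sessions)
    for (s in seq_len(config$n_sessions)) {
      z <- matrix(rnorm(tt * n), tt, n) %*% u      # rows ~ N(0, Sigma)
      x <- matrix(0, n, tt)
      x[, 1] <- z[1, ]
      if (tt > 1) {
        innov_scale <- sqrt(1 - phi^2)
        for (t in 2:tt) x[, t] <- phi * x[, t - 1] + innov_scale * z[t, ]
      }
      rownames(x) <- region_names(n)
      sessions[[s]] <- session_series(
        x, tr_seconds = config$tr_seconds,
        subject_id = record$id, session_id = sprintf("ses%02d", s)
      )
      tr_walk <- apply(matrix(rnorm(tt * 3, sd = 0.02), tt, 3), 2, cumsum)
      rot_walk <- apply(matrix(rnorm(tt * 3, sd = 2e-4), tt, 3), 2, cumsum)
      tr_walk <- sweep(tr_walk, 2, tr_walk[1, ])
      rot_walk <- sweep(rot_walk, 2, rot_walk[1, ])
      if (!is.null(inject_motion_violation) &&
          s == inject_motion_violation) {
        tr_walk[max(2, tt %/% 2), 1] <- 2.5
      }
      mo <- cbind(tr_walk, rot_walk)
      colnames(mo) <- c("tx", "ty", "tz", "rx", "ry", "rz")
      motion[[s]] <- mo
    }
    structure(
      list(record = record, sessions = sessions, motion = motion,
           ground_truth_hubs = as.integer(hubs)),
      class = "synthetic_subject"
    )
  })
}

region_names <- function(n) sprintf("r%04d", seq_len(n) - 1L)

# Run code under a seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

#' Generate a full synthetic cohort
#'
#' Draws control and patient subjects under a [cohort_config()]: control ages
#' spread over `age_range` for both sexes, patients carrying ground-truth hub
#' region sets, clinical covariates (duration of illness loosely increasing
#' with age, AED count, QOLIE-31, LSSS) filled for patients only. All
#' randomness derives from `config$seed`; regenerating with the same config
#' is bit-identical.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort`: list with `subjects` (list of
#'   `synthetic_subject`), `metadata` (tibble: id, age, sex, group,
#'   duration_years, n_aeds, qolie31, lsss), `atlas` (tibble: region_id
#'   0-based, name, is_dmn), and the `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  if (config$n_controls < 20) {
    warn("fewer than 20 controls: normative fits will be unstable")
  }
  with_preserved_seed(config$seed, {
    n_tot <- config$n_controls + config$n_patients
    lo <- config$age_range[1]
    hi <- config$age_range[2]

    sex_c <- ifelse(runif(config$n_controls) < config$sex_ratio, "F", "M")
    # spread control ages evenly over the range within each sex so the
    # per-sex age regressions are well conditioned
    age_c <- numeric(config$n_controls)
    for (sx in c("F", "M")) {
      k <- sum(sex_c == sx)
      if (k > 0) {
        age_c[sex_c == sx] <-
          round(seq(lo, hi, length.out = k) + runif(k, -1, 1), 1)
      }
    }
    age_c <- pmin(pmax(age_c, lo), hi)

    sex_p <- ifelse(runif(config$n_patients) < config$sex_ratio, "F", "M")
    age_p <- round(runif(config$n_patients, lo, min(hi, 70)), 1)
    duration <- pmax(1, round(0.4 * (age_p - 12) + rnorm(config$n_patients, sd = 4), 1))
    duration <- pmin(duration, pmax(1, age_p - 10))

    metadata <- tibble(
      id = c(sprintf("C%03d", seq_len(config$n_controls)),
             sprintf("P%03d", seq_len(config$n_patients))),
      age = c(age_c, age_p),
      sex = c(sex_c, sex_p),
      group = rep(c("control", "patient"),
                  c(config$n_controls, config$n_patients)),
      duration_years = c(rep(NA_real_, config$n_controls), duration),
      n_aeds = c(rep(NA_integer_, config$n_controls),
                 sample(1:4, config$n_patients, replace = TRUE)),
      qolie31 = c(rep(NA_real_, config$n_controls),
                  round(runif(config$n_patients, 20, 90), 1)),
      lsss = c(rep(NA_real_, config$n_controls),
               round(runif(config$n_patients, 10, 80), 1))
    )

    hub_sets <- c(
      replicate(config$n_controls, integer(), simplify = FALSE),
      replicate(config$n_patients,
                sort(sample.int(config$n_regions, config$n_hubs) - 1L),
                simplify = FALSE)
    )
    subject_seeds <- sample.int(.Machine$integer.max - 1L, n_tot)

    subjects <- vector("list", n_tot)
    for (i in seq_len(n_tot)) {
      subjects[[i]] <- simulate_subject(
        config, metadata[i, ], hubs = hub_sets[[i]], seed = subject_seeds[i]
      )
    }
    names(subjects) <- metadata$id

    atlas <- tibble(
      region_id = seq_len(config$n_regions) - 1L,
      name = region_names(config$n_regions),
      is_dmn = as.integer(seq_len(config$n_regions) <= config$n_dmn)
    )

    structure(
      list(subjects = subjects, metadata = metadata, atlas = atlas,
           config = config),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d controls + %d patients, %d regions, %d x %d volumes\n",
    x$config$n_controls, x$config$n_patients, x$config$n_regions,
    x$config$n_sessions, x$config$n_volumes
  ))
  invisible(x)
}
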