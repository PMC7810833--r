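# build a control cohort of score profiles from a score-generating function
# score_fun(age, sex) -> numeric vector over regions (used for both measures)
make_profiles <- function(n_per_sex, score_fun, ages = NULL) {
  rows <- list(); meta <- list(); k <- 0
  for (sx in c("F", "M")) {
    if (is.null(ages)) ages_sx <- seq(20, 80, length.out = n_per_sex)
    else ages_sx <- ages
    for (i in seq_along(ages_sx)) {
      k <- k + 1
      id <- sprintf("S%03d", k)
      sc <- score_fun(ages_sx[i], sx)
      rows[[k]] <- tibble::tibble(
        subject_id = id, region_id = seq_along(sc) - 1L,
        nac0 = sc, nac1 = sc
      )
      meta[[k]] <- tibble::tibble(id = id, age = ages_sx[i], sex = sx)
    }
  }
  list(profiles = dplyr::bind_rows(rows), metadata = dplyr::bind_rows(meta))
}

flat_model <- function(mean_int, sd_int, regions = 0L,
                       mean_slope = 0, sd_slope = 0) {
  grid <- expand.grid(region_id = regions, sex = c("F", "M"),
                      measure = c("nac0", "nac1"),
                      stringsAsFactors = FALSE)
  m <- tibble::as_tibble(grid)
  m$mean_intercept <- mean_int; m$mean_slope <- mean_slope
  m$sd_intercept <- sd_int; m$sd_slope <- sd_slope
  m$sd_floor <- 1e-12; m$n <- 50L; m$age_min <- 18; m$age_max <- 84
  structure(m, sd_mode = "age_regressed",
            class = c("normative_model", class(m)))
}

test_that("noiseless linear age trends are recovered exactly", {
  fn <- function(age, sex) c(0.2 + 0.001 * age, 0.3 - 0.001 * age, 0.25, 0.25)
  d <- make_profiles(15, fn)
  model <- fit_normative(d$profiles, d$metadata)
  r0 <- model[model$region_id == 0 & model$sex == "F" &
                model$measure == "nac0", ]
  expect_equal(r0$mean_intercept, 0.2, tolerance = 1e-10)
  expect_equal(r0$mean_slope, 0.001, tolerance = 1e-10)
  r1 <- model[model$region_id == 1 & model$sex == "M" &
                model$measure == "nac1", ]
  expect_equal(r1$mean_slope, -0.001, tolerance = 1e-10)
  # zero noise: SD line collapses to the (tiny) floor
  thr <- threshold_at(model, 0L, "F", "nac0", 40)
  expect_equal(as.numeric(thr), 0.2 + 0.001 * 40, tolerance = 1e-6)
})

test_that("the mean fit equals brute-force normal equations", {
  set.seed(10)
  fn <- function(age, sex) 0.25 + 0.0005 * age + rnorm(4, sd = 0.01)
  d <- make_profiles(12, fn)
  model <- fit_normative(d$profiles, d$metadata)
  for (sx in c("F", "M")) {
    ages <- d$metadata$age[d$metadata$sex == sx]
    ids <- d$metadata$id[d$metadata$sex == sx]
    y <- vapply(ids, function(i) {
      d$profiles$nac0[d$profiles$subject_id == i & d$profiles$region_id == 2]
    }, numeric(1))
    x <- cbind(1, ages)
    beta <- solve(t(x) %*% x, t(x) %*% y)
    row <- model[model$region_id == 2 & model$sex == sx &
                   model$measure == "nac0", ]
    expect_equal(row$mean_intercept, beta[1], tolerance = 1e-10)
    expect_equal(row$mean_slope, beta[2], tolerance = 1e-10)
  }
})

test_that("the dispersion fit estimates the true sigma (Monte-Carlo)", {
  set.seed(11)
  fn <- function(age, sex) 0.3 + rnorm(6, sd = 0.05)
  d <- make_profiles(200, fn)
  model <- fit_normative(d$profiles, d$metadata)
  for (age in c(25, 50, 75)) {
    sd_hat <- with(model[model$sex == "F" & model$measure == "nac0", ],
                   pmax(sd_intercept + sd_slope * age, sd_floor))
    expect_true(all(abs(sd_hat - 0.05) < 0.01))
  }
  # pooled mode agrees with the homoscedastic truth too
  mp <- fit_normative(d$profiles, d$metadata, sd_mode = "pooled")
  sd_pooled <- mp$sd_intercept[mp$sex == "M" & mp$measure == "nac0"]
  expect_true(all(abs(sd_pooled - 0.05) < 0.01))
})

test_that("threshold_at returns mean + 2 SD with extrapolation flags", {
  m <- flat_model(0.30, 0.05)
  expect_equal(as.numeric(threshold_at(m, 0L, "F", "nac0", 40)), 0.40)
  expect_equal(as.numeric(threshold_at(m, 0L, "F", "nac0", 70)), 0.40)

  m2 <- flat_model(0.2, 0.05, mean_slope = 0.001)
  expect_equal(as.numeric(threshold_at(m2, 0L, "M", "nac1", 40)), 0.34)
  # monotone in age when both slopes are non-negative
  ages <- c(20, 35, 50, 65, 80)
  m3 <- flat_model(0.2, 0.01, mean_slope = 0.002, sd_slope = 0.0005)
  thr <- vapply(ages, function(a) as.numeric(threshold_at(m3, 0L, "F", "nac0", a)),
                numeric(1))
  expect_true(all(diff(thr) > 0))
  # extrapolation warning outside the fitted range
  expect_warning(t90 <- threshold_at(m, 0L, "F", "nac0", 90), "extrapolat")
  expect_true(attr(t90, "extrapolated"))
  expect_error(threshold_at(m, 5L, "F", "nac0", 40), "not in the model")
})

test_that("abnormality uses a strict inequality at mean + 2 SD", {
  m <- flat_model(0.30, 0.05, regions = 0:2)
  prof <- tibble::tibble(
    subject_id = "P", region_id = 0:2,
    nac0 = c(0.40, 0.40 + 1e-9, 0.39),        # at, just above, below
    nac1 = c(0.10, 0.10, 0.10)
  )
  rec <- tibble::tibble(id = "P", age = 50, sex = "F")
  ab <- detect_abnormal(prof, rec, m)
  sets <- abnormal_sets(ab)
  expect_identical(sets$ar0, 1L)
  expect_identical(sets$ar1, integer())
})

test_that("detection is monotone in the score", {
  m <- flat_model(0.30, 0.05, regions = 0:3)
  rec <- tibble::tibble(id = "P", age = 50, sex = "F")
  base <- tibble::tibble(subject_id = "P", region_id = 0:3,
                         nac0 = c(0.45, 0.42, 0.20, 0.30),
                         nac1 = c(0.45, 0.42, 0.20, 0.30))
  ar0 <- abnormal_sets(detect_abnormal(base, rec, m))$ar0
  bumped <- base
  bumped$nac0 <- base$nac0 + 0.05
  ar0_b <- abnormal_sets(detect_abnormal(bumped, rec, m))$ar0
  expect_true(all(ar0 %in% ar0_b))
})

test_that("held-out subjects drawn from the model are flagged at the 2 SD tail rate", {
  set.seed(12)
  fn <- function(age, sex) 0.3 + 0.0003 * age + rnorm(6, sd = 0.05)
  d <- make_profiles(150, fn)
  model <- fit_normative(d$profiles, d$metadata)
  flags <- 0; total <- 0
  for (k in 1:300) {
    sx <- if (k %% 2) "F" else "M"
    age <- runif(1, 20, 80)
    draw <- simulate_model_scores(model, sx, age)
    prof <- tidyr::pivot_wider(draw, names_from = "measure",
                               values_from = "score")
    prof$subject_id <- "H"
    ab <- detect_abnormal(prof, tibble::tibble(id = "H", age = age, sex = sx),
                          model)
    flags <- flags + sum(ab$abnormal)
    total <- total + nrow(ab)
  }
  rate <- flags / total
  expect_lt(abs(rate - 0.0228), 0.01)
})

test_that("mixed canonical and rescaled scales are rejected", {
  fn <- function(age, sex) { s <- 0.2 + runif(5, 0, 0.1); s / sum(s) }
  set.seed(13)
  d <- make_profiles(12, fn)
  mixed <- d$profiles
  # rescale one subject to max = 1 (the display scale)
  i <- mixed$subject_id == "S001"
  mixed$nac0[i] <- mixed$nac0[i] / max(mixed$nac0[i])
  expect_error(fit_normative(mixed, d$metadata), "common scale")

  model <- fit_normative(d$profiles, d$metadata)
  prof <- d$profiles[d$profiles$subject_id == "S002", ]
  rescaled <- prof
  rescaled$nac0 <- prof$nac0 / max(prof$nac0)
  rec <- d$metadata[d$metadata$id == "S002", ]
  expect_error(detect_abnormal(rescaled, rec, model), "different scale")
})

test_that("degenerate cohorts are rejected", {
  fn <- function(age, sex) rep(0.25, 4)
  d <- make_profiles(12, fn)
  only_f <- d$metadata$id[d$metadata$sex == "F"]
  expect_error(
    fit_normative(d$profiles[d$profiles$subject_id %in% only_f, ],
                  d$metadata[d$metadata$sex == "F", ]),
    "single-sex"
  )
  d2 <- make_profiles(11, fn, ages = rep(40, 11))
  expect_error(fit_normative(d2$profiles, d2$metadata), "degenerate ages")
  d3 <- make_profiles(5, fn)
  expect_error(fit_normative(d3$profiles, d3$metadata), "at least 10")
})
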