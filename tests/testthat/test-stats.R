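test_that("distribution chi-square matches hand and brute-force arithmetic", {
  # identical distribution: statistic 0, p = 1
  ref <- c(0.5, 0.5)
  scores <- c(rep(0.25, 50), rep(0.75, 50))
  res <- distribution_chisq(scores, ref, breaks = c(0, 0.5, 1))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # all 388 regions in one bin against a 50/50 reference: chi-square = 388
  res2 <- distribution_chisq(rep(0.25, 388), ref, breaks = c(0, 0.5, 1))
  expect_equal(res2$statistic, 388)
  expect_equal(res2$df, 1)

  # brute force on an arbitrary fixture (no merging needed)
  set.seed(20)
  scores <- runif(200)
  breaks <- seq(0, 1, by = 0.25)
  ref <- c(0.3, 0.3, 0.2, 0.2)
  obs <- as.vector(table(cut(scores, breaks, include.lowest = TRUE)))
  expd <- ref * 200
  brute <- sum((obs - expd)^2 / expd)
  res3 <- distribution_chisq(scores, ref, breaks)
  expect_equal(res3$statistic, brute, tolerance = 1e-12)
  expect_equal(res3$p_value, pchisq(brute, 3, lower.tail = FALSE))
})

test_that("sparse bins are merged until every expected count is at least 5", {
  breaks <- seq(0, 1, by = 0.2)
  ref <- c(0.01, 0.01, 0.48, 0.25, 0.25) # two bins with expected 1 at n = 100
  scores <- runif(100)
  res <- distribution_chisq(scores, ref, breaks)
  expect_lte(res$n_bins, 4)
  expect_equal(res$df, res$n_bins - 1)
  expect_error(
    distribution_chisq(runif(4), c(0.5, 0.5), breaks = c(0, 0.5, 1)),
    NA
  ) # small n still works: merging stops at 2 bins
})

test_that("rank-sum comparison reproduces exact rank arithmetic", {
  x <- 1:10; y <- 11:20
  res <- count_comparison(x, y)
  w <- sum(rank(c(x, y))[1:10]) # = 55
  mu <- 10 * 21 / 2
  sigma <- sqrt(10 * 10 * 21 / 12)
  expect_equal(res$z, (w - mu) / sigma, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pnorm(-abs(res$z)), tolerance = 1e-12)
  expect_equal(res$median_x, 5.5)
  # antisymmetric under group swap
  expect_equal(count_comparison(y, x)$z, -res$z)
  # identical samples: p ~ 1
  expect_gt(count_comparison(1:9, 1:9)$p_value, 0.95)
  # all tied
  tied <- count_comparison(rep(3, 5), rep(3, 7))
  expect_equal(tied$z, 0)
  expect_equal(tied$p_value, 1)
})

test_that("rank-sum p matches wilcox.test without continuity correction", {
  set.seed(21)
  x <- rpois(12, 10); y <- rpois(15, 14)
  res <- count_comparison(x, y)
  ref <- suppressWarnings(
    wilcox.test(x, y, exact = FALSE, correct = FALSE)
  )
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("spearman matches the mid-rank oracle, with and without ties", {
  x <- c(1, 5, 2, 8, 4, 9, 3, 7)
  y <- x^3 - 2 * x # strictly monotone
  expect_equal(spearman(x, y)$r, 1)

  # 8-point tied fixture against brute-force mid-rank Pearson
  xt <- c(1, 2, 2, 3, 4, 4, 4, 5)
  yt <- c(2, 1, 3, 3, 5, 4, 6, 6)
  res <- spearman(xt, yt)
  rx <- rank(xt); ry <- rank(yt)
  brute <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(res$r, brute, tolerance = 1e-12)
  # cross-check against the base R implementation
  expect_equal(res$r, cor(xt, yt, method = "spearman"), tolerance = 1e-12)
  expect_error(spearman(rep(1, 6), 1:6), "constant")
})

test_that("partial spearman equals rank-residual correlation", {
  set.seed(22)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30); z <- rnorm(30)
  res <- spearman_partial(x, y, z)
  # independent oracle: correlate residuals of rank regressions
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  ex <- residuals(lm(rx ~ rz)); ey <- residuals(lm(ry ~ rz))
  expect_equal(res$r, cor(ex, ey), tolerance = 1e-10)
  # reduction: rank-orthogonal covariate recovers the plain coefficient
  x8 <- 1:8
  z8 <- c(4, 8, 1, 5, 2, 6, 7, 3) # sum(i * z8) = 162 => rank cor 0 with 1:8
  expect_equal(cor(rank(x8), rank(z8)), 0)
  y8 <- x8 + 2
  expect_equal(spearman_partial(x8, y8, z8)$r, spearman(x8, y8)$r,
               tolerance = 1e-12)
})

test_that("connection percentage counts edges over C(n,2)", {
  a <- matrix(0, 5, 5)
  clique <- c(1, 2, 3)
  a[clique, clique] <- 1; diag(a) <- 0
  expect_equal(connection_percentage(a, c(0L, 1L, 2L)), 100)
  b <- matrix(0, 4, 4)
  b[1, 2] <- b[2, 1] <- b[2, 3] <- b[3, 2] <- 1
  expect_equal(connection_percentage(b, 0:2), 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(connection_percentage(matrix(0, 4, 4), 0:3), 0)
  expect_true(is.na(connection_percentage(a, 1L)))
})

test_that("cohen kappa matches the marginal-product definition", {
  # identical labelings with both classes present
  l <- c(rep(1, 5), rep(0, 10))
  expect_equal(cohen_kappa(l, l), 1)
  # hand-computed: 388 regions, 20 both-abnormal, 10+10 discordant
  a <- c(rep(1, 20), rep(1, 10), rep(0, 10), rep(0, 348))
  b <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 348))
  po <- 368 / 388
  pe <- (30 / 388)^2 + (358 / 388)^2
  expect_equal(cohen_kappa(a, b), (po - pe) / (1 - pe), tolerance = 1e-12)
  expect_equal(cohen_kappa(a, b), 0.639, tolerance = 1e-3)
  # independent labelings hover near zero
  set.seed(23)
  ka <- replicate(50, cohen_kappa(rbinom(388, 1, 0.1), rbinom(388, 1, 0.1)))
  expect_lt(abs(mean(ka)), 0.05)
  # both constant and identical
  expect_equal(cohen_kappa(rep(0, 10), rep(0, 10)), 1)
})

test_that("DMN enrichment reproduces the worked percentages", {
  atlas <- tibble::tibble(region_id = 0:387,
                          name = sprintf("r%03d", 0:387),
                          is_dmn = as.integer(0:387 < 100))
  expect_equal(dmn_enrichment(0:387, atlas)$expected_pct, 100 * 100 / 388,
               tolerance = 1e-12)
  # 19 of 33 regions in the DMN -> 57.6%
  set1 <- c(0:18, 100:113)
  e1 <- dmn_enrichment(set1, atlas)
  expect_equal(e1$observed_pct, 100 * 19 / 33, tolerance = 1e-12)
  expect_equal(round(e1$observed_pct, 1), 57.6)
  expect_lt(e1$p_value, 0.05)
  # 26 of 41 -> 63.4%
  set2 <- c(0:25, 100:114)
  e2 <- dmn_enrichment(set2, atlas)
  expect_equal(round(e2$observed_pct, 1), 63.4)
  # exactly the expected proportion: statistic 0
  prop_set <- c(0:99, 100:387) # all regions: 100/388 exactly
  expect_equal(dmn_enrichment(prop_set, atlas)$statistic, 0)
  # brute-force statistic
  n <- length(set1); p0 <- 100 / 388
  obs <- c(19, n - 19); expd <- c(n * p0, n * (1 - p0))
  expect_equal(e1$statistic, sum((obs - expd)^2 / expd), tolerance = 1e-12)
})

test_that("DMN enrichment null rejects near the nominal 5% rate", {
  atlas <- tibble::tibble(region_id = 0:387, name = "x",
                          is_dmn = as.integer(0:387 < 100))
  set.seed(24)
  p <- replicate(1000, {
    dmn_enrichment(sample(0:387, 50), atlas)$p_value
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("edge-count ANCOVA matches brute-force residual-sum-of-squares F", {
  set.seed(25)
  n <- 12
  group <- rep(c("a", "b"), each = 6)
  age <- runif(n, 20, 70)
  edges <- 5000 + 30 * age + 400 * (group == "b") + rnorm(n, sd = 50)
  res <- edges_ancova(edges, group, age)

  rss <- function(x) sum(residuals(x)^2)
  f0 <- lm(edges ~ age); f1 <- lm(edges ~ age + factor(group))
  f2 <- lm(edges ~ age * factor(group))
  f_group <- (rss(f0) - rss(f1)) / (rss(f1) / f1$df.residual)
  f_int <- (rss(f1) - rss(f2)) / (rss(f2) / f2$df.residual)
  expect_equal(res$F[res$term == "group"], f_group, tolerance = 1e-10)
  expect_equal(res$F[res$term == "group:age"], f_int, tolerance = 1e-10)
  expect_equal(res$df, c(1, 1))

  # strong group separation: overwhelming significance
  edges2 <- 5000 + 500 * (group == "b") + rnorm(n, sd = 1e-4)
  expect_lt(edges_ancova(edges2, group, age)$p_value[1], 1e-10)

  # identical groups (mirrored design): group F near zero
  age3 <- rep(runif(6, 20, 70), 2)
  edges3 <- 100 + 2 * age3
  res3 <- edges_ancova(edges3 + rep(rnorm(6, sd = 1), 2),
                       rep(c("a", "b"), each = 6), age3)
  expect_lt(res3$F[1], 1e-10)
  expect_error(edges_ancova(1:10, rep("a", 10), runif(10)), "two groups")
})

test_that("distribution chi-square holds its nominal type-I error", {
  set.seed(26)
  breaks <- seq(0, 1, by = 0.1)
  ref <- c(2, 3, 6, 9, 12, 10, 7, 5, 4, 2)
  ref <- ref / sum(ref)
  n_regions <- 388
  rejections <- replicate(1000, {
    counts <- as.vector(rmultinom(1, n_regions, ref))
    scores <- rep(utils::head(breaks, -1) + 0.05, counts)
    distribution_chisq(scores, ref, breaks)$p_value < 0.05
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.02)
})
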