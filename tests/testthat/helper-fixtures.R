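# Shared fixtures, all generated in code.

make_series <- function(data, tr = 3, id = "S1", ses = "ses01") {
  session_series(as.matrix(data), tr_seconds = tr, subject_id = id,
                 session_id = ses)
}

# small cohort config for fast end-to-end tests
small_config <- function(...) {
  cohort_config(
    n_controls = 30, n_patients = 3, n_regions = 40, n_dmn = 10,
    n_sessions = 2, n_volumes = 60, n_communities = 4, n_hubs = 3,
    seed = 11, ...
  )
}

# Erdos-Renyi adjacency matrix, guaranteed at least one edge
random_graph <- function(n, p = 0.2) {
  a <- matrix(0L, n, n)
  up <- upper.tri(a)
  a[up] <- rbinom(sum(up), 1, p)
  a <- a + t(a)
  if (sum(a) == 0) a[1, 2] <- a[2, 1] <- 1L
  a
}

# brute-force alpha-centrality series via explicit matrix powers
brute_series <- function(a, alpha, order_n) {
  acc <- matrix(0, nrow(a), ncol(a))
  pw <- diag(nrow(a))
  for (k in 0:order_n) {
    pw <- pw %*% a
    acc <- acc + alpha^k * pw
  }
  acc
}

is_connected_graph <- function(a) {
  n <- nrow(a)
  reach <- (diag(n) + a) > 0
  for (k in seq_len(ceiling(log2(n)) + 1)) reach <- (reach %*% reach) > 0
  all(reach[1, ])
}

expect_tbl_row <- function(x) {
  expect_s3_class(x, "tbl_df")
  expect_identical(nrow(x), 1L)
}
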