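#' Dominant eigenvalue of an adjacency matrix
#'
#' Largest eigenvalue lambda of the binary symmetric adjacency matrix,
#' computed by symmetric eigendecomposition. For a graph with at least one
#' edge lambda > 0; an empty graph returns 0 (eigenvector-like centrality
#' is then undefined).
#'
#' @param a An [binarize()] result or a binary symmetric matrix.
#' @return The largest eigenvalue, a non-negative scalar.
#' @export
#' @examples
#' k4 <- matrix(1, 4, 4); diag(k4) <- 0
#' dominant_eigenvalue(k4) # 3: complete graph, lambda = degree
dominant_eigenvalue <- function(a) {
  a <- adjacency_matrix(a)
  if (sum(a) == 0) return(0)
  max(eigen(a, symmetric = TRUE, only.values = TRUE)$values)
}

adjacency_matrix <- function(a) {
  if (inherits(a, "adjacency")) a <- a$a
  a <- as.matrix(a)
  if (nrow(a) != ncol(a)) abort("adjacency matrix must be square")
  a
}

#' Partial sum of the alpha-centrality matrix series
#'
#' The matrix power series `C = A + alpha A^2 + alpha^2 A^3 + ... +
#' alpha^n A^(n+1)` (n + 1 terms), evaluated by iterated multiplication.
#' At `alpha = 0` this is exactly `A`; at `alpha = 1/lambda` the terms stop
#' decaying but the normalized quantity [nac_scores()] still converges.
#'
#' @param a Adjacency matrix (or [binarize()] result).
#' @param alpha Attenuation coefficient, `0 <= alpha <= 1/lambda`.
#' @param order_n Series order n, default 20.
#' @return The region x region matrix `C`; symmetric for symmetric input.
#' @export
alpha_centrality_series <- function(a, alpha, order_n = 20) {
  a <- adjacency_matrix(a)
  stopifnot(order_n >= 1, alpha >= 0)
  lambda <- dominant_eigenvalue(a)
  if (lambda > 0 && alpha > 1 / lambda + 1e-12) {
    abort(sprintf("alpha = %g exceeds 1/lambda = %g; series not normalizable",
                  alpha, 1 / lambda))
  }
  acc <- a
  p <- a
  for (k in seq_len(order_n)) {
    p <- alpha * (p %*% a)
    acc <- acc + p
  }
  acc
}

#' Normalized alpha-centrality region scores
#'
#' The series matrix `C` is normalized by the sum of all its elements; the
#' per-region score is the row sum of the normalized matrix, so the scores
#' sum to 1. At `alpha = 0` the score is exactly `degree / sum(degree)`
#' (degree centrality); at `alpha = 1/lambda` it converges to the dominant
#' eigenvector direction (eigenvector centrality).
#'
#' Row sums of the series are accumulated by the vector recursion
#' `u_0 = A 1`, `u_k = alpha A u_(k-1)` — algebraically identical to row
#' sums of [alpha_centrality_series()] but O(n^2) per term.
#'
#' @inheritParams alpha_centrality_series
#' @return Numeric vector of per-region scores summing to 1.
#' @export
#' @examples
#' star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
#' nac_scores(star, 0) # degree-proportional: 0.5, 1/6, 1/6, 1/6
nac_scores <- function(a, alpha, order_n = 20) {
  a <- adjacency_matrix(a)
  stopifnot(order_n >= 1, alpha >= 0)
  if (sum(a) == 0) abort("empty graph: centrality undefined")
  lambda <- dominant_eigenvalue(a)
  if (alpha > 1 / lambda + 1e-12) {
    abort(sprintf("alpha = %g exceeds 1/lambda = %g; series not normalizable",
                  alpha, 1 / lambda))
  }
  u <- rowSums(a)
  s <- u
  for (k in seq_len(order_n)) {
    u <- alpha * as.vector(a %*% u)
    s <- s + u
  }
  s / sum(s)
}

#' Per-subject centrality profile
#'
#' Computes both normalized alpha-centrality variants for one subject's
#' graph: `nac0` at `alpha = 0` (degree-like) and `nac1` at
#' `alpha = 1/lambda` (eigenvector-like), on the canonical sum-to-1 scale,
#' plus max-rescaled copies (score / max score, maximum exactly 1) used for
#' distribution histograms. An edgeless graph yields `NA` scores and an
#' empty-graph flag; a graph whose adjacency is disconnected is flagged but
#' analysed whole (lambda from the full spectrum).
#'
#' @param a Adjacency matrix (or [binarize()] result).
#' @param order_n Series order, default 20.
#' @param subject_id Identifier stored in the output.
#' @return A `centrality_profile` tibble with columns `subject_id`,
#'   `region_id` (0-based), `nac0`, `nac1`, `nac0_rescaled`,
#'   `nac1_rescaled`; attributes `lambda_max`, `order_n`, `scale`
#'   (`"canonical"`), `n_edges`, `connected`.
#' @export
compute_profile <- function(a, order_n = 20, subject_id = NA_character_) {
  a <- adjacency_matrix(a)
  n <- nrow(a)
  n_edges <- sum(a) / 2
  lambda <- dominant_eigenvalue(a)
  if (n_edges == 0) {
    prof <- tibble(
      subject_id = subject_id, region_id = seq_len(n) - 1L,
      nac0 = NA_real_, nac1 = NA_real_,
      nac0_rescaled = NA_real_, nac1_rescaled = NA_real_
    )
    return(new_centrality_profile(prof, lambda, order_n, n_edges,
                                  connected = FALSE))
  }
  nac0 <- nac_scores(a, 0, order_n)
  nac1 <- nac_scores(a, 1 / lambda, order_n)
  prof <- tibble(
    subject_id = subject_id, region_id = seq_len(n) - 1L,
    nac0 = nac0, nac1 = nac1,
    nac0_rescaled = nac0 / max(nac0), nac1_rescaled = nac1 / max(nac1)
  )
  new_centrality_profile(prof, lambda, order_n, n_edges,
                         connected = is_connected(a))
}

new_centrality_profile <- function(prof, lambda, order_n, n_edges, connected) {
  structure(prof, lambda_max = lambda, order_n = order_n, n_edges = n_edges,
            connected = connected, scale = "canonical",
            class = c("centrality_profile", class(prof)))
}

# Connectivity of the graph by breadth-first reach from node 1,
# ignoring isolated nodes is NOT done: isolated nodes count as disconnection.
is_connected <- function(a) {
  n <- nrow(a)
  reached <- logical(n)
  reached[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nbrs <- which(rowSums(a[, frontier, drop = FALSE]) > 0)
    frontier <- nbrs[!reached[nbrs]]
    reached[frontier] <- TRUE
  }
  all(reached)
}
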