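# Compositional transforms and MCMC convergence diagnostics.

#' Isometric log-ratio basis
#'
#' Orthonormal K x (K-1) basis of the hyperplane orthogonal to 1, so that
#' `z = t(V) %*% log(p)` maps the K-part simplex to unconstrained
#' coordinates and `p = softmax(V %*% z)` maps back.
#'
#' @param K Number of parts (>= 2).
#' @return K x (K-1) matrix with orthonormal columns.
#' @export
ilr_basis <- function(K) {
  stopifnot(K >= 2)
  V <- matrix(0, K, K - 1)
  for (j in seq_len(K - 1)) {
    V[seq_len(j), j] <- 1 / j
    V[j + 1, j] <- -1
    V[, j] <- V[, j] * sqrt(j / (j + 1))
  }
  V
}

#' Map ILR coordinates to the simplex
#' @param z Numeric vector of length K-1.
#' @param V Basis from [ilr_basis] (recomputed when `NULL`).
#' @return Proportion vector of length K summing to 1.
#' @export
ilr_inverse <- function(z, V = NULL) {
  K <- length(z) + 1
  if (is.null(V)) V <- ilr_basis(K)
  clr <- as.vector(V %*% z)
  e <- exp(clr - max(clr))
  e / sum(e)
}

#' Map a simplex vector to ILR coordinates
#' @param p Proportion vector (all > 0).
#' @param V Basis from [ilr_basis] (recomputed when `NULL`).
#' @return Numeric vector of length K-1.
#' @export
ilr_transform <- function(p, V = NULL) {
  if (is.null(V)) V <- ilr_basis(length(p))
  as.vector(crossprod(V, log(p)))
}

#' Split-Rhat potential scale reduction
#'
#' Each chain is split in half; Rhat compares between- and within-sequence
#' variance across the resulting 2M sequences. Values near 1 indicate the
#' chains are sampling the same distribution.
#'
#' @param chains Numeric matrix, iterations x chains.
#' @return Scalar Rhat (1 when the parameter is constant).
#' @export
split_rhat <- function(chains) {
  chains <- as.matrix(chains)
  n <- nrow(chains)
  half <- floor(n / 2)
  seqs <- do.call(cbind, lapply(seq_len(ncol(chains)), function(j)
    cbind(chains[seq_len(half), j], chains[half + seq_len(half), j])))
  m <- ncol(seqs); len <- nrow(seqs)
  mu <- colMeans(seqs)
  W <- mean(apply(seqs, 2, stats::var))
  if (!is.finite(W) || W == 0) return(1)
  B <- len * stats::var(mu)
  varplus <- (len - 1) / len * W + B / len
  sqrt(varplus / W)
}

#' Effective sample size
#'
#' Autocorrelation-based ESS pooled across chains, truncated at the first
#' lag where the paired autocorrelation sum turns negative (Geyer initial
#' positive sequence).
#'
#' @param chains Numeric matrix, iterations x chains.
#' @return Scalar effective sample size.
#' @export
effective_sample_size <- function(chains) {
  chains <- as.matrix(chains)
  n <- nrow(chains); m <- ncol(chains)
  if (all(apply(chains, 2, stats::var) == 0)) return(m * n)
  max_lag <- min(n - 1, 500)
  acfs <- vapply(seq_len(m), function(j)
    as.vector(stats::acf(chains[, j], lag.max = max_lag,
                         plot = FALSE, demean = TRUE)$acf),
    numeric(max_lag + 1))
  rho <- rowMeans(acfs)
  s <- 0
  t <- 1
  while (t + 1 <= max_lag) {
    pair <- rho[t + 1] + rho[t + 2]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  max(m * n / (1 + 2 * s), 1)
}
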