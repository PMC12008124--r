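#' Diffusion map embedding
#'
#' Nonlinear dimension reduction by the spectral decomposition of a
#' Markov transition matrix built on a Gaussian kernel over pairwise
#' Euclidean distances.  With `alpha = 1` the kernel is density
#' normalised before the Markov normalisation, which removes the
#' influence of sampling density and approximates the Laplace-Beltrami
#' operator on the data manifold.  Coordinates are the top non-trivial
#' right eigenvectors of the transition matrix, each scaled by its
#' eigenvalue (diffusion time 1); the trivial constant eigenvector
#' (eigenvalue 1) is dropped.
#'
#' The kernel bandwidth defaults to the Berry-Harlim-Giannakis
#' autotuning rule: over a logarithmic grid of candidate bandwidths,
#' pick the one maximising the slope of `log` kernel sum versus `log`
#' bandwidth.
#'
#' @param x numeric matrix (entities x features).
#' @param n_evec number of non-trivial coordinates to keep (must be
#'   `< nrow(x)`).
#' @param alpha density-normalisation exponent in `[0, 1]` (default 1).
#' @param epsilon `"bgh"` for autotuning or a positive number (the
#'   kernel is `exp(-d^2 / epsilon)`).
#' @return coordinate matrix (entities x `n_evec`, rownames preserved)
#'   with attributes `eigenvalues` (descending) and `epsilon`.
#' @export
diffusion_map <- function(x, n_evec, alpha = 1, epsilon = "bgh") {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n_evec >= n) stop("n_evec must be smaller than the number of entities")
  stopifnot(alpha >= 0, alpha <= 1)
  D2 <- as.matrix(stats::dist(x))^2
  eps <- if (identical(epsilon, "bgh")) bgh_epsilon(D2) else as.numeric(epsilon)
  K <- exp(-D2 / eps)
  if (any(rowSums(K) - 1 < 1e-12)) {
    warning("kernel graph is (nearly) disconnected at the chosen bandwidth")
  }
  q <- rowSums(K)
  Ka <- K / (outer(q^alpha, q^alpha))      # density normalisation
  d <- rowSums(Ka)
  # symmetric conjugate of the Markov matrix P = D^-1 Ka
  S <- Ka / outer(sqrt(d), sqrt(d))
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  # right eigenvectors of P = D^{-1/2} (eigenvectors of S); the leading
  # one is constant with eigenvalue 1
  psi <- eig$vectors / sqrt(d)
  lam <- eig$values
  keep <- seq_len(n_evec) + 1L             # drop trivial eigenpair
  coords <- sweep(psi[, keep, drop = FALSE], 2, lam[keep], "*")
  rownames(coords) <- rownames(x)
  attr(coords, "eigenvalues") <- lam[keep]
  attr(coords, "epsilon") <- eps
  coords
}

# Berry-Harlim-Giannakis bandwidth autotuning on squared distances:
# maximise the log-log slope of the kernel sum over a bandwidth grid.
# The chosen bandwidth is floored at the value that keeps the kernel
# graph connected at the nearest-neighbour scale (a Markov chain over
# isolated points carries no geometry), which matters for strongly
# clustered data where the slope criterion favours the smallest scale.
bgh_epsilon <- function(D2) {
  off <- D2[upper.tri(D2)]
  off <- off[off > 0]
  if (!length(off)) return(1)
  grid <- 2^seq(log2(min(off)) - 4, log2(max(off)) + 4, by = 0.25)
  logT <- vapply(grid, function(e) log(mean(exp(-D2 / e))), numeric(1))
  slope <- diff(logT) / diff(log(grid))
  i <- which.max(slope)
  eps <- sqrt(grid[i] * grid[i + 1])
  D2nn <- D2
  diag(D2nn) <- Inf
  eps_connect <- max(apply(D2nn, 1, min)) / 3
  max(eps, eps_connect)
}
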