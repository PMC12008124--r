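#' Sequence similarity in diffusion space
#'
#' Pairwise Euclidean distances between entity feature rows are turned
#' into similarities with a Gaussian kernel,
#' `s_ij = exp(-d_ij^2 / (2 sigma^2))`, with `sigma` the median
#' off-diagonal distance.  A raw distance cannot be averaged with the
#' GIP kernel (where larger means more similar) nor feed the
#' degree-normalised graph propagation, so the kernel conversion keeps
#' the range `(0, 1]` commensurate with GIP.  An alternative conversion
#' (`one_minus_minmax`: `1 - d/max(d)`) is available for comparison.
#'
#' @param features entity x feature matrix (rownames = ids).
#' @param conversion `"gaussian"` (default) or `"one_minus_minmax"`.
#' @return symmetric similarity matrix with unit diagonal; attribute
#'   `"conversion"` records the rule used.
#' @export
sequence_similarity <- function(features,
                                conversion = c("gaussian", "one_minus_minmax")) {
  conversion <- match.arg(conversion)
  stopifnot(nrow(features) >= 2L)
  D <- as.matrix(stats::dist(features))
  off <- D[upper.tri(D)]
  if (conversion == "gaussian") {
    sigma <- stats::median(off)
    if (sigma <= 0) {
      warning("all entities identical in feature space: similarity is all ones")
      S <- matrix(1, nrow(D), ncol(D), dimnames = dimnames(D))
    } else {
      S <- exp(-D^2 / (2 * sigma^2))
    }
  } else {
    mx <- max(off)
    S <- if (mx <= 0) matrix(1, nrow(D), ncol(D), dimnames = dimnames(D))
         else 1 - D / mx
  }
  diag(S) <- 1
  S <- (S + t(S)) / 2
  attr(S, "conversion") <- conversion
  S
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' For the ncRNA axis, `S(i, j) = exp(-lambda * ||A[i, ] - A[j, ]||^2)`
#' with bandwidth `lambda = 1 / mean_k ||A[k, ]||^2` taken over all
#' ncRNA rows; the drug axis is the same computation on columns.
#' Entities with similar interaction profiles in the (training)
#' adjacency get similarity near 1.
#'
#' @param A binary adjacency matrix (ncRNAs x drugs).
#' @param axis `"ncrna"` (rows) or `"drug"` (columns).
#' @return symmetric similarity matrix, entries in `(0, 1]`, unit
#'   diagonal; attribute `"lambda"` carries the bandwidth.
#' @export
gip_kernel <- function(A, axis = c("ncrna", "drug")) {
  axis <- match.arg(axis)
  stopifnot(all(A %in% c(0, 1)))
  P <- if (axis == "ncrna") A else t(A)    # profiles as rows
  norms <- rowSums(P^2)
  if (sum(norms) == 0) {
    stop("all-zero adjacency: GIP bandwidth lambda is undefined")
  }
  lambda <- 1 / mean(norms)
  G <- tcrossprod(P)
  D2 <- outer(norms, norms, "+") - 2 * G   # squared profile distances
  D2[D2 < 0] <- 0
  S <- exp(-lambda * D2)
  diag(S) <- 1
  dimnames(S) <- list(rownames(P), rownames(P))
  attr(S, "lambda") <- lambda
  S
}

#' Fuse sequence and GIP similarity
#'
#' Elementwise average of the two similarity matrices.
#'
#' @param seq,gip same-shape similarity matrices over the same entity
#'   ordering.
#' @return fused similarity matrix `(seq + gip) / 2`.
#' @export
fuse_similarity <- function(seq, gip) {
  if (!all(dim(seq) == dim(gip))) stop("similarity shape mismatch")
  if (!is.null(rownames(seq)) && !is.null(rownames(gip)) &&
      !identical(rownames(seq), rownames(gip))) {
    stop("similarity entity orderings differ")
  }
  S <- (unclass(seq) + unclass(gip)) / 2
  attr(S, "conversion") <- NULL
  attr(S, "lambda") <- NULL
  S
}
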