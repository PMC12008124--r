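#' Symmetric degree-normalised propagation matrix
#'
#' `D^{-1/2} S D^{-1/2}` with `D` the degree matrix (row sums) of the
#' fused similarity `S`; this is the fixed propagation operator of the
#' graph convolution.
#'
#' @param S square similarity matrix.
#' @return normalised propagation matrix.
#' @export
gcn_propagation <- function(S) {
  d <- rowSums(S)
  if (any(d <= 0)) {
    stop("zero-degree node in similarity graph: add self-loops ",
         "(unit diagonal) before propagation")
  }
  S / outer(sqrt(d), sqrt(d))
}

# Glorot-uniform matrix init.
glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

#' Initialise GCN weights
#'
#' @param d_in input feature width.
#' @param hidden hidden width of every layer.
#' @param n_layers number of layers (default 2).
#' @param seed integer seed.
#' @return list of weight matrices.
#' @export
gcn_init <- function(d_in, hidden, n_layers = 2L, seed = 1L) {
  set.seed(seed)
  dims <- c(d_in, rep(hidden, n_layers))
  lapply(seq_len(n_layers), function(l) glorot(dims[l], dims[l + 1]))
}

#' Graph convolution forward pass
#'
#' `H^{l+1} = ReLU(D^{-1/2} S D^{-1/2} H^l W^l)`, applied once per
#' layer.  ncRNAs and drugs each get their own independent stack over
#' their own fused similarity graph.
#'
#' @param S fused similarity matrix (or a precomputed propagation
#'   matrix via `propagated = TRUE`).
#' @param H0 input features (rows match `S`).
#' @param weights list of per-layer weight matrices ([gcn_init()]).
#' @param propagated set to `TRUE` when `S` is already the normalised
#'   propagation matrix.
#' @return output feature matrix after the last layer.
#' @export
gcn_forward <- function(S, H0, weights, propagated = FALSE) {
  P <- if (propagated) S else gcn_propagation(S)
  gcn_fwd(P, H0, weights)$out
}

# forward with caches kept for backprop
gcn_fwd <- function(P, X, Ws) {
  Hs <- vector("list", length(Ws) + 1L); Hs[[1]] <- X
  pres <- vector("list", length(Ws))
  H <- X
  for (l in seq_along(Ws)) {
    pre <- P %*% H %*% Ws[[l]]
    H <- pmax(pre, 0)
    pres[[l]] <- pre; Hs[[l + 1L]] <- H
  }
  list(out = H, Hs = Hs, pres = pres)
}

gcn_bwd <- function(P, Ws, cache, dOut) {
  dWs <- vector("list", length(Ws))
  dH <- dOut
  for (l in rev(seq_along(Ws))) {
    dPre <- dH * (cache$pres[[l]] > 0)
    PH <- P %*% cache$Hs[[l]]
    dWs[[l]] <- crossprod(PH, dPre)
    dH <- crossprod(P, dPre %*% t(Ws[[l]]))
  }
  list(dWs = dWs, dX = dH)
}

#' Build the heterogeneous bipartite graph mask
#'
#' Nodes are the ncRNAs (first) and the drugs; undirected edges are the
#' training-fold resistance pairs, plus self-loops by default so every
#' node has a defined neighbourhood in the attention aggregation.
#' Optional within-class blocks (used by the "no GCN" ablation) are
#' passed as `extra`.
#'
#' @param m,n counts of ncRNAs and drugs.
#' @param edges two-column matrix/data.frame of (ncRNA index, drug
#'   index) training positives.
#' @param self_loops add diagonal self-edges (default `TRUE`).
#' @param extra optional (m + n) square 0/1 matrix OR-ed into the mask.
#' @return (m + n) x (m + n) 0/1 neighbourhood mask.
#' @export
build_hetero_graph <- function(m, n, edges, self_loops = TRUE, extra = NULL) {
  N <- m + n
  M <- matrix(0, N, N)
  edges <- as.matrix(edges)
  if (nrow(edges)) {
    if (any(edges[, 1] < 1 | edges[, 1] > m | edges[, 2] < 1 | edges[, 2] > n)) {
      stop("edge references unknown node index")
    }
    M[cbind(edges[, 1], m + edges[, 2])] <- 1
    M[cbind(m + edges[, 2], edges[, 1])] <- 1
  }
  if (!is.null(extra)) M <- pmax(M, (extra > 0) + 0)
  if (self_loops) diag(M) <- 1
  M
}

#' Initialise GAT weights
#'
#' @param d_in input width of the first layer.
#' @param hidden width of every attention layer.
#' @param n_layers number of layers (default 4).
#' @param seed integer seed.
#' @return list of per-layer parameter lists `W` (weight matrix) and
#'   `a` (attention vector of length `2 * hidden`).
#' @export
gat_init <- function(d_in, hidden, n_layers = 4L, seed = 1L) {
  set.seed(seed)
  dims <- c(d_in, rep(hidden, n_layers))
  lapply(seq_len(n_layers), function(l) {
    list(W = glorot(dims[l], dims[l + 1]),
         a = stats::runif(2 * dims[l + 1], -sqrt(6 / (2 * dims[l + 1])),
                          sqrt(6 / (2 * dims[l + 1]))))
  })
}

#' Attention coefficients of one GAT layer
#'
#' `alpha_ij = softmax_{j in N_i} LeakyReLU(a^T [W h_i || W h_j])`.
#' Rows of nodes with at least one neighbour sum to 1; rows of isolated
#' nodes are all zero (their layer output is the zero vector).
#'
#' @param H node features.
#' @param W layer weight matrix.
#' @param a attention vector (length `2 * ncol(W)`).
#' @param mask 0/1 neighbourhood mask ([build_hetero_graph()]).
#' @param slope LeakyReLU negative slope (default 0.2).
#' @return attention coefficient matrix (rows = aggregating node).
#' @export
gat_attention <- function(H, W, a, mask, slope = 0.2) {
  gat_layer_fwd(H, W, a, mask, slope)$att
}

gat_layer_fwd <- function(H, W, a, mask, slope) {
  h <- ncol(W)
  Z <- H %*% W
  f <- as.vector(Z %*% a[seq_len(h)])
  g <- as.vector(Z %*% a[h + seq_len(h)])
  Sraw <- outer(f, rep(1, length(g))) + outer(rep(1, length(f)), g)
  E <- ifelse(Sraw > 0, Sraw, slope * Sraw)
  En <- ifelse(mask > 0, E, -Inf)
  rowmax <- apply(En, 1, max)
  has_nb <- is.finite(rowmax)
  expE <- matrix(0, nrow(En), ncol(En))
  if (any(has_nb)) {
    expE[has_nb, ] <- exp(En[has_nb, , drop = FALSE] - rowmax[has_nb])
  }
  denom <- rowSums(expE)
  att <- expE / ifelse(denom > 0, denom, 1)
  pre <- att %*% Z
  out <- pmax(pre, 0)
  list(out = out, att = att, Z = Z, Sraw = Sraw, pre = pre)
}

gat_layer_bwd <- function(H, W, a, slope, cache, dOut) {
  h <- ncol(W)
  Z <- cache$Z; att <- cache$att
  dPre <- dOut * (cache$pre > 0)
  dAtt <- dPre %*% t(Z)
  dZ <- crossprod(att, dPre)
  rs <- rowSums(att * dAtt)
  dE <- att * (dAtt - rs)                       # softmax jacobian, rowwise
  dSraw <- dE * ifelse(cache$Sraw > 0, 1, slope)
  df <- rowSums(dSraw)
  dg <- colSums(dSraw)
  a1 <- a[seq_len(h)]; a2 <- a[h + seq_len(h)]
  dZ <- dZ + outer(df, a1) + outer(dg, a2)
  da <- c(as.vector(crossprod(Z, df)), as.vector(crossprod(Z, dg)))
  dW <- crossprod(H, dZ)
  dH <- dZ %*% t(W)
  list(dW = dW, da = da, dH = dH)
}

#' Graph attention network forward pass
#'
#' Stacks [gat_attention()]-weighted aggregation layers
#' (`H_i^{l+1} = ReLU(sum_j alpha_ij W H_j^l)`) over the heterogeneous
#' graph; feature rows must be ordered ncRNAs first, then drugs.
#'
#' @param mask neighbourhood mask from [build_hetero_graph()].
#' @param H stacked ncRNA + drug feature matrix.
#' @param weights list from [gat_init()].
#' @param slope LeakyReLU negative slope.
#' @return output feature matrix after the last layer.
#' @export
gat_forward <- function(mask, H, weights, slope = 0.2) {
  for (l in seq_along(weights)) {
    H <- gat_layer_fwd(H, weights[[l]]$W, weights[[l]]$a, mask, slope)$out
  }
  H
}

#' Inner-product association scores
#'
#' `logistic(H_r H_d^T)`: every ncRNA-drug pair scored by the sigmoid
#' of the dot product of its two feature rows.
#'
#' @param H_r ncRNA feature matrix.
#' @param H_d drug feature matrix.
#' @return m x n score matrix with entries in (0, 1).
#' @export
score_matrix <- function(H_r, H_d) {
  if (ncol(H_r) != ncol(H_d)) stop("feature width mismatch")
  stats::plogis(tcrossprod(H_r, H_d))
}

# ---- end-to-end training ---------------------------------------------------

# Full forward pass; returns caches for backprop.
gnn_fwd <- function(params, Pr, Pd, Xr, Xd, mask, slope, variant) {
  m <- nrow(Xr)
  if (variant == "no_gat") {
    cr <- gcn_fwd(Pr, Xr, params$gcn_r)
    cd <- gcn_fwd(Pd, Xd, params$gcn_d)
    return(list(Hr = cr$out, Hd = cd$out, cr = cr, cd = cd))
  }
  if (variant == "no_gcn") {
    H0 <- rbind(Xr, Xd)
    caches <- vector("list", length(params$gat))
    H <- H0
    for (l in seq_along(params$gat)) {
      caches[[l]] <- gat_layer_fwd(H, params$gat[[l]]$W, params$gat[[l]]$a,
                                   mask, slope)
      H <- caches[[l]]$out
    }
    return(list(Hr = H[seq_len(m), , drop = FALSE],
                Hd = H[-seq_len(m), , drop = FALSE],
                gat_caches = caches, gat_inputs = H0))
  }
  cr <- gcn_fwd(Pr, Xr, params$gcn_r)
  cd <- gcn_fwd(Pd, Xd, params$gcn_d)
  H0 <- rbind(cr$out, cd$out)
  caches <- vector("list", length(params$gat))
  H <- H0
  for (l in seq_along(params$gat)) {
    caches[[l]] <- gat_layer_fwd(H, params$gat[[l]]$W, params$gat[[l]]$a,
                                 mask, slope)
    H <- caches[[l]]$out
  }
  list(Hr = H[seq_len(m), , drop = FALSE], Hd = H[-seq_len(m), , drop = FALSE],
       cr = cr, cd = cd, gat_caches = caches, gat_inputs = H0)
}

# BCE loss over selected pairs + gradient wrt Hr, Hd.
pair_bce <- function(Hr, Hd, ridx, didx, y) {
  logits <- rowSums(Hr[ridx, , drop = FALSE] * Hd[didx, , drop = FALSE])
  p <- stats::plogis(logits)
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  dlogit <- (p - y) / length(y)
  dHr <- matrix(0, nrow(Hr), ncol(Hr))
  dHd <- matrix(0, nrow(Hd), ncol(Hd))
  contrib_r <- dlogit * Hd[didx, , drop = FALSE]
  contrib_d <- dlogit * Hr[ridx, , drop = FALSE]
  rs <- rowsum(contrib_r, ridx)
  dHr[as.integer(rownames(rs)), ] <- rs
  ds <- rowsum(contrib_d, didx)
  dHd[as.integer(rownames(ds)), ] <- ds
  list(loss = loss, dHr = dHr, dHd = dHd)
}

# Full backward pass mirroring gnn_fwd.
gnn_bwd <- function(params, Pr, Pd, Xr, Xd, mask, slope, variant,
                    fwd, dHr, dHd) {
  grads <- list()
  m <- nrow(Xr)
  if (variant == "no_gat") {
    grads$gcn_r <- gcn_bwd(Pr, params$gcn_r, fwd$cr, dHr)$dWs
    grads$gcn_d <- gcn_bwd(Pd, params$gcn_d, fwd$cd, dHd)$dWs
    return(grads)
  }
  dH <- rbind(dHr, dHd)
  gat_grads <- vector("list", length(params$gat))
  for (l in rev(seq_along(params$gat))) {
    Hin <- if (l == 1L) fwd$gat_inputs else fwd$gat_caches[[l - 1L]]$out
    bw <- gat_layer_bwd(Hin, params$gat[[l]]$W, params$gat[[l]]$a, slope,
                        fwd$gat_caches[[l]], dH)
    gat_grads[[l]] <- list(W = bw$dW, a = bw$da)
    dH <- bw$dH
  }
  grads$gat <- gat_grads
  if (variant == "full") {
    grads$gcn_r <- gcn_bwd(Pr, params$gcn_r, fwd$cr,
                           dH[seq_len(m), , drop = FALSE])$dWs
    grads$gcn_d <- gcn_bwd(Pd, params$gcn_d, fwd$cd,
                           dH[-seq_len(m), , drop = FALSE])$dWs
  }
  grads
}

# Adam over an arbitrary nested list of numeric arrays.
adam_state <- function(params) {
  zeros <- rapply(params, function(x) x * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mh <- m / (1 - b1^state$t); vh <- v / (1 - b2^state$t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

#' Train the GCN + GAT association model on one fold
#'
#' End-to-end gradient training (full-batch Adam, binary cross-entropy)
#' of the per-class graph convolution stacks and the heterogeneous
#' attention stack.  The loss runs over the supplied training positives
#' and reliable negatives only; unlabeled pairs outside the negative
#' set never enter the loss.  Deterministic under `seed`.
#'
#' Ablation variants: `"no_gcn"` feeds the unified features straight
#' into the attention stack and adds within-class edges where the fused
#' similarity exceeds its row median; `"no_gat"` scores the GCN outputs
#' directly.
#'
#' @param Xr,Xd unified ncRNA / drug feature matrices.
#' @param Sr,Sd fused similarity matrices (training fold).
#' @param edges integer matrix of training-positive (ncRNA, drug) index
#'   pairs defining the bipartite graph.
#' @param train_pairs data frame with integer columns `ridx`, `didx`
#'   and 0/1 column `y` (positives and reliable negatives).
#' @param hidden hidden width of all layers.
#' @param gcn_layers,gat_layers stack depths.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param slope LeakyReLU negative slope.
#' @param seed integer seed for initialisation.
#' @param variant `"full"`, `"no_gcn"` or `"no_gat"`.
#' @return list with `scores` (m x n matrix), `params`, `loss_trace`,
#'   `Hr`, `Hd` (final features) and `mask`.
#' @export
train_gnn <- function(Xr, Xd, Sr, Sd, edges, train_pairs,
                      hidden = 64L, gcn_layers = 2L, gat_layers = 4L,
                      lr = 1e-3, epochs = 300L, slope = 0.2, seed = 1L,
                      variant = c("full", "no_gcn", "no_gat")) {
  variant <- match.arg(variant)
  m <- nrow(Xr); n <- nrow(Xd)
  Pr <- gcn_propagation(Sr); Pd <- gcn_propagation(Sd)

  extra <- NULL
  if (variant == "no_gcn") {
    thr_block <- function(S) {
      med <- apply(S, 1, stats::median)
      (S > med) + 0
    }
    extra <- matrix(0, m + n, m + n)
    extra[seq_len(m), seq_len(m)] <- thr_block(Sr)
    extra[m + seq_len(n), m + seq_len(n)] <- thr_block(Sd)
  }
  mask <- build_hetero_graph(m, n, edges, self_loops = TRUE, extra = extra)

  d_in <- ncol(Xr)
  params <- list()
  if (variant != "no_gcn") {
    params$gcn_r <- gcn_init(d_in, hidden, gcn_layers, seed = seed)
    params$gcn_d <- gcn_init(ncol(Xd), hidden, gcn_layers, seed = seed + 1L)
  }
  if (variant != "no_gat") {
    gat_in <- if (variant == "no_gcn") d_in else hidden
    params$gat <- gat_init(gat_in, hidden, gat_layers, seed = seed + 2L)
  }

  st <- adam_state(params)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    fwd <- gnn_fwd(params, Pr, Pd, Xr, Xd, mask, slope, variant)
    bce <- pair_bce(fwd$Hr, fwd$Hd, train_pairs$ridx, train_pairs$didx,
                    train_pairs$y)
    if (!is.finite(bce$loss)) {
      stop("training diverged (non-finite loss) at epoch ", ep,
           "; last finite loss: ",
           if (ep > 1) signif(trace[ep - 1], 6) else "none")
    }
    trace[ep] <- bce$loss
    grads <- gnn_bwd(params, Pr, Pd, Xr, Xd, mask, slope, variant,
                     fwd, bce$dHr, bce$dHd)
    grads <- grads[names(params)]
    upd <- adam_step(params, grads, st, lr)
    params <- upd$params; st <- upd$state
  }
  fwd <- gnn_fwd(params, Pr, Pd, Xr, Xd, mask, slope, variant)
  scores <- score_matrix(fwd$Hr, fwd$Hd)
  dimnames(scores) <- list(rownames(Xr), rownames(Xd))
  list(scores = scores, params = params, loss_trace = trace,
       Hr = fwd$Hr, Hd = fwd$Hd, mask = mask)
}
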