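# Independent per-node loop references for the two network layers.
gcn_loop <- function(S, H, Ws) {
  d <- rowSums(S)
  P <- matrix(0, nrow(S), ncol(S))
  for (i in seq_len(nrow(S))) for (j in seq_len(ncol(S))) {
    P[i, j] <- S[i, j] / sqrt(d[i] * d[j])
  }
  for (W in Ws) {
    Hn <- matrix(0, nrow(H), ncol(W))
    for (i in seq_len(nrow(H))) {
      acc <- numeric(ncol(H))
      for (j in seq_len(nrow(H))) acc <- acc + P[i, j] * H[j, ]
      Hn[i, ] <- pmax(acc %*% W, 0)
    }
    H <- Hn
  }
  H
}

gat_loop <- function(mask, H, weights, slope) {
  lrelu <- function(x) ifelse(x > 0, x, slope * x)
  for (lw in weights) {
    W <- lw$W; a <- lw$a; h <- ncol(W)
    Z <- H %*% W
    Hn <- matrix(0, nrow(H), h)
    for (i in seq_len(nrow(H))) {
      nb <- which(mask[i, ] > 0)
      if (!length(nb)) next
      e <- vapply(nb, function(j) lrelu(sum(a * c(Z[i, ], Z[j, ]))),
                  numeric(1))
      al <- exp(e - max(e)); al <- al / sum(al)
      acc <- numeric(h)
      for (t in seq_along(nb)) acc <- acc + al[t] * Z[nb[t], ]
      Hn[i, ] <- pmax(acc, 0)
    }
    H <- Hn
  }
  H
}

test_that("identity propagation reduces the GCN to repeated ReLU", {
  H0 <- matrix(c(-1, 2, 0.5, -3, 1, 4), 3, 2)
  Ws <- list(diag(2), diag(2))
  out <- gcn_forward(diag(3), H0, Ws)
  expect_equal(out, pmax(H0, 0))
})

test_that("gcn_forward matches the per-node loop oracle", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    S <- matrix(runif(n * n), n, n); S <- (S + t(S)) / 2; diag(S) <- 1
    H <- matrix(rnorm(n * 3), n, 3)
    Ws <- list(matrix(rnorm(3 * 4, sd = .5), 3, 4),
               matrix(rnorm(4 * 4, sd = .5), 4, 4))
    expect_lt(max(abs(gcn_forward(S, H, Ws) - gcn_loop(S, H, Ws))), 1e-8)
  }
})

test_that("zero-degree nodes are rejected with a self-loop hint", {
  S <- diag(3); S[2, 2] <- 0
  expect_error(gcn_forward(S, matrix(1, 3, 2), list(diag(2))), "self-loop")
})

test_that("attention coefficients are a masked softmax", {
  set.seed(22)
  H <- matrix(rnorm(8), 4, 2)
  W <- diag(2); a <- c(1, -1, 0.5, 2)
  # single neighbour -> alpha 1
  mask <- matrix(0, 4, 4); mask[1, 2] <- 1
  al <- gat_attention(H, W, a, mask)
  expect_equal(al[1, 2], 1)
  # two neighbours with identical features -> 0.5 each
  H2 <- H; H2[3, ] <- H2[2, ]
  mask2 <- matrix(0, 4, 4); mask2[1, 2] <- 1; mask2[1, 3] <- 1
  al2 <- gat_attention(H2, W, a, mask2)
  expect_equal(unname(al2[1, 2:3]), c(0.5, 0.5))
  # three neighbours match a hand-evaluated softmax
  mask3 <- matrix(0, 4, 4); mask3[1, 2:4] <- 1
  al3 <- gat_attention(H, W, a, mask3, slope = 0.2)
  lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
  e <- vapply(2:4, function(j) lrelu(sum(a * c(H[1, ], H[j, ]))), numeric(1))
  expect_equal(unname(al3[1, 2:4]), unname(exp(e) / sum(exp(e))),
               tolerance = 1e-12)
})

test_that("attention rows over neighbours sum to one at every layer", {
  set.seed(23)
  n <- 7
  mask <- matrix(rbinom(n * n, 1, 0.5), n, n); diag(mask) <- 1
  H <- matrix(rnorm(n * 3), n, 3)
  weights <- gat_init(3, 4, n_layers = 3, seed = 2)
  for (l in seq_along(weights)) {
    al <- gat_attention(H, weights[[l]]$W, weights[[l]]$a, mask)
    expect_equal(rowSums(al), rep(1, n), tolerance = 1e-6)
    H <- gat_forward(mask, H, weights[l])
  }
})

test_that("gat_forward matches the per-node loop oracle", {
  set.seed(24)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    mask <- matrix(rbinom(n * n, 1, 0.4), n, n); diag(mask) <- 1
    H <- matrix(rnorm(n * 3), n, 3)
    weights <- gat_init(3, 4, n_layers = 2, seed = rep)
    expect_lt(max(abs(gat_forward(mask, H, weights) -
                      gat_loop(mask, H, weights, 0.2))), 1e-8)
  }
})

test_that("isolated nodes produce zero vectors and empty graphs vanish", {
  H <- matrix(rnorm(6), 3, 2)
  weights <- gat_init(2, 2, n_layers = 1, seed = 1)
  out <- gat_forward(matrix(0, 3, 3), H, weights)
  expect_true(all(out == 0))
  mask <- matrix(0, 3, 3); mask[1, 2] <- 1
  out2 <- gat_forward(mask, H, weights)
  expect_true(all(out2[2, ] == 0) && all(out2[3, ] == 0))
})

test_that("the score head is the elementwise logistic inner product", {
  Hr <- matrix(c(1, 0, 0, 1, 2, -1), 3, 2, byrow = TRUE)
  Hd <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  S <- score_matrix(Hr, Hd)
  expect_equal(dim(S), c(3L, 2L))
  expect_equal(S[1, 1], plogis(0))         # orthogonal rows -> 0.5
  expect_equal(S[3, 1], plogis(-1))
  expect_equal(S[3, 2], plogis(2))
  expect_true(all(S > 0 & S < 1))
  expect_error(score_matrix(Hr, matrix(1, 2, 3)), "width mismatch")
})

test_that("hetero graph mask is bipartite, undirected, self-looped", {
  M <- build_hetero_graph(3, 2, edges = cbind(c(1, 3), c(2, 1)))
  expect_equal(dim(M), c(5L, 5L))
  expect_equal(M[1, 3 + 2], 1); expect_equal(M[3 + 2, 1], 1)
  expect_equal(diag(M), rep(1, 5))
  expect_true(all(M[1:3, 1:3] == diag(3)))  # no within-class edges
  expect_error(build_hetero_graph(3, 2, cbind(4, 1)), "unknown node")
})

test_that("analytic gradients match finite differences", {
  set.seed(25)
  m <- 4; n <- 3; h <- 3
  Xr <- matrix(rnorm(m * 2), m, 2); Xd <- matrix(rnorm(n * 2), n, 2)
  Sr <- matrix(runif(m * m), m, m); Sr <- (Sr + t(Sr)) / 2; diag(Sr) <- 1
  Sd <- matrix(runif(n * n), n, n); Sd <- (Sd + t(Sd)) / 2; diag(Sd) <- 1
  edges <- cbind(c(1, 2), c(1, 3))
  pairs <- data.frame(ridx = c(1, 2, 3, 4), didx = c(1, 3, 2, 2),
                      y = c(1, 1, 0, 0))
  Pr <- gcn_propagation(Sr); Pd <- gcn_propagation(Sd)
  mask <- build_hetero_graph(m, n, edges)
  params <- list(gcn_r = gcn_init(2, h, 1, seed = 1),
                 gcn_d = gcn_init(2, h, 1, seed = 2),
                 gat = gat_init(h, h, 2, seed = 3))
  loss_of <- function(p) {
    fwd <- dmgat:::gnn_fwd(p, Pr, Pd, Xr, Xd, mask, 0.2, "full")
    dmgat:::pair_bce(fwd$Hr, fwd$Hd, pairs$ridx, pairs$didx, pairs$y)$loss
  }
  fwd <- dmgat:::gnn_fwd(params, Pr, Pd, Xr, Xd, mask, 0.2, "full")
  bce <- dmgat:::pair_bce(fwd$Hr, fwd$Hd, pairs$ridx, pairs$didx, pairs$y)
  gr <- dmgat:::gnn_bwd(params, Pr, Pd, Xr, Xd, mask, 0.2, "full",
                        fwd, bce$dHr, bce$dHd)
  eps <- 1e-6
  check <- function(get, set, gval) {
    p2 <- set(eps); l1 <- loss_of(p2)
    p3 <- set(-eps); l0 <- loss_of(p3)
    expect_equal((l1 - l0) / (2 * eps), gval, tolerance = 1e-4)
  }
  for (probe in 1:8) {
    set.seed(100 + probe)
    part <- sample(c("gcn_r", "gat_W", "gat_a"), 1)
    if (part == "gcn_r") {
      i <- sample(length(params$gcn_r[[1]]), 1)
      check(NULL, function(d) {
        p <- params; p$gcn_r[[1]][i] <- p$gcn_r[[1]][i] + d; p
      }, gr$gcn_r[[1]][i])
    } else if (part == "gat_W") {
      l <- sample(2, 1); i <- sample(length(params$gat[[l]]$W), 1)
      check(NULL, function(d) {
        p <- params; p$gat[[l]]$W[i] <- p$gat[[l]]$W[i] + d; p
      }, gr$gat[[l]]$W[i])
    } else {
      l <- sample(2, 1); i <- sample(length(params$gat[[l]]$a), 1)
      check(NULL, function(d) {
        p <- params; p$gat[[l]]$a[i] <- p$gat[[l]]$a[i] + d; p
      }, gr$gat[[l]]$a[i])
    }
  }
})

test_that("training is deterministic, starts at log 2, and can overfit", {
  set.seed(26)
  m <- 10; n <- 6
  Xr <- matrix(rnorm(m * 4), m, 4, dimnames = list(paste0("r", 1:m), NULL))
  Xd <- matrix(rnorm(n * 4), n, 4, dimnames = list(paste0("d", 1:n), NULL))
  Sr <- matrix(runif(m * m, 0, .5), m, m); Sr <- (Sr + t(Sr)) / 2
  diag(Sr) <- 1
  Sd <- matrix(runif(n * n, 0, .5), n, n); Sd <- (Sd + t(Sd)) / 2
  diag(Sd) <- 1
  edges <- cbind(1:5, rep(1:3, length.out = 5))
  pairs <- data.frame(ridx = c(1:5, 6:10),
                      didx = c(rep(1:3, length.out = 5),
                               rep(4:6, length.out = 5)),
                      y = rep(c(1, 0), each = 5))
  fit1 <- train_gnn(Xr, Xd, Sr, Sd, edges, pairs, hidden = 8,
                    epochs = 400, seed = 3)
  fit2 <- train_gnn(Xr, Xd, Sr, Sd, edges, pairs, hidden = 8,
                    epochs = 400, seed = 3)
  expect_identical(fit1$loss_trace, fit2$loss_trace)
  # balanced classes at (near-zero-score) initialisation: BCE ~ log 2
  expect_equal(fit1$loss_trace[1], log(2), tolerance = 0.05)
  # the fold is trivially separable, so training discriminates it fully
  sc <- fit1$scores[cbind(pairs$ridx, pairs$didx)]
  expect_gt(auc_score(sc, pairs$y), 0.99)
})

test_that("relabeling nodes permutes the score matrix identically", {
  set.seed(27)
  m <- 6; n <- 4
  Xr <- matrix(rnorm(m * 3), m, 3); Xd <- matrix(rnorm(n * 3), n, 3)
  Sr <- matrix(runif(m * m), m, m); Sr <- (Sr + t(Sr)) / 2; diag(Sr) <- 1
  Sd <- matrix(runif(n * n), n, n); Sd <- (Sd + t(Sd)) / 2; diag(Sd) <- 1
  edges <- cbind(c(1, 2, 5), c(1, 2, 3))
  pairs <- data.frame(ridx = c(1, 2, 5, 3), didx = c(1, 2, 3, 4),
                      y = c(1, 1, 1, 0))
  fit <- train_gnn(Xr, Xd, Sr, Sd, edges, pairs, hidden = 5, epochs = 40,
                   seed = 4)
  pr <- sample(m); pd <- sample(n)
  inv_r <- order(pr); inv_d <- order(pd)
  fit_p <- train_gnn(Xr[pr, ], Xd[pd, ], Sr[pr, pr], Sd[pd, pd],
                     cbind(inv_r[edges[, 1]], inv_d[edges[, 2]]),
                     data.frame(ridx = inv_r[pairs$ridx],
                                didx = inv_d[pairs$didx], y = pairs$y),
                     hidden = 5, epochs = 40, seed = 4)
  expect_equal(fit_p$scores[inv_r, inv_d], fit$scores, tolerance = 1e-8)
})

test_that("ablation variants wire the specified shortcuts", {
  fx <- ci_fixture()
  emb <- fx$embedding
  Xr <- emb$features$ncrna[1:12, ]; Xd <- emb$features$drug[1:6, ]
  Sr <- sequence_similarity(Xr); Sd <- sequence_similarity(Xd)
  edges <- cbind(c(1, 4, 7), c(1, 2, 3))
  pairs <- data.frame(ridx = c(1, 4, 7, 2, 5), didx = c(1, 2, 3, 4, 5),
                      y = c(1, 1, 1, 0, 0))
  for (v in c("no_gcn", "no_gat")) {
    fit <- train_gnn(Xr, Xd, Sr, Sd, edges, pairs, hidden = 6,
                     epochs = 10, seed = 5, variant = v)
    expect_true(all(fit$scores > 0 & fit$scores < 1))
  }
  # no_gcn: within-class (diagonal-block) edges appear in the mask
  fit_ng <- train_gnn(Xr, Xd, Sr, Sd, edges, pairs, hidden = 6,
                      epochs = 2, seed = 5, variant = "no_gcn")
  expect_gt(sum(fit_ng$mask[1:12, 1:12]) , 12)  # more than self-loops
  # no_gat has no attention parameters; no_gcn has no convolution ones
  expect_null(fit_ng$params$gcn_r)
  fit_na <- train_gnn(Xr, Xd, Sr, Sd, edges, pairs, hidden = 6,
                      epochs = 2, seed = 5, variant = "no_gat")
  expect_null(fit_na$params$gat)
})
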