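#' Split text into overlapping k-mers
#'
#' Sequences (RNA or SMILES) are decomposed into overlapping windows of
#' length `k` at stride 1, preserving order, so that the token stream
#' keeps the positional context the word2vec window exploits.
#'
#' @param text character string.
#' @param k window length (default 3).
#' @return character vector of `max(0, nchar(text) - k + 1)` tokens.
#' @export
tokenize <- function(text, k = 3L) {
  stopifnot(k >= 1L)
  n <- nchar(text)
  if (n < k) return(character())
  substring(text, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

#' Build a k-mer corpus from an entity table
#'
#' @param entities entity data frame.
#' @param k k-mer length.
#' @return named list of token vectors, one per entity.
#' @export
kmer_corpus <- function(entities, k = 3L) {
  docs <- lapply(entities$text, tokenize, k = k)
  names(docs) <- entities$id
  docs
}

#' Train k-mer token embeddings (CBOW word2vec)
#'
#' Continuous bag-of-words word2vec with negative sampling, trained by
#' the package's single-threaded seeded trainer so results are
#' bit-reproducible.  Separate models should be trained for the RNA
#' corpus and the SMILES corpus: the token alphabets differ and sharing
#' a model would pollute the context statistics.
#'
#' @param corpus list of token vectors (see [kmer_corpus()]).
#' @param d_w2v embedding dimension.
#' @param window context window half-width.
#' @param epochs training epochs, or `NULL` (default) for the adaptive
#'   rule: enough passes that every token type receives about 900
#'   gradient updates (`900 * vocabulary / corpus tokens`, clamped to
#'   5..1000).  Sparse vocabularies (SMILES 3-mers, where most tokens
#'   occur once or twice) need hundreds of passes before token vectors
#'   organise by context, while dense ones (the 64 RNA 3-mers) degrade
#'   when trained far past that point.
#' @param negative negative samples per positive.
#' @param seed integer seed.
#' @return numeric matrix, one row per distinct token (rownames are the
#'   tokens), `d_w2v` columns; attribute `"epochs"` records the epoch
#'   count used.
#' @export
train_token_embedding <- function(corpus, d_w2v = 64L, window = 5L,
                                  epochs = NULL, negative = 5L, seed = 1L) {
  corpus <- corpus[lengths(corpus) > 0L]
  if (!length(corpus)) stop("empty corpus")
  vocab <- sort(unique(unlist(corpus, use.names = FALSE)))
  docs <- lapply(corpus, function(d) match(d, vocab) - 1L)
  if (is.null(epochs)) {
    epochs <- min(1000L, max(5L, round(900 * length(vocab) /
                                         sum(lengths(corpus)))))
  }
  emb <- .cbow_train(docs, length(vocab), as.integer(d_w2v),
                     as.integer(window), as.integer(epochs),
                     as.integer(negative), 0.025, as.integer(seed))
  attr(emb, "epochs") <- epochs
  rownames(emb) <- vocab
  emb
}

#' Stack token embeddings into a fixed-shape per-entity array
#'
#' Each entity becomes a (T x d) matrix of its token vectors in
#' sequence order; sequences longer than `T` are truncated, shorter
#' ones zero-padded, so all entities of a class share one shape.
#'
#' @param docs list of token vectors.
#' @param embedding token embedding matrix (rownames = tokens).
#' @param T common token length.
#' @return 3D array `[entity, position, dimension]` with entity
#'   dimnames.
#' @export
stack_features <- function(docs, embedding, T) {
  stopifnot(T >= 1L)
  d <- ncol(embedding)
  out <- array(0, dim = c(length(docs), T, d),
               dimnames = list(names(docs), NULL, NULL))
  for (i in seq_along(docs)) {
    toks <- utils::head(docs[[i]], T)
    if (!length(toks)) next
    hit <- match(toks, rownames(embedding))
    if (anyNA(hit)) stop("token absent from embedding: ", toks[is.na(hit)][1])
    out[i, seq_along(toks), ] <- embedding[hit, , drop = FALSE]
  }
  out
}

#' Flatten stacked features by variance maximisation
#'
#' One trainable linear map from the flattened (T*d) token stack to
#' `d_flat` dimensions, fitted by Adam on the objective of maximising
#' the total variance of the output matrix across entities (inputs are
#' standardised first).  The intent is that linear compression spreads
#' entities in feature space instead of collapsing them.  A
#' deterministic PCA route (`method = "pca"`) gives the same interface
#' with a closed-form map.
#'
#' @param stack 3D array from [stack_features()].
#' @param d_flat output width.
#' @param epochs Adam steps (gradient method).
#' @param lr Adam learning rate.
#' @param seed seed for the map initialisation.
#' @param method `"grad"` (variance-maximising training) or `"pca"`.
#' @return entity x `d_flat` matrix; attribute `"loss_trace"` carries
#'   the per-epoch objective (negative total variance) for the gradient
#'   method.
#' @export
flatten_variance_max <- function(stack, d_flat = 64L, epochs = 200L,
                                 lr = 1e-3, seed = 1L,
                                 method = c("grad", "pca")) {
  method <- match.arg(method)
  n <- dim(stack)[1]
  stopifnot(n >= 2L)
  X <- matrix(stack, nrow = n)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  X <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  p <- ncol(X)

  if (method == "pca") {
    k <- min(d_flat, n - 1L, p)
    pc <- stats::prcomp(X, center = FALSE, rank. = k)
    Y <- matrix(0, n, d_flat, dimnames = list(rownames(stack), NULL))
    Y[, seq_len(k)] <- pc$x
    return(Y)
  }

  set.seed(seed)
  W <- matrix(stats::rnorm(p * d_flat, sd = 1 / sqrt(p)), p, d_flat)
  if (all(abs(sweep(X, 2, X[1, ])) < 1e-12)) {
    warning("all entities identical: variance objective is degenerate, ",
            "returning the map at initialisation")
    Y <- X %*% W
    rownames(Y) <- rownames(stack)
    return(Y)
  }
  m1 <- matrix(0, p, d_flat); v1 <- matrix(0, p, d_flat)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- numeric(epochs)
  for (t in seq_len(epochs)) {
    Y <- X %*% W
    Yc <- sweep(Y, 2, colMeans(Y))
    loss <- -sum(Yc^2) / (n - 1)            # negative total variance
    trace[t] <- loss
    G <- -(2 / (n - 1)) * crossprod(X, Yc)  # dloss/dW
    m1 <- b1 * m1 + (1 - b1) * G
    v1 <- b2 * v1 + (1 - b2) * G^2
    mh <- m1 / (1 - b1^t); vh <- v1 / (1 - b2^t)
    W <- W - lr * mh / (sqrt(vh) + eps)
  }
  Y <- X %*% W
  rownames(Y) <- rownames(stack)
  attr(Y, "loss_trace") <- trace
  Y
}

#' Ablation encoders: one-hot, TF-IDF, bag-of-words
#'
#' Sequence-order-free encoders used by the ablation study in place of
#' word2vec: `bow` counts tokens, `onehot` marks token presence, and
#' `tfidf` weights counts by smoothed inverse document frequency
#' `log((1 + n) / (1 + df)) + 1` (so a token present in every document
#' gets weight `log(1) + 1 = 1`).
#'
#' @param docs list of token vectors.
#' @param method `"onehot"`, `"tfidf"` or `"bow"`.
#' @param vocab optional fixed vocabulary (defaults to the tokens seen
#'   in `docs`).
#' @return entity x vocabulary numeric matrix.
#' @export
encode_alternative <- function(docs, method = c("onehot", "tfidf", "bow"),
                               vocab = NULL) {
  method <- match.arg(method)
  if (is.null(vocab)) vocab <- sort(unique(unlist(docs, use.names = FALSE)))
  counts <- t(vapply(docs, function(d) {
    tabulate(match(d, vocab), nbins = length(vocab))
  }, numeric(length(vocab))))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(docs))
  dimnames(counts) <- list(names(docs), vocab)
  switch(method,
    bow = counts,
    onehot = (counts > 0) + 0,
    tfidf = {
      n <- nrow(counts)
      df <- colSums(counts > 0)
      idf <- log((1 + n) / (1 + df)) + 1
      sweep(counts, 2, idf, "*")
    })
}

#' Unify per-class feature widths
#'
#' A linear layer per entity class maps its diffusion-coordinate width
#' to one shared width `d_unified`, so ncRNA and drug features can feed
#' the same downstream networks.  The map is identity-padded (the first
#' `min(d_in, d_unified)` coordinates pass through, extra columns are
#' zero), which is deterministic and reproduces the input exactly when
#' `d_unified` equals the class width.  The ncRNA matrix is the
#' row-concatenation of the lncRNA block (first) and the miRNA block.
#'
#' @param lnc,mir,drug per-class coordinate matrices (rownames = ids).
#' @param d_unified shared output width.
#' @return list with `ncrna` ((n_lnc + n_mir) x d_unified) and `drug`
#'   (n_drug x d_unified) matrices.
#' @export
unify_features <- function(lnc, mir, drug, d_unified = 64L) {
  stopifnot(d_unified >= 1L)
  pad <- function(x) {
    k <- min(ncol(x), d_unified)
    out <- matrix(0, nrow(x), d_unified, dimnames = list(rownames(x), NULL))
    out[, seq_len(k)] <- x[, seq_len(k)]
    out
  }
  list(ncrna = rbind(pad(lnc), pad(mir)), drug = pad(drug))
}
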