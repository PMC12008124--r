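#' Pipeline configuration
#'
#' All tunable parameters of the pipeline with their defaults.  Values
#' the method fixes: 3-mer tokens, a 2-layer GCN, a 4-layer GAT, and
#' per-class diffusion eigenvector counts of 9 (lncRNA), 150 (miRNA)
#' and 40 (drug) — roughly a quarter of each class's size at
#' curated-data scale.  When a configured eigenvector count is
#' infeasible for a small class (it must stay below the class size),
#' it falls back to a quarter of the class size.
#'
#' @param ... named overrides of any field: `k` (k-mer length),
#'   `d_w2v`, `window`, `w2v_epochs`, `negative` (word2vec),
#'   `T_percentile` (token-length percentile for stacking), `d_flat`,
#'   `flatten_epochs`, `flatten_lr`, `flatten_method` (flattener),
#'   `n_evec` (named lnc/mir/drug vector), `alpha`, `use_diffusion`,
#'   `d_unified`, `encoder` (`"word2vec"`, `"onehot"`, `"tfidf"`,
#'   `"bow"`), `conversion` (distance-to-similarity rule), `n_trees`
#'   (mining forest), `mine_mode` (`"per_fold"` or `"global"`),
#'   `hidden`, `gcn_layers`, `gat_layers`, `lr`, `epochs`, `slope`,
#'   `variant` (`"full"`, `"no_gcn"`, `"no_gat"`), `threshold`.
#' @return a `dmgat_config` list.
#' @export
dmgat_config <- function(...) {
  cfg <- list(
    k = 3L, d_w2v = 64L, window = 5L, w2v_epochs = NULL, negative = 5L,
    T_percentile = 0.95,
    d_flat = 64L, flatten_epochs = 200L, flatten_lr = 1e-3,
    flatten_method = "grad",
    n_evec = c(lnc = 9L, mir = 150L, drug = 40L), alpha = 1,
    use_diffusion = TRUE, d_unified = 64L,
    encoder = "word2vec", conversion = "gaussian",
    n_trees = 100L, mine_mode = "per_fold",
    hidden = 64L, gcn_layers = 2L, gat_layers = 4L,
    lr = 1e-3, epochs = 300L, slope = 0.2,
    variant = "full", threshold = 0.5)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "dmgat_config"
  cfg
}

# n_evec fallback for classes smaller than the configured count.
resolve_n_evec <- function(requested, n) {
  if (requested < n) return(as.integer(requested))
  max(2L, min(as.integer(floor(n / 4)), n - 2L))
}

#' Embed entities into unified feature space
#'
#' The label-free embedding branch: 3-mer tokenisation, CBOW word2vec
#' (separate models for the RNA and SMILES corpora), stacking to a
#' common token length (class-wise `T_percentile` quantile of token
#' counts), variance-maximising flattening, per-class diffusion maps,
#' and width unification.  The `encoder` config switches in the
#' ablation encoders (one-hot / TF-IDF / bag-of-words), which replace
#' the word2vec + flatten stage; `use_diffusion = FALSE` skips the
#' diffusion map.
#'
#' @param entities entity data frame (any order; the canonical order is
#'   applied internally).
#' @param config a [dmgat_config()].
#' @param seed integer seed.
#' @return a `dmgat_embedding` list: `features` (unified `ncrna`,
#'   `drug` matrices), `coords` (per-class pre-unification matrices),
#'   `ids` (per-class id vectors), `config`.
#' @export
dmgat_embed <- function(entities, config = dmgat_config(), seed = 1L) {
  entities <- order_entities(entities)
  parts <- split(entities, factor(entities$kind,
                                  levels = c("lncRNA", "miRNA", "drug")))
  if (any(vapply(parts[c("lncRNA", "miRNA", "drug")], nrow, 0L) < 3L)) {
    stop("each entity class needs at least 3 members")
  }
  docs <- lapply(parts, kmer_corpus, k = config$k)

  class_flat <- function(doc_sets, emb_seed) {
    # doc_sets: named list of per-class corpora sharing one vocabulary
    if (config$encoder == "word2vec") {
      emb <- train_token_embedding(
        do.call(c, unname(doc_sets)), d_w2v = config$d_w2v,
        window = config$window, epochs = config$w2v_epochs,
        negative = config$negative, seed = emb_seed)
      lapply(seq_along(doc_sets), function(i) {
        ds <- doc_sets[[i]]
        T <- max(1L, ceiling(stats::quantile(lengths(ds),
                                             config$T_percentile)))
        st <- stack_features(ds, emb, T)
        flatten_variance_max(st, d_flat = config$d_flat,
                             epochs = config$flatten_epochs,
                             lr = config$flatten_lr,
                             seed = emb_seed + i,
                             method = config$flatten_method)
      })
    } else {
      vocab <- sort(unique(unlist(doc_sets, use.names = FALSE)))
      lapply(doc_sets, encode_alternative, method = config$encoder,
             vocab = vocab)
    }
  }
  rna_flat <- class_flat(list(lnc = docs$lncRNA, mir = docs$miRNA),
                         emb_seed = seed)
  drug_flat <- class_flat(list(drug = docs$drug), emb_seed = seed + 10L)
  flat <- list(lnc = rna_flat[[1]], mir = rna_flat[[2]],
               drug = drug_flat[[1]])

  coords <- if (config$use_diffusion) {
    Map(function(x, nm) {
      ne <- resolve_n_evec(config$n_evec[[nm]], nrow(x))
      diffusion_map(x, n_evec = ne, alpha = config$alpha)
    }, flat, c("lnc", "mir", "drug"))
  } else flat

  feats <- unify_features(coords$lnc, coords$mir, coords$drug,
                          d_unified = config$d_unified)
  # column standardisation: diffusion coordinates are eigenvalue-scaled
  # and tiny, which conditions the downstream gradient training badly;
  # zero-variance (padding) columns are left at zero
  feats <- lapply(feats, function(M) {
    s <- apply(M, 2, stats::sd)
    mu <- colMeans(M)
    keep <- s > 1e-12
    M[, keep] <- sweep(sweep(M[, keep, drop = FALSE], 2, mu[keep]), 2,
                       s[keep], "/")
    M
  })
  structure(list(features = feats, coords = coords,
                 ids = list(lnc = parts$lncRNA$id, mir = parts$miRNA$id,
                            ncrna = rownames(feats$ncrna),
                            drug = parts$drug$id),
                 config = config),
            class = "dmgat_embedding")
}

# Mine reliable negatives given a training view of the data.
mine_negatives <- function(pos, sen, candidates, emb, n_trees, seed) {
  clf <- train_pu_classifier(
    pair_features(pos, emb$features$ncrna, emb$features$drug),
    pair_features(sen, emb$features$ncrna, emb$features$drug),
    n_trees = n_trees, seed = seed)
  sc <- score_pairs(clf, pair_features(candidates, emb$features$ncrna,
                                       emb$features$drug))
  select_reliable_negatives(sc, candidates, sen, nrow(pos))
}

#' Fit the association model on a full dataset
#'
#' The main fitting function: builds the resistance adjacency, embeds
#' all entities, fuses sequence and GIP similarity per class, mines
#' reliable negatives from the unlabeled pairs (random forest trained
#' on resistance versus sensitivity pairs, balanced to the positive
#' count), and trains the GCN + GAT network end-to-end on positives
#' versus reliable negatives.  Use [dmgat_cv()] for honest performance
#' estimation; a full-data fit is for ranking novel candidate pairs.
#'
#' @param entities entity data frame ([read_fasta()] / [read_smiles()]
#'   output, row-bound).
#' @param associations association data frame ([read_associations()]).
#' @param config a [dmgat_config()].
#' @param seed integer seed controlling every random stage.
#' @param curate apply [curate_associations()] first (default `FALSE`;
#'   curated inputs are usually prepared explicitly).
#' @param embedding optionally, a precomputed [dmgat_embed()] result.
#' @return an object of class `dmgat` with components `scores` (m x n
#'   predicted association probabilities), `negatives` (the mined
#'   negative set), `embedding`, `similarity` (`ncrna`, `drug` fused
#'   matrices), `fit` (network training artifacts), `table`, `A`,
#'   `config`, `seed`.
#' @seealso [predict.dmgat()], [dmgat_cv()], [rank_predictions()]
#' @export
dmgat <- function(entities, associations, config = dmgat_config(),
                  seed = 1L, curate = FALSE, embedding = NULL) {
  cl <- match.call()
  if (curate) associations <- curate_associations(associations)
  entities <- order_entities(entities)
  used <- unique(c(associations$ncrna_id, associations$drug_id))
  miss <- setdiff(used, entities$id)
  if (length(miss)) stop("association id(s) without entity: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  if (is.null(embedding)) {
    embedding <- dmgat_embed(entities, config, seed = seed)
  }
  row_ids <- embedding$ids$ncrna
  col_ids <- embedding$ids$drug
  A <- build_adjacency(associations, row_ids, col_ids)

  seq_r <- sequence_similarity(embedding$features$ncrna, config$conversion)
  seq_d <- sequence_similarity(embedding$features$drug, config$conversion)
  Sr <- fuse_similarity(seq_r, gip_kernel(A, "ncrna"))
  Sd <- fuse_similarity(seq_d, gip_kernel(A, "drug"))

  pos <- associations[associations$label == "resistance",
                      c("ncrna_id", "drug_id")]
  sen <- associations[associations$label == "sensitivity",
                      c("ncrna_id", "drug_id")]
  key <- function(r, d) paste(r, d, sep = "\r")
  all_r <- rep(row_ids, times = length(col_ids))
  all_d <- rep(col_ids, each = length(row_ids))
  unk_mask <- !key(all_r, all_d) %in% key(associations$ncrna_id,
                                          associations$drug_id)
  unknown <- data.frame(ncrna_id = all_r[unk_mask], drug_id = all_d[unk_mask],
                        stringsAsFactors = FALSE)
  negatives <- mine_negatives(pos, sen, unknown, embedding,
                              n_trees = config$n_trees, seed = seed + 100L)

  edges <- cbind(match(pos$ncrna_id, row_ids), match(pos$drug_id, col_ids))
  train_pairs <- data.frame(
    ridx = c(edges[, 1], match(negatives$ncrna_id, row_ids)),
    didx = c(edges[, 2], match(negatives$drug_id, col_ids)),
    y = rep(c(1, 0), c(nrow(pos), nrow(negatives))))
  fit <- train_gnn(embedding$features$ncrna, embedding$features$drug,
                   Sr, Sd, edges, train_pairs,
                   hidden = config$hidden, gcn_layers = config$gcn_layers,
                   gat_layers = config$gat_layers, lr = config$lr,
                   epochs = config$epochs, slope = config$slope,
                   seed = seed + 200L, variant = config$variant)
  structure(list(scores = fit$scores, negatives = negatives,
                 embedding = embedding,
                 similarity = list(ncrna = Sr, drug = Sd),
                 fit = fit, table = associations, A = A,
                 config = config, seed = seed, call = cl),
            class = "dmgat")
}

#' @export
print.dmgat <- function(x, ...) {
  m <- nrow(x$scores); n <- ncol(x$scores)
  cat("ncRNA-drug association model (GCN + GAT in diffusion space)\n")
  cat(sprintf("  entities: %d ncRNAs x %d drugs (%d candidate pairs)\n",
              m, n, m * n))
  cat(sprintf("  labels:   %d resistance, %d sensitivity\n",
              sum(x$table$label == "resistance"),
              sum(x$table$label == "sensitivity")))
  cat(sprintf("  training: %d positives vs %d reliable negatives (%d mined)\n",
              sum(x$table$label == "resistance"), nrow(x$negatives),
              sum(x$negatives$provenance == "mined_unknown")))
  cat(sprintf("  network:  %d-layer GCN, %d-layer GAT, hidden width %d (%s)\n",
              x$config$gcn_layers, x$config$gat_layers, x$config$hidden,
              x$config$variant))
  cat(sprintf("  final training loss: %.4f\n",
              utils::tail(x$fit$loss_trace, 1)))
  invisible(x)
}

#' @export
summary.dmgat <- function(object, k = 10L, ...) {
  top <- rank_predictions(object$scores, object$table, k = k)
  out <- list(model = object, top = top,
              train_metrics = local({
                tp <- object$table[object$table$label == "resistance", ]
                neg <- object$negatives
                sc <- c(object$scores[cbind(match(tp$ncrna_id,
                                                  rownames(object$scores)),
                                            match(tp$drug_id,
                                                  colnames(object$scores)))],
                        object$scores[cbind(match(neg$ncrna_id,
                                                  rownames(object$scores)),
                                            match(neg$drug_id,
                                                  colnames(object$scores)))])
                compute_metrics(sc, rep(c(1, 0), c(nrow(tp), nrow(neg))),
                                object$config$threshold)
              }))
  class(out) <- "summary.dmgat"
  out
}

#' @export
print.summary.dmgat <- function(x, ...) {
  print(x$model)
  cat("\nTraining-set metrics (positives vs reliable negatives):\n")
  print(round(x$train_metrics, 4), row.names = FALSE)
  cat("\nTop predicted unlabeled associations:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' Predict from a fitted model
#'
#' @param object a fitted [dmgat()] model.
#' @param type `"scores"` for the full m x n score matrix, `"ranking"`
#'   for the top-`k` unlabeled pairs ([rank_predictions()]).
#' @param k ranking length (default 20).
#' @param ... unused.
#' @return score matrix or ranked pair data frame.
#' @export
predict.dmgat <- function(object, type = c("scores", "ranking"), k = 20L,
                          ...) {
  type <- match.arg(type)
  if (type == "scores") return(object$scores)
  rank_predictions(object$scores, object$table, k = k)
}

#' @export
plot.dmgat <- function(x, ...) {
  graphics::plot(x$fit$loss_trace, type = "l", xlab = "epoch",
                 ylab = "binary cross-entropy",
                 main = "Training loss", ...)
  invisible(x)
}

#' Rank unlabeled pairs by predicted score
#'
#' Pairs with any known label (resistance or sensitivity) are
#' excluded; the remaining pairs are sorted by descending score, ties
#' broken lexicographically by (ncRNA id, drug id).
#'
#' @param scores m x n score matrix with id dimnames.
#' @param table association data frame of known labels.
#' @param k number of pairs to return (default 20; truncated with a
#'   warning if fewer unlabeled pairs exist).
#' @return data frame `ncrna_id`, `drug_id`, `score`, `rank`.
#' @export
rank_predictions <- function(scores, table, k = 20L) {
  rid <- rep(rownames(scores), times = ncol(scores))
  did <- rep(colnames(scores), each = nrow(scores))
  known <- paste(table$ncrna_id, table$drug_id, sep = "\r")
  keep <- !paste(rid, did, sep = "\r") %in% known
  df <- data.frame(ncrna_id = rid[keep], drug_id = did[keep],
                   score = as.vector(scores)[keep], stringsAsFactors = FALSE)
  if (k > nrow(df)) {
    warning("only ", nrow(df), " unlabeled pairs available; truncating")
    k <- nrow(df)
  }
  df <- df[order(-df$score, df$ncrna_id, df$drug_id, method = "radix"), ]
  df <- utils::head(df, k)
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Per-drug feature cohesion
#'
#' For each drug with at least two associated ncRNAs, the mean pairwise
#' cosine similarity of the associated ncRNAs' feature vectors.  A high
#' value means the ncRNAs tied to that drug sit close together in
#' feature space.  Modes: `"known"` uses the labeled resistance
#' associations, `"predicted"` uses each drug's top-scoring unlabeled
#' ncRNAs (degree-matched to its known count), `"random"` assigns
#' degree-matched random ncRNA sets.
#'
#' @param features ncRNA feature matrix (id rownames).
#' @param table association data frame.
#' @param mode `"known"`, `"predicted"` or `"random"`.
#' @param scores score matrix (required for `mode = "predicted"`).
#' @param seed seed for the random assignment.
#' @return named numeric vector of per-drug mean cosine similarities
#'   (drugs with fewer than 2 associated ncRNAs are skipped).
#' @export
cohesion_analysis <- function(features, table,
                              mode = c("known", "predicted", "random"),
                              scores = NULL, seed = 1L) {
  mode <- match.arg(mode)
  res <- table[table$label == "resistance", , drop = FALSE]
  deg <- table(res$drug_id)
  drugs <- names(deg)[deg >= 2L]
  if (mode == "predicted" && is.null(scores)) {
    stop("mode = 'predicted' needs the score matrix")
  }
  if (mode == "random") set.seed(seed)
  mean_cos <- function(M) {
    M <- M / pmax(sqrt(rowSums(M^2)), 1e-12)
    G <- tcrossprod(M)
    mean(G[upper.tri(G)])
  }
  out <- vapply(drugs, function(d) {
    ids <- switch(mode,
      known = res$ncrna_id[res$drug_id == d],
      predicted = {
        known_ids <- res$ncrna_id[res$drug_id == d]
        s <- scores[, d]
        s <- s[!names(s) %in% known_ids]
        names(sort(s, decreasing = TRUE))[seq_len(deg[[d]])]
      },
      random = sample(rownames(features), deg[[d]]))
    mean_cos(features[ids, , drop = FALSE])
  }, numeric(1))
  names(out) <- drugs
  out
}
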