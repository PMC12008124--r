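#' Cross-validated evaluation of the pipeline
#'
#' The 5-fold protocol: positives, sensitivities and unknowns are each
#' partitioned into `k` folds; per fold the GIP similarities are
#' recomputed from the training adjacency (held-out positives zeroed),
#' reliable negatives are mined from training-side data only, the
#' network is trained on training positives versus mined negatives,
#' and metrics are computed on the held-out positives (label 1) versus
#' held-out unknowns (label 0).  A leakage audit asserts per fold that
#' no test positive appears in the training edges, the loss pairs, or
#' the GIP input.
#'
#' @param entities entity data frame.
#' @param associations association data frame.
#' @param k number of folds (default 5).
#' @param config a [dmgat_config()].
#' @param seed integer seed.
#' @param embedding optional precomputed [dmgat_embed()] result (the
#'   embedding is label-free, so it is shared across folds).
#' @return an object of class `dmgat_cv`: `metrics` (per-fold data
#'   frame), `mean` (fold means), `folds`, `negatives` (per-fold
#'   list), `scores` (per-fold score matrices), `audit` (per-fold
#'   leakage checks, all must be `TRUE`), `config`, `seed`.
#' @export
dmgat_cv <- function(entities, associations, k = 5L,
                     config = dmgat_config(), seed = 1L, embedding = NULL) {
  entities <- order_entities(entities)
  if (is.null(embedding)) embedding <- dmgat_embed(entities, config, seed)
  row_ids <- embedding$ids$ncrna
  col_ids <- embedding$ids$drug
  A <- build_adjacency(associations, row_ids, col_ids)
  folds <- make_folds(associations, row_ids, col_ids, k = k,
                      seed = seed + 1L)
  seq_r <- sequence_similarity(embedding$features$ncrna, config$conversion)
  seq_d <- sequence_similarity(embedding$features$drug, config$conversion)
  key <- function(df) paste(df$ncrna_id, df$drug_id, sep = "\r")

  global_neg <- NULL
  if (config$mine_mode == "global") {
    pos_all <- folds$pos[, c("ncrna_id", "drug_id")]
    sen_all <- folds$sen[, c("ncrna_id", "drug_id")]
    unk_all <- folds$unk[, c("ncrna_id", "drug_id")]
    global_neg <- mine_negatives(pos_all, sen_all, unk_all, embedding,
                                 n_trees = config$n_trees,
                                 seed = seed + 100L)
    # verified pairs follow the sensitivity partition, mined pairs the
    # fold of their unknown-set membership
    gk <- key(global_neg)
    global_neg$fold <- ifelse(
      global_neg$provenance == "verified_sensitivity",
      folds$sen$fold[match(gk, key(folds$sen))],
      folds$unk$fold[match(gk, key(folds$unk))])
  }

  metrics <- vector("list", k)
  neg_list <- vector("list", k)
  score_list <- vector("list", k)
  audit <- logical(k)
  for (i in seq_len(k)) {
    ref <- fold_gip_refresh(A, folds, i)
    Sr <- fuse_similarity(seq_r, ref$gip_r)
    Sd <- fuse_similarity(seq_d, ref$gip_d)

    tr_pos <- folds$pos[folds$pos$fold != i, c("ncrna_id", "drug_id")]
    tr_sen <- folds$sen[folds$sen$fold != i, c("ncrna_id", "drug_id")]
    te_pos <- folds$pos[folds$pos$fold == i, c("ncrna_id", "drug_id")]
    te_unk <- folds$unk[folds$unk$fold == i, c("ncrna_id", "drug_id")]

    negatives <- if (config$mine_mode == "global") {
      global_neg[global_neg$fold != i,
                 c("ncrna_id", "drug_id", "provenance", "score")]
    } else {
      cand <- folds$unk[folds$unk$fold != i, c("ncrna_id", "drug_id")]
      mine_negatives(tr_pos, tr_sen, cand, embedding,
                     n_trees = config$n_trees, seed = seed + 100L + i)
    }
    neg_list[[i]] <- negatives

    edges <- cbind(match(tr_pos$ncrna_id, row_ids),
                   match(tr_pos$drug_id, col_ids))
    train_pairs <- data.frame(
      ridx = c(edges[, 1], match(negatives$ncrna_id, row_ids)),
      didx = c(edges[, 2], match(negatives$drug_id, col_ids)),
      y = rep(c(1, 0), c(nrow(tr_pos), nrow(negatives))))
    fit <- train_gnn(embedding$features$ncrna, embedding$features$drug,
                     Sr, Sd, edges, train_pairs,
                     hidden = config$hidden, gcn_layers = config$gcn_layers,
                     gat_layers = config$gat_layers, lr = config$lr,
                     epochs = config$epochs, slope = config$slope,
                     seed = seed + 200L + i, variant = config$variant)
    score_list[[i]] <- fit$scores

    # training negatives drawn from the test-fold unknowns would make a
    # pair both a training label and a test point; exclude defensively
    te_unk <- te_unk[!key(te_unk) %in% key(negatives), , drop = FALSE]
    test <- rbind(te_pos, te_unk)
    y <- rep(c(1L, 0L), c(nrow(te_pos), nrow(te_unk)))
    sc <- fit$scores[cbind(match(test$ncrna_id, row_ids),
                           match(test$drug_id, col_ids))]
    metrics[[i]] <- cbind(fold = i,
                          compute_metrics(sc, y, config$threshold))

    audit[i] <- all(
      ref$A_train[cbind(match(te_pos$ncrna_id, row_ids),
                        match(te_pos$drug_id, col_ids))] == 0,
      !key(te_pos) %in% key(tr_pos),
      !key(te_pos) %in% key(negatives))
  }
  metrics <- do.call(rbind, metrics)
  structure(list(metrics = metrics,
                 mean = colMeans(metrics[, -1, drop = FALSE]),
                 folds = folds, negatives = neg_list, scores = score_list,
                 audit = audit, config = config, seed = seed),
            class = "dmgat_cv")
}

#' @export
print.dmgat_cv <- function(x, ...) {
  k <- max(x$metrics$fold)
  cat(sprintf("%d-fold cross-validation (%s variant, %s encoder)\n",
              k, x$config$variant, x$config$encoder))
  cat("mean over folds:\n")
  print(round(x$mean, 4))
  if (!all(x$audit)) cat("WARNING: leakage audit failed for fold(s) ",
                         paste(which(!x$audit), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.dmgat_cv <- function(object, ...) {
  cat("Per-fold metrics:\n")
  print(round(object$metrics, 4), row.names = FALSE)
  cat("\nMean:\n")
  print(round(object$mean, 4))
  cat("\nLeakage audit passed: ", all(object$audit), "\n")
  invisible(object)
}

#' @export
plot.dmgat_cv <- function(x, ...) {
  graphics::barplot(x$metrics$auc, names.arg = x$metrics$fold,
                    xlab = "fold", ylab = "AUC", ylim = c(0, 1),
                    main = "Per-fold AUC", ...)
  graphics::abline(h = x$mean[["auc"]], lty = 2)
  invisible(x)
}

#' Layer-count grid sweep
#'
#' Runs [dmgat_cv()] for every combination of GCN and GAT stack depths
#' and collects the mean metrics per grid cell.
#'
#' @param entities,associations dataset.
#' @param gcn_range,gat_range integer vectors of stack depths.
#' @param k folds per cell.
#' @param config base [dmgat_config()].
#' @param seed integer seed (shared across cells so the folds match).
#' @return data frame with one row per (gcn_layers, gat_layers) cell
#'   and the mean metrics.
#' @export
sweep_layers <- function(entities, associations, gcn_range = 1:5,
                         gat_range = 1:5, k = 5L,
                         config = dmgat_config(), seed = 1L) {
  stopifnot(length(gcn_range) > 0, length(gat_range) > 0)
  entities <- order_entities(entities)
  embedding <- dmgat_embed(entities, config, seed)
  grid <- expand.grid(gcn_layers = gcn_range, gat_layers = gat_range)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    cfg <- config
    cfg$gcn_layers <- grid$gcn_layers[g]
    cfg$gat_layers <- grid$gat_layers[g]
    cv <- dmgat_cv(entities, associations, k = k, config = cfg,
                   seed = seed, embedding = embedding)
    cbind(grid[g, , drop = FALSE], as.data.frame(as.list(cv$mean)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
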