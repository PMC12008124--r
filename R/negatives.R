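#' Pair features for the PU classifier
#'
#' A (ncRNA, drug) pair is represented by the concatenation of the
#' ncRNA's and the drug's unified embedding rows (width
#' `2 * d_unified`).  These label-free embeddings — not GNN outputs —
#' feed the random forest, since negative mining has to run before the
#' network is trained (it defines the training labels).
#'
#' @param pairs data frame with columns `ncrna_id`, `drug_id`.
#' @param ncrna_feat,drug_feat unified feature matrices with id
#'   rownames.
#' @return numeric matrix, one row per pair.
#' @export
pair_features <- function(pairs, ncrna_feat, drug_feat) {
  ri <- match(pairs$ncrna_id, rownames(ncrna_feat))
  ci <- match(pairs$drug_id, rownames(drug_feat))
  if (anyNA(ri) || anyNA(ci)) stop("pair references unknown entity id")
  out <- cbind(ncrna_feat[ri, , drop = FALSE], drug_feat[ci, , drop = FALSE])
  rownames(out) <- paste(pairs$ncrna_id, pairs$drug_id, sep = "|")
  out
}

#' Train the positive-versus-sensitivity random forest
#'
#' Random forest probability model separating resistance pairs (class
#' `"pos"`) from verified sensitivity pairs (class `"neg"`), used to
#' score unlabeled pairs for reliable-negative mining.
#'
#' @param pos,neg pair feature matrices (see [pair_features()]).
#' @param n_trees number of trees.
#' @param seed integer seed (forest growth is seeded, so predictions
#'   are reproducible).
#' @return a `randomForest` object.
#' @export
train_pu_classifier <- function(pos, neg, n_trees = 100L, seed = 1L) {
  if (!nrow(pos) || !nrow(neg)) stop("both classes must be non-empty")
  x <- rbind(pos, neg)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- factor(rep(c("pos", "neg"), c(nrow(pos), nrow(neg))),
              levels = c("neg", "pos"))
  set.seed(seed)
  randomForest::randomForest(x = x, y = y, ntree = n_trees)
}

#' Score pairs with the PU classifier
#'
#' @param clf forest from [train_pu_classifier()].
#' @param feats pair feature matrix.
#' @return probability of the resistance class per pair.
#' @export
score_pairs <- function(clf, feats) {
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  stats::predict(clf, feats, type = "prob")[, "pos"]
}

#' Select reliable negative pairs
#'
#' All verified sensitivity pairs are taken as negatives; the remaining
#' quota up to `n_pos` is filled with the unlabeled pairs the
#' classifier scores least resistance-like (ties broken by
#' lexicographic pair id), so the final negative set is exactly equal
#' in size to the positive set.
#'
#' @param scores named resistance scores for the candidate unknown
#'   pairs (see below).
#' @param unknown_pairs data frame (`ncrna_id`, `drug_id`) of candidate
#'   unlabeled pairs, aligned with `scores`.
#' @param sensitivity_pairs data frame of verified sensitivity pairs.
#' @param n_pos number of positive pairs to balance against.
#' @return data frame with columns `ncrna_id`, `drug_id`, `provenance`
#'   (`"verified_sensitivity"` or `"mined_unknown"`) and `score` (`NA`
#'   for verified pairs); exactly `n_pos` rows.
#' @export
select_reliable_negatives <- function(scores, unknown_pairs,
                                      sensitivity_pairs, n_pos) {
  n_sen <- nrow(sensitivity_pairs)
  if (n_pos < n_sen) {
    stop("more verified sensitivity pairs than positives (n_pos < |sens|)")
  }
  need <- n_pos - n_sen
  if (need > nrow(unknown_pairs)) {
    stop("not enough unlabeled pairs to mine ", need, " negatives")
  }
  ord <- order(scores, unknown_pairs$ncrna_id, unknown_pairs$drug_id,
               method = "radix")
  take <- utils::head(ord, need)
  mined <- data.frame(ncrna_id = unknown_pairs$ncrna_id[take],
                      drug_id = unknown_pairs$drug_id[take],
                      provenance = rep("mined_unknown", length(take)),
                      score = unname(scores[take]),
                      stringsAsFactors = FALSE)
  verified <- data.frame(ncrna_id = sensitivity_pairs$ncrna_id,
                         drug_id = sensitivity_pairs$drug_id,
                         provenance = rep("verified_sensitivity", n_sen),
                         score = rep(NA_real_, n_sen),
                         stringsAsFactors = FALSE)
  out <- rbind(verified, mined)
  rownames(out) <- NULL
  out
}
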