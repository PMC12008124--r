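#' Partition a dataset into cross-validation folds
#'
#' The positive (resistance), sensitivity and unknown pair sets are
#' each split uniformly at random into `k` folds whose sizes differ by
#' at most one.  Fold `i`'s training side uses the complements of the
#' held-out subsets; its test side is the held-out positives plus the
#' held-out unknowns.
#'
#' @param table association data frame.
#' @param row_ids,col_ids the full ncRNA and drug id universes (needed
#'   to enumerate the unknown pairs).
#' @param k number of folds (default 5).
#' @param seed integer seed for the random assignment.
#' @return a `fold_partition` list with data frames `pos`, `sen`,
#'   `unk`, each with columns `ncrna_id`, `drug_id`, `fold`.
#' @export
make_folds <- function(table, row_ids, col_ids, k = 5L, seed = 1L) {
  stopifnot(k >= 2L)
  key <- function(r, d) paste(r, d, sep = "\r")
  pos <- table[table$label == "resistance", c("ncrna_id", "drug_id")]
  sen <- table[table$label == "sensitivity", c("ncrna_id", "drug_id")]
  all_r <- rep(row_ids, times = length(col_ids))
  all_d <- rep(col_ids, each = length(row_ids))
  known <- key(table$ncrna_id, table$drug_id)
  is_unk <- !key(all_r, all_d) %in% known
  unk <- data.frame(ncrna_id = all_r[is_unk], drug_id = all_d[is_unk],
                    stringsAsFactors = FALSE)
  sets <- list(pos = pos, sen = sen, unk = unk)
  small <- names(sets)[vapply(sets, nrow, 0L) < k]
  if (length(small)) {
    stop("class(es) with fewer members than folds: ",
         paste(small, collapse = ", "))
  }
  set.seed(seed)
  out <- lapply(sets, function(df) {
    df$fold <- sample(rep_len(seq_len(k), nrow(df)))
    rownames(df) <- NULL
    df
  })
  structure(c(out, list(k = k, seed = seed)), class = "fold_partition")
}

#' Recompute the adjacency and GIP similarity for one fold
#'
#' The held-out positives of fold `i` are zeroed in the adjacency
#' before the GIP kernels are computed, so the interaction profiles
#' seen in training never contain test information; the fused
#' similarities must therefore be rebuilt per fold.
#'
#' @param A full binary adjacency matrix (dimnames = ids).
#' @param folds a [make_folds()] partition.
#' @param i fold index.
#' @return list with `A_train` (test positives zeroed), `gip_r`,
#'   `gip_d`.
#' @export
fold_gip_refresh <- function(A, folds, i) {
  test_pos <- folds$pos[folds$pos$fold == i, , drop = FALSE]
  A_train <- A
  if (nrow(test_pos)) {
    ri <- match(test_pos$ncrna_id, rownames(A))
    ci <- match(test_pos$drug_id, colnames(A))
    A_train[cbind(ri, ci)] <- 0L
  }
  list(A_train = A_train,
       gip_r = gip_kernel(A_train, "ncrna"),
       gip_d = gip_kernel(A_train, "drug"))
}
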