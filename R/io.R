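#' Read a FASTA file into an entity table
#'
#' Entities are the atoms of the pipeline: an ncRNA (lncRNA or miRNA,
#' text over the RNA alphabet) or a drug (text is a SMILES string).
#' They are kept in a plain data frame with columns `id`, `kind`,
#' `text`.  DNA-style `T` characters are normalised to `U` for ncRNA
#' records so that miRBase- and LncBook-style exports mix freely.
#'
#' @param path path to a multi-record FASTA file.
#' @param kind entity class to assign: `"lncRNA"` or `"miRNA"`.
#' @return data frame with columns `id`, `kind`, `text`, one row per
#'   FASTA record (zero rows for an empty file).
#' @export
read_fasta <- function(path, kind = c("miRNA", "lncRNA")) {
  kind <- match.arg(kind)
  stopifnot(file.exists(path))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    return(entity_table(character(), character(), character()))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  txt <- toupper(as.character(seqs))
  txt <- gsub("T", "U", txt, fixed = TRUE)
  bad <- which(nchar(txt) == 0L | is.na(ids) | nchar(ids) == 0L)
  if (length(bad)) {
    stop("malformed FASTA record(s) at index: ", paste(bad, collapse = ", "))
  }
  entity_table(ids, rep(kind, length(ids)), txt)
}

#' Read a drug SMILES table
#'
#' @param path TSV file with header columns `drug_id` and `smiles`.
#' @return data frame with columns `id`, `kind` (`"drug"`), `text`.
#' @export
read_smiles <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug_id", "smiles")
  if (!all(need %in% names(df))) {
    stop("SMILES file must have columns: ", paste(need, collapse = ", "))
  }
  entity_table(df$drug_id, rep("drug", nrow(df)), df$smiles)
}

# Internal constructor; enforces the entity invariants (unique ids,
# non-empty text, class-appropriate alphabet).
entity_table <- function(id, kind, text) {
  id <- as.character(id); kind <- as.character(kind); text <- as.character(text)
  if (anyDuplicated(id)) {
    stop("duplicate entity id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (length(id)) {
    if (any(nchar(text) == 0L)) stop("empty sequence text")
    ok_kind <- kind %in% c("lncRNA", "miRNA", "drug")
    if (!all(ok_kind)) stop("unknown entity kind: ", kind[!ok_kind][1])
    rna <- kind != "drug"
    if (any(rna) && any(grepl("[^AUCGN]", text[rna]))) {
      stop("ncRNA sequence contains non-RNA characters (allowed: A,U,C,G,N)")
    }
    if (any(!rna) && any(grepl("[^[:print:]]", text[!rna]))) {
      stop("SMILES string contains non-printable characters")
    }
  }
  data.frame(id = id, kind = kind, text = text, stringsAsFactors = FALSE)
}

#' Canonical entity ordering
#'
#' Matrix rows follow a deterministic order so that every run produces
#' identical artifacts: lncRNAs first, then miRNAs, each block
#' alphabetical by id; drugs alphabetical.
#'
#' @param entities entity data frame (see [read_fasta()]).
#' @return the entity data frame reordered.
#' @export
order_entities <- function(entities) {
  rank <- match(entities$kind, c("lncRNA", "miRNA", "drug"))
  entities[order(rank, entities$id, method = "radix"), , drop = FALSE]
}

#' Read a labeled association table
#'
#' Associations are (ncRNA, drug) pairs labeled `resistance` or
#' `sensitivity`; every unlisted pair is implicitly unknown, so unknown
#' pairs are never stored.  Exact duplicate rows are collapsed; a pair
#' carrying both labels is rejected because the label classes must
#' partition the pair space.
#'
#' @param path TSV file with header columns `ncrna_id`, `drug_id`, `label`.
#' @return data frame with columns `ncrna_id`, `drug_id`, `label`.
#' @export
read_associations <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("ncrna_id", "drug_id", "label")
  if (!all(need %in% names(df))) {
    stop("association file must have columns: ", paste(need, collapse = ", "))
  }
  association_table(df[, need])
}

# Validate and normalise an association record data frame.
association_table <- function(df, allow_conflicts = FALSE) {
  bad <- setdiff(unique(df$label), c("resistance", "sensitivity"))
  if (length(bad)) stop("invalid association label(s): ", paste(bad, collapse = ", "))
  df <- unique(df[, c("ncrna_id", "drug_id", "label")])
  key <- paste(df$ncrna_id, df$drug_id, sep = "\r")
  if (!allow_conflicts && anyDuplicated(key)) {
    con <- unique(key[duplicated(key)])
    stop("pair(s) labeled both resistance and sensitivity: ",
         paste(gsub("\r", "/", con), collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Curate a raw association table
#'
#' Cleaning applied to the merged raw associations: exact duplicates are
#' collapsed, pairs carrying both a resistance and a sensitivity label
#' are dropped as ambiguous, and every ncRNA linked to only a single
#' drug by resistance is removed together with all of its records.  The
#' degree-1 filter is iterated to a fixed point, since removing one
#' ncRNA's records can drop another ncRNA to degree 1.
#'
#' @param table association data frame (conflicting labels tolerated).
#' @return curated association data frame; `curate_associations` is
#'   idempotent and never adds records.
#' @export
curate_associations <- function(table) {
  df <- unique(table[, c("ncrna_id", "drug_id", "label")])
  key <- paste(df$ncrna_id, df$drug_id, sep = "\r")
  conflicted <- unique(key[duplicated(key)])
  df <- df[!key %in% conflicted, , drop = FALSE]
  repeat {
    res <- df[df$label == "resistance", , drop = FALSE]
    deg <- table(res$ncrna_id)
    drop_ids <- names(deg)[deg == 1L]
    if (!length(drop_ids)) break
    df <- df[!df$ncrna_id %in% drop_ids, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Build the binary resistance adjacency matrix
#'
#' The m x n matrix A with `a[i, j] = 1` iff ncRNA i has a resistance
#' association with drug j.  Sensitivity and unknown pairs are both 0:
#' A encodes resistance only.
#'
#' @param table association data frame.
#' @param row_ids ordered ncRNA ids (rows).
#' @param col_ids ordered drug ids (columns).
#' @return binary matrix with `dimnames = list(row_ids, col_ids)`.
#' @export
build_adjacency <- function(table, row_ids, col_ids) {
  if (anyDuplicated(row_ids) || anyDuplicated(col_ids)) {
    stop("row_ids/col_ids must be duplicate-free")
  }
  A <- matrix(0L, length(row_ids), length(col_ids),
              dimnames = list(row_ids, col_ids))
  res <- table[table$label == "resistance", , drop = FALSE]
  if (nrow(res)) {
    ri <- match(res$ncrna_id, row_ids)
    ci <- match(res$drug_id, col_ids)
    if (anyNA(ri) || anyNA(ci)) {
      miss <- c(res$ncrna_id[is.na(ri)], res$drug_id[is.na(ci)])
      stop("record id(s) missing from id lists: ",
           paste(unique(miss), collapse = ", "))
    }
    A[cbind(ri, ci)] <- 1L
  }
  A
}

#' Write / read a numeric matrix as TSV with an id column
#'
#' Features and similarity matrices are persisted in a plain-text form
#' (first column `id`, then one column per feature dimension) so that
#' downstream steps can be re-run without repeating embedding.
#'
#' @param x numeric matrix with rownames.
#' @param path output TSV path.
#' @return `write_matrix_tsv` returns `path` invisibly;
#'   `read_matrix_tsv` returns the matrix with rownames restored.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write an association table as TSV
#'
#' @param table association data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(table, path) {
  utils::write.table(table[, c("ncrna_id", "drug_id", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
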