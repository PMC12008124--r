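# Shared fixtures, built in code.  The desk-scale synthetic dataset and
# its embedding are expensive (~30 s), so they are memoised and shared
# across test files.

micro_config <- function(seed = 1L) {
  synthetic_config("ci", n_lnc = 4L, n_mir = 16L, n_drug = 8L,
                   lnc_len = c(80L, 120L), density_res = 0.12,
                   density_sen = 0.05, seed = seed)
}

fast_config <- function(...) {
  dmgat_config(flatten_epochs = 50L, epochs = 60L, n_trees = 50L, ...)
}

ci_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config("ci", seed = 1)
      ent <- generate_entities(cfg)
      pl <- plant_associations(cfg, ent)
      emb <- dmgat_embed(ent[, c("id", "kind", "text")], dmgat_config(),
                         seed = 1)
      cache <<- list(cfg = cfg, entities = ent, table = pl$table,
                     truth = pl$truth, embedding = emb)
    }
    cache
  }
})

# small labeled association data frame used by io tests
toy_assoc <- function() {
  data.frame(
    ncrna_id = c("r1", "r2", "r2", "r3", "r3", "r4"),
    drug_id  = c("d1", "d1", "d2", "d1", "d3", "d2"),
    label    = c("resistance", "resistance", "resistance", "resistance",
                 "sensitivity", "sensitivity"),
    stringsAsFactors = FALSE)
}

write_tsv_tmp <- function(df) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}
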