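test_that("fold partition is exact: disjoint, covering, balanced", {
  fx <- ci_fixture()
  rows <- fx$embedding$ids$ncrna; cols <- fx$embedding$ids$drug
  folds <- make_folds(fx$table, rows, cols, k = 5, seed = 3)
  key <- function(df) paste(df$ncrna_id, df$drug_id)
  for (nm in c("pos", "sen", "unk")) {
    df <- folds[[nm]]
    expect_false(anyDuplicated(key(df)) > 0)
    sizes <- tabulate(df$fold, 5)
    expect_lte(diff(range(sizes)), 1)
  }
  # coverage: pos + sen + unk tile the full pair universe
  total <- nrow(folds$pos) + nrow(folds$sen) + nrow(folds$unk)
  expect_equal(total, length(rows) * length(cols))
  # five positives with k = 5 give one per fold
  mini <- data.frame(ncrna_id = paste0("r", 1:5), drug_id = "d1",
                     label = "resistance", stringsAsFactors = FALSE)
  mini <- rbind(mini, data.frame(ncrna_id = paste0("r", 1:5), drug_id = "d2",
                                 label = "sensitivity"))
  f2 <- make_folds(mini, paste0("r", 1:5), paste0("d", 1:3), k = 5, seed = 1)
  expect_equal(sort(f2$pos$fold), 1:5)
  expect_error(make_folds(mini[1:6, ], paste0("r", 1:5), paste0("d", 1:3),
                          k = 5), "fewer members")
})

test_that("2693 positives split as 539/539/539/538/538", {
  rows <- paste0("r", 1:55); cols <- paste0("d", 1:50)
  pairs <- expand.grid(ncrna_id = rows, drug_id = cols,
                       stringsAsFactors = FALSE)
  tab <- rbind(
    data.frame(pairs[1:2693, ], label = "resistance"),
    data.frame(pairs[2694:2703, ], label = "sensitivity"))
  folds <- make_folds(tab, rows, cols, k = 5, seed = 2)
  expect_equal(sort(tabulate(folds$pos$fold, 5), decreasing = TRUE),
               sort(c(539, 539, 539, 538, 538), decreasing = TRUE))
})

test_that("per-fold GIP refresh zeroes exactly the held-out positives", {
  fx <- ci_fixture()
  rows <- fx$embedding$ids$ncrna; cols <- fx$embedding$ids$drug
  A <- build_adjacency(fx$table, rows, cols)
  folds <- make_folds(fx$table, rows, cols, k = 5, seed = 3)
  full_gip <- gip_kernel(A, "ncrna")
  for (i in c(1, 4)) {
    ref <- fold_gip_refresh(A, folds, i)
    n_test <- sum(folds$pos$fold == i)
    expect_equal(sum(A) - sum(ref$A_train), n_test)
    expect_false(isTRUE(all.equal(unclass(ref$gip_r), unclass(full_gip))))
  }
  # a row whose positives are all held out has a zero training profile
  two_rows <- data.frame(ncrna_id = c(rows[1], rows[1], rows[2]),
                         drug_id = c(cols[1], cols[2], cols[3]),
                         label = "resistance", stringsAsFactors = FALSE)
  A1 <- build_adjacency(two_rows, rows, cols)
  fake <- list(pos = data.frame(two_rows[1:2, 1:2], fold = 1L))
  ref1 <- fold_gip_refresh(A1, fake, 1)
  expect_true(all(ref1$A_train[rows[1], ] == 0))
  expect_equal(ref1$gip_r[rows[1], rows[1]], 1)
})

test_that("ranking excludes known pairs and sorts by score", {
  scores <- matrix(c(.9, .2, .8, .4, .7, .6), 2, 3,
                   dimnames = list(c("r1", "r2"), c("d1", "d2", "d3")))
  known <- data.frame(ncrna_id = c("r1", "r2"), drug_id = c("d1", "d3"),
                      label = c("resistance", "sensitivity"),
                      stringsAsFactors = FALSE)
  rk <- rank_predictions(scores, known, k = 4)
  expect_false(any(paste(rk$ncrna_id, rk$drug_id) %in%
                   paste(known$ncrna_id, known$drug_id)))
  expect_equal(rk$score, sort(rk$score, decreasing = TRUE))
  expect_equal(rk$ncrna_id[1], "r1"); expect_equal(rk$drug_id[1], "d2")
  expect_warning(rank_predictions(scores, known, k = 10), "truncating")
  # brute-force agreement on a random matrix
  set.seed(41)
  sc2 <- matrix(runif(20), 4, 5,
                dimnames = list(paste0("r", 1:4), paste0("d", 1:5)))
  rk2 <- rank_predictions(sc2, known[0, ], k = 20)
  expect_equal(rk2$score, sort(as.vector(sc2), decreasing = TRUE))
})

test_that("cohesion analysis matches its cosine definition", {
  feats <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1))
  tab <- data.frame(ncrna_id = c("a", "b", "a", "c"),
                    drug_id = c("d1", "d1", "d2", "d2"),
                    label = "resistance", stringsAsFactors = FALSE)
  co <- cohesion_analysis(feats, tab, "known")
  expect_equal(co[["d1"]], 1)      # identical vectors
  expect_equal(co[["d2"]], 0)      # orthogonal vectors
  # degree-matched random mode is seeded and spans the feature rows
  r1 <- cohesion_analysis(feats, tab, "random", seed = 5)
  r2 <- cohesion_analysis(feats, tab, "random", seed = 5)
  expect_identical(r1, r2)
  expect_error(cohesion_analysis(feats, tab, "predicted"), "score matrix")
})

test_that("the cv protocol holds its structural invariants on a micro run", {
  cfg <- micro_config(seed = 2)
  ent <- generate_entities(cfg)
  pl <- plant_associations(cfg, ent)
  cv <- dmgat_cv(ent[, c("id", "kind", "text")], pl$table, k = 2,
                 config = fast_config(gcn_layers = 1L, gat_layers = 1L),
                 seed = 2)
  expect_equal(nrow(cv$metrics), 2L)
  expect_length(cv$scores, 2L)
  expect_length(cv$negatives, 2L)
  expect_true(all(cv$audit))
  m <- as.matrix(cv$metrics[, -1])
  expect_true(all(m >= 0 & m <= 1))
  # no test positive in training edges or loss pairs, by construction
  key <- function(df) paste(df$ncrna_id, df$drug_id)
  for (i in 1:2) {
    te <- cv$folds$pos[cv$folds$pos$fold == i, ]
    tr <- cv$folds$pos[cv$folds$pos$fold != i, ]
    expect_length(intersect(key(te), key(tr)), 0L)
    expect_length(intersect(key(te), key(cv$negatives[[i]])), 0L)
  }
})

test_that("global mining mode partitions negatives by unknown fold", {
  cfg <- micro_config(seed = 6)
  ent <- generate_entities(cfg)
  pl <- plant_associations(cfg, ent)
  cv <- dmgat_cv(ent[, c("id", "kind", "text")], pl$table, k = 2,
                 config = fast_config(mine_mode = "global",
                                      gcn_layers = 1L, gat_layers = 1L),
                 seed = 6)
  expect_true(all(cv$audit))
  key <- function(df) paste(df$ncrna_id, df$drug_id)
  unk_key <- key(cv$folds$unk)
  for (i in 1:2) {
    neg <- cv$negatives[[i]]
    mined <- neg[neg$provenance == "mined_unknown", ]
    # mined training negatives come from unknowns outside the test fold
    folds_of_mined <- cv$folds$unk$fold[match(key(mined), unk_key)]
    expect_true(all(folds_of_mined != i))
  }
  # the two folds' negative sets differ (complement structure)
  expect_false(identical(key(cv$negatives[[1]]), key(cv$negatives[[2]])))
})

test_that("the layer sweep covers the requested factorial grid", {
  cfg <- micro_config(seed = 4)
  ent <- generate_entities(cfg)
  pl <- plant_associations(cfg, ent)
  grid <- sweep_layers(ent[, c("id", "kind", "text")], pl$table,
                       gcn_range = 1:2, gat_range = 1:2, k = 2,
                       config = fast_config(epochs = 20L), seed = 3)
  expect_equal(nrow(grid), 4L)
  expect_setequal(paste(grid$gcn_layers, grid$gat_layers),
                  c("1 1", "2 1", "1 2", "2 2"))
  expect_true(all(grid$auc >= 0 & grid$auc <= 1))
})

test_that("fitted model objects print, summarise, predict and plot", {
  cfg <- micro_config(seed = 5)
  ent <- generate_entities(cfg)
  pl <- plant_associations(cfg, ent)
  fit <- dmgat(ent[, c("id", "kind", "text")], pl$table,
               config = fast_config(), seed = 5)
  expect_s3_class(fit, "dmgat")
  expect_output(print(fit), "ncRNA-drug association model")
  sm <- summary(fit, k = 5)
  expect_output(print(sm), "Top predicted")
  sc <- predict(fit)
  expect_equal(dim(sc), c(cfg$n_lnc + cfg$n_mir, cfg$n_drug))
  rk <- predict(fit, type = "ranking", k = 5)
  expect_equal(nrow(rk), 5L)
  expect_false(any(paste(rk$ncrna_id, rk$drug_id) %in%
                   paste(pl$table$ncrna_id, pl$table$drug_id)))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
  # determinism of the whole fit
  fit2 <- dmgat(ent[, c("id", "kind", "text")], pl$table,
                config = fast_config(), seed = 5)
  expect_equal(fit$scores, fit2$scores, tolerance = 1e-12)
})
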