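# Evidence matrix, signal vector, abundance weights, tissue signal.

five_layers <- c("de", "gwas", "methylation", "de_novo", "open_chromatin")

test_that("evidence matrix is the binary layer-membership indicator", {
  lists <- list(de = c("P1"), gwas = character(0), methylation = c("P1"),
                de_novo = character(0), open_chromatin = character(0))
  E <- evidence_matrix(lists, c("P1", "P2"))
  expect_equal(sort(E$layers), sort(five_layers))
  expect_equal(sum(E$values["P1", ]), 2)          # DE + methylation
  expect_equal(unname(E$values["P1", c("de", "methylation")]), c(1L, 1L))
  expect_equal(sum(E$values["P2", ]), 0)          # no evidence anywhere

  # repeated hits within a layer stay binary; absent genes are dropped
  E2 <- evidence_matrix(list(de = c("P1", "P1", "P9")), c("P1", "P2"))
  expect_equal(unname(E2$values["P1", "de"]), 1L)
  expect_equal(E2$dropped$de, "P9")
  expect_error(evidence_matrix(list(de = "P1"), character(0)), "universe")
})

test_that("evidence matrix matches a set-membership oracle on random lists", {
  set.seed(404)
  genes <- sprintf("G%03d", 1:100)
  lists <- lapply(setNames(five_layers, five_layers),
                  function(ly) sample(genes, sample(5:40, 1L)))
  E <- evidence_matrix(lists, genes)
  for (ly in five_layers)
    for (g in sample(genes, 25L))
      expect_identical(E$values[g, ly] == 1L, g %in% lists[[ly]])
})

test_that("signal vector sums evidence layers (DE+methylated gene scores 2)", {
  lists <- list(de = c("P1", "P4"), gwas = "P4", methylation = c("P1", "P4"),
                de_novo = "P4", open_chromatin = character(0))
  S <- signal_vector(evidence_matrix(lists, c("P1", "P2", "P4")))
  expect_identical(S, c(P1 = 2L, P2 = 0L, P4 = 4L))
  expect_true(all(S >= 0 & S <= length(lists)))
})

test_that("signal vector is invariant under layer-order permutation", {
  set.seed(11)
  genes <- sprintf("G%02d", 1:40)
  lists <- lapply(setNames(five_layers, five_layers),
                  function(ly) sample(genes, 10L))
  s1 <- signal_vector(evidence_matrix(lists, genes))
  s2 <- signal_vector(evidence_matrix(lists[sample(five_layers)], genes))
  expect_identical(s1, s2)
})

test_that("abundance levels map to the fixed weight scale", {
  expect_equal(expression_weight("High"), 1)
  expect_equal(expression_weight("Medium"), 0.75)
  expect_equal(expression_weight("Low"), 0.5)
  expect_equal(expression_weight("Not detected"), 0.25)
  # case / whitespace / underscore normalization
  expect_equal(expression_weight(c(" high ", "NOT_DETECTED")), c(1, 0.25))
  expect_error(expression_weight("absent"), "unknown abundance")
})

test_that("weight matrix fills observed cells and imputes missing ones", {
  catalog <- tissue_catalog(c("cerebral cortex", "liver"),
                            c("neuronal cells", "hepatocytes"),
                            c(TRUE, FALSE))
  ab <- data.frame(gene_id = c("P1", "P1"),
                   tissue = c("cerebral cortex", "liver"),
                   cell_type = c("neuronal cells", "hepatocytes"),
                   level = c("High", "Low"))
  W <- build_weight_matrix(ab, catalog, c("P1", "P2"))
  expect_equal(unname(W["P1", ]), c(1, 0.5))
  expect_equal(unname(W["P2", ]), c(0.25, 0.25))     # default policy
  expect_equal(attr(W, "n_missing"), 2L)

  W9 <- build_weight_matrix(ab, catalog, c("P1", "P2"), missing_weight = 0.9)
  expect_equal(unname(W9["P2", ]), c(0.9, 0.9))

  conflict <- rbind(ab, data.frame(gene_id = "P1", tissue = "liver",
                                   cell_type = "hepatocytes", level = "High"))
  expect_error(build_weight_matrix(conflict, catalog, "P1"), "conflicting")
})

test_that("weight matrix matches a per-cell dictionary-lookup oracle", {
  set.seed(55)
  genes <- sprintf("G%02d", 1:30)
  catalog <- tissue_catalog(paste0("tissue", 1:6), paste0("cell", 1:6),
                            c(TRUE, TRUE, rep(FALSE, 4L)))
  rows <- expand.grid(gene_id = genes, col = seq_len(6L),
                      stringsAsFactors = FALSE)
  rows <- rows[runif(nrow(rows)) < 0.7, ]           # leave some missing
  ab <- data.frame(gene_id = rows$gene_id,
                   tissue = catalog$tissue[rows$col],
                   cell_type = catalog$cell_type[rows$col],
                   level = sample(c("High", "Medium", "Low", "Not detected"),
                                  nrow(rows), replace = TRUE))
  W <- build_weight_matrix(ab, catalog, genes)
  map <- c(High = 1, Medium = 0.75, Low = 0.5, `Not detected` = 0.25)
  for (k in sample(nrow(ab), 50L)) {
    lab <- paste(ab$tissue[k], ab$cell_type[k], sep = "|")
    expect_identical(W[ab$gene_id[k], lab], unname(map[ab$level[k]]))
  }
  seen <- paste(ab$gene_id, ab$tissue)
  for (g in genes)
    for (j in seq_len(6L))
      if (!(paste(g, catalog$tissue[j]) %in% seen))
        expect_identical(W[g, catalog$label[j]], 0.25)
})

test_that("tissue signal is the columnwise product w_ij * S_i", {
  W <- matrix(c(0.75, 1, 0.5, 0.25), 2L, 2L,
              dimnames = list(c("P1", "P2"), c("a|x", "b|y")))
  S <- c(P1 = 2L, P2 = 3L)
  Sst <- tissue_signal(W, S)
  expect_equal(Sst["P1", "a|x"], 1.5)               # 2 x 0.75
  expect_equal(Sst["P2", "b|y"], 0.75)
  expect_equal(unname(Sst["P2", "a|x"]), 3)         # weight 1 is identity

  set.seed(66)
  W2 <- matrix(sample(c(1, .75, .5, .25), 50 * 8, TRUE), 50L, 8L)
  S2 <- sample(0:5, 50L, TRUE)
  out <- tissue_signal(W2, S2)
  for (i in sample(50L, 10L))
    for (j in seq_len(8L))
      expect_identical(out[i, j], W2[i, j] * S2[i])
  expect_error(tissue_signal(W2, S2[-1L]), "alignment")

  Wn <- W
  rownames(Wn) <- c("P2", "P1")
  expect_error(tissue_signal(Wn, S), "alignment")
})

test_that("S* row maxima respect the weight ceiling and all-High collapses to S", {
  set.seed(13)
  G <- 40L; T <- 6L
  W <- matrix(sample(c(1, .75, .5, .25), G * T, TRUE), G, T)
  S <- sample(1:5, G, TRUE)
  Sst <- tissue_signal(W, S)
  for (i in seq_len(G)) {
    if (any(W[i, ] == 1)) expect_equal(max(Sst[i, ]), S[i])
    else expect_lt(max(Sst[i, ]), S[i])
  }
  all_high <- tissue_signal(matrix(1, G, T), S)
  expect_equal(all_high, matrix(rep(S, T), G, T))
})
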