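# Seeded input generators and the hand-checkable worked example.

test_that("generation is deterministic given the seed", {
  sp <- synthetic_spec(n_nodes = 120L, rng_seed = 9L)
  a <- generate_inputs(sp)
  b <- generate_inputs(sp)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- generate_inputs(synthetic_spec(n_nodes = 120L, rng_seed = 10L))
  expect_false(identical(a$edges, c$edges))
})

test_that("edge counts follow the requested random-graph model", {
  empty <- generate_inputs(synthetic_spec(n_nodes = 50L, p = 0,
                                          n_seed_genes = 5L, rng_seed = 3L))
  expect_equal(nrow(empty$edges), 0L)

  sp <- synthetic_spec(n_nodes = 500L, p = 0.02, rng_seed = 7L)
  si <- generate_inputs(sp)
  m <- choose(500L, 2L)
  expected <- 0.02 * m
  sd3 <- 3 * sqrt(m * 0.02 * 0.98)
  expect_gt(nrow(si$edges), expected - sd3)
  expect_lt(nrow(si$edges), expected + sd3)

  ba <- generate_inputs(synthetic_spec(n_nodes = 200L, edge_model = "ba",
                                       ba_m = 3L, rng_seed = 5L))
  deg <- table(c(ba$edges$protein_a, ba$edges$protein_b))
  expect_gt(max(deg), 3 * stats::median(as.integer(deg)))  # hub-heavy tail
})

test_that("planted modules are wired, co-localized, and brain-High", {
  si <- generate_inputs(planted_world())
  expect_length(si$module_nodes, 25L)
  expect_setequal(si$seed_genes, si$module_nodes)

  # internal wiring near p_within on top of the background
  pairs <- utils::combn(si$module_nodes, 2L)
  key <- paste(pmin(si$edges$protein_a, si$edges$protein_b),
               pmax(si$edges$protein_a, si$edges$protein_b))
  wired <- mean(paste(pmin(pairs[1L, ], pairs[2L, ]),
                      pmax(pairs[1L, ], pairs[2L, ])) %in% key)
  expect_gt(wired, 0.5)

  # shared micro-domain on every module node
  loc <- localization_annotation(si$localization)
  shared <- Reduce(intersect, loc$assignments[si$module_nodes])
  expect_gte(length(shared), 1L)

  # abundance: High in every brain column, never High elsewhere
  ab <- si$abundance[si$abundance$gene_id %in% si$module_nodes, ]
  lab <- paste(ab$tissue, ab$cell_type, sep = "|")
  brain <- lab %in% si$catalog$label[si$catalog$is_brain]
  expect_true(all(ab$level[brain] == "High"))
  expect_true(all(ab$level[!brain] %in% c("Low", "Not detected")))
})

test_that("null signatures avoid the planted module", {
  sp <- synthetic_spec(n_nodes = 300L, p = 0.02, n_seed_genes = 25L,
                       planted_module = list(size = 25L, p_within = 0.6),
                       null_signatures = TRUE, rng_seed = 11L)
  si <- generate_inputs(sp)
  expect_length(intersect(si$seed_genes, si$module_nodes), 0L)
})

test_that("generated bundles round-trip through every loader", {
  si <- generate_inputs(synthetic_spec(n_nodes = 80L, p = 0.06,
                                       n_seed_genes = 10L, rng_seed = 2L))
  dir <- withr::local_tempdir()
  write_input_bundle(si, dir)
  expect_setequal(list.files(dir),
                  c("edges.tsv", "localization.tsv", "abundance.tsv",
                    "catalog.tsv", "evidence", "manifest.json"))

  net <- load_edge_list(file.path(dir, "edges.tsv"))
  expect_equal(nrow(net$edges), nrow(si$edges))
  loc <- load_localizations(file.path(dir, "localization.tsv"))
  expect_setequal(names(loc$assignments),
                  unique(si$localization$protein_id))
  ab <- read_abundance(file.path(dir, "abundance.tsv"))
  expect_equal(nrow(ab), nrow(si$abundance))
  evid <- read_evidence_dir(file.path(dir, "evidence"))
  expect_setequal(names(evid), names(si$evidence))
  expect_setequal(unname(unlist(evid)), unname(unlist(si$evidence)))
  cat2 <- read_catalog(file.path(dir, "catalog.tsv"))
  expect_equal(cat2$label, si$catalog$label)
  expect_equal(cat2$is_brain, si$catalog$is_brain)
})

test_that("infeasible specs are rejected up front", {
  expect_error(synthetic_spec(n_nodes = 10L, n_seed_genes = 5L,
                              planted_module = list(size = 20L)),
               "larger than the graph")
  expect_error(synthetic_spec(n_nodes = 50L, n_seed_genes = 30L,
                              planted_module = list(size = 10L)),
               "fewer planted-module genes")
})

test_that("the worked example carries its documented intermediates", {
  fx <- worked_example_fixture()
  net <- ppi_network(fx$edges)
  loc <- localization_annotation(fx$localization)
  A <- build_affinity(net, loc)
  Am <- as.matrix(A$values)

  expect_equal(Am["P1", "P2"], 1.5)                 # the one amplified pair
  expect_equal(sum(Am == 1.5), 2L)
  expect_equal(unname(degree_vector(A)), c(2.5, 2.5, 3, 2, 1))

  S <- signal_vector(evidence_matrix(fx$evidence, net$nodes))
  expect_identical(S, c(P1 = 2L, P2 = 0L, P3 = 1L, P4 = 0L, P5 = 0L))

  W <- build_weight_matrix(fx$abundance, fx$catalog, net$nodes)
  expect_equal(unname(W["P1", ]), c(1, 0.5))
  Sst <- tissue_signal(W, S)
  expect_equal(unname(Sst["P1", ]), c(2, 1))

  # end-to-end against the dense oracle pipeline
  pl <- run_pipeline(fx, verbose = FALSE)
  O <- oracle_affinity(net$nodes, fx$edges,
                       split(fx$localization$micro_domain,
                             fx$localization$protein_id), 1.5)
  dense <- oracle_power_apply(oracle_transition(O), Sst, pl$result$t_stop)
  expect_lt(max(abs(pl$result$smoothed - dense)), 1e-12)
  expect_lte(pl$result$diagnostics$r[pl$result$t_stop], 0.05)
})
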