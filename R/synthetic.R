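# Seeded generators for every pipeline input, with plantable modules
# for leave-one-out recovery experiments.

.domain_pool <- c("Nucleus", "Cytosol", "Vesicles", "Mitochondria",
                  "Plasma membrane", "Endoplasmic reticulum",
                  "Golgi apparatus", "Nucleoli", "Centrosome",
                  "Microtubules", "Actin filaments", "Nuclear speckles",
                  "Nuclear bodies", "Peroxisomes", "Lysosomes",
                  "Cell junctions")

.brain_pool <- list(c("cerebral cortex", "neuronal cells"),
                    c("cerebellum", "Purkinje cells"),
                    c("hippocampus", "neuronal cells"),
                    c("caudate", "neuronal cells"),
                    c("cerebral cortex", "glial cells"),
                    c("cerebellum", "cells in granular layer"))

.other_pool <- list(c("liver", "hepatocytes"),
                    c("lung", "pneumocytes"),
                    c("heart muscle", "cardiomyocytes"),
                    c("kidney", "cells in tubules"),
                    c("pancreas", "islet cells"),
                    c("skin", "keratinocytes"),
                    c("colon", "enterocytes"),
                    c("testis", "Leydig cells"),
                    c("spleen", "lymphocytes"),
                    c("stomach", "glandular cells"),
                    c("thyroid", "glandular cells"),
                    c("adrenal gland", "cortical cells"),
                    c("skeletal muscle", "myocytes"),
                    c("bone marrow", "hematopoietic cells"),
                    c("ovary", "follicle cells"),
                    c("prostate", "glandular cells"),
                    c("esophagus", "squamous cells"),
                    c("bladder", "urothelial cells"),
                    c("placenta", "trophoblasts"),
                    c("salivary gland", "glandular cells"))

.default_layers <- c("de", "gwas", "methylation", "de_novo", "open_chromatin")

#' Specification of a synthetic input bundle
#'
#' Describes the random world the generator emulates: a PPI-like graph
#' (Erdős–Rényi for exchangeable nulls or Barabási–Albert for hub-heavy
#' realism), random micro-domain assignments, qualitative abundance
#' levels per tissue/cell column, and per-layer Bernoulli evidence on a
#' set of seed genes. An optional planted module concentrates seed genes
#' into a densely wired, co-localized cluster with High abundance in the
#' brain columns — the ground truth the recovery tests look for.
#'
#' Defaults describe a workstation-scale instance: a 200-node
#' Erdős–Rényi graph at edge probability 0.05, 8 micro-domains with
#' about one assignment per protein, 10 tissue/cell columns of which 2
#' are brain, 5 omics layers, and 20 seed genes with per-layer hit
#' probability 0.4.
#'
#' @param n_nodes number of proteins.
#' @param edge_model `"er"` (Erdős–Rényi `G(n, p)`) or `"ba"`
#'   (Barabási–Albert preferential attachment).
#' @param p edge probability for the ER model.
#' @param ba_m edges added per step for the BA model.
#' @param n_domains size of the micro-domain catalog.
#' @param domain_lambda Poisson mean of the per-protein domain count
#'   (capped at `n_domains`; zero-domain proteins are legitimate).
#' @param n_tissues number of (tissue, cell-type) columns.
#' @param brain_columns how many of them are flagged as brain.
#' @param n_layers number of omics evidence layers.
#' @param n_seed_genes number of genes carrying evidence.
#' @param evidence_prob per-layer Bernoulli hit probability for seed
#'   genes (at least one hit is enforced so every seed has `S_i > 0`).
#' @param planted_module `NULL`, or a list with `size`, `p_within`
#'   (internal wiring probability) and `brain_high` (force High
#'   abundance in brain columns and Low / Not detected elsewhere).
#' @param null_signatures draw the evidence genes disjoint from the
#'   planted module, to measure background rates against a module that
#'   carries no signal.
#' @param rng_seed integer seed controlling all randomness.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_nodes = 200L, edge_model = c("er", "ba"),
                           p = 0.05, ba_m = 3L, n_domains = 8L,
                           domain_lambda = 1.2, n_tissues = 10L,
                           brain_columns = 2L, n_layers = 5L,
                           n_seed_genes = 20L, evidence_prob = 0.4,
                           planted_module = NULL, null_signatures = FALSE,
                           rng_seed = 1L) {
  edge_model <- match.arg(edge_model)
  stopifnot(n_nodes >= 2L, p >= 0, p <= 1, n_domains >= 1L,
            n_tissues >= 1L, brain_columns >= 1L,
            brain_columns <= n_tissues, n_layers >= 1L,
            n_seed_genes >= 1L, n_seed_genes <= n_nodes,
            evidence_prob > 0, evidence_prob <= 1)
  if (!is.null(planted_module)) {
    planted_module <- modifyList(list(size = 15L, p_within = 0.8,
                                      brain_high = TRUE), planted_module)
    if (planted_module$size > n_nodes)
      stop("infeasible spec: planted module larger than the graph")
    if (planted_module$p_within < 0 || planted_module$p_within > 1)
      stop("'p_within' must lie in [0, 1]")
    if (!null_signatures && planted_module$size < n_seed_genes)
      stop("infeasible spec: fewer planted-module genes than seed genes")
  }
  structure(list(n_nodes = as.integer(n_nodes), edge_model = edge_model,
                 p = p, ba_m = as.integer(ba_m),
                 n_domains = as.integer(n_domains),
                 domain_lambda = domain_lambda,
                 n_tissues = as.integer(n_tissues),
                 brain_columns = as.integer(brain_columns),
                 n_layers = as.integer(n_layers),
                 n_seed_genes = as.integer(n_seed_genes),
                 evidence_prob = evidence_prob,
                 planted_module = planted_module,
                 null_signatures = null_signatures,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

.make_catalog <- function(n_tissues, brain_columns) {
  pick <- function(pool, k, prefix) {
    if (k <= length(pool)) {
      m <- do.call(rbind, pool[seq_len(k)])
    } else {
      extra <- cbind(paste0(prefix, "_tissue_", seq_len(k - length(pool))),
                     paste0(prefix, "_cells_", seq_len(k - length(pool))))
      m <- rbind(do.call(rbind, pool), extra)
    }
    m
  }
  b <- pick(.brain_pool, brain_columns, "brain")
  o <- pick(.other_pool, n_tissues - brain_columns, "other")
  if (n_tissues - brain_columns == 0L) o <- NULL
  m <- rbind(b, o)
  tissue_catalog(m[, 1L], m[, 2L],
                 c(rep(TRUE, brain_columns),
                   rep(FALSE, n_tissues - brain_columns)))
}

.layer_names <- function(L) {
  if (L <= length(.default_layers)) .default_layers[seq_len(L)]
  else c(.default_layers, paste0("layer_", seq_len(L - length(.default_layers))))
}

#' Generate a synthetic input bundle
#'
#' Draws every input the pipeline consumes — edge list, localization
#' table, abundance table, per-layer evidence gene lists, and the
#' tissue/cell catalog — deterministically from the spec's seed. When a
#' planted module is requested, its nodes are mutually wired at
#' `p_within` (on top of the background graph), share one dedicated
#' micro-domain, and (if `brain_high`) carry High abundance in every
#' brain column and Low / Not detected elsewhere; seed genes are the
#' module nodes unless `null_signatures` diverts the evidence away from
#' the module.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_inputs` with `edges` (data frame),
#'   `localization` (data frame), `abundance` (data frame), `evidence`
#'   (named list of gene vectors), `catalog` ([tissue_catalog()]),
#'   `seed_genes`, `module_nodes`, and the `spec` itself.
#' @export
generate_inputs <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("'spec' must be a synthetic_spec")
  set.seed(spec$rng_seed)
  n <- spec$n_nodes
  nodes <- sprintf("G%04d", seq_len(n))

  g <- if (spec$edge_model == "er") {
    igraph::sample_gnp(n, spec$p)
  } else {
    igraph::sample_pa(n, m = spec$ba_m, directed = FALSE)
  }
  el <- igraph::as_edgelist(g, names = FALSE)

  module_nodes <- character(0)
  if (!is.null(spec$planted_module)) {
    mod <- sort(sample.int(n, spec$planted_module$size))
    module_nodes <- nodes[mod]
    pairs <- utils::combn(mod, 2L)
    wire <- runif(ncol(pairs)) < spec$planted_module$p_within
    el <- rbind(el, t(pairs[, wire, drop = FALSE]))
  }
  if (nrow(el)) {
    lo <- pmin(el[, 1L], el[, 2L])
    hi <- pmax(el[, 1L], el[, 2L])
    keep <- !duplicated(paste(lo, hi)) & lo != hi
    edges <- data.frame(protein_a = nodes[lo[keep]],
                        protein_b = nodes[hi[keep]],
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(protein_a = character(0), protein_b = character(0),
                        stringsAsFactors = FALSE)
  }

  domains <- if (spec$n_domains <= length(.domain_pool))
    .domain_pool[seq_len(spec$n_domains)]
  else c(.domain_pool,
         paste0("domain_", seq_len(spec$n_domains - length(.domain_pool))))
  k_dom <- pmin(rpois(n, spec$domain_lambda), spec$n_domains)
  loc_rows <- lapply(seq_len(n), function(i) {
    if (k_dom[i] == 0L) return(NULL)
    data.frame(protein_id = nodes[i],
               micro_domain = sample(domains, k_dom[i]),
               stringsAsFactors = FALSE)
  })
  localization <- do.call(rbind, loc_rows) %||%
    data.frame(protein_id = character(0), micro_domain = character(0))
  if (length(module_nodes)) {
    shared <- domains[1L]
    extra <- data.frame(protein_id = module_nodes, micro_domain = shared,
                        stringsAsFactors = FALSE)
    localization <- unique(rbind(localization, extra))
  }

  catalog <- .make_catalog(spec$n_tissues, spec$brain_columns)
  levels_pool <- c("High", "Medium", "Low", "Not detected")
  lv <- matrix(sample(levels_pool, n * spec$n_tissues, replace = TRUE,
                      prob = c(0.15, 0.30, 0.30, 0.25)),
               nrow = n, ncol = spec$n_tissues)
  if (length(module_nodes) && isTRUE(spec$planted_module$brain_high)) {
    mi <- match(module_nodes, nodes)
    lv[mi, catalog$is_brain] <- "High"
    lv[mi, !catalog$is_brain] <- sample(c("Low", "Not detected"),
                                        length(mi) * sum(!catalog$is_brain),
                                        replace = TRUE)
  }
  abundance <- data.frame(
    gene_id = rep(nodes, times = spec$n_tissues),
    tissue = rep(catalog$tissue, each = n),
    cell_type = rep(catalog$cell_type, each = n),
    level = as.vector(lv),
    stringsAsFactors = FALSE)

  if (spec$null_signatures) {
    pool <- setdiff(nodes, module_nodes)
    if (length(pool) < spec$n_seed_genes)
      stop("infeasible spec: not enough genes outside the module for null signatures")
    seed_genes <- sort(sample(pool, spec$n_seed_genes))
  } else if (length(module_nodes)) {
    seed_genes <- sort(sample(module_nodes, spec$n_seed_genes))
  } else {
    seed_genes <- sort(sample(nodes, spec$n_seed_genes))
  }
  layers <- .layer_names(spec$n_layers)
  hit <- matrix(rbinom(length(seed_genes) * spec$n_layers, 1L,
                       spec$evidence_prob) == 1L,
                nrow = length(seed_genes))
  none <- which(rowSums(hit) == 0L)
  for (i in none) hit[i, sample.int(spec$n_layers, 1L)] <- TRUE
  evidence <- lapply(seq_len(spec$n_layers),
                     function(j) seed_genes[hit[, j]])
  names(evidence) <- layers

  structure(list(edges = edges, localization = localization,
                 abundance = abundance, evidence = evidence,
                 catalog = catalog, seed_genes = seed_genes,
                 module_nodes = module_nodes, spec = spec),
            class = "synthetic_inputs")
}

#' Write a synthetic input bundle to disk
#'
#' Emits exactly the delimited formats the loaders consume —
#' `edges.tsv`, `localization.tsv`, `abundance.tsv`, `catalog.tsv`, one
#' `evidence/<layer>.txt` gene list per layer — plus `manifest.json`
#' recording the spec and seed.
#'
#' @param inputs a [generate_inputs()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_input_bundle <- function(inputs, dir) {
  if (!inherits(inputs, "synthetic_inputs"))
    stop("'inputs' must come from generate_inputs()")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "evidence"), showWarnings = FALSE)
  tsv <- function(df, name)
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  tsv(inputs$edges, "edges.tsv")
  tsv(inputs$localization, "localization.tsv")
  tsv(inputs$abundance, "abundance.tsv")
  tsv(inputs$catalog[, c("tissue", "cell_type", "is_brain")], "catalog.tsv")
  for (ly in names(inputs$evidence))
    writeLines(inputs$evidence[[ly]],
               file.path(dir, "evidence", paste0(ly, ".txt")))
  spec <- inputs$spec
  class(spec) <- NULL
  jsonlite::write_json(
    list(spec = spec, seed_genes = inputs$seed_genes,
         module_nodes = inputs$module_nodes,
         package_version = as.character(packageVersion("netdiffuse"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, null = "null",
    pretty = TRUE)
  invisible(dir)
}

#' Hand-checkable five-protein worked example
#'
#' A fixed miniature instance used across the unit tests: five proteins
#' P1..P5 on the edges P1–P2, P1–P3, P2–P3, P3–P4, P4–P5; P1 and P2
#' share the Nucleus micro-domain (the only amplified pair), P3 sits in
#' the Cytosol, P5 in Vesicles, P4 is unannotated. Five omics layers;
#' P1 is hit in the differential-expression and methylation layers
#' (signal 2), P3 only in the GWAS layer (signal 1). Two tissue
#' columns: (cerebral cortex, neuronal cells) flagged brain, and
#' (liver, hepatocytes).
#'
#' The documented intermediates: affinity entry `A[P1,P2] = 1.5` and
#' `A[P2,P3] = 1`; degrees (2.5, 2.5, 3, 2, 1); abundance weights put
#' P1 at (1, 0.5), so its tissue signal row is (2, 1).
#'
#' @return A `synthetic_inputs`-shaped list (edges, localization,
#'   abundance, evidence, catalog, seed_genes).
#' @export
worked_example_fixture <- function() {
  edges <- data.frame(
    protein_a = c("P1", "P1", "P2", "P3", "P4"),
    protein_b = c("P2", "P3", "P3", "P4", "P5"),
    stringsAsFactors = FALSE)
  localization <- data.frame(
    protein_id = c("P1", "P2", "P3", "P5"),
    micro_domain = c("Nucleus", "Nucleus", "Cytosol", "Vesicles"),
    stringsAsFactors = FALSE)
  catalog <- tissue_catalog(c("cerebral cortex", "liver"),
                            c("neuronal cells", "hepatocytes"),
                            c(TRUE, FALSE))
  abundance <- data.frame(
    gene_id = rep(c("P1", "P2", "P3", "P4", "P5"), each = 2L),
    tissue = rep(catalog$tissue, 5L),
    cell_type = rep(catalog$cell_type, 5L),
    level = c("High", "Low",
              "Medium", "Low",
              "Medium", "Medium",
              "Low", "High",
              "Not detected", "High"),
    stringsAsFactors = FALSE)
  evidence <- list(de = "P1", gwas = "P3", methylation = "P1",
                   de_novo = character(0), open_chromatin = character(0))
  structure(list(edges = edges, localization = localization,
                 abundance = abundance, evidence = evidence,
                 catalog = catalog, seed_genes = c("P1", "P3"),
                 module_nodes = character(0), spec = NULL),
            class = "synthetic_inputs")
}
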