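# Post-diffusion ranking: per-gene argmax location, brain-unique sets,
# known/novel split, leave-one-out recovery.

#' Classify genes by the tissue location of their signal maximum
#'
#' Each gene is scored by its own post-diffusion profile: the set of
#' columns attaining its row-wise maximum (after rounding to
#' `digits = 12` significant digits to absorb floating-point noise).
#' Genes with a positive maximum fall into exactly one of three classes:
#' * `brain_unique` — every argmax column is a brain column (the max
#'   strictly exceeds every non-brain column);
#' * `brain_and_elsewhere` — the maximum is attained in the brain and in
#'   at least one other tissue (ties across compartments);
#' * `non_brain` — no argmax column is a brain column.
#' Genes whose profile is identically zero are labelled `no_signal`.
#' `is_seed` marks genes with nonzero input signal (known evidence);
#' brain-unique non-seed genes are the novel candidates.
#'
#' @param result a [run_diffusion()] result or a G x T matrix with gene
#'   rownames and catalog-label colnames.
#' @param catalog a [tissue_catalog()] describing the columns; must flag
#'   at least one brain column.
#' @param seed_signal named signal vector from [signal_vector()]; genes
#'   absent from it count as non-seed.
#' @param digits significant digits used for tie comparison.
#' @return Data frame of class `ranked_genes` with columns `gene_id`,
#'   `class`, `is_seed`, `max_intensity`, `argmax_columns`
#'   (semicolon-joined labels); the per-column intensity matrix is kept
#'   in attribute `intensities` and per-column ranks (ties = min) in
#'   attribute `column_ranks`.
#' @export
classify_genes <- function(result, catalog, seed_signal, digits = 12L) {
  X <- if (inherits(result, "diffusion_result")) result$smoothed else as.matrix(result)
  if (!inherits(catalog, "tissue_catalog")) stop("'catalog' must be a tissue_catalog")
  if (ncol(X) != nrow(catalog))
    stop("result has ", ncol(X), " columns but the catalog describes ",
         nrow(catalog))
  brain <- which(catalog$is_brain)
  if (!length(brain))
    stop("configuration error: catalog flags no brain columns")
  genes <- rownames(X) %||% paste0("g", seq_len(nrow(X)))
  s <- seed_signal[genes]
  s[is.na(s)] <- 0
  Xr <- signif(X, digits)
  mx <- apply(Xr, 1L, max)
  cls <- character(nrow(X))
  argmax_chr <- character(nrow(X))
  for (g in seq_len(nrow(X))) {
    if (mx[g] <= 0) {
      cls[g] <- "no_signal"
      argmax_chr[g] <- ""
      next
    }
    am <- which(Xr[g, ] == mx[g])
    inb <- am %in% brain
    cls[g] <- if (all(inb)) "brain_unique"
              else if (any(inb)) "brain_and_elsewhere"
              else "non_brain"
    argmax_chr[g] <- paste(catalog$label[am], collapse = ";")
  }
  out <- data.frame(gene_id = genes,
                    class = cls,
                    is_seed = as.numeric(s) > 0,
                    max_intensity = unname(mx),
                    argmax_columns = argmax_chr,
                    stringsAsFactors = FALSE)
  attr(out, "intensities") <- X
  attr(out, "column_ranks") <- apply(-X, 2L, rank, ties.method = "min")
  attr(out, "catalog") <- catalog
  class(out) <- c("ranked_genes", "data.frame")
  out
}

#' Per-column counts of top-ranked genes
#'
#' For every (tissue, cell-type) column, counts the genes whose argmax
#' set includes that column, split into seed (known evidence) and
#' non-seed (novel) genes. A gene tied across several columns is counted
#' in each, so the column counts can sum to more than the gene count.
#'
#' @param table a [classify_genes()] result.
#' @return Data frame with columns `label`, `tissue`, `cell_type`,
#'   `is_brain`, `n_seed`, `n_novel`, `n_total`.
#' @export
summarize_by_column <- function(table) {
  if (!inherits(table, "ranked_genes")) stop("'table' must come from classify_genes()")
  catalog <- attr(table, "catalog")
  hits <- strsplit(table$argmax_columns, ";", fixed = TRUE)
  n_seed <- n_novel <- setNames(integer(nrow(catalog)), catalog$label)
  for (g in seq_len(nrow(table))) {
    h <- hits[[g]]
    if (!length(h) || identical(h, "")) next
    if (table$is_seed[g]) n_seed[h] <- n_seed[h] + 1L else n_novel[h] <- n_novel[h] + 1L
  }
  data.frame(label = catalog$label, tissue = catalog$tissue,
             cell_type = catalog$cell_type, is_brain = catalog$is_brain,
             n_seed = unname(n_seed), n_novel = unname(n_novel),
             n_total = unname(n_seed + n_novel),
             stringsAsFactors = FALSE)
}

#' Leave-one-out recovery of seed genes
#'
#' Repeats the diffusion while removing, one trial at a time, a seed
#' gene whose post-diffusion maximum lies in the brain: the gene's
#' entire evidence row is zeroed (all layers — the strongest removal;
#' set `layers` to restrict it), the signal and tissue matrices are
#' rebuilt, the diffusion is rerun on the unchanged network, and the
#' trial is scored as recovered when the removed gene's new maximum
#' still falls in a brain column — i.e. the network neighborhood alone
#' re-identifies the gene's tissue of action.
#'
#' @param pipeline a [run_pipeline()] result.
#' @param seeds_to_remove genes to remove, one per trial; default
#'   samples `n_trials` genes from the seed genes whose argmax includes
#'   a brain column.
#' @param n_trials number of trials when sampling (default 20).
#' @param rng_seed integer seed for the trial sampling.
#' @param layers evidence layers to zero; `NULL` (default) removes all.
#' @return list of class `holdout_report`: `trials` (data frame with
#'   gene, recovered flag, t_stop) and `recovery_fraction`.
#' @export
holdout_recovery <- function(pipeline, seeds_to_remove = NULL,
                             n_trials = 20L, rng_seed = 1L, layers = NULL) {
  if (!inherits(pipeline, "diffusion_pipeline"))
    stop("'pipeline' must come from run_pipeline()")
  ranked <- pipeline$ranked
  brain_labels <- pipeline$catalog$label[pipeline$catalog$is_brain]
  argmax_in_brain <- vapply(strsplit(ranked$argmax_columns, ";", fixed = TRUE),
                            function(h) any(h %in% brain_labels), logical(1L))
  pool <- ranked$gene_id[ranked$is_seed & argmax_in_brain]
  if (is.null(seeds_to_remove)) {
    if (!length(pool))
      stop("no seed genes with a brain-column maximum to sample from")
    set.seed(rng_seed)
    seeds_to_remove <- sample(pool, n_trials,
                              replace = n_trials > length(pool))
  }
  bad <- setdiff(seeds_to_remove, pipeline$evidence$genes)
  if (length(bad))
    stop("removed gene(s) not in the working universe: ",
         paste(bad, collapse = ", "))
  not_seed <- setdiff(seeds_to_remove,
                      names(pipeline$signal)[pipeline$signal > 0])
  if (length(not_seed))
    stop("gene(s) to remove carry no evidence: ",
         paste(not_seed, collapse = ", "))
  trials <- lapply(seeds_to_remove, function(g) {
    E2 <- pipeline$evidence
    if (is.null(layers)) E2$values[g, ] <- 0L else E2$values[g, layers] <- 0L
    S2 <- signal_vector(E2)
    S_star2 <- tissue_signal(pipeline$weights, S2)
    res2 <- rediffuse(pipeline, S_star2)
    row <- signif(res2$smoothed[g, ], 12L)
    recovered <- max(row) > 0 &&
      any(colnames(res2$smoothed)[row == max(row)] %in% brain_labels)
    data.frame(gene = g, recovered = recovered, t_stop = res2$t_stop,
               stringsAsFactors = FALSE)
  })
  trials <- do.call(rbind, trials)
  structure(list(trials = trials,
                 recovery_fraction = mean(trials$recovered)),
            class = "holdout_report")
}

#' @export
print.holdout_report <- function(x, ...) {
  cat(sprintf("holdout recovery: %d trials, %.1f%% recovered\n",
              nrow(x$trials), 100 * x$recovery_fraction))
  invisible(x)
}

# Rerun the diffusion of a fitted pipeline on a new signal matrix,
# keeping the operator, isolate handling, and termination settings.
rediffuse <- function(pipeline, S_star_full) {
  cfg <- pipeline$config
  active <- pipeline$transition$nodes
  res <- run_diffusion(pipeline$transition,
                       S_star_full[active, , drop = FALSE],
                       r_threshold = cfg$r_threshold, t_max = cfg$t_max,
                       operator = cfg$operator)
  res$smoothed <- splice_isolates(res$smoothed, S_star_full, active)
  res
}

# Reassemble the full gene x tissue matrix: diffused rows for active
# nodes, untouched input rows for isolates.
splice_isolates <- function(smoothed_active, S_star_full, active_nodes) {
  full <- as.matrix(S_star_full)
  full[active_nodes, ] <- smoothed_active
  full
}
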