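# Evidence matrix, signal vector, abundance weights, tissue signal matrix.

#' Tissue / cell-type catalog
#'
#' The columns of the tissue-specific signal matrix: unique
#' (tissue, cell_type) pairs, a subset of which are flagged as the
#' target compartment (called "brain" throughout, after the intended
#' use on neuropsychiatric traits, though any tissue set can be
#' flagged).
#'
#' @param tissue,cell_type character vectors of equal length.
#' @param is_brain logical vector flagging target columns.
#' @return A data frame of class `tissue_catalog` with columns `tissue`,
#'   `cell_type`, `is_brain`, and the display `label` "tissue|cell".
#' @export
tissue_catalog <- function(tissue, cell_type, is_brain) {
  tissue <- trimws(as.character(tissue))
  cell_type <- trimws(as.character(cell_type))
  is_brain <- as.logical(is_brain)
  if (length(tissue) != length(cell_type) ||
      length(tissue) != length(is_brain))
    stop("'tissue', 'cell_type' and 'is_brain' must have equal length")
  if (anyNA(is_brain)) stop("'is_brain' must be TRUE/FALSE with no NA")
  label <- paste(tissue, cell_type, sep = "|")
  if (anyDuplicated(label))
    stop("duplicate (tissue, cell_type) pairs: ",
         paste(unique(label[duplicated(label)]), collapse = ", "))
  structure(data.frame(tissue = tissue, cell_type = cell_type,
                       is_brain = is_brain, label = label,
                       stringsAsFactors = FALSE),
            class = c("tissue_catalog", "data.frame"))
}

#' Read a tissue/cell catalog from a delimited file
#'
#' Expects header columns (tissue, cell_type, is_brain).
#'
#' @param path file to read.
#' @return A [tissue_catalog()].
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("tissue", "cell_type", "is_brain")
  if (!all(need %in% names(df)))
    stop("catalog must have columns: ", paste(need, collapse = ", "))
  tissue_catalog(df$tissue, df$cell_type, df$is_brain)
}

#' Build the binary evidence matrix
#'
#' `e_ij = 1` iff gene i appears in the gene list of omics layer j
#' (differential expression, GWAS, methylation, ...). Layers are
#' pre-thresholded upstream; a gene hit by several studies within one
#' layer still scores a single 1. Layer order is canonicalized
#' alphabetically. Genes listed in a layer but absent from the working
#' universe are dropped and recorded in the `dropped` field.
#'
#' @param layer_gene_lists named list, one character vector of gene IDs
#'   per omics layer.
#' @param gene_universe ordered character vector of the genes (rows).
#' @return Object of class `evidence`: list with `values` (G x L binary
#'   matrix, dimnames genes x layers), `genes`, `layers`, `dropped`
#'   (named list of IDs outside the universe).
#' @export
evidence_matrix <- function(layer_gene_lists, gene_universe) {
  if (!length(gene_universe)) stop("empty gene universe")
  gene_universe <- as.character(gene_universe)
  if (anyDuplicated(gene_universe)) stop("gene universe has duplicates")
  if (is.null(names(layer_gene_lists)) ||
      anyDuplicated(names(layer_gene_lists)))
    stop("layer lists must have unique names")
  layers <- sort(names(layer_gene_lists))
  E <- matrix(0L, nrow = length(gene_universe), ncol = length(layers),
              dimnames = list(gene_universe, layers))
  dropped <- list()
  for (ly in layers) {
    g <- unique(as.character(layer_gene_lists[[ly]]))
    out <- setdiff(g, gene_universe)
    if (length(out)) dropped[[ly]] <- out
    E[intersect(g, gene_universe), ly] <- 1L
  }
  structure(list(values = E, genes = gene_universe, layers = layers,
                 dropped = dropped),
            class = "evidence")
}

#' @export
print.evidence <- function(x, ...) {
  cat(sprintf("evidence matrix: %d genes x %d layers, %d hits (%d IDs dropped)\n",
              nrow(x$values), ncol(x$values), sum(x$values),
              length(unlist(x$dropped))))
  invisible(x)
}

#' Additive signal vector from the evidence matrix
#'
#' `S_i = sum_j e_ij`: one point per omics layer with a hit, so a gene
#' that is both differentially expressed and differentially methylated
#' gets `S_i = 2`, and `0 <= S_i <= L`.
#'
#' @param E an [evidence_matrix()].
#' @return Named integer vector aligned to the gene universe.
#' @export
signal_vector <- function(E) {
  if (!inherits(E, "evidence")) stop("'E' must be an evidence matrix")
  s <- as.integer(rowSums(E$values))
  names(s) <- E$genes
  s
}

#' Map qualitative protein-abundance levels to numeric weights
#'
#' High = 1, Medium = 0.75, Low = 0.5, Not detected = 0.25. Labels are
#' case- and whitespace-normalized; any other label is an error (no
#' silent default).
#'
#' @param level character vector of abundance labels.
#' @return Numeric vector of weights.
#' @examples
#' expression_weight(c("High", "medium", "NOT DETECTED"))
#' @export
expression_weight <- function(level) {
  key <- gsub("[_ ]+", " ", trimws(tolower(as.character(level))))
  map <- c("high" = 1, "medium" = 0.75, "low" = 0.5, "not detected" = 0.25)
  w <- unname(map[key])
  if (anyNA(w))
    stop("unknown abundance level(s): ",
         paste(unique(level[is.na(w)]), collapse = ", "),
         " (expected High, Medium, Low, Not detected)")
  w
}

#' Build the gene x (tissue, cell-type) abundance weight matrix
#'
#' Each cell holds the [expression_weight()] of the protein's abundance
#' level in that tissue/cell column. (gene, column) pairs absent from
#' the table get `missing_weight`, defaulting to 0.25 — the "Not
#' detected" floor. Duplicated rows are allowed when they agree;
#' conflicting levels for the same (gene, tissue, cell) are an error.
#'
#' @param abundance data frame with columns `gene_id`, `tissue`,
#'   `cell_type`, `level`.
#' @param catalog a [tissue_catalog()]; must cover every (tissue, cell)
#'   pair in the table.
#' @param gene_universe ordered character vector of genes (rows).
#' @param missing_weight weight for unobserved (gene, column) pairs.
#' @return G x T numeric matrix with dimnames (genes, column labels) and
#'   attribute `n_missing` (count of imputed cells).
#' @export
build_weight_matrix <- function(abundance, catalog, gene_universe,
                                missing_weight = 0.25) {
  if (!inherits(catalog, "tissue_catalog")) stop("'catalog' must be a tissue_catalog")
  gene_universe <- as.character(gene_universe)
  need <- c("gene_id", "tissue", "cell_type", "level")
  if (!all(need %in% names(abundance)))
    stop("abundance table must have columns: ", paste(need, collapse = ", "))
  W <- matrix(missing_weight, nrow = length(gene_universe),
              ncol = nrow(catalog),
              dimnames = list(gene_universe, catalog$label))
  ab <- abundance[abundance$gene_id %in% gene_universe, , drop = FALSE]
  if (nrow(ab)) {
    col_lab <- paste(trimws(ab$tissue), trimws(ab$cell_type), sep = "|")
    jj <- match(col_lab, catalog$label)
    if (anyNA(jj))
      stop("abundance rows reference (tissue, cell_type) pairs outside the catalog: ",
           paste(unique(col_lab[is.na(jj)]), collapse = ", "))
    w <- expression_weight(ab$level)
    key <- paste(ab$gene_id, col_lab)
    conflict <- tapply(w, key, function(v) length(unique(v)) > 1L)
    if (any(conflict))
      stop("conflicting abundance levels for: ",
           paste(head(names(conflict)[conflict], 10L), collapse = "; "))
    ii <- match(ab$gene_id, gene_universe)
    W[cbind(ii, jj)] <- w
  }
  attr(W, "n_missing") <- length(gene_universe) * nrow(catalog) -
    length(unique(paste(ab$gene_id, paste(trimws(ab$tissue),
                                          trimws(ab$cell_type), sep = "|"))))
  W
}

#' Tissue/cell-specific signal matrix
#'
#' `S*_ij = w_ij * S_i`: the additive evidence signal of each gene,
#' scaled per column by that gene's abundance weight in the tissue/cell.
#' Rows of W and entries of S must be aligned on the same gene order.
#'
#' @param W weight matrix from [build_weight_matrix()].
#' @param S signal vector from [signal_vector()].
#' @return G x T numeric matrix with the same dimnames as W.
#' @export
tissue_signal <- function(W, S) {
  if (nrow(W) != length(S))
    stop("alignment error: W has ", nrow(W), " rows but S has length ",
         length(S))
  if (!is.null(rownames(W)) && !is.null(names(S)) &&
      !identical(rownames(W), names(S)))
    stop("alignment error: gene order of W and S differ")
  out <- W * as.numeric(S)
  attr(out, "n_missing") <- NULL
  out
}

#' Read evidence gene lists, one file per omics layer
#'
#' Each plain-text file holds one gene ID per line; the layer name is
#' the file name without extension.
#'
#' @param dir directory containing the layer files.
#' @param pattern file-name filter (default `"\\.txt$"`).
#' @return Named list of character vectors, suitable for
#'   [evidence_matrix()].
#' @export
read_evidence_dir <- function(dir, pattern = "\\.txt$") {
  if (!dir.exists(dir)) stop("evidence directory not found: ", dir)
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (!length(files)) stop("no evidence files matching ", pattern, " in ", dir)
  lists <- lapply(files, function(f) {
    g <- trimws(readLines(f, warn = FALSE))
    g[nzchar(g) & !startsWith(g, "#")]
  })
  names(lists) <- sub("\\.[^.]*$", "", basename(files))
  lists
}

#' Read evidence as a single two-column (layer, gene) table
#'
#' @param path delimited file with header columns `layer`, `gene_id`.
#' @return Named list of character vectors.
#' @export
read_evidence_table <- function(path) {
  if (!file.exists(path)) stop("evidence table not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("layer", "gene_id") %in% names(df)))
    stop("evidence table must have columns: layer, gene_id")
  lapply(split(df$gene_id, df$layer), unique)
}

#' Read a protein-abundance table from a delimited file
#'
#' @param path tab-delimited file with header columns `gene_id`,
#'   `tissue`, `cell_type`, `level`.
#' @return Data frame ready for [build_weight_matrix()].
#' @export
read_abundance <- function(path) {
  if (!file.exists(path)) stop("abundance file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "tissue", "cell_type", "level")
  if (!all(need %in% names(df)))
    stop("abundance table must have columns: ", paste(need, collapse = ", "))
  df
}
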