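# PPI network construction, localization annotation, affinity matrix.

#' Construct a protein-protein interaction network
#'
#' Builds an undirected simple graph from a two-column table of protein
#' identifiers. Duplicate interactions are collapsed regardless of the
#' order the two endpoints appear in; self-loops are removed unless
#' `keep_self_loops = TRUE`. Identifiers are opaque strings; no ID
#' mapping is attempted. Node order is canonicalized alphabetically so
#' that downstream matrices are reproducible across input permutations.
#'
#' @param edges data frame or matrix whose first two columns hold the
#'   interacting identifiers; extra columns are ignored.
#' @param keep_self_loops keep rows with identical endpoints as loops
#'   instead of dropping them (default drops and counts them).
#' @return An object of class `ppi_network`: a list with `nodes` (sorted
#'   unique identifiers), `edges` (integer matrix of node-index pairs,
#'   first index <= second), `n`, and the audit counts `n_raw_rows`,
#'   `n_duplicates`, `n_self_loops`.
#' @examples
#' net <- ppi_network(data.frame(a = c("P1", "P2", "P1"),
#'                               b = c("P2", "P1", "P2")))
#' net$n          # 2 nodes
#' nrow(net$edges) # 1 edge
#' @seealso [load_edge_list()] to read from disk, [build_affinity()]
#' @export
ppi_network <- function(edges, keep_self_loops = FALSE) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!is.data.frame(edges) || ncol(edges) < 2L)
    stop("'edges' must be a data frame with at least two identifier columns")
  if (nrow(edges) == 0L)
    stop("empty network: the edge table has no rows")
  a <- trimws(as.character(edges[[1L]]))
  b <- trimws(as.character(edges[[2L]]))
  bad <- which(is.na(a) | is.na(b) | a == "" | b == "")
  if (length(bad))
    stop("malformed edge row(s) with missing identifiers at row(s): ",
         paste(head(bad, 5L), collapse = ", "))
  n_raw <- length(a)
  is_self <- a == b
  n_self <- sum(is_self)
  if (!keep_self_loops) {
    a_use <- a[!is_self]
    b_use <- b[!is_self]
  } else {
    a_use <- a
    b_use <- b
  }
  nodes <- sort(unique(c(a, b)))
  i <- match(a_use, nodes)
  j <- match(b_use, nodes)
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  dup <- duplicated(paste(lo, hi))
  em <- cbind(i = lo[!dup], j = hi[!dup])
  structure(list(nodes = nodes,
                 edges = em,
                 n = length(nodes),
                 n_raw_rows = n_raw,
                 n_duplicates = sum(dup),
                 n_self_loops = n_self,
                 keep_self_loops = keep_self_loops),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges (%d raw rows; %d duplicates, %d self-loops %s)\n",
              x$n, nrow(x$edges), x$n_raw_rows, x$n_duplicates, x$n_self_loops,
              if (x$keep_self_loops) "kept" else "removed"))
  invisible(x)
}

#' Read an undirected edge list from a delimited text file
#'
#' Accepts tab- or comma-delimited files with two identifier columns.
#' An optional header row is auto-detected (first field looking like a
#' column name such as "protein_a" or "gene1") unless `header` is set
#' explicitly. Lines starting with `#` and blank lines are skipped.
#'
#' @param path file to read.
#' @param sep field separator; `NULL` (default) picks tab if the first
#'   data line contains one, otherwise comma.
#' @param header `TRUE`/`FALSE`, or `NA` (default) to auto-detect.
#' @param keep_self_loops passed to [ppi_network()].
#' @return A [ppi_network()] object.
#' @export
load_edge_list <- function(path, sep = NULL, header = NA,
                           keep_self_loops = FALSE) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty network: no data rows in ", path)
  if (is.null(sep)) sep <- if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L))
    stop("malformed edge row (fewer than two columns) at line ",
         lineno[which(nf < 2L)[1L]], " of ", path)
  a <- trimws(vapply(parts, `[[`, character(1L), 1L))
  b <- trimws(vapply(parts, `[[`, character(1L), 2L))
  if (is.na(header))
    header <- grepl("^(protein|gene|node|source|target|interactor|id)",
                    a[1L], ignore.case = TRUE)
  if (isTRUE(header)) {
    a <- a[-1L]
    b <- b[-1L]
  }
  if (!length(a)) stop("empty network: only a header row in ", path)
  ppi_network(data.frame(a = a, b = b, stringsAsFactors = FALSE),
              keep_self_loops = keep_self_loops)
}

#' Build a subcellular-localization annotation
#'
#' Records which micro-domains (nucleus, cytosol, vesicles, ...) each
#' protein is annotated to. A protein may carry zero, one, or several
#' domains; proteins absent from the input are simply unannotated.
#'
#' @param assignments either a data frame whose first two columns are
#'   (protein_id, micro_domain) with one row per pair, or a named list of
#'   character vectors of domains.
#' @param catalog the permitted domain names. `NULL` (default) takes the
#'   catalog from the data.
#' @param strict if `TRUE` (default) any domain outside `catalog` is an
#'   error; if `FALSE` the catalog is extended.
#' @return An object of class `localization`: list with `catalog`
#'   (sorted domain names) and `assignments` (named list of domain sets).
#' @export
localization_annotation <- function(assignments, catalog = NULL,
                                    strict = TRUE) {
  if (is.data.frame(assignments)) {
    if (ncol(assignments) < 2L)
      stop("localization table needs (protein_id, micro_domain) columns")
    ids <- trimws(as.character(assignments[[1L]]))
    dom <- trimws(as.character(assignments[[2L]]))
    lst <- lapply(split(dom, ids), unique)
  } else if (is.list(assignments)) {
    lst <- lapply(assignments, function(d) unique(trimws(as.character(d))))
  } else stop("'assignments' must be a data frame or a named list")
  seen <- sort(unique(unlist(lst, use.names = FALSE)))
  if (is.null(catalog)) catalog <- seen
  unknown <- setdiff(seen, catalog)
  if (length(unknown)) {
    if (strict)
      stop("unknown micro-domain(s) not in catalog: ",
           paste(unknown, collapse = ", "))
    catalog <- sort(union(catalog, unknown))
  }
  structure(list(catalog = sort(catalog), assignments = lst),
            class = "localization")
}

#' Read a (protein_id, micro_domain) table from a delimited text file
#'
#' One row per (protein, domain) pair; proteins recur across rows to
#' accumulate multiple domains. An empty file yields an annotation in
#' which every node is unannotated.
#'
#' @inheritParams load_edge_list
#' @inheritParams localization_annotation
#' @return A [localization_annotation()] object.
#' @export
load_localizations <- function(path, catalog = NULL, strict = TRUE,
                               sep = NULL, header = NA) {
  if (!file.exists(path)) stop("localization file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  if (!length(lines))
    return(localization_annotation(list(), catalog = catalog %||% character(0),
                                   strict = strict))
  if (is.null(sep)) sep <- if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("malformed localization row at line ", which(lengths(parts) < 2L)[1L])
  ids <- trimws(vapply(parts, `[[`, character(1L), 1L))
  dom <- trimws(vapply(parts, `[[`, character(1L), 2L))
  if (is.na(header))
    header <- grepl("^(protein|gene|node|id)", ids[1L], ignore.case = TRUE)
  if (isTRUE(header)) {
    ids <- ids[-1L]
    dom <- dom[-1L]
  }
  if (!length(ids))
    return(localization_annotation(list(), catalog = catalog %||% character(0),
                                   strict = strict))
  localization_annotation(data.frame(ids, dom, stringsAsFactors = FALSE),
                          catalog = catalog, strict = strict)
}

#' Build the localization-adjusted affinity matrix
#'
#' The affinity matrix A of an n-node network is symmetric with
#' `a_ij = amplification` if proteins i and j interact and their
#' micro-domain sets intersect, `a_ij = 1` if they interact without a
#' shared domain (including when either protein is unannotated), and
#' `a_ij = 0` otherwise. The default amplification of 1.5 encodes that
#' interactors confined to the same subcellular compartment are more
#' likely to truly interact; setting it to 1 recovers the plain
#' unweighted adjacency matrix.
#'
#' @param network a [ppi_network()].
#' @param localization a [localization_annotation()], or `NULL` for no
#'   amplification.
#' @param amplification positive edge weight for co-localized pairs
#'   (default 1.5).
#' @return An object of class `affinity`: list with `values` (sparse
#'   symmetric `Matrix` with node dimnames), `amplification`, `nodes`.
#' @examples
#' net <- ppi_network(data.frame(a = "P1", b = "P2"))
#' loc <- localization_annotation(list(P1 = "Nucleus", P2 = "Nucleus"))
#' build_affinity(net, loc)$values["P1", "P2"]  # 1.5
#' @export
build_affinity <- function(network, localization = NULL,
                           amplification = 1.5) {
  if (!inherits(network, "ppi_network")) stop("'network' must be a ppi_network")
  if (!is.numeric(amplification) || length(amplification) != 1L ||
      amplification <= 0)
    stop("'amplification' must be a positive scalar")
  if (network$n == 0L) stop("empty network")
  e <- network$edges
  w <- rep(1, nrow(e))
  if (!is.null(localization) && nrow(e)) {
    if (!inherits(localization, "localization"))
      stop("'localization' must be a localization annotation")
    dom <- localization$assignments
    da <- dom[network$nodes[e[, 1L]]]
    db <- dom[network$nodes[e[, 2L]]]
    co <- mapply(function(x, y) {
      length(x) > 0L && length(y) > 0L && length(intersect(x, y)) > 0L
    }, da, db, USE.NAMES = FALSE)
    w[co] <- amplification
  }
  is_self <- e[, 1L] == e[, 2L]
  i <- c(e[, 1L], e[!is_self, 2L])
  j <- c(e[, 2L], e[!is_self, 1L])
  x <- c(w, w[!is_self])
  A <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(network$n, network$n),
                            dimnames = list(network$nodes, network$nodes))
  structure(list(values = A, amplification = amplification,
                 nodes = network$nodes),
            class = "affinity")
}

#' @export
print.affinity <- function(x, ...) {
  cat(sprintf("affinity matrix: %d x %d, %d nonzero entries, amplification %.3g\n",
              nrow(x$values), ncol(x$values), Matrix::nnzero(x$values),
              x$amplification))
  invisible(x)
}

#' Drop degree-zero nodes from a network
#'
#' The Markov operator `D^-1 A` is undefined for isolated nodes. The
#' pipeline removes them before normalization and defines their output
#' signal as their input signal (they neither send nor receive).
#'
#' @param network a [ppi_network()].
#' @return list with `network` (isolates removed, indices rebuilt) and
#'   `removed` (character vector of dropped node identifiers).
#' @export
drop_isolates <- function(network) {
  if (!inherits(network, "ppi_network")) stop("'network' must be a ppi_network")
  used <- sort(unique(as.integer(network$edges)))
  removed <- setdiff(seq_len(network$n), used)
  if (!length(removed))
    return(list(network = network, removed = character(0)))
  keep_nodes <- network$nodes[used]
  remap <- integer(network$n)
  remap[used] <- seq_along(used)
  em <- cbind(i = remap[network$edges[, 1L]], j = remap[network$edges[, 2L]])
  net2 <- structure(list(nodes = keep_nodes, edges = em,
                         n = length(keep_nodes),
                         n_raw_rows = network$n_raw_rows,
                         n_duplicates = network$n_duplicates,
                         n_self_loops = network$n_self_loops,
                         keep_self_loops = network$keep_self_loops),
                    class = "ppi_network")
  list(network = net2, removed = network$nodes[removed])
}
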