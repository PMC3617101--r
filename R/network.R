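#' Build an interaction network from an edge-list data frame
#'
#' Constructs the undirected simple graph that all scoring methods operate on.
#' Multi-edges (including reversed duplicates) collapse to a single edge and
#' self-loops are dropped, mirroring the non-redundant merge of curated
#' interaction sources; any mechanism or direction columns beyond the first
#' two are ignored, since none of the scoring equations uses edge direction.
#'
#' @param edges A data frame whose first two columns are source and target
#'   node identifiers (coerced to character). Extra columns are ignored.
#' @param nodes Optional character vector of node identifiers to include even
#'   if they have no edges (isolated nodes are retained with degree 0).
#'   Identifiers appearing in `edges` but not in `nodes` are appended.
#' @return An `interaction_network` object: node identifiers in
#'   first-appearance order, a deduplicated edge tibble, and accessors for
#'   degrees and neighborhoods.
#' @examples
#' net <- as_interaction_network(data.frame(from = c("A", "B", "A", "B"),
#'                                          to   = c("B", "A", "A", "C")))
#' network_nodes(net)   # "A" "B" "C"
#' network_degrees(net) # A-B and B-C survive; A-A and the reversed dup do not
#' @export
as_interaction_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L) {
    abort("`edges` must have at least two columns (source, target).")
  }
  from <- as.character(edges[[1L]])
  to <- as.character(edges[[2L]])
  if (anyNA(from) || anyNA(to)) abort("Edge endpoints must not be NA.")
  # first-appearance node order, interleaving source/target per row
  node_order <- unique(c(rbind(from, to)))
  if (!is.null(nodes)) node_order <- unique(c(as.character(nodes), node_order))
  keep <- from != to
  from <- from[keep]
  to <- to[keep]
  key <- paste(pmin(from, to), pmax(from, to), sep = "\r")
  first <- !duplicated(key)
  edge_tbl <- tibble(from = from[first], to = to[first])
  if (length(node_order) == 0L) abort("Network has no nodes.")
  structure(
    list(nodes = node_order, edges = edge_tbl),
    class = "interaction_network"
  )
}

#' Read an interaction network from an edge-list file
#'
#' Accepts whitespace/tab-separated edge lists
#' (`source<TAB>target[<TAB>mechanism<TAB>direction]`) and SIF
#' (`source relation target`). Comment lines and the extra columns are
#' ignored.
#'
#' @param path Path to the edge-list file.
#' @param format `"tsv"` (default; columns 1 and 2 are the endpoints) or
#'   `"sif"` (columns 1 and 3 are the endpoints).
#' @param comment_prefix Lines starting with this prefix are skipped.
#' @return An [as_interaction_network()] object.
#' @export
read_network <- function(path, format = c("tsv", "sif"),
                         comment_prefix = "#") {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  is_data <- nzchar(trimws(lines)) & !startsWith(trimws(lines), comment_prefix)
  idx <- which(is_data)
  if (length(idx) == 0L) abort(sprintf("No edges found in '%s'.", path))
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  # tolerate a header row of the kind write_network() produces
  hdr <- tolower(fields[[1L]])
  if (length(hdr) >= 2L &&
      hdr[1L] %in% c("from", "source") && hdr[2L] %in% c("to", "target")) {
    fields <- fields[-1L]
    idx <- idx[-1L]
    if (length(fields) == 0L) abort(sprintf("No edges found in '%s'.", path))
  }
  min_cols <- if (format == "sif") 3L else 2L
  bad <- which(vapply(fields, length, 1L) < min_cols)
  if (length(bad) > 0L) {
    abort(sprintf("Malformed line %d in '%s': expected at least %d columns.",
                  idx[bad[1L]], path, min_cols))
  }
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", if (format == "sif") 3L else 2L)
  as_interaction_network(tibble(from = from, to = to))
}

#' Write a network as a two-column TSV edge list
#'
#' Only nodes with at least one edge survive an edge-list serialization;
#' isolated nodes must be re-supplied via the `nodes` argument of
#' [as_interaction_network()] when reconstructing.
#'
#' @param net An `interaction_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "interaction_network"))
  write_tsv_plain(net$edges, path)
}

#' @method print interaction_network
#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network: %d nodes, %d edges>\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Node identifiers of a network, in first-appearance order
#' @param net An `interaction_network`.
#' @return Character vector of node ids.
#' @export
network_nodes <- function(net) net$nodes

#' Node degrees
#' @param net An `interaction_network`.
#' @return A tibble with columns `node` and `degree`.
#' @export
network_degrees <- function(net) {
  deg <- Matrix::colSums(build_adjacency(net))
  tibble(node = net$nodes, degree = as.integer(deg))
}

#' Neighborhood of a node
#' @param net An `interaction_network`.
#' @param node A node identifier.
#' @return Character vector of adjacent node ids.
#' @export
network_neighbors <- function(net, node) {
  if (!node %in% net$nodes) abort(sprintf("Node '%s' not in network.", node))
  with(net$edges, sort(c(to[from == node], from[to == node])))
}

#' Binary adjacency matrix of a network
#'
#' @param net An `interaction_network`.
#' @return A sparse symmetric 0/1 matrix with zero diagonal, rows and columns
#'   indexed in the network's node order.
#' @export
build_adjacency <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  n <- length(net$nodes)
  i <- match(net$edges$from, net$nodes)
  j <- match(net$edges$to, net$nodes)
  adj <- Matrix::sparseMatrix(
    i = c(i, j), j = c(j, i), x = 1,
    dims = c(n, n), dimnames = list(net$nodes, net$nodes)
  )
  adj
}

#' Column-stochastic normalization of an adjacency matrix
#'
#' Divides every column by its degree so that each column of a non-isolated
#' node sums to 1; the result is the transition matrix of the random walk.
#' Columns of degree-0 nodes stay all-zero and are flagged as dangling so the
#' walk can redirect their mass to the restart vector.
#'
#' @param adj A 0/1 adjacency matrix from [build_adjacency()].
#' @return A `normalized_adjacency` object with fields `matrix`,
#'   `normalization = "column_stochastic"`, and logical `dangling` per node.
#' @export
normalize_stochastic <- function(adj) {
  deg <- Matrix::colSums(adj)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  m <- adj %*% Matrix::Diagonal(x = inv)
  dimnames(m) <- dimnames(adj)
  structure(
    list(matrix = m, normalization = "column_stochastic",
         dangling = setNames(deg == 0, colnames(adj))),
    class = "normalized_adjacency"
  )
}

#' Symmetric degree normalization of an adjacency matrix
#'
#' Each entry is divided by the square root of the product of the endpoint
#' degrees, `e(i,j) / sqrt(deg(i) deg(j))`; this is the smoothing operator of
#' network propagation and compensates for hubs picking up flow by chance.
#'
#' @inheritParams normalize_stochastic
#' @return A `normalized_adjacency` with `normalization = "symmetric_degree"`.
#' @export
normalize_symmetric <- function(adj) {
  deg <- Matrix::colSums(adj)
  inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  d_half <- Matrix::Diagonal(x = inv_sqrt)
  m <- d_half %*% adj %*% d_half
  dimnames(m) <- dimnames(adj)
  structure(
    list(matrix = m, normalization = "symmetric_degree",
         dangling = setNames(deg == 0, colnames(adj))),
    class = "normalized_adjacency"
  )
}

#' @method print normalized_adjacency
#' @export
print.normalized_adjacency <- function(x, ...) {
  cat(sprintf("<normalized_adjacency [%s]: %d nodes, %d dangling>\n",
              x$normalization, ncol(x$matrix), sum(x$dangling)))
  invisible(x)
}
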