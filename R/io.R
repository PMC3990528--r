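#' Write / read a network as Matrix Market + node table
#'
#' \code{write_network} stores the adjacency as a Matrix Market coordinate
#' pattern file (\code{<path>.mtx}, 1-based indices per the MTX standard,
#' row = origin, column = target) and the node metadata as a tab-separated
#' table (\code{<path>.nodes.tsv}) with columns \code{node_id} (0-based),
#' \code{ei_label} and \code{struct_class}. \code{read_network} reverses the
#' operation and validates the structural invariants; the round trip is
#' exact.
#'
#' @param net A \code{directed_network}.
#' @param path File path prefix (without extension).
#' @return \code{write_network}: \code{path}, invisibly.
#'   \code{read_network}: a \code{directed_network}.
#' @examples
#' net <- build_ring_lattice(
#'   topology_config(n_exc = 16, n_inh = 4, k_from_exc = 4, k_from_inh = 2))
#' p <- file.path(tempdir(), "lat16")
#' write_network(net, p)
#' identical(as.matrix(read_network(p)$adj), as.matrix(net$adj))
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "directed_network"))
  Matrix::writeMM(net$adj, paste0(path, ".mtx"))
  nodes <- data.frame(node_id = seq_len(nrow(net$adj)) - 1L,
                      ei_label = net$ei,
                      struct_class = net$struct_class)
  write.table(nodes, paste0(path, ".nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  mtx <- paste0(path, ".mtx"); tsv <- paste0(path, ".nodes.tsv")
  if (!file.exists(mtx) || !file.exists(tsv))
    stop("missing network files: ", mtx, " / ", tsv)
  adj <- as(as(Matrix::readMM(mtx), "nMatrix"), "CsparseMatrix")
  nodes <- read.delim(tsv, stringsAsFactors = FALSE)
  need <- c("node_id", "ei_label", "struct_class")
  if (!all(need %in% names(nodes)))
    stop("node table must have columns node_id, ei_label, struct_class")
  nodes <- nodes[order(nodes$node_id), , drop = FALSE]
  if (nrow(nodes) != nrow(adj) || nrow(adj) != ncol(adj))
    stop("node table and adjacency dimensions do not match")
  if (!all(nodes$node_id == seq_len(nrow(adj)) - 1L))
    stop("node_id must enumerate 0 .. n-1")
  if (!all(nodes$ei_label %in% c("E", "I")))
    stop("unknown E/I label in node table")
  if (!all(nodes$struct_class %in% 1:3))
    stop("unknown structural class label in node table")
  if (is.unsorted(match(nodes$ei_label, c("E", "I"))))
    stop("E nodes must precede I nodes")
  net <- structure(list(adj = adj,
                        ei = nodes$ei_label,
                        struct_class = as.integer(nodes$struct_class),
                        n_exc = sum(nodes$ei_label == "E"),
                        n_inh = sum(nodes$ei_label == "I"),
                        provenance = list(topology = "file",
                                          constant_indegree = FALSE,
                                          source = path)),
                   class = "directed_network")
  if (any(Matrix::diag(net$adj) != 0))
    stop("self-edges are not allowed")
  net
}
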