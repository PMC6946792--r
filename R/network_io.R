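#' Write a network to GraphML or edge-list TSV
#'
#' GraphML (via \pkg{igraph}) carries all node attributes (taxonomy ranks,
#' domain, module, role) and edge attributes (rho, sign, q); the edge-list
#' TSV carries source, target, rho, sign and q. Reading the file back
#' reproduces the graph.
#'
#' @param net an AssociationNetwork
#' @param path output file
#' @param format \code{"graphml"} or \code{"edgelist"}
#' @return invisibly, \code{path}
#' @export
writeNetwork <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  g <- networkGraph(net)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.table(edgeTable(net), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a network written by \code{\link{writeNetwork}}
#'
#' @param path file path
#' @param format \code{"graphml"} or \code{"edgelist"}
#' @return an AssociationNetwork
#' @export
readNetwork <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  g <- if (format == "graphml") {
    igraph::read_graph(path, format = "graphml")
  } else {
    et <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    if (nrow(et) == 0L) {
      igraph::make_empty_graph(0, directed = FALSE)
    } else {
      igraph::graph_from_data_frame(et, directed = FALSE)
    }
  }
  g <- igraph::as_undirected(g, mode = "each")
  new("AssociationNetwork", graph = g)
}
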