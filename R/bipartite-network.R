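#' Construct a bipartite miRNA-target network
#'
#' The network is a directed bipartite graph: regulatory edges run from a
#' miRNA node to each of its target genes. Nodes live in exactly one of the
#' two partitions; self-edges and duplicate edges are rejected.
#'
#' @param edges a two-column data frame (or object coercible to one) with
#'   columns `mirna` and `target`, one row per directed regulatory edge.
#' @param mirnas,targets optional character vectors of additional node ids
#'   (isolated nodes without edges).
#' @return an object of class `bipartite_network`: a list with elements
#'   `nodes` (data frame with columns `id`, `partition`) and `edges`
#'   (data frame with columns `mirna`, `target`).
#' @examples
#' net <- bipartite_network(data.frame(mirna = c("m1", "m1"),
#'                                     target = c("g1", "g2")))
#' net
#' @export
bipartite_network <- function(edges, mirnas = NULL, targets = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  abort_if(ncol(edges) < 2, "`edges` needs columns mirna and target")
  names(edges)[1:2] <- c("mirna", "target")
  edges <- edges[, c("mirna", "target")]
  edges$mirna <- as.character(edges$mirna)
  edges$target <- as.character(edges$target)
  abort_if(any(edges$mirna == edges$target),
           "self-edges are not allowed in a bipartite network")
  edges <- unique(edges)
  m_ids <- unique(c(edges$mirna, as.character(mirnas)))
  t_ids <- unique(c(edges$target, as.character(targets)))
  both <- intersect(m_ids, t_ids)
  abort_if(length(both) > 0,
           paste0("node(s) appear in both partitions: ",
                  paste(head(both, 5), collapse = ", ")),
           class = "mirhub_partition_error")
  nodes <- data.frame(
    id = c(m_ids, t_ids),
    partition = c(rep("miRNA", length(m_ids)), rep("target", length(t_ids))),
    stringsAsFactors = FALSE
  )
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat("bipartite_network:", sum(x$nodes$partition == "miRNA"), "miRNAs,",
      sum(x$nodes$partition == "target"), "targets,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

n_nodes <- function(net) nrow(net$nodes)
n_edges <- function(net) nrow(net$edges)

# Undirected simple igraph projection used by all global statistics and
# centrality scores. Node order follows net$nodes$id. Plain igraph inputs
# (not necessarily bipartite) are accepted and projected the same way.
as_igraph_undirected <- function(net) {
  if (inherits(net, "igraph")) {
    g <- igraph::as_undirected(net, mode = "collapse")
    if (is.null(igraph::V(g)$name)) {
      igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
    }
    return(igraph::simplify(g))
  }
  g <- igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = net$nodes$id
  )
  igraph::simplify(g)
}

graph_size <- function(net) {
  if (inherits(net, "igraph")) igraph::vcount(net) else n_nodes(net)
}

#' Read a miRNA-target edge list
#'
#' Supports plain tab-separated edge lists (`miRNA<TAB>target[<TAB>target...]`)
#' and the SIF dialect (`miRNA <interaction> target [target ...]`,
#' whitespace-delimited). Duplicate records are collapsed; the miRNA
#' partition is inferred from the column role.
#'
#' @param path path to the file (or a character vector of lines via
#'   `text =`).
#' @param dialect `"tsv"` or `"sif"`.
#' @param text optional character vector of lines, used instead of `path`.
#' @return a [bipartite_network()].
#' @export
read_network <- function(path, dialect = c("tsv", "sif"), text = NULL) {
  dialect <- match.arg(dialect)
  lines <- if (is.null(text)) readLines(path) else text
  lines <- lines[nzchar(trimws(lines))]
  mirna <- character(0); target <- character(0)
  for (i in seq_along(lines)) {
    fields <- if (dialect == "tsv") {
      strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    } else {
      strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
    }
    fields <- fields[nzchar(fields)]
    need <- if (dialect == "tsv") 2L else 3L
    abort_if(length(fields) < need,
             sprintf("line %d: expected at least %d fields, got %d",
                     i, need, length(fields)),
             class = "mirhub_parse_error")
    tgt <- if (dialect == "tsv") fields[-1] else fields[-(1:2)]
    mirna <- c(mirna, rep(fields[[1]], length(tgt)))
    target <- c(target, tgt)
  }
  bipartite_network(data.frame(mirna = mirna, target = target,
                               stringsAsFactors = FALSE))
}

#' Write a network as TSV or SIF
#'
#' @param net a [bipartite_network()].
#' @param path output path.
#' @param dialect `"tsv"` (one edge per line) or `"sif"` (one miRNA per
#'   line with all its targets, interaction type `regulates`).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    lines <- paste(net$edges$mirna, net$edges$target, sep = "\t")
  } else {
    sp <- split(net$edges$target, net$edges$mirna)
    sp <- sp[unique(net$edges$mirna)]  # preserve first-appearance order
    lines <- vapply(names(sp), function(m) {
      paste(c(m, "regulates", sp[[m]]), collapse = "\t")
    }, character(1))
  }
  writeLines(lines, path)
  invisible(path)
}
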