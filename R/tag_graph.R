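#' Build the shared-tag app graph
#'
#' Vertices are apps; an undirected edge connects two apps whenever their tag
#' sets intersect, weighted by the number of shared tags. Only assignments
#' that passed the inclusion filter should be supplied. Vertex order is
#' deterministic (sorted by `app_id`); there are no self-loops.
#'
#' @param assignments included tag assignments ([auto_tag_corpus()] rows with
#'   `included = TRUE`).
#' @param min_shared minimum shared-tag count for an edge (default 1).
#' @param weighted if `FALSE`, collapse all edge weights to 1 for
#'   sensitivity runs.
#' @return an [igraph::graph] with vertex attribute `name` (app ids) and edge
#'   attribute `weight`.
#' @export
build_graph <- function(assignments, min_shared = 1L, weighted = TRUE) {
  if (anyDuplicated(assignments$app_id))
    stop("duplicate app_id: ",
         assignments$app_id[duplicated(assignments$app_id)][1], call. = FALSE)
  ord <- order(assignments$app_id)
  ids <- assignments$app_id[ord]
  tag_sets <- assignments$tags[ord]
  n <- length(ids)
  all_tags <- sort(unique(unlist(tag_sets)))
  if (n == 0 || length(all_tags) == 0) {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = ids)
    return(g)
  }
  inc <- Matrix::sparseMatrix(
    i = rep(seq_len(n), lengths(tag_sets)),
    j = match(unlist(tag_sets), all_tags),
    x = 1, dims = c(n, length(all_tags)))
  shared <- Matrix::tcrossprod(inc)
  shared <- Matrix::triu(shared, k = 1)
  tr <- Matrix::summary(shared)
  tr <- tr[tr$x >= min_shared, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[tr$i], to = ids[tr$j]),
    directed = FALSE,
    vertices = data.frame(name = ids))
  igraph::E(g)$weight <- if (weighted) as.numeric(tr$x) else rep(1, nrow(tr))
  g
}

#' Write / read an app graph as GraphML
#'
#' Round-trips vertices, edges and weights losslessly.
#'
#' @param graph an app graph from [build_graph()].
#' @param path file path.
#' @return `read_app_graph()` returns the graph; the writer returns `path`
#'   invisibly.
#' @export
write_app_graph <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_app_graph
#' @export
read_app_graph <- function(path) {
  g <- tryCatch(igraph::read_graph(path, format = "graphml"),
                error = function(e) stop("failed to parse GraphML file '", path,
                                         "': ", conditionMessage(e), call. = FALSE))
  if (igraph::ecount(g) > 0 && is.null(igraph::E(g)$weight))
    igraph::E(g)$weight <- 1
  g
}

#' Write an app graph as a three-column TSV edge list
#'
#' Columns `from`, `to`, `weight`, with a header line.
#' @inheritParams write_app_graph
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  if (is.null(el$weight)) el$weight <- rep(1, nrow(el))
  lines <- c("from\tto\tweight",
             if (nrow(el)) paste(el$from, el$to, el$weight, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
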