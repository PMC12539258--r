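# Cell adjacency graphs. Two constructions:
#  * mask_expansion: cells interact when their masks touch after each is
#    expanded by param_um (default 4 um), i.e. when the Euclidean set
#    distance between the two masks is at most 2 * param_um;
#  * delaunay_maxlen: Delaunay edges between centroids, retaining edges no
#    longer than param_um (default 30 um).

#' Cell adjacency graph
#'
#' @param nodes character vector of cell ids.
#' @param edges two-column matrix/data.frame of undirected edges (cell
#'   ids); self loops forbidden.
#' @param method construction method.
#' @param param_um construction parameter in micrometres.
#' @return object of class \code{cell_graph} wrapping an igraph.
#' @export
cell_graph <- function(nodes, edges, method = "manual", param_um = NA_real_) {
  nodes <- as.character(nodes)
  edges <- as.matrix(edges)
  if (nrow(edges) && any(edges[, 1] == edges[, 2]))
    stop("self loops are not allowed")
  if (nrow(edges) && !all(as.character(edges) %in% nodes))
    stop("edge endpoint not among nodes")
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges[, 1][seq_len(nrow(edges))]),
                   to = as.character(edges[, 2][seq_len(nrow(edges))])),
    directed = FALSE,
    vertices = data.frame(name = nodes))
  g <- igraph::simplify(g)
  structure(list(graph = g, nodes = nodes, method = method,
                 param_um = param_um),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("<cell_graph> %d node(s), %d edge(s) [%s, %.3g um]\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$method, x$param_um))
  invisible(x)
}

#' Edge list of a cell graph
#' @param graph a \code{cell_graph}.
#' @return data.frame with columns \code{from}, \code{to}.
#' @export
graph_edges <- function(graph) {
  e <- igraph::as_edgelist(graph$graph)
  data.frame(from = e[, 1], to = e[, 2])
}

#' Build a cell adjacency graph
#'
#' @param cells for \code{delaunay_maxlen}: a \code{\link{cell_table}} (or
#'   data.frame) with \code{cell_id, x_um, y_um}. Ignored for
#'   \code{mask_expansion} if \code{masks} is given.
#' @param masks for \code{mask_expansion}: a \code{\link{label_mask}} of
#'   cell regions.
#' @param method \code{"mask_expansion"} (edge iff masks touch after each
#'   is dilated by \code{param_um}) or \code{"delaunay_maxlen"} (Delaunay
#'   edges of length at most \code{param_um}).
#' @param param_um expansion distance (default 4) or maximum edge length
#'   (default 30).
#' @return a \code{\link{cell_graph}}.
#' @export
build_adjacency_graph <- function(cells = NULL, masks = NULL,
                                  method = c("mask_expansion",
                                             "delaunay_maxlen"),
                                  param_um = NULL) {
  method <- match.arg(method)
  if (method == "mask_expansion") {
    if (is.null(masks)) stop("mask_expansion requires masks")
    if (is.null(param_um)) param_um <- 4
    lab <- masks$labels
    s <- masks$pixel_size_um
    ids <- mask_labels(lab)
    pix <- which(lab > 0L)
    fl <- factor(lab[pix], levels = ids)
    edges <- list()
    for (l in ids) {
      dl <- EBImage::distmap(matrix(as.numeric(lab != l), nrow(lab))) * s
      mind <- tapply(dl[pix], fl, min)
      nb <- ids[!is.na(mind) & mind <= 2 * param_um & ids > l]
      if (length(nb))
        edges[[length(edges) + 1L]] <- cbind(as.character(l),
                                             as.character(nb))
    }
    edges <- if (length(edges)) do.call(rbind, edges) else
      matrix(character(0), 0, 2)
    return(cell_graph(as.character(ids), edges, method, param_um))
  }
  # delaunay_maxlen
  if (is.null(cells)) stop("delaunay_maxlen requires cells")
  if (is.null(param_um)) param_um <- 30
  ids <- as.character(cells$cell_id)
  x <- cells$x_um; y <- cells$y_um
  n <- length(x)
  if (n < 2L)
    return(cell_graph(ids, matrix(character(0), 0, 2), method, param_um))
  edges <- .delaunay_edges(x, y)
  if (nrow(edges)) {
    len <- sqrt((x[edges[, 1]] - x[edges[, 2]])^2 +
                (y[edges[, 1]] - y[edges[, 2]])^2)
    edges <- edges[len <= param_um, , drop = FALSE]
  }
  cell_graph(ids, cbind(ids[edges[, 1]], ids[edges[, 2]]), method, param_um)
}

# Delaunay edge index pairs; degenerate (collinear) configurations fall
# back to the path graph along the line, which is the limit triangulation.
.delaunay_edges <- function(x, y) {
  n <- length(x)
  if (n == 2L) return(cbind(1L, 2L))
  dd <- try(deldir::deldir(x, y, suppressMsge = TRUE), silent = TRUE)
  if (!inherits(dd, "try-error")) {
    e <- dd$delsgs
    return(cbind(as.integer(e$ind1), as.integer(e$ind2)))
  }
  # collinear: sort along the principal direction and chain neighbours
  v <- prcomp(cbind(x, y))$x[, 1]
  o <- order(v)
  cbind(o[-n], o[-1])
}
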