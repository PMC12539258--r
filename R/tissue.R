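# Tumour-stroma tissue segmentation and local point density.

#' Tumour/stroma compartment assignment with island reassignment
#'
#' Step 1 ("naive"): a cell is tumour iff it is positive for the tumour
#' marker (cytokeratin by default). Step 2: on the naive labelling, groups
#' (connected components of same-label cells on the adjacency graph) of
#' fewer than \code{small_max} stroma cells connected by at least one graph
#' edge to a group of more than \code{large_min} tumour cells are
#' reassigned to tumour, and symmetrically for small tumour groups against
#' large stroma groups. All reassignments are evaluated on the naive
#' labelling and applied simultaneously in a single pass. Inequalities are
#' strict on both sides: a 5-cell group is never reassigned, and a 10-cell
#' neighbour never triggers reassignment (defaults).
#'
#' @param table a \code{\link{cell_table}}; needs \code{pos_<marker>}
#'   unless \code{tumor} is given.
#' @param graph a \code{\link{cell_graph}} over the same cells.
#' @param marker tumour marker name (default \code{"CK"}).
#' @param tumor optional logical vector overriding the naive labelling.
#' @param small_max groups strictly smaller than this may be reassigned
#'   (default 5).
#' @param large_min neighbouring groups strictly larger than this trigger
#'   reassignment (default 10).
#' @return the table with a \code{compartment} column
#'   (\code{"tumor"}/\code{"stroma"}).
#' @export
segment_tissue <- function(table, graph, marker = "CK", tumor = NULL,
                           small_max = 5, large_min = 10) {
  stopifnot(inherits(graph, "cell_graph"))
  ids <- as.character(table$cell_id)
  if (!setequal(ids, graph$nodes))
    stop("graph nodes and table cells differ")
  if (is.null(tumor)) {
    col <- paste0("pos_", marker)
    if (!col %in% names(table))
      stop("cell table lacks column ", col, "; supply `tumor` instead")
    tumor <- table[[col]]
  }
  stopifnot(length(tumor) == nrow(table))
  g <- graph$graph
  vn <- igraph::V(g)$name
  lab <- setNames(tumor, ids)[vn]

  # connected components among same-label cells
  comp_of <- integer(length(vn)); names(comp_of) <- vn
  ncomp <- 0L
  for (what in c(TRUE, FALSE)) {
    sub <- igraph::induced_subgraph(g, vn[lab == what])
    if (igraph::vcount(sub)) {
      cm <- igraph::components(sub)$membership
      comp_of[names(cm)] <- cm + ncomp
      ncomp <- ncomp + max(cm)
    }
  }
  sizes <- tabulate(comp_of, nbins = ncomp)
  comp_lab <- vapply(split(lab, comp_of), function(v) v[1], logical(1))
  comp_lab <- comp_lab[as.character(seq_len(ncomp))]

  # component adjacency from graph edges crossing components
  el <- igraph::as_edgelist(g)
  flip <- logical(ncomp)
  if (nrow(el)) {
    ca <- comp_of[el[, 1]]; cb <- comp_of[el[, 2]]
    cross <- ca != cb
    adj <- unique(rbind(cbind(ca[cross], cb[cross]),
                        cbind(cb[cross], ca[cross])))
    for (k in seq_len(ncomp)) {
      if (sizes[k] >= small_max) next
      nb <- adj[adj[, 1] == k, 2]
      opp <- nb[comp_lab[nb] != comp_lab[k]]
      if (any(sizes[opp] > large_min)) flip[k] <- TRUE
    }
  }
  new_lab <- lab
  new_lab[flip[comp_of]] <- !lab[flip[comp_of]]
  table$compartment <- ifelse(new_lab[ids], "tumor", "stroma")
  cell_table(table)
}

#' Local point density by disk counts
#'
#' The density at point i is the number of points at Euclidean distance
#' strictly less than \code{radius_um} (the point itself included, i.e.
#' neighbours excluding self, plus one) divided by the disk area, reported
#' in cells per square millimetre. The open-disk convention mirrors the
#' strict density threshold used by the TLS rule; squared distances within
#' one part in 1e9 of the squared radius are treated as boundary ties and
#' excluded, so regular lattices whose shells fall exactly on the radius
#' are counted identically regardless of floating-point rounding.
#'
#' @param points data.frame with \code{x_um}, \code{y_um}.
#' @param radius_um disk radius (default 50).
#' @return numeric vector of densities (cells/mm^2), one per point.
#' @export
local_density <- function(points, radius_um = 50) {
  if (radius_um <= 0) stop("radius_um must be positive")
  x <- points$x_um; y <- points$y_um
  n <- length(x)
  if (!n) return(numeric(0))
  counts <- integer(n)
  chunk <- 512L
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    dx <- outer(x[i0:i1], x, "-")
    dy <- outer(y[i0:i1], y, "-")
    counts[i0:i1] <- rowSums(dx * dx + dy * dy <
                               radius_um^2 * (1 - 1e-9))
  }
  counts / (pi * (radius_um / 1000)^2)
}
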