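# Alpha shapes from the Delaunay triangulation: the alpha complex keeps
# every Delaunay triangle whose circumradius is at most alpha; the alpha
# shape is the boundary of the kept triangles (edges belonging to exactly
# one kept triangle). Each connected set of kept triangles outlines one
# polygon; its area is the summed triangle area and its members are the
# vertices of its triangles. Degenerate inputs (fewer than three points, or
# collinear configurations that admit no triangulation) fall back to
# distance-linked components with a convex-hull outline of zero area.

.circumradius <- function(x, y) {
  a <- sqrt((x[2] - x[1])^2 + (y[2] - y[1])^2)
  b <- sqrt((x[3] - x[2])^2 + (y[3] - y[2])^2)
  c <- sqrt((x[1] - x[3])^2 + (y[1] - y[3])^2)
  ar2 <- abs((x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1]))
  if (ar2 <= 0) return(Inf)
  a * b * c / (2 * ar2)
}

.tri_area <- function(x, y) {
  abs((x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1])) / 2
}

#' Alpha shape of a planar point set
#'
#' @param x,y point coordinates (micrometres).
#' @param alpha_um alpha radius: triangles of the Delaunay triangulation
#'   with circumradius at most this are kept.
#' @return list of components, each a list with \code{members} (point
#'   indices), \code{area_um2} and \code{boundary} (matrix of ring
#'   vertices, closed, or NULL for degenerate components).
#' @export
alpha_shape <- function(x, y, alpha_um) {
  n <- length(x)
  if (n < 3L) return(list())
  dd <- try(deldir::deldir(x, y, suppressMsge = TRUE), silent = TRUE)
  if (inherits(dd, "try-error")) return(.alpha_fallback(x, y, alpha_um))
  tl <- deldir::triang.list(dd)
  if (!length(tl)) return(.alpha_fallback(x, y, alpha_um))
  keep <- Filter(function(tr) .circumradius(tr$x, tr$y) <= alpha_um, tl)
  if (!length(keep)) return(list())

  tri_idx <- lapply(keep, function(tr) as.integer(tr$ptNum))
  # connect triangles through shared vertices -> component per point set
  edges <- do.call(rbind, lapply(tri_idx, function(v)
    cbind(v, v[c(2, 3, 1)])))
  g <- igraph::graph_from_edgelist(apply(edges, 2L, as.character),
                                   directed = FALSE)
  g <- igraph::simplify(g)
  memb <- igraph::components(g)$membership
  comp_of_tri <- vapply(tri_idx, function(v)
    memb[[as.character(v[1])]], numeric(1))

  lapply(sort(unique(comp_of_tri)), function(k) {
    tris <- which(comp_of_tri == k)
    members <- sort(unique(unlist(tri_idx[tris])))
    area <- sum(vapply(keep[tris], function(tr) .tri_area(tr$x, tr$y),
                       numeric(1)))
    # boundary edges: appear in exactly one kept triangle of the component
    ekey <- do.call(rbind, lapply(tri_idx[tris], function(v)
      t(apply(cbind(v, v[c(2, 3, 1)]), 1L, sort))))
    key <- paste(ekey[, 1], ekey[, 2])
    bnd <- ekey[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    list(members = members, area_um2 = area,
         boundary = .assemble_ring(bnd, x, y))
  })
}

# order boundary edges into a closed ring; returns coordinates of the
# longest ring (outer boundary), or NULL if assembly fails
.assemble_ring <- function(bnd, x, y) {
  if (!nrow(bnd)) return(NULL)
  rings <- list()
  remaining <- bnd
  while (nrow(remaining)) {
    ring <- remaining[1, ]
    remaining <- remaining[-1, , drop = FALSE]
    repeat {
      last <- ring[length(ring)]
      nxt <- which(remaining[, 1] == last | remaining[, 2] == last)
      if (!length(nxt)) break
      e <- remaining[nxt[1], ]
      remaining <- remaining[-nxt[1], , drop = FALSE]
      ring <- c(ring, if (e[1] == last) e[2] else e[1])
    }
    rings[[length(rings) + 1L]] <- ring
  }
  ring <- rings[[which.max(vapply(rings, length, integer(1)))]]
  if (ring[1] == ring[length(ring)]) ring <- ring[-length(ring)]
  cbind(x_um = x[ring], y_um = y[ring])
}

# degenerate fallback: distance-linked components, convex-hull outline
.alpha_fallback <- function(x, y, alpha_um) {
  n <- length(x)
  d <- as.matrix(dist(cbind(x, y)))
  g <- igraph::graph_from_adjacency_matrix(d <= 2 * alpha_um & d > 0,
                                           mode = "undirected")
  memb <- igraph::components(g)$membership
  lapply(sort(unique(memb)), function(k) {
    members <- which(memb == k)
    h <- grDevices::chull(x[members], y[members])
    list(members = members, area_um2 = 0,
         boundary = cbind(x_um = x[members][h], y_um = y[members][h]))
  })
}
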