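# Patch detection. Two flavours mirror the two imaging pipelines:
#  * detect_tls: dense B-cell (CD20+CK-) patches as tertiary-lymphoid-
#    structure proxies in whole-slide mIF data -- local density strictly
#    above 2000 cells/mm^2, alpha-shape outline, at least 40 cells;
#  * detect_patches: neighbourhood-graph patches in IMC data -- connected
#    components of at least 25 member-type cells, then expansion to all
#    cells within a fixed distance of a core member (10 um for CD20
#    patches, 25 um for tumour patches).

#' Patch set
#'
#' @param patches list of patches, each with \code{patch_id},
#'   \code{members} (cell ids or point indices), \code{core} (subset of
#'   members), \code{boundary}, \code{area_um2}.
#' @param kind \code{"TLS"}, \code{"CD20"} or \code{"tumor"}.
#' @param params named list of parameters used.
#' @return object of class \code{patch_set}.
#' @export
patch_set <- function(patches, kind = c("TLS", "CD20", "tumor"),
                      params = list()) {
  kind <- match.arg(kind)
  for (p in patches)
    if (!all(p$core %in% p$members))
      stop("core members must be a subset of members")
  structure(list(patches = patches, kind = kind, params = params),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> kind %s, %d patch(es)\n", x$kind,
              length(x$patches)))
  for (p in x$patches)
    cat(sprintf("  %s: %d member(s), %d core, area %.0f um^2\n",
                p$patch_id, length(p$members), length(p$core), p$area_um2))
  invisible(x)
}

#' Number of patches in a patch set
#' @param set a \code{patch_set}.
#' @export
n_patches <- function(set) length(set$patches)

#' Detect dense B-cell patches (TLS proxies)
#'
#' Points whose local density (\code{\link{local_density}}) is strictly
#' above \code{density_threshold} are kept; the alpha shape of the kept
#' points is computed and each connected polygon is a candidate patch
#' whose members are the kept points belonging to it. Patches with fewer
#' than \code{min_cells} members are dropped. No expansion is applied:
#' TLS patches contain only density-passing B cells.
#'
#' @param b_cells data.frame of B-cell positions (\code{x_um, y_um}),
#'   already filtered upstream (CD20+ CK-).
#' @param density_threshold minimum local density, cells/mm^2, strict
#'   (default 2000).
#' @param min_cells minimum patch size (default 40).
#' @param radius_um density disk radius (default 50).
#' @param alpha_um alpha-shape radius (default 50, tied to the density
#'   radius).
#' @return a \code{\link{patch_set}} of kind \code{"TLS"}.
#' @export
detect_tls <- function(b_cells, density_threshold = 2000, min_cells = 40,
                       radius_um = 50, alpha_um = 50) {
  params <- list(density_threshold = density_threshold,
                 min_cells = min_cells, radius_um = radius_um,
                 alpha_um = alpha_um)
  if (!nrow(b_cells))
    return(patch_set(list(), "TLS", params))
  dens <- local_density(b_cells, radius_um = radius_um)
  kept <- which(dens > density_threshold)
  if (length(kept) < 3L) return(patch_set(list(), "TLS", params))
  comps <- alpha_shape(b_cells$x_um[kept], b_cells$y_um[kept], alpha_um)
  comps <- Filter(function(cmp) length(cmp$members) >= min_cells, comps)
  ids <- if ("cell_id" %in% names(b_cells)) as.character(b_cells$cell_id)
  else as.character(seq_len(nrow(b_cells)))
  patches <- lapply(seq_along(comps), function(i) {
    cmp <- comps[[i]]
    mem <- ids[kept[cmp$members]]
    list(patch_id = sprintf("TLS_%d", i), members = mem, core = mem,
         boundary = cmp$boundary, area_um2 = cmp$area_um2)
  })
  patch_set(patches, "TLS", params)
}

#' Detect neighbourhood-graph patches with distance expansion
#'
#' Core patches are connected components of the adjacency graph restricted
#' to cells of the member phenotypes, retained when they hold at least
#' \code{min_cells} cells. Every cell of any phenotype whose centroid lies
#' within \code{expand_um} (inclusive) of the nearest core-member centroid
#' joins the patch. Membership is monotone in \code{expand_um}. The patch
#' outline is the alpha shape of the member centroids.
#'
#' @param cells a \code{\link{cell_table}} with \code{cell_id, x_um, y_um,
#'   phenotype}.
#' @param graph a \code{\link{cell_graph}} over the same cells.
#' @param member_types phenotypes forming patch cores (e.g.
#'   \code{c("B", "BnT")}).
#' @param min_cells minimum core size (default 25).
#' @param expand_um expansion distance; 10 for CD20 patches, 25 for tumour
#'   patches (default 0 = no expansion).
#' @param kind patch kind label.
#' @param alpha_um alpha radius for the outline (default 50).
#' @return a \code{\link{patch_set}}.
#' @export
detect_patches <- function(cells, graph, member_types, min_cells = 25,
                           expand_um = 0, kind = c("CD20", "tumor", "TLS"),
                           alpha_um = 50) {
  kind <- match.arg(kind)
  stopifnot(inherits(graph, "cell_graph"))
  params <- list(member_types = member_types, min_cells = min_cells,
                 expand_um = expand_um, alpha_um = alpha_um)
  ids <- as.character(cells$cell_id)
  member <- cells$phenotype %in% member_types
  if (!any(member)) return(patch_set(list(), kind, params))
  sub <- igraph::induced_subgraph(graph$graph, ids[member])
  cm <- igraph::components(sub)$membership
  cores <- split(names(cm), cm)
  cores <- Filter(function(v) length(v) >= min_cells, cores)
  if (!length(cores)) return(patch_set(list(), kind, params))
  x <- setNames(cells$x_um, ids); y <- setNames(cells$y_um, ids)
  patches <- lapply(seq_along(cores), function(i) {
    core <- cores[[i]]
    # distance from every cell to the nearest core-member centroid
    dx <- outer(cells$x_um, x[core], "-")
    dy <- outer(cells$y_um, y[core], "-")
    nearest <- sqrt(apply(dx * dx + dy * dy, 1L, min))
    mem <- ids[nearest <= expand_um | ids %in% core]
    sh <- alpha_shape(x[mem], y[mem], alpha_um)
    area <- sum(vapply(sh, function(cmp) cmp$area_um2, numeric(1)))
    bnd <- if (length(sh)) sh[[which.max(vapply(sh, function(cmp)
      length(cmp$members), integer(1)))]]$boundary else NULL
    list(patch_id = sprintf("%s_%d", kind, i), members = mem, core = core,
         boundary = bnd, area_um2 = area)
  })
  patch_set(patches, kind, params)
}

#' Export a patch set as GeoJSON (polygons) plus a membership CSV
#'
#' @param set a \code{patch_set}.
#' @param geojson_path,csv_path output paths.
#' @export
write_patch_set <- function(set, geojson_path, csv_path) {
  feats <- lapply(set$patches, function(p) {
    ring <- p$boundary
    coords <- if (is.null(ring)) list() else {
      ring <- rbind(ring, ring[1, , drop = FALSE])  # close the ring
      list(lapply(seq_len(nrow(ring)), function(i) as.numeric(ring[i, ])))
    }
    list(type = "Feature",
         properties = list(patch_id = p$patch_id, kind = set$kind,
                           n_members = length(p$members),
                           area_um2 = p$area_um2),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       geojson_path, auto_unbox = TRUE, digits = NA)
  mem <- do.call(rbind, lapply(set$patches, function(p)
    data.frame(patch_id = p$patch_id, cell_id = p$members,
               core = p$members %in% p$core)))
  if (is.null(mem))
    mem <- data.frame(patch_id = character(0), cell_id = character(0),
                      core = logical(0))
  write.csv(mem, csv_path, row.names = FALSE)
  invisible(set)
}
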