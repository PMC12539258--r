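# Nuclear segmentation from the DAPI channel, Voronoi-constrained cell
# expansion, cytoplasm derivation and cross-method mask matching.
#
# Nuclei: adaptive (local-mean) thresholding, hole filling, small-object
# removal, then watershed on the Euclidean distance map restricted to the
# foreground. Cells: in the absence of a membrane stain, each nucleus is
# extended by up to 5 um or until meeting a neighbouring nucleus
# (a distance-constrained Voronoi partition of the background). Cytoplasm
# is the set difference cell minus nucleus, label by label.

# Exact local mean over a w x w window (w odd) via an integral image with
# replicated borders; unlike FFT convolution this is free of ringing, so a
# zero-intensity pixel never exceeds its local mean.
.box_mean <- function(x, w) {
  h <- (w - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  xp <- x[c(rep(1L, h), seq_len(nr), rep(nr, h)),
          c(rep(1L, h), seq_len(nc), rep(nc, h)), drop = FALSE]
  S <- matrix(0, nr + w, nc + w)
  S[-1, -1] <- apply(apply(xp, 2L, cumsum), 1L, cumsum) |> t()
  m <- (S[(1 + w):(nr + w), (1 + w):(nc + w)] -
          S[1:nr, (1 + w):(nc + w)] - S[(1 + w):(nr + w), 1:nc] +
          S[1:nr, 1:nc]) / (w * w)
  pmax(m, 0)  # cancellation in the running sums can leave ~ -1e-13
}

#' Segment nuclei from a DAPI image
#'
#' Pipeline: (i) foreground = pixels strictly exceeding the local mean over
#' a square window of side \code{window_um}, minus \code{offset};
#' (ii) holes filled; (iii) objects smaller than \code{min_area_um2}
#' removed; (iv) Euclidean distance transform of the foreground;
#' (v, vi) watershed of the negated distance map restricted to the
#' foreground, with basins whose peaks are closer than
#' \code{min_peak_sep_um} merged. Deterministic for fixed input and
#' parameters. An all-zero (or constant) image yields an empty mask.
#'
#' @param dapi numeric matrix (single channel), finite, non-negative.
#' @param pixel_size_um pixel size in micrometres.
#' @param window_um side of the local-mean window (default 51).
#' @param offset subtracted from the local mean before comparison
#'   (default 0; larger values admit more foreground).
#' @param min_area_um2 minimum object area kept (default 8).
#' @param min_peak_sep_um minimum separation of watershed peaks
#'   (default 4).
#' @return a \code{\link{label_mask}} (8-connectivity objects).
#' @export
segment_nuclei <- function(dapi, pixel_size_um, window_um = 51, offset = 0,
                           min_area_um2 = 8, min_peak_sep_um = 4) {
  stopifnot(is.matrix(dapi), all(is.finite(dapi)), all(dapi >= 0))
  if (window_um <= 0) stop("window_um must be positive")
  s <- pixel_size_um
  w <- max(3L, round(window_um / s))
  if (w %% 2L == 0L) w <- w + 1L
  lm <- .box_mean(dapi, w)
  fg <- dapi > (lm - offset)
  if (!any(fg)) return(label_mask(matrix(0L, nrow(dapi), ncol(dapi)), s,
                                  validate = FALSE))
  fg <- EBImage::fillHull(matrix(as.numeric(fg), nrow(dapi))) > 0
  lab <- label_components(fg, connectivity = 8L)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = max(lab)) * s^2
    lab[lab > 0L & areas[pmax(lab, 1L)] < min_area_um2] <- 0L
    fg <- lab > 0L
  }
  if (!any(fg)) return(label_mask(matrix(0L, nrow(dapi), ncol(dapi)), s,
                                  validate = FALSE))
  dm <- EBImage::distmap(matrix(as.numeric(fg), nrow(dapi)))
  ws <- EBImage::watershed(dm, tolerance = 1,
                           ext = max(1L, round(min_peak_sep_um / s)))
  out <- matrix(as.integer(ws), nrow(dapi), ncol(dapi))
  # compact label ids
  ids <- mask_labels(out)
  if (length(ids)) out[out > 0L] <- match(out[out > 0L], ids)
  label_mask(out, s, validate = FALSE)
}

#' Segmentation result (nuclei, cells, cytoplasm)
#'
#' @param nuclei,cells,cytoplasm \code{\link{label_mask}}s sharing shape,
#'   pixel size and label ids; every nucleus pixel carries the same cell
#'   label, and cytoplasm = cells minus nuclei per label.
#' @return object of class \code{segmentation_result}.
#' @export
segmentation_result <- function(nuclei, cells, cytoplasm) {
  stopifnot(inherits(nuclei, "label_mask"), inherits(cells, "label_mask"),
            inherits(cytoplasm, "label_mask"))
  if (!identical(dim(nuclei$labels), dim(cells$labels)))
    stop("mask shapes differ")
  nn <- nuclei$labels > 0L
  if (any(cells$labels[nn] != nuclei$labels[nn]))
    stop("cells must contain nuclei with identical labels")
  if (any(cytoplasm$labels != ifelse(nn, 0L, cells$labels)))
    stop("cytoplasm must equal cells minus nuclei per label")
  structure(list(nuclei = nuclei, cells = cells, cytoplasm = cytoplasm,
                 pixel_size_um = nuclei$pixel_size_um),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d cell(s), %d x %d px, %.3g um/px\n",
              length(mask_labels(x$nuclei)), nrow(x$nuclei$labels),
              ncol(x$nuclei$labels), x$pixel_size_um))
  invisible(x)
}

#' Expand nuclei into cell regions (distance-constrained Voronoi)
#'
#' Every background pixel joins the label of the nucleus with the smallest
#' Euclidean set distance (distance to the nearest nucleus pixel, computed
#' on the pixel grid), provided that distance is at most
#' \code{max_dist_um}; ties go to the smaller label id. Equivalently, each
#' nucleus grows by up to \code{max_dist_um} or until meeting the Voronoi
#' boundary of a neighbouring nucleus.
#'
#' @param nuclei a \code{\link{label_mask}}.
#' @param max_dist_um maximum expansion distance (default 5).
#' @return a \code{\link{segmentation_result}}.
#' @export
expand_cells <- function(nuclei, max_dist_um = 5) {
  stopifnot(inherits(nuclei, "label_mask"), max_dist_um >= 0)
  s <- nuclei$pixel_size_um
  lab <- nuclei$labels
  ids <- mask_labels(lab)
  best_d <- matrix(Inf, nrow(lab), ncol(lab))
  best_l <- matrix(0L, nrow(lab), ncol(lab))
  for (l in ids) {  # ids ascending: strict '<' gives ties to smaller label
    x <- matrix(as.numeric(lab != l), nrow(lab))
    dl <- EBImage::distmap(x) * s
    upd <- dl < best_d
    best_d[upd] <- dl[upd]
    best_l[upd] <- l
  }
  cells <- ifelse(best_d <= max_dist_um, best_l, 0L)
  storage.mode(cells) <- "integer"
  cyto <- ifelse(lab > 0L, 0L, cells)
  storage.mode(cyto) <- "integer"
  segmentation_result(
    nuclei,
    label_mask(cells, s, connectivity = nuclei$connectivity,
               validate = FALSE),
    label_mask(cyto, s, connectivity = nuclei$connectivity,
               validate = FALSE))
}

#' Match two label masks by overlap coefficient
#'
#' For every intersecting label pair the Szymkiewicz-Simpson overlap
#' coefficient \code{|A and B| / min(|A|, |B|)} is computed. Pairs with a
#' coefficient strictly above 0.5 are retained and assembled into a
#' bipartite match graph; each connected component is classified by its
#' side cardinalities as \code{"1 - 1"}, \code{"1 - many"},
#' \code{"many - 1"} or \code{"many - many"} (at least two labels on both
#' sides). Labels with no retained partner are reported as
#' \code{"1 - missing"} (mask A) or \code{"missing - 1"} (mask B).
#'
#' @param mask_a,mask_b \code{\link{label_mask}}s of equal shape and pixel
#'   size.
#' @param threshold retention threshold on the coefficient (strict;
#'   default 0.5).
#' @return object of class \code{match_report}: \code{pairs} (all
#'   intersecting pairs with coefficients and retention flag),
#'   \code{components} (one row per matched component or unmatched label),
#'   \code{class_counts}.
#' @export
match_masks <- function(mask_a, mask_b, threshold = 0.5) {
  stopifnot(inherits(mask_a, "label_mask"), inherits(mask_b, "label_mask"))
  if (!identical(dim(mask_a$labels), dim(mask_b$labels)))
    stop("mask shapes differ")
  if (mask_a$pixel_size_um != mask_b$pixel_size_um)
    stop("pixel sizes differ")
  a <- mask_a$labels; b <- mask_b$labels
  ids_a <- mask_labels(a); ids_b <- mask_labels(b)
  size_a <- tabulate(a[a > 0L], nbins = max(a, 1L))
  size_b <- tabulate(b[b > 0L], nbins = max(b, 1L))
  both <- a > 0L & b > 0L
  if (any(both)) {
    tab <- table(A = a[both], B = b[both])
    idx <- which(tab > 0, arr.ind = TRUE)
    pairs <- data.frame(
      label_a = as.integer(rownames(tab))[idx[, 1]],
      label_b = as.integer(colnames(tab))[idx[, 2]],
      intersection = as.integer(tab[idx]))
    pairs$size_a <- size_a[pairs$label_a]
    pairs$size_b <- size_b[pairs$label_b]
    pairs$overlap <- pairs$intersection / pmin(pairs$size_a, pairs$size_b)
    pairs$retained <- pairs$overlap > threshold
  } else {
    pairs <- data.frame(label_a = integer(0), label_b = integer(0),
                        intersection = integer(0), size_a = integer(0),
                        size_b = integer(0), overlap = numeric(0),
                        retained = logical(0))
  }
  ret <- pairs[pairs$retained, , drop = FALSE]
  comp_rows <- list()
  if (nrow(ret)) {
    g <- igraph::graph_from_edgelist(
      cbind(paste0("A", ret$label_a), paste0("B", ret$label_b)),
      directed = FALSE)
    cm <- igraph::components(g)$membership
    for (k in sort(unique(cm))) {
      v <- names(cm)[cm == k]
      na <- sum(startsWith(v, "A")); nb <- sum(startsWith(v, "B"))
      cls <- if (na == 1L && nb == 1L) "1 - 1"
      else if (na == 1L) "1 - many"
      else if (nb == 1L) "many - 1"
      else "many - many"
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        class = cls,
        labels_a = paste(sort(as.integer(sub("^A", "", v[startsWith(v, "A")]))),
                         collapse = ";"),
        labels_b = paste(sort(as.integer(sub("^B", "", v[startsWith(v, "B")]))),
                         collapse = ";"))
    }
  }
  matched_a <- unique(ret$label_a); matched_b <- unique(ret$label_b)
  for (l in setdiff(ids_a, matched_a))
    comp_rows[[length(comp_rows) + 1L]] <-
      data.frame(class = "1 - missing", labels_a = as.character(l),
                 labels_b = "")
  for (l in setdiff(ids_b, matched_b))
    comp_rows[[length(comp_rows) + 1L]] <-
      data.frame(class = "missing - 1", labels_a = "",
                 labels_b = as.character(l))
  components <- if (length(comp_rows)) do.call(rbind, comp_rows) else
    data.frame(class = character(0), labels_a = character(0),
               labels_b = character(0))
  classes <- c("1 - 1", "1 - many", "many - 1", "many - many",
               "1 - missing", "missing - 1")
  counts <- setNames(vapply(classes, function(cl)
    sum(components$class == cl), integer(1)), classes)
  structure(list(pairs = pairs, components = components,
                 class_counts = counts, threshold = threshold),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat("<match_report>\n")
  print(x$class_counts)
  invisible(x)
}

#' Export a match report as a pair-table CSV plus class-count JSON
#' @param report a \code{match_report}.
#' @param csv_path,json_path output paths.
#' @export
write_match_report <- function(report, csv_path, json_path) {
  write.csv(report$pairs, csv_path, row.names = FALSE)
  jsonlite::write_json(as.list(report$class_counts), json_path,
                       auto_unbox = TRUE)
  invisible(report)
}
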