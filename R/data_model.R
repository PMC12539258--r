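#' @importFrom stats median quantile sd rnorm runif rpois rmultinom setNames
#' @importFrom utils read.csv write.csv head
NULL

# ---- MarkerImageStack --------------------------------------------------

#' Multi-channel marker image stack
#'
#' Container for an H x W x C grid of non-negative pixel intensities with a
#' channel manifest and a physical pixel size. The raw and unmixed image
#' carrier for both mIF and IMC modalities.
#'
#' Coordinate convention used throughout the package: continuous micrometre
#' coordinates with the origin at the top-left pixel corner, x pointing
#' right (columns) and y pointing down (rows); the centre of pixel
#' \code{(r, c)} (1-based) is at \code{((c - 0.5) * s, (r - 0.5) * s)} where
#' \code{s} is the pixel size in micrometres.
#'
#' @param pixels numeric array H x W x C (a matrix is promoted to C = 1),
#'   finite and non-negative.
#' @param channels data.frame with columns \code{channel_id}, \code{marker},
#'   \code{fluorophore}; one row per channel, marker names unique.
#' @param pixel_size_um physical pixel size in micrometres (> 0).
#' @param image_id character scalar identifier.
#' @param modality \code{"mIF"} or \code{"IMC"}.
#' @return An object of class \code{image_stack}.
#' @export
image_stack <- function(pixels, channels, pixel_size_um, image_id = "image",
                        modality = c("mIF", "IMC")) {
  modality <- match.arg(modality)
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have H, W >= 1")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("pixel intensities must be finite and >= 0")
  channels <- as.data.frame(channels)
  need <- c("channel_id", "marker", "fluorophore")
  if (!all(need %in% names(channels)))
    stop("channel manifest needs columns: ", paste(need, collapse = ", "))
  if (nrow(channels) != dim(pixels)[3])
    stop("channel manifest has ", nrow(channels), " rows but image has ",
         dim(pixels)[3], " channels")
  if (anyDuplicated(channels$marker))
    stop("duplicate marker name in channel manifest: ",
         paste(unique(channels$marker[duplicated(channels$marker)]),
               collapse = ", "))
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  dimnames(pixels) <- list(NULL, NULL, channels$marker)
  structure(
    list(pixels = pixels, channels = channels,
         pixel_size_um = as.numeric(pixel_size_um),
         image_id = as.character(image_id), modality = modality),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack> %s [%s] %d x %d px, %d channel(s), %.3g um/px\n",
              x$image_id, x$modality, d[1], d[2], d[3], x$pixel_size_um))
  cat("  markers:", paste(x$channels$marker, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one channel of an image stack as a matrix
#'
#' @param stack an \code{image_stack}.
#' @param marker marker name or channel index.
#' @return H x W numeric matrix.
#' @export
get_channel <- function(stack, marker) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(marker)) {
    i <- match(marker, stack$channels$marker)
    if (is.na(i)) stop("unknown marker: ", marker)
  } else i <- as.integer(marker)
  stack$pixels[, , i]
}

# ---- LabelMask ---------------------------------------------------------

#' Integer-labelled pixel mask
#'
#' An H x W integer grid where 0 is background and positive integers are
#' object ids (nuclei, cells or cytoplasm regions). Label ids need not be
#' consecutive, but each label's pixel set must be connected under the
#' declared connectivity.
#'
#' @param labels integer matrix (H x W), values >= 0.
#' @param pixel_size_um pixel size in micrometres.
#' @param connectivity 4 or 8 (default 8).
#' @param validate check the per-label connectivity invariant (default TRUE;
#'   O(labels * pixels), disable for very large masks).
#' @return An object of class \code{label_mask}.
#' @export
label_mask <- function(labels, pixel_size_um, connectivity = 8L,
                       validate = TRUE) {
  stopifnot(is.matrix(labels))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be positive")
  storage.mode(labels) <- "integer"
  m <- structure(list(labels = labels,
                      pixel_size_um = as.numeric(pixel_size_um),
                      connectivity = connectivity),
                 class = "label_mask")
  if (validate) {
    bad <- Filter(function(l) {
      cc <- label_components(labels == l, connectivity = connectivity)
      max(cc) > 1L
    }, mask_labels(m))
    if (length(bad))
      stop("label(s) not connected under ", connectivity, "-connectivity: ",
           paste(head(bad, 5L), collapse = ", "))
  }
  m
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px, %d object(s), %.3g um/px, %d-conn\n",
              nrow(x$labels), ncol(x$labels), length(mask_labels(x)),
              x$pixel_size_um, x$connectivity))
  invisible(x)
}

#' Sorted positive label ids present in a mask
#' @param mask a \code{label_mask} or integer matrix.
#' @return increasing integer vector of object ids.
#' @export
mask_labels <- function(mask) {
  m <- if (inherits(mask, "label_mask")) mask$labels else mask
  v <- sort(unique(as.vector(m)))
  v[v > 0L]
}

#' Connected-component labelling of a binary image
#'
#' 4-connectivity uses \code{EBImage::bwlabel} directly; 8-connectivity
#' additionally merges components that touch diagonally.
#'
#' @param binary logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of component labels (0 background), labels
#'   consecutive from 1 in raster order of first occurrence.
#' @export
label_components <- function(binary, connectivity = 8L) {
  b <- matrix(as.numeric(binary != 0), nrow(binary), ncol(binary))
  lab <- EBImage::bwlabel(b)
  lab <- matrix(as.integer(lab), nrow(b), ncol(b))
  if (connectivity == 8L && max(lab) > 1L) {
    # merge 4-components that touch corner-to-corner
    nr <- nrow(lab); nc <- ncol(lab)
    a <- lab[-nr, -nc]; d <- lab[-1, -1]        # down-right diagonal
    b2 <- lab[-nr, -1]; c2 <- lab[-1, -nc]      # down-left diagonal
    pairs <- rbind(cbind(a[a > 0 & d > 0 & a != d], d[a > 0 & d > 0 & a != d]),
                   cbind(b2[b2 > 0 & c2 > 0 & b2 != c2],
                         c2[b2 > 0 & c2 > 0 & b2 != c2]))
    if (nrow(pairs)) {
      g <- igraph::graph_from_edgelist(
        matrix(as.character(pairs), ncol = 2L), directed = FALSE)
      g <- igraph::simplify(g)
      comp <- igraph::components(g)$membership
      remap <- seq_len(max(lab))
      remap[as.integer(names(comp))] <-
        max(lab) + comp  # temporary ids, then compact below
      lab[lab > 0] <- remap[lab[lab > 0]]
    }
  }
  # compact to 1..K in raster order of first occurrence
  pos <- which(lab > 0)
  if (length(pos)) {
    first <- !duplicated(lab[pos])
    key <- lab[pos][first]
    lab[pos] <- match(lab[pos], key)
  }
  lab
}

# ---- CellTable ---------------------------------------------------------

#' Construct / validate a cell table
#'
#' One row per segmented cell: identity, centroid (micrometres, origin at
#' the top-left pixel corner), area, per-(marker, region, statistic) scores
#' (columns \code{<marker>_<region>_<stat>}), active scores
#' (\code{score_<marker>}), positivity flags (\code{pos_<marker>}),
#' phenotype, tumour/stroma compartment, TLS membership and free annotation
#' columns.
#'
#' @param df data.frame with at least \code{image_id, cell_id, x_um, y_um,
#'   area_um2}.
#' @return the validated data.frame with class \code{cell_table}.
#' @export
cell_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("image_id", "cell_id", "x_um", "y_um", "area_um2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cell table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (anyDuplicated(df[c("image_id", "cell_id")]))
      stop("duplicate (image_id, cell_id) in cell table")
    if (any(df$area_um2 <= 0)) stop("area_um2 must be > 0")
    if (any(df$x_um < 0) || any(df$y_um < 0))
      stop("coordinates must be >= 0")
  }
  class(df) <- unique(c("cell_table", class(df)))
  df
}

#' Marker names for which a cell table carries positivity flags
#' @param table a cell table.
#' @return character vector of marker names.
#' @export
table_markers <- function(table) {
  sub("^pos_", "", grep("^pos_", names(table), value = TRUE))
}

# ---- ThresholdSet ------------------------------------------------------

#' Per-marker score definitions and positivity thresholds
#'
#' Each marker is scored by one summary statistic over one region; a cell is
#' positive for the marker iff its score is strictly above the threshold.
#'
#' @param df data.frame with columns \code{marker}, \code{region}
#'   (nucleus/cytoplasm/cell), \code{statistic} (mean/median/p75/p90) and
#'   \code{threshold} (finite, intensity units).
#' @return validated data.frame of class \code{threshold_set}.
#' @export
threshold_set <- function(df) {
  df <- as.data.frame(df)
  need <- c("marker", "region", "statistic", "threshold")
  if (!all(need %in% names(df)))
    stop("threshold set needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$marker)) stop("one threshold entry per marker")
  if (!all(df$region %in% c("nucleus", "cytoplasm", "cell")))
    stop("region must be nucleus, cytoplasm or cell")
  if (!all(df$statistic %in% c("mean", "median", "p75", "p90")))
    stop("statistic must be one of mean, median, p75, p90")
  if (!all(is.finite(df$threshold))) stop("thresholds must be finite")
  class(df) <- unique(c("threshold_set", class(df)))
  df
}

# ---- QCReport ----------------------------------------------------------

qc_report <- function(status, reasons, marker_flags = character(0)) {
  stopifnot(status %in% c("PASS", "WARN", "FAIL"))
  if (status == "FAIL" && !any(reasons$level == "FAIL"))
    stop("FAIL report must record at least one FAIL-level reason")
  structure(list(status = status, reasons = reasons,
                 marker_flags = marker_flags),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>", x$status, "\n")
  if (nrow(x$reasons))
    for (i in seq_len(nrow(x$reasons)))
      cat(sprintf("  [%s] %s: %s\n", x$reasons$level[i], x$reasons$rule_id[i],
                  x$reasons$message[i]))
  invisible(x)
}
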