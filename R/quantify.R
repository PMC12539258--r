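# Per-cell marker quantification and threshold-based phenotyping.

.region_stats <- c("mean", "median", "p75", "p90")

.stat_fun <- function(stat) {
  switch(stat,
         mean = mean,
         median = median,
         p75 = function(x) unname(quantile(x, 0.75, type = 7)),
         p90 = function(x) unname(quantile(x, 0.90, type = 7)),
         stop("unknown statistic: ", stat))
}

#' Quantify marker signal per cell
#'
#' For every cell and marker channel, summary statistics (mean, median,
#' 75th and 90th percentile) of pixel intensities are computed over the
#' nucleus, cytoplasm and whole-cell regions. Cells whose cytoplasm is
#' empty get missing values (NA) for cytoplasm statistics, not zeros.
#' Centroids (micrometres, top-left-corner origin) and areas are computed
#' from the cell mask.
#'
#' @param stack an \code{\link{image_stack}} sharing shape and pixel size
#'   with the masks.
#' @param seg a \code{\link{segmentation_result}}.
#' @param statistics subset of \code{c("mean","median","p75","p90")}.
#' @param markers channels to quantify (default: all).
#' @return a \code{\link{cell_table}} with columns
#'   \code{<marker>_<region>_<stat>}.
#' @export
quantify_cells <- function(stack, seg, statistics = .region_stats,
                           markers = stack$channels$marker) {
  stopifnot(inherits(stack, "image_stack"),
            inherits(seg, "segmentation_result"))
  statistics <- match.arg(statistics, .region_stats, several.ok = TRUE)
  d <- dim(stack$pixels)
  if (!identical(d[1:2], dim(seg$cells$labels)))
    stop("stack and masks have different shapes")
  if (stack$pixel_size_um != seg$pixel_size_um)
    stop("stack and masks have different pixel sizes")
  extra <- setdiff(mask_labels(seg$cells), mask_labels(seg$nuclei))
  if (length(extra))
    stop("label(s) present in cells but not in nuclei: ",
         paste(head(extra, 5), collapse = ", "))

  s <- stack$pixel_size_um
  ids <- mask_labels(seg$cells)
  cl <- seg$cells$labels
  idx_cell <- which(cl > 0L)
  fl <- factor(cl[idx_cell], levels = ids)
  rows <- ((idx_cell - 1L) %% d[1]) + 1L
  cols <- ((idx_cell - 1L) %/% d[1]) + 1L
  npx <- as.integer(table(fl))
  out <- data.frame(
    image_id = stack$image_id, cell_id = ids,
    x_um = as.numeric(tapply((cols - 0.5) * s, fl, mean)),
    y_um = as.numeric(tapply((rows - 0.5) * s, fl, mean)),
    area_um2 = npx * s^2)

  region_index <- list(
    nucleus = seg$nuclei$labels, cytoplasm = seg$cytoplasm$labels,
    cell = cl)
  for (marker in markers) {
    ch <- get_channel(stack, marker)
    for (rg in names(region_index)) {
      m <- region_index[[rg]]
      idx <- which(m > 0L)
      f <- factor(m[idx], levels = ids)
      vals <- split(ch[idx], f)
      for (st in statistics) {
        fun <- .stat_fun(st)
        v <- vapply(vals, function(x) if (length(x)) fun(x) else NA_real_,
                    numeric(1))
        out[[paste(marker, rg, st, sep = "_")]] <- unname(v)
      }
    }
  }
  cell_table(out)
}

#' Apply positivity thresholds to a cell table
#'
#' Each marker's active score (\code{score_<marker>}) is the configured
#' (region, statistic) column; the positivity flag \code{pos_<marker>} is
#' TRUE iff the score is strictly above the threshold (a score exactly at
#' the threshold is negative). Missing scores (e.g. empty cytoplasm) count
#' as negative. Idempotent: flags are recomputed from scores on every call.
#'
#' @param table a \code{\link{cell_table}} carrying the configured score
#'   columns.
#' @param thresholds a \code{\link{threshold_set}}.
#' @return the table with \code{score_*} and \code{pos_*} columns set.
#' @export
apply_thresholds <- function(table, thresholds) {
  thresholds <- threshold_set(thresholds)
  for (i in seq_len(nrow(thresholds))) {
    mk <- thresholds$marker[i]
    col <- paste(mk, thresholds$region[i], thresholds$statistic[i], sep = "_")
    if (!col %in% names(table))
      stop("cell table lacks score column '", col, "' for marker ", mk)
    sc <- table[[col]]
    table[[paste0("score_", mk)]] <- sc
    table[[paste0("pos_", mk)]] <- !is.na(sc) & sc > thresholds$threshold[i]
  }
  cell_table(table)
}

#' Assign phenotypes from positivity flags
#'
#' Each cell's combination of \code{pos_*} flags is matched against the
#' key's rules; conflicts are resolved by the marker priority order and
#' unmatched combinations fall back to the key's fallback label. Invariant
#' to cell ordering.
#'
#' @param table a \code{\link{cell_table}} with \code{pos_<marker>} columns
#'   for all key markers.
#' @param key a \code{\link{phenotype_key}}.
#' @return the table with a \code{phenotype} column.
#' @export
assign_phenotypes <- function(table, key) {
  stopifnot(inherits(key, "phenotype_key"))
  cols <- paste0("pos_", key$markers)
  miss <- setdiff(cols, names(table))
  if (length(miss))
    stop("cell table lacks positivity flag(s): ", paste(miss, collapse = ", "))
  lut <- validate_phenotype_key(key)          # all 2^M combos, resolved once
  m <- length(key$markers)
  if (nrow(table)) {
    flags <- as.matrix(table[cols]) * 1L
    idx <- as.integer(flags %*% 2^(seq_len(m) - 1L)) + 1L
    table$phenotype <- lut$phenotype[idx]
  } else table$phenotype <- character(0)
  cell_table(table)
}
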