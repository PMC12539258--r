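# Readers/writers for the plain-text and TIFF dialects used by the package.
# Supported image dialect: plain multi-page TIFF plus a sidecar CSV manifest
# (channel_id, marker, fluorophore, pixel_size_um, ...). Pyramidal
# multispectral containers (QPTIFF) are out of scope; convert upstream.

#' Read a multi-channel image stack from a multi-page TIFF
#'
#' @param path TIFF file, one page per channel.
#' @param manifest data.frame or path to a CSV with columns
#'   \code{channel_id, marker, fluorophore} and optionally
#'   \code{pixel_size_um}, \code{image_id}, \code{modality},
#'   \code{intensity_scale}.
#' @param pixel_size_um pixel size override; required when the manifest does
#'   not carry one.
#' @return an \code{\link{image_stack}}.
#' @export
read_image_stack <- function(path, manifest, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.character(manifest)) manifest <- read.csv(manifest)
  manifest <- as.data.frame(manifest)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  if (nrow(manifest) != length(pages))
    stop("manifest has ", nrow(manifest), " channels but TIFF has ",
         length(pages), " pages")
  if (is.null(pixel_size_um)) {
    if (!"pixel_size_um" %in% names(manifest))
      stop("pixel size missing: supply pixel_size_um or a manifest column")
    pixel_size_um <- manifest$pixel_size_um[1]
  }
  scale <- if ("intensity_scale" %in% names(manifest))
    manifest$intensity_scale[1] else 1
  px <- array(0, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) px[, , i] <- pages[[i]] * scale
  px[px < 0] <- 0
  image_stack(px, manifest[c("channel_id", "marker", "fluorophore")],
              pixel_size_um,
              image_id = if ("image_id" %in% names(manifest))
                as.character(manifest$image_id[1]) else "image",
              modality = if ("modality" %in% names(manifest))
                manifest$modality[1] else "mIF")
}

#' Write an image stack as multi-page float TIFF plus manifest CSV
#'
#' Intensities are scaled into [0, 1] by a power-of-two factor recorded in
#' the manifest (\code{intensity_scale}; exact in binary floating point)
#' and stored as 32-bit samples (2^32 - 1 levels). The quantization step
#' is \code{scale / 2^32}, i.e. a relative precision of about 2.3e-10;
#' integer-valued intensities (e.g. 8/16-bit camera counts) are recovered
#' exactly after rounding.
#'
#' @param stack an \code{\link{image_stack}}.
#' @param path output TIFF path.
#' @param manifest_path output manifest CSV path (default: same name with
#'   \code{_manifest.csv}).
#' @return invisibly, the manifest data.frame.
#' @export
write_image_stack <- function(stack, path,
                              manifest_path = sub("\\.tiff?$", "_manifest.csv",
                                                  path)) {
  stopifnot(inherits(stack, "image_stack"))
  mx <- max(stack$pixels, 1)
  scale <- 2^ceiling(log2(mx))
  pages <- lapply(seq_len(dim(stack$pixels)[3]),
                  function(i) stack$pixels[, , i] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  man <- cbind(stack$channels,
               pixel_size_um = stack$pixel_size_um,
               image_id = stack$image_id, modality = stack$modality,
               intensity_scale = scale)
  write.csv(man, manifest_path, row.names = FALSE)
  invisible(man)
}

#' Read / write an integer label mask as TIFF
#'
#' Labels are stored as 16-bit unsigned integers (max 65535 objects).
#' @param mask a \code{\link{label_mask}}.
#' @param path TIFF path.
#' @param pixel_size_um pixel size for reading.
#' @param connectivity declared object connectivity for reading.
#' @return \code{read_label_mask}: a \code{label_mask};
#'   \code{write_label_mask}: invisibly, the path.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask$labels) > 65535L) stop("more than 65535 labels")
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path, pixel_size_um, connectivity = 8L) {
  p <- tiff::readTIFF(path)
  if (length(dim(p)) == 3L) p <- p[, , 1]
  label_mask(matrix(as.integer(round(p * 65535)), nrow(p), ncol(p)),
             pixel_size_um, connectivity = connectivity, validate = FALSE)
}

# Canonical column order of the exported cell table CSV; unknown extra
# columns are preserved after these (annotation passthrough).
.cell_table_core <- c("image_id", "cell_id", "x_um", "y_um", "area_um2")

.cell_table_order <- function(nm) {
  score_def <- grep("_(nucleus|cytoplasm|cell)_(mean|median|p75|p90)$", nm,
                    value = TRUE)
  act <- grep("^score_", nm, value = TRUE)
  pos <- grep("^pos_", nm, value = TRUE)
  tail_cols <- intersect(c("phenotype", "compartment", "in_tls"), nm)
  rest <- setdiff(nm, c(.cell_table_core, score_def, act, pos, tail_cols))
  c(intersect(.cell_table_core, nm), sort(score_def), sort(act), sort(pos),
    tail_cols, rest)
}

#' Write / read a cell table CSV
#'
#' UTF-8, comma-separated, '.' decimal, one header row. Column order:
#' identity and geometry (\code{image_id, cell_id, x_um, y_um, area_um2}),
#' per-(marker, region, statistic) scores, active \code{score_*} columns,
#' \code{pos_*} flags, \code{phenotype}, \code{compartment}, \code{in_tls},
#' then any extra annotation columns (preserved verbatim). Numeric fields
#' round-trip losslessly at >= 6 significant digits.
#'
#' @param table a \code{\link{cell_table}}.
#' @param path CSV path.
#' @return \code{read_cell_table}: a \code{cell_table}.
#' @export
write_cell_table <- function(table, path) {
  table <- cell_table(table)
  df <- as.data.frame(table)[, .cell_table_order(names(table)), drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    # shortest decimal representation that reparses exactly
    ifelse(is.na(x), NA, vapply(x, function(v) format(v, digits = 15), ""))
  })
  write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  for (nm in grep("^(pos_|in_tls)", names(df), value = TRUE))
    df[[nm]] <- as.logical(df[[nm]])
  cell_table(df)
}

#' Serialize / load a mixing model
#'
#' The mixing matrix is written as CSV (rows = channels, columns = sources)
#' and the metadata (background offsets, source names) as a JSON sidecar.
#'
#' @param model a \code{mixing_model}.
#' @param path CSV path; metadata goes to \code{<path>.json}.
#' @return \code{read_mixing_model}: a \code{mixing_model}.
#' @export
write_mixing_model <- function(model, path) {
  stopifnot(inherits(model, "mixing_model"))
  m <- as.data.frame(model$matrix)
  write.csv(cbind(channel = rownames(model$matrix), m), path,
            row.names = FALSE)
  jsonlite::write_json(
    list(sources = model$sources, background = model$background,
         autofluorescence = model$autofluorescence),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mixing_model
#' @export
read_mixing_model <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$channel
  mixing_model(m, sources = meta$sources, background = meta$background,
               autofluorescence = meta$autofluorescence)
}
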