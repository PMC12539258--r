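# End-to-end pipelines chaining the stages, plus configuration handling.
# run_mif_pipeline: unmix -> segment nuclei -> expand cells -> quantify ->
# thresholds -> phenotypes -> tissue segmentation -> TLS detection -> QC.
# run_concordance: landmark alignment -> per-type bivariate pattern ->
# cross-L statistics -> MAD test -> co-localization call.

.default_config <- function() list(
  image = NULL, manifest = NULL, out_dir = NULL, seed = 1L,
  unmixing = list(enabled = FALSE, model = NULL,
                  keep_autofluorescence = FALSE),
  segmentation = list(dapi_marker = "DAPI", window_um = 51, offset = 0,
                      min_area_um2 = 8, min_peak_sep_um = 4,
                      expansion_um = 5),
  thresholds = NULL,
  phenotype_key = NULL, phenotype_priority = NULL,
  phenotype_fallback = "other",
  tissue = list(marker = "CK", small_max = 5, large_min = 10,
                graph_method = "delaunay_maxlen", graph_param_um = 30),
  tls = list(b_phenotype = "B", density_threshold = 2000, min_cells = 40,
             radius_um = 50, alpha_um = 50),
  qc = list(missing_folded_fraction = 0,
            markers_missing_signal = character(0), fully_necrotic = FALSE))

#' Load and validate a pipeline configuration
#'
#' Unknown keys (top-level or within a stage block) are rejected; known
#' keys override the documented defaults.
#'
#' @param config named list, or path to a YAML/JSON file.
#' @return validated configuration list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  base <- .default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(config)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]])) &&
        is.list(config[[k]])) {
      bad <- setdiff(names(config[[k]]), names(base[[k]]))
      if (length(bad))
        stop("unknown key(s) in config block '", k, "': ",
             paste(bad, collapse = ", "))
      base[[k]][names(config[[k]])] <- config[[k]]
    } else base[[k]] <- config[[k]]
  }
  structure(base, class = c("pipeline_config", "list"))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the mIF quantification pipeline
#'
#' Executes unmixing (optional), nuclear segmentation, cell expansion,
#' per-cell quantification, thresholding, phenotype assignment,
#' tumour-stroma tissue segmentation, TLS detection and sample QC. When
#' \code{out_dir} is set, stage outputs (cell table CSV, masks, patches,
#' QC report) and a machine-readable provenance record (configuration
#' hash, seed, package version) are persisted; identical configurations
#' reproduce identical outputs.
#'
#' @param config a \code{\link{pipeline_config}} (or list / YAML path).
#'   Required entries: \code{image} (an \code{image_stack}, or TIFF path
#'   with \code{manifest}), \code{thresholds} (\code{threshold_set},
#'   data.frame or CSV path) covering every quantified marker, and
#'   \code{phenotype_key} (a \code{phenotype_key} or CSV path).
#' @return list with \code{table} (cell table), \code{seg}
#'   (\code{segmentation_result}), \code{tls} (\code{patch_set}),
#'   \code{qc} (\code{qc_report}) and \code{provenance}.
#' @export
run_mif_pipeline <- function(config) {
  cfg <- pipeline_config(config)

  stack <- .stage("load_image", {
    if (inherits(cfg$image, "image_stack")) cfg$image
    else read_image_stack(cfg$image, cfg$manifest)
  })
  if (isTRUE(cfg$unmixing$enabled)) {
    stack <- .stage("unmix", {
      model <- if (inherits(cfg$unmixing$model, "mixing_model"))
        cfg$unmixing$model else read_mixing_model(cfg$unmixing$model)
      keep_dapi <- get_channel(stack, cfg$segmentation$dapi_marker)
      un <- unmix(stack, model, cfg$unmixing$keep_autofluorescence)
      # re-attach the (already clean) DAPI channel for segmentation
      px <- array(0, dim(un$pixels) + c(0, 0, 1))
      px[, , 1] <- keep_dapi
      px[, , -1] <- un$pixels
      image_stack(px, rbind(
        data.frame(channel_id = 0, marker = cfg$segmentation$dapi_marker,
                   fluorophore = cfg$segmentation$dapi_marker),
        un$channels), un$pixel_size_um, un$image_id, un$modality)
    })
  }

  thr <- .stage("thresholds", {
    t <- cfg$thresholds
    if (is.null(t)) stop("no thresholds configured")
    if (is.character(t)) t <- read.csv(t)
    t <- threshold_set(t)
    quantified <- setdiff(stack$channels$marker,
                          cfg$segmentation$dapi_marker)
    miss <- setdiff(quantified, t$marker)
    if (length(miss))
      stop("no threshold for marker(s): ", paste(miss, collapse = ", "))
    t
  })
  key <- .stage("phenotype_key", {
    k <- cfg$phenotype_key
    if (is.null(k)) stop("no phenotype key configured")
    if (is.character(k))
      k <- read_phenotype_key(k, priority = cfg$phenotype_priority,
                              fallback = cfg$phenotype_fallback)
    stopifnot(inherits(k, "phenotype_key"))
    k
  })

  seg <- .stage("segment_nuclei", {
    p <- cfg$segmentation
    nuclei <- segment_nuclei(get_channel(stack, p$dapi_marker),
                             stack$pixel_size_um, window_um = p$window_um,
                             offset = p$offset,
                             min_area_um2 = p$min_area_um2,
                             min_peak_sep_um = p$min_peak_sep_um)
    expand_cells(nuclei, max_dist_um = p$expansion_um)
  })
  table <- .stage("quantify", {
    quantify_cells(stack, seg,
                   markers = setdiff(stack$channels$marker,
                                     cfg$segmentation$dapi_marker))
  })
  table <- .stage("thresholds", apply_thresholds(table, thr))
  table <- .stage("phenotype", assign_phenotypes(table, key))
  graph <- .stage("tissue_graph", build_adjacency_graph(
    cells = table, masks = seg$cells,
    method = cfg$tissue$graph_method,
    param_um = cfg$tissue$graph_param_um))
  table <- .stage("tissue", segment_tissue(
    table, graph, marker = cfg$tissue$marker,
    small_max = cfg$tissue$small_max, large_min = cfg$tissue$large_min))
  tls <- .stage("tls", {
    b <- table[table$phenotype == cfg$tls$b_phenotype, , drop = FALSE]
    detect_tls(b, density_threshold = cfg$tls$density_threshold,
               min_cells = cfg$tls$min_cells,
               radius_um = cfg$tls$radius_um,
               alpha_um = cfg$tls$alpha_um)
  })
  table$in_tls <- as.character(table$cell_id) %in%
    unlist(lapply(tls$patches, `[[`, "members"))
  qc <- .stage("qc", sample_qc(
    missing_folded_fraction = cfg$qc$missing_folded_fraction,
    markers_missing_signal = cfg$qc$markers_missing_signal,
    fully_necrotic = cfg$qc$fully_necrotic))

  prov <- list(package = "plexquant",
               version = as.character(utils::packageVersion("plexquant")),
               config_hash = rlang::hash(unclass(cfg)[setdiff(
                 names(cfg), "out_dir")]), seed = cfg$seed,
               image_id = stack$image_id)
  out <- list(table = table, seg = seg, tls = tls, qc = qc,
              provenance = prov, graph = graph)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(cfg$out_dir, f)
    write_cell_table(table, p("cells.csv"))
    write_label_mask(seg$nuclei, p("nuclei.tif"))
    write_label_mask(seg$cells, p("cells.tif"))
    write_patch_set(tls, p("tls.geojson"), p("tls_members.csv"))
    write_qc_report(qc, p("qc.json"), p("qc.txt"))
    jsonlite::write_json(prov, p("provenance.json"), auto_unbox = TRUE)
  }
  out
}

#' Cross-modality co-localization concordance
#'
#' Aligns the mIF cells into the IMC frame with a landmark similarity
#' transform, then, for every requested cell type present in both
#' modalities, builds the bivariate IMC/mIF pattern on the intersection
#' window and computes the cross-type L curve, its signed area score, the
#' MAD envelope test and the co-localization call. Types absent from one
#' modality are flagged \code{"absent"} and not tested.
#'
#' @param imc_cells,mif_cells cell tables with \code{x_um, y_um,
#'   phenotype}.
#' @param landmarks data.frame with columns \code{mif_x, mif_y, imc_x,
#'   imc_y}; at least \code{min_landmarks} rows.
#' @param cell_types types to compare (default: union of phenotypes).
#' @param min_landmarks minimum landmark pairs (default 4).
#' @param nsim CSR realizations for the MAD test (default 99).
#' @param seed integer seed for the MAD simulations.
#' @param radii_n number of radii steps (default 128).
#' @param alpha significance bound for the call (default 0.01).
#' @return data.frame: one row per cell type with \code{n_imc, n_mif,
#'   area_um2, p_value, call} plus the transform as attribute
#'   \code{"transform"}.
#' @export
run_concordance <- function(imc_cells, mif_cells, landmarks,
                            cell_types = NULL, min_landmarks = 4,
                            nsim = 99, seed = 1L, radii_n = 128L,
                            alpha = 0.01) {
  stopifnot(all(c("mif_x", "mif_y", "imc_x", "imc_y") %in%
                  names(landmarks)))
  if (nrow(landmarks) < min_landmarks)
    stop("at least ", min_landmarks, " landmark pairs required (got ",
         nrow(landmarks), ")")
  tr <- estimate_similarity_transform(
    cbind(landmarks$mif_x, landmarks$mif_y),
    cbind(landmarks$imc_x, landmarks$imc_y))
  if (is.null(cell_types))
    cell_types <- sort(union(imc_cells$phenotype, mif_cells$phenotype))
  rows <- lapply(seq_along(cell_types), function(i) {
    ct <- cell_types[i]
    n_imc <- sum(imc_cells$phenotype == ct)
    n_mif <- sum(mif_cells$phenotype == ct)
    if (n_imc == 0L || n_mif == 0L)
      return(data.frame(cell_type = ct, n_imc = n_imc, n_mif = n_mif,
                        area_um2 = NA_real_, p_value = NA_real_,
                        call = "absent"))
    pat <- pair_modalities(imc_cells, mif_cells, tr, cell_type = ct)
    radii <- default_radii(pat$window, n = radii_n)
    cur <- kcross(pat, "IMC", "mIF", radii)
    area <- l_area_score(cur)
    mt <- mad_test(pat, "IMC", "mIF", nsim = nsim, radii = radii,
                   seed = seed + i)
    data.frame(cell_type = ct, n_imc = cur$n_i, n_mif = cur$n_j,
               area_um2 = area, p_value = mt$p_value,
               call = colocalization_call(area, mt$p_value, alpha))
  })
  out <- do.call(rbind, rows)
  attr(out, "transform") <- tr
  out
}
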