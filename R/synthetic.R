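# Seeded synthetic-data generators. These stand in for stained tissue:
# nuclei are Gaussian-blurred disks on a dark background (the DAPI
# channel), marker channels take a phenotype-determined on/off level over
# each cell region plus truncated Gaussian noise, and ground truth (masks,
# centroids, phenotypes) is exactly consistent with the placement. Point-
# pattern generators (CSR / grid / Thomas clusters) feed the spatial
# statistics, and the batch-series generator emulates a control cell
# pellet acquired with every staining batch.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# Separable Gaussian blur with a truncated (compact-support) kernel,
# radius 2.5 sigma, replicated borders. Spatial convolution keeps strict
# zeros outside the kernel support, unlike FFT-based blurring.
.gauss_blur <- function(x, sigma_px) {
  r <- max(1L, ceiling(2 * sigma_px))
  k <- exp(-(-r:r)^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  conv1 <- function(m) {  # along rows, replicate edges
    n <- nrow(m)
    mp <- m[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k))
      out <- out + k[i] * mp[(i - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(x))))
}

#' Synthetic tissue scenario
#'
#' @param width_um,height_um window size.
#' @param pixel_size_um pixel size (default 1).
#' @param n_cells number of nuclei to place.
#' @param nucleus_radius_um nucleus radius (single value or range).
#' @param min_separation_um minimum centre-to-centre separation; must be
#'   at least twice the maximum radius unless overlap is intended.
#' @param expansion_um cell expansion distance for the ground-truth cell
#'   mask (default 5).
#' @param phenotypes named numeric vector of phenotype proportions
#'   (must sum to 1).
#' @param markers named list: marker -> list(on, off, sd, positive_in =
#'   character vector of phenotypes); on must exceed off.
#' @param dapi_level,dapi_sd,dapi_blur_sigma_um DAPI disk level, noise sd
#'   and Gaussian blur sigma.
#' @param positions optional n x 2 matrix of hand-placed centres (um).
#' @param seed integer seed.
#' @return object of class \code{tissue_scenario}.
#' @export
tissue_scenario <- function(width_um = 200, height_um = 200,
                            pixel_size_um = 1, n_cells = 30,
                            nucleus_radius_um = 4,
                            min_separation_um = 14, expansion_um = 5,
                            phenotypes = c(Tumor = 0.5, T = 0.3,
                                           other = 0.2),
                            markers = list(
                              CK = list(on = 100, off = 0, sd = 0,
                                        positive_in = "Tumor"),
                              CD3 = list(on = 100, off = 0, sd = 0,
                                         positive_in = "T")),
                            dapi_level = 100, dapi_sd = 0,
                            dapi_blur_sigma_um = 1, positions = NULL,
                            seed = 1L) {
  if (abs(sum(phenotypes) - 1) > 1e-9)
    stop("phenotype proportions must sum to 1")
  for (mk in names(markers)) {
    m <- markers[[mk]]
    if (m$on <= m$off)
      stop("marker ", mk, ": on-level must exceed off-level")
    if (!all(m$positive_in %in% names(phenotypes)))
      stop("marker ", mk, ": unknown phenotype in positive_in")
  }
  structure(as.list(environment()), class = "tissue_scenario")
}

#' Generate a synthetic tissue image with ground truth
#'
#' @param scenario a \code{\link{tissue_scenario}}.
#' @return list with \code{stack} (\code{image_stack}: DAPI plus one
#'   channel per marker), \code{truth} (\code{segmentation_result}) and
#'   \code{table} (ground-truth \code{cell_table} with phenotypes and
#'   positivity flags).
#' @export
generate_tissue_image <- function(scenario) {
  stopifnot(inherits(scenario, "tissue_scenario"))
  sc <- scenario
  .with_seed(sc$seed, {
    s <- sc$pixel_size_um
    H <- round(sc$height_um / s); W <- round(sc$width_um / s)
    rmax <- max(sc$nucleus_radius_um)
    # placement: rejection sampling with minimum separation
    if (is.null(sc$positions)) {
      margin <- rmax + s
      pos <- matrix(NA_real_, sc$n_cells, 2)
      placed <- 0L; tries <- 0L
      while (placed < sc$n_cells) {
        tries <- tries + 1L
        if (tries > 2000L * sc$n_cells)
          stop("infeasible packing: cannot place ", sc$n_cells,
               " nuclei at separation ", sc$min_separation_um)
        p <- c(runif(1, margin, sc$width_um - margin),
               runif(1, margin, sc$height_um - margin))
        if (placed == 0L ||
            min((pos[seq_len(placed), 1] - p[1])^2 +
                (pos[seq_len(placed), 2] - p[2])^2) >=
            sc$min_separation_um^2) {
          placed <- placed + 1L
          pos[placed, ] <- p
        }
      }
    } else pos <- as.matrix(sc$positions)
    n <- nrow(pos)
    radii <- if (length(sc$nucleus_radius_um) > 1L)
      runif(n, min(sc$nucleus_radius_um), max(sc$nucleus_radius_um))
    else rep(sc$nucleus_radius_um, n)

    # rasterize nuclei (pixel centres within radius of the disk centre)
    xc <- ((seq_len(W)) - 0.5) * s
    yc <- ((seq_len(H)) - 0.5) * s
    lab <- matrix(0L, H, W)
    for (i in seq_len(n)) {
      cspan <- which(abs(xc - pos[i, 1]) <= radii[i])
      rspan <- which(abs(yc - pos[i, 2]) <= radii[i])
      for (r in rspan) {
        hit <- cspan[(xc[cspan] - pos[i, 1])^2 +
                       (yc[r] - pos[i, 2])^2 <= radii[i]^2]
        lab[r, hit] <- i
      }
    }
    nuclei <- label_mask(lab, s, validate = FALSE)
    truth <- expand_cells(nuclei, max_dist_um = sc$expansion_um)

    phen <- sample(names(sc$phenotypes), n, replace = TRUE,
                   prob = sc$phenotypes)

    noisy <- function(base, sd) {
      if (sd > 0) base <- base + matrix(rnorm(H * W, 0, sd), H, W)
      pmax(base, 0)
    }
    dapi <- matrix(0, H, W); dapi[lab > 0L] <- sc$dapi_level
    if (sc$dapi_blur_sigma_um > 0)
      dapi <- .gauss_blur(dapi, sc$dapi_blur_sigma_um / s)
    dapi <- noisy(dapi, sc$dapi_sd)

    chans <- list(DAPI = dapi)
    cl <- truth$cells$labels
    for (mk in names(sc$markers)) {
      m <- sc$markers[[mk]]
      img <- matrix(m$off, H, W)
      on_cells <- which(phen %in% m$positive_in)
      img[cl %in% on_cells] <- m$on
      chans[[mk]] <- noisy(img, m$sd)
    }
    px <- array(0, c(H, W, length(chans)))
    for (i in seq_along(chans)) px[, , i] <- chans[[i]]
    stack <- image_stack(
      px, data.frame(channel_id = seq_along(chans),
                     marker = names(chans),
                     fluorophore = names(chans)),
      s, image_id = sprintf("synthetic_seed%d", sc$seed), modality = "mIF")

    ids <- mask_labels(truth$cells)
    tbl <- data.frame(
      image_id = stack$image_id, cell_id = ids,
      x_um = pos[ids, 1], y_um = pos[ids, 2],
      area_um2 = tabulate(cl[cl > 0L], nbins = n)[ids] * s^2,
      phenotype = phen[ids])
    for (mk in names(sc$markers))
      tbl[[paste0("pos_", mk)]] <-
        phen[ids] %in% sc$markers[[mk]]$positive_in
    list(stack = stack, truth = truth, table = cell_table(tbl),
         scenario = sc)
  })
}

#' Generate a point pattern (CSR, grid or Thomas clusters)
#'
#' @param kind \code{"csr"} (binomial with fixed \code{n}, or Poisson with
#'   \code{intensity_per_mm2}), \code{"grid"} (square lattice with
#'   \code{spacing_um}, so intensity 1/spacing^2) or \code{"thomas"}
#'   (Poisson parents with \code{parent_intensity_per_mm2}, Poisson
#'   offspring counts with mean \code{mean_offspring}, isotropic Gaussian
#'   displacement \code{cluster_sigma_um}).
#' @param window \code{c(x0, y0, x1, y1)} in micrometres.
#' @param seed integer seed.
#' @param n,intensity_per_mm2,spacing_um,parent_intensity_per_mm2,
#'   mean_offspring,cluster_sigma_um kind-specific parameters.
#' @param mark mark value assigned to all points (default "all").
#' @return a \code{\link{point_pattern}}.
#' @export
generate_point_pattern <- function(kind = c("csr", "grid", "thomas"),
                                   window, seed = 1L, n = NULL,
                                   intensity_per_mm2 = NULL,
                                   spacing_um = NULL,
                                   parent_intensity_per_mm2 = NULL,
                                   mean_offspring = NULL,
                                   cluster_sigma_um = 10,
                                   mark = "all") {
  kind <- match.arg(kind)
  if (window[3] <= window[1] || window[4] <= window[2])
    stop("degenerate window")
  a <- window[3] - window[1]; b <- window[4] - window[2]
  area_mm2 <- a * b / 1e6
  pts <- .with_seed(seed, switch(
    kind,
    csr = {
      if (is.null(n)) {
        if (is.null(intensity_per_mm2)) stop("csr needs n or intensity")
        if (intensity_per_mm2 <= 0) stop("intensity must be positive")
        n <- rpois(1, intensity_per_mm2 * area_mm2)
      }
      data.frame(x_um = runif(n, window[1], window[3]),
                 y_um = runif(n, window[2], window[4]))
    },
    grid = {
      if (is.null(spacing_um) || spacing_um <= 0)
        stop("grid needs positive spacing_um")
      gx <- seq(window[1] + spacing_um / 2, window[3], by = spacing_um)
      gy <- seq(window[2] + spacing_um / 2, window[4], by = spacing_um)
      expand.grid(x_um = gx, y_um = gy)
    },
    thomas = {
      if (is.null(parent_intensity_per_mm2) || is.null(mean_offspring))
        stop("thomas needs parent intensity and mean offspring")
      npar <- rpois(1, parent_intensity_per_mm2 * area_mm2)
      if (npar == 0L) data.frame(x_um = numeric(0), y_um = numeric(0))
      else {
        px <- runif(npar, window[1], window[3])
        py <- runif(npar, window[2], window[4])
        cnt <- rpois(npar, mean_offspring)
        x <- rep(px, cnt) + rnorm(sum(cnt), 0, cluster_sigma_um)
        y <- rep(py, cnt) + rnorm(sum(cnt), 0, cluster_sigma_um)
        keep <- x >= window[1] & x <= window[3] &
          y >= window[2] & y <= window[4]
        data.frame(x_um = x[keep], y_um = y[keep])
      }
    }))
  pts$mark <- mark
  point_pattern(pts, window)
}

#' Compact hexagonally packed cluster of points
#'
#' Points are laid on a triangular lattice with the given spacing and the
#' \code{n} closest to the centre are kept, yielding the densest compact
#' cluster with that spacing.
#'
#' @param n number of points.
#' @param spacing_um lattice spacing.
#' @param center \code{c(x, y)} cluster centre in micrometres.
#' @return data.frame with \code{x_um}, \code{y_um}.
#' @export
hex_cluster <- function(n, spacing_um = 10, center = c(0, 0)) {
  k <- ceiling(sqrt(n)) + 3L
  g <- expand.grid(i = -k:k, j = -k:k)
  x <- (g$i + g$j / 2) * spacing_um
  y <- g$j * spacing_um * sqrt(3) / 2
  o <- order(x^2 + y^2)
  data.frame(x_um = x[o[seq_len(n)]] + center[1],
             y_um = y[o[seq_len(n)]] + center[2])
}

#' Generate a spectral-mixing scenario (single-stain library + mixed image)
#'
#' Forward model per pixel: \code{c = M a + background (+ noise)}. Each
#' single-stain stack activates one source on a sparse set of bright
#' pixels; the unstained stack carries only the background (plus the
#' autofluorescence source when its abundance level is positive).
#'
#' @param M channels x sources mixing matrix (column-normalized,
#'   non-negative); the last column is the autofluorescence source unless
#'   named otherwise.
#' @param background per-channel offset.
#' @param dims image size in pixels \code{c(H, W)}.
#' @param level abundance level of bright pixels.
#' @param bright_fraction fraction of bright pixels per single stain.
#' @param noise_sd additive Gaussian channel noise (truncated at 0).
#' @param pixel_size_um pixel size.
#' @param seed integer seed.
#' @param autofluorescence name of the autofluorescence source.
#' @return list with \code{single_stains} (named list of stacks incl. the
#'   unstained one), \code{mixed} (stack), \code{abundance} (H x W x S
#'   ground truth), \code{model} (\code{mixing_model}).
#' @export
generate_mixing_scenario <- function(M, background = rep(0, nrow(M)),
                                     dims = c(32, 32), level = 100,
                                     bright_fraction = 0.05, noise_sd = 0,
                                     pixel_size_um = 1, seed = 1L,
                                     autofluorescence =
                                       "autofluorescence") {
  M <- as.matrix(M)
  sources <- colnames(M)
  if (is.null(sources)) stop("M must have column (source) names")
  if (!autofluorescence %in% sources)
    stop("M needs an autofluorescence column named '", autofluorescence,
         "'")
  model <- mixing_model(M, sources = sources, background = background,
                        autofluorescence = autofluorescence)
  C <- nrow(M); H <- dims[1]; W <- dims[2]
  manifest <- data.frame(channel_id = seq_len(C),
                         marker = rownames(M) %||% paste0("ch", seq_len(C)),
                         fluorophore = sources[seq_len(min(C,
                                                           length(sources)))])
  # channel f is the primary channel of source f (identity layout)
  if (C >= length(sources)) {
    manifest$fluorophore <- c(sources,
                              rep("none", C - length(sources)))[seq_len(C)]
  }
  .with_seed(seed, {
    mk_stack <- function(abund, id) {
      X <- matrix(abund, H * W, length(sources)) # pixels x S
      pix <- X %*% t(M) + matrix(background, H * W, C, byrow = TRUE)
      if (noise_sd > 0) pix <- pix + rnorm(length(pix), 0, noise_sd)
      pix[pix < 0] <- 0
      image_stack(array(pix, c(H, W, C)), manifest, pixel_size_um,
                  image_id = id)
    }
    singles <- list()
    abund_single <- function(src) {
      A <- matrix(0, H * W, length(sources))
      nb <- max(1L, round(bright_fraction * H * W))
      A[sample(H * W, nb), match(src, sources)] <- level
      A
    }
    for (src in setdiff(sources, autofluorescence))
      singles[[src]] <- mk_stack(abund_single(src), paste0("stain_", src))
    singles[[autofluorescence]] <-
      mk_stack(matrix(0, H * W, length(sources)), "unstained")
    truth <- matrix(runif(H * W * length(sources), 0, level),
                    H * W, length(sources))
    mixed <- mk_stack(truth, "mixed")
    list(single_stains = singles, mixed = mixed,
         abundance = array(truth, c(H, W, length(sources))),
         model = model)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic control-pellet batch series
#'
#' Per batch, cell-type counts are multinomial around a base composition
#' and per-(cell type, marker) mean expressions are the base means under
#' multiplicative log-normal noise \code{exp(sigma * z)}, which keeps
#' means positive and gives a theoretical CV of
#' \code{sqrt(exp(sigma^2) - 1)} (approximately sigma for small sigma).
#'
#' @param n_batches number of batches (>= 2; the control-pellet series
#'   motivating this generator had 11).
#' @param base_composition named numeric vector of cell-type proportions.
#' @param n_cells_per_batch cells per batch (default 500).
#' @param base_means cell-type x marker matrix of base mean expressions
#'   (dimnames required); zero entries mark irrelevant pairs.
#' @param sigma multiplicative noise level (>= 0).
#' @param seed integer seed.
#' @return list with \code{counts} (batch x type), \code{means} (batch x
#'   type x marker array), \code{relevance} (type -> markers with positive
#'   base mean).
#' @export
generate_batch_series <- function(n_batches = 11, base_composition,
                                  n_cells_per_batch = 500, base_means,
                                  sigma = 0.1, seed = 1L) {
  stopifnot(n_batches >= 2, sigma >= 0)
  base_composition <- base_composition / sum(base_composition)
  cts <- names(base_composition)
  stopifnot(!is.null(cts), !is.null(dimnames(base_means)))
  base_means <- as.matrix(base_means)[cts, , drop = FALSE]
  mks <- colnames(base_means)
  .with_seed(seed, {
    counts <- t(rmultinom(n_batches, n_cells_per_batch, base_composition))
    colnames(counts) <- cts
    rownames(counts) <- paste0("batch", seq_len(n_batches))
    means <- array(rep(base_means, each = n_batches),
                   c(n_batches, length(cts), length(mks)),
                   dimnames = list(rownames(counts), cts, mks))
    if (sigma > 0)
      means <- means * exp(sigma * array(rnorm(length(means)), dim(means)))
    relevance <- lapply(setNames(cts, cts),
                        function(ct) mks[base_means[ct, ] > 0])
    list(counts = counts, means = means, relevance = relevance)
  })
}
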