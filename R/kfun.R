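# Cross-type second-order statistics for marked point patterns in a
# rectangular window, and the Monte-Carlo machinery used to decide whether
# two cell types occupy the same spatial locations:
#
#   Khat_ij(r) = |W| / (n_i n_j) * sum_{u in i} sum_{v in j, v != u}
#                1(d(u, v) <= r) e(u, v)
#
# with the translation edge correction e(u, v) = |W| / |W intersect
# W_(v - u)| (closed form for rectangles), Lhat = sqrt(Khat / pi)
# (expectation r under complete spatial randomness), the signed area
# between Lhat(r) and r as a co-localization score, and a maximum-absolute-
# deviation (MAD) envelope test against CSR realizations with the observed
# point counts.

#' Marked point pattern in a rectangular window
#'
#' @param points data.frame with \code{x_um}, \code{y_um} and optionally a
#'   \code{mark} column (cell type and/or modality).
#' @param window numeric \code{c(x0, y0, x1, y1)} in micrometres; all
#'   points must lie inside and the area must be positive.
#' @return object of class \code{point_pattern}.
#' @export
point_pattern <- function(points, window) {
  stopifnot(length(window) == 4L)
  if (window[3] <= window[1] || window[4] <= window[2])
    stop("window area must be positive")
  points <- as.data.frame(points)
  stopifnot(all(c("x_um", "y_um") %in% names(points)))
  if (nrow(points)) {
    inside <- points$x_um >= window[1] & points$x_um <= window[3] &
      points$y_um >= window[2] & points$y_um <= window[4]
    if (!all(inside)) stop(sum(!inside), " point(s) outside the window")
  }
  if (!"mark" %in% names(points)) points$mark <- "all"
  structure(list(points = points, window = as.numeric(window)),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("<point_pattern> %d point(s) in [%g, %g] x [%g, %g] um\n",
              nrow(x$points), x$window[1], x$window[3], x$window[2],
              x$window[4]))
  print(table(x$points$mark))
  invisible(x)
}

.window_sides <- function(window) c(window[3] - window[1],
                                    window[4] - window[2])

#' Default radii grid for second-order statistics
#'
#' 512 steps from 0 to one quarter of the shorter window side.
#' @param window \code{c(x0, y0, x1, y1)}.
#' @param n number of steps (default 512).
#' @export
default_radii <- function(window, n = 512L) {
  seq(0, min(.window_sides(window)) / 4, length.out = n + 1L)
}

#' Cross-type K and L functions
#'
#' @param pattern a \code{\link{point_pattern}}.
#' @param type_i,type_j mark values of the two types (may be equal).
#' @param radii ascending radii grid starting at 0; must not exceed one
#'   quarter of the shorter window side (default:
#'   \code{\link{default_radii}}).
#' @param correction \code{"translation"} (default) or \code{"none"}.
#' @return object of class \code{spatial_curve} with fields \code{r},
#'   \code{k}, \code{l}, \code{n_i}, \code{n_j}, \code{window},
#'   \code{correction}.
#' @export
kcross <- function(pattern, type_i, type_j, radii = NULL,
                   correction = c("translation", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(pattern, "point_pattern"))
  w <- pattern$window
  sides <- .window_sides(w)
  if (is.null(radii)) radii <- default_radii(w)
  radii <- as.numeric(radii)
  if (!length(radii)) stop("radii grid is empty")
  if (is.unsorted(radii, strictly = TRUE) || radii[1] < 0)
    stop("radii must be non-negative and strictly increasing")
  if (max(radii) > min(sides) / 4 + 1e-9)
    stop("rmax exceeds one quarter of the shorter window side")
  pi_idx <- which(pattern$points$mark == type_i)
  pj_idx <- which(pattern$points$mark == type_j)
  if (!length(pi_idx)) stop("no points of type '", type_i, "'")
  if (!length(pj_idx)) stop("no points of type '", type_j, "'")
  xi <- pattern$points$x_um[pi_idx]; yi <- pattern$points$y_um[pi_idx]
  xj <- pattern$points$x_um[pj_idx]; yj <- pattern$points$y_um[pj_idx]
  area <- prod(sides)

  dx <- outer(xi, xj, "-"); dy <- outer(yi, yj, "-")
  d <- sqrt(dx^2 + dy^2)
  keep <- !(outer(pi_idx, pj_idx, "=="))        # exclude identical points
  e <- if (correction == "translation")
    area / ((sides[1] - abs(dx)) * (sides[2] - abs(dy))) else
      array(1, dim(d))
  dv <- d[keep]; ev <- e[keep]
  o <- order(dv)
  dv <- dv[o]; cum <- cumsum(ev[o])
  pos <- findInterval(radii, dv)                # pairs with d <= r
  k <- area / (length(pi_idx) * length(pj_idx)) *
    ifelse(pos > 0, cum[pmax(pos, 1L)], 0)
  structure(list(r = radii, k = k, l = sqrt(k / pi),
                 n_i = length(pi_idx), n_j = length(pj_idx),
                 window = w, correction = correction,
                 type_i = type_i, type_j = type_j),
            class = "spatial_curve")
}

#' @export
print.spatial_curve <- function(x, ...) {
  cat(sprintf(
    "<spatial_curve> L_%s,%s on [0, %.3g] um (%d radii, %s correction)\n",
    x$type_i, x$type_j, max(x$r), length(x$r), x$correction))
  invisible(x)
}

#' Signed area between the estimated and theoretical L functions
#'
#' Trapezoidal integral of L(r) - r over the radii grid. Positive values
#' indicate that the two types co-occur in space more than expected under
#' complete spatial randomness.
#'
#' @param curve a \code{spatial_curve}.
#' @return area in square micrometres (sign preserved).
#' @export
l_area_score <- function(curve) {
  pracma::trapz(curve$r, curve$l - curve$r)
}

#' Maximum-absolute-deviation envelope test against CSR
#'
#' The statistic is \code{T = max_r |L(r) - r|}. The null distribution is
#' built from \code{nsim} simulated realizations of complete spatial
#' randomness (binomial processes with the observed per-type point counts
#' in the same window); the rank-based p-value is
#' \code{(1 + #\{T_k >= T_obs\}) / (nsim + 1)}, so the smallest attainable
#' p with 99 simulations is 0.01.
#'
#' @inheritParams kcross
#' @param nsim number of CSR realizations (default 99).
#' @param seed optional integer seed (caller's RNG state is preserved).
#' @return list with \code{statistic}, \code{p_value}, \code{nsim},
#'   \code{sim_statistics}.
#' @export
mad_test <- function(pattern, type_i, type_j, nsim = 99, radii = NULL,
                     seed = NULL, correction = c("translation", "none")) {
  correction <- match.arg(correction)
  stopifnot(nsim >= 1)
  w <- pattern$window
  if (is.null(radii)) radii <- default_radii(w)
  if (!length(radii)) stop("radii grid is empty")
  obs <- kcross(pattern, type_i, type_j, radii, correction)
  t_obs <- max(abs(obs$l - obs$r))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n_i <- obs$n_i; n_j <- obs$n_j
  t_sim <- vapply(seq_len(nsim), function(k) {
    pts <- data.frame(
      x_um = runif(n_i + n_j, w[1], w[3]),
      y_um = runif(n_i + n_j, w[2], w[4]),
      mark = rep(c("i", "j"), c(n_i, n_j)))
    cur <- kcross(point_pattern(pts, w), "i", "j", radii, correction)
    max(abs(cur$l - cur$r))
  }, numeric(1))
  p <- (1 + sum(t_sim >= t_obs)) / (nsim + 1)
  list(statistic = t_obs, p_value = p, nsim = nsim, sim_statistics = t_sim)
}

#' Co-localization decision
#'
#' Two cell types are called co-localized iff the area between the
#' estimated and expected L functions is strictly positive AND the MAD
#' test p-value is at most \code{alpha}.
#'
#' @param area signed L-area score.
#' @param p_value MAD-test p-value.
#' @param alpha significance bound (default 0.01, inclusive).
#' @return \code{"colocalized"} or \code{"not_colocalized"}.
#' @export
colocalization_call <- function(area, p_value, alpha = 0.01) {
  stopifnot(is.finite(area), is.finite(p_value))
  if (area > 0 && p_value <= alpha) "colocalized" else "not_colocalized"
}

#' Pair two modality cell tables into one bivariate pattern
#'
#' Transforms the mIF coordinates into the IMC frame, intersects the two
#' (axis-aligned) windows and returns a bivariate pattern marked by
#' modality, optionally restricted to one cell type.
#'
#' @param imc_cells,mif_cells cell tables (\code{x_um, y_um}, optionally
#'   \code{phenotype}).
#' @param transform a \code{similarity_transform} mapping mIF coordinates
#'   into the IMC frame.
#' @param cell_type optional phenotype filter applied to both tables.
#' @param imc_window,mif_window windows \code{c(x0, y0, x1, y1)}; default:
#'   bounding box of the respective table.
#' @return a \code{\link{point_pattern}} with marks \code{"IMC"} /
#'   \code{"mIF"}.
#' @export
pair_modalities <- function(imc_cells, mif_cells, transform,
                            cell_type = NULL, imc_window = NULL,
                            mif_window = NULL) {
  if (!is.null(cell_type)) {
    imc_cells <- imc_cells[imc_cells$phenotype == cell_type, , drop = FALSE]
    mif_cells <- mif_cells[mif_cells$phenotype == cell_type, , drop = FALSE]
  }
  bbox <- function(df) c(min(df$x_um), min(df$y_um), max(df$x_um),
                         max(df$y_um))
  if (is.null(imc_window)) imc_window <- bbox(imc_cells)
  if (is.null(mif_window)) mif_window <- bbox(mif_cells)
  corners <- cbind(x_um = mif_window[c(1, 3, 1, 3)],
                   y_um = mif_window[c(2, 2, 4, 4)])
  tc <- apply_transform(transform, corners)
  mw <- c(min(tc[, 1]), min(tc[, 2]), max(tc[, 1]), max(tc[, 2]))
  win <- c(pmax(imc_window[1:2], mw[1:2]), pmin(imc_window[3:4], mw[3:4]))
  if (win[3] <= win[1] || win[4] <= win[2])
    stop("empty intersection window between the two modalities")
  mif_t <- apply_transform(transform, mif_cells[c("x_um", "y_um")])
  inside <- function(df) df[df$x_um >= win[1] & df$x_um <= win[3] &
                              df$y_um >= win[2] & df$y_um <= win[4], ,
                            drop = FALSE]
  a <- inside(imc_cells[c("x_um", "y_um")]); a$mark <- "IMC"
  b <- inside(mif_t); b$mark <- "mIF"
  point_pattern(rbind(a, b), win)
}
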