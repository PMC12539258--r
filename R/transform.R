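# Landmark alignment between paired modality images (e.g. an IMC ROI and
# the matching region of the mIF slide) via a least-squares similarity
# transform: x' = s R x + t, with optional reflection, estimated in closed
# form from the centred cross-covariance SVD (Umeyama/Procrustes).

#' Similarity transform
#'
#' @param scale s > 0.
#' @param theta rotation angle, radians.
#' @param tx,ty translation, micrometres.
#' @param reflection reflect across the x axis before rotating.
#' @param rmse residual RMSE of the fit (informational).
#' @return object of class \code{similarity_transform}.
#' @export
similarity_transform <- function(scale = 1, theta = 0, tx = 0, ty = 0,
                                 reflection = FALSE, rmse = NA_real_) {
  if (scale <= 0) stop("scale must be positive")
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  if (reflection) R <- R %*% diag(c(1, -1))
  structure(list(scale = scale, theta = theta, tx = tx, ty = ty,
                 reflection = reflection, A = scale * R,
                 t = c(tx, ty), rmse = rmse),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "<similarity_transform> s=%.6g theta=%.6g rad t=(%.6g, %.6g)%s RMSE=%.3g\n",
    x$scale, x$theta, x$tx, x$ty,
    if (x$reflection) " reflected" else "", x$rmse))
  invisible(x)
}

#' Apply / invert a similarity transform
#'
#' @param transform a \code{similarity_transform}.
#' @param points data.frame or matrix with x/y in the first two columns
#'   (or \code{x_um}/\code{y_um}).
#' @return points of the same shape, transformed.
#' @export
apply_transform <- function(transform, points) {
  xy <- .as_xy(points)
  out <- t(transform$A %*% t(xy) + transform$t)
  .restore_xy(points, out)
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  Ai <- solve(transform$A)
  ti <- as.numeric(-Ai %*% transform$t)
  out <- similarity_transform(scale = 1 / transform$scale,
                              theta = atan2(Ai[2, 1], Ai[1, 1]),
                              tx = ti[1], ty = ti[2],
                              reflection = transform$reflection)
  out$A <- Ai; out$t <- ti
  out
}

.as_xy <- function(points) {
  if (is.matrix(points)) return(points[, 1:2, drop = FALSE])
  if (all(c("x_um", "y_um") %in% names(points)))
    return(cbind(points$x_um, points$y_um))
  as.matrix(points[, 1:2])
}

.restore_xy <- function(points, xy) {
  if (is.matrix(points)) {
    points[, 1:2] <- xy
    return(points)
  }
  if (all(c("x_um", "y_um") %in% names(points))) {
    points$x_um <- xy[, 1]; points$y_um <- xy[, 2]
    return(points)
  }
  points[, 1] <- xy[, 1]; points[, 2] <- xy[, 2]
  points
}

#' Estimate a similarity (or affine) transform from landmark pairs
#'
#' Closed-form least squares: for the similarity model, rotation from the
#' SVD of the centred cross-covariance, scale from the trace ratio and
#' translation from the centroids; at least 2 pairs required (4 or more
#' recommended). The affine model solves the normal equations and needs at
#' least 3 non-collinear pairs.
#'
#' @param src_points,dst_points matched landmark coordinates (data.frame
#'   with \code{x_um,y_um} or 2-column matrix); the fit maps src to dst.
#' @param allow_reflection permit an orientation-reversing fit.
#' @param type \code{"similarity"} (default) or \code{"affine"}.
#' @return a \code{similarity_transform} (affine fits return scale/theta
#'   of the nearest similarity with the exact matrix in \code{A}).
#' @export
estimate_similarity_transform <- function(src_points, dst_points,
                                          allow_reflection = FALSE,
                                          type = c("similarity", "affine")) {
  type <- match.arg(type)
  S <- .as_xy(src_points); D <- .as_xy(dst_points)
  if (nrow(S) != nrow(D)) stop("landmark lists differ in length")
  n <- nrow(S)
  if (n < 2L) stop("at least 2 landmark pairs required")
  if (anyDuplicated(S)) stop("duplicate source landmarks")
  ms <- colMeans(S); md <- colMeans(D)
  Sc <- sweep(S, 2L, ms); Dc <- sweep(D, 2L, md)
  var_s <- sum(Sc^2) / n
  if (var_s == 0) stop("degenerate (coincident) source landmarks")

  if (type == "affine") {
    if (n < 3L) stop("affine fit needs at least 3 pairs")
    X <- cbind(S, 1)
    if (qr(X)$rank < 3L) stop("degenerate (collinear) landmarks for affine")
    B <- solve(crossprod(X), crossprod(X, D))   # 3 x 2
    A <- t(B[1:2, ]); tt <- B[3, ]
    sv <- svd(A)
    out <- similarity_transform(scale = exp(mean(log(sv$d))),
                                theta = atan2(A[2, 1], A[1, 1]),
                                tx = tt[1], ty = tt[2])
    out$A <- A; out$t <- tt
  } else {
    H <- crossprod(Sc, Dc) / n                  # src' dst cross-covariance
    sv <- svd(H)
    d <- diag(2)
    refl <- FALSE
    if (det(sv$v %*% t(sv$u)) < 0) {
      if (allow_reflection) refl <- TRUE else d[2, 2] <- -1
    }
    R <- sv$v %*% d %*% t(sv$u)                 # maps src -> dst
    s <- sum(sv$d * diag(d)) / var_s
    if (s <= 0) stop("degenerate landmark configuration (non-positive scale)")
    tt <- md - s * R %*% ms
    out <- similarity_transform(scale = s, theta = atan2(R[2, 1], R[1, 1]),
                                tx = tt[1], ty = tt[2])
    out$A <- s * R; out$t <- as.numeric(tt)
    out$reflection <- refl
  }
  res <- t(out$A %*% t(S) + out$t) - D
  out$rmse <- sqrt(mean(rowSums(res^2)))
  out
}
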