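# Linear spectral unmixing. Each acquired channel mixes the signals of all
# fluorophores plus tissue autofluorescence:
#   c = M a + b,   a >= 0
# where M (channels x sources) holds the column-normalized emission spectra,
# b the per-channel background offset, and a the per-pixel fluorophore
# abundances. M is estimated from a library of single-stain images plus one
# unstained (autofluorescence) image; abundances are recovered per pixel by
# non-negative least squares.

#' Mixing model
#'
#' @param matrix channels x sources matrix, non-negative, each column
#'   summing to 1 (within 1e-9).
#' @param sources source names (fluorophores plus one autofluorescence
#'   source); defaults to column names.
#' @param background per-channel non-negative offset.
#' @param autofluorescence name of the autofluorescence source.
#' @return object of class \code{mixing_model}.
#' @export
mixing_model <- function(matrix, sources = colnames(matrix),
                         background = rep(0, nrow(matrix)),
                         autofluorescence = "autofluorescence") {
  matrix <- as.matrix(matrix)
  if (is.null(sources)) stop("sources must be named")
  if (ncol(matrix) != length(sources)) stop("one source per column required")
  if (ncol(matrix) > nrow(matrix))
    stop("more sources than channels: underdetermined model")
  if (any(matrix < 0)) stop("mixing matrix entries must be >= 0")
  cs <- colSums(matrix)
  if (any(abs(cs - 1) > 1e-9))
    stop("mixing matrix columns must sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")")
  if (any(background < 0)) stop("background offsets must be >= 0")
  colnames(matrix) <- sources
  structure(list(matrix = matrix, sources = sources,
                 background = as.numeric(background),
                 autofluorescence = autofluorescence),
            class = "mixing_model")
}

#' @export
print.mixing_model <- function(x, ...) {
  cat(sprintf("<mixing_model> %d channel(s) x %d source(s)\n",
              nrow(x$matrix), ncol(x$matrix)))
  print(round(x$matrix, 4))
  invisible(x)
}

#' Estimate a mixing model from a single-stain library
#'
#' The per-channel background offset is the per-channel median of the
#' unstained image. Each source's spectral column is the per-channel median
#' over the \code{top_fraction} brightest pixels of the stain's designated
#' primary channel, background-subtracted, clipped at zero and normalized
#' to sum 1. The unstained image doubles as the autofluorescence stain; if
#' it carries no structure above its own background (e.g. a constant
#' image), the autofluorescence spectrum defaults to an indicator of its
#' designated channel.
#'
#' @param single_stain_stacks named list of \code{\link{image_stack}}s, one
#'   per fluorophore plus one unstained entry named
#'   \code{autofluorescence}; all must share the channel manifest. Each
#'   name must match a \code{fluorophore} entry of the manifest (its
#'   primary channel).
#' @param top_fraction fraction of brightest primary-channel pixels used
#'   (default 0.01).
#' @param autofluorescence name of the unstained entry.
#' @return a \code{\link{mixing_model}}.
#' @export
estimate_mixing_model <- function(single_stain_stacks, top_fraction = 0.01,
                                  autofluorescence = "autofluorescence") {
  stopifnot(length(single_stain_stacks) >= 2L,
            !is.null(names(single_stain_stacks)))
  if (!autofluorescence %in% names(single_stain_stacks))
    stop("library must contain an unstained entry named '",
         autofluorescence, "'")
  man <- single_stain_stacks[[1]]$channels
  for (s in single_stain_stacks)
    if (!identical(s$channels$fluorophore, man$fluorophore))
      stop("all library stacks must share the channel manifest")
  sources <- c(setdiff(names(single_stain_stacks), autofluorescence),
               autofluorescence)
  primary <- match(sources, man$fluorophore)
  if (anyNA(primary))
    stop("no manifest channel for source(s): ",
         paste(sources[is.na(primary)], collapse = ", "))

  un <- single_stain_stacks[[autofluorescence]]$pixels
  background <- apply(un, 3L, median)

  col_for <- function(src) {
    st <- single_stain_stacks[[src]]$pixels
    p <- st[, , primary[match(src, sources)]]
    if (max(p) <= 0) {
      # a blank unstained image is legitimate (handled by the fallback);
      # a blank single stain is not
      if (src == autofluorescence) return(rep(0, nrow(man)))
      stop("single-stain image for '", src, "' has all-zero signal")
    }
    cut <- quantile(p, 1 - top_fraction, type = 7)
    sel <- which(p >= cut)
    v <- apply(st, 3L, function(ch) median(ch[sel])) - background
    pmax(v, 0)
  }
  cols <- vapply(sources, col_for, numeric(nrow(man)))
  # autofluorescence fallback: constant unstained image has no residual
  if (sum(cols[, autofluorescence]) <= 0) {
    cols[, autofluorescence] <- 0
    cols[primary[match(autofluorescence, sources)], autofluorescence] <- 1
  }
  bad <- sources[colSums(cols) <= 0]
  if (length(bad))
    stop("no signal above background for source(s): ",
         paste(bad, collapse = ", "))
  cols <- sweep(cols, 2L, colSums(cols), "/")
  rownames(cols) <- man$marker
  mixing_model(cols, sources = sources, background = background,
               autofluorescence = autofluorescence)
}

#' Unmix a multi-channel image into fluorophore abundances
#'
#' Per pixel, finds abundances \code{a >= 0} minimizing
#' \code{||(c - background) - M a||_2} (non-negative least squares,
#' active-set). Pixels are independent, so the result does not depend on
#' processing order. The returned stack has one channel per
#' non-autofluorescence source.
#'
#' @param stack an \code{\link{image_stack}} whose channel count equals the
#'   model's row count.
#' @param model a \code{\link{mixing_model}}.
#' @param keep_autofluorescence also return the autofluorescence abundance
#'   channel (default FALSE).
#' @return an \code{\link{image_stack}} of abundances.
#' @export
unmix <- function(stack, model, keep_autofluorescence = FALSE) {
  stopifnot(inherits(stack, "image_stack"), inherits(model, "mixing_model"))
  M <- model$matrix
  d <- dim(stack$pixels)
  if (d[3] != nrow(M))
    stop("stack has ", d[3], " channels but model expects ", nrow(M))
  sv <- svd(M, nu = 0, nv = 0)$d
  if (min(sv) < 1e-10 * max(sv))
    stop(sprintf(
      "rank-deficient mixing matrix (singular values %s; condition %.3g)",
      paste(signif(sv, 3), collapse = ", "), max(sv) / min(sv)))

  X <- matrix(stack$pixels, nrow = prod(d[1:2]), ncol = d[3])  # pixels x C
  X <- sweep(X, 2L, model$background, "-")
  # unconstrained solution first; active-set NNLS only where it goes negative
  A <- t(solve(crossprod(M), crossprod(M, t(X))))              # pixels x S
  neg <- which(apply(A, 1L, function(a) any(a < -1e-12)))
  for (i in neg) A[i, ] <- pracma::lsqnonneg(M, X[i, ])$x
  A[A < 0] <- 0

  keep <- if (keep_autofluorescence) model$sources else
    setdiff(model$sources, model$autofluorescence)
  idx <- match(keep, model$sources)
  out <- array(A[, idx], c(d[1], d[2], length(idx)))
  image_stack(out,
              data.frame(channel_id = seq_along(keep), marker = keep,
                         fluorophore = keep),
              stack$pixel_size_um, image_id = stack$image_id,
              modality = stack$modality)
}
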