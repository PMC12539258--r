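# Batch-stability coefficients of variation for control samples (cell
# pellets acquired with every staining batch) and per-sample QC rules.
# CV = sd / mean with the sample standard deviation (n - 1).

.cv <- function(x) {
  m <- mean(x)
  if (m == 0) return(0)
  sd(x) / m
}

#' CV of cell-type fractions across batches
#'
#' Counts are converted to within-batch fractions; the coefficient of
#' variation of each type's fraction is computed across batches.
#'
#' @param counts batch x cell-type matrix (or data.frame) of non-negative
#'   counts; at least 2 batches.
#' @return named numeric vector of CVs, one per cell type.
#' @export
celltype_fraction_cv <- function(counts) {
  m <- as.matrix(counts)
  if (nrow(m) < 2L) stop("at least 2 batches required")
  if (any(m < 0)) stop("counts must be non-negative")
  tot <- rowSums(m)
  if (any(tot == 0)) stop("batch with zero total count: ",
                          paste(which(tot == 0), collapse = ", "))
  fr <- m / tot
  apply(fr, 2L, .cv)
}

#' Marker-expression CVs across batches, restricted to relevant cell types
#'
#' For each (marker, cell type) pair declared relevant, the CV of the
#' per-batch mean expression is computed across batches; the final
#' per-marker CV is the unweighted mean over that marker's relevant cell
#' types (CVs are computed within cell type first because expression
#' levels differ strongly between cell types). Markers relevant to no cell
#' type are omitted with a warning.
#'
#' @param means 3-d array batch x cell-type x marker (dimnames required on
#'   cell types and markers), or a long data.frame with columns
#'   \code{batch, cell_type, marker, mean}.
#' @param relevance named list: cell type -> character vector of markers
#'   expressed in that type.
#' @return object of class \code{batch_cv_report}: \code{per_pair}
#'   (marker, cell_type, cv), \code{per_marker} (final CVs),
#'   \code{n_batches}.
#' @export
marker_cv <- function(means, relevance) {
  if (is.data.frame(means)) {
    stopifnot(all(c("batch", "cell_type", "marker", "mean") %in%
                    names(means)))
    batches <- sort(unique(means$batch))
    cts <- sort(unique(means$cell_type))
    mks <- sort(unique(means$marker))
    arr <- array(NA_real_, c(length(batches), length(cts), length(mks)),
                 dimnames = list(batches, cts, mks))
    arr[cbind(match(means$batch, batches), match(means$cell_type, cts),
              match(means$marker, mks))] <- means$mean
    means <- arr
  }
  stopifnot(length(dim(means)) == 3L)
  if (dim(means)[1] < 2L) stop("at least 2 batches required")
  cts <- dimnames(means)[[2]]; mks <- dimnames(means)[[3]]
  rows <- list()
  for (ct in intersect(names(relevance), cts))
    for (mk in intersect(relevance[[ct]], mks)) {
      v <- means[, ct, mk]
      if (all(is.finite(v)))
        rows[[length(rows) + 1L]] <-
          data.frame(marker = mk, cell_type = ct, cv = .cv(v))
    }
  per_pair <- if (length(rows)) do.call(rbind, rows) else
    data.frame(marker = character(0), cell_type = character(0),
               cv = numeric(0))
  orphan <- setdiff(mks, unique(per_pair$marker))
  if (length(orphan))
    warning("marker(s) relevant to no cell type omitted: ",
            paste(orphan, collapse = ", "))
  per_marker <- vapply(split(per_pair$cv, per_pair$marker), mean,
                       numeric(1))
  structure(list(per_pair = per_pair, per_marker = per_marker,
                 n_batches = dim(means)[1]),
            class = "batch_cv_report")
}

#' @export
print.batch_cv_report <- function(x, ...) {
  cat(sprintf("<batch_cv_report> %d batches, %d marker(s)\n", x$n_batches,
              length(x$per_marker)))
  print(round(sort(x$per_marker), 4))
  invisible(x)
}

#' Per-sample quality-control rules
#'
#' A sample FAILs when more than half of its tissue is missing or folded
#' (strictly above 0.5; exactly half is a warning), when more than one
#' marker has missing signal, or when the whole sample is necrotic. One
#' missing-signal marker, or a missing/folded fraction in (0, 0.5], is a
#' warning.
#'
#' @param missing_folded_fraction fraction of missing or folded tissue in
#'   [0, 1].
#' @param markers_missing_signal character vector of markers flagged by
#'   the operator as having no signal.
#' @param fully_necrotic logical.
#' @return a \code{qc_report} with status PASS/WARN/FAIL and per-rule
#'   reasons.
#' @export
sample_qc <- function(missing_folded_fraction = 0,
                      markers_missing_signal = character(0),
                      fully_necrotic = FALSE) {
  stopifnot(missing_folded_fraction >= 0, missing_folded_fraction <= 1)
  reasons <- data.frame(rule_id = character(0), level = character(0),
                        message = character(0), quantity = numeric(0))
  add <- function(rule, level, msg, q) rbind(
    reasons, data.frame(rule_id = rule, level = level, message = msg,
                        quantity = q))
  if (missing_folded_fraction > 0.5) {
    reasons <- add("tissue_missing", "FAIL",
                   sprintf("%.0f%% of tissue missing or folded (> 50%%)",
                           100 * missing_folded_fraction),
                   missing_folded_fraction)
  } else if (missing_folded_fraction > 0) {
    reasons <- add("tissue_missing", "WARN",
                   sprintf("%.0f%% of tissue missing or folded",
                           100 * missing_folded_fraction),
                   missing_folded_fraction)
  }
  nm <- length(markers_missing_signal)
  if (nm > 1L) {
    reasons <- add("marker_signal", "FAIL",
                   paste("missing signal for markers:",
                         paste(markers_missing_signal, collapse = ", ")), nm)
  } else if (nm == 1L) {
    reasons <- add("marker_signal", "WARN",
                   paste("missing signal for marker",
                         markers_missing_signal), nm)
  }
  if (fully_necrotic)
    reasons <- add("necrosis", "FAIL", "entire sample necrotic", 1)
  status <- if (any(reasons$level == "FAIL")) "FAIL"
  else if (any(reasons$level == "WARN")) "WARN" else "PASS"
  qc_report(status, reasons, marker_flags = markers_missing_signal)
}

#' Write a QC report as JSON and human-readable text
#' @param report a \code{qc_report}.
#' @param json_path,txt_path output paths.
#' @export
write_qc_report <- function(report, json_path, txt_path = NULL) {
  jsonlite::write_json(
    list(status = report$status, reasons = report$reasons,
         marker_flags = report$marker_flags),
    json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    on.exit(close(con))
    writeLines(c(paste("QC status:", report$status),
                 sprintf("[%s] %s: %s", report$reasons$level,
                         report$reasons$rule_id, report$reasons$message)),
               con)
  }
  invisible(report)
}
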