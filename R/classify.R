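# Harness around a pluggable cell-type classifier: the unknown-label rule
# applied to class-probability vectors, evaluation metrics, and a
# deterministic stratified train/test split. The classifier itself (e.g. a
# random forest over marker intensities) is any object honouring a
# fit/predict_proba contract and is not re-derived here.

#' Apply the unknown-label rule to class probabilities
#'
#' A cell keeps its argmax class label iff the maximum class probability is
#' at least \code{threshold_pct} percent; strictly below that it is
#' labelled \code{"unknown"}.
#'
#' @param probabilities numeric matrix (cells x classes) with column names,
#'   rows non-negative and summing to 1 within 1e-6; or a data.frame.
#' @param threshold_pct probability floor in percent (default 30).
#' @return character vector of labels.
#' @export
assign_unknown <- function(probabilities, threshold_pct = 30) {
  p <- as.matrix(probabilities)
  if (ncol(p) == 0L || nrow(p) == 0L) stop("empty probability matrix")
  if (is.null(colnames(p))) stop("probability columns must be named")
  if (any(p < 0)) stop("probabilities must be non-negative")
  rs <- rowSums(p)
  if (any(abs(rs - 1) > 1e-6))
    stop("probability rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  mx <- apply(p, 1L, max)
  arg <- colnames(p)[apply(p, 1L, which.max)]
  ifelse(mx >= threshold_pct / 100, arg, "unknown")
}

#' Evaluate a classifier against ground-truth labels
#'
#' Builds the truth-by-predicted confusion matrix (including any
#' \code{"unknown"} predictions) and per-class one-vs-rest metrics:
#' TPR = TP/(TP+FN), FPR = FP/(FP+TN), overall accuracy = trace/total and
#' MacroF1 = unweighted mean of per-class F1 over classes present in the
#' truth (declared classes absent from the truth are excluded with a
#' warning).
#'
#' @param truth,predicted character vectors of equal length.
#' @param labels declared class set (default: union of observed labels,
#'   excluding "unknown" from the metric classes).
#' @return object of class \code{classifier_eval}: \code{confusion},
#'   \code{per_class} (TPR/FPR/F1), \code{accuracy}, \code{macro_f1}.
#' @export
evaluate_classifier <- function(truth, predicted,
                                labels = sort(unique(c(truth, predicted)))) {
  if (length(truth) != length(predicted))
    stop("truth and predicted have different lengths")
  pred_levels <- sort(unique(c(labels, predicted)))
  conf <- table(factor(truth, levels = sort(unique(c(labels, truth)))),
                factor(predicted, levels = pred_levels))
  classes <- setdiff(labels, "unknown")
  absent <- classes[!classes %in% truth]
  if (length(absent)) {
    warning("class(es) absent from truth excluded from MacroF1: ",
            paste(absent, collapse = ", "))
    classes <- setdiff(classes, absent)
  }
  n <- length(truth)
  per <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    fp <- sum(truth != cl & predicted == cl)
    tn <- n - tp - fn - fp
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = cl, tpr = rec,
               fpr = if (fp + tn > 0) fp / (fp + tn) else 0,
               precision = prec, f1 = f1)
  }))
  structure(list(confusion = conf, per_class = per,
                 accuracy = sum(truth == predicted) / n,
                 macro_f1 = mean(per$f1)),
            class = "classifier_eval")
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf("<classifier_eval> accuracy %.3f, MacroF1 %.3f\n",
              x$accuracy, x$macro_f1))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Deterministic (optionally stratified) train/test split
#'
#' @param table data.frame to split.
#' @param fraction training fraction in (0, 1) (default 0.8).
#' @param seed integer seed; the same seed always yields the same split.
#'   The caller's RNG state is preserved.
#' @param stratify_by optional column name; each stratum is split
#'   \code{round(fraction * n)} / rest, so observed proportions are
#'   preserved within one item per stratum. Strata smaller than 2 raise a
#'   warning and go entirely to the training set.
#' @return list with elements \code{train} and \code{test}.
#' @export
split_train_test <- function(table, fraction = 0.8, seed = 1L,
                             stratify_by = NULL) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (!is.null(stratify_by) && !stratify_by %in% names(table))
    stop("no such column: ", stratify_by)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- nrow(table)
  strata <- if (is.null(stratify_by)) rep("all", n) else
    as.character(table[[stratify_by]])
  take <- logical(n)
  for (s in sort(unique(strata))) {
    idx <- which(strata == s)
    if (length(idx) < 2L) {
      warning("stratum '", s, "' has fewer than 2 items; kept in train")
      take[idx] <- TRUE
      next
    }
    k <- round(fraction * length(idx))
    take[sample(idx, k)] <- TRUE
  }
  list(train = table[take, , drop = FALSE],
       test = table[!take, , drop = FALSE])
}
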