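# Phenotype keys: ordered marker-pattern -> phenotype rules with a marker
# priority order for conflict resolution. A cell's positivity combination is
# matched against every rule; if several match, the rule whose required-
# positive marker ranks highest in the priority order wins (this reproduces
# the convention of labelling CD3+CD163+ cells as T cells when CD3 is
# prioritized over CD163). Combinations matching no rule get the fallback
# label ("other" by default).

#' Construct a phenotype key
#'
#' @param rules data.frame with one column per marker (values \code{"+"},
#'   \code{"-"} or \code{"any"}) plus a \code{phenotype} column; row order is
#'   kept but plays no role in resolution.
#' @param priority character vector of marker names, highest priority first;
#'   must cover every marker used by the rules. May be omitted when no two
#'   rules can match the same combination.
#' @param fallback label for combinations matching no rule.
#' @param validate exhaustively check completeness/unambiguity over all
#'   2^M combinations (requires M <= 12).
#' @return object of class \code{phenotype_key}.
#' @export
phenotype_key <- function(rules, priority = NULL, fallback = "other",
                          validate = TRUE) {
  rules <- as.data.frame(rules, stringsAsFactors = FALSE)
  if (!"phenotype" %in% names(rules)) stop("rules need a phenotype column")
  markers <- setdiff(names(rules), "phenotype")
  if (!length(markers)) stop("rules need at least one marker column")
  pat <- as.matrix(rules[markers])
  if (!all(pat %in% c("+", "-", "any")))
    stop("rule cells must be '+', '-' or 'any'")
  if (!is.null(priority)) {
    extra <- setdiff(markers, priority)
    if (length(extra))
      stop("priority order does not cover marker(s): ",
           paste(extra, collapse = ", "))
  }
  key <- structure(list(rules = rules, markers = markers,
                        priority = priority, fallback = fallback),
                   class = "phenotype_key")
  if (validate) validate_phenotype_key(key)
  key
}

#' @export
print.phenotype_key <- function(x, ...) {
  cat(sprintf("<phenotype_key> %d rule(s) over %d marker(s); fallback '%s'\n",
              nrow(x$rules), length(x$markers), x$fallback))
  invisible(x)
}

# label one positivity combination (named logical vector) under a key;
# returns the label, or stop()s on unresolvable ambiguity
.match_combination <- function(key, flags) {
  pat <- as.matrix(key$rules[key$markers])
  ok <- vapply(seq_len(nrow(pat)), function(i) {
    p <- pat[i, ]
    all((p == "any") | (p == "+" & flags) | (p == "-" & !flags))
  }, logical(1))
  hits <- which(ok)
  if (!length(hits)) return(key$fallback)
  if (length(hits) == 1L) return(key$rules$phenotype[hits])
  # several rules match: rank each by its highest-priority required-positive
  # marker; smaller rank wins, rules requiring no positive marker rank last
  if (is.null(key$priority))
    stop("ambiguous phenotype key (no priority order): combination ",
         .combo_string(flags), " matches rules ",
         paste(hits, collapse = ", "))
  rank_of <- function(i) {
    pos <- key$markers[pat[i, ] == "+"]
    if (!length(pos)) return(length(key$priority) + 1L)
    min(match(pos, key$priority))
  }
  rk <- vapply(hits, rank_of, integer(1))
  best <- hits[rk == min(rk)]
  lab <- unique(key$rules$phenotype[best])
  if (length(best) > 1L && length(lab) > 1L)
    stop("ambiguous phenotype key: combination ", .combo_string(flags),
         " matches rules ", paste(best, collapse = ", "),
         " at equal priority")
  lab[1L]
}

.combo_string <- function(flags) {
  paste0(names(flags), ifelse(flags, "+", "-"), collapse = "")
}

#' Exhaustively validate a phenotype key
#'
#' Enumerates all 2^M marker combinations (M <= 12) and checks that each
#' maps to exactly one phenotype after priority resolution.
#'
#' @param key a \code{phenotype_key}.
#' @return invisibly, a data.frame of all combinations and their labels.
#' @export
validate_phenotype_key <- function(key) {
  m <- length(key$markers)
  if (m > 12L) stop("exhaustive validation limited to 12 markers (got ",
                    m, ")")
  combos <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  colnames(combos) <- key$markers
  labels <- vapply(seq_len(nrow(combos)), function(i)
    .match_combination(key, setNames(combos[i, ], key$markers)),
    character(1))
  invisible(data.frame(combos, phenotype = labels, check.names = FALSE))
}

#' Read a phenotype key from CSV
#'
#' The CSV has one column per marker (cells \code{+}, \code{-} or
#' \code{any}) plus a \code{phenotype} column. The priority order may be
#' given as a \code{priority} argument or as a special final row with
#' phenotype \code{".priority"} whose cells hold integer ranks (1 =
#' highest).
#'
#' @param path CSV path.
#' @param priority character vector of markers, highest first (optional).
#' @param fallback fallback label.
#' @return a validated \code{\link{phenotype_key}}.
#' @export
read_phenotype_key <- function(path, priority = NULL, fallback = "other") {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  prow <- df$phenotype == ".priority"
  if (any(prow)) {
    ranks <- as.integer(df[which(prow)[1], setdiff(names(df), "phenotype")])
    priority <- setdiff(names(df), "phenotype")[order(ranks)]
    df <- df[!prow, , drop = FALSE]
  }
  phenotype_key(df, priority = priority, fallback = fallback)
}

#' Write a phenotype key to CSV
#' @param key a \code{phenotype_key}.
#' @param path CSV path.
#' @export
write_phenotype_key <- function(key, path) {
  df <- key$rules
  if (!is.null(key$priority)) {
    pr <- as.list(setNames(match(key$markers, key$priority), key$markers))
    pr$phenotype <- ".priority"
    df <- rbind(df, as.data.frame(pr, check.names = FALSE))
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
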