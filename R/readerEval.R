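## Diagnostic-accuracy statistics for reader studies: 2x2 contingency
## tables, sensitivity/specificity/accuracy, Cohen's kappa and the ASPECTS
## discrepancy rule. The printed-precision convention is truncation (floor),
## not rounding: 100*100/105 = 95.238 prints as 95.23.

#' Build a 2x2 contingency table
#'
#' @param truth logical (or 0/1) truth labels.
#' @param calls logical (or 0/1) reader calls, same length.
#' @return a [ContingencyTable-class].
#' @export
contingency <- function(truth, calls) {
  if (length(truth) != length(calls))
    stop("truth and calls must have equal length")
  truth <- as.logical(truth); calls <- as.logical(calls)
  new("ContingencyTable",
      tp = sum(truth & calls), fp = sum(!truth & calls),
      tn = sum(!truth & !calls), fn = sum(truth & !calls))
}

#' @rdname contingency
#' @param tp,fp,tn,fn counts (for tables quoted from published results).
#' @export
contingencyCounts <- function(tp, fp, tn, fn) {
  new("ContingencyTable", tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn))
}

setMethod("show", "ContingencyTable", function(object) {
  cat(sprintf("ContingencyTable: TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              object@tp, object@fp, object@tn, object@fn,
              object@tp + object@fp + object@tn + object@fn))
})

#' Truncate a percentage to a printed precision
#'
#' Published tables are reproducible under truncation to the printed number
#' of decimals, not rounding (103/105 = 98.095... prints as 98.09).
#'
#' @param x value(s) to truncate.
#' @param digits decimal places kept.
#' @return truncated value(s).
#' @export
truncateToPrecision <- function(x, digits = 2) {
  f <- 10^digits
  floor(x * f + 1e-9) / f
}

#' Sensitivity, specificity and accuracy of a contingency table
#'
#' Percentages at full precision, with truncated companions at a chosen
#' printed precision.
#'
#' @param table a [ContingencyTable-class].
#' @param digits printed precision for the truncated values (default 2).
#' @return list with \code{sensitivity}, \code{specificity},
#'   \code{accuracy} (percent, full precision) and \code{truncated}, a named
#'   numeric vector at the printed precision.
#' @examples
#' diagnosticMetrics(contingencyCounts(32, 0, 71, 2))$truncated
#' @export
diagnosticMetrics <- function(table, digits = 2) {
  tp <- table@tp; fp <- table@fp; tn <- table@tn; fn <- table@fn
  if (tp + fn == 0) stop("undefined metric: sensitivity (no positive cases)")
  if (tn + fp == 0) stop("undefined metric: specificity (no negative cases)")
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  acc <- 100 * (tp + tn) / (tp + fp + tn + fn)
  list(sensitivity = sens, specificity = spec, accuracy = acc,
       truncated = c(sensitivity = truncateToPrecision(sens, digits),
                     specificity = truncateToPrecision(spec, digits),
                     accuracy = truncateToPrecision(acc, digits)))
}

#' Unweighted Cohen's kappa between two raters
#'
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with expected agreement from the
#' marginal products. Identical vectors with more than one category present
#' give kappa = 1; two constant, agreeing raters leave kappa undefined.
#'
#' @param calls1,calls2 equal-length categorical vectors.
#' @return kappa (a number in [-1, 1]).
#' @export
cohenKappa <- function(calls1, calls2) {
  if (length(calls1) != length(calls2))
    stop("rater vectors must have equal length")
  n <- length(calls1)
  if (n == 0) stop("rater vectors must be non-empty")
  cats <- sort(unique(c(as.character(calls1), as.character(calls2))))
  t1 <- factor(as.character(calls1), levels = cats)
  t2 <- factor(as.character(calls2), levels = cats)
  tab <- table(t1, t2)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12)
    stop("kappa undefined: both raters constant in the same category")
  (po - pe) / (1 - pe)
}

#' Flag ASPECTS scoring discrepancies between two readers
#'
#' ASPECTS is a 10-point score of early ischemic change; a between-platform
#' or between-reader difference of more than one point counts as a
#' discrepancy.
#'
#' @param scores1,scores2 integer vectors of ASPECTS values in [0, 10].
#' @return logical vector: TRUE where |scores1 - scores2| > 1.
#' @export
aspectsDiscrepancy <- function(scores1, scores2) {
  if (length(scores1) != length(scores2))
    stop("score vectors must have equal length")
  s <- c(scores1, scores2)
  if (any(is.na(s)) || any(s < 0 | s > 10))
    stop("ASPECTS scores must lie in [0, 10]")
  abs(scores1 - scores2) > 1
}

#' Packaged reader-study contingency counts
#'
#' The published per-finding TP/FP/TN/FN counts for both readers, with the
#' printed sensitivity/specificity/accuracy strings, shipped as a plain-CSV
#' fixture.
#'
#' @return data.frame with columns reader, finding, tp, fp, tn, fn and the
#'   printed metric strings.
#' @export
readerStudyCounts <- function() {
  path <- system.file("extdata", "reader_study_counts.csv", package = "teleCT")
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = c(
    reader = "integer", finding = "character", tp = "integer",
    fp = "integer", tn = "integer", fn = "integer",
    sensitivity = "character", specificity = "character",
    accuracy = "character"))
}

.printedDecimals <- function(s) {
  dot <- regexpr(".", s, fixed = TRUE)
  if (dot < 0) 0L else nchar(s) - dot
}

#' Recompute every published metric cell from its counts
#'
#' For each reader x finding row of the packaged counts, recomputes
#' sensitivity, specificity and accuracy and truncates each to the decimals
#' of the corresponding printed value.
#'
#' @return data.frame with computed full-precision and printed-precision
#'   values next to the published ones, plus a \code{matches} flag.
#' @examples
#' tab <- reproduceStudyTables()
#' all(tab$matches)
#' @export
reproduceStudyTables <- function() {
  counts <- readerStudyCounts()
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    row <- counts[i, ]
    m <- diagnosticMetrics(contingencyCounts(row$tp, row$fp, row$tn, row$fn))
    for (metric in c("sensitivity", "specificity", "accuracy")) {
      printed <- row[[metric]]
      d <- .printedDecimals(printed)
      value <- truncateToPrecision(m[[metric]], d)
      rows[[length(rows) + 1L]] <- data.frame(
        reader = row$reader, finding = row$finding, metric = metric,
        full = m[[metric]], computed = value,
        published = as.numeric(printed),
        matches = abs(value - as.numeric(printed)) < 0.005 + 1e-9)
    }
  }
  do.call(rbind, rows)
}
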