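#' Confusion counts of a labeled screen
#'
#' @param tp,fn,fp,tn non-negative integer counts (true positives, false
#'   negatives, false positives, true negatives).
#' @return An object of class \code{confusion_counts} with derived
#'   \code{n_actives = tp + fn} and \code{n_decoys = fp + tn}.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  vals <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  stopifnot(all(vals >= 0), all(vals == round(vals)))
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp), tn = as.integer(tn),
                 n_actives = as.integer(tp + fn),
                 n_decoys = as.integer(fp + tn)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d / FN %d (actives %d); FP %d / TN %d (decoys %d)\n",
              x$tp, x$fn, x$n_actives, x$fp, x$tn, x$n_decoys))
  invisible(x)
}

#' Tally screening outcomes against activity labels
#'
#' @param labels a data.frame with columns \code{molecule_id} and
#'   \code{label} (\code{"active"} or \code{"decoy"}), or a named character
#'   vector of labels.
#' @param table a screening table (see \code{\link{screen_features}}).
#'   Rows flagged \code{error} count as non-hits.
#' @return A \code{\link{confusion_counts}}.
#' @export
counts_from_screen <- function(labels, table) {
  if (!is.data.frame(labels))
    labels <- data.frame(molecule_id = names(labels), label = unname(labels),
                         stringsAsFactors = FALSE)
  stopifnot(all(c("molecule_id", "label") %in% names(labels)),
            all(labels$label %in% c("active", "decoy")))
  lab <- stats::setNames(labels$label, labels$molecule_id)
  unlabeled <- setdiff(table$molecule_id, names(lab))
  if (length(unlabeled))
    stop("unlabeled molecule id(s): ", paste(unlabeled, collapse = ", "),
         call. = FALSE)
  is_active <- lab[table$molecule_id] == "active"
  hit <- table$hit & !table$error
  confusion_counts(tp = sum(is_active & hit),
                   fn = sum(is_active & !hit),
                   fp = sum(!is_active & hit),
                   tn = sum(!is_active & !hit))
}

#' Validation statistics of a screening model
#'
#' The six canonical virtual-screening statistics computed from confusion
#' counts: sensitivity (true-positive rate) = TP / actives; specificity =
#' TN / decoys; false-positive rate = FP / decoys; accuracy = (TP + TN) /
#' (actives + decoys); positive predictive value = TP / (TP + FP);
#' negative predictive value = TN / (TN + FN). Each is reported both as a
#' fraction and as a percentage; a statistic whose denominator is zero is
#' \code{NA} (undefined) while the others are still computed.
#'
#' @param counts a \code{\link{confusion_counts}}.
#' @return An object of class \code{validation_metrics}: list with
#'   \code{counts}, \code{fraction} (named numeric) and \code{percent}.
#' @examples
#' metrics_from_counts(confusion_counts(tp = 45, fn = 11, fp = 16, tn = 191))
#' @export
metrics_from_counts <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  frac <- c(
    sensitivity = safe_div(counts$tp, counts$n_actives),
    specificity = safe_div(counts$tn, counts$n_decoys),
    fpr         = safe_div(counts$fp, counts$n_decoys),
    accuracy    = safe_div(counts$tp + counts$tn,
                           counts$n_actives + counts$n_decoys),
    ppv         = safe_div(counts$tp, counts$tp + counts$fp),
    npv         = safe_div(counts$tn, counts$tn + counts$fn)
  )
  structure(list(counts = counts, fraction = frac, percent = frac * 100),
            class = "validation_metrics")
}

#' @export
print.validation_metrics <- function(x, ...) {
  print(x$counts)
  labels <- c(sensitivity = "Sensitivity (TPR)", specificity = "Specificity",
              fpr = "False positive rate", accuracy = "Accuracy",
              ppv = "Positive predictive value",
              npv = "Negative predictive value")
  for (k in names(labels)) {
    val <- x$percent[[k]]
    cat(sprintf("  %-26s %s\n", labels[[k]],
                if (is.na(val)) "undefined" else sprintf("%.2f%%", val)))
  }
  invisible(x)
}

#' @export
as.data.frame.validation_metrics <- function(x, ...) {
  data.frame(metric = names(x$fraction), fraction = unname(x$fraction),
             percent = unname(x$percent), stringsAsFactors = FALSE)
}
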