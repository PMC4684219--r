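#' Call hot spots from ddG values
#'
#' A mutation is called a hot spot when its ddG is at or above the
#' threshold (inclusive). The default prediction threshold of 1.5 kcal/mol
#' compensates for the regressor's tendency to underestimate ddG; true
#' labels use 2.0 kcal/mol.
#'
#' @param ddg numeric ddG value(s), kcal/mol.
#' @param threshold kcal/mol (default 1.5).
#' @return logical vector.
#' @export
classify_hotspot <- function(ddg, threshold = 1.5) {
  ddg >= threshold
}

#' True hot-spot label from an observation
#'
#' Numeric observations are hot spots at ddG >= `threshold` (default
#' 2 kcal/mol); categorical observations are hot spots only when labeled
#' 'Strong' (Intermediate/Weak/Insignificant are not).
#'
#' @param observed numeric ddG or character category vector; logicals pass
#'   through.
#' @param threshold kcal/mol cutoff for numeric observations.
#' @return logical vector.
#' @export
true_label <- function(observed, threshold = 2) {
  if (is.logical(observed)) return(observed)
  if (is.numeric(observed)) return(observed >= threshold)
  obs <- as.character(observed)
  valid <- c("Strong", "Intermediate", "Weak", "Insignificant")
  bad <- setdiff(unique(obs), valid)
  if (length(bad) > 0)
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  obs == "Strong"
}

#' Hot-spot classification metrics
#'
#' Confusion counts and the derived metrics with hot spots as the positive
#' class: precision TP/(TP+FP), recall TP/(TP+FN), F1 (harmonic mean),
#' accuracy (TP+TN)/n, specificity TN/(TN+FP), negative precision
#' TN/(TN+FN). A ratio whose denominator is zero is reported as NA
#' (undefined), not 0. When both sides are numeric, the Pearson
#' correlation of predicted vs observed ddG is included.
#'
#' @param predicted numeric ddG predictions, or logical/0-1 calls.
#' @param observed numeric ddG, categorical labels, or logical truth.
#' @param pred_threshold threshold for numeric predictions (kcal/mol).
#' @param obs_threshold threshold for numeric observations (kcal/mol).
#' @return list of class `hotspot_metrics`.
#' @export
hotspot_metrics <- function(predicted, observed, pred_threshold = 1.5,
                            obs_threshold = 2) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 1)
  pred_call <- if (is.numeric(predicted) && !all(predicted %in% c(0, 1)))
    classify_hotspot(predicted, pred_threshold) else as.logical(predicted)
  truth <- true_label(observed, obs_threshold)
  tp <- sum(pred_call & truth)
  fp <- sum(pred_call & !truth)
  tn <- sum(!pred_call & !truth)
  fn <- sum(!pred_call & truth)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  p <- if (is.numeric(predicted) && is.numeric(observed) &&
           length(predicted) >= 3 &&
           stats::sd(predicted) > 0 && stats::sd(observed) > 0)
    pearson_cc(predicted, observed) else NA_real_
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 precision = precision, recall = recall, F1 = f1,
                 accuracy = ratio(tp + tn, tp + fp + tn + fn),
                 specificity = ratio(tn, tn + fp),
                 negative_precision = ratio(tn, tn + fn),
                 pcc = p),
            class = "hotspot_metrics")
}

#' @export
print.hotspot_metrics <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  for (nm in c("precision", "recall", "F1", "accuracy", "specificity",
               "negative_precision", "pcc")) {
    v <- x[[nm]]
    cat(sprintf("  %-18s %s\n", nm,
                if (is.na(v)) "undefined" else sprintf("%.3f", v)))
  }
  invisible(x)
}

#' Pearson correlation of predicted vs observed ddG
#'
#' @param pred,obs numeric vectors of equal length (at least 3), neither
#'   constant.
#' @return Pearson product-moment correlation; NA with a warning for a
#'   constant series.
#' @export
pearson_cc <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(pred) >= 3)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    warning("constant series: correlation undefined")
    return(NA_real_)
  }
  stats::cor(pred, obs)
}

#' Load the bundled three-complex benchmark
#'
#' Published predictions of five hot-spot predictors on four residues
#' shared by three complexes (1TH1, 1JPP, 3OUX), with curated categorical
#' labels. Used to validate the metric definitions against printed
#' results.
#'
#' @return data frame with columns `complex`, `residue`, `observed`,
#'   `robetta_ddg`, `crf_ddg`, `hotpoint`, `kfc2a`, `kfc2b`.
#' @export
three_complex_benchmark <- function() {
  utils::read.delim(hotspot_extdata("three_complex_benchmark.tsv"),
                    comment.char = "#", stringsAsFactors = FALSE)
}
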