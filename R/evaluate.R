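## ---- evaluation against annotated gain/loss labels --------------------------

ANNOT_LEVELS <- c("GoF", "LoF")
PRED_LEVELS <- c("GoF", "LoF", "SoF", "CoF")

#' Confusion matrix of annotated versus predicted types
#'
#' Rows are the database annotation (GoF/LoF, the only annotated classes);
#' columns are the four predicted categories.
#'
#' @param annotated character vector of `"GoF"`/`"LoF"` labels.
#' @param predicted character vector of `"GoF"`/`"LoF"`/`"SoF"`/`"CoF"`.
#' @return 2 x 4 integer matrix of counts.
#' @export
confusion_matrix <- function(annotated, predicted) {
  if (length(annotated) != length(predicted)) {
    stop("annotated and predicted must have equal length")
  }
  if (!all(annotated %in% ANNOT_LEVELS)) stop("annotations must be GoF or LoF")
  if (!all(predicted %in% PRED_LEVELS)) stop("invalid predicted label")
  table(factor(annotated, ANNOT_LEVELS), factor(predicted, PRED_LEVELS))
}

#' Binary metrics restricted to predicted gain/loss calls
#'
#' Sensitivity (with respect to GoF), specificity, and accuracy computed on
#' the 2 x 2 block of predicted-GoF and predicted-LoF calls only; variants
#' predicted SoF or CoF do not enter the metrics. A zero denominator yields
#' `NA` (undefined), never 0.
#'
#' @param confusion 2 x 4 count matrix from [confusion_matrix()].
#' @return named list with `sensitivity`, `specificity`, `accuracy`, `n_used`.
#' @export
binary_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == 2L, ncol(confusion) >= 2L)
  gg <- confusion["GoF", "GoF"]; gl <- confusion["GoF", "LoF"]
  lg <- confusion["LoF", "GoF"]; ll <- confusion["LoF", "LoF"]
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  list(sensitivity = safe_div(gg, gg + gl),
       specificity = safe_div(ll, ll + lg),
       accuracy = safe_div(gg + ll, gg + gl + lg + ll),
       n_used = gg + gl + lg + ll)
}

#' ROC sweep over the score cutoff
#'
#' Classifies every variant at each cutoff in `t_grid` from its
#' `(S0, Sx)` score pair, computes the restricted binary metrics, and
#' returns the operating points plus a trapezoidal AUC (anchored at (0,0)
#' and (1,1) in false-positive-rate coordinates).
#'
#' @param score_pairs data frame with numeric columns `S0` and `Sx`.
#' @param annotated `"GoF"`/`"LoF"` annotation per variant.
#' @param t_grid numeric vector of cutoffs to sweep.
#' @return list with `curve` (data frame: t, sensitivity, fpr) and `auc`.
#' @export
roc_over_cutoff <- function(score_pairs, annotated, t_grid) {
  if (length(t_grid) == 0L) stop("empty cutoff grid")
  if (length(annotated) == 0L) stop("no annotated variants")
  stopifnot(nrow(score_pairs) == length(annotated))
  pts <- lapply(t_grid, function(t) {
    pred <- vapply(seq_len(nrow(score_pairs)), function(i) {
      classify_variant(list(target_score = score_pairs$S0[i],
                            min_other_score = score_pairs$Sx[i]),
                       cutoff = t)$predicted
    }, character(1))
    m <- binary_metrics(confusion_matrix(annotated, pred))
    data.frame(t = t, sensitivity = m$sensitivity, fpr = 1 - m$specificity)
  })
  curve <- do.call(rbind, pts)
  ok <- stats::complete.cases(curve)
  xs <- c(0, curve$fpr[ok], 1)
  ys <- c(0, curve$sensitivity[ok], 1)
  o <- order(xs, ys)
  xs <- xs[o]; ys <- ys[o]
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  list(curve = curve, auc = auc)
}

#' Keep only confident classifications
#'
#' Retains results whose maximum confidence score strictly exceeds `floor`;
#' no-call results are dropped.
#'
#' @param results list of `soft_classification` objects.
#' @param floor probability floor (default 0.5).
#' @return filtered list.
#' @export
filter_by_confidence <- function(results, floor = 0.5) {
  if (floor < 0 || floor > 1) stop("floor must be in [0, 1]")
  Filter(function(r) {
    !isTRUE(r$no_call) && max(r$confidence) > floor
  }, results)
}

#' Transactivity class from a median promoter activity
#'
#' Labels TP53-style transactivation measurements by the conventional
#' cutpoints 20 / 75 / 140 (median over promoter-specific activity levels,
#' percent of wild type). Boundary values are assigned to the
#' upper-adjacent class via half-open intervals.
#'
#' @param median_activity nonnegative numeric vector.
#' @return character vector: `"nonfunctional"`, `"partially functional"`,
#'   `"functional"`, or `"supertrans"`.
#' @export
transactivity_class <- function(median_activity) {
  if (any(!is.finite(median_activity)) || any(median_activity < 0)) {
    stop("median activity must be nonnegative")
  }
  as.character(cut(median_activity,
                   breaks = c(-Inf, 20, 75, 140, Inf), right = FALSE,
                   labels = c("nonfunctional", "partially functional",
                              "functional", "supertrans")))
}
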