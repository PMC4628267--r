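## ---- logistic soft classification ------------------------------------------

#' Probability of losing the original subfamily's function
#'
#' Logistic transform of the target-cluster score relative to the cutoff:
#' `1 / (1 + exp(-(S0 - t)))`. The log odds are linear in the cutoff, so
#' `S0 = t` maps to probability 0.5.
#'
#' @param target_score variant score against the target-cluster profile.
#' @param cutoff score cutoff t.
#' @return probability in (0, 1).
#' @export
loss_probability <- function(target_score, cutoff) {
  if (!is.finite(target_score)) stop("non-finite target score")
  if (!is.finite(cutoff)) stop("non-finite cutoff")
  plogis(target_score - cutoff)
}

#' Probability of acquiring another subfamily's function
#'
#' Logistic transform of the cutoff relative to the minimum non-target
#' cluster score: `1 / (1 + exp(-(t - Sx)))`. Small or negative `Sx` (the
#' mutant fits some other subfamily better than the wild type does) pushes
#' this toward 1.
#'
#' @param min_other_score minimum variant score over non-target clusters.
#' @param cutoff score cutoff t.
#' @return probability in (0, 1).
#' @export
gain_probability <- function(min_other_score, cutoff) {
  if (!is.finite(min_other_score)) stop("non-finite minimum other-cluster score")
  if (!is.finite(cutoff)) stop("non-finite cutoff")
  plogis(cutoff - min_other_score)
}

#' Combine loss and acquire probabilities into four confidence scores
#'
#' Treating loss of the original function (probability L) and acquisition of
#' a new function (probability A) as independent, the four outcome
#' confidences are the branch products of the combination tree:
#' LoF = L(1-A), SoF = LA, GoF = (1-L)A, CoF = (1-L)(1-A). They always sum
#' to one.
#'
#' @param loss_prob,acquire_prob probabilities in \[0, 1\].
#' @return named numeric vector `c(LoF, SoF, GoF, CoF)`.
#' @export
confidence_scores <- function(loss_prob, acquire_prob) {
  if (!is.numeric(loss_prob) || loss_prob < 0 || loss_prob > 1) {
    stop("loss_prob must be in [0, 1]")
  }
  if (!is.numeric(acquire_prob) || acquire_prob < 0 || acquire_prob > 1) {
    stop("acquire_prob must be in [0, 1]")
  }
  c(LoF = loss_prob * (1 - acquire_prob),
    SoF = loss_prob * acquire_prob,
    GoF = (1 - loss_prob) * acquire_prob,
    CoF = (1 - loss_prob) * (1 - acquire_prob))
}

#' Recover a score from a printed probability
#'
#' Inverts [loss_probability()] (`which = "loss"`: `t + ln(p/(1-p))`) or
#' [gain_probability()] (`which = "gain"`: `t - ln(p/(1-p))`). Round-trips
#' with the forward transforms to machine precision.
#'
#' @param p probability strictly inside (0, 1).
#' @param cutoff score cutoff t used when `p` was computed.
#' @param which `"loss"` or `"gain"`.
#' @return the underlying score.
#' @export
invert_logistic <- function(p, cutoff, which = c("loss", "gain")) {
  which <- match.arg(which)
  if (!is.numeric(p) || p <= 0 || p >= 1) stop("p must be strictly inside (0, 1)")
  if (which == "loss") cutoff + qlogis(p) else cutoff - qlogis(p)
}

TYPE_TIE_ORDER <- c("LoF", "SoF", "CoF", "GoF")

#' Classify a variant from its score set
#'
#' Converts the target score and the minimum other-cluster score into the
#' loss and acquire probabilities at the given cutoff, combines them into
#' four confidence scores, and predicts the type attaining the maximum
#' confidence; exact ties resolve in the order LoF, SoF, CoF, GoF. When no
#' eligible non-target cluster exists the acquire probability is 0 (the
#' variant can only be LoF or CoF). A `no_call` score set passes through
#' with unset confidences. Calls whose maximum confidence does not exceed
#' 0.5 are flagged `low_confidence`.
#'
#' @param scores a [variant_score_set()], or any list with `target_score`,
#'   `min_other_score` and optionally `no_call`.
#' @param cutoff score cutoff t (default 2.7).
#' @return an object of class `soft_classification` with fields `loss_prob`,
#'   `acquire_prob`, `cutoff`, `confidence` (named length-4 vector),
#'   `predicted`, `no_call`, `low_confidence`.
#' @export
classify_variant <- function(scores, cutoff = 2.7) {
  if (isTRUE(scores$no_call)) {
    return(structure(list(loss_prob = NA_real_, acquire_prob = NA_real_,
                          cutoff = cutoff,
                          confidence = setNames(rep(NA_real_, 4L), c("LoF", "SoF", "GoF", "CoF")),
                          predicted = "no_call", no_call = TRUE,
                          low_confidence = NA),
                     class = "soft_classification"))
  }
  L <- loss_probability(scores$target_score, cutoff)
  A <- if (is.na(scores$min_other_score)) 0 else gain_probability(scores$min_other_score, cutoff)
  conf <- confidence_scores(L, A)
  predicted <- TYPE_TIE_ORDER[which.max(conf[TYPE_TIE_ORDER])]
  structure(list(loss_prob = L, acquire_prob = A, cutoff = cutoff,
                 confidence = conf, predicted = predicted, no_call = FALSE,
                 low_confidence = max(conf) <= 0.5),
            class = "soft_classification")
}

#' @export
print.soft_classification <- function(x, ...) {
  if (x$no_call) {
    cat("soft_classification: no call (insignificant bit scores)\n")
    return(invisible(x))
  }
  cat(sprintf("soft_classification: %s (L = %.3f, A = %.3f, t = %g)\n",
              x$predicted, x$loss_prob, x$acquire_prob, x$cutoff))
  print(round(x$confidence, 3))
  invisible(x)
}
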