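# Overlap evaluation against a reference (radiologist-style) mask.
# TN is never computed: the metric set is TN-free, and in an ROI the
# background would dominate it.

#' Pixel confusion counts between reference and segmentation
#'
#' `tp` is the overlap of the two masks, `fp` the pixels only the
#' segmentation claims, `fn` the pixels only the reference claims.
#'
#' @param ref reference 0/1 mask.
#' @param seg segmentation 0/1 mask, same shape.
#' @return list of class `"confusion_counts"` with integer `tp`, `fp`, `fn`.
#' @export
confusion <- function(ref, seg) {
  .validate_mask(ref, "ref")
  .validate_mask(seg, "seg")
  if (!identical(dim(ref), dim(seg)))
    stop("ref and seg shapes differ", call. = FALSE)
  r <- ref == 1; s <- seg == 1
  structure(list(tp = sum(r & s), fp = sum(!r & s), fn = sum(r & !s)),
            class = "confusion_counts")
}

#' The six overlap ratios
#'
#' From pixel counts `tp`, `fp`, `fn`:
#' \deqn{Hitting = TP/(TP+FN), \quad Missing = FN/(TP+FN), \quad
#'       OverHitting = FP/(TP+FN)}
#' \deqn{RelativeHitting = TP/(TP+FP), \quad RelativeMissing = FN/(TP+FP)}
#' \deqn{Kappa = 2\,Hitting / (2\,Hitting + Missing + OverHitting)}
#' Hitting is the fraction of the reference mass that was found; Missing
#' the fraction missed; OverHitting the false area relative to the mass
#' size (may exceed 1); the Relative pair normalizes by the segmentation
#' size instead. Kappa is computed from the unrounded ratios and is
#' algebraically the Dice coefficient `2TP/(2TP+FP+FN)`.
#'
#' @param c a `"confusion_counts"` object, or a list/vector with `tp`,
#'   `fp`, `fn`.
#' @return named numeric vector: `hitting`, `missing`, `over_hitting`,
#'   `relative_hitting`, `relative_missing`, `kappa` at full precision.
#' @seealso [metrics_report()] for the 2-decimal view.
#' @export
#' @examples
#' compute_metrics(list(tp = 4517, fp = 635, fn = 825))
compute_metrics <- function(c) {
  tp <- as.numeric(c[["tp"]]); fp <- as.numeric(c[["fp"]])
  fn <- as.numeric(c[["fn"]])
  if (any(is.na(c(tp, fp, fn))) || any(c(tp, fp, fn) < 0))
    stop("tp, fp, fn must be non-negative counts", call. = FALSE)
  if (tp + fn == 0)
    stop("tp + fn = 0: the reference mask is empty", call. = FALSE)
  if (tp + fp == 0)
    stop("tp + fp = 0: the segmentation mask is empty", call. = FALSE)
  hitting <- tp / (tp + fn)
  missing <- fn / (tp + fn)
  over_hitting <- fp / (tp + fn)
  relative_hitting <- tp / (tp + fp)
  relative_missing <- fn / (tp + fp)
  kappa <- 2 * hitting / (2 * hitting + missing + over_hitting)
  c(hitting = hitting, missing = missing, over_hitting = over_hitting,
    relative_hitting = relative_hitting, relative_missing = relative_missing,
    kappa = kappa)
}

#' Two-decimal metric report
#'
#' The reporting view of [compute_metrics()]: every ratio rounded to two
#' decimals, half away from zero.
#'
#' @inheritParams compute_metrics
#' @return named numeric vector of the six ratios rounded to 2 decimals.
#' @export
metrics_report <- function(c) {
  round_half_away(compute_metrics(c), 2)
}

#' Dice coefficient of two masks
#'
#' Convenience wrapper: `2 TP / (2 TP + FP + FN)`, identical to the
#' `kappa` entry of [compute_metrics()].
#'
#' @inheritParams confusion
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(ref, seg) {
  cc <- confusion(ref, seg)
  if (cc$tp + cc$fp + cc$fn == 0) return(1)
  2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP = %d, FP = %d, FN = %d\n",
              x$tp, x$fp, x$fn))
  invisible(x)
}
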