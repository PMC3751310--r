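## Support-recovery scoring against simulation truth.

#' Confusion counts of a selected support
#'
#' Compares the selected feature sets of both sides against the true
#' supports. A feature counts as selected iff its loading entry is exactly
#' nonzero (the solver's thresholding produces exact zeros, so no magnitude
#' cutoff is applied).
#'
#' @param selectedX,selectedY integer indices of the selected features per
#'   side.
#' @param truth a [SimTruth-class] object.
#' @return A list with integer fields \code{tpX}, \code{fpX}, \code{fnX},
#'   \code{tnX}, \code{tpY}, \code{fpY}, \code{fnY}, \code{tnY}; per side
#'   the four counts sum to that side's feature count.
#' @seealso [ttpr()], [tfpr()], [totalDiscordance()]
#' @export
confusionCounts <- function(selectedX, selectedY, truth) {
  stopifnot(is(truth, "SimTruth"))
  p <- length(truth@thetaX); q <- length(truth@thetaY)
  selectedX <- unique(as.integer(selectedX))
  selectedY <- unique(as.integer(selectedY))
  if (length(selectedX) && (min(selectedX) < 1L || max(selectedX) > p))
    stop("selectedX contains out-of-range indices", call. = FALSE)
  if (length(selectedY) && (min(selectedY) < 1L || max(selectedY) > q))
    stop("selectedY contains out-of-range indices", call. = FALSE)
  side <- function(sel, supp, nFeat) {
    tp <- length(intersect(sel, supp))
    fp <- length(setdiff(sel, supp))
    fn <- length(setdiff(supp, sel))
    tn <- nFeat - tp - fp - fn
    c(tp = tp, fp = fp, fn = fn, tn = tn)
  }
  x <- side(selectedX, truth@supportX, p)
  y <- side(selectedY, truth@supportY, q)
  list(tpX = x[["tp"]], fpX = x[["fp"]], fnX = x[["fn"]], tnX = x[["tn"]],
       tpY = y[["tp"]], fpY = y[["fp"]], fnY = y[["fn"]], tnY = y[["tn"]])
}

#' Total true/false positive rates and total discordance
#'
#' The pooled-side recovery metrics:
#' TTPR = (TP_X + TP_Y) / (TP_X + FN_X + TP_Y + FN_Y),
#' TFPR = (FP_X + FP_Y) / (FP_X + TN_X + FP_Y + TN_Y),
#' TD = FP_X + FN_X + FP_Y + FN_Y. TD = 0 iff the support is recovered
#' exactly. A zero denominator (e.g. an all-null truth for TTPR) raises an
#' error rather than silently returning 0.
#'
#' @param counts a list from [confusionCounts()].
#' @return \code{ttpr}/\code{tfpr}: a number in \[0, 1\];
#'   \code{totalDiscordance}: a nonnegative integer.
#' @examples
#' \dontrun{
#' cc <- confusionCounts(sel$x, sel$y, sim$truth)
#' ttpr(cc); tfpr(cc); totalDiscordance(cc)
#' }
#' @export
ttpr <- function(counts) {
  den <- counts$tpX + counts$fnX + counts$tpY + counts$fnY
  if (den == 0) stop("TTPR undefined: no true features in either side",
                     call. = FALSE)
  (counts$tpX + counts$tpY) / den
}

#' @rdname ttpr
#' @export
tfpr <- function(counts) {
  den <- counts$fpX + counts$tnX + counts$fpY + counts$tnY
  if (den == 0) stop("TFPR undefined: no null features in either side",
                     call. = FALSE)
  (counts$fpX + counts$fpY) / den
}

#' @rdname ttpr
#' @export
totalDiscordance <- function(counts) {
  counts$fpX + counts$fnX + counts$fpY + counts$fnY
}
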