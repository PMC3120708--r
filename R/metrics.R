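#' Per-protein distance between a lab-confirmed and a predicted site
#'
#' The distance along one protein is the larger of the start and end
#' overshoots, clamped at zero:
#' \deqn{\Delta = \max(0,\; start_{lab} - start_{pred},\; end_{pred} - end_{lab})}
#' It is zero exactly when the prediction is contained in the lab range —
#' lab ranges frequently over-estimate the true site, so containment counts
#' as a perfect match — and grows when the prediction overshoots the lab
#' range on either side.
#'
#' @param lab,pred 1-based inclusive intervals \code{c(start, end)}.
#' @return Non-negative integer distance in residues.
#' @examples
#' deltaProtein(c(411, 468), c(426, 467))  # containment: 0
#' deltaProtein(c(10, 30), c(40, 60))      # 30
#' @export
deltaProtein <- function(lab, pred) {
  lab <- .checkRange(lab, "lab interval")
  pred <- .checkRange(pred, "predicted interval")
  max(0L, lab[1L] - pred[1L], pred[2L] - lab[2L])
}

#' Distance Measure between predicted and lab-confirmed site pairs
#'
#' Per-protein clamped overshoots (\code{\link{deltaProtein}}) are scaled by
#' protein length and combined by vector addition:
#' \deqn{DM = \frac{1}{\sqrt 2}\sqrt{\left(\frac{\Delta_A}{L_A-1}\right)^2 +
#'   \left(\frac{\Delta_B}{L_B-1}\right)^2}}
#' The \eqn{1/\sqrt 2} factor keeps DM in [0, 1]: 0 means the prediction is
#' contained in the lab site on both proteins; 1 means single-residue sites
#' at opposite ends of both proteins. Normalising by \eqn{L - 1} makes that
#' extreme exactly 1 for any length; a length-1 protein contributes ratio 0.
#'
#' @param labA,labB lab-confirmed intervals \code{c(start, end)} on proteins
#'   A and B.
#' @param predA,predB predicted intervals.
#' @param lenA,lenB protein lengths in residues.
#' @return List with \code{deltaA}, \code{deltaB} (residues), \code{ratioA},
#'   \code{ratioB} (dimensionless) and \code{dm} in [0, 1].
#' @examples
#' distanceMeasure(c(10, 90), c(10, 90), c(40, 50), c(40, 50), 100, 100)$dm
#' distanceMeasure(c(1, 1), c(1, 1), c(100, 100), c(100, 100), 100, 100)$dm
#' @export
distanceMeasure <- function(labA, labB, predA, predB, lenA, lenB) {
  labA <- .checkRange(labA, "labA"); labB <- .checkRange(labB, "labB")
  predA <- .checkRange(predA, "predA"); predB <- .checkRange(predB, "predB")
  if (labA[2L] > lenA || predA[2L] > lenA)
    stop("interval exceeds protein A length", call. = FALSE)
  if (labB[2L] > lenB || predB[2L] > lenB)
    stop("interval exceeds protein B length", call. = FALSE)
  dA <- deltaProtein(labA, predA)
  dB <- deltaProtein(labB, predB)
  rA <- if (lenA > 1L) dA / (lenA - 1L) else 0
  rB <- if (lenB > 1L) dB / (lenB - 1L) else 0
  list(deltaA = dA, deltaB = dB, ratioA = rA, ratioB = rB,
       dm = sqrt((rA^2 + rB^2) / 2))
}

#' Best-of-k distance over ranked predictions
#'
#' The minimum DM over the k highest-ranked predictions of a pair — the
#' error achieved when wet-lab validation is attempted on the top k candidate
#' sites.
#'
#' @param dms numeric vector of DM values ordered by prediction rank.
#' @param k number of leading predictions to consider.
#' @return Minimum of the first \code{k} values (of all values when fewer
#'   than \code{k} exist); \code{NA} for an empty vector, signalling that the
#'   pair is excluded from averages.
#' @examples
#' bestOfK(c(0.4, 0.1, 0.3), 2)
#' @export
bestOfK <- function(dms, k) {
  stopifnot(k >= 1L)
  if (!length(dms)) return(NA_real_)
  min(dms[seq_len(min(k, length(dms)))])
}
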