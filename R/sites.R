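#' Find the tallest unmasked landscape cell
#'
#' Ties are broken deterministically: smallest row index i, then smallest
#' column index j.
#'
#' @param landscape a \code{\link{Landscape}}.
#' @param mask optional logical matrix of cells to exclude.
#' @return \code{list(i, j, height)}, or \code{NULL} when every cell is
#'   masked or every unmasked height is zero.
#' @export
findGlobalPeak <- function(landscape, mask = NULL) {
  H <- landscapeMatrix(landscape)
  if (!length(H)) return(NULL)
  Hm <- H
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(H)))
    Hm[mask] <- -1L
  }
  top <- max(Hm)
  if (top <= 0L) return(NULL)
  hits <- which(Hm == top, arr.ind = TRUE)
  k <- order(hits[, 1L], hits[, 2L])[1L]
  list(i = unname(hits[k, 1L]), j = unname(hits[k, 2L]), height = top)
}

#' Is a peak a spurious spike?
#'
#' A peak is spurious when any in-bounds axial neighbour lies below
#' \code{percentPeak} times the peak height, i.e. a minimum of one walk step
#' in that direction is impossible. Directions falling outside the matrix are
#' treated as satisfied, so boundary peaks are not auto-rejected.
#'
#' @param landscape a \code{\link{Landscape}}.
#' @param peak \code{list(i, j, height)} as from \code{\link{findGlobalPeak}}.
#' @param params a \code{\link{SiteParams}} (only \code{percentPeak} is used).
#' @return Single logical.
#' @export
isSpuriousPeak <- function(landscape, peak, params = siteParams()) {
  H <- landscapeMatrix(landscape)
  i <- peak$i; j <- peak$j
  stopifnot(i >= 1L, i <= nrow(H), j >= 1L, j <= ncol(H))
  t <- params@percentPeak * H[i, j]
  nb <- rbind(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))
  inb <- nb[, 1L] >= 1L & nb[, 1L] <= nrow(H) &
         nb[, 2L] >= 1L & nb[, 2L] <= ncol(H)
  any(H[nb[inb, , drop = FALSE]] < t)
}

#' Walk down from a peak to delimit its site rectangle
#'
#' From peak (i, j) the walk proceeds independently in the four axial
#' directions (up, down, left, right), continuing while the landscape stays
#' at or above \code{percentPeak} times the peak height, and stopping at the
#' first cell below the threshold or at the matrix boundary. The four run
#' extents define the window-index rectangle of the predicted site.
#'
#' @inheritParams isSpuriousPeak
#' @param percentPeak walk threshold as a fraction of the peak height.
#' @param mask optional logical matrix: cells already claimed by a
#'   higher-ranked site. The walk also stops at a masked cell, which keeps
#'   rectangles of distinct ranks cell-disjoint.
#' @return Named integer vector \code{c(i0, i1, j0, j1)}; always contains the
#'   peak.
#' @export
walkPeak <- function(landscape, peak, percentPeak = 0.30, mask = NULL) {
  if (isSpuriousPeak(landscape, peak,
                     siteParams(percentPeak = percentPeak)))
    stop("walkPeak called on a spurious peak (contract violation)",
         call. = FALSE)
  H <- landscapeMatrix(landscape)
  if (is.null(mask)) mask <- matrix(FALSE, nrow(H), ncol(H))
  i <- peak$i; j <- peak$j
  t <- percentPeak * H[i, j]
  ok <- function(i2, j2) H[i2, j2] >= t && !mask[i2, j2]
  i0 <- i; while (i0 > 1L && ok(i0 - 1L, j)) i0 <- i0 - 1L
  i1 <- i; while (i1 < nrow(H) && ok(i1 + 1L, j)) i1 <- i1 + 1L
  j0 <- j; while (j0 > 1L && ok(i, j0 - 1L)) j0 <- j0 - 1L
  j1 <- j; while (j1 < ncol(H) && ok(i, j1 + 1L)) j1 <- j1 + 1L
  c(i0 = i0, i1 = i1, j0 = j0, j1 = j1)
}

#' Convert a window-index rectangle to residue ranges
#'
#' The residue range on each protein is the union of the residues covered by
#' the rectangle's windows: \code{[i0, i1 + w - 1]} and \code{[j0, j1 + w - 1]},
#' 1-based inclusive.
#'
#' @param rect named integer vector \code{c(i0, i1, j0, j1)} from
#'   \code{\link{walkPeak}}.
#' @param w window length of the landscape.
#' @return Named integer vector \code{c(startA, endA, startB, endB)}.
#' @examples
#' rectToRanges(c(i0 = 2, i1 = 4, j0 = 2, j1 = 4), w = 3)
#' @export
rectToRanges <- function(rect, w) {
  rect <- as.integer(rect[c("i0", "i1", "j0", "j1")])
  w <- as.integer(w)
  c(startA = rect[1L], endA = rect[2L] + w - 1L,
    startB = rect[3L], endB = rect[4L] + w - 1L)
}

# Shrink a walked rectangle until it contains no masked (already claimed)
# cell. The axial walk already avoids masked cells on the peak's own row and
# column, so any masked cell lies off-axis and trimming the corresponding
# side towards the peak removes it; rectangles of distinct ranks therefore
# stay cell-disjoint.
.clipToMask <- function(rect, mask, i, j) {
  repeat {
    sub <- mask[rect["i0"]:rect["i1"], rect["j0"]:rect["j1"], drop = FALSE]
    if (!any(sub)) return(rect)
    hit <- which(sub, arr.ind = TRUE)[1L, ]
    r <- rect["i0"] + hit[1L] - 1L
    c <- rect["j0"] + hit[2L] - 1L
    if (r < i) rect["i0"] <- rect["i0"] + 1L
    else if (r > i) rect["i1"] <- rect["i1"] - 1L
    else if (c < j) rect["j0"] <- rect["j0"] + 1L
    else rect["j1"] <- rect["j1"] - 1L
  }
}

#' Predict ranked binding sites from a landscape
#'
#' If the tallest peak is below \code{minPeakHeight} the landscape makes no
#' predictions (the gate that drops diffuse, featureless landscapes).
#' Otherwise peaks are visited in decreasing height: spurious spikes are
#' masked cell-by-cell and skipped; a genuine peak is walked, recorded, and
#' its whole rectangle is masked so later peaks describe disjoint sites. The
#' loop ends after \code{maxPeaks} predictions or when no unmasked peak
#' reaches \code{minPeakHeight}.
#'
#' @param landscape a \code{\link{Landscape}}.
#' @param params a \code{\link{SiteParams}}.
#' @return data.frame with one row per prediction: \code{idA}, \code{idB},
#'   \code{rank}, \code{peakHeight}, residue ranges \code{startA}/\code{endA}/
#'   \code{startB}/\code{endB}, and the window rectangle \code{i0}, \code{i1},
#'   \code{j0}, \code{j1}. Ranks follow decreasing peak height.
#' @export
predictSites <- function(landscape, params = siteParams()) {
  H <- landscapeMatrix(landscape)
  out <- .emptyPredictions()
  if (!length(H) || max(H) < params@minPeakHeight) return(out)
  ids <- queryIds(landscape)
  w <- windowLength(landscape)
  # spurious spikes are masked from the peak search only; rectangles claimed
  # by earlier ranks also stop the walk, keeping predictions cell-disjoint
  spurMask <- matrix(FALSE, nrow(H), ncol(H))
  claimMask <- matrix(FALSE, nrow(H), ncol(H))
  rank <- 0L
  repeat {
    p <- findGlobalPeak(landscape, spurMask | claimMask)
    if (is.null(p) || p$height < params@minPeakHeight) break
    if (isSpuriousPeak(landscape, p, params)) {
      spurMask[p$i, p$j] <- TRUE
      next
    }
    rect <- walkPeak(landscape, p, params@percentPeak, claimMask)
    rect <- .clipToMask(rect, claimMask, p$i, p$j)
    rr <- rectToRanges(rect, w)
    rank <- rank + 1L
    out[rank, c("idA", "idB")] <- as.list(ids)
    out[rank, c("rank", "peakHeight")] <- list(rank, p$height)
    out[rank, names(rr)] <- as.list(rr)
    out[rank, names(rect)] <- as.list(rect)
    claimMask[rect["i0"]:rect["i1"], rect["j0"]:rect["j1"]] <- TRUE
    if (rank >= params@maxPeaks) break
  }
  out
}
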