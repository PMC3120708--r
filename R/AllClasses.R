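#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
NULL

# Residues accepted everywhere: the 20 standard amino acids plus 'X' (unknown).
.AA_OK <- c("A","C","D","E","F","G","H","I","K","L",
            "M","N","P","Q","R","S","T","V","W","Y","X")

#' Window-matching parameters
#'
#' Controls how a sequence window from a query protein is matched against a
#' database protein when building a co-occurrence landscape.
#'
#' In \code{"exact"} mode a window matches a database protein when it occurs
#' as a contiguous substring ('X' matches only itself). In \code{"similarity"}
#' mode a window matches when some window of the database protein scores at
#' least \code{scoreThreshold} under the named substitution matrix (summed
#' per-position scores; 'X' never matches any position).
#'
#' @slot w single integer, window length in residues.
#' @slot mode \code{"exact"} or \code{"similarity"}.
#' @slot substitutionMatrix name of a substitution matrix shipped with
#'   \pkg{Biostrings} (e.g. \code{"BLOSUM62"}); used only in similarity mode.
#' @slot scoreThreshold minimum summed substitution score for a similarity
#'   match; required in similarity mode.
#'
#' @examples
#' MatchParams(w = 3)
#' MatchParams(w = 3, mode = "similarity", scoreThreshold = 12)
#' @export MatchParams
#' @exportClass MatchParams
MatchParams <- setClass("MatchParams",
  representation(w = "integer", mode = "character",
                 substitutionMatrix = "character", scoreThreshold = "numeric"),
  prototype(w = 20L, mode = "exact",
            substitutionMatrix = "BLOSUM62", scoreThreshold = NA_real_))

setValidity("MatchParams", function(object) {
  msg <- character()
  if (length(object@w) != 1L || is.na(object@w) || object@w < 1L)
    msg <- c(msg, "'w' must be a single integer >= 1")
  if (!object@mode %in% c("exact", "similarity"))
    msg <- c(msg, "'mode' must be \"exact\" or \"similarity\"")
  if (identical(object@mode, "similarity") && !is.finite(object@scoreThreshold))
    msg <- c(msg, "'scoreThreshold' is required in similarity mode")
  if (length(msg)) msg else TRUE
})

#' @describeIn MatchParams user constructor.
#' @param w,mode,substitutionMatrix,scoreThreshold see slots.
#' @export
matchParams <- function(w = 20L, mode = c("exact", "similarity"),
                        substitutionMatrix = "BLOSUM62",
                        scoreThreshold = NA_real_) {
  mode <- match.arg(mode)
  new("MatchParams", w = as.integer(w), mode = mode,
      substitutionMatrix = substitutionMatrix,
      scoreThreshold = as.numeric(scoreThreshold))
}

#' Site-calling parameters
#'
#' Tuning knobs for peak selection and the walk algorithm.
#'
#' @slot percentPeak fraction in (0, 1]: the walk stops when the landscape
#'   drops below \code{percentPeak} times the current peak height. Lower
#'   values extend the predicted sites further down the hill.
#' @slot minPeakHeight integer: landscapes whose tallest peak is below this
#'   count make no predictions at all (default 10).
#' @slot maxPeaks integer: number of ranked sites to report (default 3).
#'
#' A minimum of one walk step in each in-bounds direction is always enforced:
#' peaks with an axial neighbour below the walk threshold are rejected as
#' spurious spikes (see \code{\link{isSpuriousPeak}}).
#'
#' @examples
#' SiteParams()
#' SiteParams(percentPeak = 0.5, maxPeaks = 1)
#' @export SiteParams
#' @exportClass SiteParams
SiteParams <- setClass("SiteParams",
  representation(percentPeak = "numeric", minPeakHeight = "integer",
                 maxPeaks = "integer"),
  prototype(percentPeak = 0.30, minPeakHeight = 10L, maxPeaks = 3L))

setValidity("SiteParams", function(object) {
  msg <- character()
  if (!(length(object@percentPeak) == 1L && object@percentPeak > 0 &&
        object@percentPeak <= 1))
    msg <- c(msg, "'percentPeak' must be in (0, 1]")
  if (object@minPeakHeight < 1L) msg <- c(msg, "'minPeakHeight' must be >= 1")
  if (object@maxPeaks < 1L) msg <- c(msg, "'maxPeaks' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn SiteParams user constructor.
#' @param percentPeak,minPeakHeight,maxPeaks see slots.
#' @export
siteParams <- function(percentPeak = 0.30, minPeakHeight = 10L, maxPeaks = 3L) {
  new("SiteParams", percentPeak = as.numeric(percentPeak),
      minPeakHeight = as.integer(minPeakHeight),
      maxPeaks = as.integer(maxPeaks))
}

#' Database of known binary interactions
#'
#' Deduplicated unordered protein-identifier pairs together with the sequence
#' lookup needed to scan them. Self-interactions are permitted and flagged in
#' the \code{isSelf} column of \code{dbPairs()}.
#'
#' @slot pairs data.frame with columns \code{idA}, \code{idB} (canonical
#'   lexicographic order within each row) and \code{isSelf}.
#' @slot proteome named \code{AAStringSet}, one entry per protein id.
#'
#' @seealso \code{\link{readInteractionPairs}}, \code{\link{computeLandscape}}
#' @export
#' @exportClass InteractionDB
setClass("InteractionDB",
  representation(pairs = "data.frame", proteome = "AAStringSet"))

setValidity("InteractionDB", function(object) {
  msg <- character()
  p <- object@pairs
  if (!all(c("idA", "idB", "isSelf") %in% names(p)))
    return("'pairs' must have columns idA, idB, isSelf")
  ids <- names(object@proteome)
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate protein ids in proteome")
  unknown <- setdiff(c(p$idA, p$idB), ids)
  if (length(unknown))
    msg <- c(msg, paste0("pair ids missing from proteome: ",
                         paste(head(unknown, 5L), collapse = ", ")))
  if (nrow(p) && any(p$idA > p$idB))
    msg <- c(msg, "pairs must be stored in canonical (sorted) order")
  if (anyDuplicated(paste(p$idA, p$idB)))
    msg <- c(msg, "duplicate unordered pairs")
  if (length(msg)) msg else TRUE
})

#' Construct an InteractionDB from an id-pair table and a proteome
#'
#' @param pairs data.frame (or 2-column matrix) of protein id pairs; order
#'   within a row is ignored and duplicates collapse.
#' @param proteome named \code{AAStringSet} (see \code{\link{readProteome}}).
#' @return An \code{InteractionDB}.
#' @examples
#' prot <- Biostrings::AAStringSet(c(P1 = "MKLV", P2 = "QMKL"))
#' InteractionDB(data.frame(idA = "P1", idB = "P2"), prot)
#' @export
InteractionDB <- function(pairs, proteome) {
  pairs <- as.data.frame(pairs)
  a <- as.character(pairs[[1L]]); b <- as.character(pairs[[2L]])
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(paste(lo, hi))
  df <- data.frame(idA = lo[keep], idB = hi[keep],
                   isSelf = lo[keep] == hi[keep],
                   stringsAsFactors = FALSE)
  df <- df[order(df$idA, df$idB), , drop = FALSE]
  rownames(df) <- NULL
  new("InteractionDB", pairs = df, proteome = proteome)
}

#' Co-occurrence landscape over a query protein pair
#'
#' Integer matrix \code{H} over window-start index pairs: \code{H[i, j]} is
#' the number of oriented database pairs (X, Y) in which window i of query A
#' re-occurs in X and window j of query B re-occurs in Y. Each unordered
#' database pair contributes both orientations unless it is a self-pair.
#'
#' @slot idA,idB query protein identifiers.
#' @slot w window length used.
#' @slot H integer matrix, \code{(lenA - w + 1) x (lenB - w + 1)}; zero
#'   dimensions when a query is shorter than \code{w}.
#'
#' @seealso \code{\link{computeLandscape}}, \code{\link{predictSites}}
#' @export
#' @exportClass Landscape
setClass("Landscape",
  representation(idA = "character", idB = "character", w = "integer",
                 H = "matrix"))

setValidity("Landscape", function(object) {
  msg <- character()
  if (!is.integer(object@H)) msg <- c(msg, "'H' must be an integer matrix")
  else if (length(object@H) && any(object@H < 0L))
    msg <- c(msg, "landscape counts must be non-negative")
  if (object@w < 1L) msg <- c(msg, "'w' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Parameters of the synthetic fixture generator
#'
#' Describes a self-contained study: a random proteome in which one or more
#' motif pairs are planted in carrier proteins, an interaction database built
#' from carrier-carrier pairs plus background noise pairs, and one held-out
#' query pair per motif pair whose true site rectangle is recorded as ground
#' truth.
#'
#' @slot nProteins number of proteins in the proteome.
#' @slot lengthRange integer length-2, uniform protein length range.
#' @slot motifPairs list of motif-pair descriptions (see
#'   \code{\link{motifPair}}).
#' @slot backgroundRate probability that any non-carrier-cross unordered pair
#'   is added to the database as noise.
#' @slot seed mandatory integer seed; identical seeds give byte-identical
#'   outputs.
#'
#' @export SynthParams
#' @exportClass SynthParams
SynthParams <- setClass("SynthParams",
  representation(nProteins = "integer", lengthRange = "integer",
                 motifPairs = "list", backgroundRate = "numeric",
                 seed = "integer"))

setValidity("SynthParams", function(object) {
  msg <- character()
  if (object@nProteins < 2L) msg <- c(msg, "'nProteins' must be >= 2")
  if (length(object@lengthRange) != 2L ||
      object@lengthRange[1L] < 1L ||
      object@lengthRange[1L] > object@lengthRange[2L])
    msg <- c(msg, "'lengthRange' must be c(min, max) with 1 <= min <= max")
  if (!(object@backgroundRate >= 0 && object@backgroundRate <= 1))
    msg <- c(msg, "'backgroundRate' must be in [0, 1]")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "'seed' is mandatory")
  for (mp in object@motifPairs) {
    need <- c("motifLength", "nCarriersA", "nCarriersB", "density")
    if (!all(need %in% names(mp)))
      msg <- c(msg, "each motif pair needs motifLength, nCarriersA, nCarriersB, density")
    else {
      if (!(mp$density >= 0 && mp$density <= 1))
        msg <- c(msg, "motif-pair 'density' must be in [0, 1]")
      if (mp$nCarriersA < 1L || mp$nCarriersB < 1L)
        msg <- c(msg, "carrier counts must be >= 1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Describe one planted motif pair
#'
#' @param motifA,motifB explicit amino-acid strings, or \code{NULL} to draw
#'   random motifs of length \code{motifLength} from the generator's seed.
#' @param motifLength motif length in residues (default 12). Must be at least
#'   the window length used downstream; lengths strictly greater than the
#'   window give the planted peak an axial support block, which the
#'   spurious-spike filter requires (see the package vignette).
#' @param nCarriersA,nCarriersB number of proteins carrying each motif.
#' @param density fraction of carrierA x carrierB pairs entered into the
#'   interaction database.
#' @return A list suitable for the \code{motifPairs} slot of
#'   \code{\link{SynthParams}}.
#' @export
motifPair <- function(motifA = NULL, motifB = NULL, motifLength = 12L,
                      nCarriersA = 6L, nCarriersB = 6L, density = 1.0) {
  list(motifA = motifA, motifB = motifB,
       motifLength = as.integer(motifLength),
       nCarriersA = as.integer(nCarriersA),
       nCarriersB = as.integer(nCarriersB),
       density = as.numeric(density))
}

#' @describeIn SynthParams user constructor.
#' @param nProteins,lengthRange,motifPairs,backgroundRate,seed see slots.
#' @export
synthParams <- function(seed, nProteins = 24L, lengthRange = c(80L, 200L),
                        motifPairs = list(motifPair()),
                        backgroundRate = 0.02) {
  if (missing(seed)) stop("'seed' is mandatory for the synthetic generator")
  new("SynthParams", nProteins = as.integer(nProteins),
      lengthRange = as.integer(lengthRange), motifPairs = motifPairs,
      backgroundRate = as.numeric(backgroundRate), seed = as.integer(seed))
}
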