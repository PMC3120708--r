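#' Accessors for siteScape objects
#'
#' @param x an \code{InteractionDB} or \code{Landscape}.
#' @name accessors
NULL

#' @rdname accessors
#' @return \code{dbPairs}: data.frame of canonical unordered pairs
#'   (\code{idA}, \code{idB}, \code{isSelf}).
#' @export
setGeneric("dbPairs", function(x) standardGeneric("dbPairs"))

#' @rdname accessors
#' @return \code{proteome}: the named \code{AAStringSet} backing \code{x}.
#' @export
setGeneric("proteome", function(x) standardGeneric("proteome"))

#' @rdname accessors
#' @return \code{landscapeMatrix}: the integer count matrix.
#' @export
setGeneric("landscapeMatrix", function(x) standardGeneric("landscapeMatrix"))

#' @rdname accessors
#' @return \code{windowLength}: the window length \code{w}.
#' @export
setGeneric("windowLength", function(x) standardGeneric("windowLength"))

#' @rdname accessors
#' @return \code{queryIds}: character vector \code{c(idA, idB)}.
#' @export
setGeneric("queryIds", function(x) standardGeneric("queryIds"))

#' @rdname accessors
#' @export
setMethod("dbPairs", "InteractionDB", function(x) x@pairs)

#' @rdname accessors
#' @export
setMethod("proteome", "InteractionDB", function(x) x@proteome)

#' @rdname accessors
#' @export
setMethod("landscapeMatrix", "Landscape", function(x) x@H)

#' @rdname accessors
#' @export
setMethod("windowLength", "Landscape", function(x) x@w)

#' @rdname accessors
#' @export
setMethod("queryIds", "Landscape", function(x) c(x@idA, x@idB))

setMethod("show", "InteractionDB", function(object) {
  p <- object@pairs
  cat("InteractionDB with", nrow(p), "unordered pair(s) over",
      length(object@proteome), "protein(s)\n")
  if (any(p$isSelf)) cat("  including", sum(p$isSelf), "self-pair(s)\n")
})

setMethod("show", "Landscape", function(object) {
  d <- dim(object@H)
  cat(sprintf("Landscape %s x %s (w = %d): %d x %d window pairs\n",
              object@idA, object@idB, object@w, d[1L], d[2L]))
  if (length(object@H))
    cat("  max height:", max(object@H), "\n")
  else
    cat("  empty (a query protein is shorter than w)\n")
})

setMethod("show", "MatchParams", function(object) {
  cat(sprintf("MatchParams: w = %d, mode = %s", object@w, object@mode))
  if (identical(object@mode, "similarity"))
    cat(sprintf(" (%s, threshold %g)", object@substitutionMatrix,
                object@scoreThreshold))
  cat("\n")
})

setMethod("show", "SiteParams", function(object) {
  cat(sprintf(
    "SiteParams: percentPeak = %g, minPeakHeight = %d, maxPeaks = %d\n",
    object@percentPeak, object@minPeakHeight, object@maxPeaks))
})

setMethod("show", "SynthParams", function(object) {
  cat(sprintf(
    "SynthParams: %d proteins (length %d-%d), %d motif pair(s), background rate %g, seed %d\n",
    object@nProteins, object@lengthRange[1L], object@lengthRange[2L],
    length(object@motifPairs), object@backgroundRate, object@seed))
})
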