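#' Domain most overlapping a predicted site
#'
#' Among a protein's annotations, returns the one maximising the residue
#' overlap with the site interval. Ties go to the longer annotation, then to
#' the lexicographically smallest accession, so the choice is deterministic.
#'
#' @param site interval \code{c(start, end)}, 1-based inclusive.
#' @param annotations data.frame of that protein's annotations (columns
#'   \code{accession}, \code{name}, \code{start}, \code{end}; a
#'   \code{proteinId} column is permitted and ignored).
#' @return One-row data.frame, or \code{NULL} when no annotation overlaps.
#' @export
bestOverlapDomain <- function(site, annotations) {
  site <- .checkRange(site, "site")
  if (is.null(annotations) || !nrow(annotations)) return(NULL)
  ov <- .overlapLen(site[1L], site[2L], annotations$start, annotations$end)
  if (max(ov) == 0L) return(NULL)
  len <- annotations$end - annotations$start + 1L
  k <- order(-ov, -len, annotations$accession)[1L]
  annotations[k, , drop = FALSE]
}

# Split predictions into: both sides overlapping an annotation ("domain"),
# neither side ("clean"), or mixed. Used by both reporting paths.
.annotationSides <- function(predictions, annotations) {
  hasOverlap <- function(id, s, e) {
    ann <- annotations[annotations$proteinId == id, , drop = FALSE]
    nrow(ann) > 0L && any(.overlapLen(s, e, ann$start, ann$end) > 0L)
  }
  ovA <- mapply(hasOverlap, predictions$idA, predictions$startA,
                predictions$endA)
  ovB <- mapply(hasOverlap, predictions$idB, predictions$startB,
                predictions$endB)
  list(both = ovA & ovB, neither = !ovA & !ovB, mixed = xor(ovA, ovB))
}

#' Count co-occurring domain pairs across predicted sites
#'
#' For each qualifying predicted site pair, the best-overlap domain is taken
#' on each side; when both sides map to a domain the unordered domain-name
#' pair is counted. With \code{dmThreshold} set, only predictions whose
#' \code{dm} column is strictly below the threshold qualify (the
#' high-confidence filter; 0.20 is the conventional cut).
#'
#' @param predictions data.frame of predictions; must carry a \code{dm}
#'   column when \code{dmThreshold} is given.
#' @param annotations data.frame from \code{\link{readDomainAnnotations}}.
#' @param dmThreshold optional numeric; keep predictions with
#'   \code{dm < dmThreshold}.
#' @return data.frame \code{nameA}, \code{nameB} (canonical lexicographic
#'   order), \code{count}, sorted by descending count then names.
#' @export
domainPairCounts <- function(predictions, annotations, dmThreshold = NULL) {
  predictions <- as.data.frame(predictions)
  if (!is.null(dmThreshold)) {
    if (is.null(predictions$dm))
      stop("'dmThreshold' given but predictions carry no 'dm' column",
           call. = FALSE)
    predictions <- predictions[!is.na(predictions$dm) &
                                 predictions$dm < dmThreshold, , drop = FALSE]
  }
  empty <- data.frame(nameA = character(), nameB = character(),
                      count = integer(), stringsAsFactors = FALSE)
  if (!nrow(predictions)) return(empty)
  keys <- character()
  for (r in seq_len(nrow(predictions))) {
    p <- predictions[r, ]
    dA <- bestOverlapDomain(c(p$startA, p$endA),
      annotations[annotations$proteinId == p$idA, , drop = FALSE])
    dB <- bestOverlapDomain(c(p$startB, p$endB),
      annotations[annotations$proteinId == p$idB, , drop = FALSE])
    if (!is.null(dA) && !is.null(dB))
      keys <- c(keys, paste(min(dA$name, dB$name), max(dA$name, dB$name),
                            sep = "\t"))
  }
  if (!length(keys)) return(empty)
  tab <- table(keys)
  nm <- do.call(rbind, strsplit(names(tab), "\t", fixed = TRUE))
  out <- data.frame(nameA = nm[, 1L], nameB = nm[, 2L],
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out[order(-out$count, out$nameA, out$nameB), , drop = FALSE]
}

#' Report predicted sites free of any known annotation
#'
#' Site pairs where neither predicted range overlaps any annotation of its
#' protein are candidate novel re-occurring motifs. Each such pair yields one
#' row per protein side carrying the peak height and the literal site
#' subsequence; rows are sorted by descending peak height. Mixed pairs (one
#' side annotated) belong to neither this report nor the domain-pair counts
#' and are mentioned via \code{message}.
#'
#' @param predictions data.frame from \code{\link{predictSites}}.
#' @param annotations data.frame from \code{\link{readDomainAnnotations}}.
#' @param proteome named \code{AAStringSet} for subsequence extraction.
#' @return data.frame \code{proteinId}, \code{peakHeight}, \code{sequence}.
#' @export
unannotatedSites <- function(predictions, annotations, proteome) {
  predictions <- as.data.frame(predictions)
  empty <- data.frame(proteinId = character(), peakHeight = integer(),
                      sequence = character(), stringsAsFactors = FALSE)
  if (!nrow(predictions)) return(empty)
  sides <- .annotationSides(predictions, annotations)
  if (any(sides$mixed))
    message(sum(sides$mixed),
            " site pair(s) annotated on one side only were excluded")
  clean <- predictions[sides$neither, , drop = FALSE]
  if (!nrow(clean)) return(empty)
  seqs <- as.character(proteome)
  rows <- lapply(seq_len(nrow(clean)), function(r) {
    p <- clean[r, ]
    data.frame(
      proteinId = c(p$idA, p$idB),
      peakHeight = rep(as.integer(p$peakHeight), 2L),
      sequence = c(substr(seqs[[p$idA]], p$startA, p$endA),
                   substr(seqs[[p$idB]], p$startB, p$endB)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$peakHeight, out$proteinId), , drop = FALSE]
}
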