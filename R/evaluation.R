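#' Draw a random site pair (baseline predictor)
#'
#' On each protein independently the start is uniform over \{1..len\} and the
#' end uniform over the remaining length \{start..len\}. Draws come from R's
#' global RNG; seed the stream (e.g. \code{set.seed}) for reproducibility —
#' \code{\link{evaluatePredictions}} does this with its mandatory seed.
#'
#' @param lenA,lenB protein lengths in residues.
#' @return List with intervals \code{rangeA} and \code{rangeB}.
#' @examples
#' set.seed(1)
#' randomSitePair(100, 250)
#' @export
randomSitePair <- function(lenA, lenB) {
  draw <- function(len) {
    stopifnot(len >= 1L)
    s <- sample.int(len, 1L)
    e <- s + sample.int(len - s + 1L, 1L) - 1L
    c(s, e)
  }
  list(rangeA = draw(as.integer(lenA)), rangeB = draw(as.integer(lenB)))
}

# DM bins in percent: [0,10), ..., [40,50), [50, Inf).
.dmBin <- function(dm, edges) {
  cut(dm * 100, breaks = c(edges, Inf), right = FALSE,
      labels = c(sprintf("[%d,%d)", edges[-length(edges)], edges[-1L]),
                 sprintf(">=%d", edges[length(edges)])))
}

#' Enrichment of predicted over random DM values by bin
#'
#' Counts predicted and random DM values in 10-point percentage bins (a final
#' open bin collects DM >= 50\%) and reports their ratio per bin. Values > 1
#' in the low bins mean the predictor places more sites near the
#' lab-confirmed site than chance would.
#'
#' @param predDM,randDM numeric DM vectors (NAs dropped).
#' @param edges increasing bin edges in percent (default
#'   \code{c(0, 10, 20, 30, 40, 50)}).
#' @return data.frame with \code{bin}, \code{countPredicted},
#'   \code{countRandom}, \code{enrichment} (NA where the random count is 0).
#' @export
enrichmentTable <- function(predDM, randDM, edges = seq(0L, 50L, 10L)) {
  predDM <- predDM[!is.na(predDM)]
  randDM <- randDM[!is.na(randDM)]
  cp <- table(.dmBin(predDM, edges))
  cr <- table(.dmBin(randDM, edges))
  out <- data.frame(bin = names(cp),
                    countPredicted = as.integer(cp),
                    countRandom = as.integer(cr),
                    enrichment = ifelse(cr > 0,
                                        as.integer(cp) / as.integer(cr), NA),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Evaluate site predictions against lab-confirmed site pairs
#'
#' For every lab pair with at least one prediction, computes the DM of the
#' rank-1..k predictions and the best-of-k minima, draws \code{nRandom}
#' matched random site pairs as a baseline (the best-of-k analogue uses the
#' first 1..k random slots, the rank-1 comparison uses slot 1 only), bins
#' both into an enrichment table per k, and compares the rank-1 predicted and
#' random DM distributions with a two-sample Kolmogorov-Smirnov test. Pairs
#' whose landscape was gated (no predictions) are excluded from averages and
#' counted.
#'
#' @param predictions data.frame as from \code{\link{predictSites}} (rows for
#'   many pairs may be concatenated).
#' @param labSites data.frame from \code{\link{readLabSites}}.
#' @param proteome named \code{AAStringSet} covering every id in
#'   \code{labSites}.
#' @param k number of ranked predictions to consider (default 3).
#' @param nRandom random sites drawn per pair (default 3).
#' @param seed mandatory integer seed for the random baseline.
#' @return List of class \code{"siteScapeEval"}: \code{perPair} (per-pair
#'   best-of-k and random DMs plus the rank-1 per-protein breakdown),
#'   \code{perRank} (long DM table), \code{averages} (mean predicted and
#'   random best-of-k per k), \code{ks} (statistic, p.value, method),
#'   \code{enrichment} (one table per k), \code{nGated}, \code{nEvaluated}.
#' @export
evaluatePredictions <- function(predictions, labSites, proteome, k = 3L,
                                nRandom = 3L, seed) {
  if (missing(seed)) stop("'seed' is mandatory for the random baseline",
                          call. = FALSE)
  stopifnot(k >= 1L, nRandom >= 1L)
  set.seed(as.integer(seed))
  predictions <- as.data.frame(predictions)
  perPair <- list(); perRank <- list()
  nGated <- 0L
  for (r in seq_len(nrow(labSites))) {
    ls <- labSites[r, ]
    for (id in c(ls$idA, ls$idB))
      if (!id %in% names(proteome))
        stop(sprintf("no sequence for protein %s (pair %s-%s)",
                     id, ls$idA, ls$idB), call. = FALSE)
    lenA <- Biostrings::width(proteome[ls$idA])
    lenB <- Biostrings::width(proteome[ls$idB])
    direct <- predictions$idA == ls$idA & predictions$idB == ls$idB
    flipped <- predictions$idA == ls$idB & predictions$idB == ls$idA
    pp <- predictions[direct | flipped, , drop = FALSE]
    if (any(flipped)) {
      fl <- pp$idA == ls$idB
      pp[fl, c("startA", "endA", "startB", "endB")] <-
        pp[fl, c("startB", "endB", "startA", "endA")]
    }
    pp <- pp[order(pp$rank), , drop = FALSE]
    # matched random baseline is drawn for every pair so the stream does not
    # depend on which pairs were gated
    rnd <- replicate(nRandom, randomSitePair(lenA, lenB), simplify = FALSE)
    if (!nrow(pp)) {
      nGated <- nGated + 1L
      next
    }
    bd <- lapply(seq_len(min(nrow(pp), k)), function(q)
      distanceMeasure(c(ls$startA, ls$endA), c(ls$startB, ls$endB),
                      c(pp$startA[q], pp$endA[q]), c(pp$startB[q], pp$endB[q]),
                      lenA, lenB))
    dms <- vapply(bd, `[[`, numeric(1L), "dm")
    rdms <- vapply(rnd, function(rs)
      distanceMeasure(c(ls$startA, ls$endA), c(ls$startB, ls$endB),
                      rs$rangeA, rs$rangeB, lenA, lenB)$dm, numeric(1L))
    row <- data.frame(idA = ls$idA, idB = ls$idB, lenA = lenA, lenB = lenB,
                      nPredictions = nrow(pp),
                      ratioA1 = bd[[1L]]$ratioA, ratioB1 = bd[[1L]]$ratioB,
                      stringsAsFactors = FALSE)
    for (q in seq_len(k)) {
      row[[paste0("bestOf", q)]] <- bestOfK(dms, q)
      row[[paste0("randBest", q)]] <- bestOfK(rdms[seq_len(min(q, nRandom))], q)
    }
    rd <- rep(NA_real_, length(dms))
    nrd <- min(length(dms), nRandom)
    rd[seq_len(nrd)] <- rdms[seq_len(nrd)]
    perPair[[length(perPair) + 1L]] <- row
    perRank[[length(perRank) + 1L]] <-
      data.frame(idA = ls$idA, idB = ls$idB, rank = seq_along(dms), dm = dms,
                 randomDm = rd, stringsAsFactors = FALSE)
  }
  perPair <- if (length(perPair))
    do.call(rbind, c(perPair, list(make.row.names = FALSE))) else NULL
  perRank <- if (length(perRank))
    do.call(rbind, c(perRank, list(make.row.names = FALSE))) else NULL
  if (is.null(perPair)) {
    out <- list(perPair = NULL, perRank = NULL, averages = NULL, ks = NULL,
                enrichment = NULL, nGated = nGated, nEvaluated = 0L,
                k = as.integer(k), seed = as.integer(seed))
    class(out) <- c("siteScapeEval", "list")
    return(out)
  }
  averages <- data.frame(
    k = seq_len(k),
    meanPredicted = vapply(seq_len(k), function(q)
      mean(perPair[[paste0("bestOf", q)]]), numeric(1L)),
    meanRandom = vapply(seq_len(k), function(q)
      mean(perPair[[paste0("randBest", q)]]), numeric(1L)))
  ksfit <- suppressWarnings(
    stats::ks.test(perPair$bestOf1, perPair$randBest1))
  enrichment <- lapply(seq_len(k), function(q)
    enrichmentTable(perPair[[paste0("bestOf", q)]],
                    perPair[[paste0("randBest", q)]]))
  names(enrichment) <- paste0("k", seq_len(k))
  out <- list(perPair = perPair, perRank = perRank, averages = averages,
              ks = list(statistic = unname(ksfit$statistic),
                        p.value = ksfit$p.value, method = ksfit$method),
              enrichment = enrichment, nGated = nGated,
              nEvaluated = nrow(perPair), k = as.integer(k),
              seed = as.integer(seed))
  class(out) <- c("siteScapeEval", "list")
  out
}

#' @export
print.siteScapeEval <- function(x, ...) {
  cat("Site-prediction evaluation:", x$nEvaluated, "pair(s) scored,",
      x$nGated, "gated\n")
  if (!is.null(x$averages)) {
    cat("Average DM (predicted vs random) by best-of-k:\n")
    print(x$averages, row.names = FALSE)
    cat(sprintf("Rank-1 KS: D = %.3f, p = %.3g\n",
                x$ks$statistic, x$ks$p.value))
  }
  invisible(x)
}

#' Per-protein contributions to rank-1 prediction error
#'
#' Splits each evaluated pair's rank-1 DM into the two per-protein
#' contributions and audits whether proteins recurring across many validation
#' pairs dominate the error. A protein's individual score is its length-scaled
#' overshoot mapped through the DM combiner with the partner term zeroed,
#' i.e. \code{ratio / sqrt(2)}, so it lives on the DM scale and the vector
#' sum of the two scores recovers the pair DM.
#'
#' @param report a \code{"siteScapeEval"} list from
#'   \code{\link{evaluatePredictions}}.
#' @return data.frame with \code{proteinId}, \code{frequency} (occurrences
#'   across pairs) and \code{meanContribution}, sorted by descending
#'   frequency then id.
#' @export
perProteinContributions <- function(report) {
  pp <- report$perPair
  if (is.null(pp) || !nrow(pp))
    return(data.frame(proteinId = character(), frequency = integer(),
                      meanContribution = numeric(), stringsAsFactors = FALSE))
  long <- data.frame(proteinId = c(pp$idA, pp$idB),
                     contribution = c(pp$ratioA1, pp$ratioB1) / sqrt(2),
                     stringsAsFactors = FALSE)
  agg <- stats::aggregate(contribution ~ proteinId, long,
                          function(v) c(n = length(v), mean = mean(v)))
  out <- data.frame(proteinId = agg$proteinId,
                    frequency = as.integer(agg$contribution[, "n"]),
                    meanContribution = unname(agg$contribution[, "mean"]),
                    stringsAsFactors = FALSE)
  out[order(-out$frequency, out$proteinId), , drop = FALSE]
}
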