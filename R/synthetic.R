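#' Generate a synthetic study with planted binding motifs
#'
#' Builds a self-contained fixture with known ground truth: a random
#' proteome (uniform residues over the 20 standard letters), one or more
#' motif pairs overwritten into disjoint groups of carrier proteins at
#' recorded positions, an interaction database containing carrierA x carrierB
#' pairs at the requested density plus background noise pairs, and one
#' held-out query pair per motif pair (its first A- and B-carrier) that is
#' removed from the database and listed in the lab-site table with its true
#' insertion ranges. Carrier motifs are also emitted as synthetic domain
#' annotations. All draws come from the mandatory seed; identical parameters
#' give byte-identical files.
#'
#' @param params a \code{\link{SynthParams}}.
#' @param dir optional directory; when given, writes \code{proteome.fasta},
#'   \code{pairs.tsv}, \code{lab_sites.tsv}, \code{annotations.tsv} and
#'   \code{truth.json} there.
#' @return List of class \code{"siteScapeDataset"}: \code{proteome}
#'   (AAStringSet), \code{db} (\code{\link{InteractionDB}}),
#'   \code{labSites}, \code{annotations} (data.frames), \code{truth} (one
#'   entry per held-out query pair: ids, true ranges, carrier lists, the
#'   expected minimum peak height — the number of carrier cross pairs kept in
#'   the database — and the true landscape cell), and \code{params}.
#' @examples
#' ds <- generateDataset(synthParams(seed = 1, nProteins = 12,
#'   motifPairs = list(motifPair(motifLength = 8, nCarriersA = 3,
#'                               nCarriersB = 3))))
#' ds$truth[[1]]$rangeA
#' @export
generateDataset <- function(params, dir = NULL) {
  stopifnot(is(params, "SynthParams"))
  set.seed(params@seed)
  aa20 <- .AA_OK[.AA_OK != "X"]
  n <- params@nProteins
  nCarTotal <- sum(vapply(params@motifPairs,
                          function(mp) mp$nCarriersA + mp$nCarriersB,
                          numeric(1L)))
  if (nCarTotal > n)
    stop("carrier counts exceed nProteins", call. = FALSE)
  lens <- sample(seq(params@lengthRange[1L], params@lengthRange[2L]), n,
                 replace = TRUE)
  for (mp in params@motifPairs)
    if (mp$motifLength > params@lengthRange[1L])
      stop("motif longer than the shortest allowed protein", call. = FALSE)
  ids <- sprintf("SYN%03d", seq_len(n))
  seqs <- vapply(lens, function(L)
    paste(sample(aa20, L, replace = TRUE), collapse = ""), character(1L))
  names(seqs) <- ids

  nextFree <- 1L
  crossPairs <- list(); labRows <- list(); annRows <- list(); truth <- list()
  heldOut <- character()
  for (m in seq_along(params@motifPairs)) {
    mp <- params@motifPairs[[m]]
    mlen <- mp$motifLength
    motifA <- mp$motifA
    if (is.null(motifA))
      motifA <- paste(sample(aa20, mlen, replace = TRUE), collapse = "")
    motifB <- mp$motifB
    if (is.null(motifB))
      motifB <- paste(sample(aa20, mlen, replace = TRUE), collapse = "")
    if (nchar(motifA) != mlen || nchar(motifB) != mlen)
      stop("explicit motifs must have length 'motifLength'", call. = FALSE)
    carA <- ids[nextFree:(nextFree + mp$nCarriersA - 1L)]
    nextFree <- nextFree + mp$nCarriersA
    carB <- ids[nextFree:(nextFree + mp$nCarriersB - 1L)]
    nextFree <- nextFree + mp$nCarriersB
    # overwrite (not insert) so protein lengths and coordinates stay fixed
    plant <- function(id, motif) {
      L <- nchar(seqs[[id]])
      pos <- sample.int(L - nchar(motif) + 1L, 1L)
      substr(seqs[[id]], pos, pos + nchar(motif) - 1L) <<- motif
      pos
    }
    posA <- vapply(carA, plant, integer(1L), motif = motifA)
    posB <- vapply(carB, plant, integer(1L), motif = motifB)
    qA <- carA[1L]; qB <- carB[1L]
    heldOut <- c(heldOut, paste(min(qA, qB), max(qA, qB)))
    cross <- expand.grid(idA = carA, idB = carB, stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(cross)) <= mp$density
    keep[cross$idA == qA & cross$idB == qB] <- FALSE
    cross <- cross[keep, , drop = FALSE]
    crossPairs[[m]] <- cross
    labRows[[m]] <- data.frame(
      idA = qA, idB = qB,
      startA = posA[[qA]], endA = posA[[qA]] + mlen - 1L,
      startB = posB[[qB]], endB = posB[[qB]] + mlen - 1L,
      stringsAsFactors = FALSE)
    annRows[[m]] <- data.frame(
      proteinId = c(carA, carB),
      accession = rep(sprintf(c("SYNMOT%dA", "SYNMOT%dB"), m),
                      c(length(carA), length(carB))),
      name = rep(sprintf(c("plantedMotif%dA", "plantedMotif%dB"), m),
                 c(length(carA), length(carB))),
      start = c(posA, posB),
      end = c(posA, posB) + mlen - 1L,
      stringsAsFactors = FALSE)
    truth[[paste(qA, qB, sep = "|")]] <- list(
      idA = qA, idB = qB,
      rangeA = c(posA[[qA]], posA[[qA]] + mlen - 1L),
      rangeB = c(posB[[qB]], posB[[qB]] + mlen - 1L),
      motifA = motifA, motifB = motifB,
      carriersA = carA, carriersB = carB,
      expectedMinPeakHeight = nrow(cross),
      cell = c(i = posA[[qA]], j = posB[[qB]]))
  }
  crossPairs <- do.call(rbind, crossPairs)
  crossKey <- paste(pmin(crossPairs$idA, crossPairs$idB),
                    pmax(crossPairs$idA, crossPairs$idB))

  # background noise pairs over everything that is not a carrier cross pair
  allPairs <- t(utils::combn(ids, 2L))
  allKey <- paste(allPairs[, 1L], allPairs[, 2L])
  candidate <- !(allKey %in% crossKey) & !(allKey %in% heldOut)
  bg <- allPairs[candidate & stats::runif(length(allKey)) <= params@backgroundRate,
                 , drop = FALSE]
  pairs <- rbind(crossPairs,
                 data.frame(idA = bg[, 1L], idB = bg[, 2L],
                            stringsAsFactors = FALSE))

  proteome <- Biostrings::AAStringSet(seqs)
  ds <- list(proteome = proteome,
             db = InteractionDB(pairs, proteome),
             labSites = do.call(rbind, labRows),
             annotations = do.call(rbind, annRows),
             truth = truth,
             params = params)
  class(ds) <- c("siteScapeDataset", "list")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    Biostrings::writeXStringSet(proteome, file.path(dir, "proteome.fasta"))
    utils::write.table(dbPairs(ds$db)[, c("idA", "idB")],
                       file.path(dir, "pairs.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(ds$labSites, file.path(dir, "lab_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(ds$annotations, file.path(dir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    ds$dir <- dir
  }
  ds
}

#' @export
print.siteScapeDataset <- function(x, ...) {
  cat("Synthetic interaction study:", length(x$proteome), "proteins,",
      nrow(dbPairs(x$db)), "database pairs,",
      length(x$truth), "held-out query pair(s)\n")
  invisible(x)
}

#' True landscape cell of a planted query pair
#'
#' @param dataset a \code{"siteScapeDataset"} from
#'   \code{\link{generateDataset}} (or its \code{truth} element).
#' @param idA,idB query pair ids (order-insensitive).
#' @return Named integer vector \code{c(i, j)}: window start indices of the
#'   planted motifs on the two query proteins, in the orientation asked for.
#' @export
expectedPeakCell <- function(dataset, idA, idB) {
  truth <- if (inherits(dataset, "siteScapeDataset")) dataset$truth
           else dataset
  direct <- truth[[paste(idA, idB, sep = "|")]]
  if (!is.null(direct)) return(direct$cell)
  flipped <- truth[[paste(idB, idA, sep = "|")]]
  if (!is.null(flipped))
    return(c(i = unname(flipped$cell["j"]), j = unname(flipped$cell["i"])))
  stop(sprintf("no planted query pair %s-%s in ground truth", idA, idB),
       call. = FALSE)
}
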