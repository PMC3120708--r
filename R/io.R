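#' Read a proteome from a FASTA file
#'
#' Sequences are uppercased and validated against the 20-letter amino-acid
#' alphabet plus 'X'. The protein id is the first whitespace-delimited token
#' of the FASTA header and must be unique.
#'
#' @param path FASTA file.
#' @return Named \code{AAStringSet}, one entry per protein.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1", "mklv", ">P2", "QMKL"), fa)
#' readProteome(fa)
#' @export
readProteome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  aa <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      # the Biostrings reader silently drops codes outside its alphabet;
      # surface that as the validation failure it is
      if (grepl("invalid one-letter sequence code", conditionMessage(w)))
        stop("illegal residue character(s) in ", path, call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (!length(aa)) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(aa))
  if (any(!nzchar(ids)))
    stop("malformed FASTA header: empty id in ", path, call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate protein id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  seqs <- toupper(as.character(aa))
  if (any(!nzchar(seqs)))
    stop("empty sequence for record ", ids[!nzchar(seqs)][1L], call. = FALSE)
  badChars <- vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    paste(unique(ch[!ch %in% .AA_OK]), collapse = "")
  }, character(1L))
  if (any(nzchar(badChars))) {
    i <- which(nzchar(badChars))[1L]
    stop(sprintf("illegal residue character(s) '%s' in protein %s",
                 badChars[i], ids[i]), call. = FALSE)
  }
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Read a known-interaction pair list
#'
#' Two-column TSV of protein ids. Pairs are deduplicated as unordered pairs;
#' ids absent from the proteome are skipped with a warning giving the count.
#'
#' @param path 2-column TSV ('#' comments allowed).
#' @param proteome named \code{AAStringSet} from \code{\link{readProteome}}.
#' @return An \code{\link{InteractionDB}}.
#' @export
readInteractionPairs <- function(path, proteome) {
  tsv <- .readTsv(path, 2L, "pair list")
  a <- vapply(tsv$fields, `[`, character(1L), 1L)
  b <- vapply(tsv$fields, `[`, character(1L), 2L)
  known <- a %in% names(proteome) & b %in% names(proteome)
  if (any(!known))
    warning(sum(!known), " pair(s) with ids missing from the proteome ",
            "were skipped", call. = FALSE)
  if (!any(known))
    return(InteractionDB(data.frame(idA = character(), idB = character()),
                         proteome))
  InteractionDB(data.frame(idA = a[known], idB = b[known],
                           stringsAsFactors = FALSE), proteome)
}

#' Read lab-confirmed binding-site pairs
#'
#' Six-column TSV: idA, idB, startA, endA, startB, endB, with 1-based
#' inclusive residue coordinates. Degenerate records (non-positive
#' coordinates or start > end) are rejected.
#'
#' @param path 6-column TSV.
#' @return data.frame with columns \code{idA}, \code{idB}, \code{startA},
#'   \code{endA}, \code{startB}, \code{endB}.
#' @export
readLabSites <- function(path) {
  tsv <- .readTsv(path, 6L, "lab-site table")
  f <- tsv$fields
  df <- data.frame(
    idA = vapply(f, `[`, character(1L), 1L),
    idB = vapply(f, `[`, character(1L), 2L),
    startA = .asInt(vapply(f, `[`, character(1L), 3L), "lab-site table", tsv$lineno),
    endA   = .asInt(vapply(f, `[`, character(1L), 4L), "lab-site table", tsv$lineno),
    startB = .asInt(vapply(f, `[`, character(1L), 5L), "lab-site table", tsv$lineno),
    endB   = .asInt(vapply(f, `[`, character(1L), 6L), "lab-site table", tsv$lineno),
    stringsAsFactors = FALSE)
  bad <- df$startA < 1L | df$startB < 1L | df$startA > df$endA |
    df$startB > df$endB
  if (any(bad))
    stop(sprintf(
      "degenerate site record at line %d (%s-%s): need 1 <= start <= end",
      tsv$lineno[bad][1L], df$idA[bad][1L], df$idB[bad][1L]), call. = FALSE)
  df
}

#' Read a domain-annotation table
#'
#' Five-column TSV: protein id, accession, name, start, end (1-based
#' inclusive). Multiple, possibly overlapping annotations per protein are
#' allowed.
#'
#' @param path 5-column TSV.
#' @return data.frame with columns \code{proteinId}, \code{accession},
#'   \code{name}, \code{start}, \code{end}.
#' @export
readDomainAnnotations <- function(path) {
  tsv <- .readTsv(path, 5L, "annotation table")
  f <- tsv$fields
  if (!length(f))
    return(data.frame(proteinId = character(), accession = character(),
                      name = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  df <- data.frame(
    proteinId = vapply(f, `[`, character(1L), 1L),
    accession = vapply(f, `[`, character(1L), 2L),
    name = vapply(f, `[`, character(1L), 3L),
    start = .asInt(vapply(f, `[`, character(1L), 4L), "annotation table", tsv$lineno),
    end   = .asInt(vapply(f, `[`, character(1L), 5L), "annotation table", tsv$lineno),
    stringsAsFactors = FALSE)
  bad <- df$start < 1L | df$start > df$end
  if (any(bad))
    stop(sprintf("invalid annotation interval at line %d (%s)",
                 tsv$lineno[bad][1L], df$proteinId[bad][1L]), call. = FALSE)
  df
}

#' Write / read site predictions
#'
#' Predictions are stored as TSV with header columns idA, idB, rank,
#' peak_height, startA, endA, startB, endB (1-based inclusive), rows ordered
#' by pair and then rank. \code{readPredictions} restores the same in-memory
#' values, so write-then-read round-trips exactly.
#'
#' @param predictions data.frame as returned by \code{\link{predictSites}}.
#' @param path output (or input) TSV path.
#' @return \code{writePredictions}: invisibly, the path.
#' @export
writePredictions <- function(predictions, path) {
  cols <- c("idA", "idB", "rank", "peakHeight",
            "startA", "endA", "startB", "endB")
  df <- as.data.frame(predictions)[, cols, drop = FALSE]
  df <- df[order(df$idA, df$idB, df$rank), , drop = FALSE]
  names(df)[names(df) == "peakHeight"] <- "peak_height"
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePredictions
#' @return \code{readPredictions}: data.frame with the columns above
#'   (\code{peakHeight} spelled as in \code{\link{predictSites}} output).
#' @export
readPredictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("idA", "idB", "rank", "peak_height",
            "startA", "endA", "startB", "endB")
  if (!all(need %in% names(df)))
    stop("prediction table missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  names(df)[names(df) == "peak_height"] <- "peakHeight"
  df[order(df$idA, df$idB, df$rank), , drop = FALSE]
}

#' Dump a landscape matrix as TSV
#'
#' Debug/inspection helper: writes the count matrix with window start indices
#' as header row and first column.
#'
#' @param landscape a \code{\link{Landscape}}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeLandscape <- function(landscape, path) {
  H <- landscapeMatrix(landscape)
  m <- cbind(i = seq_len(nrow(H)), H)
  colnames(m) <- c("i", seq_len(ncol(H)))
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
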