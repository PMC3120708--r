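#' Enumerate sliding windows of a protein
#'
#' @param protein protein sequence (id, named character scalar, or
#'   \code{AAStringSet} of length 1).
#' @param w window length.
#' @return data.frame with columns \code{start} (1-based window start) and
#'   \code{window}; zero rows when the protein is shorter than \code{w}.
#' @examples
#' proteinWindows(c(P = "MKLV"), 2)
#' @export
proteinWindows <- function(protein, w) {
  p <- .asProtein(protein)
  w <- as.integer(w)
  n <- nchar(p) - w + 1L
  if (n < 1L)
    return(data.frame(start = integer(), window = character(),
                      stringsAsFactors = FALSE))
  starts <- seq_len(n)
  data.frame(start = starts,
             window = substring(p, starts, starts + w - 1L),
             stringsAsFactors = FALSE)
}

# Load a substitution matrix shipped with Biostrings by name.
.subMatrix <- function(name) {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(err) FALSE)
  if (!ok || !exists(name, envir = e))
    stop("unknown substitution matrix: ", name, call. = FALSE)
  get(name, envir = e)
}

# Summed substitution scores of `win` against every window of `target`.
# 'X' never matches any position in similarity mode: its score is -Inf.
.windowScores <- function(win, target, mat) {
  w <- nchar(win)
  n <- nchar(target) - w + 1L
  if (n < 1L) return(numeric())
  qc <- strsplit(win, "", fixed = TRUE)[[1L]]
  tc <- strsplit(target, "", fixed = TRUE)[[1L]]
  lut <- matrix(-Inf, nrow = length(.AA_OK), ncol = length(.AA_OK),
                dimnames = list(.AA_OK, .AA_OK))
  common <- intersect(.AA_OK, rownames(mat))
  lut[common, common] <- mat[common, common]
  lut["X", ] <- -Inf
  lut[, "X"] <- -Inf
  vapply(seq_len(n), function(j) {
    sum(lut[cbind(qc, tc[j:(j + w - 1L)])])
  }, numeric(1L))
}

#' Does a query window re-occur in a database protein?
#'
#' Exact mode: substring occurrence ('X' matches only itself). Similarity
#' mode: some window of the target scores at least
#' \code{params@scoreThreshold} under the substitution matrix; 'X' never
#' matches any position.
#'
#' @param window character scalar of length \code{params@w}.
#' @param target target protein (id form accepted as in
#'   \code{\link{proteinWindows}}).
#' @param params a \code{\link{MatchParams}}.
#' @return Single logical.
#' @examples
#' windowMatch("KL", c(X = "QMKL"), matchParams(w = 2))
#' @export
windowMatch <- function(window, target, params = matchParams()) {
  stopifnot(nchar(window) == params@w)
  tgt <- .asProtein(target, arg = "target")
  if (identical(params@mode, "exact"))
    return(grepl(toupper(window), tgt, fixed = TRUE))
  sc <- .windowScores(toupper(window), tgt, .subMatrix(params@substitutionMatrix))
  length(sc) > 0L && max(sc) >= params@scoreThreshold
}

#' Match profile of a query protein against one database protein
#'
#' The set of query window start indices whose window re-occurs in the
#' database protein. Pure in its inputs, hence cacheable per
#' (query, database protein); \code{\link{computeLandscape}} caches it
#' internally with bit-identical results.
#'
#' @inheritParams windowMatch
#' @param query query protein.
#' @return Sorted integer vector of window starts (possibly empty).
#' @examples
#' matchProfile(c(A = "MKLV"), c(X = "QMKL"), matchParams(w = 2))
#' @export
matchProfile <- function(query, target, params = matchParams()) {
  qw <- proteinWindows(query, params@w)
  if (!nrow(qw)) return(integer())
  tgt <- .asProtein(target, arg = "target")
  if (identical(params@mode, "exact")) {
    tw <- proteinWindows(stats::setNames(tgt, "t"), params@w)
    return(qw$start[qw$window %in% tw$window])
  }
  mat <- .subMatrix(params@substitutionMatrix)
  hit <- vapply(qw$window, function(win) {
    sc <- .windowScores(win, tgt, mat)
    length(sc) > 0L && max(sc) >= params@scoreThreshold
  }, logical(1L))
  qw$start[hit]
}

#' Compute the co-occurrence landscape for a query protein pair
#'
#' For every oriented database pair (X, Y) — each unordered pair contributes
#' both orientations unless it is a self-pair — cell (i, j) is incremented
#' when window i of query A re-occurs in X and window j of query B re-occurs
#' in Y. The increment is one per oriented pair regardless of how many
#' positions match, so every entry is bounded by twice the number of database
#' pairs and the landscape does not depend on the order of ids in the pair
#' file.
#'
#' @param A,B query proteins: ids resolved in \code{proteome(db)}, named
#'   character scalars, or \code{AAStringSet}s of length 1.
#' @param db an \code{\link{InteractionDB}}.
#' @param params a \code{\link{MatchParams}}.
#' @param excludeQueryPair drop the unordered pair \{idA, idB\} from the
#'   database before counting (default \code{TRUE}; prevents a trivial
#'   self-hit when a validation pair is also a training pair).
#' @return A \code{\link{Landscape}}; its matrix has zero extent on a side
#'   whose query protein is shorter than \code{w}.
#' @examples
#' prot <- Biostrings::AAStringSet(c(Q1 = "MKLV", Q2 = "AAGW",
#'                                   X = "QMKL", Y = "GAAG"))
#' db <- InteractionDB(data.frame(idA = "X", idB = "Y"), prot)
#' landscapeMatrix(computeLandscape("Q1", "Q2", db, matchParams(w = 2)))
#' @export
computeLandscape <- function(A, B, db, params = matchParams(),
                             excludeQueryPair = TRUE) {
  stopifnot(is(db, "InteractionDB"))
  pa <- .asProtein(A, proteome(db), "A")
  pb <- .asProtein(B, proteome(db), "B")
  idA <- if (is.null(names(pa))) NA_character_ else names(pa)
  idB <- if (is.null(names(pb))) NA_character_ else names(pb)
  w <- params@w
  nA <- nchar(pa) - w + 1L
  nB <- nchar(pb) - w + 1L
  if (nA < 1L || nB < 1L) {
    return(new("Landscape", idA = as.character(idA), idB = as.character(idB),
               w = w, H = matrix(integer(), max(nA, 0L), max(nB, 0L))))
  }
  pairs <- dbPairs(db)
  if (excludeQueryPair && !is.na(idA) && !is.na(idB)) {
    lo <- min(idA, idB); hi <- max(idA, idB)
    pairs <- pairs[!(pairs$idA == lo & pairs$idB == hi), , drop = FALSE]
  }
  H <- matrix(0L, nA, nB)
  if (nrow(pairs)) {
    seqs <- as.character(proteome(db))
    involved <- unique(c(pairs$idA, pairs$idB))
    profA <- lapply(seqs[involved], function(s)
      matchProfile(pa, stats::setNames(s, "t"), params))
    profB <- lapply(seqs[involved], function(s)
      matchProfile(pb, stats::setNames(s, "t"), params))
    names(profA) <- names(profB) <- involved
    addOrient <- function(x, y) {
      ia <- profA[[x]]; jb <- profB[[y]]
      if (length(ia) && length(jb))
        H[ia, jb] <<- H[ia, jb] + 1L
    }
    for (r in seq_len(nrow(pairs))) {
      x <- pairs$idA[r]; y <- pairs$idB[r]
      addOrient(x, y)
      if (x != y) addOrient(y, x)
    }
  }
  new("Landscape", idA = as.character(idA), idB = as.character(idB),
      w = w, H = H)
}
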