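# Internal helpers shared across modules.

# Read a tab-separated file with '#'-prefixed comment lines, enforcing a
# fixed column count. Returns a list of character vectors plus original line
# numbers (for error messages).
.readTsv <- function(path, ncol, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != ncol)
  if (length(bad))
    stop(sprintf("%s: line %d has %d column(s), expected %d", what,
                 idx[bad[1L]], lengths(fields)[bad[1L]], ncol),
         call. = FALSE)
  list(fields = fields, lineno = idx)
}

# Strict integer coercion with file context.
.asInt <- function(x, what, lineno) {
  ok <- grepl("^[+-]?[0-9]+$", x)
  if (!all(ok))
    stop(sprintf("%s: non-integer coordinate '%s' at line %d", what,
                 x[!ok][1L], lineno[!ok][1L]), call. = FALSE)
  as.integer(x)
}

# Overlap length of two 1-based inclusive intervals (vectorised).
.overlapLen <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

# Validate a 1-based inclusive interval given as c(start, end).
.checkRange <- function(r, what = "interval") {
  if (length(r) != 2L || anyNA(r))
    stop(what, " must be c(start, end)", call. = FALSE)
  if (r[1L] < 1L || r[1L] > r[2L])
    stop(sprintf("invalid %s [%s, %s]: need 1 <= start <= end", what,
                 r[1L], r[2L]), call. = FALSE)
  invisible(as.integer(r))
}

# Coerce a query protein argument to a single named uppercase sequence.
# Accepts a protein id (resolved in `proteome`), a named character scalar, or
# an AAStringSet/AAString of length one.
.asProtein <- function(x, proteome = NULL, arg = "protein") {
  if (is(x, "AAStringSet")) {
    if (length(x) != 1L) stop(arg, " must be a single protein", call. = FALSE)
    return(stats::setNames(toupper(as.character(x[[1L]])), names(x)))
  }
  if (is(x, "AAString")) return(stats::setNames(toupper(as.character(x)), NA))
  if (is.character(x) && length(x) == 1L) {
    if (!is.null(proteome) && x %in% names(proteome))
      return(stats::setNames(toupper(as.character(proteome[[x]])), x))
    if (is.null(names(x)))
      stop(arg, ": pass a named sequence or an id present in the proteome",
           call. = FALSE)
    return(stats::setNames(toupper(unname(x)), names(x)))
  }
  stop(arg, " must be an id, a named sequence, or an AAStringSet of length 1",
       call. = FALSE)
}

# Empty prediction table with the documented column set.
.emptyPredictions <- function() {
  data.frame(idA = character(), idB = character(), rank = integer(),
             peakHeight = integer(), startA = integer(), endA = integer(),
             startB = integer(), endB = integer(),
             i0 = integer(), i1 = integer(), j0 = integer(), j1 = integer(),
             stringsAsFactors = FALSE)
}
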