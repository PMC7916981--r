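#' @import methods
#' @importFrom Biostrings RNAStringSet writeXStringSet readBStringSet subseq width
#' @importClassesFrom Biostrings RNAStringSet
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Mature miRNA sequence set
#'
#' An `RNAStringSet` subclass holding named mature miRNA sequences
#' (5' to 3', alphabet ACGU). Every sequence must be at least 8 nt so that
#' the seed region -- positions 2-7 of the mature sequence, 1-based
#' inclusive, the primary determinant of target recognition -- exists and a
#' position-8 pairing can be evaluated for 7mer/8mer site classes.
#'
#' @slot NULL inherits all slots from `RNAStringSet`.
#' @seealso [seedRegion()], [readMirnaTable()]
#' @export
setClass("MiRNASet", contains = "RNAStringSet")

setValidity("MiRNASet", function(object) {
  msg <- character()
  if (length(object)) {
    if (is.null(names(object)) || any(is.na(names(object))) ||
        any(names(object) == ""))
      msg <- c(msg, "all miRNAs must be named")
    if (anyDuplicated(names(object)))
      msg <- c(msg, "miRNA names must be unique")
    if (any(width(object) < 8))
      msg <- c(msg, sprintf(
        "mature sequences must be >= 8 nt (seed region 2-7 plus position 8); offending: %s",
        paste(names(object)[width(object) < 8], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MiRNASet
#'
#' @param x A named character vector or `RNAStringSet` of mature miRNA
#'   sequences, 5' to 3'. DNA input (T) is normalized to RNA (U); mixed
#'   case is folded to upper case.
#' @return A [MiRNASet-class] object.
#' @examples
#' mirs <- MiRNASet(c("hsa-miR-425-5p" = "AAUGACACGAUCACUCCCGUUGA"))
#' seedRegion(mirs)
#' @export
MiRNASet <- function(x) {
  if (is(x, "XStringSet")) {
    nm <- names(x)
    x <- as.character(x)
    names(x) <- nm
  }
  seqs <- vapply(seq_along(x), function(i) {
    normalizeRna(x[[i]], context = names(x)[i])
  }, character(1))
  names(seqs) <- names(x)
  new("MiRNASet", RNAStringSet(seqs))
}

#' Seed region of mature miRNAs
#'
#' Extracts the seed -- nucleotides 2-7 of the mature sequence (1-based,
#' inclusive; length exactly 6).
#'
#' @param x A [MiRNASet-class].
#' @return An `RNAStringSet` of 6-mers, one per miRNA, same names.
#' @export
setGeneric("seedRegion", function(x) standardGeneric("seedRegion"))

#' @rdname seedRegion
setMethod("seedRegion", "MiRNASet", function(x) {
  subseq(RNAStringSet(x), start = 2L, end = 7L)
})

setMethod("show", "MiRNASet", function(object) {
  cat(sprintf("MiRNASet with %d mature sequence(s)\n", length(object)))
  if (length(object)) {
    df <- data.frame(
      name = names(object),
      length = width(object),
      seed = as.character(seedRegion(object)),
      stringsAsFactors = FALSE
    )
    print(utils::head(df, 10), row.names = FALSE)
    if (length(object) > 10) cat("...\n")
  }
  invisible(object)
})

# Normalize a nucleotide string to the RNA alphabet ACGU.
# T -> U, case folded; any other symbol is an error naming the character.
normalizeRna <- function(s, context = NULL) {
  s <- toupper(as.character(s))
  s <- gsub("T", "U", s, fixed = TRUE)
  bad <- regmatches(s, regexpr("[^ACGU]", s))
  if (length(bad) && nzchar(bad)) {
    where <- if (!is.null(context) && !is.na(context)) paste0(" in '", context, "'") else ""
    stop(sprintf("non-nucleotide symbol '%s'%s: sequences must contain only A, C, G, U/T",
                 bad, where), call. = FALSE)
  }
  s
}

#' Read 3'-UTR sequences from FASTA
#'
#' Reads a FASTA file of candidate target 3'-UTR sequences and normalizes
#' them to the RNA alphabet (T is silently mapped to U since UTRs are
#' commonly distributed as DNA; any symbol outside ACGT/U is an error).
#' The header token before the first whitespace becomes the gene symbol.
#' Only the plus strand as supplied is used downstream: 3'-UTR targeting
#' is strand-defined.
#'
#' @param path Path to a FASTA file.
#' @return A named `RNAStringSet`, one element per FASTA entry; the full
#'   header line is kept in `metadata()$source_id`.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">G1 demo", "ACGT"), f)
#' readUtrFasta(f)
#' @export
readUtrFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  checkFastaShape(path)
  raw <- readBStringSet(path)
  headers <- names(raw)
  genes <- sub("\\s.*$", "", headers)
  seqs <- vapply(seq_along(raw), function(i) {
    normalizeRna(as.character(raw[[i]]), context = genes[i])
  }, character(1))
  names(seqs) <- genes
  out <- RNAStringSet(seqs)
  metadata(out)$source_id <- headers
  out
}

# Line-level sanity check so parse errors can name the offending line.
checkFastaShape <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (!length(nonempty))
    stop("malformed FASTA at line 1: file is empty", call. = FALSE)
  if (!startsWith(trimws(lines[nonempty[1]]), ">"))
    stop(sprintf("malformed FASTA at line %d: expected '>' header before sequence",
                 nonempty[1]), call. = FALSE)
  isHeader <- startsWith(trimws(lines), ">")
  headerIdx <- which(isHeader)
  for (h in headerIdx) {
    nxt <- lines[-seq_len(h)]
    nxtNonempty <- which(nzchar(trimws(nxt)))
    if (!length(nxtNonempty) || startsWith(trimws(nxt[nxtNonempty[1]]), ">"))
      stop(sprintf("malformed FASTA at line %d: header with empty sequence", h),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Write UTR sequences to FASTA
#'
#' @param utrs A named `RNAStringSet` (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeUtrFasta <- function(utrs, path) {
  if (!is(utrs, "XStringSet")) utrs <- RNAStringSet(utrs)
  writeXStringSet(utrs, filepath = path)
  invisible(path)
}

#' Read a mature miRNA table
#'
#' Reads a TSV with columns `name` and `sequence` (mature miRNA sequences,
#' 5' to 3') and derives the seed region (positions 2-7). Records are
#' returned in file order.
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A [MiRNASet-class].
#' @export
readMirnaTable <- function(path) {
  if (!file.exists(path)) stop("miRNA table not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("name", "sequence")
  if (!all(req %in% colnames(tab)))
    stop("miRNA table must have columns 'name' and 'sequence'", call. = FALSE)
  seqs <- tab$sequence
  names(seqs) <- tab$name
  MiRNASet(seqs)
}

#' Extract a window around a region of a UTR
#'
#' Expands a core region `[centerStart, centerEnd)` (0-based, half-open)
#' by `flank` nucleotides on each side, truncating at the UTR boundaries.
#' Truncation is recorded: the achieved flank lengths are returned so
#' callers can tell a full window from a clipped one. Windows are never
#' padded.
#'
#' @param utr A single UTR sequence (`RNAString`, `RNAStringSet` of length
#'   one, or character scalar).
#' @param centerStart,centerEnd 0-based half-open bounds of the core
#'   region; must satisfy `0 <= centerStart < centerEnd <= length(utr)`.
#' @param flank Non-negative number of nucleotides requested on each side.
#' @return A list with elements `start`, `end` (0-based half-open window
#'   bounds), `sequence` (the extracted RNA substring), `flank5`, `flank3`
#'   (achieved flank lengths).
#' @examples
#' w <- extractWindow(strrep("A", 200), 100, 122, 70)
#' c(w$start, w$end)  # 30 192
#' @export
extractWindow <- function(utr, centerStart, centerEnd, flank) {
  s <- utrAsCharacter(utr)
  n <- nchar(s)
  if (flank < 0) stop("flank must be non-negative", call. = FALSE)
  if (!(centerStart >= 0 && centerStart < centerEnd && centerEnd <= n))
    stop(sprintf(
      "window center [%d,%d) out of bounds for UTR of length %d (need 0 <= start < end <= length)",
      centerStart, centerEnd, n), call. = FALSE)
  start <- max(0L, as.integer(centerStart - flank))
  end <- min(n, as.integer(centerEnd + flank))
  list(
    start = start,
    end = end,
    sequence = substr(s, start + 1L, end),
    flank5 = as.integer(centerStart - start),
    flank3 = as.integer(end - centerEnd)
  )
}

# Coerce the various single-sequence representations to a character scalar.
utrAsCharacter <- function(utr) {
  if (is(utr, "XStringSet")) {
    if (length(utr) != 1L)
      stop("expected a single UTR sequence", call. = FALSE)
    return(as.character(utr[[1L]]))
  }
  if (is(utr, "XString")) return(as.character(utr))
  if (is.character(utr) && length(utr) == 1L) return(utr)
  stop("unsupported UTR representation", call. = FALSE)
}
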