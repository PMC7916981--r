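#' @useDynLib miRtaq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Fold an RNA sequence (minimum free energy, stacking model)
#'
#' Predicts a single minimum-free-energy secondary structure. The default
#' backend is an internal dynamic program over nested structures scored
#' with the embedded nearest-neighbor stacking table ([rnaStackTable()]):
#' the energy of a structure is the sum of stacking terms over directly
#' adjacent pairs, loops carry no penalty, the minimum hairpin loop is 3
#' unpaired nucleotides and pseudoknots are excluded. Because the empty
#' structure is always available, the reported energy is never positive.
#' Ties are broken toward fewer pairs, then the smallest pairing partner,
#' so the result is deterministic.
#'
#' The backend is pluggable: pass any `function(sequence)` returning a
#' list with elements `dotbracket` and `delta_g` to substitute a full
#' thermodynamic folding engine without changing downstream contracts.
#'
#' @param sequence RNA string (character scalar, `RNAString`, or
#'   length-one `RNAStringSet`); DNA `T` is normalized to `U`.
#' @param backend `"internal"` or a replacement folding function.
#' @return A list of class `FoldResult` with elements `sequence`,
#'   `dotbracket`, `delta_g` (kcal/mol, `<= 0`).
#' @examples
#' foldRNA("GGGGAAAACCCC")$dotbracket  # "((((....))))"
#' @export
foldRNA <- function(sequence, backend = "internal") {
  s <- normalizeRna(utrAsCharacter(sequence))
  if (!nzchar(s)) stop("cannot fold an empty sequence", call. = FALSE)
  if (is.function(backend)) {
    res <- backend(s)
    out <- list(sequence = s, dotbracket = res$dotbracket, delta_g = res$delta_g)
    class(out) <- "FoldResult"
    return(out)
  }
  code <- match(strsplit(s, "")[[1]], c("A", "C", "G", "U")) - 1L
  res <- .foldStackDP(code, rnaStackTable())
  db <- partnerToDotBracket(res$partner)
  out <- list(sequence = s, dotbracket = db, delta_g = res$energy)
  class(out) <- "FoldResult"
  out
}

#' @export
print.FoldResult <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket, "\n", sep = "")
  cat(sprintf("delta G = %.2f kcal/mol\n", x$delta_g))
  invisible(x)
}

# 0-based partner vector (-1 = unpaired) -> dot-bracket string
partnerToDotBracket <- function(partner) {
  ch <- rep(".", length(partner))
  paired <- which(partner >= 0L)
  opens <- paired[partner[paired] + 1L > paired]
  ch[opens] <- "("
  ch[partner[opens] + 1L] <- ")"
  paste(ch, collapse = "")
}

#' Parse dot-bracket notation into a pair table
#'
#' @param dotbracket A string over `.`, `(`, `)` (Vienna dialect, no
#'   pseudoknots).
#' @return An integer vector the length of the input: `pairTable[i]` is
#'   the 1-based partner of position `i`, or `NA` if unpaired.
#' @examples
#' parseDotBracket("((..))")  # 6 5 NA NA 2 1
#' @export
parseDotBracket <- function(dotbracket) {
  ch <- strsplit(dotbracket, "")[[1]]
  bad <- which(!ch %in% c(".", "(", ")"))
  if (length(bad))
    stop(sprintf("invalid dot-bracket character '%s' at index %d", ch[bad[1]], bad[1]),
         call. = FALSE)
  n <- length(ch)
  pt <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack))
        stop(sprintf("unbalanced dot-bracket: unmatched ')' at index %d", i),
             call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[j] <- i
      pt[i] <- j
    }
  }
  if (length(stack))
    stop(sprintf("unbalanced dot-bracket: unmatched '(' at index %d", stack[length(stack)]),
         call. = FALSE)
  pt
}

#' Decompose a secondary structure into loops and stems
#'
#' Standard loop decomposition of a nested structure: maximal runs of
#' stacked pairs form stems; an unpaired region closed by a single pair is
#' a hairpin loop; closed by two pairs on both sides, an interior loop
#' (length is the sum of both sides); on one side only, a bulge loop;
#' enclosed by three or more pairs, a multibranch loop; and unpaired runs
#' at the exterior level (5'/3' free ends and joints between stems) are
#' exterior segments. Every position is assigned exactly once: to one
#' stem or to one non-stem element. Element lengths count unpaired
#' nucleotides, except stems where they count base pairs.
#'
#' @param dotbracket Dot-bracket string, or a `FoldResult` from
#'   [foldRNA()] (in which case `sequence` is taken from it).
#' @param sequence Optional RNA string; when supplied, each stem's
#'   attributed free energy (`element_dg`, the sum of its stacking terms
#'   from [rnaStackTable()]) is filled in.
#' @return A data.frame with columns `kind`, `length`, `positions`
#'   (list column of 0-based indices), `element_dg`, `label`
#'   (`NA` until [labelElements()] is applied).
#' @examples
#' decomposeStructure("((((....))))")
#' @export
decomposeStructure <- function(dotbracket, sequence = NULL) {
  if (inherits(dotbracket, "FoldResult")) {
    sequence <- dotbracket$sequence
    dotbracket <- dotbracket$dotbracket
  }
  pt <- parseDotBracket(dotbracket)
  n <- length(pt)
  chars <- if (!is.null(sequence)) strsplit(normalizeRna(sequence), "")[[1]] else NULL
  if (!is.null(chars) && length(chars) != n)
    stop("sequence and dot-bracket lengths differ", call. = FALSE)

  kinds <- character(0); lens <- integer(0); poss <- list(); dgs <- numeric(0)
  addEl <- function(kind, positions, len = length(positions), dg = NA_real_) {
    kinds[[length(kinds) + 1L]] <<- kind
    lens[[length(lens) + 1L]] <<- as.integer(len)
    poss[[length(poss) + 1L]] <<- as.integer(positions - 1L)  # 0-based
    dgs[[length(dgs) + 1L]] <<- dg
  }

  # stems: maximal runs of stacked pairs
  opens <- which(!is.na(pt) & pt > seq_len(n))
  for (i in opens) {
    j <- pt[i]
    stacked_out <- i > 1L && j < n && !is.na(pt[i - 1L]) && pt[i - 1L] == j + 1L
    if (stacked_out) next  # not the outermost pair of its stem
    len <- 1L
    while (!is.na(pt[i + len]) && pt[i + len] == j - len) len <- len + 1L
    positions <- c(i:(i + len - 1L), (j - len + 1L):j)
    dg <- NA_real_
    if (!is.null(chars) && len > 1L) {
      k <- i + seq_len(len - 1L) - 1L
      dg <- sum(stackEnergy(chars[k], chars[k + 1L], chars[pt[k]], chars[pt[k] - 1L]))
    } else if (!is.null(chars)) {
      dg <- 0
    }
    addEl("stem", positions, len = len, dg = dg)
  }

  # loops closed by each pair
  for (i in opens) {
    j <- pt[i]
    p <- i + 1L
    children <- list(); unpaired <- integer(0)
    while (p < j) {
      if (is.na(pt[p])) { unpaired <- c(unpaired, p); p <- p + 1L }
      else { children[[length(children) + 1L]] <- c(p, pt[p]); p <- pt[p] + 1L }
    }
    nb <- length(children)
    if (nb == 0L) {
      addEl("hairpin_loop", unpaired)
    } else if (nb == 1L) {
      if (!length(unpaired)) next  # stacked pair: interior of a stem
      left <- unpaired[unpaired < children[[1L]][1L]]
      right <- unpaired[unpaired > children[[1L]][2L]]
      kind <- if (length(left) && length(right)) "interior_loop" else "bulge_loop"
      addEl(kind, unpaired)
    } else {
      addEl("multibranch_loop", unpaired)
    }
  }

  # exterior segments: maximal unpaired runs at the top level
  p <- 1L; run <- integer(0)
  flush <- function() { if (length(run)) addEl("exterior_segment", run); run <<- integer(0) }
  while (p <= n) {
    if (is.na(pt[p])) { run <- c(run, p); p <- p + 1L }
    else { flush(); p <- pt[p] + 1L }
  }
  flush()

  data.frame(
    kind = kinds,
    length = lens,
    positions = I(poss),
    element_dg = dgs,
    label = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Destabilising-element length cutoffs
#'
#' Minimum lengths (in nucleotides; stems are never DSEs) at which a loop
#' or exterior segment counts as a destabilising element favoring miRNA
#' access: hairpin loop >= 11, interior loop >= 9 (both sides summed),
#' bulge loop >= 7, multibranch loop >= 11, exterior segment (free end or
#' joint sequence) >= 11.
#'
#' @param hairpin,interior,bulge,multibranch,exterior Integer cutoffs.
#' @return A named list of cutoffs.
#' @export
dseCutoffs <- function(hairpin = 11, interior = 9, bulge = 7,
                       multibranch = 11, exterior = 11) {
  list(hairpin_loop = hairpin, interior_loop = interior, bulge_loop = bulge,
       multibranch_loop = multibranch, exterior_segment = exterior)
}

#' Label structure elements as destabilising or stabilising
#'
#' Applies the kind-specific length cutoffs: loops and exterior segments
#' at or above their cutoff are labelled `DSE` (destabilising element),
#' stems are labelled `SE` (stabilising element), everything else
#' `neutral`. The label is a pure function of `(kind, length)` given the
#' cutoffs, so lowering a cutoff can only add DSE labels.
#'
#' @param elements Output of [decomposeStructure()].
#' @param cutoffs A list from [dseCutoffs()].
#' @return `elements` with the `label` column filled.
#' @export
labelElements <- function(elements, cutoffs = dseCutoffs()) {
  lab <- rep("neutral", nrow(elements))
  lab[elements$kind == "stem"] <- "SE"
  for (kind in names(cutoffs)) {
    sel <- elements$kind == kind & elements$length >= cutoffs[[kind]]
    lab[sel] <- "DSE"
  }
  elements$label <- lab
  elements
}
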