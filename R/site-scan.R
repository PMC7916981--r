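#' Scan UTRs for seed-complementary miRNA binding sites
#'
#' Slides a hexamer window over each UTR and evaluates antiparallel
#' pairing against the miRNA seed (mature positions 2-7). G:U pairs are
#' counted as wobbles up to `maxWobble`; wobbles beyond that budget
#' degrade to mismatches. A window is reported when its mismatch count
#' (non-Watson-Crick, non-wobble positions, plus over-budget wobbles) is
#' at most `maxMismatch`. The site class is upgraded from `6mer-seed` to
#' `7mer` when the target position opposite miRNA position 8 also pairs
#' Watson-Crick, and to `8mer` when additionally the target position
#' opposite miRNA position 1 is an A (canonical seed-site nomenclature).
#' Overlapping sites are all reported; coordinates are 0-based half-open
#' on the target and span 6/7/8 nt for the three classes.
#'
#' @param mirnas A [MiRNASet-class] or named character vector of mature
#'   miRNA sequences.
#' @param utrs A named `RNAStringSet` or named character vector of UTRs.
#' @param maxMismatch Mismatch budget within the seed pairing (default 1).
#' @param maxWobble G:U wobble budget within the seed pairing (default 1).
#' @return A data.frame with columns `mirna`, `gene`, `start`, `end`,
#'   `site_class`, `mismatches`, `wobbles`, `alignment` (target 5'->3'
#'   over miRNA 3'->5'), sorted by `mirna`, `gene`, `start`.
#' @examples
#' scanSeedSites(c(m = "AAUGACACGAUCACUCCCGUUGA"), c(G1 = "AAAAUGUCAUAAAA"))
#' @export
scanSeedSites <- function(mirnas, utrs, maxMismatch = 1, maxWobble = 1) {
  mir <- asNamedCharacter(mirnas, "miRNA")
  utr <- asNamedCharacter(utrs, "UTR")
  rows <- list()
  for (mn in names(mir)) {
    m <- strsplit(normalizeRna(mir[[mn]], mn), "")[[1]]
    if (length(m) < 8)
      stop(sprintf("mature miRNA '%s' shorter than 8 nt", mn), call. = FALSE)
    for (gn in names(utr)) {
      t <- strsplit(normalizeRna(utr[[gn]], gn), "")[[1]]
      L <- length(t)
      if (L < 6) next
      for (s in 0:(L - 6)) {
        hit <- evalSeedWindow(m, t, s, maxWobble)
        if (hit$mismatches > maxMismatch) next
        cls <- classifySite(m, t, s)
        coords <- siteCoords(s, cls)
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = mn, gene = gn,
          start = coords[1], end = coords[2],
          site_class = cls,
          mismatches = hit$mismatches, wobbles = hit$wobbles,
          alignment = renderAlignment(m, t, s, cls),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  collectSiteRows(rows)
}

# Pairing of the seed (miRNA 2-7) against target window [s, s+6), 0-based.
# miRNA position 2 pairs target s+5, ..., position 7 pairs target s.
evalSeedWindow <- function(m, t, s, maxWobble) {
  mb <- m[2:7]
  tb <- t[(s + 6):(s + 1)]  # antiparallel: reversed target window
  wc <- sum(isWatsonCrick(mb, tb))
  wob <- sum(isWobble(mb, tb))
  wobUsed <- min(wob, maxWobble)
  list(mismatches = 6L - wc - wobUsed, wobbles = wobUsed)
}

classifySite <- function(m, t, s) {
  L <- length(t)
  cls <- "6mer-seed"
  if (s - 1 >= 0 && isWatsonCrick(m[8], t[s])) {  # t[s] is 0-based position s-1
    cls <- "7mer"
    if (s + 6 <= L - 1 && t[s + 7] == "A") cls <- "8mer"
  }
  cls
}

siteCoords <- function(s, cls) {
  switch(cls,
    "6mer-seed" = c(s, s + 6L),
    "7mer" = c(s - 1L, s + 6L),
    "8mer" = c(s - 1L, s + 7L)
  )
}

renderAlignment <- function(m, t, s, cls) {
  span <- siteCoords(s, cls)
  tIdx <- (span[1] + 1L):span[2]                  # 1-based target indices
  mPos <- (s + 6L) - tIdx + 2L                    # miRNA position opposite each
  top <- t[tIdx]
  bottom <- ifelse(mPos >= 1L & mPos <= length(m), m[mPos], "-")
  sym <- vapply(seq_along(tIdx), function(k) {
    if (bottom[k] == "-") return(" ")
    if (isWatsonCrick(bottom[k], top[k])) "|"
    else if (isWobble(bottom[k], top[k])) ":"
    else " "
  }, character(1))
  paste0("5'-", paste(top, collapse = ""), "-3'\n   ",
         paste(sym, collapse = ""), "\n3'-",
         paste(bottom, collapse = ""), "-5'")
}

collectSiteRows <- function(rows) {
  if (!length(rows)) {
    return(data.frame(
      mirna = character(0), gene = character(0),
      start = integer(0), end = integer(0), site_class = character(0),
      mismatches = integer(0), wobbles = integer(0), alignment = character(0),
      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna, out$gene, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

asNamedCharacter <- function(x, what) {
  if (is(x, "XStringSet")) {
    nm <- names(x)
    x <- as.character(x)
    names(x) <- nm
  }
  if (!is.character(x) || is.null(names(x)) || any(names(x) == ""))
    stop(sprintf("%s input must be a named character vector or XStringSet", what),
         call. = FALSE)
  x
}

#' Free energy of an aligned miRNA:target heteroduplex
#'
#' Sums nearest-neighbor stacking contributions ([rnaStackTable()]) over
#' consecutive paired positions of an ungapped antiparallel alignment;
#' each unpaired position adds a fixed penalty. The two strands must be
#' equal length; position `i` of the miRNA (5'->3') faces position `i` of
#' the target (3'->5').
#'
#' @param mirnaSub miRNA substring, 5' to 3'.
#' @param targetSub Target substring, 3' to 5' (aligned antiparallel).
#' @param pairing Optional character vector over
#'   `c("WC", "wobble", "unpaired")`, one entry per position. If omitted
#'   it is derived from base complementarity.
#' @param unpairedPenalty Energy added per unpaired position (kcal/mol,
#'   default +0.5).
#' @return A list of class `DuplexResult` with `energy` (kcal/mol) and
#'   `pairing` (per-position pair codes).
#' @examples
#' duplexEnergy("GGGG", "CCCC")$energy  # 3 stacked GG/CC terms = -9.9
#' @export
duplexEnergy <- function(mirnaSub, targetSub, pairing = NULL,
                         unpairedPenalty = 0.5) {
  m <- strsplit(normalizeRna(mirnaSub), "")[[1]]
  t <- strsplit(normalizeRna(targetSub), "")[[1]]
  if (length(m) != length(t))
    stop("aligned substrings must have equal length", call. = FALSE)
  if (is.null(pairing)) {
    pairing <- ifelse(isWatsonCrick(m, t), "WC",
                      ifelse(isWobble(m, t), "wobble", "unpaired"))
  } else {
    if (length(pairing) != length(m))
      stop("pairing mask must match alignment length", call. = FALSE)
    bad <- pairing != "unpaired" & !canPair(m, t)
    if (any(bad))
      stop(sprintf("pairing mask marks non-pairable bases at position %d",
                   which(bad)[1]), call. = FALSE)
  }
  paired <- pairing != "unpaired"
  energy <- unpairedPenalty * sum(!paired)
  if (length(m) > 1) {
    i <- which(paired[-length(paired)] & paired[-1])
    if (length(i))
      energy <- energy + sum(stackEnergy(m[i], m[i + 1], t[i], t[i + 1]))
  }
  out <- list(energy = energy, pairing = pairing)
  class(out) <- "DuplexResult"
  out
}

#' Constrained heteroduplex site search
#'
#' Finds target sites under the constrained-search settings used for
#' pattern-based miRNA target discovery: a 7mer or 8mer seed-region
#' pairing (miRNA positions 2 to `seedLen + 1`) with at most
#' `maxUnpairedInSeed` unpaired positions and `maxWobble` G:U wobbles in
#' that region, and a full-length ungapped heteroduplex free energy at or
#' below `energyCutoff`. The duplex energy is the stacking sum of the
#' whole miRNA aligned antiparallel over the target (truncated at UTR
#' ends), via [duplexEnergy()]. Only the energy/seed constraints are
#' implemented; pattern-discovery significance statistics are not, and
#' the `pass` flag is the energy-cutoff test.
#'
#' @inheritParams scanSeedSites
#' @param energyCutoff Heteroduplex free-energy cutoff in kcal/mol
#'   (default -12; -20 is the other conventional setting).
#' @param seedLen Number of seed-region target positions, 7 or 8.
#' @param maxUnpairedInSeed Unpaired-position budget in the seed region
#'   (read as one unpaired nucleotide, not one block).
#' @param maxWobble G:U wobble budget in the seed region.
#' @param keepAll If `TRUE`, also return seed-qualified sites whose
#'   energy misses the cutoff (with `pass = FALSE`); used for near-miss
#'   reporting.
#' @return A data.frame with columns `mirna`, `gene`, `start`, `end`,
#'   `site_class`, `unpaired_in_seed`, `wobbles`, `duplex_energy`,
#'   `pass`, ordered by `mirna`, `gene`, `start`.
#' @export
rna22Sites <- function(mirnas, utrs, energyCutoff = -12, seedLen = 7,
                       maxUnpairedInSeed = 1, maxWobble = 1,
                       keepAll = FALSE) {
  if (!seedLen %in% c(7, 8))
    stop("seedLen must be 7 or 8", call. = FALSE)
  mir <- asNamedCharacter(mirnas, "miRNA")
  utr <- asNamedCharacter(utrs, "UTR")
  rows <- list()
  for (mn in names(mir)) {
    m <- strsplit(normalizeRna(mir[[mn]], mn), "")[[1]]
    nm <- length(m)
    if (nm < seedLen + 1)
      stop(sprintf("mature miRNA '%s' shorter than %d nt", mn, seedLen + 1),
           call. = FALSE)
    for (gn in names(utr)) {
      t <- strsplit(normalizeRna(utr[[gn]], gn), "")[[1]]
      L <- length(t)
      if (L < seedLen) next
      for (s in 0:(L - seedLen)) {
        # miRNA position k pairs target 0-based position s + seedLen + 1 - k
        kSeed <- 2:(seedLen + 1)
        tbSeed <- t[s + seedLen + 2 - kSeed]  # +1 for 1-based indexing
        mbSeed <- m[kSeed]
        wob <- sum(isWobble(mbSeed, tbSeed))
        wobUsed <- min(wob, maxWobble)
        unpaired <- seedLen - sum(isWatsonCrick(mbSeed, tbSeed)) - wobUsed
        if (unpaired > maxUnpairedInSeed) next
        # full-length ungapped duplex, truncated at UTR bounds
        k <- seq_len(nm)
        tpos <- s + seedLen + 1 - k           # 0-based target positions
        inRange <- tpos >= 0 & tpos <= L - 1
        dup <- duplexEnergy(paste(m[inRange], collapse = ""),
                            paste(t[tpos[inRange] + 1], collapse = ""))
        ok <- dup$energy <= energyCutoff
        if (!ok && !keepAll) next
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = mn, gene = gn, start = s, end = s + seedLen,
          site_class = paste0(seedLen, "mer"),
          unpaired_in_seed = unpaired, wobbles = wobUsed,
          duplex_energy = dup$energy, pass = ok,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(
      mirna = character(0), gene = character(0), start = integer(0),
      end = integer(0), site_class = character(0),
      unpaired_in_seed = integer(0), wobbles = integer(0),
      duplex_energy = numeric(0), pass = logical(0),
      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna, out$gene, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
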