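#' Assess target-site accessibility from local secondary structure
#'
#' Applies the structure-based accessibility criteria to one binding site:
#'
#' * **Flank free-energy gap.** Three windows are folded -- the site
#'   alone, the site plus `energyFlank` nt upstream, and the site plus
#'   `energyFlank` nt downstream (jointly by default; flanks truncated at
#'   UTR ends are used as-is and the achieved lengths recorded). The gap
#'   criterion passes when the absolute difference between the site
#'   window's free energy and either flank window's is at least
#'   `gapThreshold` kcal/mol; both signed differences are reported since
#'   either direction is informative.
#' * **Destabilising elements.** The site with `structureFlank` nt on
#'   each side is folded, decomposed ([decomposeStructure()]) and
#'   labelled ([labelElements()]); `dse_present` is `TRUE` when any DSE
#'   lies in that window.
#' * **Inhibitory structure.** With the default `"substructure"`
#'   granularity, a stem overlapping the site whose attributed free
#'   energy (sum of its stacking terms) is below `inhibitionDg` marks the
#'   site as occluded; `"window"` granularity instead tests the whole
#'   structure window's free energy.
#'
#' @param utr A single UTR sequence.
#' @param siteStart,siteEnd 0-based half-open coordinates of the site's
#'   pairing region (e.g. from [scanSeedSites()]).
#' @param energyFlank Flank width for the free-energy windows (nt,
#'   default 70).
#' @param structureFlank Flank width for the secondary-structure window
#'   (nt, default 30).
#' @param foldBackend Folding function, see [foldRNA()].
#' @param cutoffs DSE length cutoffs, see [dseCutoffs()].
#' @param inhibitionDg Inhibition threshold in kcal/mol (default -6).
#' @param gapThreshold Flank free-energy gap threshold in kcal/mol
#'   (default 10).
#' @param flankMode `"joint"` folds site+flank together (default);
#'   `"alone"` folds each flank without the site.
#' @param inhibitionGranularity `"substructure"` (default) or
#'   `"window"`.
#' @return A one-row data.frame: `start`, `end`, `site_window_dg`,
#'   `upstream_flank_dg`, `downstream_flank_dg`, `diff_upstream`,
#'   `diff_downstream`, `energy_gap_pass`, `dse_present`,
#'   `inhibitory_structure`, `upstream_flank_len`,
#'   `downstream_flank_len`.
#' @export
assessAccessibility <- function(utr, siteStart, siteEnd,
                                energyFlank = 70, structureFlank = 30,
                                foldBackend = "internal",
                                cutoffs = dseCutoffs(),
                                inhibitionDg = -6, gapThreshold = 10,
                                flankMode = c("joint", "alone"),
                                inhibitionGranularity = c("substructure", "window")) {
  flankMode <- match.arg(flankMode)
  inhibitionGranularity <- match.arg(inhibitionGranularity)
  s <- utrAsCharacter(utr)

  siteWin <- extractWindow(s, siteStart, siteEnd, 0)
  siteDg <- foldRNA(siteWin$sequence, backend = foldBackend)$delta_g

  upWin <- extractWindow(s, siteStart, siteEnd, energyFlank)
  upSpan <- c(upWin$start, siteEnd)              # site + upstream flank
  downSpan <- c(siteStart, upWin$end)            # site + downstream flank
  if (flankMode == "alone") {
    upSpan <- c(upWin$start, siteStart)
    downSpan <- c(siteEnd, upWin$end)
  }
  upDg <- foldSpanDg(s, upSpan, foldBackend)
  downDg <- foldSpanDg(s, downSpan, foldBackend)

  diffUp <- siteDg - upDg
  diffDown <- siteDg - downDg
  gapPass <- max(abs(diffUp), abs(diffDown)) >= gapThreshold

  structWin <- extractWindow(s, siteStart, siteEnd, structureFlank)
  fold <- foldRNA(structWin$sequence, backend = foldBackend)
  elements <- labelElements(decomposeStructure(fold), cutoffs)
  dsePresent <- any(elements$label == "DSE")

  relSite <- seq(siteStart - structWin$start, siteEnd - structWin$start - 1L)
  if (inhibitionGranularity == "substructure") {
    stems <- elements[elements$kind == "stem", , drop = FALSE]
    inhibitory <- FALSE
    for (k in seq_len(nrow(stems))) {
      if (!is.na(stems$element_dg[k]) && stems$element_dg[k] < inhibitionDg &&
          length(intersect(stems$positions[[k]], relSite)))
        inhibitory <- TRUE
    }
  } else {
    pt <- parseDotBracket(fold$dotbracket)
    sitePaired <- any(!is.na(pt[relSite + 1L]))
    inhibitory <- fold$delta_g < inhibitionDg && sitePaired
  }

  data.frame(
    start = siteStart, end = siteEnd,
    site_window_dg = siteDg,
    upstream_flank_dg = upDg, downstream_flank_dg = downDg,
    diff_upstream = diffUp, diff_downstream = diffDown,
    energy_gap_pass = gapPass,
    dse_present = dsePresent,
    inhibitory_structure = inhibitory,
    upstream_flank_len = upWin$flank5,
    downstream_flank_len = upWin$flank3,
    stringsAsFactors = FALSE
  )
}

foldSpanDg <- function(s, span, backend) {
  if (span[2] <= span[1]) return(0)  # empty flank window (site at UTR end)
  foldRNA(substr(s, span[1] + 1L, span[2]), backend = backend)$delta_g
}

#' Assess accessibility for a table of binding sites
#'
#' Convenience wrapper running [assessAccessibility()] for every row of a
#' site table (as produced by [scanSeedSites()]).
#'
#' @param utrs Named `RNAStringSet` or named character vector of UTRs.
#' @param sites Data.frame with columns `mirna`, `gene`, `start`, `end`.
#' @param ... Passed on to [assessAccessibility()].
#' @return A data.frame with one verdict row per site, keyed by `mirna`
#'   and `gene`.
#' @export
assessSites <- function(utrs, sites, ...) {
  utr <- asNamedCharacter(utrs, "UTR")
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    gn <- sites$gene[i]
    if (!gn %in% names(utr))
      stop(sprintf("site references unknown gene '%s'", gn), call. = FALSE)
    v <- assessAccessibility(utr[[gn]], sites$start[i], sites$end[i], ...)
    cbind(data.frame(mirna = sites$mirna[i], gene = gn,
                     stringsAsFactors = FALSE), v)
  })
  if (!length(rows)) {
    return(data.frame(
      mirna = character(0), gene = character(0), start = integer(0),
      end = integer(0), site_window_dg = numeric(0),
      upstream_flank_dg = numeric(0), downstream_flank_dg = numeric(0),
      diff_upstream = numeric(0), diff_downstream = numeric(0),
      energy_gap_pass = logical(0), dse_present = logical(0),
      inhibitory_structure = logical(0), upstream_flank_len = integer(0),
      downstream_flank_len = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
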