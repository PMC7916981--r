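# Independent brute-force oracles. These re-derive expected results from
# first principles (explicit enumeration, direct pair-table inspection)
# and deliberately share no code with the implementation beyond the
# published parameter table, which is part of the contract.

WC_PAIRS <- c("AU", "UA", "CG", "GC")
WOBBLE_PAIRS <- c("GU", "UG")

oracleChars <- function(s) strsplit(s, "")[[1]]

# Enumerate every hexamer window and count pairs explicitly.
oracleScanSites <- function(mirnaName, mirnaSeq, gene, utrSeq,
                            maxMismatch = 1, maxWobble = 1) {
  m <- oracleChars(mirnaSeq)
  u <- oracleChars(utrSeq)
  L <- length(u)
  rows <- list()
  if (L < 6) return(NULL)
  for (start in 1:(L - 5)) {            # 1-based window start
    wc <- 0L; wob <- 0L
    for (mi in 2:7) {
      tj <- start + 5 - (mi - 2)        # 1-based target partner
      pr <- paste0(m[mi], u[tj])
      if (pr %in% WC_PAIRS) wc <- wc + 1L
      else if (pr %in% WOBBLE_PAIRS) wob <- wob + 1L
    }
    wobUsed <- min(wob, maxWobble)
    mm <- 6L - wc - wobUsed
    if (mm > maxMismatch) next
    cls <- "6mer-seed"
    if (start - 1 >= 1 && paste0(m[8], u[start - 1]) %in% WC_PAIRS) {
      cls <- "7mer"
      if (start + 6 <= L && u[start + 6] == "A") cls <- "8mer"
    }
    s0 <- start - 1L                    # 0-based seed-region start
    coords <- switch(cls,
      "6mer-seed" = c(s0, s0 + 6L),
      "7mer" = c(s0 - 1L, s0 + 6L),
      "8mer" = c(s0 - 1L, s0 + 7L))
    rows[[length(rows) + 1L]] <- data.frame(
      mirna = mirnaName, gene = gene, start = coords[1], end = coords[2],
      site_class = cls, mismatches = mm, wobbles = wobUsed,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

# All nested structures (pair lists) with minimum hairpin loop 3.
oracleEnumStructures <- function(n, pairableFn) {
  rec <- function(i, j) {
    if (i >= j) return(list(list()))
    out <- rec(i + 1, j)                       # i unpaired
    if (j - i < 4) return(out)
    for (k in (i + 4):j) {
      if (!pairableFn(i, k)) next
      inner <- rec(i + 1, k - 1)
      rest <- rec(k + 1, j)
      for (a in inner) for (b in rest)
        out[[length(out) + 1L]] <- c(list(c(i, k)), a, b)
    }
    out
  }
  rec(1, n)
}

# Stand-alone stacking score of an explicit pair list.
oracleScoreStructure <- function(pairs, chars) {
  if (!length(pairs)) return(0)
  ii <- vapply(pairs, `[`, numeric(1), 1)
  jj <- vapply(pairs, `[`, numeric(1), 2)
  e <- 0
  for (k in seq_along(ii)) {
    inner <- which(ii == ii[k] + 1 & jj == jj[k] - 1)
    if (length(inner))
      e <- e + stackEnergy(chars[ii[k]], chars[ii[k] + 1],
                           chars[jj[k]], chars[jj[k] - 1])
  }
  e
}

oracleMinEnergy <- function(seq) {
  chars <- oracleChars(seq)
  pairable <- function(i, j)
    paste0(chars[i], chars[j]) %in% c(WC_PAIRS, WOBBLE_PAIRS)
  structs <- oracleEnumStructures(length(chars), pairable)
  min(vapply(structs, oracleScoreStructure, numeric(1), chars = chars))
}

# Minimal independent dot-bracket parser (1-based partners, NA unpaired).
oraclePairTable <- function(db) {
  ch <- oracleChars(db)
  pt <- rep(NA_integer_, length(ch))
  st <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") st <- c(st, i)
    else if (ch[i] == ")") { pt[i] <- st[length(st)]; pt[st[length(st)]] <- i
                             st <- st[-length(st)] }
  }
  pt
}

# Classify the loop kind of each maximal unpaired run by walking the pair
# table directly: find the directly enclosing pair (or none -> exterior),
# then count the branches of that loop.
oracleClassifyRuns <- function(db) {
  pt <- oraclePairTable(db)
  n <- length(pt)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (is.na(pt[i])) {
      j <- i
      while (j < n && is.na(pt[j + 1L])) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  classify <- function(a, b) {
    # walk left, jumping over complete helices, to the enclosing pair
    i <- a - 1L
    while (i >= 1L) {
      if (is.na(pt[i])) { i <- i - 1L; next }
      if (pt[i] > b) break           # (i, pt[i]) encloses the run
      i <- pt[i] - 1L                # skip a closed branch to our left
    }
    if (i < 1L) return("exterior_segment")
    ci <- i; cj <- pt[i]
    nb <- 0L; unp <- 0L
    p <- ci + 1L
    while (p < cj) {
      if (is.na(pt[p])) { unp <- unp + 1L; p <- p + 1L }
      else { nb <- nb + 1L; p <- pt[p] + 1L }
    }
    if (nb == 0L) return("hairpin_loop")
    if (nb >= 2L) return("multibranch_loop")
    child <- ci + 1L
    while (is.na(pt[child])) child <- child + 1L
    left <- child - ci - 1L
    right <- cj - pt[child] - 1L
    if (left > 0L && right > 0L) "interior_loop" else "bulge_loop"
  }
  lapply(runs, function(r)
    list(from = r[1], to = r[2], kind = classify(r[1], r[2])))
}

# Random valid dot-bracket of exact length n (all hairpins >= 3 nt).
randomDotbracket <- function(n) {
  rec <- function(n) {
    if (n < 5) return(strrep(".", n))
    if (runif(1) < 0.45) return(paste0(".", rec(n - 1)))
    m <- sample(3:(n - 2), 1)
    paste0("(", rec(m), ")", rec(n - 2 - m))
  }
  rec(n)
}

randomRna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Shared column set when comparing scanner output to the oracle.
SITE_COLS <- c("mirna", "gene", "start", "end", "site_class",
               "mismatches", "wobbles")
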