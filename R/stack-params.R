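#' Embedded RNA/RNA nearest-neighbor stacking parameters
#'
#' Watson-Crick and G:U wobble stacking free energies at 37 degrees C
#' (kcal/mol) from the Turner 2004 RNA parameter set. Rows index the outer
#' (closing) base pair of a stack, columns the inner pair, both written
#' 5'X...Y3' for a pair X:Y. The energy of the stack
#'
#' ```
#' 5'-X1 X2-3'
#' 3'-Y1 Y2-5'
#' ```
#'
#' with pairs X1:Y1 and X2:Y2 is `rnaStackTable()["X1Y1", "Y2X2"]`
#' (the inner pair is read on the opposite strand, per the usual
#' nearest-neighbor convention). All stacking contributions used by
#' [duplexEnergy()], [foldRNA()] and stem-energy attribution come from this
#' one table, so hand summation of table entries reproduces any energy the
#' package reports.
#'
#' @return A 6 x 6 numeric matrix with dimnames
#'   `c("CG","GC","GU","UG","AU","UA")`, energies in kcal/mol.
#' @examples
#' rnaStackTable()["GC", "CG"]  # 5'GG3'/3'CC5' stack
#' @export
rnaStackTable <- function() {
  pairs <- c("CG", "GC", "GU", "UG", "AU", "UA")
  m <- matrix(c(
    # CG     GC     GU     UG     AU     UA
    -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,  # CG
    -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,  # GC
    -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,  # GU
    -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,  # UG
    -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,  # AU
    -2.10, -2.40, -1.30, -1.00, -0.90, -1.30   # UA
  ), nrow = 6, byrow = TRUE, dimnames = list(pairs, pairs))
  m
}

# Pair type of bases x:y, or NA if not a canonical/wobble pair.
pairType <- function(x, y) {
  key <- paste0(x, y)
  ifelse(key %in% c("CG", "GC", "GU", "UG", "AU", "UA"), key, NA_character_)
}

isWatsonCrick <- function(x, y) {
  paste0(x, y) %in% c("AU", "UA", "CG", "GC")
}

isWobble <- function(x, y) {
  paste0(x, y) %in% c("GU", "UG")
}

canPair <- function(x, y) {
  !is.na(pairType(x, y))
}

#' Stacking energy of two adjacent base pairs
#'
#' Energy (kcal/mol) of the stack formed by the pairs `x1:y1` and `x2:y2`
#' in the antiparallel arrangement 5'-x1 x2-3' / 3'-y1 y2-5', looked up in
#' [rnaStackTable()]. Returns `NA` if either pair is not a Watson-Crick or
#' G:U pair.
#'
#' @param x1,x2 Top-strand bases, 5' to 3'.
#' @param y1,y2 Bottom-strand bases, 3' to 5' (so `x1` pairs `y1`).
#' @return Numeric energy in kcal/mol, or `NA`.
#' @examples
#' stackEnergy("G", "G", "C", "C")  # -3.3
#' @export
stackEnergy <- function(x1, x2, y1, y2) {
  p1 <- pairType(x1, y1)
  p2 <- pairType(y2, x2)  # inner pair read on the opposite strand
  tab <- rnaStackTable()
  out <- rep(NA_real_, length(p1))
  ok <- !is.na(p1) & !is.na(p2)
  out[ok] <- tab[cbind(p1[ok], p2[ok])]
  out
}

# Complement of RNA bases (vectorized over single characters).
rnaComplement <- function(x) {
  c(A = "U", C = "G", G = "C", U = "A")[x]
}

# Reverse complement of an RNA string given as a character scalar.
reverseComplementRna <- function(s) {
  paste(rev(rnaComplement(strsplit(s, "")[[1]])), collapse = "")
}
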