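mir425 <- c("hsa-miR-425-5p" = "AAUGACACGAUCACUCCCGUUGA")  # seed AUGACA

test_that("a perfect seed complement is found with exact coordinates", {
  hits <- scanSeedSites(mir425, c(G1 = "AAAAUGUCAUAAAA"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 4)
  expect_equal(hits$end, 10)
  expect_equal(hits$mismatches, 0)
  expect_equal(hits$wobbles, 0)
  expect_match(hits$alignment, "UGUCAU")
})

test_that("substitutions are counted as wobbles or mismatches per pair type", {
  # A->G opposite seed U forms a U:G wobble
  wob <- scanSeedSites(mir425, c(G1 = "AAAAUGUCGUAAAA"))
  expect_equal(wob$wobbles, 1)
  expect_equal(wob$mismatches, 0)
  # A->C opposite seed U pairs with nothing: a true mismatch
  mm <- scanSeedSites(mir425, c(G1 = "AAAAUGUCCUAAAA"))
  expect_equal(mm$mismatches, 1)
  expect_equal(mm$wobbles, 0)
})

test_that("wobbles beyond the budget degrade to mismatches", {
  # seed AUGACA vs target UGUUGU: G:U wobbles opposite seed positions 3/4
  utr <- c(G1 = "AAAUGUUGUAAAA")
  strict <- scanSeedSites(mir425, utr, maxMismatch = 1, maxWobble = 1)
  strict <- strict[strict$start == 3, ]
  expect_equal(strict$wobbles, 1)
  expect_equal(strict$mismatches, 1)
  roomy <- scanSeedSites(mir425, utr, maxMismatch = 0, maxWobble = 2)
  roomy <- roomy[roomy$start == 3, ]
  expect_equal(roomy$wobbles, 2)
  expect_equal(roomy$mismatches, 0)
})

test_that("hopeless targets yield no sites", {
  hits <- scanSeedSites(mir425, c(G1 = "AAAAAAAAAA"))
  expect_equal(nrow(hits), 0L)
})

test_that("site classes upgrade with position-8 pairing and the target A", {
  # miRNA positions 2-8 = AUGACAC; 7mer adds G opposite position 8
  hits7 <- scanSeedSites(mir425, c(G1 = "AAAGUGUCAUCAAA"))
  hits7 <- hits7[hits7$start == 3, ]
  expect_equal(hits7$site_class, "7mer")
  expect_equal(hits7$end - hits7$start, 7)
  hits8 <- scanSeedSites(mir425, c(G1 = "AAAGUGUCAUAAAA"))
  hits8 <- hits8[hits8$start == 3, ]
  expect_equal(hits8$site_class, "8mer")
  expect_equal(hits8$end - hits8$start, 8)
})

test_that("scanner agrees with the brute-force window enumerator", {
  set.seed(11)
  for (i in 1:100) {
    mseq <- randomRna(sample(18:23, 1))
    useq <- randomRna(sample(30:200, 1), gc = runif(1, 0.2, 0.7))
    got <- scanSeedSites(c(m = mseq), c(g = useq))
    want <- oracleScanSites("m", mseq, "g", useq)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      rownames(want) <- NULL
      expect_equal(got[, SITE_COLS], want[, SITE_COLS])
    }
  }
})

test_that("raising budgets never loses sites", {
  set.seed(12)
  for (i in 1:25) {
    mseq <- randomRna(20)
    useq <- randomRna(80)
    base <- nrow(scanSeedSites(c(m = mseq), c(g = useq), 0, 0))
    for (mm in 0:2) for (wb in 0:2) {
      n <- nrow(scanSeedSites(c(m = mseq), c(g = useq), mm, wb))
      expect_gte(n, base)
    }
    n01 <- nrow(scanSeedSites(c(m = mseq), c(g = useq), 0, 1))
    n11 <- nrow(scanSeedSites(c(m = mseq), c(g = useq), 1, 1))
    expect_gte(n11, n01)
  }
})

test_that("duplex energy is the hand summation of stack table entries", {
  tab <- rnaStackTable()
  d <- duplexEnergy("GGGG", "CCCC")
  expect_equal(d$energy, 3 * tab["GC", "CG"])
  expect_equal(d$pairing, rep("WC", 4))
  # no pairs: penalties only
  d0 <- duplexEnergy("AAAA", "AAAA")
  expect_equal(d0$energy, 4 * 0.5)
  # explicit mask forces penalties
  d1 <- duplexEnergy("GGGG", "CCCC",
                     pairing = c("WC", "WC", "unpaired", "WC"))
  expect_equal(d1$energy, tab["GC", "CG"] + 0.5)
  expect_error(duplexEnergy("GG", "CCC"), "equal length")
  expect_error(duplexEnergy("GA", "CA", pairing = c("WC", "WC")),
               "non-pairable")
})

test_that("duplex energy is invariant under 180-degree rotation of the duplex", {
  # reading the duplex from the other end (strands swapped, both reversed)
  # is the same physical molecule, so the stack summation must not change
  set.seed(13)
  rev1 <- function(s) paste(rev(oracleChars(s)), collapse = "")
  for (i in 1:50) {
    n <- sample(4:10, 1)
    m <- randomRna(n)
    t <- randomRna(n)
    expect_equal(duplexEnergy(rev1(t), rev1(m))$energy,
                 duplexEnergy(m, t)$energy)
  }
})

test_that("constrained heteroduplex search respects the energy cutoff", {
  tab <- rnaStackTable()
  mir <- c(m = "GGGGGGGGGGGG")
  utr <- c(g = paste0("AAAA", strrep("C", 12), "AAAA"))
  # full 12-pair G:C duplex: 11 stacks of 5'GG3'/3'CC5'
  strong <- 11 * tab["GC", "CG"]
  expect_lt(strong, -20)
  hits12 <- rna22Sites(mir, utr, energyCutoff = -12)
  hits20 <- rna22Sites(mir, utr, energyCutoff = -20)
  expect_true(any(hits12$duplex_energy <= -12))
  expect_equal(min(hits12$duplex_energy), strong)
  expect_true(nrow(hits20) > 0)

  weak <- c(m = "AAAAAAAAAAAA")
  wutr <- c(g = paste0("GGGG", strrep("U", 12), "GGGG"))
  # 11 stacks of 5'AA3'/3'UU5' = -9.9+0.4... stays above -12 with penalties
  expect_equal(nrow(rna22Sites(weak, wutr, energyCutoff = -12)), 0L)
})

test_that("a stricter cutoff yields a subset of sites", {
  set.seed(14)
  for (i in 1:10) {
    mir <- c(m = randomRna(21, gc = 0.6))
    utr <- c(g = randomRna(150, gc = 0.6))
    loose <- rna22Sites(mir, utr, energyCutoff = -8)
    strict <- rna22Sites(mir, utr, energyCutoff = -14)
    keyL <- paste(loose$start, loose$site_class)
    keyS <- paste(strict$start, strict$site_class)
    expect_true(all(keyS %in% keyL))
  }
})

test_that("seed-length 8 windows span eight target positions", {
  hits <- rna22Sites(c(m = "GGGGGGGGGGGG"),
                     c(g = paste0("AAAA", strrep("C", 12), "AAAA")),
                     energyCutoff = -12, seedLen = 8)
  expect_true(all(hits$end - hits$start == 8))
  expect_true(all(hits$site_class == "8mer"))
})
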