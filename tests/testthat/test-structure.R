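test_that("unpairable sequences fold to the open chain at zero energy", {
  f <- foldRNA("AAAAAAA")
  expect_equal(f$dotbracket, ".......")
  expect_equal(f$delta_g, 0)
  expect_error(foldRNA(""), "empty")
})

test_that("a GC hairpin folds to the full helix under stack-only scoring", {
  f <- foldRNA("GGGGAAAACCCC")
  expect_equal(f$dotbracket, "((((....))))")
  expect_equal(f$delta_g, 3 * rnaStackTable()["GC", "CG"])
})

test_that("folding energy is never positive", {
  set.seed(21)
  for (i in 1:200) {
    f <- foldRNA(randomRna(sample(5:60, 1), gc = runif(1, 0.1, 0.9)))
    expect_lte(f$delta_g, 0)
    expect_equal(nchar(f$dotbracket), nchar(f$sequence))
    # structure must parse and respect the minimum hairpin loop
    pt <- parseDotBracket(f$dotbracket)
    paired <- which(!is.na(pt))
    if (length(paired)) expect_true(all(abs(pt[paired] - paired) >= 4))
  }
})

test_that("the internal folder is optimal against exhaustive enumeration", {
  set.seed(22)
  for (i in 1:12) {
    s <- randomRna(sample(8:14, 1), gc = runif(1, 0.3, 0.7))
    expect_equal(foldRNA(s)$delta_g, oracleMinEnergy(s), info = s)
  }
})

test_that("a pluggable backend overrides the internal folder", {
  flat <- function(seq) list(dotbracket = strrep(".", nchar(seq)), delta_g = 0)
  f <- foldRNA("GGGGAAAACCCC", backend = flat)
  expect_equal(f$delta_g, 0)
  expect_equal(f$dotbracket, "............")
})

test_that("dot-bracket parsing recovers pairs and rejects bad input", {
  expect_equal(parseDotBracket("((..))"), c(6L, 5L, NA, NA, 2L, 1L))
  expect_true(all(is.na(parseDotBracket("...."))))
  expect_error(parseDotBracket("(()"), "index 1")
  expect_error(parseDotBracket("())"), "index 3")
  expect_error(parseDotBracket("(.x)"), "'x' at index 3")
})

test_that("decomposition matches hand-derived elements", {
  el <- decomposeStructure(strrep(".", 12))
  expect_equal(el$kind, "exterior_segment")
  expect_equal(el$length, 12)

  el <- decomposeStructure("((((....))))")
  expect_equal(sort(el$kind), c("hairpin_loop", "stem"))
  expect_equal(el$length[el$kind == "stem"], 4)
  expect_equal(el$length[el$kind == "hairpin_loop"], 4)

  el <- decomposeStructure("((((...((((...........))))...))))")
  expect_equal(sum(el$kind == "stem"), 2)
  expect_equal(el$length[el$kind == "interior_loop"], 6)
  expect_equal(el$length[el$kind == "hairpin_loop"], 11)

  # bulge: unpaired run on one side between two helices
  el <- decomposeStructure("((((..((((....))))))))")
  expect_equal(el$length[el$kind == "bulge_loop"], 2)

  # multibranch: two helices inside a closing pair
  el <- decomposeStructure("((..((((...))))..((((...))))..))")
  expect_equal(el$length[el$kind == "multibranch_loop"], 6)
})

test_that("stem energies are attributed from the stack table", {
  el <- decomposeStructure("((((....))))", sequence = "GGGGAAAACCCC")
  expect_equal(el$element_dg[el$kind == "stem"],
               3 * rnaStackTable()["GC", "CG"])
})

test_that("decomposition partitions every position exactly once", {
  set.seed(23)
  for (i in 1:200) {
    n <- sample(10:80, 1)
    db <- randomDotbracket(n)
    el <- decomposeStructure(db)
    stems <- el[el$kind == "stem", , drop = FALSE]
    loops <- el[el$kind != "stem", , drop = FALSE]
    expect_equal(sum(loops$length) + 2 * sum(stems$length), n, info = db)
    covered <- c(unlist(loops$positions), unlist(stems$positions))
    expect_equal(sort(covered), 0:(n - 1), info = db)
  }
})

test_that("run classification agrees with direct pair-table inspection", {
  set.seed(24)
  for (i in 1:200) {
    db <- randomDotbracket(sample(15:70, 1))
    el <- decomposeStructure(db)
    runs <- oracleClassifyRuns(db)
    for (r in runs) {
      pos0 <- (r$from:r$to) - 1L
      ours <- el$kind[vapply(el$positions, function(p) all(pos0 %in% p),
                             logical(1))]
      expect_equal(unique(ours), r$kind, info = db)
    }
  }
})

test_that("DSE labels flip exactly at the kind-specific cutoffs", {
  mk <- function(kind, len) data.frame(kind = kind, length = len,
                                       positions = I(list(integer(0))),
                                       element_dg = NA_real_,
                                       label = NA_character_)
  cases <- rbind(
    cbind(mk("hairpin_loop", 10), want = "neutral"),
    cbind(mk("hairpin_loop", 11), want = "DSE"),
    cbind(mk("interior_loop", 8), want = "neutral"),
    cbind(mk("interior_loop", 9), want = "DSE"),
    cbind(mk("bulge_loop", 6), want = "neutral"),
    cbind(mk("bulge_loop", 7), want = "DSE"),
    cbind(mk("multibranch_loop", 10), want = "neutral"),
    cbind(mk("multibranch_loop", 11), want = "DSE"),
    cbind(mk("exterior_segment", 10), want = "neutral"),
    cbind(mk("exterior_segment", 11), want = "DSE"),
    cbind(mk("stem", 4), want = "SE"))
  got <- labelElements(cases)
  expect_equal(got$label, cases$want)
})

test_that("lowering a cutoff never removes a DSE label", {
  set.seed(25)
  for (i in 1:50) {
    el <- decomposeStructure(randomDotbracket(60))
    strict <- labelElements(el, dseCutoffs())
    loose <- labelElements(el, dseCutoffs(hairpin = 5, interior = 5,
                                          bulge = 3, multibranch = 5,
                                          exterior = 5))
    wasDse <- strict$label == "DSE"
    expect_true(all(loose$label[wasDse] == "DSE"))
  }
})
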