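test_that("planted perfect sites are recovered with exact coordinates", {
  spec <- simulationSpec(seed = 101, nUtrs = 20, utrLength = 200)
  sim <- simulateUtrs(spec)
  expect_equal(nrow(sim$truth), 20)
  hits <- scanSeedSites(spec$mirnas, sim$utrs)
  found <- merge(sim$truth, hits,
                 by = c("gene", "mirna", "start", "end", "site_class"))
  expect_equal(nrow(found), 20)
  expect_true(all(found$mismatches.y == 0))
})

test_that("planted mismatch and wobble counts are what the scanner reports", {
  panel <- mirnaProbePanel()
  ps <- data.frame(utr = 1:12,
                   mirna = rep(names(panel)[1:4], 3),
                   class = rep(c("6mer-seed", "7mer", "8mer"), each = 4),
                   mismatches = rep(c(0L, 1L, 1L), each = 4),
                   wobbles = rep(c(1L, 0L, 1L), each = 4),
                   position = NA_integer_)
  spec <- simulationSpec(seed = 102, nUtrs = 12, utrLength = 150,
                         plantedSites = ps)
  sim <- simulateUtrs(spec)
  hits <- scanSeedSites(spec$mirnas, sim$utrs)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    hit <- hits[hits$gene == tr$gene & hits$mirna == tr$mirna &
                hits$start == tr$start & hits$end == tr$end, ]
    expect_equal(nrow(hit), 1, info = paste(tr$gene, tr$mirna))
    expect_equal(hit$site_class, tr$site_class)
    expect_equal(hit$mismatches, tr$mismatches)
    expect_equal(hit$wobbles, tr$wobbles)
  }
})

test_that("background composition follows the GC dial", {
  spec <- simulationSpec(seed = 103, nUtrs = 2, utrLength = 400,
                         backgroundGc = 0, plantedSites = data.frame(
                           utr = integer(0), mirna = character(0),
                           class = character(0), mismatches = integer(0),
                           wobbles = integer(0), position = integer(0)))
  sim <- simulateUtrs(spec)
  chars <- unique(unlist(strsplit(as.character(sim$utrs), "")))
  expect_true(all(chars %in% c("A", "U")))
})

test_that("generation is deterministic and leaves the caller RNG alone", {
  spec <- simulationSpec(seed = 104, nUtrs = 5)
  a <- simulateUtrs(spec)
  set.seed(999)
  before <- .Random.seed
  b <- simulateUtrs(spec)
  expect_identical(.Random.seed, before)
  expect_identical(as.character(a$utrs), as.character(b$utrs))
  expect_identical(a$truth, b$truth)
  ca <- simulateCq(spec)
  cb <- simulateCq(spec)
  expect_identical(cqValues(ca$cq), cqValues(cb$cq))
})

test_that("noise-free planted shifts reproduce exact fold changes", {
  groups <- c(normal = 10L, adenoma = 10L)
  shifts <- matrix(0, 2, 3, dimnames = list(c("normal", "adenoma"),
                                            c("GENE1", "REFA", "REFB")))
  shifts["adenoma", "GENE1"] <- -2
  spec <- simulationSpec(seed = 105, nPerGroup = groups, cqShifts = shifts,
                         cqNoiseSd = 0)
  sim <- simulateCq(spec)
  dcq <- deltaCq(sim$cq)
  res <- compareGroups(dcq, sampleGroups(sim$cq), "GENE1",
                       "adenoma", "normal")
  expect_equal(res$delta_delta_cq, -2)
  expect_equal(res$fold_change, 4)
})

test_that("a comonotone coupling yields sample Spearman rho of exactly -1", {
  groups <- c(normal = 30L)
  shifts <- matrix(0, 1, 4, dimnames = list("normal",
                                            c("GENE1", "MIR1", "REFA", "REFB")))
  spec <- simulationSpec(seed = 106, nPerGroup = groups, cqShifts = shifts,
                         coupling = list(mirnaAssay = "MIR1",
                                         geneAssay = "GENE1", rho = -1))
  sim <- simulateCq(spec)
  cq <- cqValues(sim$cq)
  rho <- correlateExpression(cq["MIR1", ], cq["GENE1", ])$rho
  expect_equal(rho, -1)
})

test_that("the Gaussian copula hits the requested rank correlation", {
  groups <- c(normal = 200L)
  shifts <- matrix(0, 1, 4, dimnames = list("normal",
                                            c("GENE1", "MIR1", "REFA", "REFB")))
  spec <- simulationSpec(seed = 107, nPerGroup = groups, cqShifts = shifts,
                         coupling = list(mirnaAssay = "MIR1",
                                         geneAssay = "GENE1", rho = -0.5))
  sim <- simulateCq(spec)
  cq <- cqValues(sim$cq)
  rho <- correlateExpression(cq["MIR1", ], cq["GENE1", ])$rho
  expect_lt(abs(rho - (-0.5)), 0.12)
})

test_that("written inputs round-trip through the readers", {
  dir <- withr::local_tempdir()
  spec <- simulationSpec(seed = 108, nUtrs = 4)
  paths <- writeSimulatedInputs(spec, dir)
  expect_true(all(file.exists(paths)))
  utrs <- readUtrFasta(paths[["utr_fasta"]])
  expect_equal(length(utrs), 4)
  mirs <- readMirnaTable(paths[["mirna_table"]])
  expect_equal(names(mirs), names(spec$mirnas))
  x <- readCqTable(paths[["cq_table"]])
  direct <- simulateCq(spec)
  expect_equal(cqValues(x), round(cqValues(direct$cq), 6),
               tolerance = 1e-6)
  expect_equal(sampleGroups(x), sampleGroups(direct$cq))
})

test_that("invalid specs are rejected", {
  expect_error(simulationSpec(backgroundGc = 1.2), "backgroundGc")
  expect_error(simulationSpec(nPerGroup = c(normal = 2L)), ">= 3")
  sh <- matrix(1, 1, 3, dimnames = list("normal", c("GENE1", "REFA", "REFB")))
  expect_error(simulationSpec(nPerGroup = c(normal = 5L), cqShifts = sh),
               "shift 0")
})
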