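makeCq <- function(cq, groups, roles, paired = NULL) {
  CqExperiment(cq, group = groups, role = roles, pairedNormal = paired)
}

test_that("CqExperiment validates roles, groups and Cq range", {
  m <- matrix(c(25, 27, 30, 31), nrow = 2,
              dimnames = list(c("R1", "T1"), c("s1", "s2")))
  x <- makeCq(m, c("normal", "adenoma"), c("reference", "target"))
  expect_s4_class(x, "CqExperiment")
  expect_equal(referenceAssays(x), "R1")
  expect_error(makeCq(m, c("normal", "adenoma"), c("target", "target")),
               "reference")
  bad <- m; bad[1, 1] <- 50
  expect_error(makeCq(bad, c("normal", "adenoma"), c("reference", "target")),
               "45")
})

test_that("standard-curve efficiency fits are exact for noise-free series", {
  d <- c(5, 25, 125, 625)
  fit <- fitEfficiency(d, 20 + log2(d))
  expect_equal(fit$efficiency, 2.0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-12)
  expect_lt(fit$slope, 0)
  expect_true(fit$accepted)

  # planted efficiency 1.9 is recovered by inverting the Cq model
  fit19 <- fitEfficiency(d, 21 + log(d) / log(1.9))
  expect_equal(fit19$efficiency, 1.9, tolerance = 1e-9)

  expect_error(fitEfficiency(d, rep(20, 4)), "does not vary")
  expect_error(fitEfficiency(c(5, 25), c(20, 22)), ">= 3")
})

test_that("delta-Cq normalizes against the reference aggregate", {
  m <- matrix(c(25, 27, 30), nrow = 3,
              dimnames = list(c("R1", "R2", "T1"), "s1"))
  x <- makeCq(m, "normal", c("reference", "reference", "target"))
  expect_equal(unname(deltaCq(x)["T1", "s1"]), 4)  # 30 - mean(25, 27)

  m2 <- matrix(rep(28, 3), nrow = 3,
               dimnames = list(c("R1", "R2", "T1"), "s1"))
  x2 <- makeCq(m2, "normal", c("reference", "reference", "target"))
  expect_equal(unname(deltaCq(x2)["T1", "s1"]), 0)
})

test_that("normalization cancels per-sample shifts", {
  set.seed(41)
  m <- matrix(runif(4 * 6, 20, 30), nrow = 4,
              dimnames = list(c("R1", "R2", "T1", "T2"), paste0("s", 1:6)))
  x <- makeCq(m, rep("normal", 6),
              c("reference", "reference", "target", "target"))
  shifted <- sweep(m, 2, runif(6, -3, 3), "+")
  xs <- makeCq(shifted, rep("normal", 6),
               c("reference", "reference", "target", "target"))
  expect_equal(deltaCq(xs), deltaCq(x), tolerance = 1e-12)
})

test_that("samples with missing references are excluded with a reason", {
  m <- matrix(c(25, 30, NA, 31), nrow = 2,
              dimnames = list(c("R1", "T1"), c("s1", "s2")))
  x <- makeCq(m, c("normal", "normal"), c("reference", "target"))
  expect_message(dcq <- deltaCq(x), "s2")
  expect_equal(attr(dcq, "excluded"), "s2")
  expect_true(is.na(dcq["T1", "s2"]))
})

test_that("efficiency correction rescales each assay to a log2 basis", {
  m <- matrix(c(25, 30), nrow = 2, dimnames = list(c("R1", "T1"), "s1"))
  x <- makeCq(m, "normal", c("reference", "target"))
  eff <- c(R1 = 2, T1 = 1.9)
  dcq <- deltaCq(x, efficiencyCorrection = TRUE, efficiencies = eff)
  expect_equal(unname(dcq["T1", "s1"]), log2(1.9) * 30 - 25)
  expect_error(deltaCq(x, efficiencyCorrection = TRUE), "efficiency")
})

test_that("group contrasts give the documented fold-change conventions", {
  dcq <- matrix(c(rep(4, 5), rep(5, 5)), nrow = 1,
                dimnames = list("T1", paste0("s", 1:10)))
  groups <- stats::setNames(rep(c("adenoma", "normal"), each = 5),
                            colnames(dcq))
  res <- compareGroups(dcq, groups, "T1", "adenoma", "normal")
  expect_equal(res$delta_delta_cq, -1)
  expect_equal(res$fold_change, 2)
  expect_equal(res$direction, "up")

  # a planted downregulation of +2.632 cycles reports as ~6.2-fold down
  dcq2 <- matrix(c(rep(2.632, 5), rep(0, 5)), nrow = 1,
                 dimnames = list("T1", paste0("s", 1:10)))
  res2 <- compareGroups(dcq2, groups, "T1", "adenoma", "normal")
  expect_equal(res2$fold_change, 2^(-2.632))
  expect_equal(res2$fold_change, 1 / 6.20, tolerance = 0.002)
  expect_match(res2$fold_display, "6.20-fold down")
  expect_equal(res2$log2_fold, -2.632)
})

test_that("identical paired groups give no effect and p = 1", {
  dcq <- matrix(rep(c(3, 4, 5), 2), nrow = 1,
                dimnames = list("T1", paste0("s", 1:6)))
  groups <- stats::setNames(rep(c("crc_n0", "normal"), each = 3),
                            colnames(dcq))
  paired <- stats::setNames(c("s4", "s5", "s6", NA, NA, NA), colnames(dcq))
  res <- compareGroups(dcq, groups, "T1", "crc_n0", "normal",
                       paired = TRUE, pairedNormal = paired)
  expect_equal(res$delta_delta_cq, 0)
  expect_equal(res$fold_change, 1)
  expect_equal(res$p_value, 1)
  expect_equal(res$test_name, "wilcoxon_signed_rank")
})

test_that("insufficient samples raise an analysis error listing counts", {
  dcq <- matrix(1:4, nrow = 1, dimnames = list("T1", paste0("s", 1:4)))
  groups <- stats::setNames(c("adenoma", "adenoma", "normal", "normal"),
                            colnames(dcq))
  expect_error(compareGroups(dcq, groups, "T1", "adenoma", "normal"),
               "got 2 and 2")
  expect_error(compareIndependentDdcq(c(1, 2), c(1, 2, 3)), "got 2 and 3")
})

test_that("the Mann-Whitney statistic equals the brute-force win count", {
  set.seed(42)
  a <- rnorm(10) + 2
  b <- rnorm(10)
  res <- compareIndependentDdcq(a, b, assay = "T1")
  wins <- sum(outer(a, b, ">"))
  expect_equal(res$statistic, wins)
  expect_lt(res$p_value, 0.05)

  same <- compareIndependentDdcq(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$p_value, 1)
})

test_that("Spearman correlation handles perfect and tied cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlateExpression(x, x)$rho, 1)
  expect_equal(correlateExpression(x, -x)$rho, -1)
  expect_equal(correlateExpression(x, x)$p, 0)

  # 8 paired values with one tie: compare to hand-assigned average ranks
  xs <- c(10, 20, 30, 40, 50, 60, 70, 80)
  ys <- c(3, 1, 4, 4, 6, 5, 8, 9)       # tie at value 4 (ranks 2.5, 2.5)
  rx <- 1:8
  ry <- c(2, 1, 3.5, 3.5, 6, 5, 7, 8)
  wantRho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(correlateExpression(xs, ys)$rho, wantRho)

  expect_error(correlateExpression(1:3, 1:3), ">= 4")
})

test_that("malignancy levels code the progression ordinally", {
  expect_equal(
    malignancyLevel(c("normal", "adenoma", "adenoma_early_ca",
                      "crc_n0", "crc_nplus")),
    0:4)
  expect_error(malignancyLevel("polyp"), "polyp")
})

test_that("fold change is strictly decreasing in delta-delta-Cq", {
  dd <- seq(-3, 3, by = 0.5)
  folds <- 2^(-dd)
  expect_true(all(diff(folds) < 0))
  expect_equal(folds * rev(folds), rep(1, length(dd)))
})
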