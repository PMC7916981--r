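#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats lm coef rnorm runif wilcox.test pt complete.cases sd cor
NULL

#' Quantification-cycle experiment container
#'
#' A `SummarizedExperiment` subclass holding a Cq matrix (assays x
#' samples) from qPCR. `rowData` carries the assay `role` (`"target"` or
#' `"reference"`); `colData` carries the sample `group` and an optional
#' `paired_normal` link naming the corresponding normal-mucosa sample of
#' a tumour sample. Cq values lie in (0, 45] or are `NA` (not detected).
#'
#' @export
setClass("CqExperiment", contains = "SummarizedExperiment")

setValidity("CqExperiment", function(object) {
  msg <- character()
  if (!"cq" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'cq' is required")
  rd <- rowData(object)
  if (!"role" %in% colnames(rd)) {
    msg <- c(msg, "rowData must have a 'role' column")
  } else {
    if (!all(rd$role %in% c("target", "reference")))
      msg <- c(msg, "assay role must be 'target' or 'reference'")
    if (!any(rd$role == "reference"))
      msg <- c(msg, "at least one reference assay is required")
  }
  cd <- colData(object)
  if (!"group" %in% colnames(cd)) {
    msg <- c(msg, "colData must have a 'group' column")
  } else if (any(is.na(cd$group) | cd$group == "")) {
    msg <- c(msg, "every sample needs a group label")
  }
  if ("cq" %in% SummarizedExperiment::assayNames(object)) {
    cq <- assay(object, "cq")
    if (any(!is.na(cq) & (cq <= 0 | cq > 45)))
      msg <- c(msg, "Cq values must lie in (0, 45] or be NA")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CqExperiment
#'
#' @param cq Numeric matrix of quantification cycles, assays in rows,
#'   samples in columns; dimnames required. `NA` marks a not-detected
#'   reaction.
#' @param group Character vector of sample group labels, one per column.
#' @param role Character vector of assay roles (`"target"` /
#'   `"reference"`), one per row.
#' @param pairedNormal Optional character vector linking each sample to
#'   its corresponding normal sample (`NA` where not applicable).
#' @return A [CqExperiment-class].
#' @export
CqExperiment <- function(cq, group, role, pairedNormal = NULL) {
  cq <- as.matrix(cq)
  if (is.null(rownames(cq)) || is.null(colnames(cq)))
    stop("cq matrix needs assay rownames and sample colnames", call. = FALSE)
  cd <- S4Vectors::DataFrame(group = as.character(group), row.names = colnames(cq))
  if (!is.null(pairedNormal)) cd$paired_normal <- as.character(pairedNormal)
  rd <- S4Vectors::DataFrame(role = as.character(role), row.names = rownames(cq))
  new("CqExperiment",
      SummarizedExperiment(assays = list(cq = cq), rowData = rd, colData = cd))
}

setMethod("show", "CqExperiment", function(object) {
  cq <- assay(object, "cq")
  cat(sprintf("CqExperiment: %d assay(s) x %d sample(s)\n", nrow(cq), ncol(cq)))
  cat("  reference assays:", paste(referenceAssays(object), collapse = ", "), "\n")
  grp <- table(sampleGroups(object))
  cat("  groups:", paste(sprintf("%s(%d)", names(grp), grp), collapse = ", "), "\n")
  cat(sprintf("  not detected: %d of %d Cq values\n", sum(is.na(cq)), length(cq)))
  invisible(object)
})

#' @rdname cqAccessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
#' @rdname cqAccessors
#' @export
setGeneric("assayRoles", function(x) standardGeneric("assayRoles"))
#' @rdname cqAccessors
#' @export
setGeneric("referenceAssays", function(x) standardGeneric("referenceAssays"))
#' @rdname cqAccessors
#' @export
setGeneric("pairedNormal", function(x) standardGeneric("pairedNormal"))
#' @rdname cqAccessors
#' @export
setGeneric("cqValues", function(x) standardGeneric("cqValues"))

#' Accessors for CqExperiment
#'
#' `sampleGroups()` returns the per-sample group labels; `assayRoles()`
#' the per-assay target/reference roles; `referenceAssays()` the names
#' of the reference assays; `pairedNormal()` the per-sample link to the
#' corresponding normal sample (or `NULL`); `cqValues()` the Cq matrix.
#'
#' @param x A [CqExperiment-class].
#' @name cqAccessors
NULL

#' @rdname cqAccessors
setMethod("sampleGroups", "CqExperiment", function(x) {
  stats::setNames(colData(x)$group, colnames(x))
})
#' @rdname cqAccessors
setMethod("assayRoles", "CqExperiment", function(x) {
  stats::setNames(rowData(x)$role, rownames(x))
})
#' @rdname cqAccessors
setMethod("referenceAssays", "CqExperiment", function(x) {
  rownames(x)[rowData(x)$role == "reference"]
})
#' @rdname cqAccessors
setMethod("pairedNormal", "CqExperiment", function(x) {
  cd <- colData(x)
  if (!"paired_normal" %in% colnames(cd)) return(NULL)
  stats::setNames(cd$paired_normal, colnames(x))
})
#' @rdname cqAccessors
setMethod("cqValues", "CqExperiment", function(x) assay(x, "cq"))

#' Read a Cq table from long-format TSV
#'
#' @param path TSV with columns `sample`, `group`, `assay`, `role`,
#'   `cq`, and optionally `paired_normal_id`. Empty or `ND` Cq entries
#'   are treated as not detected.
#' @return A [CqExperiment-class].
#' @export
readCqTable <- function(path) {
  if (!file.exists(path)) stop("Cq table not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample", "group", "assay", "role", "cq")
  miss <- setdiff(req, colnames(tab))
  if (length(miss))
    stop("Cq table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab$cq[tab$cq %in% c("", "ND", "NA")] <- NA
  tab$cq <- as.numeric(tab$cq)
  samples <- unique(tab$sample)
  assays <- unique(tab$assay)
  cq <- matrix(NA_real_, nrow = length(assays), ncol = length(samples),
               dimnames = list(assays, samples))
  cq[cbind(match(tab$assay, assays), match(tab$sample, samples))] <- tab$cq
  group <- tab$group[match(samples, tab$sample)]
  role <- tab$role[match(assays, tab$assay)]
  paired <- NULL
  if ("paired_normal_id" %in% colnames(tab)) {
    paired <- tab$paired_normal_id[match(samples, tab$sample)]
    paired[paired == ""] <- NA
  }
  CqExperiment(cq, group = group, role = role, pairedNormal = paired)
}

#' Fit amplification efficiency from a dilution series
#'
#' Least-squares regression of Cq on log10 of the relative template
#' concentration (`-log10(dilution factor)`), the standard-curve
#' convention, so a perfect-doubling assay has slope -3.32. Efficiency is
#' the amplification factor per cycle, `10^(-1/slope)` (2.0 = perfect
#' doubling). Fits are flagged `accepted` when the slope is negative and
#' the efficiency lies in (1, 2.3].
#'
#' @param dilution Numeric vector of dilution factors (e.g.
#'   `c(5, 25, 125, 625)` for a 4-point 5-fold series); at least 3
#'   distinct values.
#' @param cq Observed Cq at each dilution.
#' @param assay Optional assay label carried into the result.
#' @return A one-row data.frame: `assay`, `slope` (Cq per log10
#'   concentration), `efficiency`, `r_squared`, `accepted`.
#' @examples
#' d <- c(5, 25, 125, 625)
#' fitEfficiency(d, 20 + log2(d))  # efficiency 2.0, r^2 = 1
#' @export
fitEfficiency <- function(dilution, cq, assay = NA_character_) {
  if (length(dilution) != length(cq))
    stop("dilution and cq must have equal length", call. = FALSE)
  ok <- complete.cases(dilution, cq)
  dilution <- dilution[ok]; cq <- cq[ok]
  if (length(unique(dilution)) < 3)
    stop("efficiency fit needs >= 3 distinct dilution points", call. = FALSE)
  x <- -log10(dilution)  # log10 relative concentration
  fit <- lm(cq ~ x)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || abs(slope) < 1e-12)
    stop("efficiency undefined: Cq does not vary with dilution", call. = FALSE)
  ssTot <- sum((cq - mean(cq))^2)
  r2 <- if (ssTot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ssTot
  eff <- 10^(-1 / slope)
  data.frame(
    assay = assay, slope = slope, efficiency = eff, r_squared = r2,
    accepted = slope < 0 && eff > 1 && eff <= 2.3,
    stringsAsFactors = FALSE
  )
}

#' Reference-gene normalized delta-Cq
#'
#' For each target assay and sample, `deltaCq = Cq_target - aggregate(Cq
#' of reference assays)`. The default reference aggregate is the
#' arithmetic mean of reference Cq values -- equivalent to the geometric
#' mean of the linear reference quantities, the standard multi-reference
#' normalization; `referenceAggregate = "geometric"` instead takes a
#' literal geometric mean of the Cq values for sensitivity checks. With
#' `efficiencyCorrection`, every Cq is first rescaled to a common log2
#' basis as `log2(E) * Cq` using the per-assay efficiencies. Samples in
#' which any reference assay is not detected are excluded (their columns
#' are `NA`; the reason is recorded in the `"excluded"` attribute);
#' not-detected targets stay `NA` and are never imputed.
#'
#' @param x A [CqExperiment-class].
#' @param efficiencyCorrection Logical (default `FALSE`).
#' @param efficiencies Named numeric vector of per-assay amplification
#'   factors (required if `efficiencyCorrection = TRUE`).
#' @param referenceAggregate `"mean"` (default) or `"geometric"`.
#' @return A numeric matrix of delta-Cq values, target assays x samples,
#'   with an `"excluded"` attribute naming samples dropped for missing
#'   references.
#' @export
deltaCq <- function(x, efficiencyCorrection = FALSE, efficiencies = NULL,
                    referenceAggregate = c("mean", "geometric")) {
  referenceAggregate <- match.arg(referenceAggregate)
  cq <- cqValues(x)
  refs <- referenceAssays(x)
  if (!length(refs)) stop("no reference assay designated", call. = FALSE)
  if (efficiencyCorrection) {
    if (is.null(efficiencies) || !all(rownames(cq) %in% names(efficiencies)))
      stop("efficiencyCorrection requires a named efficiency for every assay",
           call. = FALSE)
    cq <- cq * log2(efficiencies[rownames(cq)])
  }
  refCq <- cq[refs, , drop = FALSE]
  refAgg <- if (referenceAggregate == "mean") colMeans(refCq)
            else exp(colMeans(log(refCq)))
  excluded <- colnames(cq)[is.na(refAgg)]
  targets <- rownames(cq)[assayRoles(x) == "target"]
  dcq <- sweep(cq[targets, , drop = FALSE], 2, refAgg, "-")
  if (length(excluded))
    message("excluding sample(s) with missing reference Cq: ",
            paste(excluded, collapse = ", "))
  attr(dcq, "excluded") <- excluded
  dcq
}

#' Compare expression between two sample groups
#'
#' Computes the group contrast `deltaDeltaCq = mean deltaCq(groupA) -
#' mean deltaCq(groupB)` (or medians) and the fold change
#' `2^(-deltaDeltaCq)`, and tests the difference with the Wilcoxon
#' signed-rank test (paired; samples linked via `pairedNormal`) or the
#' Mann-Whitney U test (independent groups), two-sided. Exact p-values
#' are used for small untied samples (n <= 12), the normal approximation
#' with tie correction otherwise. Fold changes below 1 are additionally
#' reported as x-fold down (reciprocal); the signed log2 value is kept in
#' machine-readable form.
#'
#' @param dcq Delta-Cq matrix from [deltaCq()].
#' @param groups Named group labels per sample (e.g.
#'   `sampleGroups(x)`).
#' @param assay Target assay (row of `dcq`) to compare.
#' @param groupA,groupB Group labels; `groupB` is the baseline (e.g.
#'   normal mucosa).
#' @param paired Use the signed-rank test on linked samples.
#' @param pairedNormal Named vector linking each `groupA` sample to its
#'   `groupB` sample (required when `paired = TRUE`).
#' @param center `"mean"` (default) or `"median"` for the group summary.
#' @return A one-row data.frame: `assay`, `comparison`, `n_a`, `n_b`,
#'   `delta_delta_cq`, `log2_fold`, `fold_change`, `direction`,
#'   `fold_display`, `test_name`, `statistic`, `p_value`.
#' @export
compareGroups <- function(dcq, groups, assay, groupA, groupB,
                          paired = FALSE, pairedNormal = NULL,
                          center = c("mean", "median")) {
  center <- match.arg(center)
  if (!assay %in% rownames(dcq))
    stop(sprintf("assay '%s' not found in delta-Cq matrix", assay), call. = FALSE)
  v <- dcq[assay, ]
  groups <- groups[colnames(dcq)]
  if (paired) {
    if (is.null(pairedNormal))
      stop("paired comparison requires pairedNormal links", call. = FALSE)
    aSamp <- names(groups)[groups == groupA]
    link <- pairedNormal[aSamp]
    ok <- !is.na(link) & link %in% names(v) & !is.na(v[aSamp]) & !is.na(v[link])
    a <- v[aSamp][ok]; b <- v[link[ok]]
    if (length(a) < 3)
      stop(sprintf("paired comparison needs >= 3 usable pairs, got %d", length(a)),
           call. = FALSE)
    test <- wilcoxonSignedRank(a, b)
    testName <- "wilcoxon_signed_rank"
  } else {
    a <- v[groups == groupA]; a <- a[!is.na(a)]
    b <- v[groups == groupB]; b <- b[!is.na(b)]
    if (length(a) < 3 || length(b) < 3)
      stop(sprintf("group comparison needs >= 3 usable samples per group, got %d and %d",
                   length(a), length(b)), call. = FALSE)
    test <- mannWhitneyU(a, b)
    testName <- "mann_whitney_u"
  }
  summarize <- if (center == "mean") mean else stats::median
  ddcq <- summarize(a) - summarize(b)
  fold <- 2^(-ddcq)
  direction <- if (fold >= 1) "up" else "down"
  display <- if (fold >= 1) sprintf("%.2f-fold up", fold)
             else sprintf("%.2f-fold down", 1 / fold)
  data.frame(
    assay = assay, comparison = paste(groupA, "vs", groupB),
    n_a = length(a), n_b = length(b),
    delta_delta_cq = ddcq, log2_fold = -ddcq, fold_change = fold,
    direction = direction, fold_display = display,
    test_name = testName, statistic = test$statistic, p_value = test$p,
    stringsAsFactors = FALSE
  )
}

# Exact for small untied samples, normal approximation with tie/continuity
# correction otherwise. All-zero paired differences give p = 1 by definition.
wilcoxonSignedRank <- function(a, b) {
  d <- a - b
  if (all(d == 0)) return(list(statistic = 0, p = 1))
  nz <- d[d != 0]
  exact <- length(nz) <= 12 && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = exact,
                                     correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

mannWhitneyU <- function(a, b) {
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && length(a) <= 12 && length(b) <= 12
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # degenerate: no variance anywhere
  list(statistic = unname(wt$statistic), p = min(p, 1))
}

#' Per-sample delta-delta-Cq against the corresponding normal sample
#'
#' For each sample of `group`, subtracts the delta-Cq of its linked
#' normal-mucosa sample, giving one delta-delta-Cq per case. These are
#' the units of analysis for comparisons between tumour groups.
#'
#' @inheritParams compareGroups
#' @param group Group whose samples are converted.
#' @return Named numeric vector of per-sample delta-delta-Cq values
#'   (samples without a usable link are dropped).
#' @export
pairedDeltaDelta <- function(dcq, groups, assay, group, pairedNormal) {
  v <- dcq[assay, ]
  groups <- groups[colnames(dcq)]
  samp <- names(groups)[groups == group]
  link <- pairedNormal[samp]
  ok <- !is.na(link) & link %in% names(v) & !is.na(v[samp]) & !is.na(v[link])
  stats::setNames(v[samp][ok] - v[link[ok]], samp[ok])
}

#' Compare per-sample delta-delta-Cq between two independent groups
#'
#' Mann-Whitney U test on per-case delta-delta-Cq values (each tumour
#' sample normalized to its corresponding normal first), two-sided.
#'
#' @param ddcqA,ddcqB Numeric vectors of per-sample delta-delta-Cq
#'   values for the two groups.
#' @param assay Assay label carried into the result.
#' @param comparison Comparison label.
#' @param center `"mean"` or `"median"` group summary.
#' @return A one-row data.frame in the same shape as [compareGroups()].
#' @export
compareIndependentDdcq <- function(ddcqA, ddcqB, assay = NA_character_,
                                   comparison = "A vs B",
                                   center = c("mean", "median")) {
  center <- match.arg(center)
  ddcqA <- ddcqA[!is.na(ddcqA)]; ddcqB <- ddcqB[!is.na(ddcqB)]
  if (length(ddcqA) < 3 || length(ddcqB) < 3)
    stop(sprintf("independent delta-delta-Cq comparison needs >= 3 values per group, got %d and %d",
                 length(ddcqA), length(ddcqB)), call. = FALSE)
  test <- mannWhitneyU(ddcqA, ddcqB)
  summarize <- if (center == "mean") mean else stats::median
  diff <- summarize(ddcqA) - summarize(ddcqB)
  fold <- 2^(-diff)
  data.frame(
    assay = assay, comparison = comparison,
    n_a = length(ddcqA), n_b = length(ddcqB),
    delta_delta_cq = diff, log2_fold = -diff, fold_change = fold,
    direction = if (fold >= 1) "up" else "down",
    fold_display = if (fold >= 1) sprintf("%.2f-fold up", fold)
                   else sprintf("%.2f-fold down", 1 / fold),
    test_name = "mann_whitney_u", statistic = test$statistic,
    p_value = test$p,
    stringsAsFactors = FALSE
  )
}

#' Spearman rank correlation between two expression profiles
#'
#' Rank correlation with average ranks for ties and a two-tailed p-value
#' from the t approximation. Used both for miRNA-target anticorrelation
#' (negative rho suggests repression) and for correlation with the level
#' of malignancy (see [malignancyLevel()]).
#'
#' @param x,y Paired numeric observations (same samples); pairs with
#'   missing values are dropped; at least 4 complete pairs required.
#' @return A list with `rho` and `p`.
#' @export
correlateExpression <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4)
    stop(sprintf("correlation needs >= 4 complete pairs, got %d", n), call. = FALSE)
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Ordinal malignancy level of sample groups
#'
#' Codes the adenoma-carcinoma progression ordinally for rank
#' correlation: normal mucosa 0, adenoma 1, adenoma with early carcinoma
#' 2, carcinoma without lymph-node metastases 3, with metastases 4.
#'
#' @param groups Character vector of group labels (`normal`, `adenoma`,
#'   `adenoma_early_ca`, `crc_n0`, `crc_nplus`).
#' @return Integer vector of malignancy levels.
#' @export
malignancyLevel <- function(groups) {
  lev <- c(normal = 0L, adenoma = 1L, adenoma_early_ca = 2L,
           crc_n0 = 3L, crc_nplus = 4L)
  bad <- setdiff(unique(groups), names(lev))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  unname(lev[groups])
}
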