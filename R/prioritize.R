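#' Read an evidence table for miRNA-gene pairs
#'
#' Evidence is externally supplied input (database mining is out of
#' scope): per pair, the number of databases reporting it, prior
#' association flags, and whether the miRNA is annotated as a true miRNA.
#'
#' @param path TSV with columns `mirna`, `gene`, `db_count`,
#'   `cancer_assoc`, `crc_assoc`, `gene_assoc`, `direct_validation`,
#'   `mirbase_valid` (flags as TRUE/FALSE or 1/0).
#' @return A data.frame with those columns, flags as logicals.
#' @export
readEvidenceTable <- function(path) {
  if (!file.exists(path)) stop("evidence table not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("mirna", "gene", "db_count", "cancer_assoc", "crc_assoc",
           "gene_assoc", "direct_validation", "mirbase_valid")
  miss <- setdiff(req, colnames(tab))
  if (length(miss))
    stop("evidence table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (fl in req[-(1:3)]) tab[[fl]] <- as.logical(tab[[fl]])
  if (any(tab$db_count < 0)) stop("db_count must be >= 0", call. = FALSE)
  tab
}

#' Gate candidate miRNA-gene pairs on annotation and database support
#'
#' Keeps pairs whose miRNA is annotated as a true miRNA and that either
#' have a known functional association with cancer or are reported by at
#' least two databases for the target gene. Input order is preserved.
#'
#' @param evidence Data.frame as from [readEvidenceTable()].
#' @return The kept subset of `evidence`.
#' @export
gateCandidates <- function(evidence) {
  keep <- evidence$mirbase_valid &
    (evidence$cancer_assoc | evidence$db_count >= 2)
  out <- evidence[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate evidence, sites and structure verdicts into a decision
#'
#' Computes four evidence flags per miRNA-gene pair and applies the
#' inclusion and selection rules:
#'
#' * `flag_two_dbs` -- reported by at least two databases;
#' * `flag_energy` -- folding free-energy constraints met; by default
#'   (`energyRule = "or"`) true when the flank free-energy gap passes
#'   *or* a destabilising element is present (configurable to `"and"`,
#'   or `"gap"` for the gap criterion alone);
#' * `flag_rna22` -- tri-state: `"pass"` when at least one constrained
#'   heteroduplex site meets the energy cutoff, `"near_miss"` when
#'   seed-qualified sites exist but none meets the cutoff, else
#'   `"fail"`. Counts toward selection only when `"pass"`, unless
#'   `nearMissCounts = TRUE`;
#' * `flag_direct_validation` -- carried from the evidence table.
#'
#' A pair is **included** only when a DSE is present in its site window,
#' it has a previous association with the target gene, and a previous
#' CRC association. An included pair is **selected** for the validation
#' shortlist when at least `minFlags` of the four flags are true. Pairs
#' with no sites get `flag_rna22 = "fail"` and `flag_energy = FALSE`.
#' The result is deterministic and invariant to input row order.
#'
#' @param evidence Data.frame as from [readEvidenceTable()].
#' @param rna22 Site table from [rna22Sites()] (with `keepAll = TRUE` if
#'   near-miss reporting is wanted); may be `NULL`.
#' @param verdicts Verdict table from [assessSites()]; may be `NULL`.
#' @param minFlags Selection threshold on the number of true flags
#'   (default 2).
#' @param energyRule One of `"or"`, `"and"`, `"gap"`.
#' @param nearMissCounts Whether a near-miss counts as a true
#'   heteroduplex flag (default `FALSE`).
#' @param knownMirnas,knownGenes Optional vectors of valid identifiers;
#'   evidence rows referencing anything else raise an error listing the
#'   offenders.
#' @return A data.frame with one row per evidence pair: identifiers, the
#'   four flags, `dse_present`, `included`, `selected` and a
#'   human-readable `rationale`, ordered by `gene` then `mirna`.
#' @export
prioritizeTargets <- function(evidence, rna22 = NULL, verdicts = NULL,
                              minFlags = 2, energyRule = c("or", "and", "gap"),
                              nearMissCounts = FALSE,
                              knownMirnas = NULL, knownGenes = NULL) {
  energyRule <- match.arg(energyRule)
  if (!is.null(knownMirnas)) {
    bad <- setdiff(evidence$mirna, knownMirnas)
    if (length(bad))
      stop("evidence references unknown miRNA(s): ",
           paste(sort(bad), collapse = ", "), call. = FALSE)
  }
  if (!is.null(knownGenes)) {
    bad <- setdiff(evidence$gene, knownGenes)
    if (length(bad))
      stop("evidence references unknown gene(s): ",
           paste(sort(bad), collapse = ", "), call. = FALSE)
  }

  key <- function(m, g) paste(m, g, sep = "\r")
  rows <- lapply(seq_len(nrow(evidence)), function(i) {
    ev <- evidence[i, ]
    k <- key(ev$mirna, ev$gene)

    v <- NULL
    if (!is.null(verdicts) && nrow(verdicts))
      v <- verdicts[key(verdicts$mirna, verdicts$gene) == k, , drop = FALSE]
    hasVerdict <- !is.null(v) && nrow(v) > 0
    dse <- hasVerdict && any(v$dse_present)
    gap <- hasVerdict && any(v$energy_gap_pass)
    flagEnergy <- switch(energyRule,
      or = gap || dse,
      and = gap && dse,
      gap = gap)

    r <- NULL
    if (!is.null(rna22) && nrow(rna22))
      r <- rna22[key(rna22$mirna, rna22$gene) == k, , drop = FALSE]
    flagRna22 <- if (is.null(r) || !nrow(r)) "fail"
      else if (any(r$pass)) "pass" else "near_miss"

    flags <- c(
      two_dbs = ev$db_count >= 2,
      energy = flagEnergy,
      rna22 = flagRna22 == "pass" || (nearMissCounts && flagRna22 == "near_miss"),
      direct_validation = isTRUE(ev$direct_validation)
    )
    included <- dse && isTRUE(ev$gene_assoc) && isTRUE(ev$crc_assoc)
    selected <- included && sum(flags) >= minFlags
    rationale <- paste0(
      "dbs=", ev$db_count,
      "; energy[", energyRule, "]=", ifelse(flags[["energy"]], "+", "-"),
      " (gap=", ifelse(gap, "+", "-"), ", dse=", ifelse(dse, "+", "-"), ")",
      "; heteroduplex=", flagRna22,
      "; direct=", ifelse(flags[["direct_validation"]], "+", "-"),
      "; gene_assoc=", ifelse(isTRUE(ev$gene_assoc), "+", "-"),
      "; crc_assoc=", ifelse(isTRUE(ev$crc_assoc), "+", "-"),
      "; flags=", sum(flags), "/", minFlags)
    data.frame(
      mirna = ev$mirna, gene = ev$gene,
      flag_two_dbs = flags[["two_dbs"]],
      flag_energy = flags[["energy"]],
      flag_rna22 = flagRna22,
      flag_direct_validation = flags[["direct_validation"]],
      dse_present = dse,
      included = included, selected = selected,
      rationale = rationale,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a prioritization report
#'
#' Writes the decision table as TSV with stable column and row order
#' (gene, then miRNA), so reruns on the same input are byte-identical.
#'
#' @param results Data.frame from [prioritizeTargets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePrioritizationReport <- function(results, path) {
  if (is.null(results) || !nrow(results))
    stop("no prioritization results to write", call. = FALSE)
  cols <- c("gene", "mirna", "flag_two_dbs", "flag_energy", "flag_rna22",
            "flag_direct_validation", "dse_present", "included", "selected",
            "rationale")
  out <- results[order(results$gene, results$mirna), cols, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
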