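#' Default run configuration
#'
#' All thresholds of the pipeline with their default values: seed-region
#' mismatch/wobble budgets (1/1), heteroduplex energy cutoffs (-12 and
#' -20 kcal/mol; the first is the one prioritization flags are computed
#' at), flank free-energy gap threshold (10 kcal/mol), DSE length
#' cutoffs (hairpin 11, interior 9, bulge 7, multibranch 11, exterior
#' 11), inhibition threshold (-6 kcal/mol) and the selection flag count
#' (2).
#'
#' @return A nested list with entries `paths`, `thresholds`, `flags`,
#'   `seed`.
#' @export
runConfigDefaults <- function() {
  list(
    paths = list(mirna_table = NULL, utr_fasta = NULL, evidence = NULL,
                 cq_table = NULL, out_dir = "mirtaq_out"),
    thresholds = list(
      max_mismatch = 1, max_wobble = 1,
      energy_cutoffs = c(-12, -20),
      gap_threshold = 10,
      dse_hairpin = 11, dse_interior = 9, dse_bulge = 7,
      dse_multibranch = 11, dse_exterior = 11,
      inhibition = -6,
      min_flags = 2),
    flags = list(efficiency_correction = FALSE, near_miss_counts = FALSE),
    seed = 1L
  )
}

#' Read a pipeline run configuration
#'
#' Reads a YAML config, fills unset entries from [runConfigDefaults()]
#' and validates: unknown keys are an error, and every threshold must be
#' present after merging.
#'
#' @param path YAML file; top-level keys `paths`, `thresholds`, `flags`,
#'   `seed`.
#' @return A validated config list of class `RunConfig`.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  asRunConfig(user)
}

#' @rdname readRunConfig
#' @param config A (possibly partial) config list.
#' @export
asRunConfig <- function(config) {
  def <- runConfigDefaults()
  if (is.null(config)) config <- list()
  badTop <- setdiff(names(config), names(def))
  if (length(badTop))
    stop("unknown config key(s): ", paste(badTop, collapse = ", "), call. = FALSE)
  for (sect in c("paths", "thresholds", "flags")) {
    bad <- setdiff(names(config[[sect]]), names(def[[sect]]))
    if (length(bad))
      stop(sprintf("unknown config key(s) under %s: %s", sect,
                   paste(bad, collapse = ", ")), call. = FALSE)
    def[[sect]][names(config[[sect]])] <- config[[sect]]
  }
  if (!is.null(config$seed)) def$seed <- as.integer(config$seed)
  th <- def$thresholds
  if (any(vapply(th, is.null, logical(1))))
    stop("all thresholds must be set", call. = FALSE)
  if (length(th$energy_cutoffs) < 1)
    stop("at least one heteroduplex energy cutoff is required", call. = FALSE)
  class(def) <- "RunConfig"
  def
}

configCutoffs <- function(config) {
  th <- config$thresholds
  dseCutoffs(hairpin = th$dse_hairpin, interior = th$dse_interior,
             bulge = th$dse_bulge, multibranch = th$dse_multibranch,
             exterior = th$dse_exterior)
}

requirePath <- function(config, key) {
  p <- config$paths[[key]]
  if (is.null(p) || !file.exists(p))
    stop(sprintf("config paths$%s missing or file not found: %s",
                 key, if (is.null(p)) "<unset>" else p), call. = FALSE)
  p
}

writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  path
}

#' Run individual pipeline stages or the whole pipeline
#'
#' Each stage reads its inputs from the paths in the config, writes its
#' TSV outputs into `paths$out_dir`, and appends counts to a run log
#' (`run_log.txt`, with the echoed configuration in
#' `config_echo.yaml`). `runAll()` chains scan, accessibility
#' assessment and prioritization, and runs the qPCR analysis if a Cq
#' table is configured. `runSimulate()` writes synthetic inputs for all
#' stages into `out_dir/simulated` and returns a config pointing at
#' them. Outputs are deterministic: rerunning with the same config and
#' seed reproduces files byte for byte.
#'
#' @param config A `RunConfig` from [readRunConfig()] /
#'   [asRunConfig()].
#' @return A named list of output paths (and, for `runSimulate`, the
#'   updated config), invisibly for the run functions.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
runScan <- function(config) {
  mirnas <- readMirnaTable(requirePath(config, "mirna_table"))
  utrs <- readUtrFasta(requirePath(config, "utr_fasta"))
  th <- config$thresholds
  sites <- scanSeedSites(mirnas, utrs, maxMismatch = th$max_mismatch,
                         maxWobble = th$max_wobble)
  sites$alignment <- gsub("\n", "|", sites$alignment, fixed = TRUE)
  rna22 <- rna22Sites(mirnas, utrs, energyCutoff = th$energy_cutoffs[1],
                      maxWobble = th$max_wobble, keepAll = TRUE)
  outDir <- config$paths$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(sites = writeTsv(sites, file.path(outDir, "sites.tsv")),
             rna22 = writeTsv(rna22, file.path(outDir, "rna22_sites.tsv")))
  logRun(config, "scan", c(seed_sites = nrow(sites), rna22_sites = nrow(rna22)))
  invisible(as.list(paths))
}

#' @rdname pipeline
#' @export
runAssess <- function(config) {
  utrs <- readUtrFasta(requirePath(config, "utr_fasta"))
  outDir <- config$paths$out_dir
  sitesPath <- file.path(outDir, "sites.tsv")
  if (!file.exists(sitesPath)) stop("run the scan stage first", call. = FALSE)
  sites <- utils::read.delim(sitesPath, stringsAsFactors = FALSE)
  th <- config$thresholds
  verdicts <- assessSites(utrs, sites, cutoffs = configCutoffs(config),
                          inhibitionDg = th$inhibition,
                          gapThreshold = th$gap_threshold)
  paths <- c(verdicts = writeTsv(verdicts, file.path(outDir, "verdicts.tsv")))
  logRun(config, "assess", c(verdicts = nrow(verdicts),
                             dse_present = sum(verdicts$dse_present)))
  invisible(as.list(paths))
}

#' @rdname pipeline
#' @export
runPrioritize <- function(config) {
  evidence <- readEvidenceTable(requirePath(config, "evidence"))
  outDir <- config$paths$out_dir
  verdicts <- utils::read.delim(file.path(outDir, "verdicts.tsv"),
                                stringsAsFactors = FALSE)
  rna22 <- utils::read.delim(file.path(outDir, "rna22_sites.tsv"),
                             stringsAsFactors = FALSE)
  gated <- gateCandidates(evidence)
  results <- prioritizeTargets(
    gated, rna22 = rna22, verdicts = verdicts,
    minFlags = config$thresholds$min_flags,
    nearMissCounts = isTRUE(config$flags$near_miss_counts))
  if (!nrow(results)) {
    warning("no candidate pairs survived gating; nothing to prioritize")
    return(invisible(list()))
  }
  path <- file.path(outDir, "prioritization.tsv")
  writePrioritizationReport(results, path)
  logRun(config, "prioritize",
         c(pairs = nrow(results), included = sum(results$included),
           selected = sum(results$selected)))
  invisible(list(prioritization = path))
}

#' @rdname pipeline
#' @export
runQpcr <- function(config) {
  x <- readCqTable(requirePath(config, "cq_table"))
  dcq <- suppressMessages(deltaCq(x))
  groups <- sampleGroups(x)
  pn <- pairedNormal(x)
  targets <- rownames(dcq)
  baseline <- "normal"
  rows <- list()
  for (assay in targets) {
    for (g in setdiff(unique(groups), baseline)) {
      res <- tryCatch(
        compareGroups(dcq, groups, assay, g, baseline),
        error = function(e) NULL)
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
    if (!is.null(pn) && all(c("crc_n0", "crc_nplus") %in% groups)) {
      dd0 <- pairedDeltaDelta(dcq, groups, assay, "crc_n0", pn)
      dd1 <- pairedDeltaDelta(dcq, groups, assay, "crc_nplus", pn)
      res <- tryCatch(
        compareIndependentDdcq(dd0, dd1, assay = assay,
                               comparison = "crc_n0 vs crc_nplus (ddCq)"),
        error = function(e) NULL)
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  results <- do.call(rbind, rows)
  results <- results[order(results$assay, results$comparison), , drop = FALSE]
  num <- vapply(results, is.numeric, logical(1))
  results[num] <- lapply(results[num], function(v) round(v, 10))
  outDir <- config$paths$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  path <- writeTsv(results, file.path(outDir, "qpcr_results.tsv"))
  logRun(config, "qpcr", c(comparisons = nrow(results)))
  invisible(list(qpcr = path))
}

#' @rdname pipeline
#' @export
runSimulate <- function(config) {
  spec <- simulationSpec(seed = config$seed)
  simDir <- file.path(config$paths$out_dir, "simulated")
  paths <- writeSimulatedInputs(spec, simDir)
  config$paths$mirna_table <- paths[["mirna_table"]]
  config$paths$utr_fasta <- paths[["utr_fasta"]]
  config$paths$evidence <- paths[["evidence"]]
  config$paths$cq_table <- paths[["cq_table"]]
  logRun(config, "simulate", c(files = length(paths)))
  invisible(list(config = config, paths = as.list(paths)))
}

#' @rdname pipeline
#' @export
runAll <- function(config) {
  out <- list()
  out <- c(out, runScan(config))
  out <- c(out, runAssess(config))
  out <- c(out, runPrioritize(config))
  if (!is.null(config$paths$cq_table)) out <- c(out, runQpcr(config))
  invisible(out)
}

# Append a stage record to the run log; echo the config once per run dir.
# No timestamps: logs must be reproducible byte for byte.
logRun <- function(config, stage, counts) {
  outDir <- config$paths$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  echoPath <- file.path(outDir, "config_echo.yaml")
  cfg <- unclass(config)
  cfg$paths <- cfg$paths[!vapply(cfg$paths, is.null, logical(1))]
  yaml::write_yaml(cfg, echoPath)
  line <- sprintf("[%s] miRtaq %s: %s", stage,
                  as.character(utils::packageVersion("miRtaq")),
                  paste(sprintf("%s=%s", names(counts), counts), collapse = " "))
  cat(line, "\n", sep = "", file = file.path(outDir, "run_log.txt"),
      append = !stage %in% c("scan", "simulate"))
  invisible(NULL)
}
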