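#' Built-in mature miRNA probe panel
#'
#' The eight small-RNA assay sequences used throughout the examples (the
#' seven mature miRNAs plus the RNU6B reference probe), shipped as a
#' plain-text fixture under `inst/extdata/mirna_probes.tsv`.
#'
#' @return A [MiRNASet-class].
#' @export
mirnaProbePanel <- function() {
  readMirnaTable(system.file("extdata", "mirna_probes.tsv",
                             package = "miRtaq", mustWork = TRUE))
}

# Run expr with a local, named RNG stream; the caller's RNG state is
# untouched. All generator randomness flows through this one helper.
withLocalSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

#' Specification for synthetic pipeline inputs
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the study conditions of a five-group FFPE qPCR
#' cohort: group sizes 23/11/13/10/13 (normal mucosa, adenoma, adenoma
#' with early carcinoma, CRC N0, CRC N+), Gaussian Cq noise of 0.25
#' cycles, per-assay baselines drawn once in 18-32 cycles, stable
#' reference assays, and 3'-UTRs of 300 nt with one planted perfect 8mer
#' site per UTR.
#'
#' @param seed RNG seed (integer).
#' @param nUtrs Number of synthetic UTRs.
#' @param utrLength UTR length in nt.
#' @param backgroundGc Background GC fraction in \[0, 1\].
#' @param mirnas A [MiRNASet-class] or named character vector; defaults
#'   to [mirnaProbePanel()] (RNU6B excluded from planting).
#' @param plantedSites `NULL` for the default (one perfect 8mer per UTR,
#'   miRNAs recycled), or a data.frame with columns `utr` (1-based UTR
#'   index), `mirna`, `class` (`"6mer-seed"`, `"7mer"`, `"8mer"`),
#'   `mismatches`, `wobbles`, `position` (0-based site start; `NA` =
#'   random, collision-free).
#' @param nPerGroup Named integer vector of samples per group (all
#'   `>= 3`).
#' @param cqShifts Numeric matrix of true per-group Cq shifts (groups x
#'   assays), in cycles, relative to the assay baseline; reference
#'   assays must have shift 0 everywhere.
#' @param referenceAssays Names of the stable reference assays.
#' @param cqNoiseSd Gaussian Cq noise SD in cycles.
#' @param baselineRange Range the per-assay baseline Cq is drawn from.
#' @param coupling `NULL`, or `list(mirnaAssay=, geneAssay=, rho=)`
#'   planting a rank dependence (Spearman `rho`) between two assays'
#'   noise via a Gaussian copula.
#' @return A validated list of class `SimulationSpec`.
#' @export
simulationSpec <- function(seed = 1L,
                           nUtrs = 8L,
                           utrLength = 300L,
                           backgroundGc = 0.5,
                           mirnas = NULL,
                           plantedSites = NULL,
                           nPerGroup = c(normal = 23L, adenoma = 11L,
                                         adenoma_early_ca = 13L,
                                         crc_n0 = 10L, crc_nplus = 13L),
                           cqShifts = NULL,
                           referenceAssays = c("REFA", "REFB"),
                           cqNoiseSd = 0.25,
                           baselineRange = c(18, 32),
                           coupling = NULL) {
  if (is.null(mirnas)) {
    mirnas <- mirnaProbePanel()
    mirnas <- mirnas[names(mirnas) != "RNU6B"]
  }
  mir <- asNamedCharacter(mirnas, "miRNA")
  if (backgroundGc < 0 || backgroundGc > 1)
    stop("backgroundGc must be in [0, 1]", call. = FALSE)
  if (any(nPerGroup < 3)) stop("nPerGroup must be >= 3", call. = FALSE)
  if (cqNoiseSd < 0) stop("cqNoiseSd must be >= 0", call. = FALSE)
  if (is.null(plantedSites)) {
    plantedSites <- data.frame(
      utr = seq_len(nUtrs),
      mirna = rep(names(mir), length.out = nUtrs),
      class = "8mer", mismatches = 0L, wobbles = 0L, position = NA_integer_,
      stringsAsFactors = FALSE)
  }
  if (!all(plantedSites$class %in% c("6mer-seed", "7mer", "8mer")))
    stop("planted site class must be 6mer-seed, 7mer or 8mer", call. = FALSE)
  if (!all(plantedSites$mirna %in% names(mir)))
    stop("planted site references unknown miRNA", call. = FALSE)
  if (is.null(cqShifts)) {
    groups <- names(nPerGroup)
    assays <- c("GENE1", "MIR1", referenceAssays)
    cqShifts <- matrix(0, nrow = length(groups), ncol = length(assays),
                       dimnames = list(groups, assays))
    # target gene repressed, regulatory miRNA overexpressed in lesions
    cqShifts[, "GENE1"] <- c(0, 2.63, 1.0, 1.0, 2.62)
    cqShifts[, "MIR1"] <- c(0, -3.75, -2.60, -2.88, -1.00)
  }
  if (!all(referenceAssays %in% colnames(cqShifts)))
    stop("reference assays must appear in cqShifts columns", call. = FALSE)
  if (any(cqShifts[, referenceAssays] != 0))
    stop("reference assays must have shift 0 in every group", call. = FALSE)
  if (!identical(sort(rownames(cqShifts)), sort(names(nPerGroup))))
    stop("cqShifts rows must match nPerGroup groups", call. = FALSE)
  if (!is.null(coupling)) {
    stopifnot(is.list(coupling),
              all(c("mirnaAssay", "geneAssay", "rho") %in% names(coupling)))
    if (abs(coupling$rho) > 1) stop("coupling rho must be in [-1, 1]", call. = FALSE)
    if (!all(c(coupling$mirnaAssay, coupling$geneAssay) %in% colnames(cqShifts)))
      stop("coupling assays must appear in cqShifts columns", call. = FALSE)
  }
  spec <- list(seed = as.integer(seed), nUtrs = as.integer(nUtrs),
               utrLength = as.integer(utrLength), backgroundGc = backgroundGc,
               mirnas = mir, plantedSites = plantedSites,
               nPerGroup = nPerGroup, cqShifts = cqShifts,
               referenceAssays = referenceAssays, cqNoiseSd = cqNoiseSd,
               baselineRange = baselineRange, coupling = coupling)
  class(spec) <- "SimulationSpec"
  spec
}

#' Generate synthetic UTRs with planted binding sites
#'
#' Draws i.i.d. background nucleotides at the requested GC fraction and
#' plants, at known (or random collision-free) positions, target sites
#' that are exact reverse complements of the designated miRNA's seed
#' region, with the requested number of mismatches and G:U wobbles
#' introduced at recorded positions. For planted `6mer-seed` sites the
#' base opposite miRNA position 8 is forced non-pairing (and for
#' `7mer`, the base opposite position 1 forced non-A) so the planted
#' class is exactly what a scanner should report. Deterministic for a
#' fixed spec seed.
#'
#' @param spec A [simulationSpec()].
#' @return A list with `utrs` (named `RNAStringSet`) and `truth`
#'   (data.frame: `gene`, `mirna`, `start`, `end`, `site_class`,
#'   `mismatches`, `wobbles`, `seed_start`).
#' @export
simulateUtrs <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  withLocalSeed(spec$seed, {
    gc <- spec$backgroundGc
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
    genes <- sprintf("GENE%03d", seq_len(spec$nUtrs))
    seqs <- vapply(seq_len(spec$nUtrs), function(i) {
      paste(sample(names(probs), spec$utrLength, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
    names(seqs) <- genes

    truthRows <- list()
    occupied <- lapply(seq_len(spec$nUtrs), function(i) integer(0))
    ps <- spec$plantedSites
    for (r in seq_len(nrow(ps))) {
      ui <- ps$utr[r]
      if (ui < 1 || ui > spec$nUtrs)
        stop("planted site references UTR index out of range", call. = FALSE)
      planted <- plantSite(seqs[[ui]], spec$mirnas[[ps$mirna[r]]],
                           ps$class[r], ps$mismatches[r], ps$wobbles[r],
                           ps$position[r], occupied[[ui]])
      seqs[[ui]] <- planted$sequence
      occupied[[ui]] <- c(occupied[[ui]], planted$occupied)
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        gene = genes[ui], mirna = ps$mirna[r],
        start = planted$start, end = planted$end,
        site_class = ps$class[r],
        mismatches = as.integer(ps$mismatches[r]),
        wobbles = as.integer(ps$wobbles[r]),
        seed_start = planted$seed_start,
        stringsAsFactors = FALSE)
    }
    truth <- if (length(truthRows)) do.call(rbind, truthRows) else
      data.frame(gene = character(0), mirna = character(0),
                 start = integer(0), end = integer(0),
                 site_class = character(0), mismatches = integer(0),
                 wobbles = integer(0), seed_start = integer(0))
    list(utrs = Biostrings::RNAStringSet(seqs), truth = truth)
  })
}

# Base that neither Watson-Crick- nor wobble-pairs mb (first in ACGU order
# after random draw, for recorded determinism via sample()).
nonPairingBase <- function(mb) {
  cand <- c("A", "C", "G", "U")
  cand <- cand[!isWatsonCrick(mb, cand) & !isWobble(mb, cand)]
  cand[sample.int(length(cand), 1)]
}

plantSite <- function(utrSeq, mirnaSeq, class, mismatches, wobbles, position,
                      occupied) {
  m <- strsplit(mirnaSeq, "")[[1]]
  span <- switch(class, "6mer-seed" = 6L, "7mer" = 7L, "8mer" = 8L)
  L <- nchar(utrSeq)
  # leave one guard base on each side so forced-context edits stay in range
  lo <- 1L; hi <- L - span - 1L
  if (hi < lo) stop("planted site longer than UTR", call. = FALSE)
  if (is.na(position)) {
    avail <- setdiff(lo:hi, unlist(lapply(occupied, function(o) o)))
    # exclude starts whose span would overlap an occupied position
    ok <- vapply(lo:hi, function(p) {
      !any(seq(p - 1L, p + span) %in% occupied)
    }, logical(1))
    avail <- (lo:hi)[ok]
    if (!length(avail))
      stop("no collision-free position left for planted site", call. = FALSE)
    position <- avail[sample.int(length(avail), 1)]
  } else {
    if (position < 0 || position + span > L)
      stop("planted site position out of range", call. = FALSE)
    if (any(seq(position - 1L, position + span) %in% occupied))
      stop("planted sites collide", call. = FALSE)
  }
  s <- if (class == "6mer-seed") position else position + 1L  # seed-region start
  t <- strsplit(utrSeq, "")[[1]]
  seed <- m[2:7]
  # perfect seed complement: target 0-based s..s+5 pairs miRNA 7..2
  t[(s + 1):(s + 6)] <- rev(rnaComplement(seed))
  if (class %in% c("7mer", "8mer")) {
    t[s] <- rnaComplement(m[8])                # position opposite miRNA 8
  } else if (s >= 1) {
    t[s] <- nonPairingBase(m[8])               # forbid accidental upgrade
  }
  if (class == "8mer") {
    t[s + 7] <- "A"
  } else if (s + 7 <= L) {
    if (t[s + 7] == "A") t[s + 7] <- "U"       # forbid accidental 8mer
  }
  # wobbles: need miRNA G (target C -> U) or miRNA U (target A -> G)
  eligible <- which(seed %in% c("G", "U"))
  if (wobbles > length(eligible))
    stop("requested more wobbles than G/U seed positions allow", call. = FALSE)
  wpos <- if (wobbles > 0)
    sort(eligible[sample.int(length(eligible), wobbles)]) else integer(0)
  for (k in wpos) {
    tIdx <- s + 6 - (k - 1)   # 1-based target index opposite seed position k
    t[tIdx] <- if (seed[k] == "G") "U" else "G"
  }
  # mismatches at recorded positions (never on a wobbled position)
  mpos <- setdiff(seq_len(6), wpos)
  if (mismatches > length(mpos))
    stop("requested more mismatches than seed positions allow", call. = FALSE)
  mpos <- if (mismatches > 0)
    sort(mpos[sample.int(length(mpos), mismatches)]) else integer(0)
  for (k in mpos) {
    tIdx <- s + 6 - (k - 1)
    t[tIdx] <- nonPairingBase(seed[k])
  }
  list(sequence = paste(t, collapse = ""),
       start = position, end = position + span,
       seed_start = s,
       occupied = seq(position - 1L, position + span))
}

#' Generate a synthetic Cq table with known group effects
#'
#' `Cq(sample, assay) = baseline(assay) + shift(group, assay) +
#' N(0, cqNoiseSd)`. Baselines are drawn once per assay from the spec's
#' baseline range; reference assays have shift 0 in every group. An
#' optional rank-coupled assay pair is generated through a Gaussian
#' copula: the pair's noise is bivariate normal with Pearson correlation
#' `2 sin(pi * rho / 6)`, which targets Spearman `rho` (exact comonotone
#' construction at `|rho| = 1`). Tumour samples of the CRC groups are
#' linked to corresponding normal-mucosa samples (`paired_normal`).
#'
#' @param spec A [simulationSpec()].
#' @return A list with `cq` (a [CqExperiment-class]), `shifts` (the true
#'   shift matrix), `baselines` (named vector).
#' @export
simulateCq <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  withLocalSeed(spec$seed + 1L, {
    groups <- rownames(spec$cqShifts)
    assays <- colnames(spec$cqShifts)
    nTot <- sum(spec$nPerGroup)
    sampleGroup <- rep(names(spec$nPerGroup), spec$nPerGroup)
    sampleNames <- unlist(lapply(names(spec$nPerGroup), function(g) {
      sprintf("%s_%02d", g, seq_len(spec$nPerGroup[[g]]))
    }))
    baselines <- stats::setNames(
      runif(length(assays), spec$baselineRange[1], spec$baselineRange[2]),
      assays)

    noise <- matrix(rnorm(length(assays) * nTot, 0, spec$cqNoiseSd),
                    nrow = length(assays),
                    dimnames = list(assays, sampleNames))
    if (!is.null(spec$coupling) && spec$cqNoiseSd > 0) {
      r <- 2 * sin(pi * spec$coupling$rho / 6)
      z1 <- rnorm(nTot)
      z2 <- r * z1 + sqrt(max(0, 1 - r^2)) * rnorm(nTot)
      noise[spec$coupling$mirnaAssay, ] <- spec$cqNoiseSd * z1
      noise[spec$coupling$geneAssay, ] <- spec$cqNoiseSd * z2
    }
    shiftBySample <- t(spec$cqShifts[sampleGroup, assays, drop = FALSE])
    cq <- baselines + shiftBySample + noise
    dimnames(cq) <- list(assays, sampleNames)

    paired <- rep(NA_character_, nTot)
    names(paired) <- sampleNames
    normals <- sampleNames[sampleGroup == "normal"]
    nextNormal <- 1L
    for (g in intersect(c("crc_n0", "crc_nplus"), names(spec$nPerGroup))) {
      samp <- sampleNames[sampleGroup == g]
      take <- min(length(samp), length(normals) - nextNormal + 1L)
      if (take > 0) {
        paired[samp[seq_len(take)]] <- normals[nextNormal:(nextNormal + take - 1L)]
        nextNormal <- nextNormal + take
      }
    }
    role <- ifelse(assays %in% spec$referenceAssays, "reference", "target")
    exp <- CqExperiment(cq, group = sampleGroup, role = role,
                        pairedNormal = paired)
    list(cq = exp, shifts = spec$cqShifts, baselines = baselines)
  })
}

#' Write simulated pipeline inputs to disk
#'
#' Emits the same plain-text formats the real pipeline consumes: UTR
#' FASTA, miRNA table, a permissive evidence table for the planted
#' pairs, the long-format Cq table, plus truth TSVs.
#'
#' @param spec A [simulationSpec()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeSimulatedInputs <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utrSim <- simulateUtrs(spec)
  cqSim <- simulateCq(spec)
  paths <- c(
    utr_fasta = file.path(dir, "utrs.fa"),
    mirna_table = file.path(dir, "mirnas.tsv"),
    evidence = file.path(dir, "evidence.tsv"),
    cq_table = file.path(dir, "cq.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    truth_shifts = file.path(dir, "truth_shifts.tsv"))
  writeUtrFasta(utrSim$utrs, paths[["utr_fasta"]])
  utils::write.table(
    data.frame(name = names(spec$mirnas), sequence = unname(spec$mirnas)),
    paths[["mirna_table"]], sep = "\t", quote = FALSE, row.names = FALSE)
  pairs <- unique(utrSim$truth[, c("mirna", "gene")])
  evidence <- data.frame(
    mirna = pairs$mirna, gene = pairs$gene, db_count = 2L,
    cancer_assoc = TRUE, crc_assoc = TRUE, gene_assoc = TRUE,
    direct_validation = FALSE, mirbase_valid = TRUE,
    stringsAsFactors = FALSE)
  utils::write.table(evidence, paths[["evidence"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  x <- cqSim$cq
  long <- expand.grid(assay = rownames(x), sample = colnames(x),
                      stringsAsFactors = FALSE)
  pn <- pairedNormal(x)
  long$group <- sampleGroups(x)[long$sample]
  long$paired_normal_id <- if (is.null(pn)) "" else
    ifelse(is.na(pn[long$sample]), "", pn[long$sample])
  long$role <- assayRoles(x)[long$assay]
  long$cq <- sprintf("%.6f", cqValues(x)[cbind(long$assay, long$sample)])
  utils::write.table(
    long[, c("sample", "group", "paired_normal_id", "assay", "role", "cq")],
    paths[["cq_table"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(utrSim$truth, paths[["truth_sites"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  shifts <- as.data.frame(cqSim$shifts)
  shifts <- cbind(group = rownames(shifts), shifts)
  utils::write.table(shifts, paths[["truth_shifts"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
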