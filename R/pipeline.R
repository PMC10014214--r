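## Pipeline driver: declarative run configuration (YAML), the four
## pipeline commands (simulate / benchmark / null / report) and provenance.
## A thin shell wrapper lives in exec/repobench.

#' Read and validate a run configuration
#'
#' The configuration is a single YAML document with blocks:
#' \preformatted{
#' input:
#'   standard: standard.tsv        # file mode ...
#'   signatures: signatures.tsv
#'   synthetic:                    # ... XOR synthetic mode
#'     nDrugs: 500
#'     nProteins: 64
#'     nIndications: 100
#'     nAssociations: 1200
#' benchmark:
#'   cutoffs: [10, 25, 50, 100]
#'   minIndicationSize: 2
#'   measure: rmsd
#'   alpha: 20
#' null_model:
#'   method: shuffle_similarities
#'   replicates: 20
#' metrics: [indication_accuracy, AUROC, BEDROC, NDCG]
#' seed: 1
#' outdir: runs/demo
#' }
#' Exactly one input source (files or synthetic) must be given.
#'
#' @param path path to the YAML file.
#' @param overrides named list merged over the file values (flags beat
#'   file).
#' @return A validated config list.
#' @export
readRunConfig <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg <- utils::modifyList(cfg, overrides)
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg a config list (as from YAML).
#' @export
validateRunConfig <- function(cfg) {
  inp <- cfg$input
  if (is.null(inp)) stop("config needs an 'input' block")
  hasFiles <- !is.null(inp$standard) || !is.null(inp$signatures)
  hasSynth <- !is.null(inp$synthetic)
  if (hasFiles && hasSynth)
    stop("conflicting input sources: give files XOR a synthetic block")
  if (!hasFiles && !hasSynth)
    stop("no input source: give input$standard + input$signatures, ",
         "or input$synthetic")
  if (hasFiles && (is.null(inp$standard) || is.null(inp$signatures)))
    stop("file mode needs both input$standard and input$signatures")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$outdir)) cfg$outdir <- "."
  cfg
}

configBenchmark <- function(cfg) {
  b <- cfg$benchmark
  if (is.null(b)) return(BenchmarkConfig())
  BenchmarkConfig(
    cutoffs = if (is.null(b$cutoffs)) c(10L, 25L, 50L, 100L)
              else as.integer(unlist(b$cutoffs)),
    minIndicationSize = if (is.null(b$minIndicationSize)) 2L
                        else b$minIndicationSize,
    measure = if (is.null(b$measure)) "rmsd" else b$measure,
    alpha = if (is.null(b$alpha)) 20 else b$alpha)
}

configSynthetic <- function(cfg) {
  s <- cfg$input$synthetic
  args <- s[intersect(names(s),
                      c("nDrugs", "nProteins", "nIndications",
                        "nAssociations", "sizeSkew", "signalStrength",
                        "noiseSd", "seed"))]
  if (is.null(args$seed)) args$seed <- cfg$seed
  do.call(SyntheticSpec, args)
}

## the block is named null_model because a bare `null:` key is parsed by
## YAML as the null value, losing the block
configNull <- function(cfg) {
  n <- if (!is.null(cfg$null_model)) cfg$null_model else cfg[["null"]]
  NullSpec(
    method = if (is.null(n$method)) "shuffle_similarities" else n$method,
    replicates = if (is.null(n$replicates)) 20L else n$replicates,
    seed = if (is.null(n$seed)) cfg$seed else n$seed)
}

## provenance block: config echo + seed + version. Deliberately excludes
## wall-clock time so identical configs give byte-identical outputs.
writeProvenance <- function(cfg, outdir, command) {
  prov <- list(command = command, seed = cfg$seed, config = cfg,
               package = "repoBench",
               version = as.character(utils::packageVersion("repoBench")))
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(prov)
}

loadInputs <- function(cfg) {
  if (!is.null(cfg$input$synthetic)) {
    spec <- configSynthetic(cfg)
    std <- generateStandard(spec)
    sig <- generateSignatures(std, spec)
  } else {
    if (!file.exists(cfg$input$standard))
      stop("standard file not found: ", cfg$input$standard)
    if (!file.exists(cfg$input$signatures))
      stop("signature file not found: ", cfg$input$signatures)
    std <- readAssociationStandard(cfg$input$standard)
    sig <- readSignatureMatrix(cfg$input$signatures)
  }
  list(standard = std, signatures = sig)
}

#' Pipeline commands
#'
#' The four stages of a benchmarking run, each driven by the same
#' [readRunConfig()] configuration and writing into `cfg$outdir` together
#' with a provenance block (config echo, seed, package version), so a run
#' is reproducible from its outputs alone.
#'
#' \describe{
#'   \item{`cmdSimulate`}{generate a synthetic standard + signature matrix
#'     and write them as TSV (`standard.tsv`, `signatures.tsv`).}
#'   \item{`cmdBenchmark`}{load or generate inputs, compute pairwise
#'     distances, run [runMetricSuite()] and write `report.json` /
#'     `report.tsv`.}
#'   \item{`cmdNull`}{run [runNullControl()] and write
#'     `null_report.json`.}
#'   \item{`cmdReport`}{read `report.json` (and `null_report.json` if
#'     present) and print human-readable summary tables: AIA by cutoff,
#'     aggregate metrics against their null means, and the per-indication
#'     accuracy table.}
#' }
#'
#' @param cfg config list from [readRunConfig()] / [validateRunConfig()].
#' @param quiet suppress progress messages.
#' @return `cmdSimulate`: the written paths; `cmdBenchmark` /` cmdNull`:
#'   the [MetricReport-class] (invisibly, after writing); `cmdReport`: the
#'   printed summary data.frame, invisibly.
#' @name pipeline-commands
NULL

#' @rdname pipeline-commands
#' @export
cmdSimulate <- function(cfg, quiet = FALSE) {
  cfg <- validateRunConfig(cfg)
  if (is.null(cfg$input$synthetic))
    stop("simulate needs a synthetic input block")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  dat <- loadInputs(cfg)
  stdPath <- file.path(cfg$outdir, "standard.tsv")
  sigPath <- file.path(cfg$outdir, "signatures.tsv")
  writeAssociationStandard(dat$standard, stdPath)
  writeSignatureMatrix(dat$signatures, sigPath)
  writeProvenance(cfg, cfg$outdir, "simulate")
  if (!quiet)
    message("simulate: wrote ", nAssociations(dat$standard),
            " associations and a ", nDrugs(dat$signatures), " x ",
            length(proteinIds(dat$signatures)), " signature matrix")
  invisible(c(standard = stdPath, signatures = sigPath))
}

#' @rdname pipeline-commands
#' @export
cmdBenchmark <- function(cfg, quiet = FALSE) {
  cfg <- validateRunConfig(cfg)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  dat <- loadInputs(cfg)
  bench <- configBenchmark(cfg)
  sim <- pairwiseDistances(dat$signatures, measure = bench@measure)
  metrics <- if (is.null(cfg$metrics)) suiteMetricNames()
             else unlist(cfg$metrics)
  report <- runMetricSuite(dat$standard, sim, bench, metrics = metrics)
  writeMetricReport(report, file.path(cfg$outdir, "report.json"), "json")
  writeMetricReport(report, file.path(cfg$outdir, "report.tsv"), "tsv")
  writeProvenance(cfg, cfg$outdir, "benchmark")
  if (!quiet) {
    agg <- aggregated(report)
    aiaRows <- agg[agg$metric == "AIA", , drop = FALSE]
    if (nrow(aiaRows))
      message("benchmark: AIA ",
              paste(sprintf("top%d = %.1f%%", aiaRows$cutoff, aiaRows$mean),
                    collapse = ", "))
  }
  invisible(report)
}

#' @rdname pipeline-commands
#' @export
cmdNull <- function(cfg, quiet = FALSE) {
  cfg <- validateRunConfig(cfg)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  dat <- loadInputs(cfg)
  bench <- configBenchmark(cfg)
  nullSpec <- configNull(cfg)
  sim <- pairwiseDistances(dat$signatures, measure = bench@measure)
  metrics <- if (is.null(cfg$metrics))
    c("indication_accuracy", "AUROC", "BEDROC", "NDCG")
  else unlist(cfg$metrics)
  nullRep <- runNullControl(dat$standard, bench, nullSpec, sim = sim,
                            metrics = metrics)
  writeMetricReport(nullRep, file.path(cfg$outdir, "null_report.json"),
                    "json")
  writeProvenance(cfg, cfg$outdir, "null")
  if (!quiet)
    message("null: ", nullSpec@method, " x ", nullSpec@replicates,
            " replicates written")
  invisible(nullRep)
}

#' @rdname pipeline-commands
#' @param file connection or path passed to [cat()] for the printed report.
#' @param maxIndications cap on per-indication rows printed (the full table
#'   is in `report.json`).
#' @export
cmdReport <- function(cfg, file = stdout(), maxIndications = 25L,
                      quiet = FALSE) {
  cfg <- validateRunConfig(cfg)
  repPath <- file.path(cfg$outdir, "report.json")
  if (!file.exists(repPath))
    stop("no report.json under ", cfg$outdir, "; run cmdBenchmark first")
  report <- readMetricReport(repPath)
  nullPath <- file.path(cfg$outdir, "null_report.json")
  nullRep <- if (file.exists(nullPath)) readMetricReport(nullPath) else NULL

  agg <- aggregated(report)
  out <- function(...) cat(..., "\n", sep = "", file = file, append = TRUE)
  out("== repoBench report (", cfg$outdir, ") ==")
  aiaRows <- agg[agg$metric == "AIA", , drop = FALSE]
  if (nrow(aiaRows)) {
    out("Average indication accuracy (AIA):")
    for (r in seq_len(nrow(aiaRows)))
      out(sprintf("  top%-4d %6.1f%%", aiaRows$cutoff[r], aiaRows$mean[r]))
  }
  out("Aggregate metrics (indication level; mean [IQR]):")
  ind <- agg[agg$level == "indication" & !agg$metric %in%
               c("AIA", "indication_accuracy"), , drop = FALSE]
  for (r in seq_len(nrow(ind))) {
    label <- if (is.na(ind$cutoff[r])) ind$metric[r]
             else sprintf("%s@%d", ind$metric[r], ind$cutoff[r])
    nullTxt <- ""
    if (!is.null(nullRep)) {
      na <- aggregated(nullRep)
      hit <- na$metric == ind$metric[r] & na$level == "indication" &
        (is.na(ind$cutoff[r]) & is.na(na$cutoff) |
           (!is.na(ind$cutoff[r]) & !is.na(na$cutoff) &
              na$cutoff == ind$cutoff[r]))
      if (any(hit))
        nullTxt <- sprintf("  (null %.4g)", na$mean[which(hit)[1L]])
    }
    out(sprintf("  %-16s %8.4g [%.4g, %.4g]%s", label, ind$mean[r],
                ind$q25[r], ind$q75[r], nullTxt))
  }
  pi <- perIndication(report)
  accTab <- pi[pi$metric == "indication_accuracy", , drop = FALSE]
  if (nrow(accTab)) {
    out("Per-indication accuracy (%):")
    wide <- stats::reshape(accTab[, c("indication_id", "cutoff", "value")],
                           idvar = "indication_id", timevar = "cutoff",
                           direction = "wide")
    names(wide) <- sub("^value\\.", "top", names(wide))
    hdr <- paste0(formatC(names(wide)[-1L], width = 8L), collapse = "")
    out("  ", formatC("indication", width = -14L), hdr)
    if (nrow(wide) > maxIndications) {
      out("  (showing ", maxIndications, " of ", nrow(wide),
          " indications; full table in report.json)")
      wide <- wide[seq_len(maxIndications), , drop = FALSE]
    }
    for (r in seq_len(nrow(wide))) {
      out("  ", formatC(wide$indication_id[r], width = -14L),
          paste0(formatC(sprintf("%.1f", unlist(wide[r, -1L])),
                         width = 8L), collapse = ""))
    }
  }
  invisible(agg)
}
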