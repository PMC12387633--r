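#' Pipeline configuration
#'
#' Either four block CSV paths plus a design CSV, or a
#' \code{\link{syntheticConfig}} to simulate the study.
#'
#' @param blockPaths named character vector of block CSV paths (X1..X4), or
#'   NULL to simulate.
#' @param designPath design CSV path (ignored when simulating).
#' @param synthetic a \linkS4class{SyntheticConfig} used when
#'   \code{blockPaths} is NULL.
#' @param params a \code{\link{preprocessParams}} bundle.
#' @param ncomp number of model components.
#' @param selectionRule discriminant selection rule.
#' @param outDir output directory.
#' @param seed integer seed (overrides the synthetic config's seed).
#' @return a list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(blockPaths = NULL, designPath = NULL,
                           synthetic = syntheticConfig(),
                           params = preprocessParams(), ncomp = 4,
                           selectionRule = "range-quarter",
                           outDir = "mbpls_out", seed = NULL) {
  if (!is.null(blockPaths)) {
    missing <- blockPaths[!file.exists(blockPaths)]
    if (length(missing))
      stop("block file(s) not found: ", paste(missing, collapse = ", "))
    if (is.null(designPath) || !file.exists(designPath))
      stop("design file not found")
  }
  stopifnot(ncomp >= 1)
  if (!is.null(seed)) synthetic@seed <- as.integer(seed)
  structure(list(blockPaths = blockPaths, designPath = designPath,
                 synthetic = synthetic, params = params, ncomp = ncomp,
                 selectionRule = selectionRule, outDir = outDir),
            class = "PipelineConfig")
}

#' Run the full multiblock workflow
#'
#' Loads (or simulates) the four-block study, preprocesses every block,
#' fits the multiblock PLS model, runs leave-one-out validation, selects
#' discriminant variables with group directions, computes biplot
#' coordinates for the T1/T2 and T2/T3 panels, and writes all artifacts
#' plus a run manifest with content hashes.  Identical configuration and
#' seed give byte-identical outputs.
#'
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return invisibly, a list with the model, report, selection table,
#'   biplot coordinates, study and manifest path.
#' @export
runPipeline <- function(cfg = pipelineConfig()) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  if (is.null(cfg$blockPaths)) {
    study <- stage("simulate", generateStudy(cfg$synthetic))
    blocks <- study$blocks
    design <- study$design
    stage("simulate", writeGroundTruth(study$truth,
                                       file.path(cfg$outDir, "ground_truth.json")))
  } else {
    blocks <- stage("load", mapply(readBlockMatrix, cfg$blockPaths,
                                   names(cfg$blockPaths), SIMPLIFY = FALSE))
    design <- stage("load", readStudyDesign(cfg$designPath))
    study <- list(blocks = blocks, design = design)
  }

  pp <- stage("preprocess", preprocessStudy(blocks, cfg$params))
  for (nm in names(pp$blocks))
    writeBlockMatrix(pp$blocks[[nm]],
                     file.path(cfg$outDir, sprintf("%s_preprocessed.csv", nm)))

  model <- stage("fit", fitMBPLS(pp$blocks, design, ncomp = cfg$ncomp,
                                 preprocessing = pp$fits))
  writeModelJSON(model, file.path(cfg$outDir, "model.json"))

  report <- stage("validate", evaluateModel(blocks, design, cfg$params,
                                            ncomp = cfg$ncomp))
  writeReportJSON(report, file.path(cfg$outDir, "validation.json"))

  selected <- stage("select", selectDiscriminant(model,
                                                 rule = cfg$selectionRule,
                                                 design = design))
  utils::write.csv(selected, file.path(cfg$outDir, "discriminant_variables.csv"),
                   row.names = FALSE)

  for (panel in list(c(1, 2), c(2, 3))) {
    if (max(panel) > cfg$ncomp) next
    bp <- stage("biplot", biplotCoordinates(model, selected, axes = panel))
    tag <- sprintf("T%d_T%d", panel[1], panel[2])
    utils::write.csv(bp$variables,
                     file.path(cfg$outDir, sprintf("biplot_vars_%s.csv", tag)),
                     row.names = FALSE)
    utils::write.csv(bp$scores,
                     file.path(cfg$outDir, sprintf("biplot_scores_%s.csv", tag)),
                     row.names = FALSE)
  }

  files <- setdiff(list.files(cfg$outDir, full.names = TRUE),
                   file.path(cfg$outDir, "manifest.json"))
  manifest <- list(
    package = "MBPLSmetab",
    version = as.character(utils::packageVersion("MBPLSmetab")),
    rVersion = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$synthetic@seed,
    nComponents = cfg$ncomp,
    selectionRule = cfg$selectionRule,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(model = model, report = report, selected = selected,
                 study = study,
                 manifest = file.path(cfg$outDir, "manifest.json")))
}

#' Verify a pipeline output directory against its manifest
#'
#' @param outDir pipeline output directory.
#' @return TRUE if every listed file matches its recorded hash; otherwise a
#'   character vector of mismatching files.
#' @export
verifyManifest <- function(outDir) {
  man <- jsonlite::read_json(file.path(outDir, "manifest.json"))
  bad <- character()
  for (f in names(man$files)) {
    h <- unname(tools::md5sum(file.path(outDir, f)))
    if (is.na(h) || !identical(h, man$files[[f]])) bad <- c(bad, f)
  }
  if (length(bad)) bad else TRUE
}
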