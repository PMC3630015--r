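#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file holding one) with the
#' fields: either `x`/`y` input paths or `simulate = TRUE` (with optional
#' design overrides); `method` (one of cca, rcca, pls-reg, pls-can,
#' spls-reg, spls-can); `ndim`; `keepX`/`keepY` (sparse family only);
#' `lambda1`/`lambda2` (CCA family only); `d` (similarity dimensions,
#' default `ndim`); `thresholds` (network, default 0.5); `distance`,
#' `linkage` (CIM); `circleDims`; `outDir`; `seed`; `force`.
#' Method/parameter consistency is checked before any computation.
#'
#' @param config named list or YAML path.
#' @return the normalized configuration list.
#' @export
validateConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  methods <- c("cca", "rcca", "pls-reg", "pls-can", "spls-reg", "spls-can")
  cfg <- config
  cfg$method <- cfg$method %||% "pls-can"
  if (!cfg$method %in% methods)
    stop("unknown method '", cfg$method, "'")
  cfg$ndim <- as.integer(cfg$ndim %||% 3L)
  cfg$d <- as.integer(cfg$d %||% cfg$ndim)
  cfg$thresholds <- as.numeric(cfg$thresholds %||% 0.5)
  cfg$distance <- cfg$distance %||% "euclidean"
  cfg$linkage <- cfg$linkage %||% "ward"
  cfg$circleDims <- as.integer(cfg$circleDims %||% c(1L, 2L))
  cfg$seed <- as.integer(cfg$seed %||% 42L)
  cfg$outDir <- cfg$outDir %||% "crossomics-out"
  cfg$force <- isTRUE(cfg$force)
  cfg$simulate <- isTRUE(cfg$simulate)
  sparse <- grepl("^spls", cfg$method)
  ccaFam <- cfg$method %in% c("cca", "rcca")
  if (!is.null(cfg$lambda1) || !is.null(cfg$lambda2)) {
    if (!ccaFam)
      stop("lambda parameters are only valid for the CCA family, not ",
           cfg$method)
  }
  if (!is.null(cfg$keepX) || !is.null(cfg$keepY)) {
    if (!sparse)
      stop("keepX/keepY are only valid for the sparse PLS family, not ",
           cfg$method)
  }
  if (sparse && (is.null(cfg$keepX) || is.null(cfg$keepY)))
    stop("method ", cfg$method, " requires keepX and keepY")
  if (cfg$method == "rcca" && (is.null(cfg$lambda1) || is.null(cfg$lambda2)))
    stop("method rcca requires lambda1 and lambda2")
  if (!cfg$simulate) {
    if (is.null(cfg$x) || is.null(cfg$y))
      stop("config needs input paths x and y (or simulate: true)")
    for (pp in c(cfg$x, cfg$y))
      if (!file.exists(pp)) stop("input file not found: ", pp)
  }
  cfg
}

#' Run the full pipeline
#'
#' Chains the stages end to end: simulate or read the paired data, fit the
#' requested method, compute the variable coordinates and similarity
#' matrix, and write the network(s), Clustered Image Map and Correlation
#' Circle plot together with the serialized fit and a run log into the
#' output directory. Identical configuration and seed give identical
#' numeric outputs.
#'
#' @param config named list or YAML path; see [validateConfig()].
#' @return invisibly, a named list of the created paths.
#' @export
runPipeline <- function(config) {
  cfg <- validateConfig(config)
  out <- cfg$outDir
  if (dir.exists(out) && length(dir(out)) && !cfg$force)
    stop("output directory ", out,
         " is not empty; set force: true to overwrite")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(out, "run.log")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon), add = TRUE)
  logmsg <- function(...) {
    txt <- paste0(...)
    writeLines(txt, logCon)
    message(txt)
  }
  logmsg("crossOmics ", as.character(utils::packageVersion("crossOmics")),
         " pipeline")
  logmsg("seed: ", cfg$seed, "; method: ", cfg$method, "; ndim: ", cfg$ndim)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  paths <- list(log = logPath)
  data <- stage("input", {
    if (cfg$simulate) {
      design <- do.call(simulationDesign,
                        cfg$design %||% list())
      pd <- simulatePair(design, seed = cfg$seed)
      paths$x <- file.path(out, "X.tsv"); paths$y <- file.path(out, "Y.tsv")
      writePaired(pd, paths$x, paths$y)
      logmsg("simulated ", nrow(pd@X), " samples: X ", ncol(pd@X),
             " cols, Y ", ncol(pd@Y), " cols")
      pd
    } else {
      logmsg("reading ", cfg$x, " and ", cfg$y)
      readPaired(cfg$x, cfg$y, standardize = TRUE)
    }
  })
  fit <- stage("fit", {
    f <- switch(cfg$method,
      "cca" = fitCCA(data, cfg$ndim),
      "rcca" = fitRCCA(data, cfg$ndim, cfg$lambda1, cfg$lambda2),
      "pls-reg" = fitPLS(data, cfg$ndim, "regression"),
      "pls-can" = fitPLS(data, cfg$ndim, "canonical"),
      "spls-reg" = fitSPLS(data, cfg$ndim, "regression", cfg$keepX,
                           cfg$keepY),
      "spls-can" = fitSPLS(data, cfg$ndim, "canonical", cfg$keepX,
                           cfg$keepY))
    logmsg("fit ", cfg$method, "; rho: ",
           paste(sprintf("%.4f", f@rho), collapse = " "))
    paths$fit <- file.path(out, "fit.json")
    writeFit(f, paths$fit)
    f
  })
  co <- stage("similarity", variableCoords(fit, data, cfg$d))
  M <- stage("similarity", {
    M <- pairwiseSimilarity(fit, data, cfg$d)
    paths$similarity <- file.path(out, "M.tsv")
    writeSimilarity(M, paths$similarity)
    logmsg("similarity matrix ", nrow(M@M), " x ", ncol(M@M),
           " on d = ", cfg$d)
    M
  })
  stage("network", {
    for (thr in cfg$thresholds) {
      net <- relevanceNetwork(M, thr)
      p <- file.path(out, sprintf("network_%.2f.graphml", thr))
      exportNetwork(net, p, "graphml")
      paths$network <- c(paths$network, p)
      logmsg(sprintf(
        "network at threshold %.2f: %d nodes, %d edges, %d component(s)",
        thr, nrow(net@nodes), nrow(net@edges),
        length(networkComponents(net))))
    }
  })
  stage("cim", {
    cr <- clusterSimilarity(M, cfg$distance, cfg$linkage)
    paths$cim <- file.path(out, "cim.png")
    plotCIM(cr, paths$cim)
    writeCIM(cr, file.path(out, "cim.json"))
    logmsg("CIM written (", cfg$distance, "/", cfg$linkage, ")")
  })
  stage("circle", {
    paths$circle <- file.path(out, "circle.png")
    plotCircle(co, paths$circle, dims = cfg$circleDims)
    logmsg("correlation circle written for dims ",
           paste(cfg$circleDims, collapse = ","))
  })
  invisible(paths)
}
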