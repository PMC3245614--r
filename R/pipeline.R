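#' @include AllClasses.R shells.R population.R threed.R tiff-io.R plots.R
NULL

#' Read a pipeline run configuration
#'
#' Loads a run configuration from YAML (or JSON) and validates its
#' invariants. A configuration names a \code{mode} — \code{simulate},
#' \code{analyze2d}, \code{analyze3d} or \code{compare} — an output
#' directory \code{out}, and mode-specific keys (see
#' \code{\link{runPipeline}}).
#'
#' @param path YAML or JSON file.
#' @return Validated configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    stop("config: file does not exist: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param config configuration list (as produced by \code{readRunConfig} or
#'   built in code).
#' @export
validateRunConfig <- function(config) {
  if (is.null(config$mode) ||
      !config$mode %in% c("simulate", "analyze2d", "analyze3d", "compare"))
    stop("config: mode must be one of simulate, analyze2d, analyze3d, compare")
  if (is.null(config$out))
    stop("config: an output directory 'out' is required")
  alpha <- config$alpha %||% 0.05
  if (!(alpha > 0 && alpha < 1))
    stop("config: alpha must be in (0, 1)")
  nsh <- config$n_shells %||% 5L
  if (nsh < 2L)
    stop("config: n_shells must be >= 2")
  if (config$mode %in% c("analyze2d", "analyze3d")) {
    if (is.null(config$input))
      stop(config$mode, ": an 'input' directory of TIFF files is required")
    if (!dir.exists(config$input))
      stop(config$mode, ": input path does not exist: ", config$input)
  }
  if (config$mode == "compare") {
    for (side in c("a", "b")) {
      if (is.null(config[[side]]))
        stop("compare: profile CSV paths 'a' and 'b' are required")
      if (!file.exists(config[[side]]))
        stop("compare: input path does not exist: ", config[[side]])
    }
  }
  if (config$mode == "simulate" && is.null(config$scene))
    stop("simulate: a 'scene' block is required")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## SceneConfig from the snake_case keys of a run-config 'scene' block.
.sceneFromList <- function(sc, seed = NULL) {
  args <- list(
    imageShape = sc$image_shape,
    pixelSize = sc$pixel_size_xy %||% 0.2,
    zStep = sc$z_step %||% 0.2,
    nucleusAxes = sc$nucleus_axes,
    nucleusIrregularity = sc$nucleus_irregularity %||% 0.05,
    dapiLevel = sc$dapi_level %||% 0.8,
    probeLevel = sc$probe_level %||% 1.0,
    baselineLevel = sc$baseline_level %||% 0.15,
    noiseSd = sc$noise_sd %||% 0.05,
    territoryRadius = sc$territory_radius %||% 1.0,
    territoryShape = sc$territory_shape %||% "gaussian",
    territoriesPerNucleus = sc$territories_per_nucleus %||% 2L,
    radialLaw = sc$radial_law %||% "peripheral",
    radialShape = sc$radial_shape,
    nNuclei = sc$n_nuclei %||% 50L,
    seed = seed %||% sc$seed %||% 1L)
  args <- args[!vapply(args, is.null, logical(1))]
  do.call(sceneConfig, args)
}

#' Run a pipeline stage
#'
#' Executes one reproducible pipeline stage from a configuration (a list, or
#' a YAML/JSON path). All tabular outputs are CSV with unit-bearing column
#' names, and every successful run writes \code{run_config.yaml}, a
#' machine-readable provenance record echoing the configuration and the
#' package version. Identical configuration and inputs give identical CSV
#' output.
#'
#' \describe{
#'   \item{simulate}{keys \code{scene} (snake_case \code{\link{sceneConfig}}
#'     fields), optional top-level \code{seed}. Writes one two-channel TIFF
#'     per nucleus, \code{ground_truth.csv} and \code{scene_config.yaml}.}
#'   \item{analyze2d}{keys \code{input} (directory of 2D nucleus TIFFs),
#'     \code{pixel_size_xy}, optional \code{n_shells},
#'     \code{background_subtraction}. Writes \code{shell_profiles.csv} and
#'     \code{segmentation_qc.csv}.}
#'   \item{analyze3d}{keys \code{input} (directory of z-stack TIFFs),
#'     \code{pixel_size_xy}, \code{z_step}, optional \code{min_volume},
#'     \code{expected_count}, \code{bin_width_um}. Writes
#'     \code{territory_distances.csv} and
#'     \code{frequency_raw.csv}/\code{frequency_norm_avg.csv}/
#'     \code{frequency_norm_major.csv}.}
#'   \item{compare}{keys \code{a}, \code{b} (shell-profile CSVs), optional
#'     \code{alpha}, \code{condition_a}, \code{condition_b}. Writes
#'     \code{comparison.csv} and \code{comparison.png}.}
#' }
#'
#' @param config list or path to a YAML/JSON run configuration.
#' @return Invisibly, a list of the file paths written.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- validateRunConfig(config)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- switch(config$mode,
    simulate = .runSimulate(config, out),
    analyze2d = .runAnalyze2d(config, out),
    analyze3d = .runAnalyze3d(config, out),
    compare = .runCompare(config, out))
  prov <- c(config, list(package_version =
                           as.character(utils::packageVersion("radialFISH"))))
  provPath <- file.path(out, "run_config.yaml")
  yaml::write_yaml(prov, provPath)
  invisible(c(written, provPath))
}

.runSimulate <- function(config, out) {
  scfg <- .sceneFromList(config$scene, seed = config$seed)
  if (scfg@nNuclei < 1L)
    stop("simulate: configuration error, n_nuclei must be >= 1")
  imgs <- makePopulation(scfg)
  paths <- vapply(seq_along(imgs), function(i) {
    p <- file.path(out, sprintf("nucleus_%03d.tif", i))
    writeNucleusTIFF(imgs[[i]], p)
    p
  }, character(1))
  gtPath <- file.path(out, "ground_truth.csv")
  writeGroundTruth(imgs, gtPath)
  scPath <- file.path(out, "scene_config.yaml")
  yaml::write_yaml(.configAsList(scfg), scPath)
  c(paths, gtPath, scPath)
}

.listTiffs <- function(dir, stage) {
  fl <- sort(list.files(dir, pattern = "\\.tiff?$", full.names = TRUE))
  if (!length(fl))
    stop(stage, ": no TIFF files found in ", dir)
  fl
}

.runAnalyze2d <- function(config, out) {
  px <- config$pixel_size_xy %||% 0.2
  files <- .listTiffs(config$input, "analyze2d")
  imgs <- lapply(files, readNucleusTIFF, spacing = c(px, px), zPlanes = 1L)
  masks <- lapply(imgs, segmentNucleus)
  prof <- mapply(function(im, mk) {
    measureShells(im, buildShells(mk, nShells = config$n_shells %||% 5L),
                  backgroundSubtract =
                    isTRUE(config$background_subtraction))
  }, imgs, masks, SIMPLIFY = FALSE)
  profPath <- file.path(out, "shell_profiles.csv")
  utils::write.csv(profileTable(prof), profPath, row.names = FALSE)
  qc <- data.frame(
    nucleus_id = vapply(imgs, function(im) im@id, character(1)),
    area_px = vapply(masks, nucleusArea, integer(1)),
    major_axis_um = vapply(masks, function(m) nucleusAxes(m)[1], numeric(1)),
    minor_axis_um = vapply(masks, function(m) nucleusAxes(m)[2], numeric(1)),
    threshold = vapply(masks, segThreshold, numeric(1)))
  qcPath <- file.path(out, "segmentation_qc.csv")
  utils::write.csv(qc, qcPath, row.names = FALSE)
  c(profPath, qcPath)
}

.runAnalyze3d <- function(config, out) {
  px <- config$pixel_size_xy %||% 0.2
  zs <- config$z_step %||% 0.2
  files <- .listTiffs(config$input, "analyze3d")
  recs <- do.call(rbind, lapply(files, function(f) {
    im <- readNucleusTIFF(f, spacing = c(px, px, zs))
    territoryDistances(im,
                       minVolume = config$min_volume %||% 20L,
                       expectedCount = config$expected_count %||% 2L)
  }))
  recPath <- file.path(out, "territory_distances.csv")
  utils::write.csv(recs, recPath, row.names = FALSE)
  curvePaths <- vapply(c("raw", "norm_avg", "norm_major"), function(w) {
    cv <- frequencyCurve(recs, which = w,
                         binWidth = if (w == "raw")
                           config$bin_width_um %||% 0.5 else NULL)
    p <- file.path(out, sprintf("frequency_%s.csv", w))
    utils::write.csv(cv, p, row.names = FALSE)
    p
  }, character(1))
  c(recPath, curvePaths)
}

.readProfilesCSV <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("nucleus_id", "shell", "dapi_pct", "probe_pct", "normalized")
  if (!all(need %in% names(tab)))
    stop("compare: profile CSV ", path, " must have columns ",
         paste(need, collapse = ", "))
  lapply(split(tab, tab$nucleus_id), function(rows) {
    rows <- rows[order(rows$shell), ]
    new("ShellProfile", nucleusId = as.character(rows$nucleus_id[1]),
        dapiPct = rows$dapi_pct, probePct = rows$probe_pct,
        normalized = rows$normalized)
  })
}

.runCompare <- function(config, out) {
  alpha <- config$alpha %||% 0.05
  pa <- .readProfilesCSV(config$a)
  pb <- .readProfilesCSV(config$b)
  ra <- aggregateProfiles(pa, config$condition_a %||% "A")
  rb <- aggregateProfiles(pb, config$condition_b %||% "B")
  cmp <- compareShells(ra, rb, alpha = alpha)
  cmpPath <- file.path(out, "comparison.csv")
  utils::write.csv(comparisonTable(ra, rb, comparison = cmp), cmpPath,
                   row.names = FALSE)
  pngPath <- file.path(out, "comparison.png")
  grDevices::png(pngPath, width = 900, height = 450)
  op <- graphics::par(mfrow = c(1, 2))
  plotShellHistogram(ra, comparison = cmp)
  plotShellHistogram(rb, comparison = cmp)
  graphics::par(op)
  grDevices::dev.off()
  c(cmpPath, pngPath)
}
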