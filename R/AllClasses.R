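#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## SceneConfig
## ---------------------------------------------------------------------------

#' Synthetic scene configuration
#'
#' A \code{SceneConfig} describes one simulated imaging condition: the raster
#' geometry, the nucleus, the chromosome territories and the radial law that
#' places them. A config plus its seed fully determines every raster the
#' generator emits (bit-identical reproducibility).
#'
#' Geometry is physical: nucleus semi-axes, territory radius and spacings are
#' in micrometers; the raster is derived from \code{imageShape} (rows, cols
#' and, for z-stacks, slices), \code{pixelSize} (um/pixel in x and y) and
#' \code{zStep} (um between optical sections; the class of confocal stacks
#' this emulates uses 0.2 um).
#'
#' @slot imageShape integer raster dimensions, \code{c(rows, cols)} for 2D or
#'   \code{c(rows, cols, slices)} for a z-stack.
#' @slot pixelSize numeric, lateral pixel size in um/pixel.
#' @slot zStep numeric, axial spacing in um (\code{NA} for 2D scenes).
#' @slot nucleusAxes numeric semi-axis lengths in um: \code{c(major, minor)}
#'   for 2D, \code{c(major, minor, axial)} for 3D.
#' @slot nucleusIrregularity numeric >= 0, amplitude of the low-order Fourier
#'   perturbation of the nuclear boundary radius (0 = exact ellipse).
#' @slot dapiLevel numeric, mean DAPI plateau intensity above baseline
#'   (arbitrary units).
#' @slot probeLevel numeric, peak territory intensity above baseline
#'   (arbitrary units).
#' @slot baselineLevel numeric >= 0, camera pedestal added to both channels
#'   everywhere (arbitrary units); the out-of-nucleus background level.
#' @slot noiseSd numeric >= 0, SD of additive Gaussian noise (clipped at 0).
#' @slot territoryRadius numeric, territory radius in um; Gaussian blobs use
#'   sigma = radius/2.
#' @slot territoryShape \code{"gaussian"} or \code{"disc"}.
#' @slot territoriesPerNucleus integer >= 1.
#' @slot radialLaw one of \code{"peripheral"}, \code{"intermediate"},
#'   \code{"interior"}, \code{"custom"}; a Beta law on the normalized radial
#'   coordinate r in [0,1] (0 = nuclear center, 1 = periphery).
#' @slot radialShape numeric \code{c(alpha, beta)} of the Beta law (filled in
#'   automatically for the named laws).
#' @slot nNuclei integer >= 0, cohort size.
#' @slot seed integer RNG seed.
#'
#' @seealso \code{\link{sceneConfig}}, \code{\link{makeNucleus}}
#' @export
setClass("SceneConfig",
  representation(
    imageShape           = "integer",
    pixelSize            = "numeric",
    zStep                = "numeric",
    nucleusAxes          = "numeric",
    nucleusIrregularity  = "numeric",
    dapiLevel            = "numeric",
    probeLevel           = "numeric",
    baselineLevel        = "numeric",
    noiseSd              = "numeric",
    territoryRadius      = "numeric",
    territoryShape       = "character",
    territoriesPerNucleus = "integer",
    radialLaw            = "character",
    radialShape          = "numeric",
    nNuclei              = "integer",
    seed                 = "integer"
  )
)

setValidity("SceneConfig", function(object) {
  msg <- character()
  nd <- length(object@imageShape)
  if (!nd %in% c(2L, 3L))
    msg <- c(msg, "imageShape must have length 2 (2D) or 3 (z-stack)")
  if (any(object@imageShape < 8L))
    msg <- c(msg, "imageShape entries must be >= 8 pixels")
  if (object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be > 0")
  if (nd == 3L && (is.na(object@zStep) || object@zStep <= 0))
    msg <- c(msg, "zStep must be > 0 for a z-stack scene")
  if (length(object@nucleusAxes) != nd || any(object@nucleusAxes <= 0))
    msg <- c(msg, "nucleusAxes must hold one positive semi-axis per image axis")
  if (length(object@nucleusAxes) >= 2 &&
      is.unsorted(rev(object@nucleusAxes[1:2])))
    msg <- c(msg, "nucleusAxes must be ordered major >= minor")
  if (object@nucleusIrregularity < 0)
    msg <- c(msg, "nucleusIrregularity must be >= 0")
  if (object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be >= 0")
  if (object@baselineLevel < 0)
    msg <- c(msg, "baselineLevel must be >= 0")
  if (object@territoryRadius <= 0)
    msg <- c(msg, "territoryRadius must be > 0")
  if (length(object@nucleusAxes) &&
      object@territoryRadius >= min(object@nucleusAxes))
    msg <- c(msg, "territoryRadius must be smaller than the smallest nucleus semi-axis (territory could not be placed inside the nucleus)")
  if (!object@territoryShape %in% c("gaussian", "disc"))
    msg <- c(msg, "territoryShape must be 'gaussian' or 'disc'")
  if (object@territoriesPerNucleus < 1L)
    msg <- c(msg, "territoriesPerNucleus must be >= 1")
  if (!object@radialLaw %in% c("peripheral", "intermediate", "interior", "custom"))
    msg <- c(msg, "radialLaw must be peripheral, intermediate, interior or custom")
  if (length(object@radialShape) != 2L || any(object@radialShape <= 0))
    msg <- c(msg, "radialShape must be two positive Beta parameters")
  if (object@nNuclei < 0L)
    msg <- c(msg, "nNuclei must be >= 0")
  ## the nucleus (plus a territory-radius margin) must fit in the field of view
  if (length(object@nucleusAxes) == nd && nd >= 2) {
    fov <- object@imageShape[1:2] * object@pixelSize / 2     # half-extents, um
    ## rows extend along the minor axis, cols along the major axis
    need <- c(object@nucleusAxes[2], object@nucleusAxes[1]) *
      (1 + 1.5 * object@nucleusIrregularity) + object@territoryRadius
    if (any(need > fov))
      msg <- c(msg, "nucleus axes (+ territoryRadius margin) do not fit inside imageShape")
    if (nd == 3L) {
      fovz <- object@imageShape[3] * object@zStep / 2
      if (object@nucleusAxes[3] + object@territoryRadius > fovz)
        msg <- c(msg, "axial nucleus semi-axis (+ margin) does not fit inside the stack depth")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Create a synthetic scene configuration
#'
#' Constructor for \code{\linkS4class{SceneConfig}}. Defaults describe the
#' study conditions the generator emulates: flattened fibroblast nuclei for 2D
#' erosion analysis (field 128 x 128 px at 0.2 um/px, nucleus semi-axes
#' 10 x 6.5 um) and paraformaldehyde-fixed nuclei for confocal stacks (96 x 96
#' x 40 voxels, 0.2 um lateral, 0.2 um axial, semi-axes 8 x 5 x 2.5 um), with
#' two territories of radius 1 um per nucleus and moderate additive noise.
#'
#' @param imageShape integer raster dimensions; length 2 selects a 2D scene,
#'   length 3 a z-stack.
#' @param pixelSize lateral pixel size, um/pixel.
#' @param zStep axial spacing, um (ignored for 2D scenes).
#' @param nucleusAxes nucleus semi-axes in um (major, minor[, axial]); the
#'   default depends on the dimensionality.
#' @param nucleusIrregularity boundary perturbation amplitude (>= 0).
#' @param dapiLevel,probeLevel intensity of the DAPI plateau and the
#'   territory peak above the baseline, arbitrary units.
#' @param baselineLevel camera pedestal present in both channels everywhere.
#' @param noiseSd SD of the additive Gaussian noise.
#' @param territoryRadius territory radius, um.
#' @param territoryShape \code{"gaussian"} (sigma = radius/2) or \code{"disc"}.
#' @param territoriesPerNucleus territories per nucleus (autosome default 2).
#' @param radialLaw \code{"peripheral"}, \code{"intermediate"},
#'   \code{"interior"} or \code{"custom"}.
#' @param radialShape \code{c(alpha, beta)} of a Beta law on r; required for
#'   \code{"custom"}, ignored otherwise.
#' @param nNuclei cohort size.
#' @param seed integer seed; with the config it determines all output exactly.
#' @return A validated \code{SceneConfig}.
#' @examples
#' cfg <- sceneConfig(radialLaw = "peripheral", nNuclei = 5, seed = 1)
#' img <- makeNucleus(cfg, 1)
#' @export
sceneConfig <- function(imageShape = c(128L, 128L),
                        pixelSize = 0.2,
                        zStep = 0.2,
                        nucleusAxes = NULL,
                        nucleusIrregularity = 0.05,
                        dapiLevel = 0.8,
                        probeLevel = 1.0,
                        baselineLevel = 0.15,
                        noiseSd = 0.05,
                        territoryRadius = 1.0,
                        territoryShape = c("gaussian", "disc"),
                        territoriesPerNucleus = 2L,
                        radialLaw = c("peripheral", "intermediate",
                                      "interior", "custom"),
                        radialShape = NULL,
                        nNuclei = 50L,
                        seed = 1L) {
  radialLaw <- match.arg(radialLaw)
  territoryShape <- match.arg(territoryShape)
  imageShape <- as.integer(imageShape)
  nd <- length(imageShape)
  if (is.null(nucleusAxes))
    nucleusAxes <- if (nd == 3L) c(8, 5, 2.5) else c(10, 6.5)
  if (radialLaw == "custom") {
    if (is.null(radialShape))
      stop("radialShape = c(alpha, beta) is required for radialLaw = 'custom'")
  } else {
    radialShape <- radialLawShape(radialLaw)
  }
  new("SceneConfig",
      imageShape = imageShape,
      pixelSize = as.numeric(pixelSize),
      zStep = if (nd == 3L) as.numeric(zStep) else NA_real_,
      nucleusAxes = as.numeric(nucleusAxes),
      nucleusIrregularity = as.numeric(nucleusIrregularity),
      dapiLevel = as.numeric(dapiLevel),
      probeLevel = as.numeric(probeLevel),
      baselineLevel = as.numeric(baselineLevel),
      noiseSd = as.numeric(noiseSd),
      territoryRadius = as.numeric(territoryRadius),
      territoryShape = territoryShape,
      territoriesPerNucleus = as.integer(territoriesPerNucleus),
      radialLaw = radialLaw,
      radialShape = as.numeric(radialShape),
      nNuclei = as.integer(nNuclei),
      seed = as.integer(seed))
}

#' @rdname accessors
#' @export
setMethod("spacing", "SceneConfig", function(x) {
  if (length(x@imageShape) == 3L) c(x@pixelSize, x@pixelSize, x@zStep)
  else c(x@pixelSize, x@pixelSize)
})

setMethod("show", "SceneConfig", function(object) {
  nd <- length(object@imageShape)
  cat(sprintf("SceneConfig (%s)\n", if (nd == 3L) "z-stack" else "2D"))
  cat("  imageShape: ", paste(object@imageShape, collapse = " x "),
      "  pixelSize: ", object@pixelSize, " um",
      if (nd == 3L) sprintf("  zStep: %g um", object@zStep) else "", "\n",
      sep = "")
  cat("  nucleus semi-axes (um): ",
      paste(object@nucleusAxes, collapse = ", "),
      "  irregularity: ", object@nucleusIrregularity, "\n", sep = "")
  cat(sprintf("  %d territories/nucleus, radius %g um (%s), radialLaw %s Beta(%g, %g)\n",
              object@territoriesPerNucleus, object@territoryRadius,
              object@territoryShape, object@radialLaw,
              object@radialShape[1], object@radialShape[2]))
  cat(sprintf("  nNuclei %d, seed %d, noiseSd %g\n",
              object@nNuclei, object@seed, object@noiseSd))
})

## ---------------------------------------------------------------------------
## NucleusImage
## ---------------------------------------------------------------------------

#' Two-channel nucleus image
#'
#' One nucleus's DAPI and chromosome-paint rasters (2D matrices or 3D arrays
#' of identical shape) with per-axis physical spacing in um. Synthetic images
#' additionally carry a ground-truth table of territory placements.
#'
#' @slot id character nucleus identifier.
#' @slot dapi,probe numeric rasters of identical shape, non-negative.
#' @slot spacing numeric um per pixel/voxel along each axis (row, col[, z]).
#' @slot groundTruth \code{data.frame} with columns \code{territory},
#'   \code{x_um}, \code{y_um} (\code{z_um} for stacks), \code{r_true},
#'   \code{theta}; zero rows for real images.
#' @seealso \code{\link{makeNucleus}}, \code{\link{segmentNucleus}}
#' @export
setClass("NucleusImage",
  representation(
    id = "character",
    dapi = "array",
    probe = "array",
    spacing = "numeric",
    groundTruth = "data.frame"
  )
)

setValidity("NucleusImage", function(object) {
  msg <- character()
  if (!identical(dim(object@dapi), dim(object@probe)))
    msg <- c(msg, "dapi and probe must have identical shape")
  if (any(object@dapi < 0) || any(object@probe < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (length(object@spacing) != length(dim(object@dapi)))
    msg <- c(msg, "spacing must hold one entry per image axis")
  if (any(object@spacing <= 0))
    msg <- c(msg, "spacing entries must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a NucleusImage
#'
#' @param dapi,probe numeric matrices (2D) or 3D arrays of identical shape.
#' @param spacing physical size of one pixel/voxel along each axis, um.
#' @param id nucleus identifier.
#' @param groundTruth optional territory ground-truth table (synthetic data).
#' @return A \code{\linkS4class{NucleusImage}}.
#' @export
NucleusImage <- function(dapi, probe, spacing, id = "nucleus",
                         groundTruth = NULL) {
  if (is.null(groundTruth))
    groundTruth <- data.frame(territory = integer())
  new("NucleusImage", id = as.character(id),
      dapi = as.array(dapi), probe = as.array(probe),
      spacing = as.numeric(spacing), groundTruth = groundTruth)
}

#' @rdname accessors
#' @export
setMethod("dapi", "NucleusImage", function(x) x@dapi)

#' @rdname accessors
#' @export
setMethod("probe", "NucleusImage", function(x) x@probe)

#' @rdname accessors
#' @export
setMethod("spacing", "NucleusImage", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("groundTruth", "NucleusImage", function(x) x@groundTruth)

setMethod("show", "NucleusImage", function(object) {
  d <- dim(object@dapi)
  cat(sprintf("NucleusImage '%s': %s, spacing (%s) um%s\n",
              object@id, paste(d, collapse = " x "),
              paste(object@spacing, collapse = ", "),
              if (nrow(object@groundTruth))
                sprintf(", %d ground-truth territories",
                        nrow(object@groundTruth)) else ""))
})

## ---------------------------------------------------------------------------
## NucleusMask
## ---------------------------------------------------------------------------

#' Segmented nucleus mask
#'
#' Binary support of one nucleus (single connected component, holes filled)
#' together with its geometry: pixel/voxel area, centroid, and the full major
#' and minor axis lengths in um of the moment-fitted ellipse (for stacks,
#' fitted on the largest-area z-slice).
#'
#' @slot mask logical raster, same shape as the source image.
#' @slot area integer foreground pixel/voxel count.
#' @slot centroid numeric foreground centroid in pixel coordinates.
#' @slot axes named numeric, full \code{major} and \code{minor} axis lengths
#'   in um (major >= minor > 0).
#' @slot spacing numeric um per pixel/voxel per axis.
#' @slot threshold numeric, the global threshold used (NA for user masks).
#' @seealso \code{\link{segmentNucleus}}, \code{\link{buildShells}}
#' @export
setClass("NucleusMask",
  representation(
    mask = "array",
    area = "integer",
    centroid = "numeric",
    axes = "numeric",
    spacing = "numeric",
    threshold = "numeric"
  )
)

setValidity("NucleusMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be logical")
  if (object@area <= 0L || object@area != sum(object@mask))
    msg <- c(msg, "area must equal the number of foreground pixels (> 0)")
  if (length(object@axes) != 2L || any(object@axes <= 0) ||
      object@axes[1] < object@axes[2])
    msg <- c(msg, "axes must satisfy major >= minor > 0")
  if (length(object@spacing) != length(dim(object@mask)))
    msg <- c(msg, "spacing must hold one entry per mask axis")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("maskArray", "NucleusMask", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("nucleusArea", "NucleusMask", function(x) x@area)

#' @rdname accessors
#' @export
setMethod("nucleusCentroid", "NucleusMask", function(x) x@centroid)

#' @rdname accessors
#' @export
setMethod("nucleusAxes", "NucleusMask", function(x) x@axes)

#' @rdname accessors
#' @export
setMethod("segThreshold", "NucleusMask", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("spacing", "NucleusMask", function(x) x@spacing)

setMethod("show", "NucleusMask", function(object) {
  cat(sprintf("NucleusMask: %s, area %d px, axes %.2f x %.2f um, threshold %s\n",
              paste(dim(object@mask), collapse = " x "), object@area,
              object@axes[1], object@axes[2],
              format(object@threshold, digits = 4)))
})

## ---------------------------------------------------------------------------
## ShellPartition
## ---------------------------------------------------------------------------

#' Equal-area concentric shell partition
#'
#' Labeling of every mask pixel into \code{nShells} concentric shells of equal
#' area (up to one pixel), ordered by distance to the nuclear boundary:
#' shell 1 is the most peripheral ring, shell \code{nShells} the nuclear
#' interior. Background pixels carry label 0.
#'
#' @slot labels integer raster; 0 outside the mask, 1..nShells inside.
#' @slot shellAreas integer pixel count per shell.
#' @slot nShells integer number of shells (default analysis uses 5).
#' @seealso \code{\link{buildShells}}, \code{\link{measureShells}}
#' @export
setClass("ShellPartition",
  representation(
    labels = "array",
    shellAreas = "integer",
    nShells = "integer"
  )
)

setValidity("ShellPartition", function(object) {
  msg <- character()
  k <- object@nShells
  if (k < 2L) msg <- c(msg, "nShells must be >= 2")
  if (length(object@shellAreas) != k)
    msg <- c(msg, "shellAreas must have one entry per shell")
  if (max(object@shellAreas) - min(object@shellAreas) > k - 1L)
    msg <- c(msg, "shell areas must be equal up to integer rounding")
  lab <- object@labels
  if (!all(lab %in% 0:k))
    msg <- c(msg, "labels must be 0 (background) or 1..nShells")
  if (!identical(as.integer(tabulate(lab[lab > 0L], nbins = k)),
                 object@shellAreas))
    msg <- c(msg, "shellAreas must match the label raster")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("shellLabels", "ShellPartition", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("shellAreas", "ShellPartition", function(x) x@shellAreas)

#' @rdname accessors
#' @export
setMethod("nShells", "ShellPartition", function(x) x@nShells)

setMethod("show", "ShellPartition", function(object) {
  cat(sprintf("ShellPartition: %d shells (1 = periphery), areas [%s] px\n",
              object@nShells, paste(object@shellAreas, collapse = ", ")))
})

## ---------------------------------------------------------------------------
## ShellProfile
## ---------------------------------------------------------------------------

#' Per-nucleus shell signal profile
#'
#' For one nucleus: the percentage of total in-mask DAPI and probe intensity
#' falling in each shell, and the normalized proportion
#' \code{probePct/dapiPct}. A normalized value of 1 in every shell means the
#' paint signal is distributed like bulk DNA.
#'
#' @slot nucleusId character identifier.
#' @slot dapiPct,probePct numeric percentages per shell, each summing to 100.
#' @slot normalized numeric per-shell ratio \code{probePct/dapiPct}.
#' @seealso \code{\link{measureShells}}, \code{\link{aggregateProfiles}}
#' @export
setClass("ShellProfile",
  representation(
    nucleusId = "character",
    dapiPct = "numeric",
    probePct = "numeric",
    normalized = "numeric"
  )
)

setValidity("ShellProfile", function(object) {
  msg <- character()
  k <- length(object@normalized)
  if (length(object@dapiPct) != k || length(object@probePct) != k)
    msg <- c(msg, "dapiPct, probePct and normalized must have equal length")
  if (abs(sum(object@dapiPct) - 100) > 1e-6)
    msg <- c(msg, "dapiPct must sum to 100")
  if (abs(sum(object@probePct) - 100) > 1e-6)
    msg <- c(msg, "probePct must sum to 100")
  if (any(object@normalized < 0))
    msg <- c(msg, "normalized values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("dapiPct", "ShellProfile", function(x) x@dapiPct)

#' @rdname accessors
#' @export
setMethod("probePct", "ShellProfile", function(x) x@probePct)

#' @rdname accessors
#' @export
setMethod("normalizedProfile", "ShellProfile", function(x) x@normalized)

setMethod("show", "ShellProfile", function(object) {
  cat(sprintf("ShellProfile '%s' (shell 1 = periphery)\n", object@nucleusId))
  m <- rbind(dapiPct = object@dapiPct, probePct = object@probePct,
             normalized = object@normalized)
  colnames(m) <- paste0("shell", seq_len(ncol(m)))
  print(round(m, 3))
})

## ---------------------------------------------------------------------------
## PopulationResult
## ---------------------------------------------------------------------------

#' Condition-level shell profile summary
#'
#' Aggregation of per-nucleus normalized shell profiles for one condition:
#' per-shell mean and standard error of the mean, with the underlying
#' per-nucleus matrix retained so cohorts can be compared shell-by-shell
#' (\code{\link{compareShells}}).
#'
#' @slot condition character condition label.
#' @slot profiles numeric matrix, nuclei x shells, of normalized values.
#' @slot mean,sem numeric per-shell mean and SEM (sample SD / sqrt(n)).
#' @seealso \code{\link{aggregateProfiles}}, \code{\link{compareShells}},
#'   \code{\link{classifyPosition}}
#' @export
setClass("PopulationResult",
  representation(
    condition = "character",
    profiles = "matrix",
    mean = "numeric",
    sem = "numeric"
  )
)

setValidity("PopulationResult", function(object) {
  msg <- character()
  k <- ncol(object@profiles)
  if (nrow(object@profiles) < 2L)
    msg <- c(msg, "at least 2 nuclei are required")
  if (length(object@mean) != k || length(object@sem) != k)
    msg <- c(msg, "mean and sem must have one entry per shell")
  if (any(object@sem < 0))
    msg <- c(msg, "sem must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("conditionName", "PopulationResult", function(x) x@condition)

#' @rdname accessors
#' @export
setMethod("nNuclei", "PopulationResult", function(x) nrow(x@profiles))

#' @rdname accessors
#' @export
setMethod("shellMeans", "PopulationResult", function(x) x@mean)

#' @rdname accessors
#' @export
setMethod("shellSEM", "PopulationResult", function(x) x@sem)

#' @rdname accessors
#' @export
setMethod("profileMatrix", "PopulationResult", function(x) x@profiles)

setMethod("show", "PopulationResult", function(object) {
  cat(sprintf("PopulationResult '%s': %d nuclei, %d shells (1 = periphery)\n",
              object@condition, nrow(object@profiles), ncol(object@profiles)))
  m <- rbind(mean = object@mean, sem = object@sem)
  colnames(m) <- paste0("shell", seq_len(ncol(m)))
  print(round(m, 3))
})
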