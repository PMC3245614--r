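#' @include AllClasses.R segmentation.R
NULL

#' Segment chromosome territories in a z-stack
#'
#' Otsu threshold computed on the in-mask probe intensities, followed by 3D
#' connected-component labeling (face connectivity) restricted to the nucleus
#' mask. Components below \code{minVolume} voxels are discarded as noise
#' speckle; the surviving territories are returned largest first. A count
#' differing from \code{expectedCount} (2 signals per autosome in a diploid
#' nucleus) produces a warning, not an error.
#'
#' The probe channel is lightly denoised before thresholding (per-slice
#' Gaussian blur, \code{smoothSigma} pixels): paint channels carry additive
#' camera noise whose clipped-at-zero distribution otherwise drags the Otsu
#' threshold down into the noise and fragments it into spurious small
#' components. \code{smoothSigma = 0} disables smoothing.
#'
#' @param image a z-stack \code{\linkS4class{NucleusImage}}.
#' @param mask the nucleus \code{\linkS4class{NucleusMask}} for the stack.
#' @param minVolume minimum component volume in voxels (default 20).
#' @param expectedCount expected number of territories (default 2); use
#'   \code{NA} to disable the check.
#' @param smoothSigma pre-threshold Gaussian blur SD in pixels (default 1).
#' @return List of territory voxel sets, each an integer matrix of voxel
#'   coordinates (one row per voxel, columns row/col/slice), largest first.
#' @export
segmentTerritories <- function(image, mask, minVolume = 20L,
                               expectedCount = 2L, smoothSigma = 1) {
  stopifnot(is(image, "NucleusImage"), is(mask, "NucleusMask"))
  p <- probe(image)
  if (length(dim(p)) != 3L)
    stop("segmentTerritories operates on z-stacks")
  if (smoothSigma > 0)
    for (k in seq_len(dim(p)[3]))
      p[, , k] <- EBImage::gblur(p[, , k], sigma = smoothSigma)
  m <- maskArray(mask)
  vals <- p[m]
  if (!length(vals) || max(vals) == min(vals))
    stop("territory-detection failure: no probe contrast inside the mask")
  thr <- EBImage::otsu(matrix(vals, ncol = 1), range = range(vals),
                       levels = 256L)
  fg <- p > thr & m
  if (!any(fg))
    stop("territory-detection failure: no voxels above threshold ",
         format(thr, digits = 6))
  lab <- .label3d(fg)
  sizes <- attr(lab, "sizes")
  keep <- which(sizes >= minVolume)
  if (!length(keep))
    stop("territory-detection failure: all ", length(sizes),
         " components are below minVolume = ", minVolume, " voxels")
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  if (!is.na(expectedCount) && length(keep) != expectedCount)
    warning("detected ", length(keep), " territories; expected ",
            expectedCount)
  lapply(keep, function(k) which(lab == k, arr.ind = TRUE))
}

## Boundary voxels of a mask: foreground with at least one face-adjacent
## background neighbour (array edges count as background, but segmentation
## rejects border-touching nuclei so this is a formality).
.boundaryVoxels <- function(m) {
  d <- dim(m)
  idx <- which(m)
  ai <- arrayInd(idx, d)
  bad <- logical(length(idx))
  for (ax in seq_along(d)) {
    stride <- prod(d[seq_len(ax - 1L)])
    atLo <- ai[, ax] == 1L
    atHi <- ai[, ax] == d[ax]
    bad <- bad | atLo | atHi
    inLo <- !atLo
    bad[inLo] <- bad[inLo] | !m[idx[inLo] - stride]
    inHi <- !atHi
    bad[inHi] <- bad[inHi] | !m[idx[inHi] + stride]
  }
  ai[bad, , drop = FALSE]
}

#' Distance from a territory's geometric center to the nuclear periphery
#'
#' The geometric center is the unweighted centroid of the territory voxel
#' set, converted to um. The raw distance \code{d_raw} is the minimum, over
#' all boundary voxels of the nucleus mask (mask voxels with a face-adjacent
#' background neighbour), of the anisotropic Euclidean distance in um — the
#' three-dimensional distance to the nearest nuclear periphery. Two
#' nucleus-size normalizations are reported alongside: division by the mean
#' of the fitted major and minor axis lengths, and by the major axis alone.
#'
#' @param territory voxel coordinate matrix as returned by
#'   \code{\link{segmentTerritories}}.
#' @param mask the nucleus \code{\linkS4class{NucleusMask}} (z-stack).
#' @param nucleusId,territoryId identifiers copied into the record.
#' @return One-row \code{data.frame}: \code{nucleus_id}, \code{territory_id},
#'   \code{volume_vox}, \code{center_x_um}, \code{center_y_um},
#'   \code{center_z_um}, \code{d_raw_um}, \code{d_norm_avg},
#'   \code{d_norm_major}.
#' @export
distanceToPeriphery <- function(territory, mask, nucleusId = "nucleus",
                                territoryId = 1L) {
  stopifnot(is(mask, "NucleusMask"))
  m <- maskArray(mask)
  if (length(dim(m)) != 3L)
    stop("distanceToPeriphery expects a z-stack mask")
  sp <- spacing(mask)                              # um per axis (row, col, z)
  ctrVox <- colMeans(territory)                    # fractional voxel coords
  nearest <- round(ctrVox)
  nearest <- pmin(pmax(nearest, 1), dim(m))
  if (!m[matrix(nearest, 1)])
    stop("invalid geometry: territory centroid lies outside the nucleus mask")
  ctrUm <- (ctrVox - 0.5) * sp
  bd <- .boundaryVoxels(m)
  bdUm <- sweep(bd - 0.5, 2, sp, `*`)
  d2 <- (bdUm[, 1] - ctrUm[1])^2 + (bdUm[, 2] - ctrUm[2])^2 +
        (bdUm[, 3] - ctrUm[3])^2
  dRaw <- sqrt(min(d2))
  ax <- nucleusAxes(mask)                          # full lengths, um
  data.frame(nucleus_id = nucleusId, territory_id = territoryId,
             volume_vox = nrow(territory),
             center_x_um = ctrUm[2], center_y_um = ctrUm[1],
             center_z_um = ctrUm[3],
             d_raw_um = dRaw,
             d_norm_avg = dRaw / ((ax[1] + ax[2]) / 2),
             d_norm_major = dRaw / ax[1])
}

#' Full 3D distance analysis for one nucleus
#'
#' Segments the nucleus (unless a mask is supplied), segments its
#' territories and measures each territory's center-to-periphery distance.
#'
#' @param image a z-stack \code{\linkS4class{NucleusImage}}.
#' @param mask optional precomputed \code{\linkS4class{NucleusMask}}.
#' @param ... passed to \code{\link{segmentTerritories}}.
#' @return \code{data.frame}, one row per territory (see
#'   \code{\link{distanceToPeriphery}}).
#' @export
territoryDistances <- function(image, mask = NULL, ...) {
  if (is.null(mask)) mask <- segmentNucleus(image)
  terrs <- segmentTerritories(image, mask, ...)
  do.call(rbind, lapply(seq_along(terrs), function(i)
    distanceToPeriphery(terrs[[i]], mask, nucleusId = image@id,
                        territoryId = i)))
}

#' Frequency-distribution curve of territory-periphery distances
#'
#' Bins the chosen distance measure of a set of territory records into
#' fixed-width bins starting at zero and returns the per-bin frequency — the
#' frequency-distribution curve conventionally used to compare conditions
#' (distance on the x-axis, frequency on the y-axis), overlayable across
#' conditions.
#'
#' @param records \code{data.frame} of territory records
#'   (\code{\link{territoryDistances}}), >= 1 row.
#' @param which \code{"raw"} (um), \code{"norm_avg"} or \code{"norm_major"}
#'   (dimensionless).
#' @param binWidth bin width, um for \code{"raw"} (default 0.5) or
#'   dimensionless for the normalized measures (default 0.05).
#' @return \code{data.frame} with columns \code{bin_lo}, \code{bin_hi},
#'   \code{mid}, \code{frequency}; frequencies sum to \code{nrow(records)}.
#'   Bins are left-closed, \code{[lo, hi)}.
#' @export
frequencyCurve <- function(records, which = c("raw", "norm_avg",
                                              "norm_major"),
                           binWidth = NULL) {
  which <- match.arg(which)
  if (!nrow(records))
    stop("at least one territory record is required")
  if (is.null(binWidth))
    binWidth <- if (which == "raw") 0.5 else 0.05
  if (binWidth <= 0)
    stop("parameter error: binWidth must be > 0")
  col <- switch(which, raw = "d_raw_um", norm_avg = "d_norm_avg",
                norm_major = "d_norm_major")
  v <- records[[col]]
  nb <- max(1L, ceiling(max(v) / binWidth + 1e-9))
  bin <- pmin(floor(v / binWidth), nb - 1L)        # right edge closes last bin
  counts <- tabulate(bin + 1L, nbins = nb)
  data.frame(bin_lo = (seq_len(nb) - 1L) * binWidth,
             bin_hi = seq_len(nb) * binWidth,
             mid = (seq_len(nb) - 0.5) * binWidth,
             frequency = counts)
}
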