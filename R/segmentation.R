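#' @include AllClasses.R
NULL

## Otsu threshold over all values of a raster, computed on the data's own
## range so the resulting partition is equivariant under affine intensity
## rescaling.
.otsuThreshold <- function(x) {
  v <- as.numeric(x)
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("segmentation failure: constant image (no contrast)")
  EBImage::otsu(matrix(v, ncol = 1), range = rng, levels = 256L)
}

## Largest connected component of a binary raster. 2D uses EBImage::bwlabel;
## 3D uses igraph components on the voxel face-adjacency graph.
.largestComponent <- function(fg) {
  nd <- length(dim(fg))
  if (nd == 2L) {
    lab <- EBImage::bwlabel(fg)
    sizes <- tabulate(lab[lab > 0])
  } else {
    lab <- .label3d(fg)
    sizes <- attr(lab, "sizes")
  }
  if (!length(sizes))
    return(list(mask = fg & FALSE, sizes = integer()))
  keep <- which.max(sizes)
  list(mask = lab == keep, sizes = sort(sizes, decreasing = TRUE))
}

## 3D connected-component labeling (6-connectivity) via graph components on
## face-adjacent foreground voxel pairs. Returns an integer array; component
## sizes in attr "sizes".
.label3d <- function(fg) {
  d <- dim(fg)
  idx <- which(fg)
  out <- array(0L, d)
  if (!length(idx)) {
    attr(out, "sizes") <- integer()
    return(out)
  }
  vox <- integer(prod(d))
  vox[idx] <- seq_along(idx)          # foreground voxel -> vertex id
  edges <- integer(0)
  strides <- c(1L, d[1], d[1] * d[2])
  ai <- arrayInd(idx, d)
  for (ax in 1:3) {
    ok <- ai[, ax] < d[ax]
    from <- idx[ok]
    to <- from + strides[ax]
    hit <- fg[to]
    if (any(hit))
      edges <- c(edges, rbind(vox[from[hit]], vox[to[hit]]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  out[idx] <- comp$membership
  attr(out, "sizes") <- as.integer(comp$csize)
  out
}

## Full ellipse axis lengths (um) from the second central moments of a 2D
## binary mask: a uniform ellipse with semi-axis a has coordinate variance
## a^2/4 along that axis, so semi-axes are 2*sqrt(eigenvalues).
.ellipseAxes <- function(mask2d, pixelSize) {
  pts <- which(mask2d, arr.ind = TRUE) * pixelSize
  ctr <- colMeans(pts)
  cc <- sweep(pts, 2, ctr)
  covm <- crossprod(cc) / nrow(pts)
  ev <- eigen(covm, symmetric = TRUE, only.values = TRUE)$values
  ax <- 4 * sqrt(pmax(ev, 0))              # full lengths, major first
  c(major = ax[1], minor = ax[2])
}

#' Segment the nucleus from the DAPI channel
#'
#' Produces the binary nucleus support on which shells and periphery
#' distances are defined: a global Otsu threshold on the DAPI channel,
#' followed by hole filling (per z-slice for stacks) and retention of the
#' largest connected component. For stacks the threshold is computed over
#' all voxels jointly and the largest component is taken in 3D. The centroid
#' and moment-based ellipse axis lengths (um) are computed from the 2D mask,
#' or from the largest-area z-slice of a stack.
#'
#' A user-supplied binary mask (\code{mask} argument) bypasses thresholding,
#' e.g. for interactively outlined nuclei; geometry is still computed here.
#'
#' Nuclei touching the image border are rejected: shells and boundary
#' distances are undefined for clipped nuclei. If a secondary component
#' reaches 25\% of the largest one's size the segmentation is flagged with a
#' warning and the largest component kept.
#'
#' @param image a \code{\linkS4class{NucleusImage}} (2D or z-stack).
#' @param mask optional logical raster (same shape as the image) to use
#'   instead of automatic thresholding.
#' @return A \code{\linkS4class{NucleusMask}}.
#' @examples
#' img <- makeNucleus(sceneConfig(nNuclei = 1, seed = 4), 1)
#' m <- segmentNucleus(img)
#' nucleusAxes(m)
#' @export
segmentNucleus <- function(image, mask = NULL) {
  stopifnot(is(image, "NucleusImage"))
  x <- dapi(image)
  d <- dim(x)
  nd <- length(d)
  if (is.null(mask)) {
    thr <- .otsuThreshold(x)
    fg <- x > thr
    if (!any(fg))
      stop("segmentation failure: no foreground above threshold ",
           format(thr, digits = 6))
  } else {
    stopifnot(identical(dim(mask), d))
    fg <- mask > 0
    thr <- NA_real_
  }
  ## fill interior holes slice-wise (the only holes an epi/confocal DAPI
  ## image produces are in-plane), then keep the largest component
  if (nd == 2L) {
    fg <- EBImage::fillHull(fg) > 0
  } else {
    for (k in seq_len(d[3])) fg[, , k] <- EBImage::fillHull(fg[, , k]) > 0
  }
  lc <- .largestComponent(fg)
  sizes <- lc$sizes
  if (length(sizes) > 1L && sizes[2] >= 0.25 * sizes[1])
    warning("ambiguous segmentation: secondary component is ",
            sprintf("%.0f%%", 100 * sizes[2] / sizes[1]),
            " of the largest; keeping the largest")
  fg <- lc$mask
  if (!any(fg))
    stop("segmentation failure: no foreground component")

  ## reject nuclei clipped by the field of view
  ai <- which(fg, arr.ind = TRUE)
  if (any(ai == 1L) || any(sweep(ai, 2, d) == 0L))
    stop("segmentation failure: nucleus touches the image border")

  centroid <- colMeans(ai)
  slice2d <- if (nd == 2L) fg else {
    areas <- apply(fg, 3, sum)
    fg[, , which.max(areas)]
  }
  axes <- .ellipseAxes(slice2d, image@spacing[1])
  new("NucleusMask", mask = fg, area = as.integer(sum(fg)),
      centroid = as.numeric(centroid), axes = axes,
      spacing = image@spacing, threshold = as.numeric(thr))
}
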