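#' @include AllClasses.R
NULL

#' Read and write nucleus images as TIFF
#'
#' \code{writeNucleusTIFF} stores a \code{\linkS4class{NucleusImage}} as a
#' 32-bit float multi-page TIFF: for a 2D image, page 1 = DAPI and page 2 =
#' probe; for a z-stack of Z slices, pages 1..Z hold the DAPI slices and
#' pages Z+1..2Z the probe slices. Because the TIFF baseline stores values in
#' [0,1], both channels are divided by a single common factor
#' \code{max(1, max(intensity))} before writing; the erosion-shell and
#' distance analyses are invariant to such a common positive rescaling.
#'
#' \code{readNucleusTIFF} reverses the layout. The page count must be even;
#' for \code{zPlanes = NULL} a two-page file is read as 2D and a longer file
#' as a stack of \code{pages/2} slices.
#'
#' @param image a \code{\linkS4class{NucleusImage}}.
#' @param path TIFF file path.
#' @param spacing physical spacing in um per axis for the image being read
#'   (\code{c(dy, dx)} or \code{c(dy, dx, dz)}).
#' @param zPlanes number of z-slices per channel, or \code{NULL} to infer.
#' @param id nucleus identifier for the returned object (default: file name).
#' @return \code{writeNucleusTIFF}: the path, invisibly.
#'   \code{readNucleusTIFF}: a \code{NucleusImage} (without ground truth).
#' @examples
#' img <- makeNucleus(sceneConfig(nNuclei = 1, seed = 2), 1)
#' f <- tempfile(fileext = ".tif")
#' writeNucleusTIFF(img, f)
#' rt <- readNucleusTIFF(f, spacing = spacing(img))
#' @export
writeNucleusTIFF <- function(image, path) {
  stopifnot(is(image, "NucleusImage"))
  d <- dapi(image); p <- probe(image)
  sc <- max(1, max(d), max(p))
  toPages <- function(x) {
    if (length(dim(x)) == 2L) list(x / sc)
    else lapply(seq_len(dim(x)[3]), function(k) x[, , k] / sc)
  }
  tiff::writeTIFF(c(toPages(d), toPages(p)), path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname writeNucleusTIFF
#' @export
readNucleusTIFF <- function(path, spacing, zPlanes = NULL, id = NULL) {
  if (!file.exists(path))
    stop("cannot read TIFF: file does not exist: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  np <- length(pages)
  if (np %% 2L != 0L)
    stop("malformed nucleus TIFF (odd page count): ", path)
  if (is.null(zPlanes)) zPlanes <- if (np == 2L) 1L else np %/% 2L
  if (np != 2L * zPlanes)
    stop("nucleus TIFF has ", np, " pages; expected ", 2L * zPlanes)
  if (is.null(id)) id <- sub("\\.tiff?$", "", basename(path))
  asChannel <- function(idx) {
    if (zPlanes == 1L) as.matrix(pages[[idx]])
    else array(unlist(pages[idx + seq_len(zPlanes) - 1L]),
               dim = c(dim(pages[[idx]]), zPlanes))
  }
  NucleusImage(dapi = asChannel(1L), probe = asChannel(zPlanes + 1L),
               spacing = spacing, id = id)
}

#' Write the ground-truth table of a synthetic cohort
#'
#' One row per territory: nucleus id, territory id, true center coordinates
#' in um and the true normalized radial coordinate.
#'
#' @param images list of \code{\linkS4class{NucleusImage}} with ground truth.
#' @param path CSV output path.
#' @return The table, invisibly.
#' @export
writeGroundTruth <- function(images, path) {
  rows <- lapply(images, function(im) {
    gt <- groundTruth(im)
    if (!nrow(gt)) return(NULL)
    cbind(nucleus_id = im@id, gt)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

## Plain-list view of a SceneConfig, for YAML provenance records.
.configAsList <- function(config) {
  out <- lapply(slotNames("SceneConfig"), function(s) slot(config, s))
  names(out) <- slotNames("SceneConfig")
  out
}
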