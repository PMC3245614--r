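#' @import methods
NULL

#' Accessor generics
#'
#' Accessors for the core classes: image channels, physical voxel spacing,
#' generator ground truth, mask geometry and shell/population summaries.
#'
#' @param x an object of one of the package's classes
#' @param object an object of one of the package's classes
#' @return The slot content; see the class documentation for details.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dapi", function(x) standardGeneric("dapi"))

#' @rdname accessors
#' @export
setGeneric("probe", function(x) standardGeneric("probe"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname accessors
#' @export
setGeneric("nucleusArea", function(x) standardGeneric("nucleusArea"))

#' @rdname accessors
#' @export
setGeneric("nucleusCentroid", function(x) standardGeneric("nucleusCentroid"))

#' @rdname accessors
#' @export
setGeneric("nucleusAxes", function(x) standardGeneric("nucleusAxes"))

#' @rdname accessors
#' @export
setGeneric("segThreshold", function(x) standardGeneric("segThreshold"))

#' @rdname accessors
#' @export
setGeneric("shellLabels", function(x) standardGeneric("shellLabels"))

#' @rdname accessors
#' @export
setGeneric("shellAreas", function(x) standardGeneric("shellAreas"))

#' @rdname accessors
#' @export
setGeneric("nShells", function(x) standardGeneric("nShells"))

#' @rdname accessors
#' @export
setGeneric("dapiPct", function(x) standardGeneric("dapiPct"))

#' @rdname accessors
#' @export
setGeneric("probePct", function(x) standardGeneric("probePct"))

#' @rdname accessors
#' @export
setGeneric("normalizedProfile", function(x) standardGeneric("normalizedProfile"))

#' @rdname accessors
#' @export
setGeneric("conditionName", function(x) standardGeneric("conditionName"))

#' @rdname accessors
#' @export
setGeneric("nNuclei", function(x) standardGeneric("nNuclei"))

#' @rdname accessors
#' @export
setGeneric("shellMeans", function(x) standardGeneric("shellMeans"))

#' @rdname accessors
#' @export
setGeneric("shellSEM", function(x) standardGeneric("shellSEM"))

#' @rdname accessors
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))
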