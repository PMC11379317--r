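#' @name zoosonde-accessors
#' @title Accessors for the acoustic grid classes
#' @description Slot access goes through these generics; the discriminant
#'   scores \eqn{\Sigma}MVBS and \eqn{\Delta}MVBS are derived from the two
#'   channels on the fly, so `mvbs38 == (sumMvbs - deltaMvbs)/2` and
#'   `mvbs120 == (sumMvbs + deltaMvbs)/2` hold exactly.
#' @param object an [SvGrid-class], [BiFreqCellGrid-class],
#'   [ClassMask-class] or [DensityGrid-class] object.
#' @return matrices, vectors or data.frames as appropriate.
NULL

#' @rdname zoosonde-accessors
#' @export
setGeneric("frequency", function(object) standardGeneric("frequency"))
#' @rdname zoosonde-accessors
#' @export
setGeneric("svMatrix", function(object) standardGeneric("svMatrix"))
#' @rdname zoosonde-accessors
#' @export
setGeneric("mvbs", function(object) standardGeneric("mvbs"))
#' @rdname zoosonde-accessors
#' @export
setGeneric("depthEdges", function(object) standardGeneric("depthEdges"))
#' @rdname zoosonde-accessors
#' @export
setGeneric("depthMidpoints", function(object) standardGeneric("depthMidpoints"))
#' @rdname zoosonde-accessors
#' @export
setGeneric("pingInfo", function(object) standardGeneric("pingInfo"))
#' @rdname zoosonde-accessors
#' @export
setGeneric("nPings", function(object) standardGeneric("nPings"))
#' @rdname zoosonde-accessors
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))
#' @rdname zoosonde-accessors
#' @export
setGeneric("mvbs38", function(object) standardGeneric("mvbs38"))
#' @rdname zoosonde-accessors
#' @export
setGeneric("mvbs120", function(object) standardGeneric("mvbs120"))
#' @rdname zoosonde-accessors
#' @export
setGeneric("sumMvbs", function(object) standardGeneric("sumMvbs"))
#' @rdname zoosonde-accessors
#' @export
setGeneric("deltaMvbs", function(object) standardGeneric("deltaMvbs"))
#' @rdname zoosonde-accessors
#' @export
setGeneric("excludedMask", function(object) standardGeneric("excludedMask"))
#' @rdname zoosonde-accessors
#' @export
setGeneric("maskLabels", function(object) standardGeneric("maskLabels"))
#' @rdname zoosonde-accessors
#' @export
setGeneric("maskProvenance", function(object) standardGeneric("maskProvenance"))
#' @rdname zoosonde-accessors
#' @export
setGeneric("densityField", function(object) standardGeneric("densityField"))
#' @rdname zoosonde-accessors
#' @export
setGeneric("esrField", function(object) standardGeneric("esrField"))
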