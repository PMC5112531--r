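#' @rdname TriSurface-class
#' @param x,object an object
#' @param ... unused
#' @export
setGeneric("vertices", function(x, ...) standardGeneric("vertices"))

#' @rdname TriSurface-class
#' @export
setGeneric("faces", function(x, ...) standardGeneric("faces"))

#' @rdname TriSurface-class
#' @export
setGeneric("scalars", function(x, ...) standardGeneric("scalars"))

#' @rdname TriSurface-class
#' @param name scalar field name
#' @param value numeric vector of length \code{nVertices(x)}
#' @export
setGeneric("scalar", function(x, name) standardGeneric("scalar"))

#' @rdname TriSurface-class
#' @export
setGeneric("scalar<-", function(x, name, value) standardGeneric("scalar<-"))

#' @rdname TriSurface-class
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname SurfaceSeries-class
#' @export
setGeneric("timepoints", function(x) standardGeneric("timepoints"))

#' @rdname SurfaceSeries-class
#' @param week week label
#' @export
setGeneric("whiteSurface", function(x, week) standardGeneric("whiteSurface"))

#' @rdname SurfaceSeries-class
#' @export
setGeneric("pialSurface", function(x, week) standardGeneric("pialSurface"))

#' @rdname SurfaceSeries-class
#' @export
setGeneric("generativeLabels", function(x) standardGeneric("generativeLabels"))

#' @rdname BilayerMesh-class
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname BilayerMesh-class
#' @export
setGeneric("elements", function(x) standardGeneric("elements"))

#' @rdname BilayerMesh-class
#' @export
setGeneric("layerLabels", function(x) standardGeneric("layerLabels"))

#' @rdname BilayerMesh-class
#' @export
setGeneric("specialSet", function(x) standardGeneric("specialSet"))

#' @rdname SimResult-class
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))

#' @rdname SimResult-class
#' @export
setGeneric("diagnostics", function(x) standardGeneric("diagnostics"))

#' @rdname SimResult-class
#' @export
setGeneric("simStatus", function(x) standardGeneric("simStatus"))

#' @rdname FoldOutcome-class
#' @export
setGeneric("outcomeLabel", function(x) standardGeneric("outcomeLabel"))

#' @rdname OutcomeTable-class
#' @export
setGeneric("outcomeCounts", function(x) standardGeneric("outcomeCounts"))

#' @rdname OutcomeTable-class
#' @export
setGeneric("gyrusProportion", function(x) standardGeneric("gyrusProportion"))
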