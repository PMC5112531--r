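#' Construct a TriSurface
#'
#' @param vertices numeric n x 3 matrix of coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based triangle indices, wound
#'   counter-clockwise seen from outside.
#' @param scalars named list of per-vertex numeric vectors.
#' @return a \linkS4class{TriSurface}
#' @examples
#' s <- triSurface(rbind(c(0,0,0), c(1,0,0), c(0,1,0)), rbind(c(1,2,3)))
#' nVertices(s)
#' @export
triSurface <- function(vertices, faces, scalars = list()) {
  storage.mode(faces) <- "integer"
  new("TriSurface", vertices = as.matrix(vertices), faces = faces,
      scalars = scalars)
}

#' @rdname TriSurface-class
#' @export
setMethod("vertices", "TriSurface", function(x, ...) x@vertices)

#' @rdname TriSurface-class
#' @export
setMethod("faces", "TriSurface", function(x, ...) x@faces)

#' @rdname TriSurface-class
#' @export
setMethod("scalars", "TriSurface", function(x, ...) x@scalars)

#' @rdname TriSurface-class
#' @export
setMethod("scalar", "TriSurface", function(x, name) x@scalars[[name]])

#' @rdname TriSurface-class
#' @export
setReplaceMethod("scalar", "TriSurface", function(x, name, value) {
  x@scalars[[name]] <- value
  validObject(x)
  x
})

#' @rdname TriSurface-class
#' @export
setMethod("nVertices", "TriSurface", function(x) nrow(x@vertices))

setMethod("show", "TriSurface", function(object) {
  cat(sprintf("TriSurface: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
  if (length(object@scalars))
    cat("  scalars:", paste(names(object@scalars), collapse = ", "), "\n")
})

#' @rdname SurfaceSeries-class
#' @export
setMethod("timepoints", "SurfaceSeries", function(x) x@timepoints)

#' @rdname SurfaceSeries-class
#' @export
setMethod("whiteSurface", "SurfaceSeries", function(x, week)
  x@white[[match(week, x@timepoints)]])

#' @rdname SurfaceSeries-class
#' @export
setMethod("pialSurface", "SurfaceSeries", function(x, week)
  x@pial[[match(week, x@timepoints)]])

#' @rdname SurfaceSeries-class
#' @export
setMethod("generativeLabels", "SurfaceSeries", function(x) x@labels)

setMethod("show", "SurfaceSeries", function(object) {
  cat(sprintf("SurfaceSeries: weeks %s, %d vertices (topology %s)\n",
              paste(range(object@timepoints), collapse = "-"),
              if (length(object@white)) nrow(object@white[[1]]@vertices) else 0,
              object@topologyId))
})

#' @rdname BilayerMesh-class
#' @export
setMethod("nodes", "BilayerMesh", function(x) x@nodes)

#' @rdname BilayerMesh-class
#' @export
setMethod("elements", "BilayerMesh", function(x) x@elements)

#' @rdname BilayerMesh-class
#' @export
setMethod("layerLabels", "BilayerMesh", function(x) x@layer)

#' @rdname BilayerMesh-class
#' @export
setMethod("specialSet", "BilayerMesh", function(x) x@specialSet)

setMethod("show", "BilayerMesh", function(object) {
  d <- ncol(object@nodes)
  cat(sprintf(
    "BilayerMesh (%dD): %d nodes, %d elements (%d cortex, %d core, %d special)\n",
    d, nrow(object@nodes), nrow(object@elements),
    sum(object@layer == "cortex"), sum(object@layer == "core"),
    length(object@specialSet)))
  cat(sprintf("  plate %s mm, cortex %.2f mm\n",
              paste(object@dims, collapse = " x "), object@cortexThickness))
})

#' @rdname SimResult-class
#' @export
setMethod("profiles", "SimResult", function(x) x@profiles)

#' @rdname SimResult-class
#' @export
setMethod("diagnostics", "SimResult", function(x) x@diagnostics)

#' @rdname SimResult-class
#' @export
setMethod("simStatus", "SimResult", function(x) x@status)

setMethod("show", "SimResult", function(object) {
  dg <- object@diagnostics
  cat(sprintf("SimResult [%s]: mode %s, %d frames, final g = %.3f\n",
              object@status, object@config@mode, length(object@profiles),
              if (nrow(dg)) dg$g[nrow(dg)] else NA_real_))
  if (nrow(dg))
    cat(sprintf("  max |det A - 1| = %.4f, final KE/SE = %.2e\n",
                max(dg$maxJdev), dg$ke[nrow(dg)] / max(dg$se[nrow(dg)], 1e-300)))
})

#' @rdname FoldOutcome-class
#' @export
setMethod("outcomeLabel", "FoldOutcome", function(x) x@label)

setMethod("show", "FoldOutcome", function(object) {
  cat(sprintf("FoldOutcome: %s (centre height percentile %.1f, window %.1f mm)\n",
              object@label, object@percentile, object@window))
})

#' @rdname OutcomeTable-class
#' @export
setMethod("outcomeCounts", "OutcomeTable", function(x) x@counts)

#' @rdname OutcomeTable-class
#' @export
setMethod("gyrusProportion", "OutcomeTable", function(x)
  x@counts["gyrus", ] / x@nRuns)

setMethod("show", "OutcomeTable", function(object) {
  cat("Fold outcomes at the plate centre\n")
  m <- rbind(object@counts, sum = object@nRuns)
  print(m)
  p <- gyrusProportion(object)
  for (j in seq_along(p))
    cat(sprintf("  %s: gyrus %.0f%% (95%% CI %.0f-%.0f%%)\n",
                colnames(object@counts)[j], 100 * p[j],
                100 * object@gyrusCI[1, j], 100 * object@gyrusCI[2, j]))
})

setMethod("show", "GroupTest", function(object) {
  cat(sprintf("Pooled two-sample t test: t = %.3f, df = %d\n",
              object@t, as.integer(object@dof)))
  cat(sprintf("  group means %.4f vs %.4f (sd %.4f / %.4f, n %d / %d)\n",
              object@means[1], object@means[2], object@sds[1], object@sds[2],
              object@n[1], object@n[2]))
  cat(sprintf("  p (two tails) = %.3g, p (right tail) = %.3g\n",
              object@pTwoTail, object@pRightTail))
})

setMethod("show", "Report", function(object) {
  cat("gyrogen Report\n")
  if (nrow(object@parcelSummary)) {
    cat(" Parcel thickness summary:\n")
    print(object@parcelSummary)
  }
  if (length(object@groupTest)) show(object@groupTest[[1]])
  if (length(object@outcomes)) show(object@outcomes[[1]])
  cat(sprintf(" manifest: %d runs\n", nrow(object@manifest)))
})
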