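#' @import methods
#' @importFrom stats rnorm runif var sd pt fft coef lm predict quantile
#' @importFrom utils read.csv write.csv head tail
#' @useDynLib gyrogen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Triangle surface with per-vertex scalar fields
#'
#' A triangulated surface (white- or gray-matter sheet) holding vertex
#' coordinates in millimetres, a face list, and named per-vertex scalar
#' fields (thickness, curvature, regression slope, ...).  Faces are wound
#' counter-clockwise seen from the outside, so vertex normals computed from
#' the winding point outward.
#'
#' @slot vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @slot faces integer matrix, one row per triangle, 1-based vertex indices.
#' @slot scalars named list of numeric vectors, each of length
#'   \code{nrow(vertices)}.
#' @export
setClass("TriSurface",
  representation(vertices = "matrix", faces = "matrix", scalars = "list"),
  prototype(scalars = list()))

setValidity("TriSurface", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3) return("vertices must have 3 columns")
  if (nrow(f) > 0 && ncol(f) != 3) return("faces must have 3 columns")
  if (nrow(f) > 0) {
    if (min(f) < 1 || max(f) > nrow(v))
      return("face indices out of range")
    ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    if (any(table(key) > 2)) return("non-manifold edge (shared by > 2 faces)")
  }
  for (nm in names(object@scalars))
    if (length(object@scalars[[nm]]) != nrow(v))
      return(sprintf("scalar '%s' length != number of vertices", nm))
  TRUE
})

#' Longitudinal series of white/pial surface pairs on shared topology
#'
#' White and pial surfaces for a sequence of pseudo-gestational weeks.  All
#' surfaces share one vertex/face layout, so vertex correspondence across
#' time is the identity map (the stand-in for longitudinal surface
#' registration).
#'
#' @slot timepoints integer vector of week labels.
#' @slot white,pial lists of \linkS4class{TriSurface}, one per timepoint.
#' @slot labels character vector, generative class per vertex
#'   ("gyral"/"sulcal") when known, else zero length.
#' @slot topologyId character token; equal topology tokens assert identical
#'   vertex/face layout.
#' @slot params list echoing the generator parameters (empty for imported
#'   data).
#' @export
setClass("SurfaceSeries",
  representation(timepoints = "integer", white = "list", pial = "list",
                 labels = "character", topologyId = "character",
                 params = "list"),
  prototype(labels = character(), params = list()))

setValidity("SurfaceSeries", function(object) {
  nt <- length(object@timepoints)
  if (length(object@white) != nt || length(object@pial) != nt)
    return("white/pial lists must match the number of timepoints")
  if (nt == 0) return(TRUE)
  f0 <- object@white[[1]]@faces
  nv <- nrow(object@white[[1]]@vertices)
  for (s in c(object@white, object@pial)) {
    if (nrow(s@vertices) != nv) return("vertex counts differ across series")
    if (!identical(dim(s@faces), dim(f0)) || any(s@faces != f0))
      return("face arrays differ across series (correspondence broken)")
  }
  if (length(object@labels) && length(object@labels) != nv)
    return("labels length != number of vertices")
  TRUE
})

#' Bilayer plate mesh for the growth simulator
#'
#' Structured finite-element mesh of the cortex + core plate: quadrilaterals
#' in the 2D cross-section model, hexahedra in 3D.  The top band of elements
#' of height \code{cortexThickness} is labelled \code{"cortex"}, the rest
#' \code{"core"}; \code{specialSet} holds the element ids of the centred
#' special area (the fast-growing or stiffening patch).
#'
#' @slot nodes numeric matrix of node coordinates (mm), d columns.
#' @slot elements integer matrix of 1-based connectivity (4 or 8 columns).
#' @slot layer character vector per element: "cortex" or "core".
#' @slot specialSet integer element ids, subset of the cortex elements.
#' @slot cortexThickness numeric, mm.
#' @slot dims numeric plate extents (mm): c(width, height) in 2D,
#'   c(width, depth, height) in 3D.
#' @export
setClass("BilayerMesh",
  representation(nodes = "matrix", elements = "matrix", layer = "character",
                 specialSet = "integer", cortexThickness = "numeric",
                 dims = "numeric"))

setValidity("BilayerMesh", function(object) {
  d <- ncol(object@nodes)
  if (!d %in% c(2L, 3L)) return("nodes must have 2 or 3 columns")
  if (ncol(object@elements) != 2^d)
    return("connectivity width must be 4 (2D) or 8 (3D)")
  if (length(object@layer) != nrow(object@elements))
    return("one layer label per element required")
  if (!all(object@layer %in% c("cortex", "core")))
    return("layer labels must be 'cortex' or 'core'")
  if (length(object@specialSet) &&
      !all(object@layer[object@specialSet] == "cortex"))
    return("special area must lie inside the cortex layer")
  TRUE
})

#' Material model for the bilayer
#'
#' Near-incompressible neo-Hookean solid: shear modulus \code{mu} and a
#' volumetric penalty \code{bulkPenalty} standing in for the incompressibility
#' pressure.  \code{stiffnessSchedule} is a function of the growth fraction
#' (0 at the start of growth, 1 at full growth) returning the shear-modulus
#' multiplier of the special area; it must start at 1 and be non-decreasing.
#'
#' @slot mu numeric shear modulus (Pa).
#' @slot bulkPenalty numeric volumetric penalty modulus (Pa), >= 50 mu.
#' @slot stiffnessSchedule function(growthFraction) -> multiplier.
#' @export
setClass("Material",
  representation(mu = "numeric", bulkPenalty = "numeric",
                 stiffnessSchedule = "function"))

setValidity("Material", function(object) {
  if (object@mu <= 0) return("mu must be positive")
  if (object@bulkPenalty < 50 * object@mu)
    return("bulkPenalty must be at least 50 * mu (near-incompressibility)")
  s <- vapply(seq(0, 1, length.out = 11), object@stiffnessSchedule, 0)
  if (abs(s[1] - 1) > 1e-12)
    return("stiffnessSchedule must start at multiplier 1")
  if (any(diff(s) < -1e-12))
    return("stiffnessSchedule must be non-decreasing")
  TRUE
})

#' Per-element growth multipliers
#'
#' The isotropic growth multiplier g per element (growth tensor G = g I).
#' Growth is differential: the core keeps g = 1 while the cortex grows; in
#' the fast-patch mode the special area's extra growth is
#' \code{1 + multiplier * (g - 1)} so the patch grows \code{multiplier}
#' times faster from the shared stress-free start.
#'
#' @slot g numeric vector, one multiplier per element, all >= 1.
#' @slot coreMask logical vector, TRUE for core elements (g must be 1).
#' @slot multiplier numeric, special-area rate multiplier.
#' @export
setClass("GrowthField",
  representation(g = "numeric", coreMask = "logical", multiplier = "numeric"))

setValidity("GrowthField", function(object) {
  if (length(object@g) != length(object@coreMask))
    return("g and coreMask lengths differ")
  if (any(object@g < 1 - 1e-12)) return("growth multipliers must be >= 1")
  if (any(abs(object@g[object@coreMask] - 1) > 1e-12))
    return("core elements must not grow (g = 1)")
  TRUE
})

#' Simulation configuration
#'
#' All tunables of a bilayer growth run.  Defaults give the desk-scale 2D
#' cross-section model: a 100 x 25 mm plate with a 2 mm cortex, shear
#' modulus 330 Pa in both layers, growth ramped to \code{growthMax} = 1.6.
#'
#' @slot dims plate extents (mm).
#' @slot cortexThickness cortex thickness before growth (mm).
#' @slot elemSize in-plane element size (mm); also the cortex element height.
#' @slot mu shear modulus (Pa).
#' @slot bulkRatio bulkPenalty / mu.
#' @slot growthMax target cortical growth multiplier.
#' @slot mode one of "homogeneous", "fast_patch", "stiff_patch".
#' @slot patchMultiplier growth-rate multiplier of the special area.
#' @slot patchWidth width of the special area (mm).
#' @slot stiffFinal final shear-modulus multiplier of the stiff patch.
#' @slot perturbAmplitude initial top-surface perturbation amplitude (mm).
#' @slot seed integer seed for the perturbation field.
#' @slot damping dimensionless mass-damping coefficient per step (c dt).
#' @slot dtSafety fraction of the per-element stable time step used.
#' @slot rampSteps number of explicit steps over which g ramps to growthMax.
#' @slot chunkSteps steps between diagnostic/frame records.
#' @slot stopAmplitudeFactor stop once fold amplitude exceeds this multiple
#'   of the cortex thickness (pre-self-contact stage).
#' @slot maxRelaxChunks extra relaxation chunks after the ramp.
#' @slot dimension 2 or 3.
#' @export
setClass("SimConfig",
  representation(dims = "numeric", cortexThickness = "numeric",
                 elemSize = "numeric", mu = "numeric", bulkRatio = "numeric",
                 growthMax = "numeric", mode = "character",
                 patchMultiplier = "numeric", patchWidth = "numeric",
                 stiffFinal = "numeric", perturbAmplitude = "numeric",
                 seed = "integer", damping = "numeric", dtSafety = "numeric",
                 rampSteps = "integer", chunkSteps = "integer",
                 stopAmplitudeFactor = "numeric", maxRelaxChunks = "integer",
                 dimension = "integer"))

setValidity("SimConfig", function(object) {
  if (!object@mode %in% c("homogeneous", "fast_patch", "stiff_patch"))
    return("mode must be homogeneous, fast_patch or stiff_patch")
  if (!object@dimension %in% c(2L, 3L)) return("dimension must be 2 or 3")
  for (nm in c("cortexThickness", "elemSize", "mu", "bulkRatio",
               "patchMultiplier", "patchWidth", "stiffFinal",
               "perturbAmplitude", "damping", "dtSafety"))
    if (any(slot(object, nm) <= 0))
      return(sprintf("%s must be positive", nm))
  if (object@growthMax <= 1) return("growthMax must exceed 1")
  if (any(object@dims <= 0)) return("dims must be positive")
  TRUE
})

#' Result of a growth simulation
#'
#' Trajectory of the top-surface profile plus solver diagnostics.  The
#' \code{final} list keeps the terminal nodal positions and per-element
#' growth/stiffness so the full quadrature-point state can be reconstructed
#' with \code{\link{quadratureState}}.
#'
#' @slot profiles list of matrices (x, height) per recorded frame.
#' @slot frameGrowth numeric cortical g at each recorded frame.
#' @slot diagnostics data.frame: frame, g, ke, se, maxJdev.
#' @slot mesh the \linkS4class{BilayerMesh} (reference, perturbed).
#' @slot final list: x (current positions), g, mu (per element).
#' @slot config the \linkS4class{SimConfig} used.
#' @slot status "folded", "no_instability" or "aborted".
#' @export
setClass("SimResult",
  representation(profiles = "list", frameGrowth = "numeric",
                 diagnostics = "data.frame", mesh = "BilayerMesh",
                 final = "list", config = "SimConfig", status = "character"))

#' Classification of the plate-centre fold outcome
#'
#' @slot label "gyrus", "sulcus" or "bank".
#' @slot percentile height percentile (0-100) of the centre point within the
#'   local window after detrending.
#' @slot localSlope dimensionless local surface slope at the centre.
#' @slot window full width of the classification window (mm).
#' @slot center centre coordinate (mm).
#' @export
setClass("FoldOutcome",
  representation(label = "character", percentile = "numeric",
                 localSlope = "numeric", window = "numeric",
                 center = "numeric"))

setValidity("FoldOutcome", function(object) {
  if (!object@label %in% c("gyrus", "sulcus", "bank"))
    return("label must be gyrus, sulcus or bank")
  if (object@percentile < 0 || object@percentile > 100)
    return("percentile must lie in [0, 100]")
  TRUE
})

#' Outcome counts across seeded batches
#'
#' Counts of gyrus/sulcus/bank outcomes per simulation mode, with the exact
#' binomial 95\% confidence interval on the gyrus proportion.
#'
#' @slot counts integer matrix, rows gyrus/sulcus/bank, one column per mode.
#' @slot nRuns integer completed runs per mode.
#' @slot gyrusCI numeric matrix (2 rows: lower, upper) per mode.
#' @export
setClass("OutcomeTable",
  representation(counts = "matrix", nRuns = "integer", gyrusCI = "matrix"))

setValidity("OutcomeTable", function(object) {
  if (!all(colSums(object@counts) == object@nRuns))
    return("outcome counts must sum to the number of runs per mode")
  TRUE
})

#' Two-sample pooled-variance t test result
#'
#' Student's t test under equal variances, computed from the textbook
#' pooled-variance formula.  The right-tail p value tests the alternative
#' that the first group's mean exceeds the second's.
#'
#' @slot t statistic
#' @slot dof degrees of freedom (n1 + n2 - 2)
#' @slot pTwoTail,pRightTail p values
#' @slot means,sds,n per-group summaries (length 2)
#' @export
setClass("GroupTest",
  representation(t = "numeric", dof = "numeric", pTwoTail = "numeric",
                 pRightTail = "numeric", means = "numeric", sds = "numeric",
                 n = "numeric"))

setValidity("GroupTest", function(object) {
  p <- c(object@pTwoTail, object@pRightTail)
  if (any(p < 0 | p > 1)) return("p values must lie in [0, 1]")
  TRUE
})

#' Batch report
#'
#' Machine-readable bundle of the three study summaries: the parcel-level
#' thickness comparison, the growth-rate group test, and the fold-outcome
#' counts, together with the per-run manifest.
#'
#' @slot parcelSummary data.frame or NULL-like empty df.
#' @slot groupTest \linkS4class{GroupTest} or NULL stored in a list slot.
#' @slot outcomes \linkS4class{OutcomeTable} or NULL stored in a list slot.
#' @slot manifest data.frame of run provenance (mode, index, seed, status,
#'   label).
#' @export
setClass("Report",
  representation(parcelSummary = "data.frame", groupTest = "list",
                 outcomes = "list", manifest = "data.frame"))
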