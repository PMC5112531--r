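#' Seeded perturbation field for the simulator
#'
#' @slot nodeIds indices of the perturbed top-surface nodes.
#' @slot displacements out-of-plane offsets (mm), zero mean.
#' @slot amplitude maximum absolute offset (mm).
#' @slot seed integer seed.
#' @export
setClass("PerturbationField",
  representation(nodeIds = "integer", displacements = "numeric",
                 amplitude = "numeric", seed = "integer"))

setValidity("PerturbationField", function(object) {
  if (length(object@nodeIds) != length(object@displacements))
    return("nodeIds and displacements lengths differ")
  if (max(abs(object@displacements)) > object@amplitude + 1e-12)
    return("displacements exceed the stated amplitude")
  if (abs(mean(object@displacements)) > 1e-9 * max(object@amplitude, 1))
    return("displacements must have zero mean")
  TRUE
})

# run code with a private RNG stream, restoring the caller's state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Random initial perturbation of the top surface
#'
#' Uniform offsets in [-amplitude, amplitude] on the top-surface nodes,
#' de-meaned (and rescaled into the band if de-meaning pushed any offset
#' out).  The perturbation seeds the buckling instability; it should stay
#' negligible against the model size, so a warning is issued above 10\% of
#' the cortex thickness.
#'
#' @param mesh a \linkS4class{BilayerMesh}
#' @param amplitude maximum absolute offset (mm), > 0.
#' @param seed integer seed; the field is deterministic given the seed.
#' @return a \linkS4class{PerturbationField}
#' @examples
#' mesh <- buildBilayerMesh(simConfig(dims = c(40, 15)))
#' p <- makePerturbation(mesh, 0.05, seed = 1)
#' max(abs(p@displacements)) <= 0.05
#' @export
makePerturbation <- function(mesh, amplitude, seed = 1L) {
  if (amplitude <= 0) stop("amplitude must be positive")
  if (amplitude > 0.1 * mesh@cortexThickness)
    warning("perturbation amplitude exceeds 10% of the cortex thickness")
  top <- topSurfaceNodes(mesh)
  if (!length(top)) stop("empty top-surface node set")
  d <- withSeed(seed, runif(length(top), -amplitude, amplitude))
  d <- d - mean(d)
  m <- max(abs(d))
  if (m > amplitude) d <- d * (amplitude / m)
  d <- d - mean(d)
  new("PerturbationField", nodeIds = as.integer(top), displacements = d,
      amplitude = amplitude, seed = as.integer(seed))
}

#' Parameters of the synthetic longitudinal surface generator
#'
#' Defaults are the study conditions of the longitudinal analysis: linear
#' thickness growth over pseudo-gestational weeks 25-31 with gyral slope
#' 0.35 mm/week, sulcal slope 0.10 mm/week and residual standard deviation
#' 0.26 mm, on a corrugated 100 x 100 mm sheet with fold wavelength 30 mm,
#' fold amplitude 5 mm and a 55 x 55 vertex grid (~3000 vertices).
#'
#' @param gyralSlope,sulcalSlope thickness growth rates (mm/week).
#' @param noiseSd residual sd of the thickness trajectories (mm), >= 0.
#' @param baselineThickness cortical thickness at week 25 (mm), > 0.
#' @param foldWavelength wavelength of the corrugation (mm).
#' @param foldAmplitude amplitude of the corrugation (mm), >= 0.
#' @param nFolds optional integer; overrides foldWavelength as
#'   extent / nFolds.
#' @param extent side length of the square sheet (mm).
#' @param nGrid vertices per side.
#' @param seed integer seed.
#' @return a validated parameter list (class "SynthGrowthParams")
#' @export
synthGrowthParams <- function(gyralSlope = 0.35, sulcalSlope = 0.10,
                              noiseSd = 0.26, baselineThickness = 2,
                              foldWavelength = 30, foldAmplitude = 5,
                              nFolds = NULL, extent = 100, nGrid = 55,
                              seed = 1L) {
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (baselineThickness <= 0) stop("baselineThickness must be positive")
  if (foldAmplitude < 0) stop("foldAmplitude must be >= 0")
  if (!is.null(nFolds)) foldWavelength <- extent / nFolds
  structure(list(gyralSlope = gyralSlope, sulcalSlope = sulcalSlope,
                 noiseSd = noiseSd, baselineThickness = baselineThickness,
                 foldWavelength = foldWavelength,
                 foldAmplitude = foldAmplitude, extent = extent,
                 nGrid = as.integer(nGrid), seed = as.integer(seed)),
            class = "SynthGrowthParams")
}

# corrugated sheet: structured triangulated grid, CCW seen from +z
corrugatedSheet <- function(params) {
  n <- params$nGrid
  s <- seq(0, params$extent, length.out = n)
  k <- 2 * pi / params$foldWavelength
  phi <- pi / 7 # keep nodal lines off the vertex grid
  xy <- expand.grid(x = s, y = s)
  zgen <- sin(k * xy$x + phi) * sin(k * xy$y + phi)
  z <- params$foldAmplitude * zgen
  id <- function(i, j) (j - 1L) * n + i
  i <- rep(seq_len(n - 1L), times = n - 1L)
  j <- rep(seq_len(n - 1L), each = n - 1L)
  faces <- rbind(cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
                 cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))
  list(vertices = cbind(xy$x, xy$y, z), faces = faces, zgen = zgen,
       # analytic signed curvature scale of z = A sin sin: -lap z = 2 A k^2 zgen
       curvature = 2 * params$foldAmplitude * k^2 * zgen)
}

#' Generate a synthetic longitudinal white/pial surface series
#'
#' Emulates longitudinal fetal surface pairs over weeks 25-31 on a shared
#' mesh topology (identity vertex correspondence).  The white surface is a
#' corrugated sheet whose ridges (positive analytic curvature) are labelled
#' gyral and valleys sulcal; the vertex thickness at week w is
#' \code{baselineThickness + slope(v) (w - 25) + eps},
#' \code{eps ~ N(0, noiseSd)}, floored at 0.1 mm, and the pial surface is
#' the white surface offset by that thickness along the outward vertex
#' normal.  Deterministic given \code{params$seed}.
#'
#' @param params a \code{\link{synthGrowthParams}} list.
#' @return a \linkS4class{SurfaceSeries} whose pial surfaces carry a
#'   "thickness" scalar.
#' @examples
#' ss <- makeSurfaceSeries(synthGrowthParams(nGrid = 15, noiseSd = 0))
#' timepoints(ss)
#' @export
makeSurfaceSeries <- function(params = synthGrowthParams()) {
  sheet <- corrugatedSheet(params)
  weeks <- 25:31
  labels <- ifelse(sheet$curvature > 0, "gyral", "sulcal")
  slope <- ifelse(labels == "gyral", params$gyralSlope, params$sulcalSlope)
  nv <- nrow(sheet$vertices)
  white0 <- triSurface(sheet$vertices, sheet$faces)
  nrm <- vertexNormals(white0)
  # concave regions fold onto themselves if the offset exceeds the local
  # radius of curvature (principal curvature = half the stored mean field)
  thickMax <- params$baselineThickness + pmax(slope, 0) * (max(weeks) - 25) +
    4 * params$noiseSd
  concave <- pmin(sheet$curvature / 2, 0)
  if (any(thickMax * abs(concave) >= 1))
    stop(sprintf(paste0("degenerate pial offset: fold amplitude %.2f mm with",
                        " thickness up to %.2f mm self-intersects in valleys"),
                 params$foldAmplitude, max(thickMax)))
  noise <- withSeed(params$seed,
                    matrix(rnorm(nv * length(weeks), 0, params$noiseSd),
                           nv, length(weeks)))
  white <- list(); pial <- list()
  for (t in seq_along(weeks)) {
    th <- pmax(params$baselineThickness + slope * (weeks[t] - 25) +
                 noise[, t], 0.1)
    w <- white0
    w@scalars <- list(thickness = th)
    white[[t]] <- w
    pial[[t]] <- triSurface(sheet$vertices + nrm * th, sheet$faces,
                            scalars = list(thickness = th))
  }
  new("SurfaceSeries", timepoints = as.integer(weeks), white = white,
      pial = pial, labels = labels,
      topologyId = sprintf("grid%dx%d", params$nGrid, params$nGrid),
      params = unclass(params))
}

#' Parcel-averaged cortical thickness of gyri and sulci
#'
#' The packaged table of averaged cortical thickness (mm) for the 30 gyral
#' and 31 sulcal Destrieux parcels, as printed in the source study of
#' matured-brain MRI.
#'
#' @return a data.frame (ParcelTable) with columns parcel, class
#'   ("gyral"/"sulcal") and thickness_mm.
#' @examples
#' tab <- parcelThicknessFixture()
#' table(tab$class)
#' @export
parcelThicknessFixture <- function() {
  f <- system.file("extdata", "destrieux_parcel_thickness.csv",
                   package = "gyrogen", mustWork = TRUE)
  read.csv(f, stringsAsFactors = FALSE)
}
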