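#' Simulation configuration constructor
#'
#' Defaults describe the desk-scale 2D cross-section model used for batch
#' studies: a 100 x 25 mm bilayer plate with a 2 mm cortex, equal shear
#' modulus 330 Pa in cortex and core, volumetric penalty 400 mu, cortical
#' growth ramped linearly towards g = 1.7 with the run stopping at the
#' established wrinkle stage (fold amplitude 0.6 x cortex thickness;
#' wrinkling sets in near g = 1.5), and a centred special area one
#' buckling wavelength (14 mm) wide.  The full-scale 300 x 300 x 50 mm
#' geometry is available via \code{dims} and \code{dimension = 3}.
#'
#' @param dims plate extents in mm; c(width, height) for 2D.
#' @param cortexThickness cortex thickness before growth (mm).
#' @param elemSize cortex element size (mm); the core is graded coarser
#'   in the through-thickness direction.
#' @param mu shear modulus (Pa) of both layers.
#' @param bulkRatio volumetric penalty as a multiple of mu.
#' @param growthMax cortical growth multiplier at the end of the ramp.
#' @param mode "homogeneous", "fast_patch" (special area grows
#'   \code{patchMultiplier} times faster) or "stiff_patch" (homogeneous
#'   growth, special-area stiffness ramping to \code{stiffFinal} x mu).
#' @param patchMultiplier growth-rate multiplier of the special area.
#' @param patchWidth width of the special area (mm).
#' @param stiffFinal final stiffness multiplier of the stiff patch.
#' @param perturbAmplitude amplitude of the initial top-surface perturbation
#'   (mm); default 2.5\% of the cortex thickness.
#' @param seed integer seed for the perturbation field.
#' @param damping dimensionless mass damping per step.
#' @param dtSafety fraction of the stable explicit time step used.
#' @param rampSteps explicit steps over which growth ramps to growthMax.
#' @param chunkSteps steps between recorded frames/diagnostics.
#' @param stopAmplitudeFactor stop ramping growth once the fold amplitude
#'   exceeds this multiple of the cortex thickness (the established
#'   post-instability wrinkle stage; the run then relaxes to equilibrium at
#'   fixed growth).
#' @param maxRelaxChunks extra relaxation chunks allowed after the ramp.
#' @param dimension 2 (plane cross-section) or 3.
#' @return a validated \linkS4class{SimConfig}
#' @examples
#' cfg <- simConfig(seed = 7, mode = "fast_patch")
#' cfg@patchMultiplier
#' @export
simConfig <- function(dims = NULL, cortexThickness = 2, elemSize = 1,
                      mu = 330, bulkRatio = 400, growthMax = 1.7,
                      mode = "homogeneous", patchMultiplier = 1.2,
                      patchWidth = 14, stiffFinal = 2,
                      perturbAmplitude = 0.025 * cortexThickness,
                      seed = 1L, damping = 0.01, dtSafety = 0.35,
                      rampSteps = 36000L, chunkSteps = 400L,
                      stopAmplitudeFactor = 0.6, maxRelaxChunks = 50L,
                      dimension = 2L) {
  dimension <- as.integer(dimension)
  if (is.null(dims)) dims <- if (dimension == 2L) c(100, 25) else c(60, 60, 15)
  new("SimConfig", dims = dims, cortexThickness = cortexThickness,
      elemSize = elemSize, mu = mu, bulkRatio = bulkRatio,
      growthMax = growthMax, mode = mode, patchMultiplier = patchMultiplier,
      patchWidth = patchWidth, stiffFinal = stiffFinal,
      perturbAmplitude = perturbAmplitude, seed = as.integer(seed),
      damping = damping, dtSafety = dtSafety,
      rampSteps = as.integer(rampSteps), chunkSteps = as.integer(chunkSteps),
      stopAmplitudeFactor = stopAmplitudeFactor,
      maxRelaxChunks = as.integer(maxRelaxChunks), dimension = dimension)
}

# graded through-thickness layer heights: nc cortex layers of equal height,
# core layers growing geometrically towards the bottom so that the deep core
# is at least twice as coarse as the cortex.
gradedHeights <- function(coreHeight, h0, rmax = 1.5) {
  if (coreHeight <= h0) return(coreHeight)
  for (k in 2:200) {
    f <- function(r) h0 * sum(r^(1:k)) - coreHeight
    if (f(rmax) >= 0) {
      r <- stats::uniroot(f, c(1 + 1e-9, rmax))$root
      return(h0 * r^(1:k))
    }
  }
  stop("cannot grade core mesh")
}

#' Build the bilayer plate mesh
#'
#' Structured mesh of the cortex + core plate.  The cortex band is meshed
#' with at least two element layers of size \code{elemSize}; core layers
#' coarsen geometrically towards the bottom (the deep core ends at least
#' twice as coarse as the cortex, which carries the fine mesh).  The special
#' area is the centred patch of cortex elements of width
#' \code{patchWidth}, through the full cortex thickness.
#'
#' @param config a \linkS4class{SimConfig}
#' @return a \linkS4class{BilayerMesh}
#' @examples
#' mesh <- buildBilayerMesh(simConfig(dims = c(40, 15)))
#' table(layerLabels(mesh))
#' @export
buildBilayerMesh <- function(config) {
  d <- config@dimension
  dims <- config@dims
  tc <- config@cortexThickness
  he <- config@elemSize
  H <- dims[length(dims)]
  if (config@patchWidth > dims[1])
    stop("special area wider than the plate")
  if (tc >= H) stop("cortex thicker than the plate")
  nc <- max(2L, as.integer(round(tc / he)))
  hc <- tc / nc
  coreH <- gradedHeights(H - tc, hc * 1.25)
  # heights bottom-up: coarse core first, cortex on top
  heights <- c(rev(coreH), rep(hc, nc))
  ys <- cumsum(c(0, heights))
  ys[length(ys)] <- H
  ny <- length(heights)
  nx <- as.integer(round(dims[1] / he))
  xs <- seq(0, dims[1], length.out = nx + 1)
  if (d == 2L) {
    nodes <- cbind(rep(xs, times = ny + 1), rep(ys, each = nx + 1))
    id <- function(i, j) (j - 1L) * (nx + 1L) + i
    i <- rep(seq_len(nx), times = ny)
    j <- rep(seq_len(ny), each = nx)
    elements <- cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L))
    rowOf <- j
    layer <- ifelse(rowOf > ny - nc, "cortex", "core")
    cx <- (xs[i] + xs[i + 1L]) / 2
    special <- which(layer == "cortex" &
                     abs(cx - dims[1] / 2) <= config@patchWidth / 2)
  } else {
    nyy <- as.integer(round(dims[2] / he))
    ysd <- seq(0, dims[2], length.out = nyy + 1)
    nzp <- ny + 1L
    nodes <- cbind(rep(xs, times = (nyy + 1) * nzp),
                   rep(rep(ysd, each = nx + 1), times = nzp),
                   rep(ys, each = (nx + 1) * (nyy + 1)))
    id <- function(i, j, k)
      ((k - 1L) * (nyy + 1L) + (j - 1L)) * (nx + 1L) + i
    i <- rep(seq_len(nx), times = nyy * ny)
    j <- rep(rep(seq_len(nyy), each = nx), times = ny)
    k <- rep(seq_len(ny), each = nx * nyy)
    elements <- cbind(id(i, j, k), id(i + 1L, j, k), id(i + 1L, j + 1L, k),
                      id(i, j + 1L, k), id(i, j, k + 1L), id(i + 1L, j, k + 1L),
                      id(i + 1L, j + 1L, k + 1L), id(i, j + 1L, k + 1L))
    layer <- ifelse(k > ny - nc, "cortex", "core")
    cx <- (xs[i] + xs[i + 1L]) / 2
    cy <- (ysd[j] + ysd[j + 1L]) / 2
    special <- which(layer == "cortex" &
                     abs(cx - dims[1] / 2) <= config@patchWidth / 2 &
                     abs(cy - dims[2] / 2) <= config@patchWidth / 2)
  }
  storage.mode(elements) <- "integer"
  new("BilayerMesh", nodes = nodes, elements = elements, layer = layer,
      specialSet = as.integer(special), cortexThickness = tc, dims = dims)
}

# ids of nodes on the free (top) surface of the plate; tolerant of small
# perturbation offsets of the top row
topSurfaceNodes <- function(mesh) {
  d <- ncol(mesh@nodes)
  h <- mesh@nodes[, d]
  which(h > max(h) - 0.2 * mesh@cortexThickness)
}
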