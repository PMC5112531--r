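#' Construct a BilayerMesh from raw arrays
#'
#' Mostly useful for tests and custom geometries; \code{\link{buildBilayerMesh}}
#' builds the standard graded plate.
#'
#' @param nodes numeric node coordinates (n x 2 or n x 3, mm).
#' @param elements integer connectivity (1-based; 4 or 8 columns).
#' @param layer character per element, "cortex" or "core".
#' @param specialSet integer element ids of the special area.
#' @param cortexThickness cortex thickness (mm).
#' @param dims plate extents (mm).
#' @return a \linkS4class{BilayerMesh}
#' @export
bilayerMesh <- function(nodes, elements, layer, specialSet = integer(),
                        cortexThickness, dims) {
  storage.mode(elements) <- "integer"
  new("BilayerMesh", nodes = as.matrix(nodes), elements = elements,
      layer = layer, specialSet = as.integer(specialSet),
      cortexThickness = cortexThickness, dims = dims)
}

#' Explicit solver state
#'
#' Nodal positions/velocities plus the precomputed quadrature data, lumped
#' (mass-scaled) masses and boundary constraints of a damped explicit
#' relaxation.  Time is measured in steps: the per-element density is scaled
#' so that every element has the same stable step, and \code{dt = 1}.
#'
#' @slot mesh the \linkS4class{BilayerMesh} (reference configuration,
#'   including any perturbation).
#' @slot quad quadrature data from the compiled core.
#' @slot x,v current positions and velocities (interleaved by node).
#' @slot mass lumped nodal masses.
#' @slot con constraint matrix: node id (0-based) + unit direction with
#'   zero velocity.
#' @slot mu per-element shear modulus (Pa).
#' @slot bulkPenalty volumetric penalty (Pa).
#' @slot damping dimensionless mass damping per step.
#' @slot diag list of last-step diagnostics (ke, se, maxJdev, ok).
#' @export
setClass("SolverState",
  representation(mesh = "BilayerMesh", quad = "list", x = "numeric",
                 v = "numeric", mass = "numeric", con = "matrix",
                 mu = "numeric", bulkPenalty = "numeric", damping = "numeric",
                 diag = "list"))

plateConstraints <- function(mesh) {
  nd <- mesh@nodes
  d <- ncol(nd)
  rows <- NULL
  eps <- 1e-9
  bottom <- which(nd[, d] < min(nd[, d]) + eps) - 1L
  up <- c(rep(0, d - 1), 1)
  rows <- cbind(bottom, matrix(up, length(bottom), d, byrow = TRUE))
  for (ax in seq_len(d - 1)) {
    side <- which(nd[, ax] < min(nd[, ax]) + eps |
                  nd[, ax] > max(nd[, ax]) - eps) - 1L
    dir <- rep(0, d); dir[ax] <- 1
    rows <- rbind(rows, cbind(side, matrix(dir, length(side), d, byrow = TRUE)))
  }
  unname(rows)
}

#' Create a solver state for a mesh
#'
#' Applies the initial perturbation to the reference geometry (a stress-free
#' geometric imperfection of the top surface), precomputes quadrature data,
#' scaled masses and boundary constraints (bottom face and lateral faces on
#' rollers; \code{constraints = "none"} leaves the body free, e.g. for free
#' growth checks).
#'
#' @param mesh a \linkS4class{BilayerMesh}
#' @param config a \linkS4class{SimConfig}
#' @param perturbation optional \code{PerturbationField} from
#'   \code{\link{makePerturbation}}; \code{NULL} for none.
#' @param constraints "plate" (default) or "none".
#' @param rotation optional d x d rotation matrix applied to the whole
#'   problem (geometry and constraint directions).
#' @return a \linkS4class{SolverState}
#' @export
makeSolver <- function(mesh, config, perturbation = NULL,
                       constraints = c("plate", "none"), rotation = NULL) {
  constraints <- match.arg(constraints)
  d <- ncol(mesh@nodes)
  X <- mesh@nodes
  if (!is.null(perturbation))
    X[perturbation@nodeIds, d] <- X[perturbation@nodeIds, d] +
      perturbation@displacements
  con <- if (constraints == "plate") plateConstraints(mesh) else
    matrix(0, 0, d + 1)
  # top-surface profile nodes (pre-rotation, ordered by x; centreline in 3D)
  top <- topSurfaceNodes(mesh)
  if (d == 3L) {
    mid <- mesh@dims[2] / 2
    yy <- mesh@nodes[top, 2]
    top <- top[abs(yy - mid) < 1e-9 + min(abs(yy - mid))]
  }
  top <- top[order(mesh@nodes[top, 1])]
  if (!is.null(rotation)) {
    X <- X %*% t(rotation)
    if (nrow(con)) con[, -1] <- con[, -1, drop = FALSE] %*% t(rotation)
  }
  elems0 <- mesh@elements - 1L
  quad <- if (d == 2L) feQuadData2D(X, elems0) else feQuadData3D(X, elems0)
  quad$top <- top
  K <- config@bulkRatio * config@mu
  # per-element mass scaling: equal stable step for all elements at dt = 1
  muCap <- rep(config@mu, nrow(mesh@elements))
  if (config@mode == "stiff_patch")
    muCap[mesh@specialSet] <- config@mu * config@stiffFinal
  rho <- (K + 2 * muCap) * (1 / (config@dtSafety * quad$lmin))^2
  nv <- ncol(mesh@elements)
  melem <- rho * quad$vol / nv
  mperm <- rowsum(rep(melem, nv), as.vector(mesh@elements))
  mass <- numeric(nrow(X))
  mass[as.integer(rownames(mperm))] <- mperm[, 1]
  meshP <- mesh
  meshP@nodes <- X
  new("SolverState", mesh = meshP, quad = quad,
      x = as.numeric(t(X)), v = numeric(length(X)), mass = mass, con = con,
      mu = rep(config@mu, nrow(mesh@elements)), bulkPenalty = K,
      damping = config@damping, diag = list())
}

#' Advance the explicit relaxation
#'
#' Runs \code{nsteps} damped central-difference steps towards mechanical
#' equilibrium (div sigma = 0) at fixed growth.  Internal forces come from
#' the near-incompressible neo-Hookean stress of the elastically deformed
#' state A = F G^-1; mass damping drains kinetic energy.
#'
#' @param state a \linkS4class{SolverState}
#' @param growth per-element growth multipliers (numeric vector, a scalar
#'   recycled over cortex elements only, or a \linkS4class{GrowthField}).
#' @param mu optional per-element shear moduli overriding the state's.
#' @param nsteps number of explicit steps.
#' @return the updated \linkS4class{SolverState}; \code{state@diag} holds
#'   ke, se, maxJdev and ok.
#' @export
stepExplicit <- function(state, growth, mu = NULL, nsteps = 1L) {
  mesh <- state@mesh
  ne <- nrow(mesh@elements)
  g <- if (is(growth, "GrowthField")) growth@g
       else if (length(growth) == 1L)
         ifelse(mesh@layer == "cortex", growth, 1)
       else growth
  if (length(g) != ne) stop("growth must give one multiplier per element")
  if (any(g < 1 - 1e-12)) stop("growth multipliers must be >= 1")
  if (!is.null(mu)) state@mu <- rep(mu, length.out = ne)
  d <- ncol(mesh@nodes)
  run <- if (d == 2L) feRun2D else feRun3D
  res <- run(mesh@nodes, mesh@elements - 1L, state@quad, state@x, state@v,
             as.numeric(g), state@mu, state@bulkPenalty, state@mass,
             state@con, state@damping, 1.0, as.integer(nsteps))
  if (!res$ok)
    warning(sprintf("element inversion in element %d at step %d",
                    res$badElem, res$failStep))
  state@x <- res$x
  state@v <- res$v
  state@diag <- res[c("ke", "se", "maxJdev", "maxJdevRun", "ok", "badElem",
                      "failStep")]
  state@diag$g <- as.numeric(g)
  state
}

# top-surface profile (x, height) in the mesh frame, ordered by reference x
solverProfile <- function(state, rotation = NULL) {
  d <- ncol(state@mesh@nodes)
  xc <- matrix(state@x, ncol = d, byrow = TRUE)[state@quad$top, , drop = FALSE]
  if (!is.null(rotation)) xc <- xc %*% rotation # de-rotate (R^T = R^-1)
  cbind(x = xc[, 1], height = xc[, d])
}

profileAmplitude <- function(profile) {
  h <- profile[, 2]
  x <- profile[, 1]
  r <- stats::lm.fit(cbind(1, x), h)$residuals
  max(r) - min(r)
}

#' Run a growing-bilayer simulation
#'
#' Applies the seeded perturbation, ramps the cortical growth multiplier
#' linearly to \code{growthMax} under damped explicit relaxation, and
#' records top-surface frames and diagnostics.  In \code{fast_patch} mode
#' the special area grows \code{patchMultiplier} times faster; in
#' \code{stiff_patch} mode growth is homogeneous but the special area's
#' shear modulus ramps linearly in growth to \code{stiffFinal} times mu.
#' The run stops early once the fold amplitude reaches
#' \code{stopAmplitudeFactor} times the cortex thickness (the folded,
#' pre-self-contact stage used for outcome classification); after a full
#' ramp it relaxes until the kinetic energy is negligible.  Deterministic
#' given \code{config@seed}.
#'
#' @param config a \linkS4class{SimConfig}
#' @param rotation optional rotation matrix (objectivity checks); profiles
#'   are reported in the unrotated mesh frame.
#' @param perturbation optional \code{PerturbationField} overriding the
#'   seeded default.
#' @return a \linkS4class{SimResult}
#' @examples
#' \donttest{
#' res <- runSimulation(simConfig(seed = 3, mode = "fast_patch"))
#' simStatus(res)
#' }
#' @export
runSimulation <- function(config, rotation = NULL, perturbation = NULL) {
  mesh <- buildBilayerMesh(config)
  if (is.null(perturbation))
    perturbation <- makePerturbation(mesh, config@perturbAmplitude,
                                     config@seed)
  state <- makeSolver(mesh, config, perturbation, rotation = rotation)
  ne <- nrow(mesh@elements)
  cortex <- mesh@layer == "cortex"
  spec <- mesh@specialSet
  nChunks <- max(1L, ceiling(config@rampSteps / config@chunkSteps))
  prof <- list(); fg <- numeric(); dg <- NULL
  status <- "folded"
  stopAmp <- config@stopAmplitudeFactor * config@cortexThickness
  sched <- stiffnessRamp(config@stiffFinal)
  folded <- FALSE
  for (chunk in seq_len(nChunks)) {
    f <- chunk / nChunks
    gbase <- 1 + (config@growthMax - 1) * f
    g <- rep(1, ne)
    g[cortex] <- gbase
    if (config@mode == "fast_patch")
      g[spec] <- 1 + config@patchMultiplier * (gbase - 1)
    mu <- rep(config@mu, ne)
    if (config@mode == "stiff_patch") mu[spec] <- config@mu * sched(f)
    state <- stepExplicit(state, g, mu = mu, nsteps = config@chunkSteps)
    p <- solverProfile(state, rotation)
    prof[[length(prof) + 1L]] <- p
    fg <- c(fg, gbase)
    dg <- rbind(dg, data.frame(frame = length(prof), g = gbase,
                               ke = state@diag$ke, se = state@diag$se,
                               maxJdev = state@diag$maxJdev,
                               maxJdevRun = state@diag$maxJdevRun))
    if (!state@diag$ok) { status <- "aborted"; break }
    if (profileAmplitude(p) >= stopAmp) { folded <- TRUE; break }
  }
  # runs that complete the ramp without folding relax at fixed growth until
  # the kinetic energy is negligible; amplitude-stopped runs keep the
  # detection-stage pattern (the wrinkled state is transient towards cusp
  # localisation, and the fold sites are selected at wrinkling)
  if (status != "aborted" && !folded) {
    keTol <- 1e-7
    for (r in seq_len(config@maxRelaxChunks)) {
      if (state@diag$ke < keTol * max(state@diag$se, 1e-300)) break
      state <- stepExplicit(state, g, mu = mu, nsteps = config@chunkSteps)
      p <- solverProfile(state, rotation)
      prof[[length(prof) + 1L]] <- p
      fg <- c(fg, fg[length(fg)])
      dg <- rbind(dg, data.frame(frame = length(prof), g = fg[length(fg)],
                                 ke = state@diag$ke, se = state@diag$se,
                                 maxJdev = state@diag$maxJdev,
                                 maxJdevRun = state@diag$maxJdevRun))
      if (!state@diag$ok) { status <- "aborted"; break }
    }
  }
  if (status != "aborted" &&
      profileAmplitude(prof[[length(prof)]]) < 0.1 * config@cortexThickness)
    status <- "no_instability"
  new("SimResult", profiles = prof, frameGrowth = fg,
      diagnostics = dg, mesh = state@mesh,
      final = list(x = state@x, g = g, mu = state@mu,
                   bulkPenalty = state@bulkPenalty),
      config = config, status = status)
}

#' Per-quadrature-point kinematic and stress state
#'
#' Reconstructs F, G, A = F G^-1, det A, the Cauchy stress, penalty
#' pressure, strain-energy density and principal elastic stretches at every
#' integration point of a finished run (or for explicit arrays).
#'
#' @param x a \linkS4class{SimResult}
#' @return a data.frame, one row per integration point
#' @export
setGeneric("quadratureState", function(x) standardGeneric("quadratureState"))

#' @rdname quadratureState
#' @export
setMethod("quadratureState", "SolverState", function(x) {
  mesh <- x@mesh
  if (ncol(mesh@nodes) != 2L)
    stop("quadrature state extraction is implemented in 2D")
  g <- x@diag$g
  if (is.null(g)) g <- rep(1, nrow(mesh@elements))
  m <- feState2D(mesh@nodes, mesh@elements - 1L, x@quad, x@x, g, x@mu,
                 x@bulkPenalty)
  quadStateFrame(m)
})

quadStateFrame <- function(m) {
  df <- as.data.frame(m)
  names(df) <- c("elem", "gp", "F11", "F12", "F21", "F22", "g",
                 "A11", "A12", "A21", "A22", "detA",
                 "sxx", "syy", "sxy", "p", "W", "lambda1", "lambda2")
  df
}

#' @rdname quadratureState
#' @export
setMethod("quadratureState", "SimResult", function(x) {
  mesh <- x@mesh
  d <- ncol(mesh@nodes)
  fn <- if (d == 2L) feState2D else NULL
  if (is.null(fn)) stop("quadrature state extraction is implemented in 2D")
  quad <- feQuadData2D(mesh@nodes, mesh@elements - 1L)
  m <- feState2D(mesh@nodes, mesh@elements - 1L, quad, x@final$x,
                 x@final$g, x@final$mu, x@final$bulkPenalty)
  quadStateFrame(m)
})
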