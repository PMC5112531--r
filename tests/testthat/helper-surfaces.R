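# analytic test surfaces built in code

# UV sphere: rows of latitude, outward CCW winding
makeUVSphere <- function(radius = 1, nLat = 32, nLon = 64) {
  lat <- seq(-pi / 2, pi / 2, length.out = nLat + 2)[2:(nLat + 1)]
  lon <- seq(0, 2 * pi, length.out = nLon + 1)[-(nLon + 1)]
  grid <- expand.grid(lon = lon, lat = lat)
  v <- radius * cbind(cos(grid$lat) * cos(grid$lon),
                      cos(grid$lat) * sin(grid$lon),
                      sin(grid$lat))
  idx <- function(i, j) (j - 1L) * nLon + ((i - 1L) %% nLon) + 1L
  f <- NULL
  for (j in seq_len(nLat - 1))
    for (i in seq_len(nLon))
      f <- rbind(f,
                 c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                 c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  npole <- nrow(v) + 1L; spole <- nrow(v) + 2L
  v <- rbind(v, c(0, 0, radius), c(0, 0, -radius))
  for (i in seq_len(nLon)) {
    f <- rbind(f, c(idx(i, nLat), idx(i + 1, nLat), npole),
               c(idx(i + 1, 1), idx(i, 1), spole))
  }
  triSurface(v, f)
}

# open cylinder along z, outward normals
makeCylinder <- function(radius = 2, len = 10, nCirc = 48, nz = 12) {
  th <- seq(0, 2 * pi, length.out = nCirc + 1)[-(nCirc + 1)]
  z <- seq(0, len, length.out = nz)
  g <- expand.grid(th = th, z = z)
  v <- cbind(radius * cos(g$th), radius * sin(g$th), g$z)
  idx <- function(i, j) (j - 1L) * nCirc + ((i - 1L) %% nCirc) + 1L
  f <- NULL
  for (j in seq_len(nz - 1))
    for (i in seq_len(nCirc))
      f <- rbind(f,
                 c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                 c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  triSurface(v, f)
}

# flat triangulated grid in the z = z0 plane, normals +z
makePlaneGrid <- function(n = 10, spacing = 1, z0 = 0) {
  s <- seq(0, by = spacing, length.out = n)
  g <- expand.grid(x = s, y = s)
  v <- cbind(g$x, g$y, z0)
  id <- function(i, j) (j - 1L) * n + i
  i <- rep(seq_len(n - 1L), times = n - 1L)
  j <- rep(seq_len(n - 1L), each = n - 1L)
  f <- rbind(cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
             cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))
  triSurface(v, f)
}

# a single square element bilayer "mesh" (for element-level oracles)
singleElementMesh <- function(size = 1) {
  bilayerMesh(nodes = rbind(c(0, 0), c(size, 0), c(size, size), c(0, size)),
              elements = matrix(1:4, 1), layer = "cortex",
              cortexThickness = size, dims = c(size, size * 2))
}

# small, fast 2D configuration for solver property tests (sub-instability)
tinyConfig <- function(...) {
  simConfig(dims = c(40, 12), growthMax = 1.4, rampSteps = 4000L,
            chunkSteps = 200L, maxRelaxChunks = 10L, ...)
}

# independent neo-Hookean energy for finite-difference stress oracles
refEnergy <- function(A, mu, K) {
  d <- nrow(A)
  J <- det(A)
  mu / 2 * (sum(A * A) - d - 2 * log(J)) + K / 2 * (J - 1)^2
}

# finite-difference Cauchy stress from the reference energy:
# P = dW/dA (central differences), sigma = P A^T / det(A)
fdCauchy <- function(A, mu, K, h = 1e-6) {
  d <- nrow(A)
  P <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    Ap <- A; Am <- A
    Ap[i, j] <- Ap[i, j] + h
    Am[i, j] <- Am[i, j] - h
    P[i, j] <- (refEnergy(Ap, mu, K) - refEnergy(Am, mu, K)) / (2 * h)
  }
  (P %*% t(A)) / det(A)
}
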