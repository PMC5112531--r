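test_that("zero growth is an exact equilibrium fixed point", {
  cfg <- tinyConfig()
  mesh <- buildBilayerMesh(cfg)
  st <- makeSolver(mesh, cfg)
  x0 <- st@x
  st <- stepExplicit(st, 1, nsteps = 300L)
  expect_equal(st@x, x0, tolerance = 1e-14)
  expect_lt(st@diag$ke, 1e-20)
})

test_that("a perturbed plate without growth differential never folds", {
  cfg <- tinyConfig(perturbAmplitude = 0.05)
  mesh <- buildBilayerMesh(cfg)
  p <- makePerturbation(mesh, 0.05, seed = 3)
  st <- makeSolver(mesh, cfg, p)
  st <- stepExplicit(st, 1, nsteps = 2000L)
  prof <- gyrogen:::solverProfile(st)
  amp <- max(prof[, 2]) - min(prof[, 2])
  expect_lt(amp, 0.1 * cfg@cortexThickness)
})

test_that("unconstrained homogeneous growth is stress free", {
  mesh <- singleElementMesh()
  cfg <- tinyConfig()
  st <- makeSolver(mesh, cfg, constraints = "none")
  for (g in seq(1.02, 1.3, by = 0.02))
    st <- stepExplicit(st, rep(g, 1), nsteps = 300L)
  for (k in 1:30) st <- stepExplicit(st, rep(1.3, 1), nsteps = 300L)
  qs <- quadratureState(st)
  expect_lt(max(abs(c(qs$sxx, qs$syy, qs$sxy))), 1e-6 * cfg@mu)
  # nodes scale by g: element edge length approx g * size
  xm <- matrix(st@x, ncol = 2, byrow = TRUE)
  expect_equal(max(xm[, 1]) - min(xm[, 1]), 1.3, tolerance = 1e-4)
})

test_that("fully confined growth matches the element-level energy oracle", {
  mesh <- singleElementMesh()
  cfg <- tinyConfig()
  st <- makeSolver(mesh, cfg, constraints = "none")
  # pin all nodes: constrain both axes
  st@con <- rbind(cbind(0:3, 1, 0), cbind(0:3, 0, 1))
  g <- 1.2
  st <- stepExplicit(st, rep(g, 1), nsteps = 10L)
  qs <- quadratureState(st)
  # F = I, so A = I/g at every quadrature point
  expect_equal(unique(round(qs$A11, 12)), 1 / g)
  sig <- cauchyStress(diag(1 / g, 2),
                      material(cfg@mu, cfg@bulkRatio * cfg@mu))$sigma
  fd <- fdCauchy(diag(1 / g, 2), cfg@mu, cfg@bulkRatio * cfg@mu)
  expect_equal(qs$sxx[1], sig[1, 1], tolerance = 1e-10)
  expect_lt(max(abs(sig - fd)) / max(abs(sig)), 1e-6)
})

test_that("kinetic energy decays monotonically once forcing stops", {
  cfg <- tinyConfig()
  mesh <- buildBilayerMesh(cfg)
  st <- makeSolver(mesh, cfg)
  st <- stepExplicit(st, 1.05, nsteps = 400L)
  kes <- numeric(8)
  for (i in seq_along(kes)) {
    st <- stepExplicit(st, 1.05, nsteps = 200L)
    kes[i] <- st@diag$ke
  }
  expect_true(all(diff(kes) < 0))
})

test_that("growth kinematics stay multiplicatively consistent in a run", {
  sim <- runSimulation(tinyConfig(seed = 5))
  qs <- quadratureState(sim)
  # A = F G^-1 reconstruction: A * g - F
  err <- max(abs(c(qs$A11 * qs$g - qs$F11, qs$A12 * qs$g - qs$F12,
                   qs$A21 * qs$g - qs$F21, qs$A22 * qs$g - qs$F22)))
  expect_lt(err, 1e-10)
  expect_lt(max(abs(qs$detA - 1)), 0.02)
  expect_true(all(diagnostics(sim)$maxJdev <= 0.02))
  expect_true(all(is.finite(as.matrix(diagnostics(sim)))))
})

test_that("simulation results are deterministic given the seed", {
  cfg <- tinyConfig(seed = 9)
  s1 <- runSimulation(cfg)
  s2 <- runSimulation(cfg)
  expect_identical(profiles(s1), profiles(s2))
  expect_identical(diagnostics(s1), diagnostics(s2))
})

test_that("mirroring the perturbation mirrors the deformed profile", {
  cfg <- tinyConfig(seed = 4)
  mesh <- buildBilayerMesh(cfg)
  p <- makePerturbation(mesh, cfg@perturbAmplitude, seed = 4)
  pm <- p
  pm@displacements <- rev(p@displacements) # top nodes are ordered in x
  s1 <- runSimulation(cfg, perturbation = p)
  s2 <- runSimulation(cfg, perturbation = pm)
  h1 <- profiles(s1)[[length(profiles(s1))]][, 2]
  h2 <- profiles(s2)[[length(profiles(s2))]][, 2]
  expect_equal(h2, rev(h1), tolerance = 1e-8)
})

test_that("rigidly rotating the problem leaves the profile unchanged", {
  th <- pi / 6
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  cfg <- tinyConfig(seed = 2)
  s1 <- runSimulation(cfg)
  s2 <- runSimulation(cfg, rotation = R)
  p1 <- profiles(s1)[[length(profiles(s1))]]
  p2 <- profiles(s2)[[length(profiles(s2))]]
  expect_equal(nrow(p1), nrow(p2))
  expect_lt(max(abs(p1[, 2] - p2[, 2])), 1e-5)
})

test_that("the 3D solver holds the same elementary properties", {
  nodes <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))
  nodes <- nodes[c(1, 2, 4, 3, 5, 6, 8, 7), ]
  mesh <- bilayerMesh(nodes, matrix(1:8, 1), layer = "cortex",
                      cortexThickness = 1, dims = c(1, 1, 2))
  cfg <- tinyConfig(dimension = 3)
  st <- makeSolver(mesh, cfg, constraints = "none")
  x0 <- st@x
  st <- stepExplicit(st, 1, nsteps = 100L)
  expect_lt(max(abs(st@x - x0)), 1e-10)
  for (g in seq(1.05, 1.2, by = 0.05))
    st <- stepExplicit(st, rep(g, 1), nsteps = 400L)
  for (k in 1:20) st <- stepExplicit(st, rep(1.2, 1), nsteps = 400L)
  xm <- matrix(st@x, ncol = 3, byrow = TRUE)
  expect_equal(max(xm[, 1]) - min(xm[, 1]), 1.2, tolerance = 1e-3)
  expect_true(st@diag$ok)
})
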