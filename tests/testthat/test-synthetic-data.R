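test_that("noise-free thickness trajectories are exactly linear", {
  p <- synthGrowthParams(nGrid = 15, noiseSd = 0)
  ss <- makeSurfaceSeries(p)
  expect_equal(timepoints(ss), 25:31)
  lab <- generativeLabels(ss)
  ridge <- which(lab == "gyral")[1]
  th31 <- scalar(whiteSurface(ss, 31), "thickness")
  expect_equal(th31[ridge], 2 + 0.35 * 6)
  valley <- which(lab == "sulcal")[1]
  expect_equal(th31[valley], 2 + 0.10 * 6)
})

test_that("zero growth and zero noise freeze the thickness maps", {
  p <- synthGrowthParams(nGrid = 12, gyralSlope = 0, sulcalSlope = 0,
                         noiseSd = 0)
  ss <- makeSurfaceSeries(p)
  maps <- lapply(25:31, function(w) scalar(whiteSurface(ss, w), "thickness"))
  for (m in maps[-1]) expect_identical(m, maps[[1]])
  pials <- lapply(25:31, function(w) vertices(pialSurface(ss, w)))
  for (m in pials[-1]) expect_identical(m, pials[[1]])
})

test_that("the generator is bit-deterministic given the seed", {
  p <- synthGrowthParams(nGrid = 12, seed = 77)
  s1 <- makeSurfaceSeries(p)
  s2 <- makeSurfaceSeries(p)
  expect_identical(s1, s2)
  s3 <- makeSurfaceSeries(synthGrowthParams(nGrid = 12, seed = 78))
  expect_false(identical(scalar(s1@white[[1]], "thickness"),
                         scalar(s3@white[[1]], "thickness")))
  # generation does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(3)
  set.seed(1); invisible(makeSurfaceSeries(p)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("pial surfaces lie strictly outside the white surfaces", {
  ss <- makeSurfaceSeries(synthGrowthParams(nGrid = 15))
  area <- function(s) {
    v <- vertices(s); f <- faces(s)
    e1 <- v[f[, 2], ] - v[f[, 1], ]; e2 <- v[f[, 3], ] - v[f[, 1], ]
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    sum(sqrt(rowSums(cr^2))) / 2
  }
  for (w in c(25, 28, 31)) {
    th <- computeThickness(whiteSurface(ss, w), pialSurface(ss, w))
    expect_true(all(th > 0))
    expect_gt(area(pialSurface(ss, w)), area(whiteSurface(ss, w)))
  }
})

test_that("degenerate pial offsets are rejected with a clear message", {
  p <- synthGrowthParams(nGrid = 15, foldWavelength = 10, foldAmplitude = 5,
                         baselineThickness = 4)
  expect_error(makeSurfaceSeries(p), "amplitude 5.00.*self-intersects")
})

test_that("series validity enforces shared topology", {
  ss <- makeSurfaceSeries(synthGrowthParams(nGrid = 10))
  broken <- ss
  expect_error({
    broken@white[[2]] <- makePlaneGrid(9)
    validObject(broken)
  }, "differ|counts")
})

test_that("perturbation fields honour their contracts", {
  mesh <- buildBilayerMesh(simConfig(dims = c(50, 15)))
  p <- makePerturbation(mesh, 0.05, seed = 1)
  expect_lte(max(abs(p@displacements)), 0.05)
  expect_lt(abs(mean(p@displacements)), 1e-12)
  expect_equal(length(p@nodeIds), 51)
  p2 <- makePerturbation(mesh, 0.05, seed = 2)
  expect_false(identical(p@displacements, p2@displacements))
  expect_identical(makePerturbation(mesh, 0.05, seed = 1)@displacements,
                   p@displacements)
  expect_warning(makePerturbation(mesh, 0.5, seed = 1), "10%")
  expect_error(makePerturbation(mesh, 0), "positive")
})

test_that("the packaged parcel table matches the printed values", {
  tab <- parcelThicknessFixture()
  expect_equal(sum(tab$class == "gyral"), 30)
  expect_equal(sum(tab$class == "sulcal"), 31)
  expect_equal(tab$thickness_mm[tab$parcel == "G_insular_short"], 3.73)
  expect_equal(tab$thickness_mm[tab$parcel == "S_pericallosal"], 1.83)
  expect_equal(round(mean(tab$thickness_mm[tab$class == "sulcal"]), 2), 2.59)
  expect_equal(round(mean(tab$thickness_mm[tab$class == "gyral"]), 2), 2.92)
})
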