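test_that("thickness between aligned parallel planes is the gap", {
  w <- makePlaneGrid(8, spacing = 2, z0 = 0)
  p <- makePlaneGrid(8, spacing = 2, z0 = 2.5)
  expect_equal(computeThickness(w, p), rep(2.5, nVertices(w)))
  expect_equal(computeThickness(w, w), rep(0, nVertices(w)))
  empty <- triSurface(matrix(0, 0, 3), matrix(integer(0), 0, 3))
  expect_error(computeThickness(w, empty), "empty")
})

test_that("thickness equals the all-pairs nearest-vertex oracle", {
  set.seed(21)
  for (rep in 1:5) {
    a <- triSurface(matrix(rnorm(60), ncol = 3), matrix(integer(0), 0, 3))
    b <- triSurface(matrix(rnorm(90), ncol = 3), matrix(integer(0), 0, 3))
    # brute-force oracle: explicit double loop over all vertex pairs
    oracle <- apply(vertices(a), 1, function(p)
      min(sqrt(colSums((t(vertices(b)) - p)^2))))
    expect_equal(computeThickness(a, b), oracle, tolerance = 1e-12)
  }
})

test_that("projection thickness refines but never exceeds nearest-vertex", {
  set.seed(3)
  w <- makePlaneGrid(6, spacing = 1, z0 = 0)
  pv <- vertices(makePlaneGrid(6, spacing = 1, z0 = 2))
  pv[, 1:2] <- pv[, 1:2] + 0.4 # misaligned grid
  p <- triSurface(pv, faces(makePlaneGrid(6)))
  dn <- computeThickness(w, p)
  dp <- computeThickness(w, p, method = "projection")
  expect_true(all(dp <= dn + 1e-12))
  inner <- which(dn < 2.2)
  expect_true(any(dp[inner] < dn[inner] - 1e-6))
})

test_that("MPC is +1 on the unit sphere and 0 on a plane", {
  sph <- makeUVSphere(1, nLat = 30, nLon = 66) # ~2k vertices
  mpc <- computeMPC(sph)
  expect_gt(mean(!is.na(mpc)), 0.99)
  expect_lt(max(abs(mpc[!is.na(mpc)] - 1)), 0.05)
  pl <- computeMPC(makePlaneGrid(12))
  expect_lt(max(abs(pl), na.rm = TRUE), 1e-8)
})

test_that("MPC on a cylinder is +1/R and the sign follows orientation", {
  R <- 2
  cyl <- makeCylinder(radius = R, len = 10, nCirc = 60, nz = 10)
  mpc <- computeMPC(cyl)
  interior <- which(!is.na(mpc))
  # drop boundary rows (first/last ring have one-sided neighbourhoods)
  zs <- vertices(cyl)[, 3]
  interior <- interior[zs[interior] > 1 & zs[interior] < 9]
  expect_equal(mean(mpc[interior]), 1 / R, tolerance = 0.05 / R)
  flipped <- triSurface(vertices(cyl), faces(cyl)[, c(1, 3, 2)])
  mpcF <- computeMPC(flipped)
  expect_equal(mpcF[interior], -mpc[interior], tolerance = 1e-9)
})

test_that("the magnitude and signed MPC conventions differ on saddles", {
  # saddle z = (2 y^2 - x^2)/2: convex-positive curvatures (+1, -2), so the
  # magnitude convention picks -2 and the signed convention +1
  s <- seq(-1, 1, length.out = 15)
  g <- expand.grid(x = s, y = s)
  v <- cbind(g$x, g$y, (2 * g$y^2 - g$x^2) / 2)
  f <- faces(makePlaneGrid(15))
  sad <- triSurface(v, f)
  ctr <- which(abs(g$x) < 1e-9 & abs(g$y) < 1e-9)
  mMag <- computeMPC(sad)[ctr]
  mSgn <- computeMPC(sad, convention = "signed")[ctr]
  expect_equal(mMag, -2, tolerance = 0.1)
  expect_equal(mSgn, 1, tolerance = 0.1)
})

test_that("growth-rate regression matches the closed-form OLS oracle", {
  weeks <- 25:31
  exact <- fitGrowthRate(2 + 0.35 * (weeks - 25), weeks)
  expect_equal(exact$slope, 0.35, tolerance = 1e-12)
  expect_equal(exact$intercept, 2 - 0.35 * 25, tolerance = 1e-10)
  expect_equal(exact$r2, 1)
  const <- fitGrowthRate(rep(2, 7), weeks)
  expect_equal(const$slope, 0)
  expect_equal(const$r2, 0)
  set.seed(5)
  y <- matrix(rnorm(35, 2 + 0.2 * rep(weeks - 25, each = 5)), 5)
  fit <- fitGrowthRate(y, weeks)
  for (i in 1:5) {
    lmfit <- lm(y[i, ] ~ weeks)
    expect_equal(fit$slope[i], unname(coef(lmfit)[2]), tolerance = 1e-10)
    expect_equal(fit$r2[i], summary(lmfit)$r.squared, tolerance = 1e-10)
  }
  # slope invariant to shifting week labels; R^2 invariant to scaling
  fitShift <- fitGrowthRate(y, weeks - 25)
  expect_equal(fitShift$slope, fit$slope, tolerance = 1e-12)
  fitScale <- fitGrowthRate(y * 3, weeks)
  expect_equal(fitScale$r2, fit$r2, tolerance = 1e-12)
  expect_error(fitGrowthRate(y[, 1:2], weeks[1:2]), "3 timepoints")
  expect_error(fitGrowthRate(y, rep(25, 7)), "constant")
})

test_that("R^2 filtering keeps the trustworthy vertices", {
  fit <- data.frame(slope = 1:4, intercept = 0, r2 = c(1, 1, 0.5, 0.9))
  expect_equal(filterR2(data.frame(r2 = rep(1, 5)))$fraction, 1)
  half <- filterR2(fit)
  expect_equal(half$keep, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(filterR2(data.frame(r2 = c(0.6, 0.7)))$keep, c(TRUE, TRUE))
  expect_equal(filterR2(data.frame(r2 = c(0.6, 0.7)), strict = TRUE)$keep,
               c(FALSE, TRUE))
  expect_error(filterR2(fit, threshold = 2), "\\[0, 1\\]")
})

test_that("MPC sign split excludes zeros and NAs", {
  g <- splitByMpcSign(c(-1, 1, 0, NA, 2, -3))
  expect_equal(g$positive, c(2L, 5L))
  expect_equal(g$negative, c(1L, 6L))
  sph <- makeUVSphere(1, nLat = 10, nLon = 20)
  gs <- splitByMpcSign(computeMPC(sph))
  expect_equal(length(gs$negative), 0)
  expect_gt(length(gs$positive), 0.9 * nVertices(sph))
})

test_that("pooled t test matches the reference implementation", {
  set.seed(13)
  for (i in 1:5) {
    a <- rnorm(8 + i, mean = 0.3); b <- rnorm(14, mean = 0)
    gt <- pooledTTest(a, b)
    ref2 <- t.test(a, b, var.equal = TRUE)
    refR <- t.test(a, b, var.equal = TRUE, alternative = "greater")
    expect_equal(gt@t, unname(ref2$statistic), tolerance = 1e-10)
    expect_equal(gt@dof, unname(ref2$parameter))
    expect_equal(gt@pTwoTail, ref2$p.value, tolerance = 1e-10)
    expect_equal(gt@pRightTail, refR$p.value, tolerance = 1e-10)
    # antisymmetry
    swap <- pooledTTest(b, a)
    expect_equal(swap@t, -gt@t, tolerance = 1e-12)
  }
  same <- pooledTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same@t, 0)
  expect_equal(same@pTwoTail, 1)
  expect_error(pooledTTest(c(1, 1), c(1, 1)), "pooled variance")
  expect_error(pooledTTest(1, c(1, 2)), "at least 2")
})

test_that("parcel comparison reproduces the packaged table summaries", {
  tab <- parcelThicknessFixture()
  pc <- parcelComparison(tab)
  expect_equal(round(pc$summary$mean[pc$summary$class == "sulcal"], 2), 2.59)
  expect_equal(round(pc$summary$mean[pc$summary$class == "gyral"], 2), 2.92)
  expect_equal(pc$summary$n, c(30L, 31L))
  expect_gt(pc$test@t, 0)
  expect_lt(pc$test@pRightTail, 0.01)
  twin <- data.frame(parcel = letters[1:6],
                     class = rep(c("gyral", "sulcal"), each = 3),
                     thickness_mm = rep(c(2, 3, 4), 2))
  expect_equal(parcelComparison(twin)$test@t, 0)
  expect_error(parcelComparison(twin[twin$class == "gyral", ]), "both")
})

test_that("the full pipeline recovers exact slopes on noise-free data", {
  ss <- makeSurfaceSeries(synthGrowthParams(nGrid = 25, noiseSd = 0))
  pipe <- growthRatePipeline(ss)
  pv <- pipe$perVertex
  expect_equal(pipe$keptFraction, 1)
  expect_true(all(pv$r2 == 1))
  # per-vertex slopes are exact against the generative field
  lab <- generativeLabels(ss)
  gen <- ifelse(lab == "gyral", 0.35, 0.10)
  expect_lt(max(abs(pv$slope - gen)), 1e-9)
  # estimated MPC groups agree with generative labels away from the
  # inflection bands (where the analytic curvature is near zero)
  zgen <- sin(2 * pi * vertices(whiteSurface(ss, 25))[, 1] / 30 + pi / 7) *
    sin(2 * pi * vertices(whiteSurface(ss, 25))[, 2] / 30 + pi / 7)
  away <- abs(zgen) > 0.2
  match <- mean((pv$group[away] == "positive") == (lab[away] == "gyral"),
                na.rm = TRUE)
  expect_gt(match, 0.95)
  expect_lt(pipe$test@pRightTail, 1e-6)
  expect_gt(unname(pipe$groupMeans["positive"]),
            unname(pipe$groupMeans["negative"]) + 0.15)
})
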