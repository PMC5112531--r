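test_that("growth tensor is the scaled identity with det g^d", {
  expect_equal(growthTensor(1), diag(3))
  expect_equal(growthTensor(1.2), diag(1.2, 3))
  expect_equal(det(growthTensor(1.2)), 1.728)
  expect_equal(det(growthTensor(2, dim = 2)), 4)
  expect_error(growthTensor(0.9), "resorption")
})

test_that("elastic tensor inverts the multiplicative split", {
  G <- growthTensor(1.2)
  expect_equal(elasticTensor(G, G), diag(3))
  expect_equal(elasticTensor(diag(3), G), diag(1 / 1.2, 3))
  set.seed(7)
  for (i in 1:10) {
    M <- matrix(rnorm(9), 3); Fm <- crossprod(M) + diag(3) # SPD, det > 0
    M2 <- matrix(rnorm(9), 3); Gm <- crossprod(M2) + diag(3)
    A <- elasticTensor(Fm, Gm)
    expect_lt(max(abs(A %*% Gm - Fm)), 1e-12)
  }
  expect_error(elasticTensor(diag(3), matrix(0, 3, 3)), "singular|positive")
})

test_that("Cauchy stress vanishes for undeformed and rotated states", {
  mat <- material(mu = 330)
  expect_equal(cauchyStress(diag(3), mat)$sigma, matrix(0, 3, 3))
  th <- 0.3
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  expect_lt(max(abs(cauchyStress(R, mat)$sigma)), 1e-8 * mat@mu)
  expect_error(cauchyStress(diag(c(-1, 1)), mat), "inversion|positive")
})

test_that("isochoric uniaxial stress difference is mu (lambda^2 - lambda^-2)", {
  mat <- material(mu = 330)
  for (lam in c(0.7, 0.9, 1.3, 1.8)) {
    s <- cauchyStress(diag(c(lam, 1 / lam)), mat)$sigma
    expect_equal(s[1, 1] - s[2, 2], 330 * (lam^2 - lam^-2), tolerance = 1e-12)
  }
})

test_that("stress matches the finite-difference energy oracle", {
  mu <- 330; K <- 100 * mu
  mat <- material(mu = mu, bulkPenalty = K)
  set.seed(11)
  for (d in 2:3) {
    for (i in 1:5) {
      A <- diag(d) + 0.1 * matrix(rnorm(d * d), d)
      s <- cauchyStress(A, mat)$sigma
      fd <- fdCauchy(A, mu, K)
      expect_lt(max(abs(s - fd)) / max(abs(s)), 1e-6)
    }
    # confined growth: A = I/g
    for (g in c(1.1, 1.3)) {
      A <- diag(1 / g, d)
      s <- cauchyStress(A, mat)$sigma
      fd <- fdCauchy(A, mu, K)
      expect_lt(max(abs(s - fd)) / max(abs(s)), 1e-6)
    }
  }
})

test_that("material and growth-field validity guards hold", {
  expect_error(material(mu = 330, bulkPenalty = 10 * 330), "50")
  expect_error(material(mu = -1), "positive")
  expect_error(new("GrowthField", g = c(0.5, 1), coreMask = c(FALSE, TRUE),
                   multiplier = 1.2), ">= 1")
  expect_error(new("GrowthField", g = c(1.2, 1.1), coreMask = c(FALSE, TRUE),
                   multiplier = 1.2), "core")
  gf <- new("GrowthField", g = c(1.2, 1), coreMask = c(FALSE, TRUE),
            multiplier = 1.2)
  expect_s4_class(gf, "GrowthField")
  sch <- stiffnessRamp(2)
  expect_equal(sch(0), 1)
  expect_equal(sch(1), 2)
  expect_equal(sch(0.5), 1.5)
})
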