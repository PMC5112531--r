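cosineProfile <- function(lambda = 10, extent = 100, dx = 0.25, phase = 0) {
  x <- seq(0, extent, by = dx)
  cbind(x, cos(2 * pi * x / lambda + phase))
}

test_that("cosine crest, trough and inflection get the three labels", {
  prof <- cosineProfile(lambda = 10)
  crest <- classifyCenter(prof, center = 50, window = 10)
  expect_equal(outcomeLabel(crest), "gyrus")
  expect_gt(crest@percentile, 95)
  trough <- classifyCenter(prof, center = 55, window = 10)
  expect_equal(outcomeLabel(trough), "sulcus")
  expect_lt(trough@percentile, 5)
  infl <- classifyCenter(prof, center = 52.5, window = 10)
  expect_equal(outcomeLabel(infl), "bank")
  expect_equal(infl@percentile, 50, tolerance = 0.1)
})

test_that("classification is invariant to constant and linear trends", {
  prof <- cosineProfile(lambda = 10)
  for (center in c(50, 52.5, 55)) {
    base <- classifyCenter(prof, center = center, window = 10)
    shifted <- prof; shifted[, 2] <- shifted[, 2] + 5 + 0.3 * shifted[, 1]
    mod <- classifyCenter(shifted, center = center, window = 10)
    expect_equal(outcomeLabel(mod), outcomeLabel(base))
    expect_equal(mod@percentile, base@percentile, tolerance = 1e-9)
  }
})

test_that("phase sweep matches the analytic trichotomy away from boundaries", {
  # analytic labels by percentile of cos theta under the arcsine height law:
  # P(height <= cos(theta)) = 1 - theta/pi for theta in [0, pi].  A
  # multi-period window keeps the in-window detrending correction small.
  prof <- cosineProfile(lambda = 10, dx = 0.1)
  centers <- seq(30, 70, by = 0.1)
  for (c0 in centers) {
    theta <- abs(((2 * pi * c0 / 10 + pi) %% (2 * pi)) - pi) # in [0, pi]
    pctTrue <- 100 * (1 - theta / pi)
    if (min(abs(pctTrue - c(25, 75))) < 5) next # skip threshold boundaries
    want <- if (pctTrue >= 75) "gyrus" else if (pctTrue <= 25) "sulcus"
            else "bank"
    got <- classifyCenter(prof, center = c0, window = 50)
    expect_equal(outcomeLabel(got), want,
                 label = sprintf("center %.1f (pct %.1f)", c0, pctTrue))
  }
})

test_that("labels partition the outcomes and errors fire appropriately", {
  prof <- cosineProfile()
  for (c0 in seq(40, 60, by = 0.7)) {
    o <- classifyCenter(prof, center = c0, window = 10)
    expect_true(outcomeLabel(o) %in% c("gyrus", "sulcus", "bank"))
    n <- (o@percentile >= 75) + (o@percentile <= 25)
    expect_lte(n, 1)
  }
  flat <- cbind(seq(0, 100), 0.01 * sin(seq(0, 100)))
  expect_error(classifyCenter(flat, center = 50, window = 10,
                              minAmplitude = 0.2), "no instability")
  expect_error(classifyCenter(prof, center = 2, window = 10), "cover")
})

test_that("wavelength estimation recovers the dominant period", {
  expect_equal(estimateFoldWavelength(cosineProfile(lambda = 10)), 10,
               tolerance = 0.05)
  expect_equal(estimateFoldWavelength(cosineProfile(lambda = 25)), 25,
               tolerance = 0.05)
})

test_that("outcome tabulation reports proportions and exact binomial CIs", {
  out <- tabulateOutcomes(as.list(rep(c("gyrus", "bank"), c(47, 3))),
                          "fast_patch")
  expect_equal(unname(outcomeCounts(out)["gyrus", 1]), 47)
  expect_equal(unname(gyrusProportion(out)), 0.94)
  expect_equal(unname(outcomeCounts(out)["sulcus", 1]), 0)
  all10 <- tabulateOutcomes(rep(list("gyrus"), 10), "x")
  expect_equal(unname(gyrusProportion(all10)), 1)
  expect_equal(unname(all10@gyrusCI["lower", 1]),
               stats::binom.test(10, 10)$conf.int[1], tolerance = 1e-12)
  expect_equal(unname(all10@gyrusCI["lower", 1]), 0.6915, tolerance = 1e-4)
  mixed <- tabulateOutcomes(as.list(c("gyrus", "sulcus", "bank", "gyrus")),
                            c("a", "a", "b", "b"))
  expect_equal(unname(colSums(outcomeCounts(mixed))), mixed@nRuns)
})
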