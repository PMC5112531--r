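test_that("per-run seeds are deterministic and well separated", {
  s1 <- gyrogen:::runSeed(1, "homogeneous", 1)
  expect_identical(s1, gyrogen:::runSeed(1, "homogeneous", 1))
  expect_false(s1 == gyrogen:::runSeed(1, "homogeneous", 2))
  expect_false(s1 == gyrogen:::runSeed(1, "fast_patch", 1))
  expect_false(s1 == gyrogen:::runSeed(2, "homogeneous", 1))
  seeds <- vapply(1:50, function(i) gyrogen:::runSeed(7, "fast_patch", i), 1L)
  expect_equal(length(unique(seeds)), 50)
  expect_true(all(seeds >= 0 & seeds < 2^31))
})

test_that("batches run, tabulate, cache and resume deterministically", {
  cache <- file.path(tempdir(), "gyrogen-cache-test")
  unlink(cache, recursive = TRUE)
  spec <- batchSpec(modes = "fast_patch", nRuns = 2, baseSeed = 5,
                    config = simConfig())
  b1 <- runBatch(spec, cacheDir = cache)
  expect_equal(nrow(b1$manifest), 2)
  expect_equal(sum(outcomeCounts(b1$outcomes)), 2)
  expect_equal(unname(colSums(outcomeCounts(b1$outcomes))),
               b1$outcomes@nRuns)
  expect_equal(length(list.files(cache)), 2)
  # second invocation resumes from cache and reproduces the manifest
  t0 <- Sys.time()
  b2 <- runBatch(spec, cacheDir = cache)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 2)
  expect_equal(b2$manifest, b1$manifest)
  unlink(cache, recursive = TRUE)
})

test_that("reports bundle whatever analyses are present", {
  dir1 <- file.path(tempdir(), "gyrogen-report-1")
  unlink(dir1, recursive = TRUE)
  rep1 <- makeReport(parcelTable = parcelThicknessFixture(), dir = dir1)
  expect_s4_class(rep1, "Report")
  expect_true(file.exists(file.path(dir1, "parcel_summary.csv")))
  expect_true(file.exists(file.path(dir1, "report.json")))
  expect_false(file.exists(file.path(dir1, "outcome_counts.csv")))
  js <- jsonlite::read_json(file.path(dir1, "report.json"),
                            simplifyVector = TRUE)
  expect_equal(round(js$parcel$mean[js$parcel$class == "sulcal"], 2), 2.59)
  expect_null(js$outcomes)
  # reruns are byte-identical
  dir2 <- file.path(tempdir(), "gyrogen-report-2")
  unlink(dir2, recursive = TRUE)
  makeReport(parcelTable = parcelThicknessFixture(), dir = dir2)
  expect_identical(readLines(file.path(dir1, "report.json")),
                   readLines(file.path(dir2, "report.json")))
  expect_error(makeReport(), "at least one")
  unlink(dir1, recursive = TRUE); unlink(dir2, recursive = TRUE)
})

test_that("pipeline results flow into the growth-rate report section", {
  ss <- makeSurfaceSeries(synthGrowthParams(nGrid = 15, noiseSd = 0))
  pipe <- growthRatePipeline(ss)
  d <- file.path(tempdir(), "gyrogen-report-3")
  unlink(d, recursive = TRUE)
  makeReport(pipeline = pipe, dir = d)
  js <- jsonlite::read_json(file.path(d, "report.json"), simplifyVector = TRUE)
  expect_equal(js$growthRateTest$meanPositive,
               unname(pipe$groupMeans["positive"]), tolerance = 1e-9)
  expect_equal(js$growthRateTest$pRightTail, pipe$test@pRightTail)
  expect_equal(js$growthRateTest$keptFraction, 1)
  unlink(d, recursive = TRUE)
})
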