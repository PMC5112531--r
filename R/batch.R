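# deterministic 31-bit hash of (baseSeed, mode, index) for per-run seeds;
# doubles stay exact well below 2^53 so the arithmetic is reproducible
runSeed <- function(baseSeed, mode, index) {
  h <- 0
  for (ch in utf8ToInt(mode)) h <- (h * 131 + ch) %% 2147483563
  v <- ((baseSeed %% 2147483563) * 48271) %% 2147483563
  v <- (v + h * 16807 + index * 7919) %% 2147483563
  as.integer(v)
}

configHash <- function(config) {
  s <- paste(vapply(slotNames(config), function(nm)
    paste(format(slot(config, nm), digits = 15), collapse = ","), ""),
    collapse = ";")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483563
  sprintf("%x", h)
}

#' Batch specification
#'
#' @param modes character vector of batch modes: "homogeneous",
#'   "fast_patch", and/or "stiff_patch_2", "stiff_patch_4", "stiff_patch_8".
#' @param nRuns runs per mode (scalar or per-mode vector).
#' @param baseSeed integer; per-run seeds are derived deterministically from
#'   it, the mode and the run index.
#' @param config template \linkS4class{SimConfig}; mode, seed and (for
#'   stiff modes) stiffFinal are overridden per run.
#' @return a list of class "BatchSpec"
#' @export
batchSpec <- function(modes = c("homogeneous", "fast_patch"), nRuns = 50,
                      baseSeed = 1L, config = simConfig()) {
  if (any(nRuns < 1)) stop("nRuns must be >= 1")
  structure(list(modes = modes, nRuns = rep(nRuns, length.out = length(modes)),
                 baseSeed = as.integer(baseSeed), config = config),
            class = "BatchSpec")
}

modeConfig <- function(config, mode, seed) {
  if (grepl("^stiff_patch", mode)) {
    config@stiffFinal <- as.numeric(sub("stiff_patch_?", "", mode))
    config@mode <- "stiff_patch"
  } else config@mode <- mode
  config@seed <- as.integer(seed)
  config
}

#' Run a batch of seeded simulations and classify the centre outcomes
#'
#' Runs \code{nRuns} simulations per mode with independent, deterministic
#' perturbation seeds, classifies the plate-centre outcome of each folded
#' run, and tabulates counts.  Individual run failures are recorded in the
#' manifest rather than aborting the batch.  If \code{cacheDir} is given,
#' completed runs are cached as JSON keyed by mode, index, seed and config
#' hash, so interrupted batches resume.
#'
#' @param spec a \code{\link{batchSpec}}.
#' @param cacheDir optional directory for per-run result caching.
#' @param window optional classification window (mm); default one estimated
#'   fold wavelength per profile.
#' @param verbose logical; per-run progress on stderr.
#' @return list of class "BatchResult": \code{outcomes}
#'   (\linkS4class{OutcomeTable} over completed runs), \code{manifest}
#'   (data.frame), \code{failedFraction}
#' @export
runBatch <- function(spec, cacheDir = NULL, window = NULL, verbose = FALSE) {
  rows <- list(); labs <- character(); labModes <- character()
  ch <- configHash(spec$config)
  for (m in seq_along(spec$modes)) {
    mode <- spec$modes[m]
    for (i in seq_len(spec$nRuns[m])) {
      seed <- runSeed(spec$baseSeed, mode, i)
      cfg <- modeConfig(spec$config, mode, seed)
      cache <- if (!is.null(cacheDir))
        file.path(cacheDir, sprintf("run_%s_%03d_%d_%s.json", mode, i, seed,
                                    ch))
      rec <- NULL
      if (!is.null(cache) && file.exists(cache))
        rec <- jsonlite::read_json(cache, simplifyVector = TRUE)
      if (is.null(rec)) {
        rec <- tryCatch({
          sim <- runSimulation(cfg)
          prof <- profiles(sim)[[length(profiles(sim))]]
          out <- classifyCenter(prof, center = cfg@dims[1] / 2,
                                window = window,
                                minAmplitude = 0.1 * cfg@cortexThickness)
          list(mode = mode, index = i, seed = seed, status = simStatus(sim),
               label = outcomeLabel(out), percentile = out@percentile,
               window = out@window,
               finalG = sim@frameGrowth[length(sim@frameGrowth)],
               maxJdev = max(diagnostics(sim)$maxJdev))
        }, error = function(e)
          list(mode = mode, index = i, seed = seed, status = "failed",
               label = NA_character_, percentile = NA_real_,
               window = NA_real_, finalG = NA_real_, maxJdev = NA_real_,
               error = conditionMessage(e)))
        if (!is.null(cache)) {
          dir.create(dirname(cache), recursive = TRUE, showWarnings = FALSE)
          jsonlite::write_json(rec, cache, auto_unbox = TRUE, digits = NA)
        }
      }
      if (verbose)
        message(sprintf("[%s %d/%d] seed %d -> %s", mode, i, spec$nRuns[m],
                        seed, if (is.na(rec$label)) rec$status else rec$label))
      rows[[length(rows) + 1L]] <-
        data.frame(mode = mode, index = i, seed = seed, status = rec$status,
                   label = if (is.null(rec$label)) NA_character_ else rec$label,
                   percentile = rec$percentile, finalG = rec$finalG,
                   maxJdev = rec$maxJdev)
      if (!is.na(rec$label)) {
        labs <- c(labs, rec$label)
        labModes <- c(labModes, mode)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  structure(list(
    outcomes = if (length(labs)) tabulateOutcomes(as.list(labs), labModes),
    manifest = manifest,
    failedFraction = mean(is.na(manifest$label))), class = "BatchResult")
}

#' Assemble and write the study report
#'
#' Bundles whatever analyses were run — the parcel thickness comparison,
#' the longitudinal growth-rate group test, the batch outcome counts — into
#' a \linkS4class{Report}, and (optionally) writes it to \code{dir} as CSV +
#' JSON + a plain-text summary.  Output is byte-reproducible for a given
#' base seed and configuration (no timestamps).
#'
#' @param batch optional "BatchResult" from \code{\link{runBatch}}.
#' @param pipeline optional result of \code{\link{growthRatePipeline}}.
#' @param parcelTable optional ParcelTable data.frame.
#' @param dir optional output directory.
#' @return a \linkS4class{Report}
#' @export
makeReport <- function(batch = NULL, pipeline = NULL, parcelTable = NULL,
                       dir = NULL) {
  if (is.null(batch) && is.null(pipeline) && is.null(parcelTable))
    stop("at least one completed analysis is required")
  parcel <- if (!is.null(parcelTable)) parcelComparison(parcelTable)
  rep <- new("Report",
    parcelSummary = if (!is.null(parcel)) parcel$summary else data.frame(),
    groupTest = if (!is.null(pipeline)) list(pipeline$test) else list(),
    outcomes = if (!is.null(batch) && !is.null(batch$outcomes))
      list(batch$outcomes) else list(),
    manifest = if (!is.null(batch)) batch$manifest else data.frame())
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    js <- list()
    if (nrow(rep@parcelSummary)) {
      write.csv(rep@parcelSummary, file.path(dir, "parcel_summary.csv"),
                row.names = FALSE)
      js$parcel <- rep@parcelSummary
      if (!is.null(parcel))
        js$parcelTest <- list(t = parcel$test@t, dof = parcel$test@dof,
                              pTwoTail = parcel$test@pTwoTail,
                              pRightTail = parcel$test@pRightTail)
    }
    if (length(rep@groupTest)) {
      gt <- rep@groupTest[[1]]
      js$growthRateTest <- list(
        meanPositive = gt@means[1], meanNegative = gt@means[2],
        sdPositive = gt@sds[1], sdNegative = gt@sds[2],
        n = gt@n, t = gt@t, dof = gt@dof,
        pTwoTail = gt@pTwoTail, pRightTail = gt@pRightTail,
        keptFraction = pipeline$keptFraction)
    }
    if (length(rep@outcomes)) {
      ot <- rep@outcomes[[1]]
      oc <- as.data.frame(ot@counts)
      write.csv(cbind(label = rownames(ot@counts), oc),
                file.path(dir, "outcome_counts.csv"), row.names = FALSE)
      js$outcomes <- list(counts = apply(ot@counts, 2, as.list),
                          nRuns = ot@nRuns,
                          gyrusProportion = gyrusProportion(ot),
                          gyrusCI = apply(ot@gyrusCI, 2, as.list))
    }
    if (nrow(rep@manifest))
      write.csv(rep@manifest, file.path(dir, "manifest.csv"),
                row.names = FALSE)
    jsonlite::write_json(js, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    txt <- utils::capture.output(show(rep))
    writeLines(txt, file.path(dir, "report.txt"))
  }
  rep
}
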