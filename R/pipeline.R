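#' Pipeline run configuration
#'
#' One object resolving everything a full analysis run needs; every output
#' embeds the resolved configuration and seed for provenance. All module
#' randomness derives from the single `seed` via fixed per-module offsets.
#'
#' @param seed integer master seed.
#' @param networks networks to simulate/analyze (`"CA"`, `"DG"` or both).
#' @param noiseSd generator noise SD, uV.
#' @param profiles named list of [potentiationProfile()] overrides per
#'   network (default: the network presets).
#' @param protocol a [protocolConfig()].
#' @param preprocess a [preprocessConfig()].
#' @param kcsd a [kcsdConfig()].
#' @param kcsdStride electrode subsampling stride for the CSD stage (the
#'   kernel solve is cubic in electrode count; stride 2 uses a 32 x 32
#'   sub-grid of the 64 x 64 array).
#' @param activityThresholdSd activity threshold for all detection steps.
#' @param sessionPath optional saved session directory to analyze instead
#'   of simulating.
#' @param outDir optional output directory for the JSON report, CSV tables
#'   and figures.
#' @export
runConfig <- function(seed = 1L, networks = c("CA", "DG"), noiseSd = 10,
                      profiles = list(), protocol = protocolConfig(),
                      preprocess = preprocessConfig(),
                      kcsd = kcsdConfig(basisM = 16), kcsdStride = 2L,
                      activityThresholdSd = 6, sessionPath = NULL,
                      outDir = NULL) {
  networks <- match.arg(networks, c("CA", "DG"), several.ok = TRUE)
  structure(list(seed = as.integer(seed), networks = networks,
                 noiseSd = noiseSd, profiles = profiles, protocol = protocol,
                 preprocess = preprocess, kcsd = kcsd,
                 kcsdStride = as.integer(kcsdStride),
                 activityThresholdSd = activityThresholdSd,
                 sessionPath = sessionPath, outDir = outDir),
            class = c("RunConfig", "list"))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> preprocess -> classify -> latency -> LTP
#' -> kCSD for each configured network and aggregates everything into one
#' report. Re-running with the same configuration and seed reproduces all
#' numeric outputs exactly. Any stage error aborts with the stage name and
#' cause; results of completed stages are retained in the returned state.
#'
#' @param config a [runConfig()].
#' @param geometry a [GridGeometry-class] (tests may shrink it).
#' @param layersList optional named list of [LayerMap-class] per network.
#' @return list with `report` (serializable), and `state` (per-network
#'   intermediate objects for rendering).
#' @export
runPipeline <- function(config = runConfig(), geometry = gridGeometry(),
                        layersList = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  report <- list(meta = list(package = "netLTP",
                             version = as.character(utils::packageVersion("netLTP")),
                             seed = config$seed,
                             networks = config$networks,
                             noiseSd = config$noiseSd,
                             activityThresholdSd = config$activityThresholdSd))
  state <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  plasticityAll <- NULL
  for (nw in config$networks) {
    sess <- stage(paste0("simulate/", nw), {
      if (!is.null(config$sessionPath)) {
        s <- loadSession(file.path(config$sessionPath, nw))
        if (is.null(s$layers)) stopf("missing /layers in the session container")
        s
      } else {
        simulateSession(nw, geometry = geometry,
                        layers = layersList[[nw]],
                        profile = config$profiles[[nw]],
                        noise = noiseSpec(config$noiseSd),
                        protocol = config$protocol,
                        seed = config$seed + match(nw, c("CA", "DG")) * 1000L,
                        phases = c("baseline", "post_tetanic"))
      }
    })
    pp <- config$preprocess
    geoRun <- geometry(sess$baseline)
    epB <- stage(paste0("preprocess/", nw), preprocessRecording(sess$baseline, pp))
    sess$baseline <- NULL
    epP <- stage(paste0("preprocess/", nw), preprocessRecording(sess$post_tetanic, pp))
    sess$post_tetanic <- NULL
    gc(FALSE)
    k <- if (nw == "CA") 4L else 3L
    thr <- config$activityThresholdSd
    cls <- stage(paste0("classify/", nw), {
      lapply(list(baseline = epB, post_tetanic = epP), function(ep) {
        feats <- extractFeatures(ep, thr)
        res <- classifyWaveforms(feats, k, seed = config$seed + 17L)
        sc <- scoreClassification(res, sess$layers)
        list(accuracy = sc$accuracy, confusion = sc$confusion,
             nComponents = res$nComponents, k = k)
      })
    })
    latc <- stage(paste0("latency/", nw), {
      tabB <- peakLatency(epB, thr); tabP <- peakLatency(epP, thr)
      clB <- clusterLatencies(tabB); clP <- clusterLatencies(tabP)
      list(baseline = clB$summary, post_tetanic = clP$summary,
           changePct = latencyChange(clB, clP),
           recruitmentFold = recruitment(clB, clP),
           tables = list(baseline = tabB, post_tetanic = tabP),
           clusters = list(baseline = clB, post_tetanic = clP))
    })
    ltp <- stage(paste0("ltp/", nw), {
      tc <- potentiationTimecourse(epB, epP, sess$layers, thr)
      pl <- plasticityPercent(tc)
      det <- detectLtp(tc, config$protocol)
      vv <- voltageVariationMap(epB, epP)
      list(plasticity = pl, detect = det, timecourse = tc, variation = vv)
    })
    csd <- stage(paste0("kcsd/", nw), {
      pipelineCsd(epP, geoRun, config)
    })
    rm(epB, epP); gc(FALSE)
    plasticityAll <- rbind(plasticityAll,
                           cbind(network = nw, ltp$plasticity))
    report[[nw]] <- list(
      classification = lapply(cls, function(x)
        list(accuracy = x$accuracy, nComponents = x$nComponents, k = x$k)),
      latency = list(baseline = latc$baseline,
                     post_tetanic = latc$post_tetanic,
                     changePct = as.list(latc$changePct),
                     recruitmentFold = as.list(latc$recruitmentFold)),
      ltp = list(plasticity = ltp$plasticity, detect = ltp$detect),
      kcsd = csd$summary)
    state[[nw]] <- list(layers = sess$layers, truth = sess$truth,
                        geometry = geoRun, classification = cls,
                        latency = latc, ltp = ltp, csd = csd)
  }
  report$plasticity <- plasticityAll
  out <- list(report = report, state = state, config = config)
  if (!is.null(config$outDir)) writeReportFiles(out, config$outDir)
  out
}

# CSD stage on a subsampled electrode grid at the time of the evoked extremum
pipelineCsd <- function(epPost, geometry, config) {
  mw <- meanEvokedWaveform(epPost)
  tm <- epPost@timeMs
  post <- which(tm > config$preprocess$blankMs)
  peakSample <- post[which.max(apply(abs(mw[, post, drop = FALSE]), 2, max))]
  stride <- config$kcsdStride
  rows <- seq(1L, geometry@nRows, by = stride)
  cols <- seq(1L, geometry@nCols, by = stride)
  sub <- as.vector(outer(cols, rows, function(cc, rr)
    channelIndex(geometry, rr, cc)))
  pos <- electrodePositions(geometry)[sub, c("x", "y")]
  kern <- buildKernels(pos, config$kcsd, forwardModel(),
                       estDim = c(length(rows), length(cols)))
  V <- mw[sub, peakSample]
  lambda <- selectLambda(V, kern)
  map <- estimateCsd(V, kern, as.numeric(lambda), timestamp = tm[peakSample])
  q <- quantifySinksSources(map, cellArea = (geometry@pitch * stride)^2)
  pm <- matrix(V, length(rows), length(cols), byrow = FALSE)
  list(map = map, potentials = V,
       summary = list(lambda = as.numeric(lambda), timeMs = tm[peakSample],
                      nSinks = q$nSinks, nSources = q$nSources,
                      sinkIntegral = q$sinkIntegral,
                      sourceIntegral = q$sourceIntegral))
}

writeReportFiles <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(result$report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  utils::write.csv(result$report$plasticity,
                   file.path(outDir, "plasticity.csv"), row.names = FALSE)
  for (nw in names(result$state)) {
    tc <- result$state[[nw]]$ltp$timecourse
    utils::write.csv(tc$aggregate,
                     file.path(outDir, sprintf("timecourse_%s.csv", nw)),
                     row.names = FALSE)
  }
  invisible(outDir)
}

#' Validate a pipeline report against the published schema
#'
#' Structural validation (required fields and types) against
#' `inst/schema/report.schema.json`.
#'
#' @param report the `report` element of a [runPipeline()] result (or a
#'   parsed JSON report).
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validateReport <- function(report) {
  need <- function(ok, what) if (!ok) stopf("invalid report: %s", what)
  need(is.list(report$meta), "missing meta")
  for (f in c("package", "version", "seed", "networks"))
    need(!is.null(report$meta[[f]]), paste("missing meta", f))
  nets <- report$meta$networks
  for (nw in nets) {
    sec <- report[[nw]]
    need(is.list(sec), paste("missing network section", nw))
    need(is.list(sec$classification), paste(nw, "classification"))
    for (ph in c("baseline", "post_tetanic")) {
      acc <- sec$classification[[ph]]$accuracy
      need(is.numeric(acc) && acc >= 0 && acc <= 1,
           paste(nw, ph, "accuracy in [0,1]"))
    }
    need(!is.null(sec$latency$changePct), paste(nw, "latency change"))
    need(!is.null(sec$ltp$plasticity), paste(nw, "plasticity"))
    need(is.numeric(unlist(sec$kcsd$lambda)), paste(nw, "kcsd lambda"))
  }
  pl <- report$plasticity
  need(!is.null(pl), "missing combined plasticity table")
  invisible(TRUE)
}

#' Render pipeline maps as image files
#'
#' Deterministic raster figures: pseudo-color amplitude (voltage-variation)
#' maps per phase, categorical latency maps (three cluster colors plus
#' background), the CSD map, and the layer potentiation time course.
#'
#' @param result a [runPipeline()] result.
#' @param kinds subset of `c("amplitude", "latency", "csd", "timecourse")`.
#' @param dir output directory.
#' @return character vector of files written.
#' @export
renderMaps <- function(result, kinds = c("amplitude", "latency", "csd",
                                         "timecourse"),
                       dir = ".") {
  kinds <- match.arg(kinds, several.ok = TRUE)
  unknown <- setdiff(kinds, c("amplitude", "latency", "csd", "timecourse"))
  if (length(unknown)) stopf("unknown map kind: %s", unknown[1])
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nw in names(result$state)) {
    st <- result$state[[nw]]
    geo <- st$geometry
    asMat <- function(v) matrix(v, geo@nRows, geo@nCols, byrow = TRUE)
    out <- function(name) file.path(dir, sprintf("%s_%s.png", name, nw))
    if ("amplitude" %in% kinds) {
      f <- out("amplitude")
      grDevices::png(f, 720, 360)
      graphics::par(mfrow = c(1, 2), mar = c(2, 2, 2, 1))
      vv <- st$ltp$variation
      graphics::image(t(asMat(vv$baseline))[, geo@nRows:1], zlim = c(0, 1),
                      col = grDevices::hcl.colors(64, "Inferno"), axes = FALSE, useRaster = TRUE,
                      main = "baseline variation")
      graphics::image(t(asMat(vv$post_tetanic))[, geo@nRows:1], zlim = c(0, 1),
                      col = grDevices::hcl.colors(64, "Inferno"), axes = FALSE, useRaster = TRUE,
                      main = "post-tetanic variation")
      grDevices::dev.off()
      files <- c(files, f)
    }
    if ("latency" %in% kinds) {
      f <- out("latency")
      cl <- st$latency$clusters$baseline$assignment
      v <- rep(0, nChannels(geo))
      v[cl$channel] <- as.integer(cl$cluster)
      grDevices::png(f, 420, 400)
      graphics::par(mar = c(1, 1, 2, 1))
      graphics::image(t(asMat(v))[, geo@nRows:1], zlim = c(0, 3),
                      col = c("grey90", "#1b9e77", "#d95f02", "#7570b3"),
                      axes = FALSE, useRaster = TRUE,
                      main = "temporal clusters (baseline)")
      grDevices::dev.off()
      files <- c(files, f)
    }
    if ("csd" %in% kinds) {
      f <- out("csd")
      m <- csdValues(st$csd$map)
      lim <- max(abs(m))
      grDevices::png(f, 420, 400)
      graphics::par(mar = c(1, 1, 2, 1))
      graphics::image(t(m)[, nrow(m):1], zlim = c(-lim, lim),
                      col = grDevices::hcl.colors(65, "Blue-Red 3"),
                      axes = FALSE, useRaster = TRUE,
                      main = "kCSD (evoked peak)")
      grDevices::dev.off()
      files <- c(files, f)
    }
    if ("timecourse" %in% kinds) {
      f <- out("timecourse")
      agg <- st$ltp$timecourse$aggregate
      grDevices::png(f, 560, 400)
      graphics::par(mar = c(4, 4, 2, 1))
      layers <- unique(agg$layer)
      cols <- grDevices::hcl.colors(length(layers), "Dark 3")
      graphics::plot(NULL, xlim = range(agg$timeMin), ylim = range(agg$pct),
                     xlab = "time (min from HFS)", ylab = "% of baseline",
                     main = paste(nw, "potentiation"))
      graphics::abline(h = 100, lty = 2, col = "grey50")
      for (i in seq_along(layers)) {
        s <- agg[agg$layer == layers[i], ]
        s <- s[order(s$timeMin), ]
        graphics::lines(s$timeMin, s$pct, col = cols[i], lwd = 2)
      }
      graphics::legend("topright", legend = layers, col = cols, lwd = 2,
                       bty = "n")
      grDevices::dev.off()
      files <- c(files, f)
    }
  }
  files
}
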