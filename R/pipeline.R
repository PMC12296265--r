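# One-config orchestration: from segmented object tables (or a simulated
# count dataset) through normalization, cleaning, correlation, network and
# permutation statistics, to a deterministic on-disk result bundle.

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Validate a pipeline run configuration
#'
#' Checks the structural requirements of a run config (see
#' \code{\link{runPipeline}}) before any computation: exactly one input
#' mode, two group labels, valid thresholds including an explicit alpha
#' per analyzed channel, and existing referenced files.
#'
#' @param config named list (typically from \code{yaml::read_yaml}).
#' @return the config, invisibly, or an error describing the defect.
#' @export
validateRunConfig <- function(config) {
  need <- function(cond, msg) if (!cond) stop("invalid config: ", msg,
                                              call. = FALSE)
  need(!is.null(config$output_dir), "output_dir is required")
  modes <- c("counts_csv", "simulate_counts", "mice")
  have <- modes[vapply(modes, function(m) !is.null(config[[m]]), logical(1))]
  need(length(have) == 1L,
       sprintf("exactly one input mode of {%s} is required (found: %s)",
               paste(modes, collapse = ", "),
               if (length(have)) paste(have, collapse = ", ") else "none"))
  need(length(config$groups) == 2L, "exactly two group labels are required")
  nw <- config$network
  need(!is.null(nw$r_min) && nw$r_min >= 0 && nw$r_min < 1,
       "network.r_min in [0, 1) is required")
  need(!is.null(nw$alpha), "network.alpha is required (no default is assumed)")
  alphas <- unlist(nw$alpha)
  need(all(alphas > 0 & alphas < 1), "network.alpha values must lie in (0, 1)")
  if (!is.null(config$counts_csv)) {
    for (p in unlist(config$counts_csv))
      need(file.exists(p), sprintf("counts file not found: %s", p))
  }
  if (!is.null(config$mice)) {
    need(!is.null(config$ontology) && file.exists(config$ontology),
         "ontology file is required and must exist")
    need(!is.null(config$atlas_plate) && file.exists(config$atlas_plate),
         "atlas_plate file is required and must exist")
    for (m in config$mice) {
      for (s in m$slices) {
        for (p in c(unlist(s$objects), s$points, s$coloc))
          need(file.exists(p), sprintf("file not found: %s", p))
      }
    }
  }
  invisible(config)
}

channelAlpha <- function(config, channel) {
  a <- config$network$alpha
  if (is.list(a) || length(a) > 1L) {
    v <- unlist(a)[channel]
    if (is.na(v)) stop(sprintf("no alpha configured for channel '%s'", channel))
    as.numeric(v)
  } else as.numeric(a)
}

buildMouseFromConfig <- function(mcfg, channels) {
  slices <- lapply(mcfg$slices, function(s) {
    objs <- lapply(channels, function(ch) {
      if (is.null(s$objects[[ch]])) NULL
      else importObjectTable(s$objects[[ch]], channel = ch)
    })
    names(objs) <- channels
    coloc <- if (!is.null(s$coloc)) {
      utils::read.delim(s$coloc)
    } else emptyColocTable()
    pts <- readCorrespondencePoints(s$points)
    SliceRecord(sliceId = s$slice_id, apCoordinate = as.numeric(s$ap),
                channelNames = channels,
                zThickness = if (is.null(s$z_thickness)) 9
                             else as.numeric(s$z_thickness),
                objects = objs, coloc = coloc,
                registration = fitTps(pts$source, pts$target))
  })
  MouseRecord(mcfg$id, mcfg$group, slices)
}

#' Run the full analysis pipeline from one configuration
#'
#' Input modes (exactly one): \code{counts_csv} (named per-group
#' region-count CSVs), \code{simulate_counts} (a
#' \code{\link{countSimSpec}} field list), or \code{mice} (per-slice
#' object tables plus correspondence points, an atlas plate and an
#' ontology, processed through registration, mapping and normalization).
#' Downstream, per channel: outlier cleaning (\code{outlier_sd}, default
#' 2), the shared-region filter, per-group correlation matrices,
#' thresholded networks and topology metrics, a permutation analysis of
#' correlation differences, and figures. Everything is written under
#' \code{output_dir} in \code{tables/}, \code{figures/} and \code{logs/};
#' identical configs and seeds reproduce the tables byte-for-byte.
#'
#' @param config path to a YAML run config, or the equivalent named list.
#' @return (invisibly) a list of the in-memory results per channel.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  withStage("validate", validateRunConfig(config))
  out <- config$output_dir
  for (d in file.path(out, c("tables", "figures", "logs")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(out, "logs", "params.yaml"))
  groups <- as.character(config$groups)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  # --- assemble per-group region count tables ---
  if (!is.null(config$counts_csv)) {
    tabs <- withStage("import-counts", lapply(
      stats::setNames(groups, groups),
      function(g) readRegionCountTable(config$counts_csv[[g]])))
  } else if (!is.null(config$simulate_counts)) {
    sim <- withStage("simulate-counts", {
      spc <- do.call(countSimSpec, c(config$simulate_counts[
        setdiff(names(config$simulate_counts), "plantedDiffs")],
        list(groups = groups,
             plantedDiffs = lapply(config$simulate_counts$plantedDiffs,
                                   unlist))))
      simulateRegionCounts(spc, seed = seed)
    })
    tabs <- sim$tables
  } else {
    tabs <- withStage("segmentation-import", {
      ontology <- readOntology(config$ontology)
      plate <- readAtlasPlate(config$atlas_plate)
      channels <- as.character(config$channels)
      mice <- lapply(config$mice, buildMouseFromConfig, channels = channels)
      rows <- do.call(rbind, lapply(mice, aggregateNormalize, plates = plate,
                                    ontology = ontology))
      split(rows, factor(rows$group, levels = groups))
    })
  }
  for (g in groups)
    writeRegionCountTable(tabs[[g]],
                          file.path(out, "tables",
                                    sprintf("counts_%s.csv", g)))

  sdK <- if (is.null(config$outlier_sd)) 2 else as.numeric(config$outlier_sd)
  clean <- withStage("outlier-cleaning",
                     lapply(tabs, removeOutliers, k = sdK))
  channels <- sort(unique(clean[[1]]$channel))
  nPerm <- if (is.null(config$permutation$n)) 1000
           else as.integer(config$permutation$n)

  results <- list()
  for (ch in channels) {
    alpha <- withStage("thresholds", channelAlpha(config, ch))
    chTabs <- lapply(clean, function(t) t[t$channel == ch, , drop = FALSE])
    shared <- withStage("shared-region-filter",
                        sharedRegionsFilter(chTabs[[1]], chTabs[[2]],
                                            minMice = config$min_mice))
    corrs <- withStage("correlation", lapply(shared, pairwiseCorrelations))
    nets <- withStage("network", lapply(corrs, buildNetwork,
                                        rMin = config$network$r_min,
                                        alpha = alpha))
    mets <- withStage("metrics", lapply(nets, nodeMetrics))
    perm <- withStage("permutation",
                      permutationCorrelationDiff(shared$A, shared$B,
                                                 nPerm = nPerm, seed = seed,
                                                 groups = groups))
    tdir <- file.path(out, "tables")
    for (i in 1:2) {
      g <- groups[i]
      writeCorrelationMatrix(corrs[[i]],
                             file.path(tdir, sprintf("corr_%s_%s.csv", ch, g)))
      writeEdgeList(nets[[i]],
                    file.path(tdir, sprintf("edges_%s_%s.csv", ch, g)))
      utils::write.csv(mets[[i]]$nodes,
                       file.path(tdir, sprintf("metrics_%s_%s.csv", ch, g)),
                       row.names = FALSE)
    }
    writePermutationResult(perm,
                           file.path(tdir, sprintf("permutation_%s.csv", ch)))
    results[[ch]] <- list(tables = shared, corr = corrs, networks = nets,
                          metrics = mets, permutation = perm)
  }
  withStage("figures",
            renderFigures(out, channels = channels, groups = groups,
                          dThresh = if (is.null(config$volcano$d_min)) 1
                                    else config$volcano$d_min,
                          alpha = if (is.null(config$volcano$alpha)) 0.01
                                  else config$volcano$alpha))
  invisible(results)
}

#' Render figures from a result bundle's tables
#'
#' Pure regeneration from the CSVs under \code{<bundle>/tables}: heatmaps
#' and network diagrams per group and channel, volcano and
#' parallel-coordinate plots of the permutation results, and per-region
#' correlation-distribution comparisons.
#'
#' @param bundleDir the pipeline output directory.
#' @param kinds subset of \code{c("heatmap", "network", "volcano",
#'   "parallel", "distribution")}.
#' @param channels channels to render (default: inferred from the tables).
#' @param groups the two group labels (default: inferred).
#' @param dThresh,alpha the volcano/parallel significance box.
#' @param region region for the distribution figure (default: the first
#'   region of the correlation matrix).
#' @return (invisibly) the figure paths written.
#' @export
renderFigures <- function(bundleDir,
                          kinds = c("heatmap", "network", "volcano",
                                    "parallel", "distribution"),
                          channels = NULL, groups = NULL, dThresh = 1,
                          alpha = 0.01, region = NULL) {
  tdir <- file.path(bundleDir, "tables")
  fdir <- file.path(bundleDir, "figures")
  dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
  needTable <- function(path) {
    if (!file.exists(path)) stop(sprintf("missing table: %s", path))
    path
  }
  if (is.null(channels) || is.null(groups)) {
    cfs <- list.files(tdir, pattern = "^corr_.*\\.csv$")
    parts <- regmatches(cfs, regexec("^corr_(.*)_([^_]+)\\.csv$", cfs))
    channels <- unique(vapply(parts, `[`, character(1), 2))
    groups <- unique(vapply(parts, `[`, character(1), 3))
  }
  written <- character(0)
  for (ch in channels) {
    corrs <- list()
    for (g in groups) {
      if (any(c("heatmap", "network", "distribution") %in% kinds)) {
        cf <- needTable(file.path(tdir, sprintf("corr_%s_%s.csv", ch, g)))
        cm <- utils::read.csv(cf, check.names = FALSE)
        r <- as.matrix(cm[, -1]); rownames(r) <- cm$region
        corrs[[g]] <- r
      }
      if ("heatmap" %in% kinds) {
        written <- c(written, saveFigure(
          figHeatmap(corrs[[g]], sprintf("%s correlations, %s", ch, g)),
          file.path(fdir, sprintf("heatmap_%s_%s", ch, g))))
      }
      if ("network" %in% kinds) {
        ef <- needTable(file.path(tdir, sprintf("edges_%s_%s.csv", ch, g)))
        ed <- utils::read.csv(ef, stringsAsFactors = FALSE)
        cf <- needTable(file.path(tdir, sprintf("corr_%s_%s.csv", ch, g)))
        nodes <- utils::read.csv(cf, check.names = FALSE)$region
        nw <- new("FunctionalNetwork", nodes = as.character(nodes),
                  edges = if (nrow(ed)) ed else
                    data.frame(region_a = character(), region_b = character(),
                               r = numeric(), p = numeric()),
                  rMin = 0, alpha = 1)
        written <- c(written, saveFigure(
          figNetwork(nw, sprintf("%s network, %s", ch, g)),
          file.path(fdir, sprintf("network_%s_%s", ch, g))))
      }
    }
    if (any(c("volcano", "parallel") %in% kinds)) {
      pf <- needTable(file.path(tdir, sprintf("permutation_%s.csv", ch)))
      pd <- utils::read.csv(pf, stringsAsFactors = FALSE)
      if ("volcano" %in% kinds) {
        written <- c(written, saveFigure(
          figVolcano(pd, dThresh, alpha,
                     sprintf("%s correlation differences", ch)),
          file.path(fdir, sprintf("volcano_%s", ch))))
      }
      if ("parallel" %in% kinds) {
        written <- c(written, saveFigure(
          figParallel(pd, dThresh, alpha, groups = groups,
                      title = sprintf("%s changed correlations", ch)),
          file.path(fdir, sprintf("parallel_%s", ch))))
      }
    }
    if ("distribution" %in% kinds && length(corrs) == 2L) {
      reg <- if (is.null(region)) rownames(corrs[[1]])[1] else region
      va <- corrs[[1]][reg, setdiff(colnames(corrs[[1]]), reg)]
      vb <- corrs[[2]][reg, setdiff(colnames(corrs[[2]]), reg)]
      written <- c(written, saveFigure(
        figDistribution(va[!is.na(va)], vb[!is.na(vb)], reg, groups),
        file.path(fdir, sprintf("distribution_%s_%s", ch, reg))))
    }
  }
  invisible(written)
}
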