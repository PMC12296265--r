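# Synthetic ground-truth inputs: image phantoms mimicking the two staining
# morphologies, correlated regional count data, and toy atlas plates.

withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Rejection-sample cell centres (voxel coordinates, 1-based continuous) with
# a minimum pairwise separation in um and a border margin of one radius.
placeCenters <- function(nCells, dims, voxelSize, radiusUm,
                         minSepUm = 2 * radiusUm, avoidUm = NULL,
                         maxTries = 5000L) {
  if (nCells == 0L)
    return(matrix(numeric(), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
  lims <- c(x = dims[2], y = dims[1], z = dims[3])
  vox <- voxelSize[c("x", "y", "z")]
  marg <- pmin(radiusUm / vox, (lims - 1) / 2)   # margin in voxels per axis
  centers <- matrix(NA_real_, nCells, 3, dimnames = list(NULL, c("x", "y", "z")))
  placed <- 0L
  for (tries in seq_len(maxTries)) {
    cand <- 1 + marg + stats::runif(3) * (lims - 1 - 2 * marg)
    ok <- TRUE
    if (placed > 0L) {
      d2 <- ((centers[seq_len(placed), 1] - cand[1]) * vox["x"])^2 +
            ((centers[seq_len(placed), 2] - cand[2]) * vox["y"])^2 +
            ((centers[seq_len(placed), 3] - cand[3]) * vox["z"])^2
      ok <- all(d2 >= minSepUm^2)
    }
    if (ok && !is.null(avoidUm) && nrow(avoidUm$centers)) {
      d2 <- ((avoidUm$centers[, 1] - cand[1]) * vox["x"])^2 +
            ((avoidUm$centers[, 2] - cand[2]) * vox["y"])^2 +
            ((avoidUm$centers[, 3] - cand[3]) * vox["z"])^2
      ok <- all(d2 >= avoidUm$minSepUm^2)
    }
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- cand
      if (placed == nCells) return(centers)
    }
  }
  stop(sprintf(
    "could not place %d cells at separation %.1f um; achievable maximum here is %d",
    nCells, minSepUm, placed))
}

# Add a Gaussian-profile sphere (sigma = radius / 2) to `img` in place-ish.
addSphere <- function(img, center, radiusUm, peak, voxelSize) {
  d <- dim(img)
  ext <- ceiling(1.8 * radiusUm / voxelSize[c("y", "x", "z")])
  r0 <- max(1L, floor(center["y"] - ext[1])); r1 <- min(d[1], ceiling(center["y"] + ext[1]))
  c0 <- max(1L, floor(center["x"] - ext[2])); c1 <- min(d[2], ceiling(center["x"] + ext[2]))
  p0 <- max(1L, floor(center["z"] - ext[3])); p1 <- min(d[3], ceiling(center["z"] + ext[3]))
  dy2 <- ((seq(r0, r1) - center["y"]) * voxelSize["y"])^2
  dx2 <- ((seq(c0, c1) - center["x"]) * voxelSize["x"])^2
  dz2 <- ((seq(p0, p1) - center["z"]) * voxelSize["z"])^2
  d2 <- outer(outer(dy2, dx2, `+`), dz2, `+`)
  sg <- radiusUm / 2
  img[r0:r1, c0:c1, p0:p1] <- img[r0:r1, c0:c1, p0:p1] +
    peak * exp(-d2 / (2 * sg^2))
  img
}

# Smooth multiplicative illumination field: 1 + amp * product of single-period
# sinusoids with random phase, constant across z.
illuminationField <- function(dims, amplitude) {
  phy <- stats::runif(1, 0, 2 * pi)
  phx <- stats::runif(1, 0, 2 * pi)
  gy <- sin(2 * pi * seq_len(dims[1]) / dims[1] + phy)
  gx <- sin(2 * pi * seq_len(dims[2]) / dims[2] + phx)
  g2 <- 1 + amplitude * outer(gy, gx)
  array(rep(g2, dims[3]), dims)
}

#' Default phantom geometry and intensity parameters
#'
#' The defaults mirror the imaging geometry of the workflow's source data:
#' 1.08 x 1.08 um lateral pixels with a 3 um z step. Cells are rendered as
#' Gaussian-profile spheres (sigma = radius/2) of nominal radius 6 um on a
#' noisy background carrying a low-frequency multiplicative illumination
#' gradient (default amplitude 20% of background).
#'
#' @param nCells number of cells to plant.
#' @param dims stack dimensions \code{c(ny, nx, nz)} in voxels.
#' @param voxelSize voxel size in um, named \code{c(x=, y=, z=)}.
#' @param radiusUm nominal cell radius, um.
#' @param snr peak signal amplitude divided by background noise SD.
#' @param background mean background level (arbitrary units).
#' @param noiseSd background noise SD.
#' @param gradientAmplitude relative amplitude of the illumination field.
#' @return a named list of phantom parameters.
#' @export
phantomSpec <- function(nCells = 20L, dims = c(128L, 128L, 24L),
                        voxelSize = c(x = 1.08, y = 1.08, z = 3),
                        radiusUm = 6, snr = 10, background = 100,
                        noiseSd = 20, gradientAmplitude = 0.2) {
  vox <- as.numeric(voxelSize); names(vox) <- c("x", "y", "z")
  list(nCells = as.integer(nCells), dims = as.integer(dims), voxelSize = vox,
       radiusUm = radiusUm, snr = snr, background = background,
       noiseSd = noiseSd, gradientAmplitude = gradientAmplitude)
}

renderPunctate <- function(spec, centers, channelTag, channelName) {
  dims <- spec$dims
  peak <- spec$snr * spec$noiseSd
  img <- array(0, dims)
  for (i in seq_len(nrow(centers)))
    img <- addSphere(img, centers[i, ], spec$radiusUm, peak, spec$voxelSize)
  img <- illuminationField(dims, spec$gradientAmplitude) *
    (spec$background + img) +
    stats::rnorm(prod(dims), 0, spec$noiseSd)
  img <- pmax(img, 0)
  cells <- if (nrow(centers)) {
    data.frame(id = seq_len(nrow(centers)), x = centers[, "x"],
               y = centers[, "y"], z = centers[, "z"],
               radius_um = spec$radiusUm, channel = channelTag)
  } else emptyTruthCells()
  list(stack = VoxelStack(img, spec$voxelSize, channelName), cells = cells)
}

#' Generate a punctate (filled-sphere) phantom stack
#'
#' Emulates nuclear-localized immediate-early-gene staining: bright
#' Gaussian-profile spheres on a noisy background with a low-frequency
#' illumination gradient. Centres are placed with minimum separation
#' 2 x radius; ground truth lists every planted sphere.
#'
#' @param spec a \code{\link{phantomSpec}} list.
#' @param seed RNG seed; identical seeds give bit-identical stacks.
#' @param channelName label for the returned \code{\link{VoxelStack}}.
#' @return list with elements \code{stack} (\code{VoxelStack}) and
#'   \code{truth} (\code{\link{PhantomTruth}}).
#' @examples
#' ph <- makePunctateStack(phantomSpec(nCells = 3, dims = c(48, 48, 12)),
#'                         seed = 1)
#' nrow(truthCells(ph$truth))
#' @export
makePunctateStack <- function(spec = phantomSpec(), seed = NULL,
                              channelName = "punctate") {
  withSeed(seed, {
    centers <- placeCenters(spec$nCells, spec$dims, spec$voxelSize,
                            spec$radiusUm)
    r <- renderPunctate(spec, centers, "ch1", channelName)
    list(stack = r$stack, truth = PhantomTruth(r$cells))
  })
}

# Trace one random-walk filament from a soma centre; returns voxel indices.
traceFilament <- function(center, dims, voxelSize, nSteps) {
  dir <- c(stats::rnorm(2), stats::rnorm(1) * 0.2)  # mostly lateral
  dir <- dir / sqrt(sum(dir^2))
  pos <- c(center["x"], center["y"], center["z"])
  out <- matrix(NA_real_, nSteps, 3)
  for (s in seq_len(nSteps)) {
    dir <- dir + c(stats::rnorm(2, 0, 0.3), stats::rnorm(1, 0, 0.06))
    dir <- dir / sqrt(sum(dir^2))
    # unit um step, expressed in voxels per axis
    pos <- pos + dir * 1.5 / voxelSize[c("x", "y", "z")]
    out[s, ] <- pos
  }
  rc <- cbind(round(out[, 2]), round(out[, 1]), round(out[, 3]))
  keep <- rc[, 1] >= 1 & rc[, 1] <= dims[1] & rc[, 2] >= 1 &
    rc[, 2] <= dims[2] & rc[, 3] >= 1 & rc[, 3] <= dims[3]
  rc[keep, , drop = FALSE]
}

#' Generate a soma-plus-process phantom stack
#'
#' Emulates cytoplasmic reporter staining with dendritic/axonal processes:
#' each cell is a bright soma sphere plus dimmer random-walk filaments
#' emanating from it. Ground truth lists soma centres only; the filaments
#' are the structures the soma-optimized segmentation must suppress.
#'
#' @inheritParams makePunctateStack
#' @param processesPerCell number of filaments per soma (0 reduces to the
#'   sphere phantom).
#' @param processLength filament length in steps (about 1.5 um each).
#' @param processIntensity filament intensity as a fraction of the soma
#'   peak amplitude.
#' @return list with \code{stack} and \code{truth} as in
#'   \code{\link{makePunctateStack}}.
#' @export
makeSomaProcessStack <- function(spec = phantomSpec(nCells = 15L,
                                                    dims = c(160L, 160L, 24L)),
                                 seed = NULL,
                                 processesPerCell = 3L, processLength = 25L,
                                 processIntensity = 0.35,
                                 channelName = "soma") {
  withSeed(seed, {
    centers <- placeCenters(spec$nCells, spec$dims, spec$voxelSize,
                            spec$radiusUm)
    dims <- spec$dims
    peak <- spec$snr * spec$noiseSd
    img <- array(0, dims)
    for (i in seq_len(nrow(centers)))
      img <- addSphere(img, centers[i, ], spec$radiusUm, peak, spec$voxelSize)
    if (processesPerCell > 0L && nrow(centers)) {
      fil <- array(0, dims)
      for (i in seq_len(nrow(centers))) {
        for (k in seq_len(processesPerCell)) {
          rc <- traceFilament(centers[i, ], dims, spec$voxelSize,
                              processLength)
          if (nrow(rc)) fil[rc] <- processIntensity * peak
        }
      }
      img <- pmax(img, fil)
    }
    img <- illuminationField(dims, spec$gradientAmplitude) *
      (spec$background + img) +
      stats::rnorm(prod(dims), 0, spec$noiseSd)
    img <- pmax(img, 0)
    cells <- if (nrow(centers)) {
      data.frame(id = seq_len(nrow(centers)), x = centers[, "x"],
                 y = centers[, "y"], z = centers[, "z"],
                 radius_um = spec$radiusUm, channel = "ch1")
    } else emptyTruthCells()
    list(stack = VoxelStack(img, spec$voxelSize, channelName),
         truth = PhantomTruth(cells))
  })
}

# Fractional volume of intersection of two equal spheres (radius r, centre
# distance d), relative to one sphere.
sphereOverlapFraction <- function(d, r) {
  ifelse(d >= 2 * r, 0, (4 * r + d) * (2 * r - d)^2 / (16 * r^3))
}

#' Generate a dual-channel phantom with designed co-labeled cells
#'
#' Channel 1 and channel 2 are sphere phantoms sharing one field of view; a
#' designed fraction of channel-2 cells is placed at channel-1 centres
#' (within \code{jitterUm}), mimicking a co-labeled population. Ground
#' truth records the designed pairs with their analytic fractional sphere
#' overlap (1 when jitter is 0).
#'
#' @inheritParams makePunctateStack
#' @param overlapFraction fraction of channel-2 cells co-located with
#'   channel-1 cells, in [0, 1].
#' @param nCellsCh2 number of channel-2 cells (default: same as channel 1).
#' @param jitterUm isotropic uniform jitter applied to co-located centres.
#' @return list with \code{ch1}, \code{ch2} (\code{VoxelStack}s) and
#'   \code{truth} (\code{PhantomTruth} holding both channels' cells and the
#'   designed pairs).
#' @export
makeDualChannel <- function(spec = phantomSpec(), overlapFraction = 0.5,
                            nCellsCh2 = NULL, jitterUm = 0, seed = NULL) {
  stopifnot(overlapFraction >= 0, overlapFraction <= 1)
  withSeed(seed, {
    n1 <- spec$nCells
    n2 <- if (is.null(nCellsCh2)) n1 else as.integer(nCellsCh2)
    vox <- spec$voxelSize
    centers1 <- placeCenters(n1, spec$dims, vox, spec$radiusUm)
    nCo <- round(overlapFraction * n2)
    if (nCo > n1) stop("more co-labeled cells requested than channel-1 cells")
    coIdx <- if (nCo > 0) sort(sample.int(n1, nCo)) else integer()
    centers2 <- matrix(numeric(), 0, 3,
                       dimnames = list(NULL, c("x", "y", "z")))
    if (nCo > 0) {
      jit <- matrix(stats::runif(3 * nCo, -jitterUm, jitterUm), nCo, 3)
      jitVox <- sweep(jit, 2, vox[c("x", "y", "z")], `/`)
      centers2 <- centers1[coIdx, , drop = FALSE] + jitVox
    }
    if (n2 - nCo > 0) {
      indep <- placeCenters(n2 - nCo, spec$dims, vox, spec$radiusUm,
                            avoidUm = list(centers = centers1,
                                           minSepUm = 2 * spec$radiusUm))
      centers2 <- rbind(centers2, indep)
    }
    r1 <- renderPunctate(spec, centers1, "ch1", "ch1")
    spec2 <- spec; spec2$nCells <- n2
    r2 <- renderPunctate(spec2, centers2, "ch2", "ch2")
    r2$cells$id <- seq_len(nrow(r2$cells)) + n1   # globally unique ids
    pairs <- if (nCo > 0) {
      dUm <- sqrt(rowSums(sweep(
        (centers2[seq_len(nCo), , drop = FALSE] -
           centers1[coIdx, , drop = FALSE]), 2,
        vox[c("x", "y", "z")], `*`)^2))
      data.frame(id_ch1 = coIdx, id_ch2 = r2$cells$id[seq_len(nCo)],
                 designed_overlap = sphereOverlapFraction(dUm, spec$radiusUm))
    } else emptyColocPairs()
    list(ch1 = r1$stack, ch2 = r2$stack,
         truth = PhantomTruth(rbind(r1$cells, r2$cells), pairs))
  })
}

# ---- regional count simulation -------------------------------------------

# Clip negative eigenvalues to eps and renormalize to unit diagonal.
nearestPSDCorr <- function(R, eps = 1e-8, tol = 0.1) {
  ed <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (all(ed$values >= 0)) return((R + t(R)) / 2)
  vals <- pmax(ed$values, eps)
  R2 <- ed$vectors %*% (vals * t(ed$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  dimnames(R2) <- dimnames(R)
  if (max(abs(R2 - R)) > tol)
    stop("target correlation matrix is not repairable to PSD within tolerance")
  R2
}

# Draw n rows from N(0, R) via eigen factorization; exactly-correlated
# pairs (r = 1) share a common latent draw bit-for-bit.
rmvnormCorr <- function(n, R) {
  ed <- eigen(R, symmetric = TRUE)
  vals <- pmax(ed$values, 0)
  L <- ed$vectors %*% diag(sqrt(vals), nrow = length(vals))
  matrix(stats::rnorm(n * nrow(R)), n) %*% t(L)
}

#' Specification for a simulated regional count dataset
#'
#' @param nPerGroup mice per group (>= 3).
#' @param regions character vector of region acronyms.
#' @param baseMean median regional density (cells per mm^3 scale).
#' @param dispersion log-scale SD of the lognormal count marginals.
#' @param targetCorr base latent correlation between all region pairs
#'   (scalar), or a full correlation matrix, or a named list
#'   \code{list("A|B" = r, ...)} of pair overrides on top of the scalar.
#' @param plantedDiffs named list \code{list("A|B" = c(rGroupA, rGroupB))}
#'   of pairs whose correlation differs between groups.
#' @param groups the two group labels.
#' @param channel channel tag recorded in the output tables.
#' @param seed RNG seed.
#' @return a validated simulation spec (named list).
#' @export
countSimSpec <- function(nPerGroup = 8L, regions = paste0("R", 1:10),
                         baseMean = 5000, dispersion = 0.3, targetCorr = 0,
                         plantedDiffs = list(), groups = c("CT", "IS"),
                         channel = "cfos", seed = NULL) {
  stopifnot(nPerGroup >= 3L, length(regions) >= 2L, length(groups) == 2L)
  spec <- list(nPerGroup = as.integer(nPerGroup), regions = regions,
               baseMean = baseMean, dispersion = dispersion,
               targetCorr = targetCorr, plantedDiffs = plantedDiffs,
               groups = groups, channel = channel, seed = seed)
  chk <- unlist(plantedDiffs, use.names = FALSE)
  if (length(chk) && any(abs(chk) > 1))
    stop("all target correlations must lie in [-1, 1]")
  spec
}

#' Read a count-simulation spec from YAML
#'
#' @param path YAML file with fields matching \code{\link{countSimSpec}}
#'   arguments (\code{plantedDiffs} as a mapping from "A|B" pair keys to
#'   two-element lists).
#' @return the spec list.
#' @export
readCountSimSpec <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(countSimSpec, c(
    y[intersect(names(y), c("nPerGroup", "regions", "baseMean", "dispersion",
                            "targetCorr", "groups", "channel", "seed"))],
    list(plantedDiffs = lapply(y$plantedDiffs, unlist))))
}

buildTargetMatrix <- function(spec, group) {
  k <- length(spec$regions)
  tc <- spec$targetCorr
  if (is.matrix(tc)) {
    R <- tc
  } else if (is.numeric(tc) && length(tc) == 1L) {
    R <- matrix(tc, k, k); diag(R) <- 1
  } else stop("targetCorr must be a scalar or a correlation matrix")
  dimnames(R) <- list(spec$regions, spec$regions)
  gi <- match(group, spec$groups)
  for (key in names(spec$plantedDiffs)) {
    ab <- strsplit(key, "|", fixed = TRUE)[[1]]
    if (length(ab) != 2L || !all(ab %in% spec$regions))
      stop("plantedDiffs keys must be 'regionA|regionB' with known regions")
    R[ab[1], ab[2]] <- R[ab[2], ab[1]] <- spec$plantedDiffs[[key]][gi]
  }
  if (any(abs(R) > 1)) stop("all target correlations must lie in [-1, 1]")
  nearestPSDCorr(R)
}

#' Simulate per-group regional count tables with planted correlations
#'
#' Counts are lognormal-then-rounded (positive, right-skewed) with the
#' between-region dependence imposed through a Gaussian copula whose latent
#' correlation matrix is the (PSD-repaired) target. Two groups are drawn
#' independently; \code{plantedDiffs} pairs receive different correlations
#' per group. Region volume is fixed at 1 mm^3 so density equals count.
#'
#' @param spec a \code{\link{countSimSpec}}.
#' @param seed RNG seed (overrides \code{spec$seed} when given).
#' @return list with \code{tables} (named list of two region-count
#'   data.frames, see \code{\link{regionCountTable}}) and \code{corr}
#'   (named list of the two latent target correlation matrices).
#' @export
simulateRegionCounts <- function(spec = countSimSpec(), seed = NULL) {
  if (is.null(seed)) seed <- spec$seed
  withSeed(seed, {
    out <- list(tables = list(), corr = list())
    for (g in spec$groups) {
      R <- buildTargetMatrix(spec, g)
      Z <- rmvnormCorr(spec$nPerGroup, R)
      U <- stats::pnorm(Z)
      counts <- round(stats::qlnorm(U, log(spec$baseMean), spec$dispersion))
      ids <- sprintf("%s_m%02d", g, seq_len(spec$nPerGroup))
      tab <- data.frame(
        mouse_id = rep(ids, times = length(spec$regions)),
        group = g,
        acronym = rep(spec$regions, each = spec$nPerGroup),
        channel = spec$channel,
        count = as.vector(counts),
        volume_mm3 = 1)
      tab$density <- tab$count / tab$volume_mm3
      out$tables[[g]] <- tab
      out$corr[[g]] <- R
    }
    out
  })
}

# ---- toy atlas ------------------------------------------------------------

segmentsCross <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-12) return(FALSE)
  t <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
  u <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
  t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
}

polygonsOverlap <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (segmentsCross(a[i, ], a[i %% na + 1, ], b[j, ], b[j %% nb + 1, ]))
        return(TRUE)
    }
  }
  # containment: any vertex or the centroid strictly inside the other
  if (any(pointInPolygon(a[, 1], a[, 2], b, strict = TRUE)) ||
      any(pointInPolygon(b[, 1], b[, 2], a, strict = TRUE)))
    return(TRUE)
  ca <- colMeans(a); cb <- colMeans(b)
  pointInPolygon(ca[1], ca[2], b, strict = TRUE) ||
    pointInPolygon(cb[1], cb[2], a, strict = TRUE)
}

buildOntologyFromParents <- function(acronyms, parents, rootName = "root") {
  mk <- function(acr) {
    kids <- acronyms[parents == acr]
    list(acronym = acr, name = acr,
         children = lapply(kids, mk))
  }
  tops <- acronyms[!(parents %in% acronyms)]
  list(acronym = rootName, name = rootName, children = lapply(tops, mk))
}

#' Build a toy atlas plate from a polygon layout
#'
#' Stands in for a vectorized coronal reference plate: a set of
#' non-overlapping simple polygons in atlas micrometres, each tagged with
#' an acronym and a parent link from which the ontology subtree is built.
#'
#' @param layout list of regions, each \code{list(acronym=, vertices= M x 2
#'   matrix, parent=)} (parent defaults to the root).
#' @param apCoordinate anterior-posterior coordinate of the plate, mm.
#' @param root acronym of the ontology root.
#' @return an \code{\link{AtlasPlate-class}} object.
#' @examples
#' pl <- makeToyAtlasPlate(toyGridLayout())
#' plateAcronyms(pl)
#' @export
makeToyAtlasPlate <- function(layout, apCoordinate = 0, root = "root") {
  if (length(layout) == 0L) stop("empty layout: at least one region required")
  acrs <- vapply(layout, `[[`, character(1), "acronym")
  polys <- lapply(layout, function(r) {
    v <- r$vertices
    storage.mode(v) <- "double"
    v
  })
  parents <- vapply(layout, function(r)
    if (is.null(r$parent)) root else r$parent, character(1))
  for (i in seq_along(polys)) {
    for (j in seq_len(i - 1L)) {
      if (polygonsOverlap(polys[[i]], polys[[j]]))
        stop(sprintf("regions '%s' and '%s' overlap", acrs[i], acrs[j]))
    }
  }
  new("AtlasPlate", apCoordinate = apCoordinate, acronyms = acrs,
      polygons = polys,
      ontology = buildOntologyFromParents(acrs, parents, root))
}

#' @rdname makeToyAtlasPlate
#' @param sideUm side length of each grid square, um.
#' @param acronyms four acronyms, row-major from the lower-left square.
#' @export
toyGridLayout <- function(sideUm = 1, acronyms = c("A", "B", "C", "D")) {
  sq <- function(x0, y0) {
    matrix(c(x0, y0, x0 + sideUm, y0, x0 + sideUm, y0 + sideUm,
             x0, y0 + sideUm), ncol = 2, byrow = TRUE)
  }
  list(list(acronym = acronyms[1], vertices = sq(0, 0)),
       list(acronym = acronyms[2], vertices = sq(sideUm, 0)),
       list(acronym = acronyms[3], vertices = sq(0, sideUm)),
       list(acronym = acronyms[4], vertices = sq(sideUm, sideUm)))
}

# ---- phantom IO -----------------------------------------------------------

#' Write / read a VoxelStack as a multi-page TIFF
#'
#' One file per channel; intensities are scaled into [0, 1] by
#' \code{scale} (default: the stack maximum, recorded back on read via the
#' \code{scale} argument) and stored at 16 bits per sample.
#'
#' @param stack a \code{\link{VoxelStack}}.
#' @param path output .tif path.
#' @param scale divisor applied before writing (and multiplier on read).
#' @return \code{writeVoxelStack} returns the scale used, invisibly.
#' @export
writeVoxelStack <- function(stack, path, scale = NULL) {
  img <- intensities(stack)
  if (is.null(scale)) scale <- max(img, 1e-12)
  pages <- lapply(seq_len(dim(img)[3]),
                  function(k) pmin(pmax(img[, , k] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(scale)
}

#' @rdname writeVoxelStack
#' @param voxelSize,channelName metadata for the returned stack.
#' @export
readVoxelStack <- function(path, voxelSize = c(x = 1.08, y = 1.08, z = 3),
                           channelName = "channel", scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]
    arr[, , k] <- pg * scale
  }
  VoxelStack(arr, voxelSize, channelName)
}

#' Write phantom ground truth as CSV
#'
#' Columns: id, x, y, z (voxel coordinates), radius_um, channel; designed
#' coloc pairs in a companion \code{*_pairs.csv} when present.
#'
#' @param truth a \code{\link{PhantomTruth}}.
#' @param path output .csv path.
#' @export
writePhantomTruth <- function(truth, path) {
  utils::write.csv(truthCells(truth), path, row.names = FALSE)
  if (nrow(truthColocPairs(truth))) {
    utils::write.csv(truthColocPairs(truth),
                     sub("\\.csv$", "_pairs.csv", path), row.names = FALSE)
  }
  invisible(path)
}
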