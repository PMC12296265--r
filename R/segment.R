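# Morphology-specific 3D segmentation: a punctate (filled-sphere) pipeline
# built on Fourier bandpass + rolling-ball + seeded spot growth, and a
# soma pipeline built on blur + top-percentile masking + watershed.
# Object-based colocalization and the manual-validation arithmetic live
# here too.

#' @importFrom EBImage makeBrush erode dilate gblur
NULL

# 3D watershed by immersion on a masked intensity image, 26-connectivity.
# Voxels are flooded in decreasing intensity order; a voxel touching no
# labeled neighbor starts a new basin, and basins whose dynamics (peak
# minus the merge level) fall below `tolerance` are merged into the
# deeper neighbor.
watershed3d <- function(img, mask, tolerance) {
  d <- dim(img)
  idx <- which(mask)
  if (!length(idx)) return(array(0L, d))
  idx <- idx[order(img[idx], decreasing = TRUE)]
  labels <- array(0L, d)
  offs <- neighborOffsets26()
  offLin <- offs[, 1] + offs[, 2] * d[1] + offs[, 3] * d[1] * d[2]
  parent <- integer(0); peak <- numeric(0)
  find <- function(l) { while (parent[l] != l) l <- parent[l]; l }
  co <- arrayInd(idx, d)
  for (t in seq_along(idx)) {
    v <- idx[t]
    # neighbors, guarding the array border by coordinates
    y <- co[t, 1]; x <- co[t, 2]; z <- co[t, 3]
    ok <- y + offs[, 1] >= 1 & y + offs[, 1] <= d[1] &
          x + offs[, 2] >= 1 & x + offs[, 2] <= d[2] &
          z + offs[, 3] >= 1 & z + offs[, 3] <= d[3]
    nl <- labels[v + offLin[ok]]
    nl <- nl[nl > 0L]
    if (!length(nl)) {
      parent <- c(parent, length(parent) + 1L)
      peak <- c(peak, img[v])
      labels[v] <- length(parent)
      next
    }
    roots <- unique(vapply(nl, find, integer(1)))
    best <- roots[which.max(peak[roots])]
    labels[v] <- best
    if (length(roots) > 1L) {
      lev <- img[v]
      for (r in setdiff(roots, best)) {
        if (peak[r] - lev < tolerance) parent[r] <- best
      }
    }
  }
  lab <- labels[idx]
  lab <- vapply(lab, find, integer(1))
  keep <- sort(unique(lab))
  labels[idx] <- match(lab, keep)
  labels
}

# Difference-of-Gaussians bandpass applied per z-plane in Fourier space.
# Structures between `small` and `large` voxels (lateral) are passed.
fourierBandpass <- function(img, small, large) {
  d <- dim(img)
  fy <- c(seq(0, floor(d[1] / 2)), seq(-ceiling(d[1] / 2) + 1, -1)) / d[1]
  fx <- c(seq(0, floor(d[2] / 2)), seq(-ceiling(d[2] / 2) + 1, -1)) / d[2]
  f2 <- outer(fy^2, fx^2, `+`)
  s1 <- small / 2; s2 <- large / 2
  H <- exp(-2 * pi^2 * s1^2 * f2) - exp(-2 * pi^2 * s2^2 * f2)
  out <- img
  for (k in seq_len(d[3])) {
    out[, , k] <- Re(stats::fft(stats::fft(img[, , k]) * H, inverse = TRUE)) /
      (d[1] * d[2])
  }
  out
}

# Rolling-ball background subtraction, approximated as grayscale opening
# with a disc structuring element applied per z-plane, subtracted from the
# original plane.
rollingBallSubtract <- function(img, radius) {
  d <- dim(img)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  out <- img
  for (k in seq_len(d[3])) {
    pl <- img[, , k]
    bg <- EBImage::dilate(EBImage::erode(pl, brush), brush)
    out[, , k] <- pl - bg
  }
  out
}

# Separable 3D Gaussian blur: EBImage 2D blur per plane, then a 1D
# Gaussian along z with sigma scaled by the voxel anisotropy.
gaussianBlur3d <- function(img, sigma, voxelSize) {
  d <- dim(img)
  out <- EBImage::gblur(img, sigma = sigma)
  dim(out) <- d
  sigmaZ <- sigma * voxelSize["x"] / voxelSize["z"]
  if (sigmaZ > 0.2) {
    K <- max(1L, ceiling(3 * sigmaZ))
    w <- exp(-(seq(-K, K))^2 / (2 * sigmaZ^2))
    w <- w / sum(w)
    acc <- array(0, d)
    for (s in seq(-K, K)) {
      zsrc <- pmin(pmax(seq_len(d[3]) + s, 1L), d[3])  # replicate borders
      acc <- acc + w[s + K + 1] * out[, , zsrc, drop = FALSE]
    }
    out <- acc
  }
  out
}

# 3D local maxima: voxels equal to the running maximum over a lateral disc
# (radius in voxels) and +-rz planes, strictly above minPeak. Maxima closer
# than the lateral radius (in um, using the anisotropic voxel size) are
# deduplicated keeping the brighter one.
localMaxima3d <- function(img, radius, voxelSize, minPeak) {
  d <- dim(img)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  mx <- img
  for (k in seq_len(d[3])) mx[, , k] <- EBImage::dilate(img[, , k], brush)
  rz <- max(1L, round(radius * voxelSize["x"] / voxelSize["z"]))
  mz <- mx
  for (s in seq(-rz, rz)) {
    if (s == 0) next
    zsrc <- pmin(pmax(seq_len(d[3]) + s, 1L), d[3])
    mz <- pmax(mz, mx[, , zsrc, drop = FALSE])
  }
  idx <- which(img >= mz & img > minPeak)
  if (!length(idx)) return(matrix(numeric(), 0, 4,
                                  dimnames = list(NULL, c("y", "x", "z", "value"))))
  co <- arrayInd(idx, d)
  val <- img[idx]
  ord <- order(-val)
  co <- co[ord, , drop = FALSE]; val <- val[ord]
  radUm <- radius * voxelSize["x"]
  keep <- logical(length(val))
  ky <- kx <- kz <- numeric(0)
  for (i in seq_along(val)) {
    if (length(ky)) {
      d2 <- ((ky - co[i, 1]) * voxelSize["y"])^2 +
            ((kx - co[i, 2]) * voxelSize["x"])^2 +
            ((kz - co[i, 3]) * voxelSize["z"])^2
      if (any(d2 < radUm^2)) next
    }
    keep[i] <- TRUE
    ky <- c(ky, co[i, 1]); kx <- c(kx, co[i, 2]); kz <- c(kz, co[i, 3])
  }
  cbind(y = co[keep, 1], x = co[keep, 2], z = co[keep, 3], value = val[keep])
}

neighborOffsets26 <- function() {
  g <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  as.matrix(g[!(g$dy == 0 & g$dx == 0 & g$dz == 0), ])
}

# Grow a labeled object around each seed (processed brightest-first): BFS
# over the 26-neighborhood claiming unlabeled voxels with intensity >=
# growFrac x the seed intensity.
spotGrow <- function(img, seeds, growFrac, maxVoxels = 50000L) {
  d <- dim(img)
  labels <- array(0L, d)
  offs <- neighborOffsets26()
  nextLab <- 0L
  for (i in seq_len(nrow(seeds))) {
    sy <- seeds[i, "y"]; sx <- seeds[i, "x"]; sz <- seeds[i, "z"]
    if (labels[sy, sx, sz] != 0L) next   # absorbed by a brighter object
    nextLab <- nextLab + 1L
    thr <- growFrac * seeds[i, "value"]
    labels[sy, sx, sz] <- nextLab
    frontier <- matrix(c(sy, sx, sz), 1)
    size <- 1L
    while (nrow(frontier) && size < maxVoxels) {
      cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(offs)), ,
                       drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), times = nrow(frontier)), , drop = FALSE]
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
            cand[, 2] >= 1 & cand[, 2] <= d[2] &
            cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      if (!nrow(cand)) break
      lin <- cand[, 1] + (cand[, 2] - 1L) * d[1] +
        (cand[, 3] - 1L) * d[1] * d[2]
      dup <- duplicated(lin)
      cand <- cand[!dup, , drop = FALSE]; lin <- lin[!dup]
      take <- labels[lin] == 0L & img[lin] >= thr
      lin <- lin[take]
      if (!length(lin)) break
      labels[lin] <- nextLab
      size <- size + length(lin)
      frontier <- cand[take, , drop = FALSE]
    }
  }
  labels
}

# Summarize a label volume into the per-object table; applies the volume
# filter and the optional xy edge-exclusion margin, relabeling compactly.
labelsToObjects <- function(labels, img, voxelSize, channel, minVolume,
                            maxVolume = Inf, edgeMargin = 0L) {
  d <- dim(labels)
  idx <- which(labels > 0L)
  if (!length(idx)) {
    return(new("SegmentationResult", objects = emptyObjectTable(channel),
               labels = labels, voxelSize = voxelSize, channel = channel))
  }
  lab <- labels[idx]
  co <- arrayInd(idx, d)
  nvox <- tabulate(lab)
  ids <- which(nvox >= minVolume & nvox <= maxVolume)
  if (edgeMargin > 0L && length(ids)) {
    cy <- vapply(ids, function(l) mean(co[lab == l, 1]), numeric(1))
    cx <- vapply(ids, function(l) mean(co[lab == l, 2]), numeric(1))
    inb <- cy > edgeMargin & cy <= d[1] - edgeMargin &
           cx > edgeMargin & cx <= d[2] - edgeMargin
    ids <- ids[inb]
  }
  if (!length(ids)) {
    return(new("SegmentationResult", objects = emptyObjectTable(channel),
               labels = array(0L, d), voxelSize = voxelSize,
               channel = channel))
  }
  keep <- lab %in% ids
  newLab <- match(lab, ids)   # NA for dropped
  out <- array(0L, d)
  out[idx[keep]] <- newLab[keep]
  voxVol <- prod(voxelSize)
  objs <- do.call(rbind, lapply(seq_along(ids), function(j) {
    sel <- which(newLab == j)
    data.frame(
      object_id = j, channel = channel,
      x_um = (mean(co[sel, 2]) - 1) * voxelSize["x"],
      y_um = (mean(co[sel, 1]) - 1) * voxelSize["y"],
      z_um = (mean(co[sel, 3]) - 1) * voxelSize["z"],
      voxels = length(sel),
      volume_um3 = length(sel) * voxVol,
      peak = max(img[idx[sel]]))
  }))
  rownames(objs) <- NULL
  new("SegmentationResult", objects = objs, labels = out,
      voxelSize = voxelSize, channel = channel)
}

emptyObjectTable <- function(channel = character(0)) {
  data.frame(object_id = integer(), channel = character(), x_um = numeric(),
             y_um = numeric(), z_um = numeric(), voxels = integer(),
             volume_um3 = numeric(), peak = numeric())
}

#' Default parameters for the two segmentation pipelines
#'
#' The upstream stages are fixed; the numeric values are adjustable
#' parameters. Sizes are in voxels at the default 1.08 x 1.08 x 3 um
#' geometry.
#'
#' @param bandpassSmall,bandpassLarge pass-band of the Fourier bandpass
#'   (lateral structure sizes, voxels).
#' @param rollingBallRadius rolling-ball radius (voxels, per z-plane).
#' @param maximaRadius lateral radius of the 3D local-maxima filter.
#' @param growFraction spot growth keeps voxels above this fraction of the
#'   seed intensity.
#' @param minPeak minimum seed intensity; \code{NULL} selects
#'   mean + 4 SD of the filtered stack automatically.
#' @param minVolume,maxVolume object volume filter (voxels).
#' @param edgeMargin optional xy margin (voxels); objects whose centroid
#'   falls within it are discarded (replaces interactive deletion of edge
#'   artifacts).
#' @return named parameter list.
#' @export
punctateParams <- function(bandpassSmall = 2, bandpassLarge = 20,
                           rollingBallRadius = 15, maximaRadius = 4,
                           growFraction = 0.5, minPeak = NULL,
                           minVolume = 30, maxVolume = Inf, edgeMargin = 0) {
  list(bandpassSmall = bandpassSmall, bandpassLarge = bandpassLarge,
       rollingBallRadius = rollingBallRadius, maximaRadius = maximaRadius,
       growFraction = growFraction, minPeak = minPeak, minVolume = minVolume,
       maxVolume = maxVolume, edgeMargin = edgeMargin)
}

#' @rdname punctateParams
#' @param sigma Gaussian blur sigma (lateral voxels; the z sigma is scaled
#'   by the voxel anisotropy).
#' @param topPercent brightest-pixel percentage kept by the mask
#'   (default 0.5).
#' @param tolerance watershed dynamics on the [0, 1]-normalized masked
#'   intensity; \code{NULL} selects 0.2 automatically.
#' @export
somaParams <- function(rollingBallRadius = 15, sigma = 2, topPercent = 0.5,
                       tolerance = NULL, minVolume = 30, maxVolume = Inf,
                       edgeMargin = 0) {
  list(rollingBallRadius = rollingBallRadius, sigma = sigma,
       topPercent = topPercent, tolerance = tolerance, minVolume = minVolume,
       maxVolume = maxVolume, edgeMargin = edgeMargin)
}

checkFilterSupport <- function(d, need) {
  if (min(d[1:2]) < need)
    stop(sprintf("stack (%d x %d laterally) is smaller than the filter support (%d)",
                 d[1], d[2], need))
}

#' Segment punctate (filled-sphere) staining in 3D
#'
#' Pipeline: (1) Fourier bandpass per z-plane, (2) rolling-ball background
#' subtraction per z-plane, (3) 3D local-maxima detection, (4) spot growth
#' around each maximum down to a fractional-intensity cutoff
#' (brightest-first, so touching cells stay split), (5) volume filtering.
#'
#' @param stack a \code{\link{VoxelStack}}.
#' @param params a \code{\link{punctateParams}} list.
#' @return a \code{\link{SegmentationResult-class}} with disjoint labeled
#'   objects; an empty result (no error) when no maxima are found.
#' @export
segmentPunctate <- function(stack, params = punctateParams()) {
  img <- intensities(stack)
  d <- dim(img)
  checkFilterSupport(d, max(params$bandpassLarge,
                            2 * params$rollingBallRadius + 1))
  flt <- fourierBandpass(img, params$bandpassSmall, params$bandpassLarge)
  flt <- rollingBallSubtract(flt, params$rollingBallRadius)
  minPeak <- params$minPeak
  if (is.null(minPeak)) minPeak <- mean(flt) + 4 * stats::sd(flt)
  seeds <- localMaxima3d(flt, params$maximaRadius, voxelSize(stack), minPeak)
  if (!nrow(seeds)) {
    return(new("SegmentationResult", objects = emptyObjectTable(),
               labels = array(0L, d), voxelSize = voxelSize(stack),
               channel = channelName(stack)))
  }
  labels <- spotGrow(flt, seeds, params$growFraction)
  labelsToObjects(labels, img, voxelSize(stack), channelName(stack),
                  params$minVolume, params$maxVolume, params$edgeMargin)
}

#' Segment soma staining while suppressing processes
#'
#' Pipeline: rolling-ball background subtraction, 3D Gaussian blur,
#' top-percentile binary mask (default: the 0.5% brightest voxels),
#' watershed split of the masked intensity, volume filtering. Thin
#' processes are suppressed because their blurred intensity falls below
#' the top-percentile cutoff.
#'
#' @param stack a \code{\link{VoxelStack}}.
#' @param params a \code{\link{somaParams}} list.
#' @return a \code{\link{SegmentationResult-class}}.
#' @export
segmentSoma <- function(stack, params = somaParams()) {
  if (params$topPercent <= 0 || params$topPercent > 100)
    stop("topPercent must lie in (0, 100]")
  img <- intensities(stack)
  d <- dim(img)
  checkFilterSupport(d, 2 * params$rollingBallRadius + 1)
  flt <- rollingBallSubtract(img, params$rollingBallRadius)
  flt <- gaussianBlur3d(flt, params$sigma, voxelSize(stack))
  mask <- topPercentileThreshold(flt, params$topPercent)
  if (!any(mask)) {
    return(new("SegmentationResult", objects = emptyObjectTable(),
               labels = array(0L, d), voxelSize = voxelSize(stack),
               channel = channelName(stack)))
  }
  rel <- (flt - min(flt[mask])) / (max(flt) - min(flt[mask]))
  tol <- if (is.null(params$tolerance)) 0.2 else params$tolerance
  labels <- watershed3d(rel, mask, tol)
  labelsToObjects(labels, img, voxelSize(stack), channelName(stack),
                  params$minVolume, params$maxVolume, params$edgeMargin)
}

#' Mask the brightest voxels of a stack
#'
#' Selects voxels strictly greater than the (100 - percent)-th intensity
#' percentile (linear interpolation), so a constant stack yields an empty
#' mask and the selected fraction never exceeds percent/100.
#'
#' @param stack a \code{\link{VoxelStack}} or numeric array.
#' @param percent percentage of brightest voxels, in (0, 100].
#' @return logical array of the same shape.
#' @export
topPercentileThreshold <- function(stack, percent) {
  if (percent <= 0 || percent > 100)
    stop("percent must lie in (0, 100]")
  img <- if (is(stack, "VoxelStack")) intensities(stack) else stack
  thr <- stats::quantile(img, probs = 1 - percent / 100, names = FALSE,
                         type = 7)
  img > thr
}

#' Enumerate voxel overlaps between two channels' labeled objects
#'
#' Uses the label volumes produced during single-channel segmentation to
#' identify every ordered pair of objects sharing at least one voxel.
#' Percent overlap is expressed relative to the channel-2 object's volume;
#' a channel-2 object may appear in several records.
#'
#' @param ch1,ch2 \code{\link{SegmentationResult-class}} objects (or raw
#'   integer label arrays) on the same voxel grid.
#' @return data.frame \code{(id_ch1, id_ch2, overlap_voxels,
#'   percent_overlap)}.
#' @export
computePairwiseOverlaps <- function(ch1, ch2) {
  l1 <- if (is(ch1, "SegmentationResult")) segLabels(ch1) else ch1
  l2 <- if (is(ch2, "SegmentationResult")) segLabels(ch2) else ch2
  if (!identical(dim(l1), dim(l2)))
    stop("label volumes must share the same grid shape")
  both <- which(l1 > 0L & l2 > 0L)
  if (!length(both)) return(emptyColocTable())
  size2 <- tabulate(l2[l2 > 0L])
  tab <- table(l1[both], l2[both])
  rec <- as.data.frame(tab, stringsAsFactors = FALSE)
  rec <- rec[rec$Freq > 0, ]
  out <- data.frame(id_ch1 = as.integer(rec$Var1),
                    id_ch2 = as.integer(rec$Var2),
                    overlap_voxels = as.integer(rec$Freq))
  out$percent_overlap <- 100 * out$overlap_voxels / size2[out$id_ch2]
  out <- out[order(out$id_ch1, out$id_ch2), ]
  rownames(out) <- NULL
  out
}

#' Filter overlap records into co-labeled cells
#'
#' Keeps records whose percent overlap (relative to the channel-2 object)
#' is at least \code{minPercent}. A channel-2 object surviving in several
#' records counts as a single co-labeled cell and is assigned to its
#' largest overlap (ties broken toward the lower channel-1 id), so the
#' returned row count is the number of co-labeled cells.
#'
#' @param records data.frame from \code{\link{computePairwiseOverlaps}}.
#' @param minPercent minimum percent overlap, in [0, 100].
#' @return the filtered records, one row per co-labeled cell.
#' @export
thresholdColoc <- function(records, minPercent) {
  stopifnot(minPercent >= 0, minPercent <= 100)
  rec <- records[records$percent_overlap >= minPercent, , drop = FALSE]
  if (!nrow(rec)) return(rec)
  rec <- rec[order(rec$id_ch2, -rec$percent_overlap, rec$id_ch1), ]
  rec <- rec[!duplicated(rec$id_ch2), ]
  rec <- rec[order(rec$id_ch1, rec$id_ch2), ]
  rownames(rec) <- NULL
  rec
}

#' Validate automated counts against manual counts
#'
#' The estimated true-positive count is the average of two derivations:
#' (manual total - FN) and (auto-segmented total - FP). Precision, recall
#' and F1 follow as P = TP/(TP+FP), R = TP/(TP+FN) and
#' 1/F1 = (1/P + 1/R)/2.
#'
#' @param autoTotal,manualTotal total automated / manual counts.
#' @param fp,fn false positives (detected by the algorithm alone) and
#'   false negatives (detected by the annotator alone).
#' @return named list: \code{tp, tp_estimate_a, tp_estimate_b, fp, fn,
#'   precision, recall, f1}.
#' @examples
#' validateAgainstManual(autoTotal = 95, manualTotal = 100, fp = 5, fn = 10)
#' @export
validateAgainstManual <- function(autoTotal, manualTotal, fp, fn) {
  stopifnot(autoTotal >= 0, manualTotal >= 0, fp >= 0, fn >= 0)
  if (fn > manualTotal) stop("fn cannot exceed the manual total")
  if (fp > autoTotal) stop("fp cannot exceed the automated total")
  tpA <- manualTotal - fn
  tpB <- autoTotal - fp
  tp <- (tpA + tpB) / 2
  if (tp + fp == 0 || tp + fn == 0)
    stop("precision/recall undefined: no positives to evaluate")
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  list(tp = tp, tp_estimate_a = tpA, tp_estimate_b = tpB, fp = fp, fn = fn,
       precision = precision, recall = recall,
       f1 = f1Score(precision, recall))
}

#' Harmonic-mean F1 from precision and recall
#'
#' @param precision,recall ratios in (0, 1].
#' @return F1 = 2 / (1/precision + 1/recall).
#' @export
f1Score <- function(precision, recall) {
  if (any(precision <= 0) || any(recall <= 0))
    stop("precision and recall must be positive")
  2 / (1 / precision + 1 / recall)
}

#' Score a segmentation against phantom ground truth
#'
#' Greedy nearest-centroid matching within a distance tolerance: each
#' truth cell can claim at most one detected object. Matched pairs are
#' true positives; unmatched detections are false positives; unmatched
#' truth cells are false negatives.
#'
#' @param result a \code{\link{SegmentationResult-class}}.
#' @param truth a \code{\link{PhantomTruth}} (or its \code{cells} table);
#'   only cells of \code{channelTag} are used when given.
#' @param tolUm matching radius in um (default: one nominal cell radius).
#' @param channelTag optional truth channel filter ("ch1"/"ch2").
#' @return list: \code{tp, fp, fn, precision, recall, f1}.
#' @export
segmentationScore <- function(result, truth, tolUm = NULL,
                              channelTag = NULL) {
  cells <- if (is(truth, "PhantomTruth")) truthCells(truth) else truth
  if (!is.null(channelTag)) cells <- cells[cells$channel == channelTag, ]
  objs <- segObjects(result)
  vox <- result@voxelSize
  if (is.null(tolUm)) tolUm <- if (nrow(cells)) cells$radius_um[1] else 1
  tUm <- cbind((cells$x - 1) * vox["x"], (cells$y - 1) * vox["y"],
               (cells$z - 1) * vox["z"])
  if (!nrow(objs) || !nrow(cells)) {
    tp <- 0L
  } else {
    dmat <- outer(objs$x_um, tUm[, 1], `-`)^2 +
            outer(objs$y_um, tUm[, 2], `-`)^2 +
            outer(objs$z_um, tUm[, 3], `-`)^2
    dmat <- sqrt(dmat)
    tp <- 0L
    usedObj <- logical(nrow(objs)); usedTruth <- logical(nrow(cells))
    repeat {
      dmat[usedObj, ] <- Inf; dmat[, usedTruth] <- Inf
      m <- which.min(dmat)
      if (!length(m) || dmat[m] > tolUm) break
      ij <- arrayInd(m, dim(dmat))
      usedObj[ij[1]] <- TRUE; usedTruth[ij[2]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- nrow(objs) - tp
  fn <- nrow(cells) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision > 0 &&
            recall > 0) f1Score(precision, recall) else NA_real_
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1)
}

#' Write / read a segmented-object table as tab-separated text
#'
#' Header columns: id, x_um, y_um, z_um, voxels, volume_um3, peak (the
#' import dialect of \code{\link{importObjectTable}}).
#'
#' @param result a \code{\link{SegmentationResult-class}}.
#' @param path output .tsv path.
#' @export
writeObjectTable <- function(result, path) {
  objs <- segObjects(result)
  out <- data.frame(id = objs$object_id, x_um = objs$x_um, y_um = objs$y_um,
                    z_um = objs$z_um, voxels = objs$voxels,
                    volume_um3 = objs$volume_um3, peak = objs$peak)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
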