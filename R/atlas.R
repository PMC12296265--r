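# Thin-plate-spline registration from correspondence points, point-to-region
# assignment on 2D atlas plates, and shoelace areas / region volumes.

tpsKernel <- function(r2) {
  # U(r) = r^2 log r = r2 * log(r2) / 2, with U(0) = 0
  out <- numeric(length(r2))
  pos <- r2 > 0
  out[pos] <- r2[pos] * log(r2[pos]) / 2
  out
}

#' Fit a 2D thin-plate spline to correspondence points
#'
#' Solves the standard TPS system with radial kernel U(r) = r^2 log r.
#' With \code{lambda = 0} the transform interpolates every correspondence
#' pair exactly (the behaviour used for user-corrected registration
#' points); \code{lambda > 0} trades exactness for smoothness when the
#' correspondences are noisy. With exactly 3 points the fit reduces to the
#' unique affine map.
#'
#' @param source,target N x 2 matrices (or data.frames) of matching points,
#'   N >= 3 and not collinear. For synthetic contour seeding, 32 points
#'   along the section outline is the conventional density.
#' @param lambda nonnegative regularization weight (default 0, exact
#'   interpolation).
#' @return a \code{\link{TPSTransform-class}} object.
#' @examples
#' src <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
#' tp <- fitTps(src, src + 5)
#' applyTps(tp, cbind(0.5, 0.5))
#' @export
fitTps <- function(source, target, lambda = 0) {
  source <- as.matrix(source); target <- as.matrix(target)
  storage.mode(source) <- storage.mode(target) <- "double"
  n <- nrow(source)
  if (n < 3L) stop("at least 3 correspondence points are required")
  if (!identical(dim(source), dim(target)) || ncol(source) != 2L)
    stop("source and target must be N x 2 with matching N")
  if (lambda < 0) stop("lambda must be nonnegative")
  # fit in centered, unit-RMS coordinates: the raw micrometre scale makes
  # the kernel block ~1e8 times the affine block and the system numerically
  # singular
  normScale <- function(x) {
    ctr <- colMeans(x)
    sc <- sqrt(mean(sweep(x, 2, ctr)^2))
    if (sc == 0) sc <- 1
    list(center = ctr, scale = sc)
  }
  ns <- normScale(source); nt <- normScale(target)
  srcN <- sweep(source, 2, ns$center) / ns$scale
  tgtN <- sweep(target, 2, nt$center) / nt$scale
  d2 <- outer(srcN[, 1], srcN[, 1], `-`)^2 +
        outer(srcN[, 2], srcN[, 2], `-`)^2
  K <- matrix(tpsKernel(d2), n, n) + diag(lambda, n)
  P <- cbind(1, srcN)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(tgtN, matrix(0, 3, 2))
  ok <- min(abs(eigen(crossprod(P), symmetric = TRUE,
                      only.values = TRUE)$values)) > 1e-10 * n
  coef <- if (ok) tryCatch(solve(A, rhs), error = function(e) NULL) else NULL
  if (is.null(coef))
    stop("singular TPS system: correspondence points are collinear or duplicated")
  new("TPSTransform", source = source, target = target, lambda = lambda,
      coefficients = coef,
      normalization = list(srcCenter = ns$center, srcScale = ns$scale,
                           tgtCenter = nt$center, tgtScale = nt$scale))
}

#' Apply a thin-plate-spline transform to points
#'
#' @param transform a \code{\link{TPSTransform-class}}.
#' @param points M x 2 matrix (or data.frame) of finite coordinates.
#' @return M x 2 matrix of mapped coordinates.
#' @export
applyTps <- function(transform, points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must be M x 2")
  if (any(!is.finite(points))) stop("points must be finite")
  nm <- transform@normalization
  src <- sweep(transform@source, 2, nm$srcCenter) / nm$srcScale
  ptsN <- sweep(points, 2, nm$srcCenter) / nm$srcScale
  n <- nrow(src)
  d2 <- outer(ptsN[, 1], src[, 1], `-`)^2 +
        outer(ptsN[, 2], src[, 2], `-`)^2
  U <- matrix(tpsKernel(d2), nrow(points), n)
  outN <- cbind(U, 1, ptsN) %*% transform@coefficients
  out <- sweep(outN * nm$tgtScale, 2, unname(nm$tgtCenter), `+`)
  dimnames(out) <- NULL
  out
}

# Vectorized even-odd (ray casting) point-in-polygon. strict=TRUE treats
# boundary points as outside (used for overlap checking).
pointInPolygon <- function(px, py, polygon, strict = FALSE) {
  nv <- nrow(polygon)
  xs <- polygon[, 1]; ys <- polygon[, 2]
  inside <- logical(length(px))
  onEdge <- logical(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    # boundary detection: point on segment i-j
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- ((px - xi) * dx + (py - yi) * dy) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
      onEdge <- onEdge | d2 < 1e-18
    }
    j <- i
  }
  if (strict) inside & !onEdge else inside | onEdge
}

#' Assign atlas-space points to plate regions
#'
#' Even-odd point-in-polygon test against every region polygon of a plate.
#' Boundary points are assigned to the first-listed polygon containing
#' them; points inside no polygon are labeled \code{NA} (unassigned).
#'
#' @param points M x 2 matrix of atlas coordinates (um).
#' @param plate an \code{\link{AtlasPlate-class}}.
#' @return character vector of length M: region acronyms or \code{NA}.
#' @export
assignRegion <- function(points, plate) {
  points <- as.matrix(points)
  out <- rep(NA_character_, nrow(points))
  polys <- platePolygons(plate)
  acrs <- plateAcronyms(plate)
  todo <- rep(TRUE, nrow(points))
  for (i in seq_along(polys)) {
    if (!any(todo)) break
    hit <- todo
    hit[todo] <- pointInPolygon(points[todo, 1], points[todo, 2], polys[[i]])
    out[hit] <- acrs[i]
    todo <- todo & !hit
  }
  out
}

#' Polygon area by Gauss's (shoelace) formula
#'
#' Orientation-independent (absolute value); units are the square of the
#' vertex units.
#'
#' @param vertices M x 2 matrix, M >= 3, simple polygon.
#' @return the enclosed area.
#' @export
polygonArea <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) stop("a polygon needs at least 3 vertices")
  x <- vertices[, 1]; y <- vertices[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Region volume from per-slice areas
#'
#' Volume of a mapped region: the areas measured on each section are summed
#' and multiplied by the physical thickness of the imaged stack (e.g.
#' 0.009 mm for a 9 um z-stack).
#'
#' @param areas numeric vector of per-slice areas (mm^2).
#' @param zThickness section stack thickness (mm), > 0.
#' @return volume in mm^3 (0 for an empty area list).
#' @export
regionVolume <- function(areas, zThickness) {
  if (zThickness <= 0) stop("zThickness must be positive")
  sum(areas) * zThickness
}

# ---- plate / ontology JSON io --------------------------------------------

#' Read / write an AtlasPlate as JSON
#'
#' The JSON layout is \code{{ap_coordinate, regions: [{acronym, vertices:
#' [[x, y], ...]}], ontology}}.
#'
#' @param plate an \code{\link{AtlasPlate-class}}.
#' @param path JSON file path.
#' @export
writeAtlasPlate <- function(plate, path) {
  obj <- list(
    ap_coordinate = plate@apCoordinate,
    regions = lapply(seq_along(plate@acronyms), function(i) {
      list(acronym = plate@acronyms[i],
           vertices = unname(apply(plate@polygons[[i]], 1, as.numeric,
                                   simplify = FALSE)))
    }),
    ontology = plate@ontology)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeAtlasPlate
#' @export
readAtlasPlate <- function(path) {
  obj <- jsonlite::read_json(path)
  acrs <- vapply(obj$regions, function(r) r$acronym, character(1))
  polys <- lapply(obj$regions, function(r)
    do.call(rbind, lapply(r$vertices, function(v) as.numeric(unlist(v)))))
  new("AtlasPlate", apCoordinate = as.numeric(obj$ap_coordinate),
      acronyms = acrs, polygons = polys,
      ontology = obj$ontology)
}

#' Write correspondence points as CSV
#'
#' Columns: source_x, source_y, target_x, target_y.
#'
#' @param transform a \code{\link{TPSTransform-class}} (or use
#'   \code{readCorrespondencePoints} + \code{\link{fitTps}}).
#' @param path CSV path.
#' @export
writeCorrespondencePoints <- function(transform, path) {
  utils::write.csv(data.frame(
    source_x = transform@source[, 1], source_y = transform@source[, 2],
    target_x = transform@target[, 1], target_y = transform@target[, 2]),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCorrespondencePoints
#' @return \code{readCorrespondencePoints}: list with \code{source} and
#'   \code{target} matrices, ready for \code{\link{fitTps}}.
#' @export
readCorrespondencePoints <- function(path) {
  df <- utils::read.csv(path)
  need <- c("source_x", "source_y", "target_x", "target_y")
  if (!all(need %in% names(df)))
    stop("correspondence CSV needs columns: ", paste(need, collapse = ", "))
  list(source = as.matrix(df[, c("source_x", "source_y")]),
       target = as.matrix(df[, c("target_x", "target_y")]))
}
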