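#' @import methods
NULL

#' VoxelStack: a single-channel 3D image with physical voxel size
#'
#' Stores one fluorescence channel of a confocal z-stack as a 3D array
#' indexed \code{[y, x, z]} (row, column, plane) together with the physical
#' voxel size in micrometres. All segmentation operations consume this class.
#'
#' @slot intensities 3D numeric array of nonnegative intensities, dim
#'   \code{c(ny, nx, nz)}.
#' @slot voxelSize named numeric of length 3, \code{c(x=, y=, z=)}, in
#'   micrometres; all entries positive. The default imaging geometry is
#'   1.08 x 1.08 um laterally with a 3 um z step.
#' @slot channelName single character, e.g. \code{"cfos"} or \code{"eyfp"}.
#'
#' @examples
#' vs <- VoxelStack(array(0, c(4, 4, 2)), c(x = 1.08, y = 1.08, z = 3))
#' dim(intensities(vs))
#' @export
setClass("VoxelStack",
  representation(
    intensities = "array",
    voxelSize = "numeric",
    channelName = "character"
  )
)

setValidity("VoxelStack", function(object) {
  msg <- NULL
  if (length(dim(object@intensities)) != 3L)
    msg <- c(msg, "intensities must be a 3D array")
  else if (any(dim(object@intensities) < 1L))
    msg <- c(msg, "all dimensions must be >= 1")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive finite values (x, y, z) in um")
  if (length(object@channelName) != 1L)
    msg <- c(msg, "channelName must be a single string")
  if (is.null(msg)) TRUE else msg
})

#' @param intensities 3D array \code{[y, x, z]}.
#' @param voxelSize numeric length-3 voxel size in um (x, y, z order).
#' @param channelName channel label.
#' @rdname VoxelStack-class
#' @export
VoxelStack <- function(intensities, voxelSize = c(x = 1.08, y = 1.08, z = 3),
                       channelName = "channel") {
  voxelSize <- as.numeric(voxelSize)
  names(voxelSize) <- c("x", "y", "z")
  new("VoxelStack", intensities = intensities, voxelSize = voxelSize,
      channelName = channelName)
}

#' @rdname VoxelStack-class
#' @param object,x a \code{VoxelStack}.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname VoxelStack-class
#' @export
setMethod("intensities", "VoxelStack", function(x) x@intensities)

#' @rdname VoxelStack-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname VoxelStack-class
#' @export
setMethod("voxelSize", "VoxelStack", function(x) x@voxelSize)

#' @rdname VoxelStack-class
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))
#' @rdname VoxelStack-class
#' @export
setMethod("channelName", "VoxelStack", function(x) x@channelName)

setMethod("show", "VoxelStack", function(object) {
  d <- dim(object@intensities)
  cat(sprintf(
    "VoxelStack '%s': %d x %d x %d voxels (%.2f x %.2f x %.2f um), range [%.3g, %.3g]\n",
    object@channelName, d[1], d[2], d[3],
    object@voxelSize["x"], object@voxelSize["y"], object@voxelSize["z"],
    min(object@intensities), max(object@intensities)))
})

#' PhantomTruth: ground truth for a synthetic phantom stack
#'
#' Records the designed cells of a phantom (voxel-space centroids, radius,
#' channel tag) and, for dual-channel phantoms, the designed co-labeled
#' pairs with their fractional sphere overlap.
#'
#' @slot cells data.frame with columns \code{id, x, y, z} (voxel
#'   coordinates, 1-based fractional), \code{radius_um}, \code{channel}.
#' @slot colocPairs data.frame with columns \code{id_ch1, id_ch2,
#'   designed_overlap} (fraction in [0, 1]).
#' @export
setClass("PhantomTruth",
  representation(cells = "data.frame", colocPairs = "data.frame"))

setValidity("PhantomTruth", function(object) {
  msg <- NULL
  need <- c("id", "x", "y", "z", "radius_um", "channel")
  if (!all(need %in% names(object@cells)))
    msg <- c(msg, paste("cells must have columns:", paste(need, collapse = ", ")))
  pneed <- c("id_ch1", "id_ch2", "designed_overlap")
  if (!all(pneed %in% names(object@colocPairs)))
    msg <- c(msg, paste("colocPairs must have columns:", paste(pneed, collapse = ", ")))
  else if (nrow(object@colocPairs)) {
    ov <- object@colocPairs$designed_overlap
    if (any(ov < 0 | ov > 1)) msg <- c(msg, "designed_overlap must lie in [0, 1]")
    ch1 <- object@cells$id[object@cells$channel == "ch1"]
    ch2 <- object@cells$id[object@cells$channel == "ch2"]
    if (!all(object@colocPairs$id_ch1 %in% ch1) ||
        !all(object@colocPairs$id_ch2 %in% ch2))
      msg <- c(msg, "coloc pairs must reference existing cells in both channels")
  }
  if (is.null(msg)) TRUE else msg
})

#' @rdname PhantomTruth-class
#' @param cells,colocPairs see slots.
#' @export
PhantomTruth <- function(cells, colocPairs = emptyColocPairs()) {
  new("PhantomTruth", cells = cells, colocPairs = colocPairs)
}

emptyTruthCells <- function() {
  data.frame(id = integer(), x = numeric(), y = numeric(), z = numeric(),
             radius_um = numeric(), channel = character())
}

emptyColocPairs <- function() {
  data.frame(id_ch1 = integer(), id_ch2 = integer(),
             designed_overlap = numeric())
}

#' @rdname PhantomTruth-class
#' @param x a \code{PhantomTruth}.
#' @export
setGeneric("truthCells", function(x) standardGeneric("truthCells"))
#' @rdname PhantomTruth-class
#' @export
setMethod("truthCells", "PhantomTruth", function(x) x@cells)

#' @rdname PhantomTruth-class
#' @export
setGeneric("truthColocPairs", function(x) standardGeneric("truthColocPairs"))
#' @rdname PhantomTruth-class
#' @export
setMethod("truthColocPairs", "PhantomTruth", function(x) x@colocPairs)

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: %d cells (%s), %d designed coloc pairs\n",
              nrow(object@cells),
              paste(unique(object@cells$channel), collapse = "+"),
              nrow(object@colocPairs)))
})

#' SegmentationResult: labeled objects from one channel
#'
#' Couples the per-object summary table with the labeled volume it came
#' from, so that downstream object-based colocalization can enumerate
#' voxel overlaps between channels.
#'
#' @slot objects data.frame, one row per object: \code{object_id, channel,
#'   x_um, y_um, z_um} (centroid), \code{voxels} (voxel count),
#'   \code{volume_um3}, \code{peak} (peak intensity).
#' @slot labels 3D integer array, same shape as the input stack; 0 is
#'   background, positive values are object ids. Objects are disjoint.
#' @slot voxelSize voxel size in um, as in \code{\link{VoxelStack}}.
#' @slot channel channel label.
#' @export
setClass("SegmentationResult",
  representation(objects = "data.frame", labels = "array",
                 voxelSize = "numeric", channel = "character"))

setValidity("SegmentationResult", function(object) {
  msg <- NULL
  need <- c("object_id", "channel", "x_um", "y_um", "z_um", "voxels",
            "volume_um3", "peak")
  if (!all(need %in% names(object@objects)))
    msg <- c(msg, paste("objects must have columns:", paste(need, collapse = ", ")))
  else if (nrow(object@objects) && any(object@objects$voxels < 1))
    msg <- c(msg, "every object must contain at least one voxel")
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  if (is.null(msg)) TRUE else msg
})

#' @rdname SegmentationResult-class
#' @param x a \code{SegmentationResult}.
#' @export
setGeneric("segObjects", function(x) standardGeneric("segObjects"))
#' @rdname SegmentationResult-class
#' @export
setMethod("segObjects", "SegmentationResult", function(x) x@objects)

#' @rdname SegmentationResult-class
#' @export
setGeneric("segLabels", function(x) standardGeneric("segLabels"))
#' @rdname SegmentationResult-class
#' @export
setMethod("segLabels", "SegmentationResult", function(x) x@labels)

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult '%s': %d objects in a %s-voxel volume\n",
              object@channel, nrow(object@objects),
              paste(dim(object@labels), collapse = " x ")))
})

#' TPSTransform: 2D thin-plate-spline mapping fit to correspondence points
#'
#' A smooth deformation of the plane interpolating (lambda = 0) or
#' approximating (lambda > 0) N source -> target correspondence pairs,
#' with radial kernel U(r) = r^2 log r. Used to warp section coordinates
#' into atlas space.
#'
#' @slot source,target N x 2 matrices of control points.
#' @slot lambda nonnegative regularization weight; 0 gives exact
#'   interpolation at the control points.
#' @slot coefficients (N + 3) x 2 matrix; rows 1..N are kernel weights,
#'   the last three rows the affine part (intercept, x, y) per output
#'   dimension. Fitted in normalized coordinates for numerical stability.
#' @slot normalization list with \code{srcCenter, srcScale, tgtCenter,
#'   tgtScale}: the centering/scaling composed around the spline.
#' @export
setClass("TPSTransform",
  representation(source = "matrix", target = "matrix",
                 lambda = "numeric", coefficients = "matrix",
                 normalization = "list"))

setValidity("TPSTransform", function(object) {
  msg <- NULL
  n <- nrow(object@source)
  if (n < 3L) msg <- c(msg, "at least 3 control points are required")
  if (!identical(dim(object@source), dim(object@target)))
    msg <- c(msg, "source and target must have identical dimensions")
  if (length(object@lambda) != 1L || object@lambda < 0)
    msg <- c(msg, "lambda must be a single nonnegative number")
  if (!identical(dim(object@coefficients), c(n + 3L, 2L)))
    msg <- c(msg, "coefficients must be (N + 3) x 2")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "TPSTransform", function(object) {
  cat(sprintf("TPSTransform: %d control points, lambda = %g\n",
              nrow(object@source), object@lambda))
})

#' AtlasPlate: one coronal atlas plate as labeled polygons
#'
#' A 2D reference plate at a fixed anterior-posterior coordinate. Each
#' region is a simple closed polygon in atlas micrometres (x right, y up)
#' tagged with its ontology acronym.
#'
#' @slot apCoordinate anterior-posterior position in mm from bregma.
#' @slot acronyms character vector of region acronyms, one per polygon.
#' @slot polygons list of M x 2 numeric matrices (vertices, um).
#' @slot ontology nested list \code{{acronym, name, children}} covering at
#'   least the plate's acronyms.
#' @export
setClass("AtlasPlate",
  representation(apCoordinate = "numeric", acronyms = "character",
                 polygons = "list", ontology = "list"))

setValidity("AtlasPlate", function(object) {
  msg <- NULL
  if (length(object@acronyms) != length(object@polygons))
    msg <- c(msg, "one polygon per acronym is required")
  if (length(object@polygons) == 0L)
    msg <- c(msg, "a plate must contain at least one region")
  for (p in object@polygons) {
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L) {
      msg <- c(msg, "every polygon must be an M x 2 matrix with M >= 3")
      break
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' @rdname AtlasPlate-class
#' @param x an \code{AtlasPlate}.
#' @export
setGeneric("plateAcronyms", function(x) standardGeneric("plateAcronyms"))
#' @rdname AtlasPlate-class
#' @export
setMethod("plateAcronyms", "AtlasPlate", function(x) x@acronyms)

#' @rdname AtlasPlate-class
#' @export
setGeneric("platePolygons", function(x) standardGeneric("platePolygons"))
#' @rdname AtlasPlate-class
#' @export
setMethod("platePolygons", "AtlasPlate", function(x) x@polygons)

#' @rdname AtlasPlate-class
#' @export
setGeneric("plateOntology", function(x) standardGeneric("plateOntology"))
#' @rdname AtlasPlate-class
#' @export
setMethod("plateOntology", "AtlasPlate", function(x) x@ontology)

setMethod("show", "AtlasPlate", function(object) {
  cat(sprintf("AtlasPlate at AP %.2f mm: %d regions (%s)\n",
              object@apCoordinate, length(object@acronyms),
              paste(utils::head(object@acronyms, 6), collapse = ", ")))
})

#' SliceRecord / MouseRecord / ExperimentRecord: the data hierarchy
#'
#' Slices hold per-image segmentation output, registration and exclusions;
#' mice hold slices plus group metadata; an experiment holds mice, the
#' channels analyzed and the region ontology.
#'
#' @slot sliceId image identifier, unique within a mouse.
#' @slot imagePath path of the source image (informational).
#' @slot apCoordinate matched anterior-posterior atlas coordinate, mm.
#' @slot channelNames channels present, e.g. \code{c("eyfp", "cfos")}.
#' @slot zThickness physical thickness of the imaged stack, um.
#' @slot objects named list (by channel) of segmented-object data.frames
#'   in the \code{\link{segObjects}} layout.
#' @slot coloc data.frame of co-labeled records (see
#'   \code{\link{computePairwiseOverlaps}}).
#' @slot registration a \code{\link{TPSTransform-class}} or NULL.
#' @slot excluded data.frame \code{(acronym, hemisphere)} of regions to
#'   omit from this slice ("left", "right" or "both").
#' @name SliceRecord-class
#' @aliases SliceRecord-class MouseRecord-class ExperimentRecord-class
#' @export
setClass("SliceRecord",
  representation(sliceId = "character", imagePath = "character",
                 apCoordinate = "numeric", channelNames = "character",
                 zThickness = "numeric", objects = "list",
                 coloc = "data.frame", registration = "ANY",
                 excluded = "data.frame"))

setValidity("SliceRecord", function(object) {
  msg <- NULL
  if (length(object@zThickness) != 1L || object@zThickness <= 0)
    msg <- c(msg, "zThickness must be a single positive value (um)")
  if (!is.null(object@registration) &&
      !is(object@registration, "TPSTransform"))
    msg <- c(msg, "registration must be NULL or a TPSTransform")
  if (!all(c("acronym", "hemisphere") %in% names(object@excluded)))
    msg <- c(msg, "excluded needs columns acronym, hemisphere")
  if (is.null(msg)) TRUE else msg
})

#' @rdname SliceRecord-class
#' @param sliceId,imagePath,apCoordinate,channelNames,zThickness,objects,coloc,registration,excluded see slots.
#' @export
SliceRecord <- function(sliceId, apCoordinate, channelNames,
                        zThickness = 9, imagePath = "", objects = list(),
                        coloc = emptyColocTable(), registration = NULL,
                        excluded = emptyExclusionTable()) {
  new("SliceRecord", sliceId = as.character(sliceId), imagePath = imagePath,
      apCoordinate = apCoordinate, channelNames = channelNames,
      zThickness = zThickness, objects = objects, coloc = coloc,
      registration = registration, excluded = excluded)
}

emptyExclusionTable <- function() {
  data.frame(acronym = character(), hemisphere = character())
}

emptyColocTable <- function() {
  data.frame(id_ch1 = integer(), id_ch2 = integer(),
             overlap_voxels = integer(), percent_overlap = numeric())
}

setMethod("show", "SliceRecord", function(object) {
  cat(sprintf("SliceRecord '%s' (AP %.2f mm): channels %s; %s; %d exclusions\n",
              object@sliceId, object@apCoordinate,
              paste(object@channelNames, collapse = "/"),
              if (is.null(object@registration)) "unregistered" else "registered",
              nrow(object@excluded)))
})

#' @rdname SliceRecord-class
#' @slot mouseId animal identifier.
#' @slot group experimental group label (e.g. "CT" or "IS").
#' @slot sex animal sex, informational.
#' @slot slices list of \code{SliceRecord}s with unique ids.
#' @export
setClass("MouseRecord",
  representation(mouseId = "character", group = "character",
                 sex = "character", slices = "list"))

setValidity("MouseRecord", function(object) {
  ids <- vapply(object@slices, function(s) s@sliceId, character(1))
  if (anyDuplicated(ids)) "slice ids must be unique within a mouse" else TRUE
})

#' @rdname SliceRecord-class
#' @param mouseId,group,sex,slices see slots.
#' @export
MouseRecord <- function(mouseId, group, slices = list(), sex = NA_character_) {
  new("MouseRecord", mouseId = as.character(mouseId),
      group = as.character(group), sex = sex, slices = slices)
}

setMethod("show", "MouseRecord", function(object) {
  cat(sprintf("MouseRecord '%s' (group %s): %d slices\n",
              object@mouseId, object@group, length(object@slices)))
})

#' @rdname SliceRecord-class
#' @slot mice list of \code{MouseRecord}s.
#' @slot channels channels analyzed across the experiment.
#' @slot ontology region ontology (nested list).
#' @export
setClass("ExperimentRecord",
  representation(mice = "list", channels = "character", ontology = "list"))

#' @rdname SliceRecord-class
#' @param mice,channels,ontology see slots.
#' @export
ExperimentRecord <- function(mice, channels, ontology) {
  new("ExperimentRecord", mice = mice, channels = channels,
      ontology = ontology)
}

setMethod("show", "ExperimentRecord", function(object) {
  grp <- vapply(object@mice, function(m) m@group, character(1))
  cat(sprintf("ExperimentRecord: %d mice (%s), channels %s\n",
              length(object@mice),
              paste(sprintf("%s n=%d", names(table(grp)), table(grp)),
                    collapse = ", "),
              paste(object@channels, collapse = "/")))
})

#' CorrelationMatrix: regional Pearson correlations with p-values
#'
#' Pairwise Pearson correlations between regional densities across the
#' mice of one group, with two-sided asymptotic p-values from the t
#' transform and the per-pair number of complete observations.
#'
#' @slot regions ordered acronym vector.
#' @slot r symmetric correlation matrix, unit diagonal, NA where fewer
#'   than 3 complete pairs or a constant region made r undefined.
#' @slot p symmetric p-value matrix (NA on the diagonal and wherever r is
#'   NA).
#' @slot n symmetric integer matrix of complete observations per pair.
#' @export
setClass("CorrelationMatrix",
  representation(regions = "character", r = "matrix", p = "matrix",
                 n = "matrix"))

setValidity("CorrelationMatrix", function(object) {
  msg <- NULL
  k <- length(object@regions)
  if (!all(dim(object@r) == k) || !all(dim(object@p) == k) ||
      !all(dim(object@n) == k))
    msg <- c(msg, "r, p, n must be square with one row per region")
  else {
    if (max(abs(object@r - t(object@r)), na.rm = TRUE) > 1e-12)
      msg <- c(msg, "r must be symmetric")
    dg <- diag(object@r)
    if (any(!is.na(dg) & abs(dg - 1) > 1e-12))
      msg <- c(msg, "diagonal of r must be 1")
  }
  if (is.null(msg)) TRUE else msg
})

#' @rdname CorrelationMatrix-class
#' @param x a \code{CorrelationMatrix}.
#' @export
setGeneric("corRegions", function(x) standardGeneric("corRegions"))
#' @rdname CorrelationMatrix-class
#' @export
setMethod("corRegions", "CorrelationMatrix", function(x) x@regions)

#' @rdname CorrelationMatrix-class
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))
#' @rdname CorrelationMatrix-class
#' @export
setMethod("corValues", "CorrelationMatrix", function(x) x@r)

#' @rdname CorrelationMatrix-class
#' @export
setGeneric("corPvalues", function(x) standardGeneric("corPvalues"))
#' @rdname CorrelationMatrix-class
#' @export
setMethod("corPvalues", "CorrelationMatrix", function(x) x@p)

#' @rdname CorrelationMatrix-class
#' @export
setGeneric("corN", function(x) standardGeneric("corN"))
#' @rdname CorrelationMatrix-class
#' @export
setMethod("corN", "CorrelationMatrix", function(x) x@n)

setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf("CorrelationMatrix: %d regions, %d finite pairs\n",
              length(object@regions),
              sum(!is.na(object@r[upper.tri(object@r)]))))
})

#' FunctionalNetwork: thresholded regional correlation graph
#'
#' Regions are nodes; an edge joins two regions whose correlation passed
#' both the strength threshold (|r| > rMin by default, optionally signed)
#' and the significance threshold (p < alpha). Edge weights carry the
#' signed r.
#'
#' @slot nodes region acronyms (all regions of the source matrix, so
#'   isolated nodes are preserved).
#' @slot edges data.frame \code{(region_a, region_b, r, p)}.
#' @slot rMin,alpha the thresholds used.
#' @export
setClass("FunctionalNetwork",
  representation(nodes = "character", edges = "data.frame",
                 rMin = "numeric", alpha = "numeric"))

setValidity("FunctionalNetwork", function(object) {
  msg <- NULL
  e <- object@edges
  if (!all(c("region_a", "region_b", "r", "p") %in% names(e)))
    msg <- c(msg, "edges needs columns region_a, region_b, r, p")
  else if (nrow(e)) {
    if (any(e$region_a == e$region_b)) msg <- c(msg, "self-loops are not allowed")
    key <- paste(pmin(e$region_a, e$region_b), pmax(e$region_a, e$region_b))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges are not allowed")
  }
  if (is.null(msg)) TRUE else msg
})

#' @rdname FunctionalNetwork-class
#' @param x a \code{FunctionalNetwork}.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname FunctionalNetwork-class
#' @export
setMethod("networkNodes", "FunctionalNetwork", function(x) x@nodes)

#' @rdname FunctionalNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname FunctionalNetwork-class
#' @export
setMethod("networkEdges", "FunctionalNetwork", function(x) x@edges)

setMethod("show", "FunctionalNetwork", function(object) {
  cat(sprintf("FunctionalNetwork: %d nodes, %d edges (|r| > %g, p < %g)\n",
              length(object@nodes), nrow(object@edges), object@rMin,
              object@alpha))
})

#' PermutationResult: group differences of regional correlations
#'
#' For every region pair, the observed correlation difference
#' d = r(group B) - r(group A) and its two-sided permutation p-value from
#' label shuffles that preserve group sizes, using the add-one estimator
#' p = (#\{|d_null| >= |d_obs|\} + 1) / (n_perm + 1).
#'
#' @slot pairs data.frame \code{(region_a, region_b, r_a, r_b, d, p)}.
#' @slot nPerm number of label shuffles.
#' @slot seed RNG seed used.
#' @slot groups the two group labels, A then B.
#' @export
setClass("PermutationResult",
  representation(pairs = "data.frame", nPerm = "numeric", seed = "numeric",
                 groups = "character"))

setValidity("PermutationResult", function(object) {
  p <- object@pairs$p
  if (length(p) && any(!is.na(p) & (p <= 0 | p > 1)))
    "permutation p-values must lie in (0, 1]" else TRUE
})

#' @rdname PermutationResult-class
#' @param x a \code{PermutationResult}.
#' @export
setGeneric("permPairs", function(x) standardGeneric("permPairs"))
#' @rdname PermutationResult-class
#' @export
setMethod("permPairs", "PermutationResult", function(x) x@pairs)

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult (%s - %s): %d pairs, %d shuffles, %d with p < 0.01\n",
    object@groups[2], object@groups[1], nrow(object@pairs), object@nPerm,
    sum(object@pairs$p < 0.01, na.rm = TRUE)))
})
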