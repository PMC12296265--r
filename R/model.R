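# The slice -> mouse -> experiment data model: segmentation import,
# per-hemisphere exclusions with ontology propagation, atlas mapping and
# aggregation to volume-normalized regional densities, outlier cleaning
# and the shared-region filter.

# ---- ontology helpers -----------------------------------------------------

#' Region ontology utilities
#'
#' The ontology is a nested list \code{{acronym, name, children}} (the JSON
#' tree layout). \code{ontologyAcronyms} flattens it; \code{descendantAcronyms}
#' returns the subtree below (and including) an acronym, which is how
#' exclusions propagate to child regions.
#'
#' @param ontology nested ontology list.
#' @return character vector of acronyms.
#' @export
ontologyAcronyms <- function(ontology) {
  acc <- character(0)
  walk <- function(node) {
    acc <<- c(acc, node$acronym)
    for (ch in node$children) walk(ch)
  }
  walk(ontology)
  acc
}

findOntologyNode <- function(ontology, acronym) {
  if (identical(ontology$acronym, acronym)) return(ontology)
  for (ch in ontology$children) {
    hit <- findOntologyNode(ch, acronym)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

#' @rdname ontologyAcronyms
#' @param acronym the acronym whose subtree is wanted.
#' @param includeSelf include the acronym itself (default TRUE).
#' @export
descendantAcronyms <- function(ontology, acronym, includeSelf = TRUE) {
  node <- findOntologyNode(ontology, acronym)
  if (is.null(node)) stop(sprintf("unknown acronym '%s'", acronym))
  out <- ontologyAcronyms(node)
  if (!includeSelf) out <- setdiff(out, acronym)
  out
}

#' Read / write an ontology tree as JSON
#'
#' @param path JSON file, layout \code{{acronym, name, children: [...]}}.
#' @export
readOntology <- function(path) {
  jsonlite::read_json(path)
}

#' @rdname readOntology
#' @param ontology nested ontology list.
#' @export
writeOntology <- function(ontology, path) {
  jsonlite::write_json(ontology, path, auto_unbox = TRUE)
  invisible(path)
}

# ---- segmentation import --------------------------------------------------

#' Import an external segmented-object table
#'
#' Reads a tab-separated table with one row per object. The native dialect
#' has columns \code{id, x_um, y_um, z_um, voxels, volume_um3, peak}; a
#' \code{columnMap} (native name -> file column name) adapts other export
#' dialects. Rows with zero voxels/volume are dropped with a warning, as
#' tolerated upstream artifacts.
#'
#' @param path TSV file path.
#' @param channel channel label recorded on the objects.
#' @param columnMap named character vector mapping native column names to
#'   the file's column names.
#' @return data.frame in the \code{\link{segObjects}} layout.
#' @export
importObjectTable <- function(path, channel = "channel",
                              columnMap = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.delim(path, check.names = FALSE)
  native <- c(id = "id", x_um = "x_um", y_um = "y_um", z_um = "z_um",
              voxels = "voxels", volume_um3 = "volume_um3", peak = "peak")
  if (!is.null(columnMap)) native[names(columnMap)] <- columnMap
  missing <- native[!(native %in% names(raw))]
  if (length(missing))
    stop(sprintf("object table '%s' is missing mapped column(s): %s",
                 basename(path), paste(missing, collapse = ", ")))
  df <- data.frame(object_id = as.integer(raw[[native["id"]]]),
                   channel = channel,
                   x_um = as.numeric(raw[[native["x_um"]]]),
                   y_um = as.numeric(raw[[native["y_um"]]]),
                   z_um = as.numeric(raw[[native["z_um"]]]),
                   voxels = as.integer(raw[[native["voxels"]]]),
                   volume_um3 = as.numeric(raw[[native["volume_um3"]]]),
                   peak = as.numeric(raw[[native["peak"]]]))
  bad <- df$voxels <= 0 | df$volume_um3 <= 0
  if (any(bad)) {
    warning(sprintf("dropping %d zero-volume object(s) from '%s'",
                    sum(bad), basename(path)))
    df <- df[!bad, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

# ---- exclusions -----------------------------------------------------------

#' Exclude misaligned or damaged regions from a slice
#'
#' Annotated exclusions are logged on the slice and omitted, together with
#' all their ontology descendants, from downstream aggregation for the
#' given hemisphere.
#'
#' @param slice a \code{\link{SliceRecord-class}}.
#' @param acronyms region acronyms to exclude.
#' @param hemisphere "left", "right" or "both".
#' @param ontology the experiment ontology (for validation).
#' @return the updated \code{SliceRecord}.
#' @export
excludeRegions <- function(slice, acronyms, hemisphere = "both",
                           ontology) {
  stopifnot(hemisphere %in% c("left", "right", "both"))
  known <- ontologyAcronyms(ontology)
  bad <- setdiff(acronyms, known)
  if (length(bad)) {
    hints <- vapply(bad, function(a) {
      d <- utils::adist(a, known)
      paste(known[order(d)][1:min(3, length(known))], collapse = ", ")
    }, character(1))
    stop(sprintf("unknown acronym(s): %s",
                 paste(sprintf("'%s' (did you mean: %s?)", bad, hints),
                       collapse = "; ")))
  }
  add <- data.frame(acronym = acronyms, hemisphere = hemisphere)
  slice@excluded <- unique(rbind(slice@excluded, add))
  slice
}

# Expand slice exclusions down the ontology tree into a per-hemisphere
# lookup table.
expandExclusions <- function(excluded, ontology) {
  if (!nrow(excluded)) return(emptyExclusionTable())
  out <- do.call(rbind, lapply(seq_len(nrow(excluded)), function(i) {
    acrs <- descendantAcronyms(ontology, excluded$acronym[i])
    hemi <- excluded$hemisphere[i]
    hemis <- if (hemi == "both") c("left", "right") else hemi
    expand.grid(acronym = acrs, hemisphere = hemis,
                stringsAsFactors = FALSE)
  }))
  unique(out)
}

# ---- atlas mapping and aggregation ---------------------------------------

# Sutherland-Hodgman clip of a polygon to a half-plane (x >= 0 or x <= 0).
clipPolygonHalfplane <- function(vertices, side = c("right", "left")) {
  side <- match.arg(side)
  s <- if (side == "right") 1 else -1
  inside <- function(p) s * p[1] >= 0
  n <- nrow(vertices)
  out <- matrix(numeric(), 0, 2)
  for (i in seq_len(n)) {
    a <- vertices[i, ]; b <- vertices[i %% n + 1, ]
    ain <- inside(a); bin <- inside(b)
    if (ain) out <- rbind(out, a)
    if (ain != bin) {
      t <- a[1] / (a[1] - b[1])    # intersection with x = 0
      out <- rbind(out, a + t * (b - a))
    }
  }
  out
}

hemisphereArea <- function(vertices, side) {
  cl <- clipPolygonHalfplane(vertices, side)
  if (nrow(cl) < 3L) 0 else polygonArea(cl)
}

# Map one slice's objects to atlas space and tally counts and volumes per
# (acronym, channel, hemisphere). Volumes are per-hemisphere shoelace areas
# (mm^2) times the stack thickness (mm).
mapSliceCounts <- function(slice, plate, ontology,
                           colabelChannel = "colabel") {
  if (is.null(slice@registration))
    stop(sprintf("slice '%s' is not registered", slice@sliceId))
  excl <- expandExclusions(slice@excluded, ontology)
  exclKey <- paste(excl$acronym, excl$hemisphere)
  acrs <- plateAcronyms(plate)
  polys <- platePolygons(plate)
  zmm <- slice@zThickness / 1000
  vols <- do.call(rbind, lapply(seq_along(acrs), function(i) {
    data.frame(acronym = acrs[i],
               hemisphere = c("left", "right"),
               volume_mm3 = c(hemisphereArea(polys[[i]], "left"),
                              hemisphereArea(polys[[i]], "right")) / 1e6 * zmm)
  }))
  vols <- vols[!(paste(vols$acronym, vols$hemisphere) %in% exclKey), ]

  tally <- function(objs, channel) {
    if (is.null(objs) || !nrow(objs)) {
      return(data.frame(acronym = character(), channel = character(),
                        hemisphere = character(), count = integer()))
    }
    atl <- applyTps(slice@registration, cbind(objs$x_um, objs$y_um))
    acr <- assignRegion(atl, plate)
    hemi <- ifelse(atl[, 1] < 0, "left", "right")
    keep <- !is.na(acr) & !(paste(acr, hemi) %in% exclKey)
    if (!any(keep)) {
      return(data.frame(acronym = character(), channel = character(),
                        hemisphere = character(), count = integer()))
    }
    ag <- stats::aggregate(list(count = rep(1L, sum(keep))),
                           by = list(acronym = acr[keep],
                                     hemisphere = hemi[keep]), FUN = sum)
    ag$channel <- channel
    ag[, c("acronym", "channel", "hemisphere", "count")]
  }

  counts <- do.call(rbind, c(
    lapply(names(slice@objects), function(ch) tally(slice@objects[[ch]], ch)),
    list(if (nrow(slice@coloc) && length(slice@channelNames) >= 2) {
      ch2 <- slice@objects[[slice@channelNames[2]]]
      tally(ch2[match(slice@coloc$id_ch2, ch2$object_id), , drop = FALSE],
            colabelChannel)
    })))
  list(counts = counts, volumes = vols)
}

#' Aggregate a mouse's counts across slices and normalize by region volume
#'
#' For every region and channel, cell counts mapped to the atlas are summed
#' over all of a mouse's slices and per-hemisphere exclusions; region
#' volumes (per-slice Gauss-formula areas times stack thickness) are
#' summed the same way; density is count / volume in cells per mm^3.
#' Structures not expected to contain labeled cells (fiber tracts,
#' ventricles by default) are removed, with their ontology descendants.
#'
#' @param mouse a \code{\link{SliceRecord-class}} container
#'   (\code{MouseRecord}).
#' @param plates an \code{\link{AtlasPlate-class}}, or a named list of
#'   plates keyed by slice id.
#' @param ontology the experiment ontology.
#' @param alwaysExclude acronyms always removed (with descendants).
#' @param colabelChannel channel name under which co-labeled counts are
#'   reported.
#' @return a region-count data.frame: \code{mouse_id, group, acronym,
#'   channel, count, volume_mm3, density}.
#' @export
aggregateNormalize <- function(mouse, plates, ontology,
                               alwaysExclude = c("fiber tracts", "VS"),
                               colabelChannel = "colabel") {
  known <- ontologyAcronyms(ontology)
  dropAcrs <- unique(unlist(lapply(intersect(alwaysExclude, known),
                                   function(a) descendantAcronyms(ontology, a))))
  allCounts <- list(); allVols <- list()
  for (slice in mouse@slices) {
    plate <- if (is(plates, "AtlasPlate")) plates else plates[[slice@sliceId]]
    if (is.null(plate))
      stop(sprintf("no atlas plate for slice '%s'", slice@sliceId))
    m <- mapSliceCounts(slice, plate, ontology, colabelChannel)
    allCounts[[length(allCounts) + 1L]] <- m$counts
    allVols[[length(allVols) + 1L]] <- m$volumes
  }
  counts <- do.call(rbind, allCounts)
  vols <- do.call(rbind, allVols)
  if (is.null(counts) || !nrow(counts)) return(regionCountTable(NULL))
  counts <- counts[!(counts$acronym %in% dropAcrs), , drop = FALSE]
  vols <- vols[!(vols$acronym %in% dropAcrs), , drop = FALSE]
  cag <- stats::aggregate(count ~ acronym + channel, counts, sum)
  vag <- stats::aggregate(volume_mm3 ~ acronym, vols, sum)
  out <- merge(cag, vag, by = "acronym", all.x = TRUE)
  out$volume_mm3[is.na(out$volume_mm3)] <- 0
  if (any(out$count > 0 & out$volume_mm3 <= 0))
    stop("integrity error: region with counts but zero mapped volume")
  out$density <- out$count / out$volume_mm3
  out$mouse_id <- mouse@mouseId
  out$group <- mouse@group
  out <- out[, c("mouse_id", "group", "acronym", "channel", "count",
                 "volume_mm3", "density")]
  out <- out[order(out$channel, out$acronym), ]
  rownames(out) <- NULL
  out
}

#' Construct / validate a region-count table
#'
#' The long-format table of volume-normalized regional counts: one row per
#' (mouse, region, channel) with \code{count}, \code{volume_mm3} and
#' \code{density = count / volume_mm3} (cells per mm^3).
#'
#' @param df data.frame with the required columns, or NULL for an empty
#'   table.
#' @return the validated data.frame.
#' @export
regionCountTable <- function(df = NULL) {
  cols <- c("mouse_id", "group", "acronym", "channel", "count",
            "volume_mm3", "density")
  if (is.null(df)) {
    df <- data.frame(mouse_id = character(), group = character(),
                     acronym = character(), channel = character(),
                     count = numeric(), volume_mm3 = numeric(),
                     density = numeric())
    return(df)
  }
  if (!all(cols %in% names(df)))
    stop("region count table needs columns: ", paste(cols, collapse = ", "))
  if (any(df$volume_mm3 <= 0))
    stop("every retained row must have positive volume")
  if (max(abs(df$density - df$count / df$volume_mm3)) > 1e-8)
    stop("density must equal count / volume_mm3")
  df[, cols]
}

#' Read / write a region-count table as CSV
#'
#' @param table a region-count data.frame.
#' @param path CSV path.
#' @export
writeRegionCountTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRegionCountTable
#' @export
readRegionCountTable <- function(path) {
  regionCountTable(utils::read.csv(path, stringsAsFactors = FALSE))
}

# ---- cleaning and filtering ----------------------------------------------

#' Remove regional density outliers beyond k group SDs
#'
#' Within every (group, region, channel) cell, rows whose density deviates
#' from the group mean by more than \code{k} sample standard deviations
#' (computed including the candidate row) are dropped. The rule is applied
#' in a single pass, without recomputation after removal; groups with
#' fewer than 3 values or zero SD are left untouched.
#'
#' @param table a region-count data.frame.
#' @param k SD multiplier (default 2).
#' @return the cleaned table; removed rows are attached as
#'   \code{attr(, "removed")}.
#' @export
removeOutliers <- function(table, k = 2) {
  if (!nrow(table)) {
    attr(table, "removed") <- table
    return(table)
  }
  key <- paste(table$group, table$acronym, table$channel, sep = "\r")
  keep <- rep(TRUE, nrow(table))
  for (g in unique(key)) {
    idx <- which(key == g)
    if (length(idx) < 3L) next
    d <- table$density[idx]
    s <- stats::sd(d)
    if (!is.finite(s) || s == 0) next
    keep[idx] <- abs(d - mean(d)) <= k * s
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- table[!keep, , drop = FALSE]
  out
}

#' Keep only regions represented in both experimental groups
#'
#' A (region, channel) is retained when it has a nonmissing density for
#' every mouse of each group (after cleaning); \code{minMice} relaxes the
#' requirement to a minimum number of mice per group.
#'
#' @param tableA,tableB region-count tables, one per group.
#' @param minMice minimum mice per group with data; \code{NULL} (default)
#'   requires all mice of each group.
#' @return list of the two filtered tables (\code{A}, \code{B}).
#' @export
sharedRegionsFilter <- function(tableA, tableB, minMice = NULL) {
  if (!nrow(tableA) || !nrow(tableB))
    stop("both group tables must be nonempty")
  repr <- function(tab, need) {
    ag <- stats::aggregate(list(n = tab$mouse_id),
                           by = list(acronym = tab$acronym,
                                     channel = tab$channel),
                           FUN = function(x) length(unique(x)))
    ag[ag$n >= need, c("acronym", "channel")]
  }
  needA <- if (is.null(minMice)) length(unique(tableA$mouse_id)) else minMice
  needB <- if (is.null(minMice)) length(unique(tableB$mouse_id)) else minMice
  shared <- merge(repr(tableA, needA), repr(tableB, needB),
                  by = c("acronym", "channel"))
  if (!nrow(shared))
    stop("no (region, channel) is represented in both groups")
  keyS <- paste(shared$acronym, shared$channel)
  fA <- tableA[paste(tableA$acronym, tableA$channel) %in% keyS, ]
  fB <- tableB[paste(tableB$acronym, tableB$channel) %in% keyS, ]
  rownames(fA) <- rownames(fB) <- NULL
  list(A = fA, B = fB)
}

#' Regional reactivation proportions
#'
#' The co-labeled population divided by the originally tagged (or the
#' later-active) population, per mouse and region, as a raw count ratio.
#' The result is returned in the region-count layout with unit volume so
#' it can feed the correlation machinery directly.
#'
#' @param table a region-count data.frame holding both channels.
#' @param numerator channel of the co-labeled counts.
#' @param denominator channel of the reference population.
#' @return a region-count data.frame whose \code{density} is the
#'   proportion.
#' @export
reactivationProportions <- function(table, numerator = "colabel",
                                    denominator = "eyfp") {
  num <- table[table$channel == numerator, ]
  den <- table[table$channel == denominator, ]
  m <- merge(num[, c("mouse_id", "group", "acronym", "count")],
             den[, c("mouse_id", "acronym", "count")],
             by = c("mouse_id", "acronym"), suffixes = c("_num", "_den"))
  m <- m[m$count_den > 0, ]
  out <- data.frame(mouse_id = m$mouse_id, group = m$group,
                    acronym = m$acronym,
                    channel = paste0(numerator, "/", denominator),
                    count = m$count_num / m$count_den, volume_mm3 = 1)
  out$density <- out$count
  out[order(out$mouse_id, out$acronym), ]
}
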