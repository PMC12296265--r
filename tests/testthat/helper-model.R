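# Shared builders for model-module tests: a toy ontology, atlas plates in
# micrometre coordinates, an identity registration, and slice/mouse
# constructors with objects at known positions.

testOntology <- function() {
  list(acronym = "root", name = "root", children = list(
    list(acronym = "grey", name = "grey matter", children = list(
      list(acronym = "P", name = "parent region", children = list(
        list(acronym = "c1", name = "child one", children = list()),
        list(acronym = "c2", name = "child two", children = list()))),
      list(acronym = "A", name = "region A", children = list()),
      list(acronym = "B", name = "region B", children = list()))),
    list(acronym = "fiber tracts", name = "fiber tracts", children = list(
      list(acronym = "cc", name = "corpus callosum", children = list()))),
    list(acronym = "VS", name = "ventricular systems", children = list())))
}

rectPoly <- function(x0, x1, y0, y1) {
  matrix(c(x0, y0, x1, y0, x1, y1, x0, y1), ncol = 2, byrow = TRUE)
}

# Plate in atlas um. "A" spans the midline (1 mm^2 per hemisphere);
# "B", "c1", "c2" sit right-hemisphere only; "VS" is a ventricle.
testPlate <- function() {
  new("AtlasPlate", apCoordinate = 0,
      acronyms = c("A", "B", "c1", "c2", "VS"),
      polygons = list(
        A = rectPoly(-1000, 1000, 0, 1000),
        B = rectPoly(0, 1000, -1000, 0),
        c1 = rectPoly(1100, 1600, 0, 500),
        c2 = rectPoly(1100, 1600, 600, 1100),
        VS = rectPoly(-1000, -500, -1000, -500)),
      ontology = testOntology())
}

identityTps <- function() {
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  pts <- cbind(2000 * cos(th), 2000 * sin(th))
  fitTps(pts, pts)
}

# An object table with rows at the given atlas positions (identity
# registration makes image coords == atlas coords).
objectsAt <- function(xy, channel = "cfos") {
  n <- nrow(xy)
  data.frame(object_id = seq_len(n), channel = channel,
             x_um = xy[, 1], y_um = xy[, 2], z_um = 5,
             voxels = 50L, volume_um3 = 50 * 1.08 * 1.08 * 3, peak = 200)
}

testSlice <- function(sliceId, objects, zThickness = 9, coloc = NULL,
                      excluded = NULL) {
  SliceRecord(sliceId = sliceId, apCoordinate = 0,
              channelNames = names(objects), zThickness = zThickness,
              objects = objects,
              coloc = if (is.null(coloc)) dualtrace:::emptyColocTable()
                      else coloc,
              registration = identityTps(),
              excluded = if (is.null(excluded))
                dualtrace:::emptyExclusionTable() else excluded)
}

# A region-count table built directly from a density vector.
densTable <- function(densities, group = "CT", acronym = "A",
                      channel = "cfos",
                      mice = sprintf("%s_m%02d", group, seq_along(densities))) {
  data.frame(mouse_id = mice, group = group, acronym = acronym,
             channel = channel, count = densities, volume_mm3 = 1,
             density = densities)
}
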