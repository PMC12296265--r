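# The synthetic generators: determinism, ground-truth consistency, the
# dual-channel coloc design, the correlated count simulator, and the toy
# atlas construction.

test_that("punctate phantom honours n, separation and determinism", {
  spec <- phantomSpec(nCells = 20, dims = c(96L, 96L, 16L))
  ph1 <- makePunctateStack(spec, seed = 1)
  ph2 <- makePunctateStack(spec, seed = 1)
  expect_identical(intensities(ph1$stack), intensities(ph2$stack))
  cells <- truthCells(ph1$truth)
  expect_equal(nrow(cells), 20)
  # all centres >= 2 * radius apart (um)
  vox <- voxelSize(ph1$stack)
  pm <- cbind(cells$x * vox["x"], cells$y * vox["y"], cells$z * vox["z"])
  d <- as.matrix(dist(pm))
  expect_gte(min(d[upper.tri(d)]), 2 * cells$radius_um[1] - 1e-9)
  # different seed differs
  ph3 <- makePunctateStack(spec, seed = 2)
  expect_false(identical(intensities(ph1$stack), intensities(ph3$stack)))
})

test_that("empty and unplaceable phantoms behave as specified", {
  ph <- makePunctateStack(phantomSpec(nCells = 0, dims = c(32L, 32L, 8L)),
                          seed = 1)
  expect_equal(nrow(truthCells(ph$truth)), 0)
  expect_true(all(intensities(ph$stack) >= 0))
  # far too many cells for the grid: placement error names the maximum
  expect_error(
    makePunctateStack(phantomSpec(nCells = 500, dims = c(32L, 32L, 8L)),
                      seed = 1),
    "achievable maximum")
})

test_that("soma phantom lists soma centres only and dims filaments", {
  spec <- phantomSpec(nCells = 15, dims = c(160L, 160L, 24L))
  ph <- makeSomaProcessStack(spec, seed = 3, processIntensity = 0.35)
  expect_equal(nrow(truthCells(ph$truth)), 15)
  # filament voxels are dimmer than the soma peak by the configured factor:
  # intensities away from any soma stay below processIntensity * peak plus
  # background and noise allowance
  img <- intensities(ph$stack)
  vox <- voxelSize(ph$stack)
  tr <- truthCells(ph$truth)
  co <- which(img > 0.8 * spec$snr * spec$noiseSd + spec$background,
              arr.ind = TRUE)
  if (nrow(co)) {
    d2min <- vapply(seq_len(nrow(co)), function(i) {
      min(((co[i, 1] - tr$y) * vox["y"])^2 + ((co[i, 2] - tr$x) * vox["x"])^2 +
            ((co[i, 3] - tr$z) * vox["z"])^2)
    }, numeric(1))
    expect_lt(max(sqrt(d2min)), spec$radiusUm + 1e-9)
  }
  # zero processes reduces to the sphere phantom's truth layout
  ph0 <- makeSomaProcessStack(spec, seed = 3, processesPerCell = 0)
  expect_equal(nrow(truthCells(ph0$truth)), 15)
})

test_that("dual-channel phantom plants the designed overlap fraction", {
  spec <- phantomSpec(nCells = 10, dims = c(128L, 128L, 20L))
  dc0 <- makeDualChannel(spec, overlapFraction = 0, seed = 1)
  expect_equal(nrow(truthColocPairs(dc0$truth)), 0)
  dc1 <- makeDualChannel(spec, overlapFraction = 1, seed = 1)
  pairs <- truthColocPairs(dc1$truth)
  expect_equal(nrow(pairs), 10)
  # zero jitter: identical spheres, designed overlap exactly 1
  expect_equal(pairs$designed_overlap, rep(1, 10))
  # jitter shrinks the designed overlap below 1 but keeps it in [0, 1]
  dcj <- makeDualChannel(spec, overlapFraction = 1, jitterUm = 2, seed = 1)
  ovj <- truthColocPairs(dcj$truth)$designed_overlap
  expect_true(all(ovj > 0 & ovj < 1))
  # coloc pairs never exceed min(n1, n2)
  dch <- makeDualChannel(spec, overlapFraction = 0.5, nCellsCh2 = 6, seed = 2)
  expect_lte(nrow(truthColocPairs(dch$truth)), 6)
})

test_that("perfectly correlated regions share a common latent draw", {
  spec <- countSimSpec(nPerGroup = 6, regions = c("A", "B"), targetCorr = 1)
  sim <- simulateRegionCounts(spec, seed = 11)
  tab <- sim$tables$CT
  a <- tab$density[tab$acronym == "A"]
  b <- tab$density[tab$acronym == "B"]
  expect_identical(a, b)
  expect_equal(cor(a, b), 1)
})

test_that("sampled correlations track the target across seeds", {
  # r = 0.95 at n = 12: sample r within [0.8, 1] in >= 95% of 200 seeds
  spec <- countSimSpec(nPerGroup = 12, regions = c("A", "B"),
                       targetCorr = 0.95)
  rs <- vapply(1:200, function(s) {
    tab <- simulateRegionCounts(spec, seed = s)$tables$CT
    cor(tab$density[tab$acronym == "A"], tab$density[tab$acronym == "B"])
  }, numeric(1))
  expect_gte(mean(rs >= 0.8 & rs <= 1), 0.95)
})

test_that("planted group differences flip the sample correlation sign", {
  spec <- countSimSpec(nPerGroup = 12, regions = c("A", "B", "C"),
                       plantedDiffs = list("A|B" = c(0.9, -0.9)))
  signsDiffer <- vapply(1:200, function(s) {
    sim <- simulateRegionCounts(spec, seed = s)
    r <- vapply(sim$tables, function(tab) {
      cor(tab$density[tab$acronym == "A"], tab$density[tab$acronym == "B"])
    }, numeric(1))
    r[1] > 0 && r[2] < 0
  }, logical(1))
  expect_gte(mean(signsDiffer), 0.95)
})

test_that("sample correlations converge to the target at large n", {
  spec <- countSimSpec(nPerGroup = 200, regions = c("A", "B", "C"),
                       targetCorr = 0.6)
  cm <- pairwiseCorrelations(simulateRegionCounts(spec, seed = 5)$tables$CT)
  off <- corValues(cm)[upper.tri(corValues(cm))]
  expect_true(all(abs(off - 0.6) < 0.05))
})

test_that("non-PSD targets are repaired or rejected", {
  # an impossible triple: repairable only with large distortion -> error
  R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  spec <- countSimSpec(nPerGroup = 5, regions = c("A", "B", "C"),
                       targetCorr = R)
  expect_error(simulateRegionCounts(spec, seed = 1), "not repairable")
  # a mildly indefinite matrix is repaired and sampling proceeds
  R2 <- matrix(c(1, 0.7, 0.7, 0.7, 1, -0.05, 0.7, -0.05, 1), 3, 3)
  spec2 <- countSimSpec(nPerGroup = 50, regions = c("A", "B", "C"),
                        targetCorr = R2)
  sim <- simulateRegionCounts(spec2, seed = 1)
  expect_true(all(sim$tables$CT$count >= 0))
  ev <- eigen(sim$corr$CT, symmetric = TRUE)$values
  expect_true(all(ev >= 0))
})

test_that("count-simulation specs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "nPerGroup: 5",
    "regions: [A, B, C]",
    "baseMean: 1000",
    "targetCorr: 0.3",
    "plantedDiffs:",
    "  A|B: [0.9, -0.9]",
    "seed: 7"), path)
  spec <- readCountSimSpec(path)
  expect_equal(spec$nPerGroup, 5L)
  expect_equal(spec$plantedDiffs[["A|B"]], c(0.9, -0.9))
  sim <- simulateRegionCounts(spec)
  expect_equal(sim$corr$CT["A", "B"], 0.9)
  # the IS target needs PSD repair; the ground truth is the repaired value
  expect_equal(sim$corr$IS["A", "B"], -0.9, tolerance = 0.1)
})

test_that("toy atlas plates validate their layout", {
  pl <- makeToyAtlasPlate(toyGridLayout())
  expect_equal(length(plateAcronyms(pl)), 4)
  expect_equal(sum(vapply(platePolygons(pl), polygonArea, numeric(1))), 4)
  expect_equal(assignRegion(cbind(0.5, 0.5), pl), "A")
  expect_error(makeToyAtlasPlate(list()), "empty layout")
  bad <- toyGridLayout()
  bad[[2]]$vertices <- bad[[1]]$vertices + 0.5   # overlaps region A
  expect_error(makeToyAtlasPlate(bad), "overlap")
})

test_that("phantom stacks and truth tables round-trip through disk", {
  ph <- makePunctateStack(phantomSpec(nCells = 5, dims = c(48L, 48L, 8L)),
                          seed = 9)
  tf <- withr::local_tempfile(fileext = ".tif")
  sc <- writeVoxelStack(ph$stack, tf)
  back <- readVoxelStack(tf, voxelSize(ph$stack), scale = sc)
  expect_equal(dim(intensities(back)), dim(intensities(ph$stack)))
  # 16-bit quantization: relative error bounded
  expect_lt(max(abs(intensities(back) - intensities(ph$stack))) / sc, 1e-4)
  cf <- withr::local_tempfile(fileext = ".csv")
  writePhantomTruth(ph$truth, cf)
  cells <- read.csv(cf)
  expect_equal(nrow(cells), 5)
})
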