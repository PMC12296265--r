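# The slice/mouse/experiment data model: import, exclusion, aggregation,
# normalization, outlier cleaning and the shared-region filter.

test_that("object import validates columns and drops zero-volume rows", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(id = 1:3, x_um = c(1, 2, 3), y_um = 1, z_um = 1,
                   voxels = c(50L, 60L, 70L), volume_um3 = c(5, 6, 7),
                   peak = 9)
  write.table(df, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  objs <- importObjectTable(tf, channel = "cfos")
  expect_equal(nrow(objs), 3)
  expect_equal(objs$channel, rep("cfos", 3))
  # zero-voxel row dropped with a warning
  df$voxels[2] <- 0L
  write.table(df, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_warning(objs2 <- importObjectTable(tf), "zero-volume")
  expect_equal(nrow(objs2), 2)
  # missing mapped column named in the error
  df2 <- df[, setdiff(names(df), "volume_um3")]
  write.table(df2, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(importObjectTable(tf), "volume_um3")
  # a column map adapts foreign dialects
  df3 <- df; names(df3)[names(df3) == "volume_um3"] <- "Vol (unit)"
  write.table(df3, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_warning(
    objs3 <- importObjectTable(tf, columnMap = c(volume_um3 = "Vol (unit)")),
    "zero-volume")
  expect_equal(nrow(objs3), 2)
  expect_error(importObjectTable("no/such/file.tsv"), "not found")
})

test_that("exclusions validate acronyms and suggest corrections", {
  ont <- testOntology()
  sl <- testSlice("s1", list(cfos = objectsAt(cbind(500, 500))))
  sl2 <- excludeRegions(sl, "A", "left", ont)
  expect_equal(sl2@excluded$acronym, "A")
  expect_error(excludeRegions(sl, "XYZ", "both", ont), "unknown acronym")
  err <- tryCatch(excludeRegions(sl, "gray", "both", ont),
                  error = conditionMessage)
  expect_match(err, "grey")   # nearest-match hint
})

test_that("exclusions propagate to ontology descendants", {
  ont <- testOntology()
  ex <- dualtrace:::expandExclusions(
    data.frame(acronym = "P", hemisphere = "both"), ont)
  expect_setequal(ex$acronym, c("P", "c1", "c2"))
  expect_setequal(ex$hemisphere, c("left", "right"))
})

test_that("aggregation normalizes counts by mapped region volume", {
  ont <- testOntology()
  pl <- testPlate()
  # region B: 1 mm^2 on the right -> 0.009 mm^3 at 9 um thickness;
  # 45 cells inside -> 5000 cells/mm^3
  set.seed(10)
  xyB <- cbind(runif(45, 10, 990), runif(45, -990, -10))
  m <- MouseRecord("m1", "CT", list(
    testSlice("s1", list(cfos = objectsAt(xyB)))))
  tab <- aggregateNormalize(m, pl, ont)
  rB <- tab[tab$acronym == "B", ]
  expect_equal(rB$count, 45)
  expect_equal(rB$volume_mm3, 0.009, tolerance = 1e-12)
  expect_equal(rB$density, 5000, tolerance = 1e-9)
  # two slices, 20 + 25 cells over 0.0045 + 0.0045 mm^3 -> same density
  m2 <- MouseRecord("m2", "CT", list(
    testSlice("s1", list(cfos = objectsAt(xyB[1:20, ]))),
    testSlice("s2", list(cfos = objectsAt(xyB[21:45, ])))))
  tab2 <- aggregateNormalize(m2, pl, ont)
  expect_equal(tab2[tab2$acronym == "B", "density"], 45 / 0.018,
               tolerance = 1e-9)
})

test_that("ventricles and excluded hemispheres leave the aggregate", {
  ont <- testOntology()
  pl <- testPlate()
  # cells in region A on both sides, in the ventricle, and outside plates
  xy <- rbind(cbind(runif(10, -990, -10), runif(10, 10, 990)),  # A left
              cbind(runif(15, 10, 990), runif(15, 10, 990)),    # A right
              cbind(runif(5, -990, -510), runif(5, -990, -510)),# VS
              cbind(5000, 5000))                                # unassigned
  sl <- testSlice("s1", list(cfos = objectsAt(xy)))
  m <- MouseRecord("m1", "CT", list(sl))
  tab <- aggregateNormalize(m, pl, ont)
  expect_false("VS" %in% tab$acronym)
  expect_equal(tab[tab$acronym == "A", "count"], 25)
  expect_equal(tab[tab$acronym == "A", "volume_mm3"], 0.018)
  # exclude region A on the left: its counts and volume shrink
  slx <- excludeRegions(sl, "A", "left", ont)
  mx <- MouseRecord("m1", "CT", list(slx))
  tabx <- aggregateNormalize(mx, pl, ont)
  expect_equal(tabx[tabx$acronym == "A", "count"], 15)
  expect_equal(tabx[tabx$acronym == "A", "volume_mm3"], 0.009)
  # conservation: total = placed minus ventricle, exclusions, unassigned
  expect_equal(sum(tabx$count), 15)
  expect_equal(sum(tab$count), 25)
})

test_that("co-labeled counts map through the channel-2 objects", {
  ont <- testOntology()
  pl <- testPlate()
  ch2 <- objectsAt(cbind(c(100, 200, -300), c(500, 600, 700)),
                   channel = "cfos")
  ch1 <- objectsAt(cbind(c(100, 200), c(500, 600)), channel = "eyfp")
  coloc <- data.frame(id_ch1 = 1:2, id_ch2 = 1:2,
                      overlap_voxels = 30L, percent_overlap = 60)
  sl <- testSlice("s1", list(eyfp = ch1, cfos = ch2), coloc = coloc)
  m <- MouseRecord("m1", "CT", list(sl))
  tab <- aggregateNormalize(m, pl, ont)
  expect_equal(tab[tab$channel == "colabel" & tab$acronym == "A", "count"], 2)
  prop <- reactivationProportions(tab, "colabel", "eyfp")
  expect_equal(prop$density[prop$acronym == "A"], 1)   # 2 colabel / 2 eyfp
})

test_that("the two-SD rule removes exactly the constructed outliers", {
  # nine densities of 10 plus one of 100: z ~ 2.85 -> removed
  t1 <- densTable(c(rep(10, 9), 100))
  out1 <- removeOutliers(t1, k = 2)
  expect_equal(nrow(out1), 9)
  expect_equal(attr(out1, "removed")$density, 100)
  # [1, 2, 3, 4, 100]: max z ~ 1.79 -> nothing removed
  t2 <- densTable(c(1, 2, 3, 4, 100))
  expect_equal(nrow(removeOutliers(t2, k = 2)), 5)
  # all equal: zero SD convention keeps everything
  t3 <- densTable(rep(7, 6))
  expect_equal(nrow(removeOutliers(t3, k = 2)), 6)
  # single-pass semantics: a second pass recomputes and may remove more;
  # applying to the already-cleaned table leaves it unchanged here
  out2 <- removeOutliers(out1, k = 2)
  expect_equal(nrow(out2), 9)
  # groups are cleaned independently
  t4 <- rbind(densTable(c(rep(10, 9), 100), group = "CT"),
              densTable(rep(5, 5), group = "IS"))
  out4 <- removeOutliers(t4, k = 2)
  expect_equal(sum(out4$group == "IS"), 5)
  expect_equal(sum(out4$group == "CT"), 9)
})

test_that("only regions represented in both groups survive the filter", {
  tA <- rbind(densTable(1:4, group = "CT", acronym = "A"),
              densTable(1:4, group = "CT", acronym = "B"),
              densTable(1:4, group = "CT", acronym = "onlyA"))
  tB <- rbind(densTable(5:8, group = "IS", acronym = "A"),
              densTable(5:8, group = "IS", acronym = "B"),
              densTable(5:8, group = "IS", acronym = "onlyB"))
  f <- sharedRegionsFilter(tA, tB)
  expect_setequal(unique(f$A$acronym), c("A", "B"))
  expect_setequal(unique(f$B$acronym), c("A", "B"))
  # a region missing one mouse fails the all-mice rule but passes minMice
  tA2 <- tA[!(tA$acronym == "B" & tA$mouse_id == "CT_m01"), ]
  f2 <- sharedRegionsFilter(tA2, tB)
  expect_equal(unique(f2$A$acronym), "A")
  f3 <- sharedRegionsFilter(tA2, tB, minMice = 2)
  expect_setequal(unique(f3$A$acronym), c("A", "B"))
  # disjoint region sets -> error
  expect_error(sharedRegionsFilter(
    densTable(1:3, acronym = "X"), densTable(1:3, acronym = "Y")),
    "no \\(region, channel\\)")
})

test_that("region count tables round-trip losslessly through CSV", {
  tab <- rbind(densTable(c(10, 20, 30), acronym = "A"),
               densTable(c(1.5, 2.5, 3.5), acronym = "B",
                         channel = "eyfp"))
  tf <- withr::local_tempfile(fileext = ".csv")
  writeRegionCountTable(tab, tf)
  back <- readRegionCountTable(tf)
  expect_equal(back, tab, ignore_attr = TRUE)
  bad <- tab; bad$volume_mm3[1] <- 0
  expect_error(regionCountTable(bad), "positive volume")
})

test_that("ontology utilities traverse the JSON tree", {
  ont <- testOntology()
  expect_true(all(c("root", "grey", "P", "c1", "c2", "VS") %in%
                    ontologyAcronyms(ont)))
  expect_setequal(descendantAcronyms(ont, "P"), c("P", "c1", "c2"))
  expect_setequal(descendantAcronyms(ont, "fiber tracts",
                                     includeSelf = FALSE), "cc")
  expect_error(descendantAcronyms(ont, "nope"), "unknown")
  tf <- withr::local_tempfile(fileext = ".json")
  writeOntology(ont, tf)
  expect_equal(ontologyAcronyms(readOntology(tf)), ontologyAcronyms(ont))
})

test_that("the record hierarchy enforces its invariants", {
  sl <- testSlice("s1", list(cfos = objectsAt(cbind(1, 1))))
  expect_error(MouseRecord("m", "CT", list(sl, sl)), "unique")
  expect_error(SliceRecord("s", 0, "cfos", zThickness = -1), "positive")
  m <- MouseRecord("m1", "CT", list(sl))
  ex <- ExperimentRecord(list(m), channels = "cfos",
                         ontology = testOntology())
  expect_s4_class(ex, "ExperimentRecord")
  expect_output(show(ex), "1 mice")
})
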