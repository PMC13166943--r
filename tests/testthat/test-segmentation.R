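blankStack <- function(nuclear, pixelSizeUm = 0.5) {
  testStack(nuclear_stain = nuclear, pixelSizeUm = pixelSizeUm)
}

test_that("disjoint bright disks are counted and measured exactly", {
  img <- matrix(0, 128, 128)
  centers <- list(c(20, 20), c(20, 60), c(20, 100), c(80, 30), c(80, 90))
  diskArea <- 0L
  for (ct in centers) {
    d <- diskMask(128, 128, ct[1], ct[2], 6)
    img[d] <- 200
    diskArea <- diskArea + sum(d)
  }
  seg <- segmentNuclei(blankStack(img),
                       segmentationParams(nuclearThresholdMethod = "fixed",
                                          nuclearFixedThreshold = 100))
  expect_identical(seg$count, 5L)
  expect_identical(sum(seg$mask), diskArea)
})

test_that("all-zero image yields an empty mask and zero count", {
  seg <- segmentNuclei(blankStack(matrix(0, 64, 64)),
                       segmentationParams(nuclearThresholdMethod = "fixed",
                                          nuclearFixedThreshold = 10))
  expect_identical(seg$count, 0L)
  expect_false(any(seg$mask))
})

test_that("diagonal touching resolves by connectivity, vs flood-fill oracle", {
  img <- matrix(0, 32, 32)
  img[10:12, 10:12] <- 200   # block A
  img[13:15, 13:15] <- 200   # block B, touching A at one diagonal pair
  for (conn in c(8L, 4L)) {
    seg <- segmentNuclei(blankStack(img),
                         segmentationParams(nuclearThresholdMethod = "fixed",
                                            nuclearFixedThreshold = 100,
                                            minNucleusAreaUm2 = 0,
                                            connectivity = conn))
    expect_identical(seg$count, floodFillCount(img > 100, conn))
  }
  expect_identical(
    segmentNuclei(blankStack(img),
                  segmentationParams(nuclearThresholdMethod = "fixed",
                                     nuclearFixedThreshold = 100,
                                     minNucleusAreaUm2 = 0,
                                     connectivity = 8L))$count, 1L)
  expect_identical(
    segmentNuclei(blankStack(img),
                  segmentationParams(nuclearThresholdMethod = "fixed",
                                     nuclearFixedThreshold = 100,
                                     minNucleusAreaUm2 = 0,
                                     connectivity = 4L))$count, 2L)
})

test_that("component labeling matches the flood-fill oracle on random masks", {
  for (seed in 1:5) {
    m <- randomMask(seed, 48, 48, p = 0.4)
    for (conn in c(4L, 8L))
      expect_identical(labelComponents(m, conn)$count,
                       floodFillCount(m, conn))
  }
})

test_that("Otsu on a constant image signals a degenerate image", {
  expect_error(segmentNuclei(blankStack(matrix(7, 32, 32)),
                             segmentationParams()),
               "degenerate image")
})

test_that("membrane segmentation recovers a painted annulus exactly", {
  ann <- diskMask(64, 64, 32, 32, 20) & !diskMask(64, 64, 32, 32, 16)
  img <- matrix(5, 64, 64)
  img[ann] <- 200
  st <- testStack(membrane_marker = img)
  mem <- segmentMembrane(st, segmentationParams(
    membraneThresholdMethod = "fixed", membraneFixedThreshold = 100))
  expect_identical(mem, ann)
  # threshold above the maximum gives an empty mask
  memEmpty <- segmentMembrane(st, segmentationParams(
    membraneThresholdMethod = "fixed", membraneFixedThreshold = 1000))
  expect_false(any(memEmpty))
  # control_derived requires a threshold object
  expect_error(segmentMembrane(st, segmentationParams(
    membraneThresholdMethod = "control_derived")), "PositivityThreshold")
  thr <- deriveThreshold(NULL, "membrane_marker", "fixed", 100)
  expect_identical(segmentMembrane(st, segmentationParams(
    membraneThresholdMethod = "control_derived"), thr), ann)
})

test_that("membrane mask pixel count equals the per-pixel loop oracle", {
  set.seed(11)
  img <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  mem <- segmentMembrane(testStack(membrane_marker = img),
                         segmentationParams(
                           membraneThresholdMethod = "fixed",
                           membraneFixedThreshold = 128))
  count <- 0L
  for (i in 1:64) for (j in 1:64) if (img[i, j] > 128) count <- count + 1L
  expect_identical(sum(mem), count)
})

test_that("tissue mask contains the nuclei and grows with dilation", {
  img <- matrix(0, 64, 64)
  img[diskMask(64, 64, 32, 32, 8)] <- 200
  st <- blankStack(img)
  params0 <- segmentationParams(nuclearThresholdMethod = "fixed",
                                nuclearFixedThreshold = 100,
                                tissueDilationUm = 0)
  nuc <- segmentNuclei(st, params0)$mask
  expect_identical(buildTissueMask(st, params0, nuclearMask = nuc), nuc)
  for (r in c(1, 3, 5)) {
    tis <- buildTissueMask(st, segmentationParams(
      nuclearThresholdMethod = "fixed", nuclearFixedThreshold = 100,
      tissueDilationUm = r), nuclearMask = nuc)
    expect_true(all(tis[nuc]))
    expect_gt(sum(tis), sum(nuc))
  }
})

test_that("tissue mask covers >= 99% of ground-truth cell pixels", {
  for (seed in c(2, 9)) {
    sc <- generateScene(sceneSpec(seed = seed))
    masks <- segmentCompartments(sc$stack)
    cov <- sum(masks@tissue & sc$truth@cellMask) / sum(sc$truth@cellMask)
    expect_gte(cov, 0.99)
  }
})

test_that("raising a fixed threshold never enlarges the nuclear mask", {
  sc <- generateScene(sceneSpec(seed = 4))
  prev <- NULL
  for (thr in c(200, 500, 1500, 2500)) {
    seg <- segmentNuclei(sc$stack, segmentationParams(
      nuclearThresholdMethod = "fixed", nuclearFixedThreshold = thr,
      minNucleusAreaUm2 = 0))
    if (!is.null(prev)) expect_true(all(prev | !seg$mask))  # seg ⊆ prev
    prev <- seg$mask
  }
})

test_that("nucleus count is invariant to translation and 90-degree rotation", {
  sc <- generateScene(sceneSpec(seed = 6, nCells = 6L))
  img <- getChannel(sc$stack, "nuclear_stain")
  params <- segmentationParams(nuclearThresholdMethod = "fixed",
                               nuclearFixedThreshold = 500)
  base <- segmentNuclei(blankStack(img), params)$count
  shifted <- matrix(100, 128, 128)  # background-level padding
  shifted[3:128, 1:126] <- img[1:126, 3:128]
  expect_identical(segmentNuclei(blankStack(shifted), params)$count, base)
  rot90 <- t(img)[ncol(img):1, ]
  expect_identical(segmentNuclei(blankStack(rot90), params)$count, base)
})

test_that("nucleus count is exact on noise-free scenes", {
  for (seed in 1:5) {
    sc <- generateScene(sceneSpec(seed = seed, noiseSd = 0))
    seg <- segmentNuclei(sc$stack, segmentationParams(
      nuclearThresholdMethod = "fixed", nuclearFixedThreshold = 500))
    expect_identical(seg$count, sc$truth@nucleusCount)
  }
})

test_that("watershed splitting separates touching nuclei", {
  m <- diskMask(60, 60, 30, 21, 10) | diskMask(60, 60, 30, 41, 10)
  expect_identical(labelComponents(m, 8L)$count, 1L)
  expect_identical(watershedSplit(m, 8L)$count, 2L)
  img <- matrix(0, 60, 60)
  img[m] <- 200
  seg <- segmentNuclei(blankStack(img), segmentationParams(
    nuclearThresholdMethod = "fixed", nuclearFixedThreshold = 100,
    splitTouchingNuclei = TRUE))
  expect_identical(seg$count, 2L)
})

test_that("hole filling closes interior voids only", {
  ring <- diskMask(40, 40, 20, 20, 10) & !diskMask(40, 40, 20, 20, 5)
  filled <- fillHoles(ring, 8L)
  expect_identical(filled, diskMask(40, 40, 20, 20, 10))
  solid <- diskMask(40, 40, 20, 20, 10)
  expect_identical(fillHoles(solid, 8L), solid)
})
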