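test_that("analytic truth matches the closed-form half-ellipsoid volumes", {
  spec <- smallSpec(endoRadiusED = 2.0, endoRadiusES = 1.0, lvLength = 6.0,
                    matrixSize = 96L)
  tr <- phantomTruth(spec)
  expect_equal(tr@edbvTrue, (2 / 3) * pi * 2^2 * 6, tolerance = 1e-12)
  expect_equal(tr@esbvTrue, (2 / 3) * pi * 1^2 * 6, tolerance = 1e-12)
  expect_equal(tr@edmwTrue, 1.05 * tr@edmvTrue, tolerance = 1e-12)
  expect_equal(tr@efTrue, (tr@edbvTrue - tr@esbvTrue) / tr@edbvTrue * 100,
               tolerance = 1e-12)
})

test_that("a non-contracting phantom has EF 0 and identical phases", {
  spec <- smallSpec(endoRadiusED = 1.2, endoRadiusES = 1.2)
  ph <- generatePhantom(spec)
  expect_equal(ph$truth@efTrue, 0)
  arr <- intensities(ph$stack)
  for (p in 2:nPhases(ph$stack))
    expect_identical(arr[p, , , ], arr[1, , , ])
})

test_that("voxel-count ED blood volume agrees with the analytic volume", {
  # oracle: exhaustive voxel membership count vs the closed form
  ph <- generatePhantom(smallSpec())
  tr <- ph$truth
  vox <- sum(maskArray(ph$blood)[1, , , ]) * 0.125^2 * 0.5
  expect_lt(abs(vox - tr@edbvTrue) / tr@edbvTrue, 0.05)
})

test_that("voxelization error decreases as pixels are refined", {
  # voxelization error = summed per-slice |voxel area - analytic area|
  a <- 1.3; cc <- 3.0; t <- 0.5
  aex <- analyticSliceAreas(a, cc, t)
  errs <- vapply(c(0.25, 0.125, 0.0625), function(px) {
    m <- as.integer(round(8 / px))
    ph <- generatePhantom(smallSpec(pixelSpacing = px, matrixSize = m,
                                    nPhases = 2L))
    avox <- vapply(seq_along(aex), function(s)
      sum(maskArray(ph$blood)[1, s, , ]) * px^2, numeric(1))
    sum(abs(avox - aex))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("stored EF is consistent with stored volumes across random specs", {
  set.seed(11)
  for (i in 1:20) {
    aED <- runif(1, 1.0, 2.2)
    spec <- smallSpec(matrixSize = 128L, endoRadiusED = aED,
                      endoRadiusES = runif(1, 0.5, aED),
                      wallThicknessED = runif(1, 0.3, 1.0),
                      lvLength = runif(1, 3, 7))
    tr <- phantomTruth(spec)
    expect_equal(tr@efTrue,
                 (tr@edbvTrue - tr@esbvTrue) / tr@edbvTrue * 100,
                 tolerance = 1e-9)
  }
})

test_that("phantom generation is reproducible and noise is Rician", {
  spec <- smallSpec(noiseSigma = 50, seed = 7L)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(intensities(a$stack), intensities(b$stack))
  # pure-noise background follows a Rayleigh law with mean sigma*sqrt(pi/2)
  bgSpec <- smallSpec(noiseSigma = 50, seed = 7L, intensityBg = 0,
                      intensityMyo = 1, intensityBlood = 1000)
  bg <- generatePhantom(bgSpec)
  far <- intensities(bg$stack)[1, 1, 1:5, ]  # corner rows, outside the LV
  expect_equal(mean(far), 50 * sqrt(pi / 2), tolerance = 0.1)
})

test_that("out-of-field geometry is rejected with the violated bound named", {
  expect_error(smallSpec(endoRadiusED = 4.5, endoRadiusES = 1),
               "field of view")
})

test_that("zero-SD cohorts reproduce the specified means exactly", {
  gs <- referenceGroupStats()
  gs$sd <- 0
  tab <- simulateCohort(cohortSpec(groupStats = gs, seed = 1L))
  angII <- tab[tab$group == "AngII" & tab$timepoint == "post", ]
  expect_true(all(angII$EDmw == 118.0))
  expect_true(all(angII$EDbv == 69.9))
  sal <- tab[tab$group == "saline" & tab$timepoint == "pre", ]
  expect_true(all(sal$EF == 73.0))
})

test_that("simulated group means converge to their specification", {
  cs <- cohortSpec(groupSizes = c(saline = 10000L), seed = 3L)
  tab <- simulateCohort(cs)
  post <- tab[tab$timepoint == "post", ]
  expect_lt(abs(mean(post$EDbv) - 46.6), 0.5)
  # every low-truncation cell within 3 SE; heavy-truncation cells biased up
  gs <- referenceGroupStats()
  for (p in lvParameterNames()) {
    st <- gs[gs$group == "saline" & gs$timepoint == "post" &
             gs$parameter == p, ]
    if (stats::pnorm(0, st$mean, st$sd) < 1e-3)
      expect_lt(abs(mean(post[[p]]) - st$mean), 3 * st$sd / sqrt(10000),
                label = sprintf("mean of %s", p))
  }
})

test_that("heavily truncated cells show the predicted positive bias", {
  gs <- referenceGroupStats()
  cs <- cohortSpec(groupSizes = c(AngII = 4000L), seed = 4L)
  tab <- simulateCohort(cs)
  post <- tab[tab$timepoint == "post", ]
  st <- gs[gs$group == "AngII" & gs$timepoint == "post" &
           gs$parameter == "ESbv", ]       # 26.3 +/- 18.2, ~7% below zero
  expect_gt(mean(post$ESbv), st$mean)
})

test_that("identical seeds give identical cohort tables", {
  expect_identical(simulateCohort(cohortSpec(seed = 5L)),
                   simulateCohort(cohortSpec(seed = 5L)))
})

test_that("unknown group labels are rejected", {
  expect_error(cohortSpec(groupSizes = c(ketamine = 5L)), "unknown group")
})

test_that("phantomCohort realizes drawn volumes exactly", {
  spec <- solvePhantomGeometry(44.0, 11.9, 77.1, base = smallSpec(
    matrixSize = 96L, lvLength = 6))
  tr <- phantomTruth(spec)
  expect_equal(tr@edbvTrue, 44.0, tolerance = 1e-9)
  expect_equal(tr@esbvTrue, 11.9, tolerance = 1e-9)
  expect_equal(tr@edmvTrue, 77.1, tolerance = 1e-9)
  expect_equal(tr@efTrue, (44.0 - 11.9) / 44.0 * 100, tolerance = 1e-9)

  tab <- simulateCohort(cohortSpec(
    groupSizes = c(saline = 2L, AngII = 2L), seed = 6L))
  out <- phantomCohort(tab, base = smallSpec(matrixSize = 128L,
                                             lvLength = 6),
                       generateStacks = FALSE)
  expect_length(out, 4L)
  for (el in out) {
    expect_equal(el$truth@edmwTrue, 1.05 * el$truth@edmvTrue,
                 tolerance = 1e-12)
    row <- tab[tab$animal_id == el$animal_id & tab$timepoint == "post", ]
    expect_equal(el$truth@edbvTrue, row$EDbv, tolerance = 1e-9)
  }
})

test_that("phantomCohort on an empty table returns an empty list", {
  empty <- tinyCohort()[0, ]
  expect_length(phantomCohort(empty, base = smallSpec(),
                              generateStacks = FALSE), 0L)
})

test_that("impossible volume combinations name the offending animal", {
  bad <- tinyCohort()
  bad$ESbv[bad$timepoint == "post" & bad$animal_id == "a2"] <- 99
  base <- smallSpec(matrixSize = 128L, lvLength = 6)
  expect_error(phantomCohort(bad, base = base, generateStacks = FALSE),
               "a2")
})
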