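mpSys <- membraneParams()

test_that("the paper tube geometries tie length to particle number", {
  gN <- tubeGeometry(4800, "narrow")
  expect_equal(gN$lZOverRrod, 0.00167 * 4800)
  expect_equal(gN$radiusRatio, 1.18)
  gW <- tubeGeometry(4800, "wide")
  expect_equal(gW$lZOverRrod, 0.0015 * 4800)
  expect_equal(gW$lZOverRrod, 7.2)
  expect_equal(tubeGeometry(9600, "narrow")$lZOverRrod, 0.00167 * 9600)
})

test_that("built tubes sit on the requested cylinder", {
  g <- tubeGeometry(1200, "wide")
  sp <- tubeSpec(1200L, lZ = g$lZ)
  tb <- buildTube(sp, seed = 1)
  r2d <- sqrt(tb$state@pos[, 1]^2 + tb$state@pos[, 2]^2)
  expect_lt(abs(mean(r2d) - sp@rCyl) / sp@rCyl, 0.03)
  expect_equal(nrow(tb$state@pos), 1200L)
  expect_identical(topologyType(tb$box), "tube")
  ## area bookkeeping is enforced at construction
  expect_error(new("TubeSpec", N = 1200L, rCyl = 30, lZ = g$lZ, a0 = 1.2778),
               "inconsistent")
})

test_that("the tensionless builder equilibrates to the calibrated area", {
  built <- buildFlatTensionless(flatSpec(400L), mpSys, seed = 2,
                                eqSteps = 12000L,
                                cfg = integratorConfig(seed = 2))
  sm <- built$samples
  aEnd <- mean(sm$area[sm$step > 6000]) / 400
  expect_gt(aEnd, 1.27)
  expect_lt(aEnd, 1.29)
  expect_lt(abs(built$meanTension), 0.25)
})

test_that("imposed strain shows in the sign of the tension", {
  hpS <- memrod:::.hexPatch(256L, 1.2778 * 1.05)
  tS <- measureTension(hpS$state, hpS$box, mpSys, nsteps = 4000L,
                       eqSteps = 2000L, cfg = integratorConfig(seed = 3))
  expect_gt(tS$tension, 0)
  hpC <- memrod:::.hexPatch(256L, 1.2778 * 0.95)
  tC <- measureTension(hpC$state, hpC$box, mpSys, nsteps = 4000L,
                       eqSteps = 2000L, cfg = integratorConfig(seed = 3))
  ## compressed: negative tension or buckled out of plane
  expect_true(tC$tension < 0 || membraneZSpan(tC$state) > 0.6)
})

test_that("tubulation protocols carry the curvature switch", {
  prep <- prepareTubulation(N = 400L, phiRod = 0.2, cRodTarget = 0.25,
                            mp = mpSys, seed = 1, eqSteps = 300L,
                            prodSteps = 300L, preRelaxSteps = 0L)
  expect_equal(prep$nRods, 8)
  expect_equal(prep$phiRod, 80 / 400)
  expect_length(prep$phases, 2)
  expect_equal(prep$phases[[1]]$cRod, 0)
  expect_equal(prep$phases[[2]]$cRod, 0.25)
  expect_true(prep$phases[[2]]$production)

  ## zero density: a plain flat membrane
  prep0 <- prepareTubulation(N = 144L, phiRod = 0, cRodTarget = 0.25,
                             mp = mpSys, seed = 1, eqSteps = 100L,
                             prodSteps = 100L, preRelaxSteps = 0L)
  expect_equal(prep0$nRods, 0)
  expect_true(all(prep0$state@kind == "membrane"))
})
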