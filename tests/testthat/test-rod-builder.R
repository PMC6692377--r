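test_that("a straight rod spans the full rod length end to end", {
  rod <- buildRod(rodSpec(cRod = 0, chirality = "chiral"))
  bb <- which(rod@kind == "rod_backbone")
  bb <- bb[order(rod@segmentIndex[bb])]
  span <- sqrt(sum((rod@pos[bb[10], ] - rod@pos[bb[1], ])^2))
  expect_equal(span, 10, tolerance = 1e-12)
  expect_equal(sum(rod@kind == "rod_hook"), 2L)
  ## hooks at bond length from both anchors
  l0 <- 10 / 9
  h <- which(rod@kind == "rod_hook")[1]
  d1 <- sqrt(sum((rod@pos[h, ] - rod@pos[bb[1], ])^2))
  d2 <- sqrt(sum((rod@pos[h, ] - rod@pos[bb[2], ])^2))
  expect_equal(c(d1, d2), c(l0, l0), tolerance = 1e-10)
})

test_that("handedness detection distinguishes chiral, mirrored and achiral rods", {
  chir <- buildRod(rodSpec(cRod = 0.3, chirality = "chiral"))
  expect_identical(detectHandedness(chir), "right")
  expect_identical(detectHandedness(mirrorParticleState(chir)), "left")
  ach <- buildRod(rodSpec(cRod = 0.3, chirality = "achiral_hooked"))
  expect_identical(detectHandedness(ach), "achiral")
  plain <- buildRod(rodSpec(cRod = 0.3, chirality = "achiral_plain"))
  expect_identical(detectHandedness(plain), "achiral")
  straight <- buildRod(rodSpec(cRod = 0, chirality = "chiral"))
  expect_error(detectHandedness(straight), "degenerate")
})

test_that("the mirror image of an achiral rod is superimposable, chiral is not", {
  ## the superimposing proper rotation reverses the backbone (head <-> tail),
  ## so compare after the end-for-end relabelling
  perm <- c(10:1, 12, 11)
  ach <- buildRod(rodSpec(cRod = 0.3, chirality = "achiral_hooked"))
  mi <- mirrorParticleState(ach)
  expect_lt(kabschRmsd(mi@pos[perm, ], ach@pos), 1e-6)
  chir <- buildRod(rodSpec(cRod = 0.3, chirality = "chiral"))
  mic <- mirrorParticleState(chir)
  expect_gt(min(kabschRmsd(mic@pos, chir@pos),
                kabschRmsd(mic@pos[perm, ], chir@pos)), 0.05)
})

test_that("embedding conserves the rod density bookkeeping", {
  hp <- memrod:::.hexPatch(4800L)
  rs <- rodSpec(cRod = 0.25, chirality = "chiral")
  st <- embedRods(hp$state, hp$box, 40L, rs, seed = 3)
  expect_equal(sum(st@kind != "rod_hook"), 4800L)
  expect_equal(rodAreaFraction(st), 400 / 4800)
  expect_equal(round(rodAreaFraction(st), 4), 0.0833)
  expect_equal(sum(st@kind == "rod_hook"), 80L)
  expect_identical(validateState(st, hp$box), character(0))
})

test_that("embedding is deterministic, respects overlaps, and 0 rods is a no-op", {
  hp <- memrod:::.hexPatch(400L)
  rs <- rodSpec(cRod = 0.25, chirality = "chiral")
  expect_identical(embedRods(hp$state, hp$box, 0L, rs, seed = 1), hp$state)
  a <- embedRods(hp$state, hp$box, 4L, rs, seed = 9)
  b <- embedRods(hp$state, hp$box, 4L, rs, seed = 9)
  expect_identical(a@pos, b@pos)
  c2 <- embedRods(hp$state, hp$box, 4L, rs, seed = 10)
  expect_false(identical(a@pos, c2@pos))
  ## no hard-core violations at insertion
  dm <- memrod:::.pairDistances(a@pos, a@pos, hp$box)
  diag(dm) <- Inf
  expect_gt(min(dm), 0.75)
})

test_that("protein geometry converts to the dimensionless rod curvature", {
  ## APPL1: curvature radius 5.5 nm, length 17 nm
  expect_equal(round(rodCurvatureFromGeometry(5.5, 17)), 3)
  expect_equal(rodCurvatureFromGeometry(5.5, 17), 17 / 5.5)
})
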