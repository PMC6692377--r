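mpTest <- membraneParams()

test_that("bend and tilt energies match closed forms for aligned pairs", {
  box <- simulationBox(c(50, 50, 50), "flat")
  r12 <- 1.4
  w <- wcvOracle(r12, mpTest)
  ## both orientations parallel and perpendicular to the pair axis: zero
  st0 <- particleState(rbind(c(0, 0, 0), c(r12, 0, 0)),
                       rbind(c(0, 0, 1), c(0, 0, 1)))
  bt0 <- bendTiltEnergy(st0, box, mpTest)
  expect_equal(bt0$uBend, 0, tolerance = 1e-12)
  expect_equal(bt0$uTilt, 0, tolerance = 1e-12)

  ## u_i = -u_j = rhat: |u_i - u_j|^2 = 4, both dot products +-1
  st1 <- particleState(rbind(c(0, 0, 0), c(-r12, 0, 0)),
                       rbind(c(1, 0, 0), c(-1, 0, 0)))
  bt1 <- bendTiltEnergy(st1, box, mpTest)
  expect_equal(bt1$uBend, (mpTest@kBend / 2) * 4 * w, tolerance = 1e-10)
  expect_equal(bt1$uTilt, (mpTest@kTilt / 2) * 2 * w, tolerance = 1e-10)
})

test_that("analytic gradients of every term match finite differences", {
  ms <- mixedTestState(seed = 7)
  set.seed(3)
  some <- sort(sample(nrow(ms$state@pos), 10))
  for (fl in c(1L, 2L, 4L, 8L, 16L, 31L)) {
    worst <- fdGradientCheck(ms$state, ms$box, mpTest, ms$rs, fl,
                             particles = some)
    expect_lt(worst["pos"], 1e-6)
    expect_lt(worst["orient"], 1e-6)
  }
})

test_that("pair terms vanish beyond the cutoff and are continuous across it", {
  box <- simulationBox(c(200, 200, 200), "flat")
  mk <- function(r) particleState(rbind(c(0, 0, 0), c(r, 0, 0)),
                                  rbind(c(0, 0.6, 0.8), c(0, 0, 1)))
  far <- totalEnergy(mk(mpTest@rCc + 0.5), box, mpTest)
  expect_equal(far@total, 0, tolerance = 1e-14)
  ## each term is continuous (value and slope vanish) across its own cutoff
  eIn <- totalEnergy(mk(mpTest@rCc - 1e-6), box, mpTest)@total
  eOut <- totalEnergy(mk(mpTest@rCc + 1e-6), box, mpTest)@total
  expect_lt(abs(eIn - eOut), 1e-8)
  aIn <- repulsionAttractionEnergy(mk(mpTest@sRhoCut - 1e-6), box, mpTest)$uAtt
  aOut <- repulsionAttractionEnergy(mk(mpTest@sRhoCut + 1e-6), box, mpTest)$uAtt
  expect_lt(abs(aIn - aOut), 1e-8)
  rIn <- repulsionAttractionEnergy(mk(mpTest@sRepCut - 1e-6), box, mpTest)$uRep
  rOut <- repulsionAttractionEnergy(mk(mpTest@sRepCut + 1e-6), box, mpTest)$uRep
  expect_lt(abs(rIn - rOut), 1e-8)
})

test_that("side attraction reproduces the Lennard-Jones values and pair sum", {
  box <- simulationBox(c(200, 200, 200), "flat")
  rs <- rodSpec(cRod = 0, chirality = "achiral_plain", epsilonSS = 3)
  ## two straight parallel rods; LJ acts between attraction segments only
  rodA <- buildRod(rs)
  mkPair <- function(dy) {
    pB <- rodA@pos; pB[, 2] <- pB[, 2] + dy
    particleState(rbind(rodA@pos, pB), rbind(rodA@orient, rodA@orient),
                  kind = "rod_backbone",
                  rodId = rep(c(0L, 1L), each = 10),
                  segmentIndex = c(rodA@segmentIndex, rodA@segmentIndex))
  }
  ## zero crossing at r = sigma and minimum -eps at r = 2^(1/6) sigma,
  ## checked on a single attraction-segment pair
  single <- function(r) {
    ## two 2-bead rods; only the closest cross pair is within LJ range
    st <- particleState(rbind(c(0, 0, 0), c(80, 80, 0),
                              c(r, 0, 0), c(80, 70, 0)),
                        matrix(rep(c(0, 0, 1), each = 4), 4, 3),
                        kind = "rod_backbone", rodId = c(0L, 0L, 1L, 1L),
                        segmentIndex = c(0L, 1L, 0L, 1L))
    mp0 <- membraneParams(epsRep = 0, epsAtt = 0, kBend = 0, kTilt = 0)
    rs0 <- rodSpec(cRod = 0, chirality = "achiral_plain", epsilonSS = 3,
                   nBackbone = 2L, rodLength = 1.2, kBendRod = 0,
                   kTiltRod = 0, attractionSegments = c(0L, 1L))
    sideAttractionEnergy(st, box, mp0, rs0)$uLj
  }
  expect_equal(single(1), 0, tolerance = 1e-12)
  expect_equal(single(2^(1 / 6)), -3, tolerance = 1e-10)

  ## parallel rods at contact: total matches a direct pair-sum oracle
  st <- mkPair(1.2)
  lj <- sideAttractionEnergy(st, box, mpTest, rs)$uLj
  segs <- rs@attractionSegments
  acc <- 0
  for (i in 1:10) for (j in 1:10) {
    if (!(st@segmentIndex[i] %in% segs) || !(st@segmentIndex[10 + j] %in% segs))
      next
    r <- sqrt(sum((st@pos[i, ] - st@pos[10 + j, ])^2))
    if (r >= 3) next
    sw <- if (r <= 2.5) 1 else {
      t <- (r - 2.5) / 0.5
      1 - t^3 * (10 - 15 * t + 6 * t^2)
    }
    acc <- acc + 4 * 3 * ((1 / r)^12 - (1 / r)^6) * sw
  }
  expect_equal(lj, acc, tolerance = 1e-10)
})

test_that("a straight rod at rest has zero bond and bend energy", {
  box <- simulationBox(c(100, 100, 100), "flat")
  rod <- buildRod(rodSpec(cRod = 0, chirality = "achiral_plain"))
  e <- rodInternalEnergy(rod, box, mpTest,
                         rodSpec(cRod = 0, chirality = "achiral_plain"))
  expect_equal(e$uBond, 0, tolerance = 1e-20)
  expect_equal(e$uBend, 0, tolerance = 1e-12)
})

test_that("the rod energy minimum over arcs sits at the spontaneous curvature", {
  box <- simulationBox(c(200, 200, 200), "flat")
  for (cr in c(0.25, 0.3)) {
    rs <- rodSpec(cRod = cr, chirality = "achiral_plain")
    arcE <- function(C) {
      s2 <- rs; s2@cRod <- C
      rodInternalEnergy(buildRod(s2), box, mpTest, rs)$total
    }
    cmin <- optimize(arcE, c(0.02, 0.8))$minimum
    expect_lt(abs(cmin - cr) / cr, 0.02)
    ## and the energy decreases monotonically from straight toward 1/C
    es <- vapply(seq(0.02, cr, length.out = 8), arcE, numeric(1))
    expect_true(all(diff(es) < 0))
  }
})

test_that("a hook reflected to the left-handed side is penalised", {
  box <- simulationBox(c(100, 100, 100), "flat")
  rs <- rodSpec(cRod = 0.3, chirality = "chiral")
  rod <- buildRod(rs)
  e0 <- rodInternalEnergy(rod, box, mpTest, rs)$uBond
  ## reflect one hook through the backbone (curvature) plane y = 0
  flipped <- rod
  h <- which(rod@kind == "rod_hook")[1]
  flipped@pos[h, 2] <- -flipped@pos[h, 2]
  e1 <- rodInternalEnergy(flipped, box, mpTest, rs)$uBond
  expect_gt(e1, e0 + 1)
})

test_that("the total energy is invariant under rigid motions and parity", {
  ms <- mixedTestState(seed = 21)
  e0 <- totalEnergy(ms$state, ms$box, mpTest, ms$rs)@total

  tr <- ms$state
  tr@pos <- tr@pos + matrix(rep(c(3.1, -2.2, 5.5), each = nrow(tr@pos)), ncol = 3)
  expect_equal(totalEnergy(tr, ms$box, mpTest, ms$rs)@total, e0,
               tolerance = 1e-10)

  th <- 0.7; ax <- c(1, 2, 3) / sqrt(14)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  ro <- ms$state
  ro@pos <- ms$state@pos %*% R
  ro@orient <- ms$state@orient %*% R
  expect_equal(totalEnergy(ro, ms$box, mpTest, ms$rs)@total, e0,
               tolerance = 1e-9)

  ## parity: mirror image with hooks rebuilt left-handed has the same energy
  mi <- mirrorParticleState(ms$state)
  expect_equal(totalEnergy(mi, ms$box, mpTest, ms$rs)@total, e0,
               tolerance = 1e-9)
})

test_that("energy breakdown components sum to the total", {
  ms <- mixedTestState(seed = 4)
  e <- totalEnergy(ms$state, ms$box, mpTest, ms$rs)
  expect_s4_class(e, "EnergyBreakdown")
  expect_equal(e@total,
               e@uRep + e@uAtt + e@uBend + e@uTilt + e@uRodBond + e@uLj)
  ## consistency with the individual operations
  bt <- bendTiltEnergy(ms$state, ms$box, mpTest, ms$rs)
  expect_equal(e@uBend, bt$uBend)
  ra <- repulsionAttractionEnergy(ms$state, ms$box, mpTest, ms$rs)
  expect_equal(e@uAtt, ra$uAtt)
})

test_that("orientation energies reject non-unit orientations", {
  fx <- makeFixture("flat_patch_100", seed = 1)
  bad <- fx$state
  bad@orient[3, ] <- bad@orient[3, ] * 1.5
  expect_error(bendTiltEnergy(bad, fx$box, mpTest), "unit")
})
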