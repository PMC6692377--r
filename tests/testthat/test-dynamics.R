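mpDyn <- membraneParams()

test_that("zero-temperature, zero-force dynamics leaves the state unchanged", {
  st <- particleState(rbind(c(0, 0, 0), c(8, 0, 0)),
                      rbind(c(0, 0, 1), c(0, 0, 1)))
  box <- simulationBox(c(30, 30, 30), "flat")
  mp0 <- membraneParams(kT = 0)
  out <- runDynamics(st, box, mp0, nsteps = 100, cfg = integratorConfig(seed = 1))
  expect_identical(out$state@pos, st@pos)
  expect_identical(out$state@orient, st@orient)
})

test_that("free particles diffuse with the Einstein slope 6D", {
  ## an ensemble of 200 ideal (non-interacting) particles tames the huge
  ## single-trajectory variance of the mean-square displacement
  set.seed(1)
  n <- 600
  st <- particleState(matrix(runif(3 * n, 0, 150), n, 3),
                      matrix(rep(c(0, 0, 1), each = n), n, 3))
  box <- simulationBox(c(400, 400, 400), "flat")
  mp0 <- membraneParams(epsRep = 0, epsAtt = 0, kBend = 0, kTilt = 0)
  slopeAt <- function(gamma, seed) {
    cfg <- integratorConfig(dt = 0.01, gammaT = gamma, seed = seed)
    out <- runDynamics(st, box, mp0, nsteps = 40000, cfg = cfg,
                       sampleEvery = 500)
    sm <- out$samples[-(1:20), ]
    unname(coef(lm(msdXYZ ~ time, sm))[2])
  }
  s1 <- slopeAt(1, 2)
  expect_equal(s1, 6 * 1, tolerance = 0.05)   # D = kT / (m gamma) = 1
  ## doubling the friction halves the diffusion coefficient
  s2 <- slopeAt(2, 3)
  expect_equal(s2 / s1, 0.5, tolerance = 0.1)
})

test_that("a harmonic dimer samples the Boltzmann bond-length distribution", {
  ## two bonded beads with all other interactions switched off
  mp0 <- membraneParams(epsRep = 0, epsAtt = 0, kBend = 0, kTilt = 0)
  rs0 <- rodSpec(cRod = 0, chirality = "achiral_plain", nBackbone = 2L,
                 rodLength = 1.2, bondK = 25, kBendRod = 0, kTiltRod = 0)
  st <- particleState(rbind(c(0, 0, 0), c(1.2, 0, 0)),
                      rbind(c(0, 0, 1), c(0, 0, 1)),
                      kind = "rod_backbone", rodId = 0L,
                      segmentIndex = c(0L, 1L))
  box <- simulationBox(c(300, 300, 300), "flat")
  cfg <- integratorConfig(dt = 0.01, seed = 5)
  out <- runDynamics(st, box, mp0, rs0, nsteps = 100000, cfg = cfg,
                     sampleEvery = 10000, frameEvery = 200)
  traj <- out$trajectory
  rsamp <- vapply(seq_len(nFrames(traj)), function(f) {
    p <- getFrame(traj, f)@pos
    sqrt(sum((p[1, ] - p[2, ])^2))
  }, numeric(1))
  rsamp <- rsamp[-(1:50)]
  ## Boltzmann cdf for p(r) ~ r^2 exp(-k(r-l0)^2/2)
  rr <- seq(0.4, 2.4, length.out = 4000)
  pdf <- rr^2 * exp(-25 * (rr - 1.2)^2 / 2)
  cdf <- cumsum(pdf); cdf <- cdf / cdf[length(cdf)]
  ks <- suppressWarnings(
    ks.test(rsamp, function(q) approx(rr, cdf, xout = q, rule = 2)$y))
  expect_gt(ks$p.value, 0.01)
})

test_that("energy is conserved with the thermostat disabled", {
  fx <- makeFixture("flat_patch_100", seed = 1)
  ## thermalise briefly, then run microcanonically at small dt
  warm <- runDynamics(fx$state, fx$box, mpDyn, nsteps = 500,
                      cfg = integratorConfig(dt = 0.002, seed = 3))
  out <- runDynamics(warm$state, fx$box, mpDyn, nsteps = 10000,
                     cfg = integratorConfig(dt = 5e-4, seed = 3),
                     thermostat = FALSE, sampleEvery = 500)
  sm <- out$samples
  etot <- sm$uPot + sm$kTrans + sm$kRot
  drift <- abs(etot[length(etot)] - etot[1]) / abs(etot[1])
  expect_lt(drift, 1e-4)
})

test_that("kinetic energies satisfy equipartition", {
  hp <- memrod:::.hexPatch(256L)
  out <- runDynamics(hp$state, hp$box, mpDyn, nsteps = 40000,
                     cfg = integratorConfig(dt = 0.002, seed = 2),
                     sampleEvery = 100)
  sm <- out$samples[out$samples$step > 10000, ]
  expect_equal(mean(sm$kTrans) / (1.5 * 256), 1, tolerance = 0.02)
  expect_equal(mean(sm$kRot) / 256, 1, tolerance = 0.02)
  ## orientations stay unit norm throughout
  expect_lt(max(abs(sqrt(rowSums(out$state@orient^2)) - 1)), 1e-9)
})

test_that("checkpoint restart reproduces the uninterrupted run bitwise", {
  fx <- makeFixture("flat_patch_100", seed = 1)
  cfg <- integratorConfig(seed = 17)
  full <- runDynamics(fx$state, fx$box, mpDyn, nsteps = 400, cfg = cfg)
  half1 <- runDynamics(fx$state, fx$box, mpDyn, nsteps = 200, cfg = cfg)
  half2 <- runDynamics(half1$state, half1$box, mpDyn, nsteps = 200, cfg = cfg,
                       rngState = half1$rngState)
  expect_identical(half2$state@pos, full$state@pos)
  expect_identical(half2$state@orient, full$state@orient)
  expect_identical(half2$state@vel, full$state@vel)
})

test_that("protocols apply parameter switches at the scheduled times", {
  fx <- makeFixture("flat_patch_100", seed = 1)
  rs <- rodSpec(cRod = 0, chirality = "achiral_plain")
  ## empty schedule: only the initial frame
  out0 <- runProtocol(fx$state, fx$box, mpDyn, rs, phases = list())
  expect_equal(nFrames(out0$trajectory), 1L)
  ## two-phase schedule: t = 0 at the production switch
  out <- runProtocol(fx$state, fx$box, mpDyn, rs,
                     phases = list(
                       list(steps = 200, cRod = 0),
                       list(steps = 200, cRod = 0.25, production = TRUE)),
                     cfg = integratorConfig(seed = 2), sampleEvery = 100,
                     frameEvery = 100)
  expect_equal(trajMetadata(out$trajectory)$switchTime, 0)
  expect_equal(trajMetadata(out$trajectory)$cRod, 0.25)
  sm <- out$samples
  expect_lt(min(sm$time), 0)
  expect_true(all(sm$time[sm$phase == 2][-1] > 0))
  expect_true(all(diff(frameTimes(out$trajectory)) > 0))
})

test_that("the diffusion measurement yields a positive D and stable tau", {
  dd <- measureDiffusion(mpDyn, N = 144L, seed = 2, eqSteps = 3000L,
                         prodSteps = 12000L,
                         cfg = integratorConfig(seed = 2))
  expect_gt(dd$D, 0)
  expect_equal(dd$tau, 100 / dd$D)
  ## the two half-window slopes agree (linear MSD regime)
  expect_lt(abs(dd$slopeHalves[1] - dd$slopeHalves[2]) /
            max(dd$slopeHalves), 0.75)
})
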