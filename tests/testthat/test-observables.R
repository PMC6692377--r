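# geometric constructions with known Fourier modes / radii

## particles uniformly on a cylinder surface
cylinderCloud <- function(n = 2000, R = 10, Lz = 40, seed = 1) {
  set.seed(seed)
  th <- runif(n, 0, 2 * pi)
  z <- runif(n, 0, Lz)
  particleState(cbind(R * cos(th), R * sin(th), z),
                cbind(cos(th), sin(th), 0))
}

test_that("Fourier modes vanish for a uniform cylinder and detect ellipses", {
  box <- simulationBox(c(60, 60, 40), "tube")
  ## exact axisymmetric z-uniform lattice: both lowest modes are zero
  m <- 40; nz <- 30
  thg <- rep(2 * pi * (0:(m - 1)) / m, nz) + rep((1:nz) %% 2, each = m) * pi / m
  zg <- rep(((1:nz) - 0.5) * 40 / nz, each = m)   # commensurate with Lz
  stg <- particleState(cbind(10 * cos(thg), 10 * sin(thg), zg),
                       cbind(cos(thg), sin(thg), 0))
  fmg <- fourierModes(stg, box)
  expect_lt(Mod(fmg@rQtheta), 1e-10)
  expect_lt(Mod(fmg@rQz), 1e-10)
  ## random cylinder cloud: amplitudes stay at the statistical floor
  st <- cylinderCloud(4000, R = 10, Lz = 40)
  fm <- fourierModes(st, box)
  expect_lt(Mod(fm@rQtheta), 0.5)
  expect_lt(Mod(fm@rQz), 0.5)

  ## elliptical cross-section, uniform in z: |r_qtheta| matches the
  ## analytic arc-length integral, |r_qz| stays at the floor
  a <- 13; b <- 7.7
  tt <- seq(0, 2 * pi, length.out = 20001)[-1]
  dx <- -a * sin(tt); dy <- b * cos(tt)
  ds <- sqrt(dx^2 + dy^2)
  ## particles positioned uniformly in arc length
  s <- cumsum(ds); s <- s / s[length(s)]
  n <- 6000
  ti <- approx(s, tt, xout = (seq_len(n) - 0.5) / n, rule = 2)$y
  z <- rep(seq(0, 40, length.out = 61)[-61], length.out = n)
  stE <- particleState(cbind(a * cos(ti), b * sin(ti), z),
                       cbind(cos(ti), sin(ti), 0))
  fmE <- fourierModes(stE, box)
  ## analytic oracle: integral of r e^{-2 i theta} over arc length
  x <- a * cos(tt); y <- b * sin(tt)
  r2d <- sqrt(x^2 + y^2); thp <- atan2(x, y)
  oracle <- abs(sum(r2d * exp(-2i * thp) * ds) / sum(ds))
  expect_equal(Mod(fmE@rQtheta), oracle, tolerance = 0.02)
  expect_gt(Mod(fmE@rQtheta), 5 * Mod(fmE@rQz))
})

test_that("rod density modes reach the delta-distribution limit", {
  box <- simulationBox(c(60, 60, 40), "tube")
  st <- cylinderCloud(3000, R = 10, Lz = 40, seed = 2)
  ## add rod backbone particles all at theta = 0 (x = 0, y = R line)
  nb <- 40
  rodPos <- cbind(0, rep(10, nb), seq(0.5, 39.5, length.out = nb))
  all <- particleState(rbind(st@pos, rodPos),
                       rbind(st@orient, matrix(rep(c(0, 1, 0), each = nb), nb, 3)),
                       kind = c(st@kind, rep("rod_backbone", nb)),
                       rodId = c(st@rodId, rep(0L, nb)),
                       segmentIndex = c(st@segmentIndex, rep(0L, nb)))
  ## recentring moves the axis slightly; use the recentred radius as reference
  fm <- fourierModes(all, box)
  sel <- all@kind == "rod_backbone"
  x <- all@pos[, 1] - mean(all@pos[, 1]); y <- all@pos[, 2] - mean(all@pos[, 2])
  r2dRod <- sqrt(x^2 + y^2)[sel]
  thRod <- atan2(x, y)[sel]
  expect_equal(Mod(fm@nQtheta), Mod(mean(r2dRod * exp(-2i * thRod))),
               tolerance = 1e-12)
})

test_that("Fourier moduli are invariant under rotations about the tube axis", {
  box <- simulationBox(c(60, 60, 40), "tube")
  a <- 13; b <- 7.7
  tt <- seq(0, 2 * pi, length.out = 501)[-1]
  st <- particleState(cbind(a * cos(tt), b * sin(tt), rep(1:20, 25)),
                      cbind(cos(tt), sin(tt), 0))
  f0 <- fourierModes(st, box)
  th <- 1.234
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  ro <- st; ro@pos <- st@pos %*% R; ro@orient <- st@orient %*% R
  f1 <- fourierModes(ro, box)
  expect_equal(Mod(f1@rQtheta), Mod(f0@rQtheta), tolerance = 1e-12)
  expect_equal(Mod(f1@rQz), Mod(f0@rQz), tolerance = 1e-12)
})

test_that("modes are undefined on flat topology", {
  fx <- makeFixture("flat_patch_100", seed = 1)
  expect_error(fourierModes(fx$state, fx$box), "flat")
})

test_that("the helix radius is exact for ideal geometries", {
  Lz <- 40
  box <- simulationBox(c(40, 40, Lz), "tube")
  ## dense helix: whole turns inside the slice make the slice centre exact
  R <- 6.5
  nPerTurn <- 12; pitch <- 1
  k <- 0:(40 * nPerTurn - 1)
  th <- 2 * pi * k / nPerTurn
  z <- (k / nPerTurn * pitch) %% Lz
  st <- particleState(cbind(R * cos(th), R * sin(th), z),
                      cbind(cos(th), sin(th), 0),
                      kind = "rod_backbone", rodId = 0L, segmentIndex = 0L)
  hf <- helixRadius(st, box)
  expect_equal(hf@rHel, R, tolerance = 1e-10)
  expect_gte(hf@nSl, 3L)

  ## translation along z and rotation about the axis leave it unchanged
  tr <- st; tr@pos[, 3] <- (tr@pos[, 3] + 13.7) %% Lz
  expect_equal(helixRadius(tr, box)@rHel, R, tolerance = 1e-10)
  a <- 0.77
  Rm <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ro <- st; ro@pos <- st@pos %*% Rm
  expect_equal(helixRadius(ro, box)@rHel, R, tolerance = 1e-10)

  ## two concentric rings with equal counts average to (R1+R2)/2
  m <- 60
  thr <- 2 * pi * (0:(m - 1)) / m
  ring <- function(RR) cbind(RR * cos(thr), RR * sin(thr), 20)
  st2 <- particleState(rbind(ring(4), ring(8)),
                       matrix(rep(c(0, 0, 1), each = 2 * m), ncol = 3),
                       kind = "rod_backbone", rodId = 0L, segmentIndex = 0L)
  expect_equal(helixRadius(st2, box)@rHel, 6, tolerance = 1e-10)

  ## too few rod particles in the slice is an error
  st3 <- particleState(rbind(c(4, 0, 1), c(0, 4, 39)),
                       matrix(rep(c(0, 0, 1), each = 2), ncol = 3),
                       kind = "rod_backbone", rodId = 0L, segmentIndex = 0L)
  expect_error(helixRadius(st3, box), "fewer than 3")
})

test_that("mean cluster size matches the brute-force oracle", {
  ## degenerate limits
  sc <- randomRodScatter(5, seed = 1, clump = 200)
  cl <- meanClusterSize(sc$state, sc$box, cutoff = 1.25)
  expect_equal(cl$perRod, 1)
  expect_equal(cl$perCluster, 1)

  scAll <- randomRodScatter(6, seed = 2, clump = 0.01)
  clAll <- meanClusterSize(scAll$state, scAll$box, cutoff = 1.25)
  expect_equal(clAll$perRod, 6)
  expect_equal(clAll$perCluster, 6)

  ## property: random geometric configurations, several seeds and sizes
  for (seed in 1:6) {
    nr <- sample(4:14, 1)
    sc <- randomRodScatter(nr, seed = seed + 10, clump = nr * 1.1)
    sizes <- sort(bruteClusterSizes(sc$state, sc$box, 1.25))
    cl <- meanClusterSize(sc$state, sc$box, cutoff = 1.25)
    expect_equal(sort(cl$sizes), sizes)
    expect_equal(cl$perRod, sum(sizes^2) / sum(sizes))
    expect_equal(cl$perCluster, mean(sizes))
  }
})

test_that("the vertical membrane span matches closed forms", {
  flat <- particleState(cbind(runif(200, 0, 20), runif(200, 0, 20), 3.3),
                        matrix(rep(c(0, 0, 1), each = 200), ncol = 3))
  expect_equal(membraneZSpan(flat), 0)

  h <- 2.5
  pm <- particleState(cbind(runif(200, 0, 20), runif(200, 0, 20),
                            rep(c(h, -h), each = 100)),
                      matrix(rep(c(0, 0, 1), each = 200), ncol = 3))
  expect_equal(membraneZSpan(pm), h)

  ## sinusoidal sheet z = A sin(2 pi x / L): rms = A/sqrt(2)
  L <- 32; A <- 1.7
  x <- rep(seq(0, L, length.out = 401)[-401], 4)
  y <- rep(seq(0, L, length.out = 5)[-5], each = 400)
  sin1 <- particleState(cbind(x, y, A * sin(2 * pi * x / L)),
                        matrix(rep(c(0, 0, 1), each = 1600), ncol = 3))
  expect_equal(membraneZSpan(sin1), A / sqrt(2), tolerance = 1e-3)
})

test_that("the shape classifier labels the constructed phases", {
  ell <- makeFixture("elliptical", seed = 1)
  expect_identical(as.character(classifyTubeShape(ell$state, ell$box)),
                   "elliptical")
  hel <- makeFixture("helical_wrap", seed = 1)
  expect_identical(as.character(classifyTubeShape(hel$state, hel$box)),
                   "helical_cylinder")
  ## an undeformed tube with isolated axial rods is cylindrical
  tb <- makeFixture("tube_1200", seed = 1)
  rs <- rodSpec(cRod = 0, chirality = "achiral_plain")
  R <- tubeGeometry(1200L, "wide")$rCyl
  st <- tb$state
  l0 <- rodBondLength(rs)
  for (th0 in c(0, pi / 2, pi, 3 * pi / 2)) {
    zz <- 4 + seq_len(10) * l0
    bpos <- cbind(R * cos(th0), R * sin(th0), zz)
    bor <- matrix(rep(c(cos(th0), sin(th0), 0), each = 10), 10, 3)
    st2 <- memrod:::.placeRod(st, tb$box, bpos, bor, rs)
    if (!is.null(st2)) st <- st2
  }
  expect_identical(as.character(classifyTubeShape(st, tb$box)), "cylindrical")
})
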