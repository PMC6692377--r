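test_that("the exchange rule reproduces the Metropolis closed form", {
  ## dU = 0: always accepted
  ex <- attemptExchange(1, 2, 5, 4, u = 0.999999)
  expect_equal(ex$dU, 0)
  expect_equal(ex$pAcc, 1)
  expect_true(ex$accepted)

  ## dU = +2 kBT: acceptance rate e^-2 over many trials
  set.seed(42)
  n <- 4000
  acc <- vapply(seq_len(n), function(i)
    attemptExchange(0, 2, 0, 0)$accepted, logical(1))
  p <- mean(acc)
  se <- sqrt(exp(-2) * (1 - exp(-2)) / n)
  expect_lt(abs(p - exp(-2)), 4 * se)

  ## downhill swaps always accepted
  expect_true(attemptExchange(5, 1, 5, 1, u = 0.9999)$accepted)
})

test_that("exchange dynamics on a two-state toy satisfies detailed balance", {
  ## two replicas with parameters C in {1, 2}; configurations x in {0, 1}
  ## with energies U(x, C) = C * x.  Exchange swaps the C labels.
  U <- function(x, C) C * x
  set.seed(7)
  x <- c(0L, 1L); C <- c(1, 2)
  counts <- matrix(0, 2, 2)   # joint occupation of (x at C=1, x at C=2)
  for (it in 1:40000) {
    for (k in 1:2) {          # single-site Metropolis in x
      xn <- 1L - x[k]
      if (log(runif(1)) < -(U(xn, C[k]) - U(x[k], C[k]))) x[k] <- xn
    }
    ex <- attemptExchange(U(x[1], C[1]), U(x[1], C[2]),
                          U(x[2], C[2]), U(x[2], C[1]))
    if (ex$accepted) C <- rev(C)
    i1 <- x[which(C == 1)]; i2 <- x[which(C == 2)]
    counts[i1 + 1, i2 + 1] <- counts[i1 + 1, i2 + 1] + 1
  }
  pEmp <- counts / sum(counts)
  ## exact Boltzmann enumeration: states independent at their C values
  z1 <- 1 + exp(-1); z2 <- 1 + exp(-2)
  pEx <- outer(c(1, exp(-1)) / z1, c(1, exp(-2)) / z2)
  expect_lt(max(abs(pEmp - pEx)), 0.02)
})

test_that("replica exchange on a small rod-bearing tube behaves correctly", {
  mp <- membraneParams()
  g <- tubeGeometry(240L, "wide")
  tb <- buildTube(tubeSpec(240L, lZ = g$lZ), seed = 1)
  rs <- rodSpec(cRod = 0.1, chirality = "achiral_plain")
  st <- embedRods(tb$state, tb$box, 2L, rs, seed = 4)
  cfg <- integratorConfig(dt = 0.003, seed = 9)

  ## a single-replica ladder is identical to a plain run
  lad1 <- replicaLadder(0.2, exchangeEvery = 150L, seeds = 31L)
  one <- runREMD(st, tb$box, mp, rs, lad1, nCycles = 2L, cfg = cfg)
  rs2 <- rs; rs2@cRod <- 0.2
  cfg2 <- cfg; cfg2@seed <- 31L
  plain <- runDynamics(st, tb$box, mp, rs2, nsteps = 150, cfg = cfg2)
  plain <- runDynamics(plain$state, plain$box, mp, rs2, nsteps = 150,
                       cfg = cfg2, rngState = plain$rngState)
  expect_identical(one$states[[1]]@pos, plain$state@pos)

  ## replicas with equal curvature always accept (dU identically 0)
  ladEq <- replicaLadder(c(0.2, 0.2), exchangeEvery = 100L, baseSeed = 5L)
  eq <- runREMD(st, tb$box, mp, rs, ladEq, nCycles = 3L, cfg = cfg)
  expect_true(all(eq$exchangeLog$accepted))
  expect_equal(eq$acceptanceRate[1], 1)

  ## a swap moves labels only: curvature labels remain a permutation of the
  ## ladder and acceptance probabilities are valid
  lad <- replicaLadder(c(0.05, 0.15, 0.3), exchangeEvery = 100L, baseSeed = 2L)
  out <- runREMD(st, tb$box, mp, rs, lad, nCycles = 4L, cfg = cfg)
  expect_setequal(out$cRodOf, lad@cRodValues)
  expect_true(all(out$exchangeLog$pAcc >= 0 & out$exchangeLog$pAcc <= 1))
  expect_true(all(is.finite(out$exchangeLog$dU)))
  ## walker paths visit valid ladder slots
  expect_true(all(out$walkerPath %in% 1:3))
})
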