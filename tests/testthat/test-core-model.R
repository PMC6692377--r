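test_that("minimum image wraps periodic components into [-L/2, L/2)", {
  tube <- simulationBox(c(10, 10, 20), "tube")
  flat <- simulationBox(c(10, 12, 40), "flat")

  expect_equal(minimumImage(c(0, 0, 0), tube), c(0, 0, 0))
  expect_equal(minimumImage(c(0, 0, 0.6 * 20), tube), c(0, 0, -0.4 * 20))
  ## non-periodic directions pass through
  expect_equal(minimumImage(c(7, -8, 3), tube)[1:2], c(7, -8))
  expect_equal(minimumImage(c(7, -8, 3), flat), c(-3, 4, 3))

  ## property: invariant under adding whole periods, against brute-force
  ## minimisation over k in -3..3
  set.seed(11)
  for (rep in 1:40) {
    d <- runif(3, -30, 30)
    w <- minimumImage(d, tube)
    expect_equal(minimumImage(d + c(0, 0, sample(-3:3, 1) * 20), tube), w)
    brute <- d[3] + (-3:3) * 20
    expect_equal(w[3], brute[which.min(abs(brute))])
    expect_true(w[3] >= -10 && w[3] < 10)
    ## idempotence and antisymmetry (distance symmetry)
    expect_equal(minimumImage(w, tube), w)
    expect_equal(sqrt(sum(minimumImage(-d, tube)^2)), sqrt(sum(w^2)))
  }
})

test_that("minimum image works on matrices of displacements", {
  flat <- simulationBox(c(8, 8, 30), "flat")
  m <- rbind(c(5, -5, 2), c(0.1, 0.2, 0.3))
  w <- minimumImage(m, flat)
  expect_equal(w[1, ], c(-3, 3, 2))
  expect_equal(w[2, ], c(0.1, 0.2, 0.3))
})

test_that("validateState reports orientation, rod and overlap violations", {
  fx <- makeFixture("flat_patch_100", seed = 1)
  expect_identical(validateState(fx$state, fx$box), character(0))

  bad <- fx$state
  bad@orient[7, ] <- bad@orient[7, ] * 2
  rep1 <- validateState(bad, fx$box)
  expect_length(rep1, 1)
  expect_match(rep1, "particle 7")

  ## a rod with only 9 backbone particles
  rod <- buildRod(rodSpec(cRod = 0.3, chirality = "achiral_plain"))
  incomplete <- particleState(rod@pos[-10, ], rod@orient[-10, ],
                              kind = rod@kind[-10], rodId = rod@rodId[-10],
                              segmentIndex = rod@segmentIndex[-10])
  rep2 <- validateState(incomplete, simulationBox(c(50, 50, 50), "flat"))
  expect_true(any(grepl("incomplete", rep2)))

  ## hook particle detached from its rod (bypasses constructor validity)
  rod2 <- buildRod(rodSpec(cRod = 0.3, chirality = "chiral"))
  stray <- rod2
  stray@rodId[11] <- -1L
  rep3 <- validateState(stray, simulationBox(c(50, 50, 50), "flat"))
  expect_true(any(grepl("rod_hook without a rod", rep3)) ||
              any(grepl("hook", rep3)))

  ## overlapping pair
  ov <- fx$state
  ov@pos[2, ] <- ov@pos[1, ] + c(0.3, 0, 0)
  expect_true(any(grepl("overlap", validateState(ov, fx$box))))
})

test_that("box and state validity reject malformed objects", {
  expect_error(simulationBox(c(-1, 10, 10), "flat"))
  expect_error(simulationBox(c(10, 10, 10), "sphere"))
  expect_error(particleState(matrix(0, 4, 3), matrix(0, 3, 3)))
  expect_error(particleState(matrix(0, 2, 3),
                             matrix(c(0, 0, 0, 0, 1, 1), 2, 3),
                             kind = "rod_hook", rodId = -1L))
})
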