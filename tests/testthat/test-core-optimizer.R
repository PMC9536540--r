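# The continuous dwarf mongoose optimizer and its primitives.

test_that("population initialization assigns roles, bounds and determinism", {
  ctrl <- dmoControl(nAgents = 10, nBabysitters = 3, seed = NA)
  set.seed(11)
  sw <- initPopulation(ctrl, 8)
  expect_equal(sum(sw$roles == "forager"), 7L)
  expect_equal(sum(sw$roles == "babysitter"), 3L)
  expect_true(all(sw$positions >= 0 & sw$positions <= 1))
  expect_true(all(is.na(sw$fitness)))
  expect_equal(sw$timeCounter, 0L)
  set.seed(11)
  sw2 <- initPopulation(ctrl, 8)
  expect_identical(sw, sw2)

  wide <- dmoControl(lowerBound = -5, upperBound = 3)
  set.seed(2)
  sw3 <- initPopulation(wide, 4)
  expect_true(all(sw3$positions >= -5 & sw3$positions <= 3))
  expect_error(initPopulation(ctrl, 0), "positive")
  expect_error(dmoControl(lowerBound = 1, upperBound = 0), "lowerBound")
  expect_error(dmoControl(nAgents = 3, nBabysitters = 3), "exceed")
})

test_that("alpha probabilities form a simplex with the right orientation", {
  expect_equal(alphaProbabilities(rep(0.2, 4)), rep(0.25, 4))
  expect_equal(alphaProbabilities(rep(0.2, 4), "literal"), rep(0.25, 4))
  expect_equal(alphaProbabilities(c(1, 3), "literal"), c(0.25, 0.75))
  expect_equal(alphaProbabilities(c(0.1, 0.3)), c(0.75, 0.25),
               tolerance = 1e-7)
  expect_error(alphaProbabilities(numeric(0)), "non-empty")
  expect_error(alphaProbabilities(c(0.1, -0.2)), "non-negative")
  # property: simplex + antitone in inverse mode
  set.seed(42)
  for (i in 1:20) {
    f <- runif(sample(2:8, 1))
    p <- alphaProbabilities(f)
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
    expect_true(all(diff(p[order(f)]) <= 1e-12))
  }
})

test_that("foraging candidates follow X + phi*peep and clamp to the box", {
  x <- c(0.4, 0.6)
  expect_equal(forageCandidate(x, peep = 0), x)
  expect_equal(forageCandidate(c(0.1, 0.2), peep = 2, phi = c(1, 1)),
               c(1, 1))
  expect_equal(forageCandidate(0.8, peep = 2, phi = -0.5), 0)
  expect_equal(forageCandidate(c(0.5, 0.5), peep = 0.2, phi = c(0.5, -0.5)),
               c(0.6, 0.4))
  expect_error(forageCandidate(c(1.5, 0), peep = 1), "bounds")
  set.seed(3)
  for (i in 1:20) {
    cand <- forageCandidate(runif(6), peep = 2)
    expect_true(all(cand >= 0 & cand <= 1))
  }
})

test_that("sleeping-mound scores are normalized fitness changes in [-1,1]", {
  expect_equal(sleepingMound(0.3, 0.3), 0)
  expect_equal(sleepingMound(0.2, 0.4), -0.5)
  expect_equal(sleepingMound(0, 0), 0)
  expect_error(sleepingMound(Inf, 0.2), "finite")
  set.seed(7)
  for (i in 1:50) {
    s <- sleepingMound(runif(1, 0, 10), runif(1, 0, 10))
    expect_true(s >= -1 && s <= 1)
  }
  expect_equal(averageSleepingMound(c(0, 0, 0)), 0)
  expect_equal(averageSleepingMound(c(-0.5, 0.5)), 0)
  expect_equal(averageSleepingMound(c(0.2, 0.4, 0.6)), 0.4)
  expect_error(averageSleepingMound(numeric(0)), "non-empty")
})

test_that("movement vector is the sm-weighted mean position", {
  expect_equal(movementVector(rbind(c(1, 2), c(3, 4)), c(0, 0)), c(0, 0))
  expect_equal(movementVector(rbind(c(0.5, 0.5)), 1), c(0.5, 0.5))
  expect_equal(movementVector(rbind(c(1, 0), c(0, 1)), c(0.5, 0.5)),
               c(0.25, 0.25))
  expect_error(movementVector(rbind(c(1, 0), c(0, 1)), 1), "per position")
})

test_that("collective factor runs from 1 to 0 and decreases strictly", {
  for (T in c(1, 10, 100)) {
    expect_equal(collectiveFactor(0, T), 1)
    expect_equal(collectiveFactor(T, T), 0)
  }
  expect_equal(collectiveFactor(50, 100), 0.5)
  grid <- collectiveFactor(seq(0, 100, length.out = 100), 100)
  expect_true(all(diff(grid) < 0))
  expect_error(collectiveFactor(11, 10), "iteration")
})

test_that("scout step explores or exploits around M and clamps", {
  # X = M is a fixed point of both branches
  x <- c(0.3, 0.7)
  expect_equal(scoutStep(x, x, cf = 1, phiNew = 1, phiPrev = 0), x)
  expect_equal(scoutStep(x, x, cf = 1, phiNew = 0, phiPrev = 1), x)
  # cf = 0 leaves the position unchanged
  expect_equal(scoutStep(x, c(0, 0), cf = 0, phiNew = 1, phiPrev = 0), x)
  # exploration branch, stubbed rand
  expect_equal(
    scoutStep(c(1, 0), c(0, 0), cf = 1, phiNew = 1, phiPrev = 0,
              rand = c(0.5, 0.5)),
    c(0.5, 0)
  )
  # exploitation branch moves away from M (then clamps)
  expect_equal(
    scoutStep(c(1, 0), c(0, 0), cf = 1, phiNew = 0, phiPrev = 1,
              rand = c(0.5, 0.5)),
    c(1, 0)  # 1.5 clamps to 1
  )
  # missing previous phi takes the exploitation branch
  expect_equal(
    scoutStep(c(0.8, 0.2), c(0.4, 0.4), cf = 1, phiNew = 1, phiPrev = NA,
              rand = c(1, 1)),
    c(1, 0)  # X + (X - M) = (1.2, 0) clamped
  )
  expect_error(scoutStep(c(1, 0), c(0, 0, 0), 1, 1, 0), "length")
})

test_that("babysitter exchange swaps roles only at the threshold", {
  ctrl <- dmoControl(nAgents = 6, nBabysitters = 2, seed = NA)
  set.seed(5)
  sw <- initPopulation(ctrl, 4)
  sw$fitness <- c(0.9, 0.1, 0.5, 0.7, NA, NA)
  sw$bestFitness <- 0.1
  sw$bestPosition <- sw$positions[2, ]

  # below threshold: untouched
  sw$timeCounter <- 3L
  expect_identical(babysitterExchange(sw, ctrl, exchangeL = 5L), sw)

  # bs = 0: always untouched
  ctrl0 <- dmoControl(nAgents = 6, nBabysitters = 0)
  set.seed(5)
  sw0 <- initPopulation(ctrl0, 4)
  sw0$timeCounter <- 99L
  expect_identical(babysitterExchange(sw0, ctrl0, exchangeL = 1L), sw0)

  # at threshold: the 2 worst foragers (1 and 4) are demoted, the sitters
  # re-enter with fresh positions and discarded fitness, counter resets
  sw$timeCounter <- 5L
  out <- babysitterExchange(sw, ctrl, exchangeL = 5L)
  expect_equal(out$roles[c(1, 4)], c("babysitter", "babysitter"))
  expect_equal(out$roles[5:6], c("forager", "forager"))
  expect_true(all(is.na(out$fitness[5:6])))
  expect_false(identical(out$positions[5:6, ], sw$positions[5:6, ]))
  expect_true(all(out$positions >= 0 & out$positions <= 1))
  expect_equal(out$timeCounter, 0L)
  expect_equal(out$bestFitness, 0.1)
})

test_that("the optimizer is elitist, reproducible and converges on sum(x)", {
  # constant fitness: history is flat at the constant
  rc <- dmOptimize(function(x) 0.42, 3, dmoControl(maxIter = 7, seed = 1))
  expect_equal(rc@history, rep(0.42, 7))
  expect_equal(bestFitness(rc), 0.42)

  r1 <- dmOptimize(function(x) sum(x), 4,
                   dmoControl(maxIter = 1, seed = 2))
  expect_length(r1@history, 1)

  ctrl <- dmoControl(nAgents = 10, nBabysitters = 3, maxIter = 100, seed = 9)
  r <- dmOptimize(function(x) sum(x), 5, ctrl)
  expect_true(all(diff(r@history) <= 0))
  expect_lt(bestFitness(r), 0.1)
  expect_equal(r@history[length(r@history)], bestFitness(r))

  # bit-identical repetition under the same seed
  r2 <- dmOptimize(function(x) sum(x), 5, ctrl)
  expect_identical(r@bestPosition, r2@bestPosition)
  expect_identical(r@history, r2@history)
  expect_identical(r@nEvaluations, r2@nEvaluations)

  expect_error(dmOptimize(function(x) NaN, 3, dmoControl(maxIter = 2)),
               "non-finite")
})

test_that("positions stay inside a non-unit box throughout a run", {
  ctrl <- dmoControl(nAgents = 6, nBabysitters = 2, maxIter = 30,
                     lowerBound = -2, upperBound = 5, seed = 13,
                     exchangeL = 4L)
  seen <- new.env(); seen$bad <- FALSE
  f <- function(x) {
    if (any(x < -2 - 1e-12) || any(x > 5 + 1e-12)) seen$bad <- TRUE
    sum(x^2)
  }
  r <- dmOptimize(f, 3, ctrl)
  expect_false(seen$bad)
  expect_true(all(r@bestPosition >= -2 & r@bestPosition <= 5))
  expect_true(all(diff(r@history) <= 0))
})

test_that("AUTO exchange threshold resolves to round(0.6 * D * bs)", {
  ctrl <- fsControl(nAgents = 6, nBabysitters = 2, maxIter = 2,
                    nFolds = 2, kNeighbors = 1, seed = 1)
  fit <- selectFeatures(toyFixture(), ctrl)
  expect_equal(fit@control@exchangeL, round(0.6 * 6 * 2))
})
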