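## Dwarf mongoose optimization engine: population lifecycle, alpha-group
## foraging, sleeping-mound accounting, scout movement, babysitter exchange,
## and the main minimization loop over an arbitrary fitness callback.

# Run expr with a temporary seed, restoring the ambient RNG state afterwards.
# seed = NA leaves the current stream untouched.
withSeed <- function(seed, expr) {
  if (is.na(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Recycle scalar bounds to length D and clamp a position into the box.
expandBounds <- function(control, nDims) {
  lo <- rep_len(control@lowerBound, nDims)
  hi <- rep_len(control@upperBound, nDims)
  list(lo = lo, hi = hi)
}

clampBox <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Initialize a mongoose population
#'
#' Draws `nAgents` positions i.i.d. uniform within the box. The first
#' `nAgents - nBabysitters` agents are the foraging (alpha) group; the
#' remainder are babysitters. All fitnesses start unevaluated (`NA`).
#'
#' The returned swarm is a plain list with elements `positions` (nAgents x D
#' matrix), `fitness` (numeric, NA = unevaluated), `roles` (character,
#' "forager"/"babysitter"), `timeCounter` (the exchange counter C), `prevPhi`
#' (previous iteration's mean sleeping-mound score, NA before the first
#' iteration), `bestPosition` and `bestFitness` (the elitist best-ever).
#'
#' @param control a [DMOControl-class].
#' @param nDims problem dimension (number of features for feature selection).
#' @return A swarm-state list as described above.
#' @examples
#' set.seed(1)
#' sw <- initPopulation(dmoControl(), 5)
#' table(sw$roles)
#' @export
initPopulation <- function(control, nDims) {
  validObject(control)
  nDims <- as.integer(nDims)
  if (is.na(nDims) || nDims < 1L) stop("'nDims' must be a positive integer")
  b <- expandBounds(control, nDims)
  n <- control@nAgents
  positions <- matrix(runif(n * nDims), nrow = n, ncol = nDims)
  positions <- sweep(sweep(positions, 2L, b$hi - b$lo, "*"), 2L, b$lo, "+")
  nf <- n - control@nBabysitters
  list(
    positions = positions,
    fitness = rep(NA_real_, n),
    roles = rep(c("forager", "babysitter"), c(nf, n - nf)),
    timeCounter = 0L,
    prevPhi = NA_real_,
    bestPosition = NULL,
    bestFitness = Inf
  )
}

#' Alpha selection probabilities
#'
#' Converts the foragers' fitness values (error rates, minimized) into
#' roulette probabilities for choosing the alpha female. The fitness-
#' proportional form alpha_i = fit_i / sum(fit) favours *worse* agents under
#' minimization, so the default `"inverse"` mode weights agents by
#' `1 / (fit + 1e-10)` instead; `"literal"` applies the proportional form
#' verbatim.
#'
#' @param fitnesses non-negative finite error rates, one per forager.
#' @param mode `"inverse"` (default) or `"literal"`.
#' @return A probability vector summing to 1.
#' @examples
#' alphaProbabilities(c(1, 3), mode = "literal") # 0.25 0.75
#' alphaProbabilities(c(0.1, 0.3))               # ~0.75 0.25
#' @export
alphaProbabilities <- function(fitnesses, mode = c("inverse", "literal")) {
  mode <- match.arg(mode)
  if (length(fitnesses) == 0L) stop("'fitnesses' must be non-empty")
  if (!all(is.finite(fitnesses))) stop("'fitnesses' must be finite")
  if (any(fitnesses < 0)) stop("'fitnesses' must be non-negative")
  w <- if (mode == "literal") fitnesses else 1 / (fitnesses + 1e-10)
  s <- sum(w)
  if (s <= 0) return(rep(1 / length(w), length(w)))
  w / s
}

#' Foraging candidate position
#'
#' Proposes a new food position `X + phi * peep`, with `phi` drawn uniformly
#' on \[-1, 1\] independently per dimension, then clamps to the box. The
#' input position is not modified.
#'
#' @param position current position (within bounds).
#' @param peep step-size multiplier (the alpha's vocalization coefficient).
#' @param lower,upper box bounds (scalar or per-dimension).
#' @param phi optional fixed per-dimension noise in \[-1,1\] (for testing);
#'   drawn randomly when `NULL`.
#' @return Candidate position, clamped to the box.
#' @examples
#' forageCandidate(c(0.1, 0.2), peep = 2, phi = c(1, 1)) # clamps to (1, 1)
#' @export
forageCandidate <- function(position, peep, lower = 0, upper = 1, phi = NULL) {
  d <- length(position)
  lo <- rep_len(lower, d); hi <- rep_len(upper, d)
  if (any(position < lo) || any(position > hi)) {
    stop("'position' must lie within the bounds")
  }
  if (is.null(phi)) phi <- runif(d, -1, 1)
  clampBox(position + phi * peep, lo, hi)
}

#' Sleeping-mound score
#'
#' Normalized fitness change `(fitNew - fitOld) / max(|fitNew|, |fitOld|)`,
#' with the convention 0 when both fitnesses are 0. For non-negative error
#' rates the score lies in \[-1, 1\]; negative values indicate improvement
#' under minimization.
#'
#' @param fitNew,fitOld finite fitness values (candidate and incumbent).
#' @return A single numeric score.
#' @examples
#' sleepingMound(0.2, 0.4) # -0.5
#' @export
sleepingMound <- function(fitNew, fitOld) {
  if (!is.finite(fitNew) || !is.finite(fitOld)) {
    stop("fitness values must be finite")
  }
  m <- max(abs(fitNew), abs(fitOld))
  if (m == 0) return(0)
  (fitNew - fitOld) / m
}

#' Average sleeping-mound score
#'
#' Arithmetic mean of the per-forager sleeping-mound scores; its change from
#' the previous iteration steers the scout move between exploration and
#' exploitation.
#'
#' @param smValues non-empty numeric vector of sleeping-mound scores.
#' @return Their mean.
#' @export
averageSleepingMound <- function(smValues) {
  if (length(smValues) == 0L) stop("'smValues' must be non-empty")
  mean(smValues)
}

#' Movement vector
#'
#' The sleeping-mound-weighted mean forager position,
#' `M = (1/n) * sum_i sm_i * X_i`, which pulls (or pushes) the scout move.
#'
#' @param positions forager positions, one row per forager.
#' @param smValues matching sleeping-mound scores.
#' @return Numeric vector of length `ncol(positions)`.
#' @examples
#' movementVector(rbind(c(1, 0), c(0, 1)), c(0.5, 0.5)) # 0.25 0.25
#' @export
movementVector <- function(positions, smValues) {
  positions <- rbind(positions)
  if (nrow(positions) != length(smValues)) {
    stop("one sleeping-mound score per position is required")
  }
  colSums(positions * smValues) / nrow(positions)
}

#' Collective-volatile factor
#'
#' The scout step-size schedule `CF = (1 - t/T)^(2 t/T)`, equal to 1 at
#' iteration 0 (by the zero-exponent convention) and 0 at `t = T`, strictly
#' decreasing in between.
#'
#' @param iteration current iteration t, `0 <= t <= maxIter`.
#' @param maxIter iteration budget T.
#' @return CF in \[0, 1\].
#' @examples
#' collectiveFactor(50, 100) # 0.5
#' @export
collectiveFactor <- function(iteration, maxIter) {
  if (maxIter < 1) stop("'maxIter' must be >= 1")
  if (any(iteration < 0) || any(iteration > maxIter)) {
    stop("'iteration' must lie in [0, maxIter]")
  }
  r <- iteration / maxIter
  (1 - r)^(2 * r)
}

#' Scout move
#'
#' Moves a forager relative to the movement vector M: exploration
#' `X - CF * rand * (X - M)` when the mean sleeping-mound score improved
#' (`phiNew > phiPrev`), exploitation `X + CF * rand * (X - M)` otherwise,
#' with `rand` uniform on \[0,1\] per dimension; the result is clamped to the
#' box. With no previous score (first iteration) the exploitation branch is
#' taken.
#'
#' @param position current position.
#' @param M movement vector (same length).
#' @param cf collective-volatile factor in \[0, 1\].
#' @param phiNew,phiPrev current and previous mean sleeping-mound scores;
#'   `phiPrev = NA` selects the exploitation branch.
#' @param lower,upper box bounds.
#' @param rand optional fixed per-dimension uniforms (for testing).
#' @return The moved position, clamped.
#' @examples
#' scoutStep(c(1, 0), c(0, 0), cf = 1, phiNew = 1, phiPrev = 0,
#'   rand = c(0.5, 0.5)) # exploration: (0.5, 0)
#' @export
scoutStep <- function(position, M, cf, phiNew, phiPrev,
                      lower = 0, upper = 1, rand = NULL) {
  d <- length(position)
  if (length(M) != d) stop("'M' must have the same length as 'position'")
  lo <- rep_len(lower, d); hi <- rep_len(upper, d)
  if (is.null(rand)) rand <- runif(d)
  explore <- !is.na(phiPrev) && phiNew > phiPrev
  step <- cf * rand * (position - M)
  clampBox(if (explore) position - step else position + step, lo, hi)
}

#' Babysitter exchange
#'
#' When the exchange counter has reached the threshold L, the `nBabysitters`
#' worst foragers become babysitters and the former babysitters re-enter the
#' foraging group with freshly randomized positions and discarded (NA)
#' fitness; the counter resets to 0. Otherwise the swarm is returned
#' unchanged. The elitist best-ever solution is never discarded.
#'
#' @param swarm a swarm-state list from [initPopulation()].
#' @param control a [DMOControl-class].
#' @param exchangeL resolved exchange threshold L.
#' @return The (possibly updated) swarm-state list.
#' @export
babysitterExchange <- function(swarm, control, exchangeL) {
  bs <- control@nBabysitters
  if (bs == 0L || swarm$timeCounter < exchangeL) return(swarm)
  nDims <- ncol(swarm$positions)
  b <- expandBounds(control, nDims)
  foragers <- which(swarm$roles == "forager")
  sitters <- which(swarm$roles == "babysitter")
  # worst = highest error among evaluated foragers; unevaluated sort last
  ord <- order(swarm$fitness[foragers], decreasing = TRUE, na.last = FALSE)
  demoted <- foragers[ord[seq_len(bs)]]
  swarm$roles[demoted] <- "babysitter"
  swarm$roles[sitters] <- "forager"
  for (i in sitters) {
    swarm$positions[i, ] <- b$lo + runif(nDims) * (b$hi - b$lo)
    swarm$fitness[i] <- NA_real_
  }
  swarm$timeCounter <- 0L
  swarm
}

#' Run the dwarf mongoose optimizer
#'
#' Minimizes `fitnessFn` over the box. Each iteration: the current foragers
#' are (re-)evaluated; the alpha is drawn by roulette over
#' [alphaProbabilities()]; every forager proposes a [forageCandidate()] that
#' replaces it only if strictly better (greedy acceptance, which makes the
#' best-ever trace provably non-increasing); sleeping-mound scores, their
#' mean phi and the [movementVector()] are computed from the candidate-vs-
#' incumbent fitness changes; every forager takes a [scoutStep()] steered by
#' the change in phi and shrunk by [collectiveFactor()]; the exchange counter
#' increments and [babysitterExchange()] runs. The best-ever fitness is
#' recorded after every iteration.
#'
#' A single seeded stream drives all randomness, consumed in a fixed order
#' (initialization, then per iteration: alpha draw, foraging noise, scout
#' noise, exchange redraws), so identical seeds give bit-identical runs.
#'
#' @param fitnessFn function mapping a position vector to a finite scalar
#'   (minimized).
#' @param nDims problem dimension.
#' @param control a [DMOControl-class]; `control@seed` seeds the run (NA
#'   uses the ambient RNG state).
#' @return A [DMORun-class].
#' @examples
#' res <- dmOptimize(function(x) sum(x), 5,
#'   dmoControl(maxIter = 20, seed = 42))
#' bestFitness(res)
#' @export
dmOptimize <- function(fitnessFn, nDims, control = dmoControl()) {
  validObject(control)
  t0 <- proc.time()[["elapsed"]]
  withSeed(control@seed, {
    nDims <- as.integer(nDims)
    b <- expandBounds(control, nDims)
    L <- resolveExchangeL(control, nDims)
    swarm <- initPopulation(control, nDims)
    nEval <- 0L
    evalAt <- function(x, iter) {
      v <- fitnessFn(x)
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
        stop("fitness function returned a non-finite value at iteration ",
             iter)
      }
      nEval <<- nEval + 1L
      v
    }
    history <- numeric(control@maxIter)
    for (iter in seq_len(control@maxIter)) {
      foragers <- which(swarm$roles == "forager")
      for (i in foragers) {
        swarm$fitness[i] <- evalAt(swarm$positions[i, ], iter)
        if (swarm$fitness[i] < swarm$bestFitness) {
          swarm$bestFitness <- swarm$fitness[i]
          swarm$bestPosition <- swarm$positions[i, ]
        }
      }
      p <- alphaProbabilities(swarm$fitness[foragers], control@alphaMode)
      alpha <- foragers[sample.int(length(foragers), 1L, prob = p)]
      sm <- numeric(length(foragers))
      for (j in seq_along(foragers)) {
        i <- foragers[j]
        cand <- forageCandidate(swarm$positions[i, ], control@peep,
                                b$lo, b$hi)
        fc <- evalAt(cand, iter)
        sm[j] <- sleepingMound(fc, swarm$fitness[i])
        if (fc < swarm$bestFitness) {
          swarm$bestFitness <- fc
          swarm$bestPosition <- cand
        }
        if (fc < swarm$fitness[i]) {
          swarm$positions[i, ] <- cand
          swarm$fitness[i] <- fc
        }
      }
      phi <- averageSleepingMound(sm)
      M <- movementVector(swarm$positions[foragers, , drop = FALSE], sm)
      cf <- collectiveFactor(iter, control@maxIter)
      for (i in foragers) {
        swarm$positions[i, ] <- scoutStep(swarm$positions[i, ], M, cf,
                                          phi, swarm$prevPhi, b$lo, b$hi)
      }
      swarm$prevPhi <- phi
      swarm$timeCounter <- swarm$timeCounter + 1L
      swarm <- babysitterExchange(swarm, control, L)
      history[iter] <- swarm$bestFitness
    }
    new("DMORun",
      bestPosition = as.numeric(swarm$bestPosition),
      bestFitness = swarm$bestFitness,
      history = history,
      nEvaluations = nEval,
      elapsed = proc.time()[["elapsed"]] - t0
    )
  })
}

# L = round(0.6 * D * bs), at least 1, when set to AUTO (NA).
resolveExchangeL <- function(control, nDims) {
  if (!is.na(control@exchangeL)) return(control@exchangeL)
  max(1L, as.integer(round(0.6 * nDims * control@nBabysitters)))
}
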