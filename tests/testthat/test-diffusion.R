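test_that("cosine schedule follows the squared-cosine retention profile", {
  T <- 64L; s <- 0.008
  sch <- cosineSchedule(T, delta = 0.85, s = s)
  f <- function(t) cos(((t / T + s) / (1 + s)) * pi / 2)^2
  expected <- 1 - f(0:T) / f(0)
  expected[T + 1L] <- max(expected[T + 1L], 1 - 1e-5)
  expect_equal(sch@gammaBar, expected, tolerance = 1e-10)
  ## alpha back-solve: the product reconstructs 1 - gammaBar exactly
  expect_equal(1 - cumprod(1 - sch@alpha), sch@gammaBar[-1L],
               tolerance = 1e-10)
  expect_true(all(sch@alpha >= 0 & sch@alpha <= 1))
  expect_true(all(diff(sch@gammaBar) >= -1e-12))
  ## t = 0: no corruption
  expect_equal(cumulativeTransition(sch, 0), diag(2))
  ## t = T: stationary rows (delta, 1 - delta)
  MT <- cumulativeTransition(sch, T)
  expect_equal(MT, matrix(c(0.85, 0.85, 0.15, 0.15), 2, 2),
               tolerance = 1e-4)
  expect_error(cosineSchedule(0, 0.5), "positive integer")
  expect_error(cosineSchedule(10, 1.2), "delta")
})

test_that("single-step transition matrix matches the convex mixture", {
  sch <- cosineSchedule(20, 0.9)
  ## hand-checkable values by direct construction
  sch@alpha[5] <- 0.5
  expect_equal(transitionMatrix(sch, 5),
               matrix(c(0.95, 0.45, 0.05, 0.55), 2, 2), tolerance = 1e-12)
  sch@alpha[5] <- 0
  expect_equal(transitionMatrix(sch, 5), diag(2))
  sch@alpha[5] <- 1
  expect_equal(transitionMatrix(sch, 5), priorMatrix(sch))
  expect_error(transitionMatrix(sch, 21), "in \\[1, 20\\]")
  ## row-stochastic everywhere
  for (t in 1:20) {
    M <- transitionMatrix(sch, t)
    expect_equal(rowSums(M), c(1, 1), tolerance = 1e-12)
    expect_true(all(M >= 0))
  }
})

test_that("closed-form cumulative transition equals the iterated product", {
  sch <- cosineSchedule(50, 0.92)
  M <- diag(2)
  for (t in 1:50) {
    M <- M %*% transitionMatrix(sch, t)
    expect_equal(cumulativeTransition(sch, t), M, tolerance = 1e-10)
  }
})

test_that("bridge matrices compose with cumulative transitions", {
  for (s in 1:5) {
    sch <- random_schedule(s)
    T <- nSteps(sch)
    pairs <- expand.grid(a = 0:(T - 1), b = 1:T)
    pairs <- pairs[pairs$a < pairs$b, ]
    idx <- sample(nrow(pairs), min(40, nrow(pairs)))
    for (r in idx) {
      a <- pairs$a[r]; b <- pairs$b[r]
      lhs <- cumulativeTransition(sch, a) %*% bridgeMatrix(sch, a, b)
      expect_equal(lhs, cumulativeTransition(sch, b), tolerance = 1e-10)
      B <- bridgeMatrix(sch, a, b)
      expect_equal(rowSums(B), c(1, 1), tolerance = 1e-12)
      expect_true(all(B >= -1e-15))
    }
  }
})

test_that("forward sampling honors the identity, stationary and marginal laws", {
  sch <- cosineSchedule(40, 0.9)
  net <- tiny_net(seed = 2, n = 8)
  e0 <- edgeState(net$grn)
  ## t = 0 is the identity
  expect_identical(forwardSample(e0, 0, sch, seed = 1)$states, e0$states)
  ## determinism under seed
  expect_identical(forwardSample(e0, 17, sch, seed = 5)$states,
                   forwardSample(e0, 17, sch, seed = 5)$states)
  ## masked pairs never activate
  et <- forwardSample(e0, 40, sch, seed = 5)
  expect_true(all(et$states[!e0$mask] == 0))

  ## Monte-Carlo: single pair with e0 = 1 stays 1 with prob Mbar[2,2]
  mask1 <- matrix(TRUE, 1, 1)
  one <- list(states = matrix(1, 1, 1), mask = mask1)
  t <- 25L
  Mb <- cumulativeTransition(sch, t)
  hits <- vapply(1:2000, function(i)
    forwardSample(one, t, sch, seed = i)$states[1, 1], numeric(1))
  se <- sqrt(Mb[2, 2] * (1 - Mb[2, 2]) / 2000)
  expect_lt(abs(mean(hits) - Mb[2, 2]), 3.5 * se)

  ## at t = T the marginal is the stationary row regardless of e0
  big <- 316L  # ~1e5 pairs
  maskB <- matrix(TRUE, big, big)
  for (start in c(0, 1)) {
    eb <- list(states = matrix(start, big, big), mask = maskB)
    eT <- forwardSample(eb, 40, sch, seed = 7 + start)
    freq <- mean(eT$states)
    se <- sqrt(0.1 * 0.9 / big^2)
    expect_lt(abs(freq - 0.1), 3 * se + 1e-3)
  }
})

test_that("forward marginal at T forgets the starting network (TV < 0.01)", {
  sch <- cosineSchedule(30, 0.8)
  big <- 316L
  maskB <- matrix(TRUE, big, big)
  f0 <- mean(forwardSample(list(states = matrix(0, big, big), mask = maskB),
                           30, sch, seed = 1)$states)
  f1 <- mean(forwardSample(list(states = matrix(1, big, big), mask = maskB),
                           30, sch, seed = 2)$states)
  expect_lt(abs(f0 - f1), 0.01)  # total variation of a Bernoulli pair
})

test_that("subsequence ladders are evenly spaced and anchored", {
  expect_identical(makeSubsequence(1000, 10), as.integer(seq(0, 1000, 100)))
  expect_identical(makeSubsequence(7, 7), 0:7)
  tau <- makeSubsequence(1000, 500)
  expect_length(tau, 501L)
  expect_true(all(diff(tau) == 2L))
  expect_error(makeSubsequence(10, 0), "k must be")
  expect_error(makeSubsequence(10, 11), "k must be")
})

test_that("posterior equals exhaustive-enumeration Bayes on the 2-state chain", {
  ## independent oracle: enumerate the joint p(e0, e_prev, e_t) directly
  oracle <- function(sch, tPrev, t, p0edge, j) {
    Mp <- cumulativeTransition(sch, tPrev)
    B <- bridgeMatrix(sch, tPrev, t)
    prior <- c(1 - p0edge, p0edge)
    post <- c(0, 0)
    for (i in 0:1) {
      joint <- numeric(2)
      for (k in 0:1)
        joint[k + 1] <- Mp[i + 1, k + 1] * B[k + 1, j + 1]
      if (sum(joint) > 0) post <- post + prior[i + 1] * joint / sum(joint)
    }
    post / sum(post)
  }
  set.seed(10)
  for (trial in 1:1000) {
    sch <- random_schedule(trial)
    T <- nSteps(sch)
    t <- sample(T, 1)
    tPrev <- sample(0:(t - 1), 1)
    p0 <- stats::runif(1)
    j <- sample(0:1, 1)
    et <- list(states = matrix(j, 1, 1), mask = matrix(TRUE, 1, 1))
    got <- edgePosterior(et, matrix(p0, 1, 1), t, tPrev, sch)
    want <- oracle(sch, tPrev, t, p0, j)
    expect_equal(as.numeric(got[1, 1, ]), want, tolerance = 1e-8)
    expect_equal(sum(got[1, 1, ]), 1, tolerance = 1e-10)
  }
})

test_that("posterior at tPrev = 0 with a one-hot clean prediction is one-hot", {
  sch <- cosineSchedule(30, 0.85)
  for (j in 0:1) for (i in 0:1) {
    et <- list(states = matrix(j, 1, 1), mask = matrix(TRUE, 1, 1))
    got <- edgePosterior(et, matrix(i, 1, 1), 12, 0, sch)
    expect_equal(as.numeric(got[1, 1, ]), as.numeric(0:1 == i),
                 tolerance = 1e-9)
  }
})

test_that("reverse steps are deterministic under seed and exact at delta posteriors", {
  sch <- cosineSchedule(30, 0.85)
  net <- tiny_net(seed = 4, n = 8)
  e0 <- edgeState(net$grn)
  et <- forwardSample(e0, 30, sch, seed = 2)
  ## one-hot clean prediction, tPrev = 0: lands exactly on the clean network
  out <- reverseStep(et, e0$states, 30, 0, sch, seed = 3)
  expect_identical(out$states, e0$states)
  ## determinism
  p0 <- matrix(0.4, 8, 8)
  a <- reverseStep(et, p0, 30, 14, sch, seed = 11)
  b <- reverseStep(et, p0, 30, 14, sch, seed = 11)
  expect_identical(a$states, b$states)
  expect_true(all(a$states[!et$mask] == 0))
  ## deterministic flag takes the argmax
  d1 <- reverseStep(et, e0$states, 30, 0, sch, deterministic = TRUE)
  expect_identical(d1$states, e0$states)
})

test_that("reverse single-step marginals match ancestral one-step sampling", {
  ## with the full ladder, the bridge from t-1 to t is the single-step
  ## kernel; check the sampled marginal on one pair by Monte Carlo
  sch <- cosineSchedule(12, 0.8)
  t <- 6L
  p0 <- 0.7
  et <- list(states = matrix(1, 1, 1), mask = matrix(TRUE, 1, 1))
  want <- edgePosterior(et, matrix(p0, 1, 1), t, t - 1L, sch)[1, 1, 2]
  hits <- vapply(1:4000, function(i)
    reverseStep(et, matrix(p0, 1, 1), t, t - 1L, sch, seed = i)$states[1, 1],
    numeric(1))
  se <- sqrt(want * (1 - want) / 4000)
  expect_lt(abs(mean(hits) - want), 3.5 * se)
})

test_that("delta estimation reflects training density and is clamped", {
  net <- tiny_net(seed = 6, n = 10)
  d <- estimateDelta(list(net$grn))
  dens <- nEdges(net$grn) / sum(candidateMask(net$grn))
  expect_equal(d, min(max(1 - dens, 0.5), 0.999))
  ## clamping at the dense end
  dense <- GRN(c("a", "b"), c(TRUE, TRUE), matrix(c(0, 0, 1, 0), 2, 2))
  expect_gte(estimateDelta(list(dense)), 0.5)
})

test_that("schedules round-trip through YAML", {
  sch <- cosineSchedule(25, 0.88)
  path <- tempfile(fileext = ".yaml")
  writeSchedule(sch, path)
  sch2 <- readSchedule(path)
  expect_equal(sch@alpha, sch2@alpha)
  expect_equal(sch@gammaBar, sch2@gammaBar)
  expect_equal(priorDelta(sch2), 0.88)
})
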