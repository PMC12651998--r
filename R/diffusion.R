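## Discrete two-state edge diffusion: cosine schedule, closed-form
## transition/cumulative/bridge matrices, categorical forward sampling,
## exact skip-step posteriors and reverse sampling.

#' Cosine noise schedule
#'
#' Builds a schedule whose cumulative retention
#' \eqn{1-\bar\gamma_t} follows the normalized squared-cosine profile
#' \eqn{\cos^2\!\big(\tfrac{(t/T + s)}{1 + s}\cdot\tfrac{\pi}{2}\big)} and
#' back-solves the per-step weights \eqn{\alpha_t} so that
#' \eqn{\prod_{i\le t}(1-\alpha_i) = 1-\bar\gamma_t} exactly. The terminal
#' retention is floored at \eqn{10^{-5}} so the stationary limit is reached.
#'
#' @param T Integer number of diffusion steps (>= 1).
#' @param delta Stationary no-edge probability in (0, 1); both rows of the
#'   prior matrix `S` are `(delta, 1 - delta)`.
#' @param s Profile offset (default 0.008).
#' @return A [NoiseSchedule-class] object.
#' @examples
#' sch <- cosineSchedule(50, delta = 0.9)
#' cumulativeTransition(sch, 50)  # both rows ~ (0.9, 0.1)
#' @export
cosineSchedule <- function(T, delta, s = 0.008) {
  assert_that(is_count(T, 1L), "T must be a positive integer")
  assert_that(is.numeric(delta) && length(delta) == 1L &&
                delta > 0 && delta < 1, "delta must lie in (0, 1)")
  T <- as.integer(T)
  f <- function(t) cos(((t / T + s) / (1 + s)) * pi / 2)^2
  retain <- f(0:T) / f(0)              # 1 - gammaBar_t, t = 0..T
  retain <- pmin(pmax(retain, 0), 1)
  retain[T + 1L] <- min(retain[T + 1L], 1e-5)
  ## enforce strict monotone decrease so every alpha_t is well defined
  for (t in seq_len(T) + 1L)
    retain[t] <- min(retain[t], retain[t - 1L])
  alpha <- 1 - retain[-1L] / pmax(retain[-(T + 1L)], 1e-300)
  alpha <- pmin(pmax(alpha, 0), 1)
  gammaBar <- c(0, 1 - cumprod(1 - alpha))
  new("NoiseSchedule", nSteps = T, delta = delta, s = s,
      alpha = alpha, gammaBar = gammaBar)
}

check_t <- function(schedule, t, lo = 0L) {
  assert_that(is_count(t, lo) && t <= schedule@nSteps,
              sprintf("t must be an integer in [%d, %d]", lo, schedule@nSteps))
  as.integer(t)
}

#' Single-step transition matrix
#'
#' \eqn{M_t = \alpha_t S + (1-\alpha_t) I}; rows index the previous state
#' (no-edge, edge) and columns the next state.
#'
#' @param schedule A [NoiseSchedule-class].
#' @param t Step index in `1..T`.
#' @return Row-stochastic 2x2 matrix.
#' @export
transitionMatrix <- function(schedule, t) {
  t <- check_t(schedule, t, lo = 1L)
  a <- schedule@alpha[t]
  a * priorMatrix(schedule) + (1 - a) * diag(2)
}

#' Cumulative transition matrix
#'
#' Closed form \eqn{\bar M_t = (1-\bar\gamma_t) I + \bar\gamma_t S}, equal to
#' the iterated product \eqn{\prod_{i \le t} M_i} because `S` is idempotent.
#'
#' @inheritParams transitionMatrix
#' @param t Step index in `0..T` (`t = 0` gives the identity).
#' @return Row-stochastic 2x2 matrix.
#' @export
cumulativeTransition <- function(schedule, t) {
  t <- check_t(schedule, t, lo = 0L)
  g <- schedule@gammaBar[t + 1L]
  (1 - g) * diag(2) + g * priorMatrix(schedule)
}

#' Bridge transition matrix between two schedule times
#'
#' The transition kernel from step `tPrev` to step `t > tPrev`:
#' \eqn{(1-\gamma')I + \gamma' S} with
#' \eqn{\gamma' = (\bar\gamma_t - \bar\gamma_{t_{prev}})/(1-\bar\gamma_{t_{prev}})},
#' so that \eqn{\bar M_{t_{prev}} \cdot M_{t_{prev}\to t} = \bar M_t}.
#'
#' @inheritParams transitionMatrix
#' @param tPrev,t Step indices with `0 <= tPrev < t <= T`.
#' @return Row-stochastic 2x2 matrix.
#' @export
bridgeMatrix <- function(schedule, tPrev, t) {
  tPrev <- check_t(schedule, tPrev, lo = 0L)
  t <- check_t(schedule, t, lo = 1L)
  assert_that(tPrev < t, "tPrev must be strictly less than t")
  gp <- schedule@gammaBar[tPrev + 1L]
  gt <- schedule@gammaBar[t + 1L]
  gpr <- (gt - gp) / (1 - gp)
  (1 - gpr) * diag(2) + gpr * priorMatrix(schedule)
}

#' Build an edge-state container
#'
#' @param x A [GRN-class] (states = adjacency, mask = candidate pairs) or a
#'   binary `n x n` matrix.
#' @param mask Logical candidate-pair matrix (required when `x` is a matrix).
#' @return List with elements `states` (0/1 matrix, masked pairs 0) and
#'   `mask` (logical).
#' @export
edgeState <- function(x, mask = NULL) {
  if (is(x, "GRN")) {
    mask <- candidateMask(x)
    x <- adjacency(x)
  }
  assert_that(is.matrix(x) && nrow(x) == ncol(x),
              "states must be a square matrix")
  assert_that(!is.null(mask) && is.matrix(mask) && all(dim(mask) == dim(x)),
              "a logical candidate mask of matching shape is required")
  assert_that(all(x %in% c(0, 1)), "edge states must be 0/1")
  states <- x * mask
  list(states = states, mask = mask)
}

#' Forward-corrupt a clean network to step t
#'
#' Each candidate pair is drawn independently from the categorical row of the
#' cumulative transition \eqn{\bar M_t} selected by its clean state; masked
#' pairs stay 0. `t = 0` returns the clean network unchanged.
#'
#' @param e0 Edge state from [edgeState()] (or a [GRN-class]).
#' @param t Step index in `0..T`.
#' @param schedule A [NoiseSchedule-class].
#' @param seed Integer seed.
#' @return An edge-state list at time `t`.
#' @export
forwardSample <- function(e0, t, schedule, seed = NULL) {
  if (is(e0, "GRN")) e0 <- edgeState(e0)
  t <- check_t(schedule, t, lo = 0L)
  Mb <- cumulativeTransition(schedule, t)
  p1 <- ifelse(e0$states == 1, Mb[2, 2], Mb[1, 2])
  with_seed(seed, {
    u <- matrix(stats::runif(length(p1)), nrow(p1), ncol(p1))
    states <- (u < p1) * 1
    states[!e0$mask] <- 0
    dimnames(states) <- dimnames(e0$states)
    list(states = states, mask = e0$mask)
  })
}

#' Evenly spaced inference time ladder
#'
#' Returns the strictly increasing subsequence `{0, tau_1, ..., tau_k = T}`
#' with `tau_i = round(i * T / k)`; `k = T` yields the full ladder.
#'
#' @param T Total schedule length.
#' @param k Number of reverse steps, `1 <= k <= T`.
#' @return Integer vector of length `k + 1`.
#' @examples
#' makeSubsequence(1000, 10)
#' @export
makeSubsequence <- function(T, k) {
  assert_that(is_count(T, 1L), "T must be a positive integer")
  assert_that(is_count(k, 1L) && k <= T, "k must be an integer in [1, T]")
  tau <- as.integer(round(seq_len(k) * as.double(T) / k))
  tau <- c(0L, tau)
  assert_that(all(diff(tau) >= 1L) && tau[k + 1L] == T,
              "internal error: ladder is not strictly increasing")
  tau
}

## Per-pair posterior over the state at tPrev, as two n x n probability
## matrices. p0 is the predicted probability that the CLEAN state is 1.
posterior_probs <- function(et, p0, tPrev, t, schedule) {
  B <- bridgeMatrix(schedule, tPrev, t)
  Mp <- cumulativeTransition(schedule, tPrev)
  out1 <- matrix(0, nrow(et$states), ncol(et$states))
  out0 <- out1
  floor_hit <- FALSE
  for (j in c(0L, 1L)) {                 # observed state at t
    sel <- et$states == j
    if (!any(sel)) next
    qk <- matrix(0, 2, 2)                # rows: e0 in {0,1}; cols: k in {0,1}
    for (i in c(0L, 1L)) {
      u <- B[, j + 1L] * Mp[i + 1L, ]    # unnormalized over k
      z <- sum(u)
      if (z <= 0) { u <- u + 1e-12; z <- sum(u); floor_hit <- TRUE }
      qk[i + 1L, ] <- u / z
    }
    p <- p0[sel]
    out0[sel] <- (1 - p) * qk[1, 1] + p * qk[2, 1]
    out1[sel] <- (1 - p) * qk[1, 2] + p * qk[2, 2]
  }
  if (floor_hit)
    log_msg("warn", "degenerate posterior normalizer; numerical floor applied",
            t = t, tPrev = tPrev)
  list(p0state = out0, p1state = out1)
}

#' Exact reverse posterior over candidate pairs
#'
#' For each candidate pair, computes the Bayes posterior of the state at
#' `tPrev` given the state at `t` and a predicted clean-edge distribution:
#' \eqn{q(e_{t_{prev}}{=}k \mid e_t{=}j, e_0{=}i) \propto
#' M_{t_{prev}\to t}(k, j)\, \bar M_{t_{prev}}(i, k)}, marginalized over the
#' predicted distribution of \eqn{e_0}.
#'
#' @param et Edge state at time `t`.
#' @param e0Probs `n x n` matrix of predicted probabilities that the clean
#'   state is an edge.
#' @param t,tPrev Step indices with `0 <= tPrev < t <= T`.
#' @param schedule A [NoiseSchedule-class].
#' @return Array `n x n x 2`; slice 1 is P(state at tPrev = 0), slice 2 is
#'   P(state at tPrev = 1). Each candidate pair's slice pair sums to 1.
#' @export
edgePosterior <- function(et, e0Probs, t, tPrev, schedule) {
  t <- check_t(schedule, t, lo = 1L)
  tPrev <- check_t(schedule, tPrev, lo = 0L)
  assert_that(tPrev < t, "tPrev must be strictly less than t")
  pp <- posterior_probs(et, e0Probs, tPrev, t, schedule)
  n <- nrow(et$states)
  out <- array(0, dim = c(n, n, 2))
  out[, , 1] <- pp$p0state
  out[, , 2] <- pp$p1state
  out
}

#' One reverse sampling step
#'
#' Samples each candidate pair from its [edgePosterior()]; with
#' `deterministic = TRUE` takes the argmax instead. Masked pairs stay 0.
#'
#' @inheritParams edgePosterior
#' @param seed Integer seed.
#' @param deterministic Take the posterior mode instead of sampling.
#' @return Edge-state list at time `tPrev`.
#' @export
reverseStep <- function(et, e0Probs, t, tPrev, schedule, seed = NULL,
                        deterministic = FALSE) {
  t <- check_t(schedule, t, lo = 1L)
  tPrev <- check_t(schedule, tPrev, lo = 0L)
  assert_that(tPrev < t, "tPrev must be strictly less than t")
  pp <- posterior_probs(et, e0Probs, tPrev, t, schedule)
  if (deterministic) {
    states <- (pp$p1state >= 0.5) * 1
    states[!et$mask] <- 0
    dimnames(states) <- dimnames(et$states)
    return(list(states = states, mask = et$mask))
  }
  with_seed(seed, {
    u <- matrix(stats::runif(length(pp$p1state)), nrow(pp$p1state))
    states <- (u < pp$p1state) * 1
    states[!et$mask] <- 0
    dimnames(states) <- dimnames(et$states)
    list(states = states, mask = et$mask)
  })
}

#' Stationary prior sample
#'
#' Draws an edge state from the schedule's stationary distribution (each
#' candidate pair is an edge with probability `1 - delta`); the starting
#' point of generation.
#'
#' @param mask Logical candidate-pair matrix.
#' @param schedule A [NoiseSchedule-class].
#' @param seed Integer seed.
#' @return Edge-state list.
#' @export
priorSample <- function(mask, schedule, seed = NULL) {
  with_seed(seed, {
    u <- matrix(stats::runif(length(mask)), nrow(mask))
    states <- (u < (1 - schedule@delta)) * 1
    states[!mask] <- 0
    list(states = states, mask = mask)
  })
}

#' Data-driven stationary no-edge probability
#'
#' `1 -` mean edge density of a set of training networks over their candidate
#' universes, clamped to `[0.5, 0.999]`.
#'
#' @param grns List of [GRN-class] objects.
#' @return Numeric delta.
#' @export
estimateDelta <- function(grns) {
  dens <- vapply(grns, function(g) {
    nEdges(g) / max(1, sum(candidateMask(g)))
  }, numeric(1))
  min(max(1 - mean(dens), 0.5), 0.999)
}

#' Serialize / read a schedule as YAML
#'
#' Only the defining settings (`nSteps`, `delta`, `s`) are stored; derived
#' arrays are regenerated on read.
#'
#' @param schedule A [NoiseSchedule-class].
#' @param path File path.
#' @return `writeSchedule` the path, invisibly; `readSchedule` a rebuilt
#'   [NoiseSchedule-class].
#' @export
writeSchedule <- function(schedule, path) {
  yaml::write_yaml(list(nSteps = schedule@nSteps, delta = schedule@delta,
                        s = schedule@s), path)
  invisible(path)
}

#' @rdname writeSchedule
#' @export
readSchedule <- function(path) {
  y <- yaml::read_yaml(path)
  assert_that(all(c("nSteps", "delta", "s") %in% names(y)),
              "schedule YAML must contain nSteps, delta and s")
  cosineSchedule(y$nSteps, y$delta, y$s)
}
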