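## Benchmark simulator: random sparse TF->target topologies and matched
## steady-state stochastic expression, emulating published single-cell GRN simulation protocols
## (n..2n edges, no self-loops, strictly unidirectional TF sources, 100
## cells per network).

#' Simulator configuration
#'
#' Settings for benchmark topology sampling and expression simulation. The
#' expression model is a simplified chemical-Langevin steady state: each
#' gene's production rate is its basal rate plus Hill-modulated contributions
#' from its regulators (activating or repressing), balanced against linear
#' decay, with demographic noise proportional to the square root of the total
#' reaction flux; cells are independent realizations.
#'
#' @param nMin,nMax Integer bounds of the uniform gene-count distribution.
#' @param tfFraction Fraction of genes designated transcription factors.
#' @param nCells Cells simulated per network.
#' @param basalRange Uniform range of basal production rates.
#' @param interactionRange Uniform range of absolute interaction strengths.
#' @param decayRange Uniform range of linear decay rates.
#' @param noiseScale Scale of the chemical-Langevin noise term (0 =
#'   deterministic dynamics).
#' @param hill Hill coefficient of the regulation function.
#' @param hillK Hill half-saturation constant (on the scale of basal
#'   steady-state levels).
#' @param activationProb Probability that an edge is activating (otherwise
#'   repressing).
#' @param dt Euler-Maruyama step size.
#' @param nBurn Integration steps before the state is recorded.
#' @return A validated list of class `"SimConfig"`.
#' @examples
#' cfg <- simConfig(nMin = 20, nMax = 20, nCells = 50)
#' @export
simConfig <- function(nMin = 15L, nMax = 40L, tfFraction = 0.3, nCells = 100L,
                      basalRange = c(0.5, 1.5), interactionRange = c(2, 6),
                      decayRange = c(0.8, 1.2), noiseScale = 1.0,
                      hill = 2, hillK = 1.0, activationProb = 0.7,
                      dt = 0.05, nBurn = 200L) {
  assert_that(is_count(nMin, 2L), "nMin must be an integer >= 2")
  assert_that(is_count(nMax, nMin), "nMax must be an integer >= nMin")
  assert_that(tfFraction > 0 && tfFraction < 1,
              "tfFraction must lie strictly between 0 and 1")
  assert_that(is_count(nCells, 1L), "nCells must be a positive integer")
  assert_that(noiseScale >= 0, "noiseScale must be nonnegative")
  assert_that(dt > 0 && nBurn >= 1, "dt must be > 0 and nBurn >= 1")
  structure(list(
    nMin = as.integer(nMin), nMax = as.integer(nMax),
    tfFraction = tfFraction, nCells = as.integer(nCells),
    basalRange = basalRange, interactionRange = interactionRange,
    decayRange = decayRange, noiseScale = noiseScale,
    hill = hill, hillK = hillK, activationProb = activationProb,
    dt = dt, nBurn = as.integer(nBurn)
  ), class = "SimConfig")
}

## Maximum number of placeable edges given the unidirectionality rule:
## TF -> non-TF pairs are unconstrained; each unordered TF pair contributes
## at most one direction.
max_feasible_edges <- function(n, nTF) {
  nTF * (n - nTF) + nTF * (nTF - 1) / 2
}

#' Sample a random benchmark GRN topology
#'
#' Draws a gene count uniformly from `[nMin, nMax]`, designates a fixed
#' fraction of genes as TFs, and places a uniformly drawn number of edges in
#' `[n, 2n]` under three constraints: no self-regulation, every edge source
#' is a TF, and no reciprocal pair (strict unidirectionality).
#'
#' @param config A [simConfig()] object.
#' @param seed Integer seed for reproducibility.
#' @return A [GRN-class] object.
#' @examples
#' g <- sampleGRNTopology(simConfig(nMin = 20, nMax = 20), seed = 1)
#' @export
sampleGRNTopology <- function(config, seed = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  with_seed(seed, {
    n <- if (config$nMin == config$nMax) config$nMin
         else sample(config$nMin:config$nMax, 1L)
    nTF <- max(1L, as.integer(round(config$tfFraction * n)))
    maxE <- max_feasible_edges(n, nTF)
    if (maxE < n)
      stop(sprintf(paste0("infeasible simulator configuration: %d TFs over %d ",
                          "genes admit at most %d edges but at least n = %d ",
                          "are required"), nTF, n, maxE, n), call. = FALSE)
    mHi <- min(2L * n, maxE)
    m <- if (mHi == n) n else sample(n:mHi, 1L)
    tfs <- c(rep(TRUE, nTF), rep(FALSE, n - nTF))
    ## enumerate candidate ordered pairs (TF source, non-self), shuffle, and
    ## take greedily while rejecting reciprocals; the greedy pass attains the
    ## feasibility bound because conflicts only arise within TF-TF pairs
    src <- rep(seq_len(nTF), each = n)
    tgt <- rep(seq_len(n), times = nTF)
    keep <- src != tgt
    src <- src[keep]; tgt <- tgt[keep]
    ord <- sample.int(length(src))
    A <- matrix(0, n, n)
    placed <- 0L
    for (p in ord) {
      i <- src[p]; j <- tgt[p]
      if (A[j, i] == 1) next
      A[i, j] <- 1
      placed <- placed + 1L
      if (placed == m) break
    }
    GRN(genes = sprintf("g%03d", seq_len(n)), tfMask = tfs, adjacency = A)
  })
}

## Draw the full kinetic parameterization for a gene universe. Interaction
## strengths and signs are drawn for EVERY ordered pair and masked by the
## adjacency afterwards, so edge knockouts do not shift the random stream of
## unrelated genes.
draw_kinetics <- function(n, config) {
  list(
    basal = stats::runif(n, config$basalRange[1], config$basalRange[2]),
    decay = stats::runif(n, config$decayRange[1], config$decayRange[2]),
    strength = matrix(stats::runif(n * n, config$interactionRange[1],
                                   config$interactionRange[2]), n, n),
    activating = matrix(stats::runif(n * n) < config$activationProb, n, n)
  )
}

#' Simulate steady-state expression for a network
#'
#' Integrates the chemical-Langevin dynamics
#' \deqn{dx_j = (b_j + \sum_i k_{ij}\,\mathrm{Hill}(x_i) - \lambda_j x_j)\,dt
#'   + \eta\sqrt{(p_j + \lambda_j x_j)\,dt}\;\varepsilon}
#' to approximate the stationary regime; each cell is an independent
#' realization. Activating edges use the increasing Hill function
#' \eqn{x^h/(K^h + x^h)}, repressing edges the decreasing one.
#'
#' @param grn A [GRN-class] object.
#' @param config A [simConfig()] object.
#' @param seed Integer seed.
#' @return Numeric `nCells x nGenes` matrix (cells in rows, genes in
#'   columns, gene names as column names); all entries nonnegative.
#' @examples
#' g <- sampleGRNTopology(simConfig(nMin = 10, nMax = 10, nCells = 20), 1)
#' x <- simulateExpression(g, simConfig(nMin = 10, nMax = 10, nCells = 20), 1)
#' dim(x)
#' @export
simulateExpression <- function(grn, config, seed = NULL) {
  stopifnot(is(grn, "GRN"), inherits(config, "SimConfig"))
  validObject(grn)
  n <- nGenes(grn)
  A <- adjacency(grn)
  with_seed(seed, {
    kin <- draw_kinetics(n, config)
    Wact <- kin$strength * A * kin$activating
    Wrep <- kin$strength * A * (!kin$activating)
    nc <- config$nCells
    h <- config$hill
    Kh <- config$hillK^h
    dt <- config$dt
    eta <- config$noiseScale
    X <- matrix(stats::runif(nc * n, 0, 2), nc, n) *
      matrix(kin$basal / kin$decay, nc, n, byrow = TRUE)
    basal <- matrix(kin$basal, nc, n, byrow = TRUE)
    decay <- matrix(kin$decay, nc, n, byrow = TRUE)
    for (step in seq_len(config$nBurn)) {
      Xh <- X^h
      hillAct <- Xh / (Kh + Xh)
      prod <- basal + hillAct %*% Wact + (1 - hillAct) %*% Wrep
      drift <- (prod - decay * X) * dt
      if (eta > 0) {
        noise <- eta * sqrt(pmax(prod + decay * X, 0) * dt) *
          matrix(stats::rnorm(nc * n), nc, n)
      } else noise <- 0
      X <- pmax(X + drift + noise, 0)
    }
    colnames(X) <- genes(grn)
    rownames(X) <- sprintf("cell%04d", seq_len(nc))
    X
  })
}

#' Build a train/test benchmark suite
#'
#' Draws `nTrain + nTest` independent (topology, expression) pairs; each
#' element gets its own reproducible substream derived from `seed`.
#'
#' @param config A [simConfig()] object.
#' @param nTrain,nTest Number of training / held-out networks.
#' @param seed Integer seed.
#' @return List with elements `train` and `test`, each a list of
#'   `list(grn = <GRN>, expr = <matrix>)` pairs.
#' @examples
#' suite <- makeBenchmarkSuite(simConfig(nMin = 10, nMax = 12, nCells = 30),
#'                             nTrain = 2, nTest = 1, seed = 7)
#' length(suite$train)
#' @export
makeBenchmarkSuite <- function(config, nTrain, nTest, seed = NULL) {
  assert_that(is_count(nTrain, 1L) && is_count(nTest, 1L),
              "nTrain and nTest must be positive integers")
  total <- nTrain + nTest
  base <- if (is.null(seed)) sample.int(2147483000L, 1L) else as.integer(seed)
  pairs <- lapply(seq_len(total), function(i) {
    g <- sampleGRNTopology(config, seed = substream_seed(base, i))
    x <- simulateExpression(g, config,
                            seed = substream_seed(base, i + 1000000L))
    list(grn = g, expr = x)
  })
  names(pairs) <- sprintf("net%03d", seq_len(total))
  list(train = pairs[seq_len(nTrain)],
       test = pairs[nTrain + seq_len(nTest)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
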