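## Shared fixture builders: everything is generated in code at test time.

tiny_sim_config <- function(n = 10L, nCells = 50L, ...) {
  simConfig(nMin = n, nMax = n, nCells = nCells, ...)
}

tiny_hyper <- function(mProfile = 20L, ...) {
  denoiserHyper(dX = 8L, dE = 8L, dT = 8L, L = 2L, headsGAT = 2L,
              headsNode = 2L, headsEdge = 2L, headsCross = 2L, dFF = 8L,
              mProfile = mProfile, ...)
}

tiny_net <- function(seed = 3L, n = 7L, nCells = 20L) {
  cfg <- tiny_sim_config(n = n, nCells = nCells, tfFraction = 0.4)
  g <- sampleGRNTopology(cfg, seed = seed)
  list(grn = g, expr = simulateExpression(g, cfg, seed = seed + 1L),
       cfg = cfg)
}

## Deterministic hand-built 3-gene network: g1 (TF) -> g2.
hand_grn <- function() {
  GRN(c("g1", "g2", "g3"), c(TRUE, FALSE, FALSE),
      matrix(c(0, 0, 0,
               1, 0, 0,
               0, 0, 0), 3, 3, byrow = FALSE))
}

## Random schedules for property sweeps.
random_schedule <- function(seed) {
  set.seed(seed)
  cosineSchedule(sample(5:60, 1), stats::runif(1, 0.55, 0.98))
}
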