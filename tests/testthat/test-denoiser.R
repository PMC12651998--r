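make_forward <- function(mod, net, t, sch, seedNoise = 6,
                         returnInternals = FALSE) {
  e0 <- edgeState(net$grn)
  et <- forwardSample(e0, t, sch, seed = seedNoise)
  denoiserForward(mod, et, net$expr, t, returnInternals = returnInternals)
}

test_that("forward pass has the contracted shape, mask sentinel and determinism", {
  net <- tiny_net(seed = 3, n = 7, nCells = 20)
  hy <- tiny_hyper()
  sch <- cosineSchedule(10, 0.8)
  mod <- denoiserInit(hy, sch, seed = 4)
  fw <- make_forward(mod, net, 5, sch)
  n <- nGenes(net$grn)
  expect_equal(dim(fw$logits), c(n, n, 2))
  mask <- candidateMask(net$grn)
  ## masked pairs: edge logit at the -inf sentinel, probability 0
  expect_true(all(fw$logits[, , 2][!mask] <= -1e8))
  expect_true(all(fw$p0[!mask] == 0))
  expect_true(all(fw$p0 >= 0 & fw$p0 <= 1))
  ## bit-stable repetition
  fw2 <- make_forward(mod, net, 5, sch)
  expect_identical(fw$logits, fw2$logits)
  ## gene-order mismatch is refused
  e0 <- edgeState(net$grn)
  expect_error(denoiserForward(mod, e0, net$expr[, 1:5], 5), "mismatch")
})

test_that("every attention softmax is row-normalized", {
  net <- tiny_net(seed = 9, n = 8, nCells = 20)
  hy <- tiny_hyper()
  mod <- denoiserInit(hy, cosineSchedule(10, 0.8), seed = 1)
  fw <- make_forward(mod, net, 7, cosineSchedule(10, 0.8),
                     returnInternals = TRUE)
  ints <- fw$internals
  expect_gt(length(ints$gat), 0)
  expect_gt(length(ints$nsa), 0)
  expect_gt(length(ints$cross), 0)
  expect_gt(length(ints$atte), 0)
  for (A in c(ints$gat, ints$nsa, ints$cross, ints$atte))
    expect_equal(unname(rowSums(A)), rep(1, nrow(A)), tolerance = 1e-6)
})

test_that("the forward pass is equivariant to gene permutations", {
  set.seed(31)
  for (rep in 1:3) {
    net <- tiny_net(seed = 30 + rep, n = 6, nCells = 20)
    hy <- tiny_hyper()
    sch <- cosineSchedule(10, 0.8)
    mod <- denoiserInit(hy, sch, seed = 40 + rep)
    e0 <- edgeState(net$grn)
    et <- forwardSample(e0, 6, sch, seed = 7)
    out <- denoiserForward(mod, et, net$expr, 6)
    perm <- sample(6)
    etP <- list(states = et$states[perm, perm], mask = et$mask[perm, perm])
    exprP <- net$expr[, perm]
    outP <- denoiserForward(mod, etP, exprP, 6)
    ## permuting inputs permutes outputs identically
    expect_equal(outP$p0, out$p0[perm, perm], tolerance = 1e-4)
    expect_equal(outP$logits[, , 2], out$logits[, , 2][perm, perm],
                 tolerance = 1e-4)
  }
})

test_that("FiLM reduces to identity and scaling at degenerate parameters", {
  tape <- DiffGRN:::ad_tape()
  dT <- 4L; dB <- 3L
  temb <- DiffGRN:::ad_const(matrix(c(0.3, -1, 2, 0.5), 1, dT))
  B <- matrix(rnorm(15), 5, dB)
  zeroW <- DiffGRN:::ad_const(matrix(0, dT, dB))
  zeroB <- DiffGRN:::ad_const(matrix(0, 1, dB))
  out <- DiffGRN:::film_apply(tape, temb, DiffGRN:::ad_const(B),
                              zeroW, zeroB, zeroW, zeroB)
  expect_equal(out$val, B)  # lin1 = lin2 = 0 -> identity
  cB <- DiffGRN:::ad_const(matrix(0.6, 1, dB))
  out2 <- DiffGRN:::film_apply(tape, temb, DiffGRN:::ad_const(B),
                               zeroW, zeroB, zeroW, cB)
  expect_equal(out2$val, (1 + 0.6) * B)  # lin2 = const c -> (1 + c) b
  ## random small case against scalar arithmetic
  set.seed(2)
  W1 <- matrix(rnorm(dT * dB), dT, dB); b1 <- matrix(rnorm(dB), 1)
  W2 <- matrix(rnorm(dT * dB), dT, dB); b2 <- matrix(rnorm(dB), 1)
  out3 <- DiffGRN:::film_apply(tape, temb, DiffGRN:::ad_const(B),
                               DiffGRN:::ad_const(W1), DiffGRN:::ad_const(b1),
                               DiffGRN:::ad_const(W2), DiffGRN:::ad_const(b2))
  lin1 <- temb$val %*% W1 + b1
  lin2 <- temb$val %*% W2 + b2
  want <- B
  for (r in 1:5) for (c in 1:dB)
    want[r, c] <- lin1[1, c] + lin2[1, c] * B[r, c] + B[r, c]
  expect_equal(out3$val, want, tolerance = 1e-7)
})

test_that("time gating interpolates between aggregation and skip endpoints", {
  ## the gated fusion is (1 - g) h' + g x, elementwise over features
  set.seed(3)
  H <- matrix(rnorm(12), 4, 3)
  X <- matrix(rnorm(12), 4, 3)
  for (gval in c(0, 1, 0.37)) {
    tape <- DiffGRN:::ad_tape()
    g <- DiffGRN:::ad_const(matrix(gval, 1, 3))
    gInv <- DiffGRN:::ad_sadd(tape, DiffGRN:::ad_smul(tape, g, -1), 1)
    out <- DiffGRN:::ad_add(tape,
                            DiffGRN:::ad_mul_rowvec(tape, DiffGRN:::ad_const(H), gInv),
                            DiffGRN:::ad_mul_rowvec(tape, DiffGRN:::ad_const(X), g))
    expect_equal(out$val, (1 - gval) * H + gval * X, tolerance = 1e-12)
  }
})

test_that("GATv2 on a single self-looped node applies the value map exactly", {
  ## degenerate softmax = 1, so h' = W_r h
  tape <- DiffGRN:::ad_tape()
  set.seed(4)
  X <- matrix(rnorm(3), 1, 3)
  P <- list("gat1.h1.Wl" = matrix(rnorm(6), 3, 2),
            "gat1.h1.Wr" = matrix(rnorm(6), 3, 2),
            "gat1.h1.a" = matrix(rnorm(2), 2, 1))
  Pn <- lapply(P, DiffGRN:::ad_const)
  out <- DiffGRN:::gatv2_layer_ad(tape, DiffGRN:::ad_const(X), Pn, "gat1",
                                  1L, matrix(0, 1, 1), 1L, 1L, 0.2, "concat")
  expect_equal(out$val, X %*% P[["gat1.h1.Wr"]], tolerance = 1e-10)
})

test_that("gated pooling gated pooling matches an explicit loop over nodes", {
  set.seed(6)
  n <- 9; dX <- 5; dT <- 4
  X <- matrix(rnorm(n * dX), n, dX)
  Wg <- matrix(rnorm(dX * dX) / 2, dX, dX); bg <- matrix(rnorm(dX), 1)
  Wlin <- matrix(rnorm(dX * dT) / 2, dX, dT); blin <- matrix(rnorm(dT), 1)
  tape <- DiffGRN:::ad_tape()
  gates <- DiffGRN:::ad_sigmoid(tape, DiffGRN:::ad_linear(tape,
    DiffGRN:::ad_const(X), DiffGRN:::ad_const(Wg), DiffGRN:::ad_const(bg)))
  pooled <- DiffGRN:::ad_colsum(tape, DiffGRN:::ad_mul(tape, gates,
                                                       DiffGRN:::ad_const(X)))
  out <- DiffGRN:::ad_linear(tape, pooled, DiffGRN:::ad_const(Wlin),
                             DiffGRN:::ad_const(blin))
  ## loop oracle
  acc <- matrix(0, 1, dX)
  for (i in 1:n) {
    gi <- 1 / (1 + exp(-(X[i, , drop = FALSE] %*% Wg + bg)))
    acc <- acc + gi * X[i, , drop = FALSE]
  }
  want <- acc %*% Wlin + blin
  expect_equal(out$val, want, tolerance = 1e-6)
  ## single node, gate forced to 1 (large bias): W_lin^T x + b_lin
  bigb <- matrix(1e3, 1, dX)
  tape2 <- DiffGRN:::ad_tape()
  g2 <- DiffGRN:::ad_sigmoid(tape2, DiffGRN:::ad_linear(tape2,
    DiffGRN:::ad_const(X[1, , drop = FALSE]), DiffGRN:::ad_const(Wg * 0),
    DiffGRN:::ad_const(bigb)))
  p2 <- DiffGRN:::ad_colsum(tape2, DiffGRN:::ad_mul(tape2, g2,
    DiffGRN:::ad_const(X[1, , drop = FALSE])))
  o2 <- DiffGRN:::ad_linear(tape2, p2, DiffGRN:::ad_const(Wlin),
                            DiffGRN:::ad_const(blin))
  expect_equal(o2$val, X[1, , drop = FALSE] %*% Wlin + blin,
               tolerance = 1e-8)
})

test_that("node self-attention on a single gene is the identity on values", {
  net <- tiny_net(seed = 3, n = 6, nCells = 15)
  hy <- tiny_hyper()
  ## single-token softmax: attention weight is exactly 1
  tape <- DiffGRN:::ad_tape()
  x <- DiffGRN:::ad_const(matrix(rnorm(4), 1, 4))
  S <- DiffGRN:::ad_row_softmax(tape, DiffGRN:::ad_mm(tape, x,
                                                      DiffGRN:::ad_t(tape, x)))
  expect_equal(S$val, matrix(1, 1, 1))
})

test_that("masked pairs cannot influence candidate-pair logits", {
  net <- tiny_net(seed = 12, n = 7, nCells = 20)
  hy <- tiny_hyper()
  sch <- cosineSchedule(10, 0.8)
  mod <- denoiserInit(hy, sch, seed = 5)
  e0 <- edgeState(net$grn)
  et <- forwardSample(e0, 8, sch, seed = 2)
  ## flipping a masked (non-candidate) pair's raw state must not change
  ## anything: the edge-state encoder reads masked pairs as "absent"
  st2 <- et$states
  nonc <- which(!et$mask & row(st2) != col(st2))[1]
  st2[nonc] <- 1 - st2[nonc]
  fw1 <- denoiserForward(mod, et, net$expr, 8)
  fw2 <- denoiserForward(mod, list(states = st2, mask = et$mask),
                       net$expr, 8)
  expect_equal(fw1$logits, fw2$logits, tolerance = 1e-12)
})

test_that("feedback edge states shift edge representations detectably", {
  ## with the true clean network fed back at low noise, candidate pairs that
  ## carry a feedback edge get systematically different final edge-feature
  ## channel norms than pairs that do not (~500 pairs, random inputs)
  cfg <- simConfig(nMin = 32, nMax = 32, tfFraction = 0.5, nCells = 25)
  g <- sampleGRNTopology(cfg, seed = 21)
  expr <- simulateExpression(g, cfg, seed = 22)
  hy <- tiny_hyper()
  sch <- cosineSchedule(10, 0.8)
  mod <- denoiserInit(hy, sch, seed = 33)
  e0 <- edgeState(g)
  mask <- e0$mask
  cand <- as.vector(mask)
  expect_gte(sum(cand), 450)
  ## paired contrast over ~500 pairs: switching every candidate pair's
  ## feedback state from 0 to 1 shifts each pair's own clean-edge logit in a
  ## systematic direction (one-sample t-test on the paired differences)
  z0 <- denoiserForward(mod, list(states = matrix(0, 32, 32), mask = mask),
                      expr, 1)$logits[, , 2]
  z1 <- denoiserForward(mod, list(states = (mask) * 1, mask = mask),
                      expr, 1)$logits[, , 2]
  d <- (z1 - z0)[mask]
  tt <- stats::t.test(d)
  expect_lt(tt$p.value, 0.01)
  ## single-pair sensitivity: flipping one candidate pair's feedback state
  ## moves that pair's own clean-edge logit
  fw <- denoiserForward(mod, e0, expr, 1)
  p <- which(cand & as.vector(e0$states) == 0)[1]
  st <- e0$states; st[p] <- 1
  fw2 <- denoiserForward(mod, list(states = st, mask = mask), expr, 1)
  expect_gt(abs(fw2$logits[, , 2][p] - fw$logits[, , 2][p]), 1e-8)
})

test_that("no parameter block receives an identically zero gradient", {
  net <- tiny_net(seed = 3, n = 7, nCells = 20)
  hy <- tiny_hyper()
  sch <- cosineSchedule(10, 0.8)
  mod <- denoiserInit(hy, sch, seed = 4)
  Xf <- nodeFeatures(net$expr, hy$mProfile, seed = 1)
  res <- DiffGRN:::train_step_grads(mod@params, hy, Xf, net$grn, 5, sch,
                                    2, 11)
  zeroes <- vapply(res$grads, function(g) all(g == 0), logical(1))
  expect_false(any(zeroes), info = paste(names(which(zeroes)), collapse = ","))
})

test_that("checkpoints round-trip bit-exactly through disk", {
  net <- tiny_net(seed = 3, n = 7, nCells = 20)
  hy <- tiny_hyper()
  sch <- cosineSchedule(10, 0.8)
  mod <- denoiserInit(hy, sch, seed = 4)
  path <- tempfile(fileext = ".rds")
  saveModel(mod, path)
  mod2 <- loadModel(path)
  expect_identical(mod@params, mod2@params)
  fw1 <- make_forward(mod, net, 5, sch)
  fw2 <- make_forward(mod2, net, 5, sch)
  expect_identical(fw1$logits, fw2$logits)
  ## JSON header carries the hyperparameters
  hpath <- tempfile(fileext = ".json")
  writeModelHeader(mod, hpath)
  hdr <- jsonlite::read_json(hpath)
  expect_equal(hdr$hyper$dX, mod@hyper$dX)
})

test_that("ablated architectures drop exactly the intended modules", {
  sch <- cosineSchedule(10, 0.8)
  full <- denoiserInit(tiny_hyper(), sch, seed = 1)
  woG <- denoiserInit(tiny_hyper(ablateG = TRUE), sch, seed = 1)
  woC <- denoiserInit(tiny_hyper(ablateC = TRUE), sch, seed = 1)
  woP <- denoiserInit(tiny_hyper(ablateP = TRUE), sch, seed = 1)
  expect_true(any(grepl("^gat1", names(full@params))))
  expect_false(any(grepl("^gat1", names(woG@params))))
  expect_true("enc.W" %in% names(woG@params))
  expect_true(any(grepl("ca\\.", names(full@params))))
  expect_false(any(grepl("ca\\.", names(woC@params))))
  expect_true(any(grepl("gpool", names(full@params))))
  expect_false(any(grepl("gpool", names(woP@params))))
  expect_true(any(grepl("mp\\.", names(woP@params))))
  ## ablated variants still run and train
  net <- tiny_net(seed = 3, n = 7, nCells = 20)
  for (m in list(woG, woC, woP)) {
    fw <- make_forward(m, net, 5, sch)
    expect_true(all(is.finite(fw$p0)))
  }
})
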