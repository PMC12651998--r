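## Training (forward-corrupt, predict the clean network, cross-entropy) and
## generation (reverse subsequence sampling with ensemble probability
## readout).

#' Training configuration
#'
#' @param nStepsDiffusion Diffusion schedule length `T` used for training.
#' @param epochs Passes over the training networks.
#' @param batchSize Networks per gradient update (gradients are averaged).
#' @param lr AdamW learning rate.
#' @param weightDecay AdamW decoupled weight decay.
#' @param clipNorm Global gradient-norm clip.
#' @param posWeightCap Cap on the automatic positive-class weight.
#' @param seed Integer seed governing corruption draws and initialization.
#' @param kValidation Subsequence length for validation sampling.
#' @param augmentCells Number of cell-bootstrap feature variants per network
#'   (0 disables). Each variant derives node features from a random 80%
#'   subsample of cells; steps cycle through variants, which regularizes the
#'   denoiser toward cell-resampling-stable (correlation-like) evidence
#'   instead of memorizing per-network feature signatures.
#' @param selfCorruptProb Probability that a training draw corrupts a
#'   network sampled from the model's own current prediction instead of the
#'   true one (the target stays the true network). This scheduled-sampling
#'   step exposes the denoiser to feedback of its own making, the regime it
#'   faces during generation, and counteracts the compounding of errors
#'   along reverse chains.
#' @param checkpointEvery Write a checkpoint every this many epochs to
#'   `checkpointDir` (`0` disables).
#' @param checkpointDir Directory for checkpoints.
#' @param hyper Architecture hyperparameters ([denoiserHyper()]).
#' @return Validated list of class `"TrainConfig"`.
#' @export
trainConfig <- function(nStepsDiffusion = 100L, epochs = 200L, batchSize = 1L,
                        lr = 3e-4, weightDecay = 0.01, clipNorm = 1.0,
                        posWeightCap = 20, seed = 1L, kValidation = NULL,
                        augmentCells = 8L, selfCorruptProb = 0.3,
                        checkpointEvery = 0L, checkpointDir = tempdir(),
                        hyper = denoiserHyper()) {
  assert_that(is_count(nStepsDiffusion, 1L), "nStepsDiffusion must be >= 1")
  assert_that(is_count(epochs, 1L), "epochs must be >= 1")
  assert_that(is_count(batchSize, 1L), "batchSize must be >= 1")
  if (is.null(kValidation)) kValidation <- nStepsDiffusion
  assert_that(kValidation <= nStepsDiffusion, "kValidation must be <= T")
  structure(list(nStepsDiffusion = as.integer(nStepsDiffusion),
                 epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 lr = lr, weightDecay = weightDecay, clipNorm = clipNorm,
                 posWeightCap = posWeightCap, seed = as.integer(seed),
                 kValidation = as.integer(kValidation),
                 augmentCells = as.integer(augmentCells),
                 selfCorruptProb = selfCorruptProb,
                 checkpointEvery = as.integer(checkpointEvery),
                 checkpointDir = checkpointDir, hyper = hyper),
            class = "TrainConfig")
}

#' Masked, class-weighted cross-entropy against the clean network
#'
#' Mean two-class cross-entropy over candidate pairs, optionally with a
#' positive-class weight (weighted mean normalized by the total weight, so
#' uniform logits give exactly `log(2)` regardless of weighting).
#'
#' @param logits `n x n x 2` logit array or `n^2 x 2` matrix (column-major
#'   pair order).
#' @param e0 Clean edge state ([edgeState()] list or [GRN-class]).
#' @param posWeight Weight applied to true-edge pairs.
#' @return Scalar loss.
#' @export
trainingLoss <- function(logits, e0, posWeight = 1) {
  if (is(e0, "GRN")) e0 <- edgeState(e0)
  if (is.array(logits) && length(dim(logits)) == 3L) {
    n <- dim(logits)[1]
    logits <- cbind(as.vector(logits[, , 1]), as.vector(logits[, , 2]))
  }
  cand <- as.vector(e0$mask)
  y <- as.vector(e0$states)[cand]
  z <- logits[cand, , drop = FALSE]
  zmax <- apply(z, 1L, max)
  lse <- zmax + log(exp(z[, 1] - zmax) + exp(z[, 2] - zmax))
  logp <- z[cbind(seq_along(y), y + 1L)] - lse
  w <- ifelse(y == 1, posWeight, 1)
  -sum(w * logp) / sum(w)
}

## Loss node on the tape (same quantity as trainingLoss, differentiable).
denoiser_loss_ad <- function(tape, logits, e0vec, cand, posWeight) {
  idx <- which(cand)
  z <- ad_gather(tape, logits, idx)
  zmax <- pmax(z$val[, 1], z$val[, 2])
  zc <- ad_sadd(tape, z, matrix(-zmax, length(idx), 2L))
  lse <- ad_log(tape, ad_rowsum(tape, ad_exp(tape, zc)))
  y <- e0vec[idx]
  onehot <- ad_const(cbind(1 - y, y))
  zy <- ad_rowdot(tape, zc, onehot)
  ce <- ad_sub(tape, lse, zy)
  w <- ifelse(y == 1, posWeight, 1)
  ad_smul(tape, ad_sum(tape, ad_mul(tape, ce, ad_const(matrix(w, ncol = 1L)))),
          1 / sum(w))
}

## AdamW with decoupled weight decay and global-norm clipping.
adamw_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       step = 0L)
}

adamw_update <- function(params, grads, state, lr, weightDecay = 0.01,
                         clipNorm = 1.0, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  scale <- if (clipNorm > 0 && gn > clipNorm) clipNorm / gn else 1
  state$step <- state$step + 1L
  b1c <- 1 - beta1^state$step
  b2c <- 1 - beta2^state$step
  for (nm in names(params)) {
    g <- grads[[nm]] * scale
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / b1c
    vhat <- state$v[[nm]] / b2c
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                           weightDecay * params[[nm]])
  }
  list(params = params, state = state)
}

## Positive-class weight from training-set sparsity, capped.
auto_pos_weight <- function(grns, cap = 20) {
  pos <- sum(vapply(grns, nEdges, integer(1)))
  tot <- sum(vapply(grns, function(g) sum(candidateMask(g)), numeric(1)))
  min((tot - pos) / max(1, pos), cap)
}

## One backward pass for one (network, t) draw; returns loss and gradients.
## With selfCorrupt, the noisy state is a forward corruption of a network
## sampled from the model's own (no-gradient) prediction, while the loss
## target remains the true clean network.
train_step_grads <- function(params, hyper, Xfeat, grn, t, schedule,
                             posWeight, stepSeed, selfCorrupt = FALSE) {
  e0 <- edgeState(grn)
  et <- forwardSample(e0, t, schedule, seed = stepSeed)
  if (selfCorrupt) {
    tape0 <- ad_tape()
    P0 <- wrap_params(params, tape0, trainable = FALSE)
    fw0 <- denoiser_forward_ad(tape0, P0, hyper, Xfeat, et$states, e0$mask, t)
    z <- fw0$logits$val
    zs <- z - z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
    p1 <- matrix(exp(zs[, 2]) / (exp(zs[, 1]) + exp(zs[, 2])),
                 nrow(e0$states))
    e0hat <- with_seed(stepSeed + 1L, {
      st <- (matrix(stats::runif(length(p1)), nrow(p1)) < p1) * 1
      st[!e0$mask] <- 0
      list(states = st, mask = e0$mask)
    })
    et <- forwardSample(e0hat, t, schedule, seed = stepSeed + 2L)
  }
  tape <- ad_tape()
  P <- wrap_params(params, tape, trainable = TRUE)
  fw <- denoiser_forward_ad(tape, P, hyper, Xfeat, et$states, et$mask, t)
  loss <- denoiser_loss_ad(tape, fw$logits, as.vector(e0$states),
                         as.vector(e0$mask), posWeight)
  ad_backward(tape, loss)
  grads <- lapply(P, function(p) if (is.null(p$grad)) p$val * 0 else p$grad)
  list(loss = loss$val[1, 1], grads = grads)
}

#' Train the denoiser on a suite of (network, expression) pairs
#'
#' Each optimization draw samples a training network and a uniform step
#' `t in 1..T`, corrupts the clean network with [forwardSample()], runs the
#' denoiser, and descends the masked weighted cross-entropy with AdamW.
#' Reproducible under `config$seed`.
#'
#' @param suite List of `list(grn = <GRN>, expr = <matrix>)` training pairs
#'   (e.g. `makeBenchmarkSuite(...)$train`).
#' @param config A [trainConfig()] object.
#' @param schedule Optional [NoiseSchedule-class]; by default a cosine
#'   schedule of length `config$nStepsDiffusion` with [estimateDelta()] from
#'   the training networks.
#' @param model Optional warm-start [GRNDenoiser-class].
#' @param verbose Log per-epoch losses.
#' @return A trained [GRNDenoiser-class] with a populated `trainingLog`.
#' @export
trainModel <- function(suite, config = trainConfig(), schedule = NULL,
                       model = NULL, verbose = FALSE) {
  assert_that(length(suite) >= 1L, "at least one training pair is required")
  grns <- lapply(suite, `[[`, "grn")
  if (is.null(schedule))
    schedule <- cosineSchedule(config$nStepsDiffusion, estimateDelta(grns))
  assert_that(schedule@nSteps == config$nStepsDiffusion,
              "schedule length must match config$nStepsDiffusion")
  hyper <- config$hyper
  if (is.null(model))
    model <- denoiserInit(hyper, schedule, seed = substream_seed(config$seed, 1L))
  params <- model@params
  posW <- auto_pos_weight(grns, config$posWeightCap)
  nAug <- max(1L, config$augmentCells)
  feats <- lapply(seq_along(suite), function(i) {
    expr <- suite[[i]]$expr
    if (config$augmentCells == 0L)
      return(list(nodeFeatures(expr, hyper$mProfile, seed = 1L)))
    lapply(seq_len(nAug), function(v) {
      sub <- with_seed(substream_seed(config$seed, 40000L + 100L * i + v), {
        size <- min(nrow(expr), max(hyper$mProfile, floor(0.8 * nrow(expr))))
        keep <- sample(nrow(expr), size)
        expr[sort(keep), , drop = FALSE]
      })
      nodeFeatures(sub, hyper$mProfile, seed = v)
    })
  })
  opt <- adamw_state(params)
  log <- model@trainingLog
  Tn <- schedule@nSteps
  counter <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(substream_seed(config$seed, 10000L + epoch),
                     sample.int(length(suite)))
    losses <- numeric(0)
    batch_grads <- NULL
    batch_n <- 0L
    for (i in ord) {
      counter <- counter + 1L
      draw <- with_seed(substream_seed(config$seed, 20000L + counter),
                        sample.int(Tn, 1L))
      feat <- feats[[i]][[(counter %% nAug) + 1L]]
      selfc <- config$selfCorruptProb > 0 &&
        with_seed(substream_seed(config$seed, 50000L + counter),
                  stats::runif(1)) < config$selfCorruptProb
      res <- train_step_grads(params, hyper, feat, suite[[i]]$grn,
                              draw, schedule, posW,
                              substream_seed(config$seed, 30000L + counter),
                              selfCorrupt = selfc)
      if (!is.finite(res$loss))
        stop(sprintf("training diverged (loss = %s) at epoch %d", res$loss,
                     epoch), call. = FALSE)
      losses <- c(losses, res$loss)
      batch_grads <- if (is.null(batch_grads)) res$grads
      else mapply(`+`, batch_grads, res$grads, SIMPLIFY = FALSE)
      batch_n <- batch_n + 1L
      if (batch_n == config$batchSize || i == ord[length(ord)]) {
        grads <- lapply(batch_grads, function(g) g / batch_n)
        upd <- adamw_update(params, grads, opt, config$lr, config$weightDecay,
                            config$clipNorm)
        params <- upd$params
        opt <- upd$state
        batch_grads <- NULL
        batch_n <- 0L
      }
    }
    log <- rbind(log, data.frame(epoch = epoch, loss_mean = mean(losses),
                                 loss_sd = stats::sd(losses)))
    if (verbose && (epoch %% 10L == 0L || epoch == 1L))
      log_msg("info", "epoch done", epoch = epoch,
              loss = sprintf("%.4f", mean(losses)))
    if (config$checkpointEvery > 0L && epoch %% config$checkpointEvery == 0L) {
      model@params <- params
      model@trainingLog <- log
      saveModel(model, file.path(config$checkpointDir,
                                 sprintf("denoiser_epoch%04d.rds", epoch)))
    }
  }
  model@params <- params
  model@trainingLog <- log
  model
}

#' Generate an edge-probability matrix from expression
#'
#' Runs `nEnsemble` independent reverse chains over the subsequence ladder
#' [makeSubsequence()]`(T, k)`, each starting from the stationary prior; at
#' the final reverse step the model's predicted clean-edge probabilities are
#' recorded and averaged across ensemble members.
#'
#' @param expr `cells x genes` expression matrix (columns named by gene).
#' @param model A trained [GRNDenoiser-class].
#' @param tfs Logical TF indicator defining the candidate-pair universe.
#' @param schedule Optional [NoiseSchedule-class]; defaults to the schedule
#'   fingerprint stored in the model. A schedule that contradicts the
#'   fingerprint is refused.
#' @param k Number of reverse steps (`k = T` is the full ladder).
#' @param nEnsemble Number of independent chains.
#' @param seed Integer seed.
#' @param deterministic Use posterior argmax instead of sampling within each
#'   chain.
#' @return `n x n` matrix of edge probabilities in `[0, 1]`; masked pairs 0.
#' @export
generateNetwork <- function(expr, model, tfs, schedule = NULL, k = NULL,
                            nEnsemble = 8L, seed = NULL,
                            deterministic = FALSE) {
  stopifnot(is(model, "GRNDenoiser"))
  if (is.null(schedule)) {
    assert_that(length(model@schedule) > 0,
                "model carries no schedule fingerprint; supply `schedule`")
    schedule <- cosineSchedule(model@schedule$nSteps, model@schedule$delta,
                               model@schedule$s)
  } else if (length(model@schedule) > 0) {
    ok <- schedule@nSteps == model@schedule$nSteps &&
      abs(schedule@delta - model@schedule$delta) < 1e-9
    assert_that(ok, paste0("schedule mismatch: the model was trained with T = ",
                           model@schedule$nSteps, ", delta = ",
                           signif(model@schedule$delta, 4)))
  }
  n <- ncol(expr)
  assert_that(length(tfs) == n, "tfs must have one entry per gene")
  Tn <- schedule@nSteps
  if (is.null(k)) k <- Tn
  tau <- makeSubsequence(Tn, k)
  mask <- candidatePairs(tfs)
  Xfeat <- nodeFeatures(expr, model@recipe$mProfile, seed = 1L)
  base <- if (is.null(seed)) sample.int(2147483000L, 1L) else as.integer(seed)
  acc <- matrix(0, n, n)
  for (m in seq_len(nEnsemble)) {
    et <- priorSample(mask, schedule, seed = substream_seed(base, m))
    p0 <- NULL
    for (step in rev(seq_len(k))) {
      t <- tau[step + 1L]
      tPrev <- tau[step]
      tape <- ad_tape()
      P <- wrap_params(model@params, tape, trainable = FALSE)
      fw <- denoiser_forward_ad(tape, P, model@hyper, Xfeat, et$states, mask, t)
      lmat <- fw$logits$val
      z <- lmat - apply(lmat, 1L, max)
      p1 <- exp(z[, 2]) / (exp(z[, 1]) + exp(z[, 2]))
      p0 <- matrix(p1, n, n)
      p0[!mask] <- 0
      if (tPrev == 0L && step == 1L) break
      et <- reverseStep(et, p0, t, tPrev, schedule,
                        seed = substream_seed(base, 1000L * m + step),
                        deterministic = deterministic)
    }
    acc <- acc + p0
  }
  probs <- acc / nEnsemble
  probs[!mask] <- 0
  dimnames(probs) <- list(colnames(expr), colnames(expr))
  probs
}

#' Threshold an edge-probability matrix into a GRN
#'
#' @param probs `n x n` probability matrix (gene names in dimnames).
#' @param tfs Logical TF indicator.
#' @param cutoff Probability cutoff; an edge is kept iff its probability
#'   strictly exceeds it.
#' @return A [GRN-class].
#' @export
thresholdNetwork <- function(probs, tfs, cutoff = 0.5) {
  assert_that(cutoff >= 0 && cutoff <= 1, "cutoff must lie in [0, 1]")
  mask <- candidatePairs(tfs)
  A <- (probs > cutoff) * mask
  gn <- colnames(probs)
  if (is.null(gn)) gn <- sprintf("g%03d", seq_len(ncol(probs)))
  GRN(gn, tfs, A)
}
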