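## Hybrid-attention graph-transformer denoiser: a time-gated two-layer GATv2 node encoder followed by L
## graph-transformer layers that jointly update node features X, edge
## features E and the time embedding t, emitting per-pair clean-edge logits.

#' Denoiser architecture hyperparameters
#'
#' @param dX,dE,dT Node, edge and time embedding widths.
#' @param L Number of graph-transformer layers.
#' @param headsGAT,headsNode,headsEdge,headsCross Attention head counts for
#'   the GATv2 encoder, node self-attention, pairwise edge scoring, and edge
#'   cross-attention.
#' @param dFF Feed-forward hidden width of the node branch.
#' @param lrSlope LeakyReLU negative slope.
#' @param mProfile Length of the per-gene expression profile fed to the node
#'   initializer (expression with a different cell count is aggregated to
#'   this many metacells first).
#' @param ablateG Replace the GATv2 encoder by a linear node projection.
#' @param ablateC Replace edge cross-attention by a pass-through of the
#'   self-attention edge proposal.
#' @param ablateP Replace the gated/attentive feature pooling of the time
#'   update by plain mean pooling.
#' @return Named list of validated hyperparameters.
#' @export
denoiserHyper <- function(dX = 64L, dE = 32L, dT = 64L, L = 3L,
                        headsGAT = 4L, headsNode = 4L, headsEdge = 4L,
                        headsCross = 2L, dFF = 2L * dX, lrSlope = 0.2,
                        mProfile = 100L,
                        ablateG = FALSE, ablateC = FALSE, ablateP = FALSE) {
  assert_that(dX %% headsGAT == 0 && dX %% headsNode == 0 &&
                dX %% headsEdge == 0,
              "dX must be divisible by headsGAT, headsNode and headsEdge")
  assert_that(dE %% headsCross == 0, "dE must be divisible by headsCross")
  assert_that(dT %% 2 == 0, "dT must be even (sinusoidal embedding)")
  list(dX = as.integer(dX), dE = as.integer(dE), dT = as.integer(dT),
       L = as.integer(L), headsGAT = as.integer(headsGAT),
       headsNode = as.integer(headsNode), headsEdge = as.integer(headsEdge),
       headsCross = as.integer(headsCross), dFF = as.integer(dFF),
       lrSlope = lrSlope, mProfile = as.integer(mProfile),
       ablateG = isTRUE(ablateG), ablateC = isTRUE(ablateC),
       ablateP = isTRUE(ablateP))
}

xavier <- function(nr, nc) {
  l <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -l, l), nr, nc)
}

zeros <- function(nr, nc) matrix(0, nr, nc)
ones <- function(nr, nc) matrix(1, nr, nc)

## Build the full named parameter list for a given architecture.
denoiser_init_params <- function(hyper, nFeat, seed = NULL) {
  with_seed(seed, {
    h <- hyper
    P <- list()
    P$in.W <- xavier(nFeat, h$dX); P$in.b <- zeros(1, h$dX)
    P$t.W1 <- xavier(h$dT, h$dT); P$t.b1 <- zeros(1, h$dT)
    P$t.W2 <- xavier(h$dT, h$dT); P$t.b2 <- zeros(1, h$dT)
    if (h$ablateG) {
      P$enc.W <- xavier(h$dX, h$dX); P$enc.b <- zeros(1, h$dX)
    } else {
      dG1 <- h$dX %/% h$headsGAT
      for (k in seq_len(h$headsGAT)) {
        P[[sprintf("gat1.h%d.Wl", k)]] <- xavier(h$dX, dG1)
        P[[sprintf("gat1.h%d.Wr", k)]] <- xavier(h$dX, dG1)
        P[[sprintf("gat1.h%d.a", k)]] <- xavier(dG1, 1)
        P[[sprintf("gat2.h%d.Wl", k)]] <- xavier(h$dX, h$dX)
        P[[sprintf("gat2.h%d.Wr", k)]] <- xavier(h$dX, h$dX)
        P[[sprintf("gat2.h%d.a", k)]] <- xavier(h$dX, 1)
      }
      P$gate.W <- xavier(h$dT, h$dX); P$gate.b <- zeros(1, h$dX)
      P$fuse.W <- xavier(2 * h$dX, h$dX); P$fuse.b <- zeros(1, h$dX)
    }
    P$emb.E <- xavier(3, h$dE)
    dN <- h$dX %/% h$headsNode
    dK <- h$dX %/% h$headsEdge
    dC <- h$dE %/% h$headsCross
    for (l in seq_len(h$L)) {
      pre <- sprintf("l%d.", l)
      for (k in seq_len(h$headsNode)) {
        P[[sprintf("%snsa.h%d.WQ", pre, k)]] <- xavier(h$dX, dN)
        P[[sprintf("%snsa.h%d.WK", pre, k)]] <- xavier(h$dX, dN)
        P[[sprintf("%snsa.h%d.WV", pre, k)]] <- xavier(h$dX, dN)
      }
      P[[paste0(pre, "nsa.WO")]] <- xavier(h$dX, h$dX)
      P[[paste0(pre, "nsa.bO")]] <- zeros(1, h$dX)
      P[[paste0(pre, "filmx.W1")]] <- xavier(h$dT, h$dX)
      P[[paste0(pre, "filmx.b1")]] <- zeros(1, h$dX)
      P[[paste0(pre, "filmx.W2")]] <- xavier(h$dT, h$dX)
      P[[paste0(pre, "filmx.b2")]] <- zeros(1, h$dX)
      P[[paste0(pre, "ln1.g")]] <- ones(1, h$dX)
      P[[paste0(pre, "ln1.b")]] <- zeros(1, h$dX)
      P[[paste0(pre, "ffn.W1")]] <- xavier(h$dX, h$dFF)
      P[[paste0(pre, "ffn.b1")]] <- zeros(1, h$dFF)
      P[[paste0(pre, "ffn.W2")]] <- xavier(h$dFF, h$dX)
      P[[paste0(pre, "ffn.b2")]] <- zeros(1, h$dX)
      P[[paste0(pre, "ln2.g")]] <- ones(1, h$dX)
      P[[paste0(pre, "ln2.b")]] <- zeros(1, h$dX)
      for (k in seq_len(h$headsEdge)) {
        P[[sprintf("%ses.h%d.WQ", pre, k)]] <- xavier(h$dX, dK)
        P[[sprintf("%ses.h%d.WK", pre, k)]] <- xavier(h$dX, dK)
      }
      ## nonlinear expansion of per-head pair scores into d_e channels: a
      ## hidden layer lets the edge stream respond symmetrically to scores
      ## of either sign (repression gives anti-correlated profiles)
      P[[paste0(pre, "es.W1")]] <- xavier(h$headsEdge, h$dE)
      P[[paste0(pre, "es.b1")]] <- zeros(1, h$dE)
      P[[paste0(pre, "es.W2")]] <- xavier(h$dE, h$dE)
      P[[paste0(pre, "es.b2")]] <- zeros(1, h$dE)
      P[[paste0(pre, "effn.W1")]] <- xavier(h$dE, 2L * h$dE)
      P[[paste0(pre, "effn.b1")]] <- zeros(1, 2L * h$dE)
      P[[paste0(pre, "effn.W2")]] <- xavier(2L * h$dE, h$dE)
      P[[paste0(pre, "effn.b2")]] <- zeros(1, h$dE)
      P[[paste0(pre, "lnE2.g")]] <- ones(1, h$dE)
      P[[paste0(pre, "lnE2.b")]] <- zeros(1, h$dE)
      P[[paste0(pre, "filme.W1")]] <- xavier(h$dT, h$dE)
      P[[paste0(pre, "filme.b1")]] <- zeros(1, h$dE)
      P[[paste0(pre, "filme.W2")]] <- xavier(h$dT, h$dE)
      P[[paste0(pre, "filme.b2")]] <- zeros(1, h$dE)
      if (!h$ablateC) {
        for (k in seq_len(h$headsCross)) {
          P[[sprintf("%sca.h%d.WQ", pre, k)]] <- xavier(h$dE, dC)
          P[[sprintf("%sca.h%d.WK", pre, k)]] <- xavier(h$dE, dC)
          P[[sprintf("%sca.h%d.WV", pre, k)]] <- xavier(h$dE, dC)
        }
        P[[paste0(pre, "ca.WO")]] <- xavier(h$dE, h$dE)
        P[[paste0(pre, "ca.bO")]] <- zeros(1, h$dE)
      }
      P[[paste0(pre, "lnE.g")]] <- ones(1, h$dE)
      P[[paste0(pre, "lnE.b")]] <- zeros(1, h$dE)
      if (l == h$L) next   # no time update after the last layer
      P[[paste0(pre, "tt.W")]] <- xavier(h$dT, h$dT)
      P[[paste0(pre, "tt.b")]] <- zeros(1, h$dT)
      if (h$ablateP) {
        P[[paste0(pre, "mp.Wx")]] <- xavier(h$dX, h$dT)
        P[[paste0(pre, "mp.We")]] <- xavier(h$dE, h$dT)
        P[[paste0(pre, "mp.b")]] <- zeros(1, h$dT)
      } else {
        P[[paste0(pre, "gpool.Wg")]] <- xavier(h$dX, h$dX)
        P[[paste0(pre, "gpool.bg")]] <- zeros(1, h$dX)
        P[[paste0(pre, "gpool.Wlin")]] <- xavier(h$dX, h$dT)
        P[[paste0(pre, "gpool.blin")]] <- zeros(1, h$dT)
        P[[paste0(pre, "apool.q")]] <- xavier(h$dE, 1)
        P[[paste0(pre, "apool.W")]] <- xavier(h$dE, h$dT)
        P[[paste0(pre, "apool.b")]] <- zeros(1, h$dT)
      }
    }
    P$out.W <- xavier(h$dE, 2); P$out.b <- zeros(1, 2)
    P
  })
}

#' Initialize an untrained denoiser
#'
#' @param hyper A [denoiserHyper()] list.
#' @param schedule A [NoiseSchedule-class] the model will be bound to.
#' @param seed Integer seed for parameter initialization.
#' @return A [GRNDenoiser-class].
#' @export
denoiserInit <- function(hyper = denoiserHyper(), schedule = NULL, seed = NULL) {
  nFeat <- hyper$mProfile + 6L
  params <- denoiser_init_params(hyper, nFeat, seed)
  sched <- if (is.null(schedule)) list() else
    list(nSteps = schedule@nSteps, delta = schedule@delta, s = schedule@s)
  new("GRNDenoiser", params = params, hyper = hyper,
      recipe = list(mProfile = hyper$mProfile, nFeat = nFeat,
                    summaries = c("mean", "sd", "dropout", "q10", "q50", "q90")),
      schedule = sched,
      trainingLog = data.frame(epoch = integer(), loss_mean = numeric(),
                               loss_sd = numeric()))
}

sinusoid_embedding <- function(t, d) {
  half <- d %/% 2
  freqs <- 10000^(-(seq_len(half) - 1) / half)
  matrix(c(sin(t * freqs), cos(t * freqs)), 1L, d)
}

#' Derive node features from an expression matrix
#'
#' Each gene is summarized by its standardized expression profile across
#' (meta)cells, concatenated with six marginal statistics (mean, sd, dropout
#' fraction, and the 10/50/90 percent quantiles, z-scored across genes).
#' Expression whose cell count differs from `mProfile` is aggregated to
#' `mProfile` metacells first. Every step is per-gene or symmetric across
#' genes, making the whole forward pass equivariant to gene permutations.
#'
#' @param expr `cells x genes` nonnegative matrix.
#' @param mProfile Target profile length.
#' @param seed Seed for the metacell aggregation, if needed.
#' @return `genes x (mProfile + 6)` feature matrix.
#' @export
nodeFeatures <- function(expr, mProfile, seed = NULL) {
  assert_that(is.matrix(expr) && all(expr >= 0),
              "expression must be a nonnegative cells x genes matrix")
  nc <- nrow(expr)
  M <- if (nc == mProfile) expr
  else if (nc > mProfile) metacellAggregate(expr, mProfile, seed = seed)
  else expr[rep(seq_len(nc), length.out = mProfile), , drop = FALSE]
  mu <- colMeans(M)
  sd <- apply(M, 2L, stats::sd)
  prof <- (t(M) - mu) / ifelse(sd > 1e-12, sd, 1)      # genes x mProfile
  summ <- cbind(mean = colMeans(expr),
                sd = apply(expr, 2L, stats::sd),
                dropout = colMeans(expr <= 1e-12),
                q10 = apply(expr, 2L, stats::quantile, 0.10),
                q50 = apply(expr, 2L, stats::quantile, 0.50),
                q90 = apply(expr, 2L, stats::quantile, 0.90))
  smu <- colMeans(summ)
  ssd <- apply(summ, 2L, stats::sd)
  summ <- t((t(summ) - smu) / ifelse(ssd > 1e-12, ssd, 1))
  out <- cbind(prof, summ)
  rownames(out) <- colnames(expr)
  out
}

film_apply <- function(tape, temb, b, W1, b1, W2, b2) {
  lin1 <- ad_linear(tape, temb, W1, b1)
  lin2 <- ad_linear(tape, temb, W2, b2)
  ad_add_rowvec(tape, ad_add(tape, ad_mul_rowvec(tape, b, lin2), b), lin1)
}

gatv2_layer_ad <- function(tape, X, P, prefix, heads, addmask, iofp, jofp,
                           slope, combine = c("concat", "mean"),
                           collect = NULL) {
  combine <- match.arg(combine)
  n <- nrow(X$val)
  outs <- vector("list", heads)
  for (k in seq_len(heads)) {
    Wl <- P[[sprintf("%s.h%d.Wl", prefix, k)]]
    Wr <- P[[sprintf("%s.h%d.Wr", prefix, k)]]
    a <- P[[sprintf("%s.h%d.a", prefix, k)]]
    U <- ad_mm(tape, X, Wl)
    V <- ad_mm(tape, X, Wr)
    Up <- ad_gather(tape, U, iofp)
    Vp <- ad_gather(tape, V, jofp)
    sc <- ad_mm(tape, ad_lrelu(tape, ad_add(tape, Up, Vp), slope), a)
    S <- ad_reshape(tape, sc, n, n)          # S[i, j] = score of pair (i, j)
    A <- ad_row_softmax(tape, S, addmask)    # attention of i over neighbors j
    if (!is.null(collect))
      collect$gat[[length(collect$gat) + 1L]] <- A$val
    outs[[k]] <- ad_mm(tape, A, V)
  }
  if (combine == "concat") {
    H <- outs[[1L]]
    for (k in seq_len(heads)[-1L]) H <- ad_cbind2(tape, H, outs[[k]])
  } else {
    H <- outs[[1L]]
    for (k in seq_len(heads)[-1L]) H <- ad_add(tape, H, outs[[k]])
    H <- ad_smul(tape, H, 1 / heads)
  }
  H
}

## Core forward pass on an explicit tape; P is a named list of ad nodes.
## Returns the logits node (n^2 x 2, column-major pair order p = i + (j-1)n)
## plus bookkeeping. `collect` (an environment) gathers softmax matrices for
## structural tests when supplied.
denoiser_forward_ad <- function(tape, P, hyper, Xfeat, Et, mask, t,
                              collect = NULL) {
  h <- hyper
  n <- nrow(Xfeat)
  Et <- Et * mask          # masked pairs must not contribute anywhere
  iofp <- rep(seq_len(n), times = n)
  jofp <- rep(seq_len(n), each = n)
  revidx <- jofp + (iofp - 1L) * n
  cand <- as.vector(mask)
  if (!is.null(collect)) { collect$gat <- list(); collect$nsa <- list()
                           collect$cross <- list(); collect$atte <- list() }

  tvec <- ad_const(sinusoid_embedding(t, h$dT))
  temb <- ad_linear(tape, ad_lrelu(tape, ad_linear(tape, tvec, P$t.W1, P$t.b1),
                                   h$lrSlope), P$t.W2, P$t.b2)
  X0 <- ad_linear(tape, ad_const(Xfeat), P$in.W, P$in.b)

  if (h$ablateG) {
    X <- ad_lrelu(tape, ad_linear(tape, X0, P$enc.W, P$enc.b), h$lrSlope)
  } else {
    NB <- (Et == 1) | (t(Et) == 1); diag(NB) <- TRUE
    addmask <- ifelse(NB, 0, -1e9)
    H1 <- ad_lrelu(tape, gatv2_layer_ad(tape, X0, P, "gat1", h$headsGAT,
                                        addmask, iofp, jofp, h$lrSlope,
                                        "concat", collect), h$lrSlope)
    Hp <- gatv2_layer_ad(tape, H1, P, "gat2", h$headsGAT, addmask, iofp,
                         jofp, h$lrSlope, "mean", collect)
    g <- ad_sigmoid(tape, ad_linear(tape, temb, P$gate.W, P$gate.b))
    gInv <- ad_sadd(tape, ad_smul(tape, g, -1), 1)
    Ht <- ad_add(tape, ad_mul_rowvec(tape, Hp, gInv),
                 ad_mul_rowvec(tape, X0, g))
    X <- ad_lrelu(tape, ad_linear(tape, ad_cbind2(tape, Ht, X0),
                                  P$fuse.W, P$fuse.b), h$lrSlope)
  }

  stateIdx <- ifelse(!cand, 3L, as.integer(as.vector(Et)) + 1L)
  E <- ad_gather(tape, P$emb.E, stateIdx)

  dN <- h$dX %/% h$headsNode
  dK <- h$dX %/% h$headsEdge
  dC <- h$dE %/% h$headsCross
  candRow <- matrix(ifelse(cand, 0, -1e9), 1L, n * n)

  for (l in seq_len(h$L)) {
    pre <- sprintf("l%d.", l)
    ## --- node self-attention + FiLM + residual/LN + FFN -------------------
    heads <- vector("list", h$headsNode)
    for (k in seq_len(h$headsNode)) {
      Q <- ad_mm(tape, X, P[[sprintf("%snsa.h%d.WQ", pre, k)]])
      K <- ad_mm(tape, X, P[[sprintf("%snsa.h%d.WK", pre, k)]])
      V <- ad_mm(tape, X, P[[sprintf("%snsa.h%d.WV", pre, k)]])
      S <- ad_smul(tape, ad_mm(tape, Q, ad_t(tape, K)), 1 / sqrt(dN))
      A <- ad_row_softmax(tape, S)
      if (!is.null(collect)) collect$nsa[[length(collect$nsa) + 1L]] <- A$val
      heads[[k]] <- ad_mm(tape, A, V)
    }
    O <- heads[[1L]]
    for (k in seq_len(h$headsNode)[-1L]) O <- ad_cbind2(tape, O, heads[[k]])
    O <- ad_linear(tape, O, P[[paste0(pre, "nsa.WO")]],
                   P[[paste0(pre, "nsa.bO")]])
    Fx <- film_apply(tape, temb, O,
                     P[[paste0(pre, "filmx.W1")]], P[[paste0(pre, "filmx.b1")]],
                     P[[paste0(pre, "filmx.W2")]], P[[paste0(pre, "filmx.b2")]])
    Xmid <- ad_layernorm(tape, ad_add(tape, X, Fx),
                         P[[paste0(pre, "ln1.g")]], P[[paste0(pre, "ln1.b")]])
    FF <- ad_linear(tape,
                    ad_lrelu(tape, ad_linear(tape, Xmid,
                                             P[[paste0(pre, "ffn.W1")]],
                                             P[[paste0(pre, "ffn.b1")]]),
                             h$lrSlope),
                    P[[paste0(pre, "ffn.W2")]], P[[paste0(pre, "ffn.b2")]])
    Xhat <- ad_layernorm(tape, ad_add(tape, Xmid, FF),
                         P[[paste0(pre, "ln2.g")]], P[[paste0(pre, "ln2.b")]])

    ## --- edge update: pairwise scores + FiLM'd feedback + cross-attention -
    svec <- vector("list", h$headsEdge)
    for (k in seq_len(h$headsEdge)) {
      q <- ad_mm(tape, Xhat, P[[sprintf("%ses.h%d.WQ", pre, k)]])
      kk <- ad_mm(tape, Xhat, P[[sprintf("%ses.h%d.WK", pre, k)]])
      svec[[k]] <- ad_smul(tape,
                           ad_rowdot(tape, ad_gather(tape, q, iofp),
                                     ad_gather(tape, kk, jofp)),
                           1 / sqrt(dK))
    }
    Sh <- svec[[1L]]
    for (k in seq_len(h$headsEdge)[-1L]) Sh <- ad_cbind2(tape, Sh, svec[[k]])
    Eself <- ad_linear(tape,
                       ad_lrelu(tape, ad_linear(tape, Sh,
                                                P[[paste0(pre, "es.W1")]],
                                                P[[paste0(pre, "es.b1")]]),
                                h$lrSlope),
                       P[[paste0(pre, "es.W2")]], P[[paste0(pre, "es.b2")]])
    Efeed <- film_apply(tape, temb, E,
                        P[[paste0(pre, "filme.W1")]], P[[paste0(pre, "filme.b1")]],
                        P[[paste0(pre, "filme.W2")]], P[[paste0(pre, "filme.b2")]])
    if (h$ablateC) {
      Epre <- Eself
    } else {
      couts <- vector("list", h$headsCross)
      for (k in seq_len(h$headsCross)) {
        Qc <- ad_mm(tape, Eself, P[[sprintf("%sca.h%d.WQ", pre, k)]])
        K1 <- ad_mm(tape, Efeed, P[[sprintf("%sca.h%d.WK", pre, k)]])
        V1 <- ad_mm(tape, Efeed, P[[sprintf("%sca.h%d.WV", pre, k)]])
        K2 <- ad_gather(tape, K1, revidx)
        V2 <- ad_gather(tape, V1, revidx)
        s1 <- ad_smul(tape, ad_rowdot(tape, Qc, K1), 1 / sqrt(dC))
        s2 <- ad_smul(tape, ad_rowdot(tape, Qc, K2), 1 / sqrt(dC))
        W <- ad_row_softmax(tape, ad_cbind2(tape, s1, s2))
        if (!is.null(collect))
          collect$cross[[length(collect$cross) + 1L]] <- W$val
        couts[[k]] <- ad_add(tape,
                             ad_mul_colvec(tape, V1,
                                           ad_slice_cols(tape, W, 1L)),
                             ad_mul_colvec(tape, V2,
                                           ad_slice_cols(tape, W, 2L)))
      }
      CO <- couts[[1L]]
      for (k in seq_len(h$headsCross)[-1L]) CO <- ad_cbind2(tape, CO, couts[[k]])
      CO <- ad_linear(tape, CO, P[[paste0(pre, "ca.WO")]],
                      P[[paste0(pre, "ca.bO")]])
      Epre <- ad_add(tape, Eself, CO)
    }
    Ehat <- ad_layernorm(tape, Epre, P[[paste0(pre, "lnE.g")]],
                         P[[paste0(pre, "lnE.b")]])
    EFF <- ad_linear(tape,
                     ad_lrelu(tape, ad_linear(tape, Ehat,
                                              P[[paste0(pre, "effn.W1")]],
                                              P[[paste0(pre, "effn.b1")]]),
                              h$lrSlope),
                     P[[paste0(pre, "effn.W2")]], P[[paste0(pre, "effn.b2")]])
    Ehat <- ad_layernorm(tape, ad_add(tape, Ehat, EFF),
                         P[[paste0(pre, "lnE2.g")]], P[[paste0(pre, "lnE2.b")]])

    ## --- time update (skipped at the last layer: its output would be
    ## unused, and parameters must all sit on the gradient path) -----------
    if (l == h$L) { X <- Xhat; E <- Ehat; break }
    base <- ad_linear(tape, temb, P[[paste0(pre, "tt.W")]],
                      P[[paste0(pre, "tt.b")]])
    if (h$ablateP) {
      px <- ad_smul(tape, ad_colsum(tape, Xhat), 1 / n)
      Ecand <- ad_gather(tape, Ehat, which(cand))
      pe <- ad_smul(tape, ad_colsum(tape, Ecand), 1 / max(1L, sum(cand)))
      that <- ad_add_rowvec(tape,
                            ad_add(tape, base,
                                   ad_add(tape,
                                          ad_mm(tape, px, P[[paste0(pre, "mp.Wx")]]),
                                          ad_mm(tape, pe, P[[paste0(pre, "mp.We")]]))),
                            P[[paste0(pre, "mp.b")]])
    } else {
      gates <- ad_sigmoid(tape, ad_linear(tape, Xhat,
                                          P[[paste0(pre, "gpool.Wg")]],
                                          P[[paste0(pre, "gpool.bg")]]))
      pooled <- ad_colsum(tape, ad_mul(tape, gates, Xhat))
      gp <- ad_linear(tape, pooled, P[[paste0(pre, "gpool.Wlin")]],
                      P[[paste0(pre, "gpool.blin")]])
      sc <- ad_t(tape, ad_mm(tape, Ehat, P[[paste0(pre, "apool.q")]]))
      w <- ad_row_softmax(tape, sc, candRow)
      if (!is.null(collect))
        collect$atte[[length(collect$atte) + 1L]] <- w$val
      pe <- ad_mm(tape, w, Ehat)
      ae <- ad_linear(tape, pe, P[[paste0(pre, "apool.W")]],
                      P[[paste0(pre, "apool.b")]])
      that <- ad_add(tape, ad_add(tape, base, gp), ae)
    }
    X <- Xhat; E <- Ehat; temb <- that
  }

  if (!is.null(collect)) collect$edgeFeatures <- E$val
  logits <- ad_linear(tape, E, P$out.W, P$out.b)
  sentinel <- cbind(0, ifelse(cand, 0, -1e9))
  logits <- ad_sadd(tape, logits, sentinel)
  list(logits = logits, n = n, cand = cand)
}

## Wrap plain parameter matrices as tape leaves (trainable or frozen).
wrap_params <- function(params, tape, trainable = TRUE) {
  if (trainable) lapply(params, ad_param, tape = tape)
  else lapply(params, ad_const)
}

#' Run the denoiser forward
#'
#' Produces per-ordered-pair two-class logits (no-edge, edge) for the clean
#' network given a noisy edge state, the conditioning expression matrix and
#' the diffusion step. Deterministic given parameters and inputs; masked
#' pairs carry a large negative edge logit (probability ~0).
#'
#' @param model A [GRNDenoiser-class].
#' @param et Edge state (see [edgeState()]).
#' @param expr `cells x genes` expression matrix; column order must match the
#'   edge-state gene order.
#' @param t Integer diffusion step.
#' @param returnInternals Also return attention matrices for inspection.
#' @return List with `logits` (`n x n x 2` array), `p0` (`n x n` matrix of
#'   predicted clean-edge probabilities, masked pairs 0), and optionally
#'   `internals`.
#' @export
denoiserForward <- function(model, et, expr, t, returnInternals = FALSE) {
  stopifnot(is(model, "GRNDenoiser"))
  n <- nrow(et$states)
  assert_that(ncol(expr) == n,
              sprintf("gene-order mismatch: expression has %d genes but the edge state has %d",
                      ncol(expr), n))
  if (!is.null(colnames(expr)) && !is.null(rownames(et$states)))
    assert_that(identical(colnames(expr), rownames(et$states)),
                "gene-order mismatch between expression and edge state")
  Xfeat <- nodeFeatures(expr, model@recipe$mProfile, seed = 1L)
  tape <- ad_tape()
  P <- wrap_params(model@params, tape, trainable = FALSE)
  collect <- if (returnInternals) new.env(parent = emptyenv()) else NULL
  fw <- denoiser_forward_ad(tape, P, model@hyper, Xfeat, et$states, et$mask, t,
                          collect = collect)
  lmat <- fw$logits$val
  logits <- array(0, dim = c(n, n, 2))
  logits[, , 1] <- matrix(lmat[, 1], n, n)
  logits[, , 2] <- matrix(lmat[, 2], n, n)
  z <- lmat - apply(lmat, 1L, max)
  p1 <- exp(z[, 2]) / (exp(z[, 1]) + exp(z[, 2]))
  p0 <- matrix(p1, n, n)
  p0[!et$mask] <- 0
  out <- list(logits = logits, p0 = p0)
  if (returnInternals) out$internals <- as.list(collect)
  out
}

#' Save / load a denoiser checkpoint
#'
#' The checkpoint is a single RDS file holding the full model object
#' (parameters, hyperparameters, feature recipe, schedule fingerprint,
#' training log); the round trip is bit-exact. `writeModelHeader` writes the
#' non-parameter metadata alongside as JSON for external tooling.
#'
#' @param model A [GRNDenoiser-class].
#' @param path File path.
#' @return `saveModel` the path invisibly; `loadModel` the model.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "GRNDenoiser"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  assert_that(is(model, "GRNDenoiser"), "file does not contain a GRNDenoiser")
  model
}

#' @rdname saveModel
#' @export
writeModelHeader <- function(model, path) {
  jsonlite::write_json(list(hyper = model@hyper, recipe = model@recipe,
                            schedule = model@schedule),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
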