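## Ranking metrics over candidate pairs, benchmark and ablation harnesses.

#' Area under the ROC curve (mid-rank tie convention)
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return AUROC in `[0, 1]`, or `NA` if one class is absent.
#' @export
aurocScore <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision with tied scores grouped, so permuting
#' equal-scored pairs cannot change the value.
#'
#' @inheritParams aurocScore
#' @return AUPRC in `[0, 1]`, or `NA` if there are no positives.
#' @export
auprcScore <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)   # end of each tie group
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  recall <- tp / n1
  dR <- diff(c(0, recall))
  sum(dR * prec)
}

#' F1 score at a probability cutoff
#'
#' @inheritParams aurocScore
#' @param cutoff Scores strictly above it are called edges.
#' @return F1 in `[0, 1]` (0 when precision + recall is 0).
#' @export
f1Score <- function(scores, labels, cutoff = 0.5) {
  pred <- scores > cutoff
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Score a predicted edge-probability matrix against a ground-truth GRN
#'
#' Ranks the candidate ordered pairs (TF source, non-self) of the truth's
#' universe. A truth with zero positive edges yields `NA` AUPRC with a
#' warning.
#'
#' @param probs `n x n` probability matrix.
#' @param truth A [GRN-class].
#' @param cutoff F1 cutoff.
#' @return Named list with `auroc`, `auprc`, `f1`, `f1_best` (best F1 along
#'   the precision-recall curve, labeled as such), and `n_pairs`.
#' @export
scoreNetwork <- function(probs, truth, cutoff = 0.5) {
  stopifnot(is(truth, "GRN"))
  mask <- candidateMask(truth)
  assert_that(all(dim(probs) == dim(mask)),
              "probability matrix and truth must share the gene universe")
  s <- probs[mask]
  y <- adjacency(truth)[mask]
  if (sum(y) == 0) warning("truth has zero positive edges; AUPRC undefined")
  f1b <- {
    cuts <- sort(unique(s))
    if (length(cuts) > 200) cuts <- stats::quantile(s, seq(0, 1, length.out = 200))
    max(vapply(cuts, function(cc) f1Score(s, y, cc), numeric(1)), 0)
  }
  list(auroc = aurocScore(s, y), auprc = auprcScore(s, y),
       f1 = f1Score(s, y, cutoff), f1_best = f1b, n_pairs = length(y))
}

#' Absolute-correlation baseline
#'
#' `|Pearson r|` between each candidate (TF, target) pair's expression,
#' min-max scaled to `[0, 1]` over the candidate universe. Pairs involving a
#' zero-variance gene score 0.
#'
#' @param expr `cells x genes` matrix (>= 3 cells).
#' @param tfs Logical TF indicator.
#' @return `n x n` score matrix; masked pairs 0.
#' @export
pccBaseline <- function(expr, tfs) {
  assert_that(nrow(expr) >= 3, "at least 3 cells are required")
  n <- ncol(expr)
  sds <- apply(expr, 2L, stats::sd)
  ok <- sds > 1e-12
  C <- matrix(0, n, n)
  if (sum(ok) >= 2) {
    cc <- abs(stats::cor(expr[, ok, drop = FALSE]))
    C[ok, ok] <- cc
  }
  mask <- candidatePairs(tfs)
  scale_candidates(C, mask)
}

#' Mutual-information baseline
#'
#' Histogram mutual information with 8 equal-frequency bins per gene,
#' min-max scaled to `[0, 1]` over the candidate universe.
#'
#' @inheritParams pccBaseline
#' @param nBins Number of equal-frequency bins.
#' @return `n x n` score matrix; masked pairs 0.
#' @export
miBaseline <- function(expr, tfs, nBins = 8L) {
  assert_that(nrow(expr) >= 3, "at least 3 cells are required")
  n <- ncol(expr)
  nc <- nrow(expr)
  bins <- lapply(seq_len(n), function(j) {
    v <- expr[, j]
    if (stats::sd(v) <= 1e-12) return(NULL)
    br <- unique(stats::quantile(v, seq(0, 1, length.out = nBins + 1)))
    if (length(br) < 3) return(NULL)
    as.integer(cut(v, br, include.lowest = TRUE))
  })
  M <- matrix(0, n, n)
  mask <- candidatePairs(tfs)
  for (i in which(tfs)) {
    if (is.null(bins[[i]])) next
    for (j in seq_len(n)) {
      if (j == i || is.null(bins[[j]]) || !mask[i, j]) next
      tab <- table(bins[[i]], bins[[j]]) / nc
      px <- rowSums(tab); py <- colSums(tab)
      nz <- tab > 0
      M[i, j] <- sum(tab[nz] * log(tab[nz] / outer(px, py)[nz]))
    }
  }
  scale_candidates(M, mask)
}

scale_candidates <- function(S, mask) {
  v <- S[mask]
  rng <- range(v)
  out <- matrix(0, nrow(S), ncol(S))
  if (diff(rng) > 1e-300) out[mask] <- (v - rng[1]) / diff(rng)
  dimnames(out) <- dimnames(S)
  out
}

#' Benchmark a trained model (and baselines) on a test suite
#'
#' @param suite List of held-out `list(grn, expr)` pairs.
#' @param model A trained [GRNDenoiser-class].
#' @param baselines Character subset of `c("pcc", "mi")`.
#' @param schedule Optional schedule passed to [generateNetwork()].
#' @param k,nEnsemble,seed,cutoff Generation and scoring settings.
#' @return A [MetricReport-class] with one row per (method, dataset).
#' @export
runBenchmark <- function(suite, model, baselines = c("pcc", "mi"),
                         schedule = NULL, k = NULL, nEnsemble = 8L,
                         seed = 1L, cutoff = 0.5) {
  rows <- list()
  for (d in seq_along(suite)) {
    pair <- suite[[d]]
    ds <- names(suite)[d] %||% sprintf("dataset%02d", d)
    tfs <- tfMask(pair$grn)
    methods <- list()
    if (!is.null(model))
      methods$model <- generateNetwork(pair$expr, model, tfs,
                                       schedule = schedule, k = k,
                                       nEnsemble = nEnsemble,
                                       seed = substream_seed(seed, d))
    if ("pcc" %in% baselines) methods$pcc <- pccBaseline(pair$expr, tfs)
    if ("mi" %in% baselines) methods$mi <- miBaseline(pair$expr, tfs)
    for (nm in names(methods)) {
      sc <- scoreNetwork(methods[[nm]], pair$grn, cutoff)
      rows[[length(rows) + 1L]] <-
        data.frame(method = nm, dataset = ds, auroc = sc$auroc,
                   auprc = sc$auprc, f1 = sc$f1)
    }
  }
  new("MetricReport", table = do.call(rbind, rows),
      metadata = list(seed = seed, k = k, nEnsemble = nEnsemble,
                      cutoff = cutoff,
                      model = if (is.null(model)) NA_character_
                      else object_fingerprint(model@hyper)))
}

#' Train-and-evaluate ablation variants
#'
#' Each requested variant retrains the architecture from scratch with the
#' named modules removed (`G` = GATv2 encoder replaced by a linear
#' projection, `C` = cross-attention pass-through, `P` = mean pooling) under
#' identical data and seeds, then evaluates on the test suite. An empty
#' variant string `""` denotes the full model.
#'
#' @param suiteTrain,suiteTest Training and held-out `list(grn, expr)` lists.
#' @param variants Character vector of module subsets, e.g.
#'   `c("", "G", "GCP")`.
#' @param config A [trainConfig()].
#' @param k,nEnsemble,seed Evaluation settings.
#' @return A [MetricReport-class] with one method row per variant
#'   (`"full"` for the empty subset, otherwise `"wo_<modules>"`).
#' @export
runAblation <- function(suiteTrain, suiteTest, variants = c("", "GCP"),
                        config = trainConfig(), k = NULL, nEnsemble = 8L,
                        seed = 1L) {
  tabs <- list()
  for (v in variants) {
    mods <- strsplit(toupper(v), "")[[1]]
    hy <- config$hyper
    hy$ablateG <- "G" %in% mods
    hy$ablateC <- "C" %in% mods
    hy$ablateP <- "P" %in% mods
    cfg <- config
    cfg$hyper <- do.call(denoiserHyper, hy)
    mod <- trainModel(suiteTrain, cfg)
    rep <- runBenchmark(suiteTest, mod, baselines = character(0), k = k,
                        nEnsemble = nEnsemble, seed = seed)
    tb <- reportTable(rep)
    tb$method <- if (v == "") "full" else paste0("wo_", v)
    tabs[[length(tabs) + 1L]] <- tb
  }
  new("MetricReport", table = do.call(rbind, tabs),
      metadata = list(seed = seed, k = k, nEnsemble = nEnsemble,
                      variants = variants,
                      data = object_fingerprint(lapply(suiteTrain, function(p)
                        sum(adjacency(p$grn))))))
}

#' Regulatory-intensity summary across conditions
#'
#' Per condition and TF: regulatory intensity (sum of outgoing edge
#' probabilities) and out-degree at a cutoff; across conditions: the
#' per-gene variance of intensity; and the pairwise overlap of top-`topK`
#' hub TFs.
#'
#' @param probsList Named list of `n x n` edge-probability matrices sharing
#'   a gene universe.
#' @param tfs Logical TF indicator.
#' @param cutoff Out-degree cutoff.
#' @param topK Number of hub TFs per condition.
#' @return List with `intensity` (TF x condition matrix), `outDegree`
#'   (TF x condition), `variance` (per-gene intensity variance, 0 for a
#'   single condition), `hubs` (list of top-`topK` TF names), and `overlap`
#'   (condition x condition hub-overlap counts).
#' @export
regulatorySummary <- function(probsList, tfs, cutoff = 0.5, topK = 10L) {
  assert_that(length(probsList) >= 1L, "at least one condition is required")
  n <- ncol(probsList[[1]])
  assert_that(all(vapply(probsList, function(p) all(dim(p) == n), logical(1))),
              "all conditions must share the gene universe")
  if (is.null(names(probsList)))
    names(probsList) <- sprintf("condition%02d", seq_along(probsList))
  mask <- candidatePairs(tfs)
  gn <- colnames(probsList[[1]]) %||% sprintf("g%03d", seq_len(n))
  intensity <- vapply(probsList, function(p) rowSums(p * mask), numeric(n))
  outDeg <- vapply(probsList, function(p) rowSums((p > cutoff) * mask),
                   numeric(n))
  rownames(intensity) <- rownames(outDeg) <- gn
  variance <- if (length(probsList) == 1L) stats::setNames(numeric(n), gn)
  else apply(intensity, 1L, stats::var)
  hubs <- lapply(seq_along(probsList), function(cidx) {
    tfNames <- gn[tfs]
    iv <- intensity[tfs, cidx]
    tfNames[order(iv, decreasing = TRUE)][seq_len(min(topK, sum(tfs)))]
  })
  names(hubs) <- names(probsList)
  nc <- length(probsList)
  overlap <- matrix(0L, nc, nc, dimnames = list(names(probsList),
                                                names(probsList)))
  for (a in seq_len(nc)) for (b in seq_len(nc))
    overlap[a, b] <- length(intersect(hubs[[a]], hubs[[b]]))
  list(intensity = intensity[tfs, , drop = FALSE],
       outDegree = outDeg[tfs, , drop = FALSE],
       variance = variance, hubs = hubs, overlap = overlap)
}

#' Write a metric report as TSV and JSON
#'
#' @param report A [MetricReport-class].
#' @param prefix Output path prefix (writes `<prefix>.tsv` and
#'   `<prefix>.json`).
#' @return The two paths, invisibly.
#' @export
writeReport <- function(report, prefix) {
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  utils::write.table(reportTable(report), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(table = reportTable(report),
                            means = reportMeans(report),
                            metadata = report@metadata),
                       json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(tsv, json))
}
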