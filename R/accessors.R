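#' Accessors for GRN objects
#'
#' @param x A [GRN-class] object.
#' @return `genes` the gene identifiers; `tfMask` the logical TF indicator;
#'   `adjacency` the binary adjacency matrix; `nGenes`/`nEdges` counts;
#'   `candidateMask` the logical matrix of candidate ordered pairs
#'   (TF source, non-self) over which diffusion, training and evaluation
#'   operate.
#' @name GRN-accessors
NULL

#' @rdname GRN-accessors
#' @export
setMethod("genes", "GRN", function(x) x@genes)

#' @rdname GRN-accessors
#' @export
setMethod("tfMask", "GRN", function(x) x@tfMask)

#' @rdname GRN-accessors
#' @export
setMethod("adjacency", "GRN", function(x) x@adjacency)

#' @rdname GRN-accessors
#' @export
setMethod("nGenes", "GRN", function(x) length(x@genes))

#' @rdname GRN-accessors
#' @export
setMethod("nEdges", "GRN", function(x) as.integer(sum(x@adjacency)))

#' Candidate ordered-pair mask for a TF mask
#'
#' All ordered (source, target) pairs with a TF source and distinct genes.
#'
#' @param tfs Logical TF indicator vector.
#' @return Logical `n x n` matrix.
#' @export
candidatePairs <- function(tfs) {
  n <- length(tfs)
  m <- matrix(tfs, n, n)
  diag(m) <- FALSE
  m
}

#' @rdname GRN-accessors
#' @export
setMethod("candidateMask", "GRN", function(x) candidatePairs(x@tfMask))

setMethod("show", "GRN", function(object) {
  cat(sprintf("GRN with %d genes (%d TFs), %d directed edges\n",
              nGenes(object), sum(object@tfMask), nEdges(object)))
  cat(sprintf("  candidate pairs: %d, edge density: %.3f\n",
              sum(candidateMask(object)),
              nEdges(object) / max(1, sum(candidateMask(object)))))
})

#' Accessors for NoiseSchedule objects
#'
#' @param x A [NoiseSchedule-class] object.
#' @return `nSteps` the number of diffusion steps `T`; `priorDelta` the
#'   stationary no-edge probability; `priorMatrix` the 2x2 prior matrix `S`
#'   with both rows `(delta, 1 - delta)`.
#' @name NoiseSchedule-accessors
NULL

#' @rdname NoiseSchedule-accessors
#' @export
setMethod("nSteps", "NoiseSchedule", function(x) x@nSteps)

#' @rdname NoiseSchedule-accessors
#' @export
setMethod("priorDelta", "NoiseSchedule", function(x) x@delta)

#' @rdname NoiseSchedule-accessors
#' @export
setMethod("priorMatrix", "NoiseSchedule", function(x) {
  d <- x@delta
  matrix(c(d, d, 1 - d, 1 - d), 2, 2)
})

setMethod("show", "NoiseSchedule", function(object) {
  cat(sprintf("NoiseSchedule: T = %d, delta = %.4f (cosine, s = %g)\n",
              object@nSteps, object@delta, object@s))
  cat(sprintf("  gammaBar: 0 -> %.6f\n", object@gammaBar[object@nSteps + 1L]))
})

setMethod("show", "GRNDenoiser", function(object) {
  h <- object@hyper
  cat(sprintf("GRNDenoiser: %d transformer layers, d_x=%d d_e=%d d_t=%d\n",
              h$L, h$dX, h$dE, h$dT))
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf("  %d parameter tensors, %d scalar parameters\n",
              length(object@params), np))
  if (nrow(object@trainingLog))
    cat(sprintf("  trained %d epochs, final mean loss %.4f\n",
                max(object@trainingLog$epoch),
                utils::tail(object@trainingLog$loss_mean, 1)))
  abl <- unlist(h[c("ablateG", "ablateC", "ablateP")])
  if (any(abl)) cat(sprintf("  ablated modules: %s\n",
                            paste(c("G", "C", "P")[abl], collapse = ",")))
})

#' Accessors for MetricReport objects
#'
#' @param x A [MetricReport-class] object.
#' @return `reportTable` the per-dataset table; `reportMeans` a data.frame of
#'   per-method means and standard deviations across datasets.
#' @name MetricReport-accessors
NULL

#' @rdname MetricReport-accessors
#' @export
setMethod("reportTable", "MetricReport", function(x) x@table)

#' @rdname MetricReport-accessors
#' @export
setMethod("reportMeans", "MetricReport", function(x) {
  tb <- x@table
  out <- do.call(rbind, lapply(split(tb, tb$method), function(d) {
    data.frame(method = d$method[1],
               auroc_mean = mean(d$auroc, na.rm = TRUE),
               auroc_sd = stats::sd(d$auroc, na.rm = TRUE),
               auprc_mean = mean(d$auprc, na.rm = TRUE),
               auprc_sd = stats::sd(d$auprc, na.rm = TRUE),
               f1_mean = mean(d$f1, na.rm = TRUE),
               f1_sd = stats::sd(d$f1, na.rm = TRUE),
               n_datasets = nrow(d))
  }))
  rownames(out) <- NULL
  out
})

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport\n")
  print(reportMeans(object), digits = 4)
})
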