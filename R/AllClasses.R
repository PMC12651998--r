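#' @import methods
NULL

#' GRN: a directed gene regulatory network
#'
#' Directed binary network over a fixed gene universe. Edges run from
#' transcription factors (TFs) to target genes; entry `adjacency[i, j] == 1`
#' means gene `i` regulates gene `j`. Self-regulation is excluded and every
#' edge source must be a TF.
#'
#' @slot genes Character vector of gene identifiers (unique, nonempty).
#' @slot tfMask Logical vector, `TRUE` where the gene is a transcription
#'   factor (an allowed edge source).
#' @slot adjacency Numeric `n x n` matrix with entries in `{0, 1}` and a zero
#'   diagonal.
#'
#' @seealso [GRN()], [sampleGRNTopology()], [candidateMask()]
#' @export
setClass("GRN", representation(
  genes = "character",
  tfMask = "logical",
  adjacency = "matrix"
))

setValidity("GRN", function(object) {
  n <- length(object@genes)
  msgs <- character(0)
  if (n < 1L) msgs <- c(msgs, "at least one gene is required")
  if (anyDuplicated(object@genes)) msgs <- c(msgs, "gene names must be unique")
  if (length(object@tfMask) != n)
    msgs <- c(msgs, "tfMask length must equal the number of genes")
  A <- object@adjacency
  if (!all(dim(A) == c(n, n)))
    msgs <- c(msgs, "adjacency must be n x n for n genes")
  else {
    if (!all(A %in% c(0, 1))) msgs <- c(msgs, "adjacency entries must be 0/1")
    if (any(diag(A) != 0)) msgs <- c(msgs, "self-regulatory edges are not allowed")
    src <- which(rowSums(A) > 0)
    if (length(src) && !all(object@tfMask[src]))
      msgs <- c(msgs, "every edge source must be a transcription factor")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GRN object
#'
#' @param genes Character vector of gene identifiers.
#' @param tfMask Logical vector marking transcription factors.
#' @param adjacency Binary `n x n` adjacency matrix (`[i, j] = 1` iff gene `i`
#'   regulates gene `j`).
#' @return A validated [GRN-class] object.
#' @examples
#' g <- GRN(c("tf1", "g1"), c(TRUE, FALSE),
#'          matrix(c(0, 0, 1, 0), 2, 2))
#' nEdges(g)
#' @export
GRN <- function(genes, tfMask, adjacency) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  dimnames(adjacency) <- list(genes, genes)
  new("GRN", genes = as.character(genes), tfMask = as.logical(tfMask),
      adjacency = adjacency)
}

#' NoiseSchedule: the discrete diffusion noise schedule
#'
#' Holds the per-step mixing weights \eqn{\alpha_t}, the cumulative weights
#' \eqn{\bar\gamma_t} with \eqn{1-\bar\gamma_t = \prod_{i\le t}(1-\alpha_i)},
#' and the stationary no-edge probability \eqn{\delta} defining the 2x2 prior
#' matrix `S` whose rows are both \eqn{(\delta, 1-\delta)}.
#'
#' @slot nSteps Integer, total number of diffusion steps `T`.
#' @slot delta Stationary no-edge probability in `(0, 1)`.
#' @slot s Small offset of the squared-cosine retention profile.
#' @slot alpha Numeric vector of length `T`, each in `[0, 1]`.
#' @slot gammaBar Numeric vector of length `T + 1` (index `t + 1` holds
#'   \eqn{\bar\gamma_t} for `t = 0..T`), nondecreasing from 0 to ~1.
#'
#' @seealso [cosineSchedule()], [transitionMatrix()], [cumulativeTransition()]
#' @export
setClass("NoiseSchedule", representation(
  nSteps = "integer",
  delta = "numeric",
  s = "numeric",
  alpha = "numeric",
  gammaBar = "numeric"
))

setValidity("NoiseSchedule", function(object) {
  msgs <- character(0)
  T <- object@nSteps
  if (T < 1L) msgs <- c(msgs, "nSteps must be >= 1")
  if (object@delta <= 0 || object@delta >= 1)
    msgs <- c(msgs, "delta must lie in (0, 1)")
  if (length(object@alpha) != T) msgs <- c(msgs, "alpha must have length nSteps")
  if (any(object@alpha < -1e-12) || any(object@alpha > 1 + 1e-12))
    msgs <- c(msgs, "each alpha_t must lie in [0, 1]")
  g <- object@gammaBar
  if (length(g) != T + 1L) msgs <- c(msgs, "gammaBar must have length nSteps + 1")
  else {
    if (any(diff(g) < -1e-12)) msgs <- c(msgs, "gammaBar must be nondecreasing")
    if (g[T + 1L] < 1 - 1e-4) msgs <- c(msgs, "gammaBar_T must reach ~1")
  }
  if (length(msgs)) msgs else TRUE
})

#' GRNDenoiser: parameters of the hybrid-attention denoiser
#'
#' Container for the denoiser parameters (a named list of numeric matrices),
#' the architecture hyperparameters, the recipe used to derive node features
#' from expression, the noise-schedule fingerprint the model was trained
#' under, and the training log.
#'
#' @slot params Named list of numeric parameter matrices.
#' @slot hyper Named list of architecture hyperparameters (see
#'   [denoiserHyper()]).
#' @slot recipe Named list describing expression-to-node-feature derivation.
#' @slot schedule Named list with the schedule settings (`nSteps`, `delta`,
#'   `s`) the model expects at generation time.
#' @slot trainingLog data.frame of per-epoch loss summaries (possibly empty).
#' @export
setClass("GRNDenoiser", representation(
  params = "list",
  hyper = "list",
  recipe = "list",
  schedule = "list",
  trainingLog = "data.frame"
))

#' MetricReport: benchmark metric table with run metadata
#'
#' @slot table data.frame with one row per (method, dataset) holding columns
#'   `method`, `dataset`, `auroc`, `auprc`, `f1`.
#' @slot metadata Named list (seed, subsequence length, ensemble size, model
#'   fingerprint, ...).
#' @export
setClass("MetricReport", representation(
  table = "data.frame",
  metadata = "list"
))

setValidity("MetricReport", function(object) {
  tb <- object@table
  need <- c("method", "dataset", "auroc", "auprc", "f1")
  if (!all(need %in% names(tb)))
    return(sprintf("table must contain columns: %s", paste(need, collapse = ", ")))
  num <- unlist(tb[, c("auroc", "auprc", "f1")])
  num <- num[!is.na(num)]
  if (length(num) && (any(num < -1e-12) || any(num > 1 + 1e-12)))
    return("all metrics must lie in [0, 1]")
  TRUE
})
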