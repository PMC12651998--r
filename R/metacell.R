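## Metacell aggregation: a simple k-means pooling of similar cells used to
## stabilize per-gene features against dropout before network generation.

#' Aggregate cells into metacells
#'
#' Clusters z-scored cells with k-means (`k = nMetacells`) and returns each
#' metacell as the mean of its member cells on the original scale. Runs that
#' produce an empty cluster are re-seeded.
#'
#' @param expr `cells x genes` nonnegative matrix.
#' @param nMetacells Number of metacells (`<= nrow(expr)`).
#' @param seed Integer seed.
#' @return `nMetacells x genes` matrix.
#' @export
metacellAggregate <- function(expr, nMetacells, seed = NULL) {
  assert_that(is.matrix(expr), "expr must be a matrix")
  assert_that(is_count(nMetacells, 1L) && nMetacells <= nrow(expr),
              "nMetacells must be a positive integer <= the number of cells")
  if (nMetacells == nrow(expr)) return(expr)
  sds <- apply(expr, 2L, stats::sd)
  Z <- scale(expr, center = TRUE, scale = ifelse(sds > 1e-12, sds, 1))
  for (attempt in 0:4) {
    km <- try(with_seed(if (is.null(seed)) NULL else seed + attempt,
                        stats::kmeans(Z, centers = nMetacells, nstart = 5L,
                                      iter.max = 100L)),
              silent = TRUE)
    if (!inherits(km, "try-error") && length(unique(km$cluster)) == nMetacells)
      break
  }
  if (inherits(km, "try-error"))
    stop("k-means failed to produce the requested number of metacells",
         call. = FALSE)
  agg <- rowsum(expr, group = km$cluster) / as.vector(table(km$cluster))
  ## deterministic order: clusters sorted by their first member cell
  first <- vapply(sort(unique(km$cluster)), function(cl)
    which(km$cluster == cl)[1], integer(1))
  agg <- agg[order(first), , drop = FALSE]
  rownames(agg) <- sprintf("metacell%03d", seq_len(nrow(agg)))
  colnames(agg) <- colnames(expr)
  agg
}
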