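## Plain-text interchange: expression matrices (CSV/TSV/MTX + sidecars),
## edge lists, run configuration, and run manifests.

#' Read an expression matrix
#'
#' CSV/TSV files carry cells in rows and genes in columns with a gene-name
#' header; MatrixMarket files require `<stem>_genes.tsv` and
#' `<stem>_cells.tsv` name sidecars (genes in rows of the sparse matrix).
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"mtx"`.
#' @return Numeric `cells x genes` matrix with gene column names.
#' @export
readExpression <- function(path, format = c("auto", "csv", "tsv", "mtx")) {
  format <- match.arg(format)
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop(sprintf("cannot infer format from extension '%s'", ext),
                          call. = FALSE))
  }
  if (format == "mtx") return(read_expression_mtx(path))
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          row.names = NULL, comment.char = "")
  gn <- colnames(df)
  if (anyDuplicated(gn))
    stop(sprintf("duplicated gene names in header: %s",
                 paste(unique(gn[duplicated(gn)]), collapse = ", ")),
         call. = FALSE)
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad)) {
    firstbad <- suppressWarnings(which(is.na(as.numeric(df[[bad[1]]]))))[1]
    stop(sprintf("non-numeric value in column '%s' near line %d",
                 gn[bad[1]], firstbad + 1L), call. = FALSE)
  }
  m <- as.matrix(df)
  rownames(m) <- sprintf("cell%04d", seq_len(nrow(m)))
  m
}

read_expression_mtx <- function(path) {
  stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
  gfile <- paste0(stem, "_genes.tsv")
  cfile <- paste0(stem, "_cells.tsv")
  assert_that(file.exists(gfile), sprintf("gene sidecar not found: %s", gfile))
  assert_that(file.exists(cfile), sprintf("cell sidecar not found: %s", cfile))
  m <- as.matrix(Matrix::readMM(path))
  gn <- readLines(gfile)
  cn <- readLines(cfile)
  if (length(gn) != nrow(m))
    stop(sprintf("gene sidecar %s lists %d names but the matrix has %d rows",
                 gfile, length(gn), nrow(m)), call. = FALSE)
  if (length(cn) != ncol(m))
    stop(sprintf("cell sidecar %s lists %d names but the matrix has %d columns",
                 cfile, length(cn), ncol(m)), call. = FALSE)
  if (anyDuplicated(gn))
    stop("duplicated gene names in sidecar", call. = FALSE)
  out <- t(m)
  dimnames(out) <- list(cn, gn)
  out
}

#' Write an expression matrix
#'
#' @param expr `cells x genes` matrix with gene column names.
#' @param path Output path; extension selects CSV/TSV or MTX (the latter
#'   writes gene/cell sidecars).
#' @return The path, invisibly.
#' @export
writeExpression <- function(expr, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    Matrix::writeMM(Matrix::Matrix(t(expr), sparse = TRUE), path)
    writeLines(colnames(expr), paste0(stem, "_genes.tsv"))
    writeLines(rownames(expr) %||% sprintf("cell%04d", seq_len(nrow(expr))),
               paste0(stem, "_cells.tsv"))
  } else {
    sep <- if (ext == "csv") "," else "\t"
    utils::write.table(expr, path, sep = sep, quote = FALSE, row.names = FALSE,
                       col.names = TRUE)
  }
  invisible(path)
}

#' Read a directed edge list into a GRN
#'
#' The TSV must have columns `regulator` and `target` (a `probability`
#' column, if present, is ignored here). Unknown gene names and self-edges
#' are rejected.
#'
#' @param path Edge-list TSV.
#' @param genes Gene universe (character vector).
#' @param tfs Logical TF indicator aligned with `genes`; by default every
#'   observed regulator is marked as a TF.
#' @return A [GRN-class].
#' @export
readEdges <- function(path, genes, tfs = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  assert_that(all(c("regulator", "target") %in% names(df)),
              "edge list must have 'regulator' and 'target' columns")
  unknown <- setdiff(unique(c(df$regulator, df$target)), genes)
  if (length(unknown))
    stop(sprintf("unknown gene names in edge list: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  self <- df$regulator == df$target
  if (any(self))
    stop(sprintf(paste0("self-regulatory edges are not allowed (no-self-edge ",
                        "rule); offending genes: %s"),
                 paste(unique(df$regulator[self]), collapse = ", ")),
         call. = FALSE)
  n <- length(genes)
  A <- matrix(0, n, n, dimnames = list(genes, genes))
  A[cbind(match(df$regulator, genes), match(df$target, genes))] <- 1
  if (is.null(tfs)) tfs <- genes %in% df$regulator
  GRN(genes, tfs, A)
}

#' Write a GRN or edge-probability matrix as an edge-list TSV
#'
#' Probability matrices are written with a third `probability` column sorted
#' in descending order; binary networks list their edges.
#'
#' @param x A [GRN-class] or a named `n x n` probability matrix.
#' @param path Output TSV path.
#' @param tfs TF indicator (required for probability matrices, to define the
#'   candidate universe).
#' @return The path, invisibly.
#' @export
writeEdges <- function(x, path, tfs = NULL) {
  if (is(x, "GRN")) {
    idx <- which(adjacency(x) == 1, arr.ind = TRUE)
    df <- data.frame(regulator = genes(x)[idx[, 1]],
                     target = genes(x)[idx[, 2]])
  } else {
    assert_that(!is.null(tfs), "tfs is required for probability matrices")
    mask <- candidatePairs(tfs)
    idx <- which(mask, arr.ind = TRUE)
    gn <- colnames(x) %||% sprintf("g%03d", seq_len(ncol(x)))
    df <- data.frame(regulator = gn[idx[, 1]], target = gn[idx[, 2]],
                     probability = x[idx])
    df <- df[order(-df$probability), ]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a GRN's gene roles (TF/non-TF) as TSV
#'
#' @param grn A [GRN-class].
#' @param path Output path (columns `gene`, `is_tf`).
#' @return The path, invisibly.
#' @export
writeGeneRoles <- function(grn, path) {
  utils::write.table(data.frame(gene = genes(grn),
                                is_tf = as.integer(tfMask(grn))),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGeneRoles
#' @export
readGeneRoles <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  assert_that(all(c("gene", "is_tf") %in% names(df)),
              "gene-role file must have 'gene' and 'is_tf' columns")
  stats::setNames(df$is_tf == 1, df$gene)
}

run_config_schema <- list(
  seed = "integer", out_dir = "character", log_level = "character",
  simulate = c("n_min", "n_max", "tf_fraction", "n_cells", "noise_scale",
               "activation_prob", "n_train", "n_test"),
  train = c("n_steps", "epochs", "batch_size", "lr", "weight_decay",
            "clip_norm", "pos_weight_cap", "d_x", "d_e", "d_t", "layers"),
  generate = c("k", "n_ensemble", "deterministic", "cutoff"),
  evaluate = c("baselines", "cutoff", "variants")
)

#' Read and validate a run-configuration YAML
#'
#' Unknown top-level sections or keys are rejected so that typos fail loudly
#' before any computation starts.
#'
#' @param path YAML file.
#' @return Named list of validated settings.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), names(run_config_schema))
  if (length(unknown))
    stop(sprintf("unknown configuration sections: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  for (sec in intersect(names(y), c("simulate", "train", "generate",
                                    "evaluate"))) {
    bad <- setdiff(names(y[[sec]]), run_config_schema[[sec]])
    if (length(bad))
      stop(sprintf("unknown keys in section '%s': %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  y
}

#' Write a reproducibility manifest
#'
#' Records the configuration fingerprint, seed, package and R versions, and
#' md5 checksums of the named input files — enough to re-run deterministic
#' stages bit-compatibly.
#'
#' @param dir Output directory (writes `manifest.json`).
#' @param config Configuration list.
#' @param seed Global seed.
#' @param inputs Character vector of input file paths.
#' @return Manifest path, invisibly.
#' @export
writeManifest <- function(dir, config, seed, inputs = character(0)) {
  manifest <- list(
    config_md5 = object_fingerprint(config),
    seed = seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("DiffGRN")),
    inputs = if (length(inputs))
      as.list(stats::setNames(unname(tools::md5sum(inputs)), inputs))
    else list(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE)
  invisible(path)
}
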