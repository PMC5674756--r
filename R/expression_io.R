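#' Construct an expression matrix with scale semantics
#'
#' Internal storage convention throughout the package is cells x genes
#' (rows = cells). The `scale` attribute records the value semantics:
#' `"raw_counts"` (non-negative integers, required by the Poisson model and
#' by [size_factor_normalize()]) or `"log_counts"` (finite log-transformed
#' values, expected by the Gaussian model).
#'
#' @param values Numeric matrix, cells x genes.
#' @param scale One of `"log_counts"`, `"raw_counts"`.
#' @param cell_ids,gene_ids Optional label vectors; default to existing
#'   dimnames or generated labels.
#' @return The matrix with dimnames set and a `"scale"` attribute.
#' @export
pf_expression <- function(values, scale = c("log_counts", "raw_counts"),
                          cell_ids = NULL, gene_ids = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (scale == "raw_counts") {
    if (any(values < 0) || any(values != floor(values)))
      pf_stop("raw_counts values must be non-negative integers",
              "pf_scale_error")
  } else if (any(!is.finite(values))) stop("log_counts values must be finite")
  rownames(values) <- cell_ids %||% rownames(values) %||%
    paste0("cell", seq_len(nrow(values)))
  colnames(values) <- gene_ids %||% colnames(values) %||%
    paste0("gene", seq_len(ncol(values)))
  attr(values, "scale") <- scale
  values
}

pf_scale <- function(Y) {
  sc <- attr(Y, "scale")
  if (!is.null(sc)) return(sc)
  if (all(Y >= 0) && all(Y == floor(Y))) "raw_counts" else "log_counts"
}

#' Read an expression matrix from TSV, CSV or Matrix Market files
#'
#' Dense formats expect a header row of gene identifiers and a first column
#' of cell identifiers (or the transpose, with `orientation =
#' "genes_by_cells"`). The MTX format expects sidecar label files
#' `genes.tsv` and `barcodes.tsv` next to the matrix file, one label per
#' line, matching the MTX rows and columns for `genes_by_cells` (the common
#' CellRanger layout) or the reverse for `cells_by_genes`.
#'
#' @param path File path.
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`.
#' @param orientation Layout on disk; the returned matrix is always
#'   cells x genes.
#' @param scale Value semantics recorded on the result; see
#'   [pf_expression()].
#' @return A cells x genes matrix with a `"scale"` attribute.
#' @export
read_expression <- function(path, format = c("tsv", "csv", "mtx"),
                            orientation = c("cells_by_genes", "genes_by_cells"),
                            scale = c("log_counts", "raw_counts")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (format == "mtx") {
    dir <- dirname(path)
    gpath <- file.path(dir, "genes.tsv")
    bpath <- file.path(dir, "barcodes.tsv")
    if (!file.exists(gpath) || !file.exists(bpath))
      stop("MTX input requires sidecar files genes.tsv and barcodes.tsv in ", dir)
    M <- as.matrix(Matrix::readMM(path))
    genes <- read.table(gpath, sep = "\t", header = FALSE,
                        stringsAsFactors = FALSE)[[1L]]
    cells <- read.table(bpath, sep = "\t", header = FALSE,
                        stringsAsFactors = FALSE)[[1L]]
    if (orientation == "genes_by_cells") {
      if (nrow(M) != length(genes) || ncol(M) != length(cells))
        stop("MTX dimensions (", nrow(M), " x ", ncol(M),
             ") do not match label files (", length(genes), " genes, ",
             length(cells), " cells)")
      M <- t(M)
    } else if (nrow(M) != length(cells) || ncol(M) != length(genes))
      stop("MTX dimensions (", nrow(M), " x ", ncol(M),
           ") do not match label files (", length(cells), " cells, ",
           length(genes), " genes)")
    return(pf_expression(M, scale, cell_ids = cells, gene_ids = genes))
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- read.table(path, sep = sep, header = TRUE, row.names = 1L,
                   check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df)
  if (!is.numeric(M)) {
    bad <- which(!vapply(df, is.numeric, logical(1L)))[1L]
    stop("non-numeric values in column ", bad + 1L, " ('",
         colnames(df)[bad], "') of ", path)
  }
  if (orientation == "genes_by_cells") M <- t(M)
  pf_expression(M, scale)
}

#' Median-ratio size-factor normalization and log transform
#'
#' Computes per-cell size factors as the median ratio of a cell's counts to
#' the per-gene geometric mean, over genes expressed (nonzero) in every
#' cell, then divides each cell by its factor and applies `log(x + 1)`.
#'
#' @param Y Raw-count cells x genes matrix.
#' @return A log-scale matrix (`scale = "log_counts"`) with a
#'   `"size_factors"` attribute.
#' @export
size_factor_normalize <- function(Y) {
  if (pf_scale(Y) != "raw_counts")
    stop("size_factor_normalize expects raw counts")
  zero_cells <- rownames(Y)[rowSums(Y) == 0]
  if (length(zero_cells))
    stop("cell(s) with all-zero counts: ", paste(zero_cells, collapse = ", "))
  core <- colSums(Y > 0) == nrow(Y)
  if (!any(core))
    stop("no gene is expressed in every cell; cannot form geometric-mean ",
         "reference for median-ratio size factors")
  logg <- log(Y[, core, drop = FALSE])
  ref <- colMeans(logg)                      # log geometric mean per gene
  sf <- exp(apply(sweep(logg, 2L, ref), 1L, median))
  out <- log1p(sweep(unclass(Y), 1L, sf, "/"))
  out <- pf_expression(out, "log_counts", rownames(Y), colnames(Y))
  attr(out, "size_factors") <- setNames(sf, rownames(Y))
  out
}

#' Select highly variable genes from the mean-CV2 relationship
#'
#' Ranks genes by their residual log CV^2 from a rolling-median trend of
#' log CV^2 against log mean (window of 51 genes ordered by mean) and keeps
#' the `n_keep` largest residuals. If `spikes` is given, the trend is fitted
#' on the spike-in genes only and evaluated at each endogenous gene's mean
#' by interpolation, mirroring ERCC-based selection; spike-ins themselves
#' are never retained in that mode.
#'
#' @param Y Cells x genes matrix (any scale; counts are the usual input).
#' @param n_keep Number of genes to retain.
#' @param spikes Optional regular expression identifying spike-in gene ids
#'   (e.g. `"^ERCC-"`).
#' @return `Y` restricted to the selected genes, original gene order
#'   preserved.
#' @export
filter_variable_genes <- function(Y, n_keep, spikes = NULL) {
  G <- ncol(Y)
  stopifnot(n_keep >= 1L, n_keep <= G)
  mu <- colMeans(Y)
  v <- apply(Y, 2L, var)
  if (all(v == 0)) stop("constant expression matrix: no variable genes")
  ok <- mu > 0 & v > 0
  cv2 <- ifelse(ok, v / mu^2, NA_real_)
  lmu <- log(pmax(mu, .Machine$double.xmin))
  lcv2 <- log(cv2)
  trend_at <- function(fit_idx, eval_lmu) {
    ord <- fit_idx[order(lmu[fit_idx])]
    k <- min(51L, length(ord) - (1 - length(ord) %% 2))  # odd, <= n
    if (k < 1L) k <- 1L
    tr <- runmed(lcv2[ord], k = k, endrule = "median")
    approx(lmu[ord], tr, xout = eval_lmu, rule = 2L, ties = mean)$y
  }
  resid <- rep(-Inf, G)
  if (is.null(spikes)) {
    idx <- which(ok)
    resid[idx] <- lcv2[idx] - trend_at(idx, lmu[idx])
  } else {
    sp <- grepl(spikes, colnames(Y))
    if (sum(sp & ok) < 3L) stop("fewer than 3 usable spike-in genes match '",
                                spikes, "'")
    idx <- which(ok & !sp)
    resid[idx] <- lcv2[idx] - trend_at(which(ok & sp), lmu[idx])
    if (n_keep > length(idx))
      stop("n_keep exceeds the number of endogenous genes")
  }
  keep <- sort(order(resid, decreasing = TRUE)[seq_len(n_keep)])
  out <- Y[, keep, drop = FALSE]
  attr(out, "scale") <- pf_scale(Y)
  out
}

#' Write the standard result tables of a fitted model
#'
#' Writes `relevance.tsv` (factor, type, relevance, n_annotated, n_gained,
#' n_lost), `factor_states.tsv` (cells x factors posterior means),
#' `weights.tsv` (genes x factors posterior mean weights),
#' `refinement.tsv` (factor, gene, action, posterior) and `run_log.json`
#' (configuration, seed, iteration count, convergence flag, ELBO trace).
#'
#' @param fitted A [pathfactor()] fit.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(fitted, out_dir) {
  stopifnot(inherits(fitted, "pathfactor"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  wtsv <- function(df, file, rows = FALSE)
    write.table(df, file.path(out_dir, file), sep = "\t", quote = FALSE,
                row.names = rows, col.names = if (rows) NA else TRUE)

  rel <- factor_relevance(fitted)
  wtsv(rel, "relevance.tsv")

  X <- fitted$state$X_mean
  wtsv(as.data.frame(X), "factor_states.tsv", rows = TRUE)
  W <- coef(fitted)
  wtsv(as.data.frame(W), "weights.tsv", rows = TRUE)

  refin <- refine_gene_sets(fitted)
  reftab <- do.call(rbind, lapply(names(refin), function(f) {
    r <- refin[[f]]
    rbind(
      if (nrow(r$added)) data.frame(factor = f, gene = r$added$gene,
                                    action = "added",
                                    posterior = r$added$posterior),
      if (nrow(r$removed)) data.frame(factor = f, gene = r$removed$gene,
                                      action = "removed",
                                      posterior = r$removed$posterior))
  }))
  if (is.null(reftab))
    reftab <- data.frame(factor = character(), gene = character(),
                         action = character(), posterior = numeric())
  wtsv(reftab, "refinement.tsv")

  log <- list(
    package = "pathfactor",
    noise = fitted$state$noise,
    n_cells = nrow(X), n_genes = nrow(W),
    factors = fitted$state$spec$name,
    kinds = fitted$state$spec$kind,
    hyper = unclass(fitted$hyper),
    control = unclass(fitted$control),
    seed = fitted$seed,
    converged = fitted$converged,
    n_iter = fitted$n_iter,
    elbo_trace = fitted$elbo_trace)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(out_dir, c("relevance.tsv", "factor_states.tsv",
                                 "weights.tsv", "refinement.tsv",
                                 "run_log.json")))
}
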