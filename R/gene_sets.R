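#' Read a GMT gene-set file
#'
#' Parses the tab-separated GMT format used by MSigDB and REACTOME
#' distributions: one gene set per line, with fields name, description and
#' one or more gene identifiers. Duplicate gene identifiers within a line are
#' removed; the order of sets in the file is preserved.
#'
#' @param path Path to a GMT file.
#' @return An object of class `pf_genesets`: a list with elements `sets`
#'   (named list of character vectors of gene identifiers) and `source`
#'   (the file path).
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines(c("SETA\tdesc\tg1\tg2\tg2", "SETB\tdesc\tg3\tg4"), gmt)
#' gs <- read_gmt(gmt)
#' lengths(gs$sets)
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L)
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    nms[i] <- fields[1L]
    sets[[i]] <- unique(fields[-(1:2)])
  }
  if (anyDuplicated(nms))
    stop("duplicate gene-set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  structure(list(sets = sets, source = path), class = "pf_genesets")
}

#' @export
print.pf_genesets <- function(x, ...) {
  cat("Gene-set collection:", length(x$sets), "sets",
      sprintf("(sizes %s)", if (length(x$sets))
        paste(range(lengths(x$sets)), collapse = "-") else "NA"), "\n")
  cat("Source:", x$source, "\n")
  invisible(x)
}

#' Build a binary gene-by-set annotation matrix
#'
#' Intersects each gene set with the gene universe of an expression matrix
#' and drops sets whose intersection size falls outside
#' `[min_genes, max_genes]`. Matching is exact string match after
#' case-folding; no alias resolution is attempted. The resulting incidence
#' matrix I has `I[g, k] = 1` iff gene g belongs to surviving set k, with
#' rows in the order of `gene_universe`.
#'
#' @param collection A `pf_genesets` object from [read_gmt()], or a named
#'   list of character vectors.
#' @param gene_universe Character vector of gene identifiers, in the order of
#'   the expression matrix columns.
#' @param min_genes,max_genes Minimum/maximum number of universe genes a set
#'   must annotate to be retained. Defaults keep sets estimable (>= 15 genes)
#'   while excluding near-global sets (> 1000 genes).
#' @return A binary integer matrix (genes x sets) with dimnames
#'   `list(gene_universe, surviving set names)`.
#' @export
build_annotation_matrix <- function(collection, gene_universe,
                                    min_genes = 15L, max_genes = 1000L) {
  if (inherits(collection, "pf_genesets")) collection <- collection$sets
  stopifnot(is.list(collection), length(gene_universe) >= 1L, min_genes >= 1L)
  uni_fold <- tolower(gene_universe)
  if (anyDuplicated(uni_fold))
    stop("gene_universe contains duplicated identifiers (after case-folding)")
  cols <- lapply(collection, function(genes) {
    m <- match(unique(tolower(genes)), uni_fold)
    sort(m[!is.na(m)])
  })
  sizes <- lengths(cols)
  keep <- sizes >= min_genes & sizes <= max_genes
  if (!any(keep))
    stop("no gene set has between ", min_genes, " and ", max_genes,
         " genes in the expression matrix; relax min_genes/max_genes ",
         "or check identifier conventions")
  cols <- cols[keep]
  I <- matrix(0L, nrow = length(gene_universe), ncol = length(cols),
              dimnames = list(gene_universe, names(cols)))
  for (k in seq_along(cols)) I[cols[[k]], k] <- 1L
  I
}

#' Prescreen gene sets by leading-principal-component variance
#'
#' For large annotations it is often useful to reduce the number of annotated
#' factors before fitting. Each set is scored by the proportion of variance
#' of its standardized annotated-gene submatrix captured by the leading
#' principal component, computed on a random subsample of at most
#' `subsample_cells` cells; the `keep` best-scoring sets are retained
#' (columns reordered by decreasing score). Scores are invariant to gene-wise
#' scaling of `Y` because genes are standardized first.
#'
#' @param Y Cells x genes expression matrix (genes matching the annotation
#'   rows).
#' @param annotation Binary genes x sets incidence matrix from
#'   [build_annotation_matrix()].
#' @param keep Number of sets to retain.
#' @param subsample_cells Cell subsample size used for scoring.
#' @param seed Integer seed for the cell subsample.
#' @return The annotation matrix restricted to the retained sets, with a
#'   `"prescreen_scores"` attribute giving each retained set's score.
#' @export
prescreen_gene_sets <- function(Y, annotation, keep,
                                subsample_cells = 2000L, seed = 1L) {
  stopifnot(nrow(annotation) == ncol(Y))
  if (keep <= 0L) stop("keep must be a positive integer")
  if (keep > ncol(annotation))
    stop("keep (", keep, ") exceeds the number of annotated sets (",
         ncol(annotation), ")")
  n <- nrow(Y)
  idx <- if (n > subsample_cells)
    with_seed(seed, sample.int(n, subsample_cells)) else seq_len(n)
  Ys <- Y[idx, , drop = FALSE]
  sdv <- apply(Ys, 2L, sd)
  scores <- vapply(seq_len(ncol(annotation)), function(k) {
    g <- which(annotation[, k] == 1L & sdv > 0)
    if (length(g) < 2L) return(0)
    Z <- scale(Ys[, g, drop = FALSE])
    d2 <- svd(Z, nu = 0L, nv = 0L)$d^2
    d2[1L] / sum(d2)
  }, numeric(1L))
  ord <- order(scores, decreasing = TRUE)[seq_len(keep)]
  out <- annotation[, ord, drop = FALSE]
  attr(out, "prescreen_scores") <- setNames(scores[ord], colnames(out))
  out
}
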