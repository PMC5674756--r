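#' Factor relevance report
#'
#' Relevance is the posterior mean of `1/alpha_k`, the expected variance
#' explained by factor k on its regulated genes: `rate/(shape-1)` of the
#' Gamma posterior when `shape > 1`, with the fallback `rate/shape` (and a
#' warning) otherwise. Factors are ranked by decreasing relevance; ties keep
#' assembly order. Covariate factors are reported but flagged by their
#' `kind`.
#'
#' @param fitted A [pathfactor()] fit.
#' @return A data.frame with columns factor, kind, relevance, n_annotated,
#'   n_gained, n_lost, rank; one row per factor, sorted by rank.
#' @export
factor_relevance <- function(fitted) {
  stopifnot(inherits(fitted, "pathfactor"))
  s <- fitted$state
  sh <- s$alpha_shape; ra <- s$alpha_rate
  rel <- ifelse(sh > 1, ra / (sh - 1), ra / sh)
  if (any(sh <= 1))
    warning("alpha posterior shape <= 1 for ",
            sum(sh <= 1), " factor(s); using rate/shape for their relevance")
  out <- data.frame(factor = s$spec$name, kind = s$spec$kind,
                    relevance = rel, n_annotated = NA_integer_,
                    n_gained = NA_integer_, n_lost = NA_integer_,
                    stringsAsFactors = FALSE)
  if (!is.null(fitted$churn)) {
    ann <- which(!is.na(s$spec$annotation_column))
    out$n_annotated[ann] <- fitted$churn[, "n_annotated"]
    out$n_gained[ann] <- fitted$churn[, "n_gained"]
    out$n_lost[ann] <- fitted$churn[, "n_lost"]
  }
  ord <- order(-out$relevance, seq_len(nrow(out)))
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Data-driven gene-set refinement
#'
#' Compares the posterior inclusion probabilities `gamma[g,k]` of annotated
#' factors with the input annotation: gene g is *added* to factor k iff
#' `I[g,k] == 0` and `gamma > threshold`, and *removed* iff `I[g,k] == 1`
#' and `gamma < threshold` (strict inequalities: a posterior exactly at the
#' threshold changes nothing).
#'
#' @param fitted A [pathfactor()] fit with at least one annotated factor.
#' @param threshold Posterior threshold, default 0.5.
#' @return A named list (one element per annotated factor) of lists with
#'   data.frames `added` and `removed` (columns gene, posterior).
#' @export
refine_gene_sets <- function(fitted, threshold = 0.5) {
  stopifnot(inherits(fitted, "pathfactor"))
  s <- fitted$state
  ann <- which(!is.na(s$spec$annotation_column))
  if (!length(ann)) stop("model has no annotated factors")
  genes <- s$gene_ids %||% paste0("gene", seq_len(s$n_genes))
  out <- lapply(ann, function(k) {
    I <- s$annotation[, s$spec$annotation_column[k]]
    g <- s$gamma[, k]
    add <- which(I == 0 & g > threshold)
    rem <- which(I == 1 & g < threshold)
    list(added = data.frame(gene = genes[add], posterior = unname(g[add]),
                            stringsAsFactors = FALSE),
         removed = data.frame(gene = genes[rem], posterior = unname(g[rem]),
                              stringsAsFactors = FALSE))
  })
  names(out) <- s$spec$name[ann]
  out
}

#' Residual expression after removing selected factors
#'
#' Gaussian model: `residual = Y - sum_{k in remove} E[x_k] E[w_k]'` on the
#' input scale (per-gene means are untouched, so removing nothing returns
#' the input exactly). Hurdle model with zeros: zeros are first replaced by
#' the posterior-mean latent value `E[f_{n,g}]` (dropout-model imputation)
#' and positive values by `log(y+1)`, after which the removed factors'
#' contributions are subtracted; the output is on the log scale.
#'
#' @param fitted A [pathfactor()] fit.
#' @param Y The expression matrix the model was fitted to (defaults to the
#'   stored copy).
#' @param remove Character vector of factor names whose contributions are
#'   removed.
#' @return A cells x genes matrix, `scale = "log_counts"`.
#' @export
residual_expression <- function(fitted, Y = fitted$Y,
                                remove = character(0)) {
  stopifnot(inherits(fitted, "pathfactor"))
  s <- fitted$state
  unknown <- setdiff(remove, s$spec$name)
  if (length(unknown))
    stop("unknown factor name(s): ", paste(unknown, collapse = ", "),
         "; known factors: ", paste(s$spec$name, collapse = ", "))
  Ew <- pf_w_moments(s)$Ew
  if (s$noise == "gaussian" || s$center) {
    out <- unclass(Y)
  } else if (s$noise == "hurdle") {
    out <- log1p(unclass(Y))
    Fm <- s$X_mean %*% t(Ew)
    zero <- unclass(Y) == 0
    out[zero] <- Fm[zero]
  } else {
    out <- s$X_mean %*% t(Ew)  # poisson: residuals live on the latent scale
  }
  ks <- match(remove, s$spec$name)
  if (length(ks))
    out <- out - s$X_mean[, ks, drop = FALSE] %*% t(Ew[, ks, drop = FALSE])
  pf_expression(out, "log_counts", s$cell_ids, s$gene_ids)
}

#' Export factor states for visualization
#'
#' Posterior means and standard deviations of the chosen factors, one row
#' per cell — suitable for bivariate plots or as input to an external
#' embedding (t-SNE, UMAP).
#'
#' @param fitted A [pathfactor()] fit.
#' @param factors Character vector of factor names.
#' @return A data.frame with columns `<factor>_mean` and `<factor>_sd` per
#'   requested factor.
#' @export
export_factor_states <- function(fitted, factors) {
  stopifnot(inherits(fitted, "pathfactor"), length(factors) >= 1L)
  s <- fitted$state
  ks <- match(factors, s$spec$name)
  if (anyNA(ks))
    stop("unknown factor name(s): ",
         paste(factors[is.na(ks)], collapse = ", "))
  out <- data.frame(row.names = s$cell_ids %||% seq_len(s$n_cells))
  for (i in seq_along(ks)) {
    out[[paste0(factors[i], "_mean")]] <- s$X_mean[, ks[i]]
    out[[paste0(factors[i], "_sd")]] <- sqrt(s$X_var[, ks[i]])
  }
  out
}

#' Diagnose the need for sparse unannotated factors
#'
#' Applied to a fit of the standard model (no sparse unannotated factors):
#' if any annotated factor gained plus lost at least `churn_threshold`
#' (default 100%) of its annotation during fitting, the factor has become
#' unlinked from its annotated process and the model should be refitted
#' with sparse unannotated factors (five by default).
#'
#' @param fitted A [pathfactor()] fit.
#' @param churn_threshold Churn fraction that triggers the diagnostic
#'   (inclusive).
#' @return A list with `activate` (logical) and `churn` (per-annotated-
#'   factor data.frame of n_annotated, n_gained, n_lost, churn).
#' @export
diagnose_sparse_need <- function(fitted, churn_threshold = 1.0) {
  stopifnot(inherits(fitted, "pathfactor"))
  if (any(fitted$state$spec$kind == "sparse_unannotated"))
    warning("diagnostic is intended for the standard model ",
            "(no sparse unannotated factors)")
  ch <- annotation_churn(fitted$state)
  if (is.null(ch)) stop("model has no annotated factors")
  tab <- data.frame(
    factor = fitted$state$spec$name[!is.na(fitted$state$spec$annotation_column)],
    as.data.frame(ch), stringsAsFactors = FALSE)
  list(activate = max(tab$churn) >= churn_threshold, churn = tab)
}
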