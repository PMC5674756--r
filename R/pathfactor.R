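#' Fit a pathway-informed sparse factor model
#'
#' Decomposes a cells x genes expression matrix into linear contributions
#' from observed covariates, pathway-annotated factors, sparse unannotated
#' factors and dense (confounder-like) unannotated factors,
#' `Y = X W' + psi`. Gene-set annotations inform a spike-and-slab prior on
#' the weights: annotated genes are a priori more likely to carry non-zero
#' weight, with assumed annotation error rates (`fnr`, `fpr` in
#' [pf_hyper()]) allowing the posterior to add or remove genes. An ARD prior
#' on each factor's slab precision lets unused factors deactivate; the
#' posterior mean of `1/alpha_k` is the factor's relevance. Inference is
#' deterministic coordinate-ascent variational Bayes given the seeded
#' initialization.
#'
#' @param Y Cells x genes numeric matrix (see [pf_expression()]); log-scale
#'   values for `noise = "gaussian"`, non-negative count-like values for
#'   `"hurdle"` (zeros treated as dropout, positive values modelled on the
#'   `log(y+1)` scale) and raw counts for `"poisson"`.
#' @param annotation Binary genes x sets matrix from
#'   [build_annotation_matrix()], or `NULL`.
#' @param covariates Optional N x C matrix of observed per-cell covariates.
#' @param n_sparse,n_dense Number of sparse / dense unannotated factors
#'   (defaults 5 and 3).
#' @param noise Observation model.
#' @param hyper Hyperparameters, see [pf_hyper()].
#' @param control Fit control, see [pf_control()].
#' @param seed Integer seed governing all stochastic initialization.
#' @return An object of class `pathfactor` with components `state` (the
#'   variational posteriors), `converged`, `n_iter`, `elbo`, `elbo_trace`,
#'   `churn`, `churn_flags`, `seed` and the stored input `Y`. Methods:
#'   [print()], [summary()], [coef()] (posterior mean weights),
#'   [predict()], [residuals()], [plot()], [simulate()].
#' @examples
#' sim <- simulate_dataset(pf_sim_config(n_cells = 60, n_genes = 300,
#'   n_active_pathways = 3, n_negative_pathways = 3,
#'   set_size_range = c(15, 30), seed = 7))
#' fit <- pathfactor(sim$Y, sim$true_annotation, n_sparse = 0, n_dense = 1,
#'                   seed = 7, control = pf_control(max_iter = 50))
#' head(factor_relevance(fit))
#' @export
pathfactor <- function(Y, annotation = NULL, covariates = NULL,
                       n_sparse = 5L, n_dense = 3L,
                       noise = c("gaussian", "hurdle", "poisson"),
                       hyper = pf_hyper(), control = pf_control(),
                       seed = 1L) {
  noise <- match.arg(noise)
  state <- assemble_model(Y, annotation, covariates, n_sparse, n_dense,
                          hyper, noise)
  state <- initialize_state(state, Y, seed)
  res <- fit_state(state, Y, control)
  structure(list(
    state = res$state, converged = res$converged, n_iter = res$n_iter,
    elbo = tail(res$state$elbo_trace, 1L),
    elbo_trace = res$state$elbo_trace,
    churn = res$churn, churn_flags = res$churn_flags,
    sweep_seconds = res$sweep_seconds,
    hyper = hyper, control = control, seed = as.integer(seed),
    Y = Y, call = match.call()), class = "pathfactor")
}

#' @export
print.pathfactor <- function(x, ...) {
  s <- x$state
  cat("Pathway-informed sparse factor model (", s$noise, " noise)\n", sep = "")
  cat(sprintf("  %d cells x %d genes, %d factors (%s)\n", s$n_cells,
              s$n_genes, s$K,
              paste(sprintf("%d %s", table(s$spec$kind)[unique(s$spec$kind)],
                            sub("_unannotated", "", unique(s$spec$kind))),
                    collapse = ", ")))
  cat(sprintf("  %s after %d sweeps; ELBO %.4f\n",
              if (x$converged) "converged" else "max iterations reached",
              x$n_iter, x$elbo))
  rel <- factor_relevance(x)
  cat("  top factors by relevance:",
      paste(head(rel$factor, 5L), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.pathfactor <- function(object, ...) {
  out <- list(relevance = factor_relevance(object),
              converged = object$converged, n_iter = object$n_iter,
              elbo = object$elbo, noise = object$state$noise,
              churn = object$churn,
              dims = c(cells = object$state$n_cells,
                       genes = object$state$n_genes,
                       factors = object$state$K))
  class(out) <- "summary.pathfactor"
  out
}

#' @export
print.summary.pathfactor <- function(x, ...) {
  cat(sprintf("pathfactor fit: %d cells, %d genes, %d factors (%s noise)\n",
              x$dims["cells"], x$dims["genes"], x$dims["factors"], x$noise))
  cat(sprintf("%s in %d sweeps; final ELBO %.4f\n",
              if (x$converged) "Converged" else "Stopped", x$n_iter, x$elbo))
  cat("\nFactor relevance (expected explained variance on regulated genes):\n")
  print(head(x$relevance, 10L), row.names = FALSE)
  if (nrow(x$relevance) > 10L)
    cat("... and", nrow(x$relevance) - 10L, "more factors\n")
  invisible(x)
}

#' Posterior mean factor weights
#'
#' `E[w_{g,k}] = gamma_{g,k} * mu1_{g,k}` under the coupled spike-and-slab
#' posterior.
#'
#' @param object A `pathfactor` fit.
#' @param ... Unused.
#' @return Genes x factors matrix of posterior mean weights.
#' @export
coef.pathfactor <- function(object, ...) {
  w <- pf_w_moments(object$state)$Ew
  dimnames(w) <- list(object$state$gene_ids, object$state$spec$name)
  w
}

#' Predictions from a fitted factor model
#'
#' @param object A `pathfactor` fit.
#' @param type `"reconstruction"` for the posterior-mean latent expression
#'   `E[X] E[W]' ` (gene means restored on the Gaussian/centering path), or
#'   `"states"` for the cells x factors posterior mean factor states.
#' @param ... Unused.
#' @export
predict.pathfactor <- function(object, type = c("reconstruction", "states"),
                               ...) {
  type <- match.arg(type)
  s <- object$state
  if (type == "states") return(s$X_mean)
  Fm <- s$X_mean %*% t(pf_w_moments(s)$Ew)
  if (s$center) Fm <- sweep(Fm, 2L, s$gene_means, "+")
  dimnames(Fm) <- list(s$cell_ids, s$gene_ids)
  Fm
}

#' Residual expression after removing selected factors
#'
#' Convenience method around [residual_expression()] using the stored input
#' matrix.
#'
#' @param object A `pathfactor` fit.
#' @param remove Character vector of factor names to remove (default: none).
#' @param ... Unused.
#' @export
residuals.pathfactor <- function(object, remove = character(0), ...) {
  residual_expression(object, object$Y, remove)
}

#' Plot a fitted factor model
#'
#' @param x A `pathfactor` fit.
#' @param type `"relevance"` draws a bar chart of factor relevances;
#'   `"factors"` draws a bivariate scatter of two factor states.
#' @param factors For `type = "factors"`, two factor names.
#' @param n_top Number of factors shown in the relevance chart.
#' @param ... Passed to the underlying plotting function.
#' @export
plot.pathfactor <- function(x, type = c("relevance", "factors"),
                            factors = NULL, n_top = 15L, ...) {
  type <- match.arg(type)
  if (type == "relevance") {
    rel <- factor_relevance(x)
    rel <- head(rel, n_top)
    op <- par(mar = c(9, 4, 2, 1)); on.exit(par(op))
    barplot(rel$relevance, names.arg = rel$factor, las = 2,
            ylab = "relevance (E[1/alpha])", ...)
  } else {
    if (is.null(factors) || length(factors) != 2L)
      stop("type = 'factors' needs two factor names")
    st <- export_factor_states(x, factors)
    plot(st[[paste0(factors[1L], "_mean")]],
         st[[paste0(factors[2L], "_mean")]],
         xlab = factors[1L], ylab = factors[2L], ...)
  }
  invisible(x)
}

#' Simulate expression data from the fitted model
#'
#' Draws new observations at the posterior mean reconstruction under the
#' fitted noise model: Gaussian residuals with the per-gene posterior mean
#' variance, hurdle dropout through the logistic zero process, or Poisson
#' counts through the softplus link.
#'
#' @param object A `pathfactor` fit.
#' @param nsim Number of matrices to draw.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `nsim` cells x genes matrices.
#' @export
simulate.pathfactor <- function(object, nsim = 1, seed = 1L, ...) {
  s <- object$state
  Fm <- predict(object, "reconstruction")
  sg <- sqrt(s$tau_rate / pmax(s$tau_shape - 1, 0.5))  # E[1/tau] guarded
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    eps <- matrix(rnorm(length(Fm)), nrow(Fm)) * rep(sg, each = nrow(Fm))
    out <- switch(s$noise,
      gaussian = Fm + eps,
      hurdle = {
        lat <- Fm + eps
        drop <- matrix(runif(length(Fm)) < plogis(-Fm), nrow(Fm))
        y <- pmax(expm1(lat), 0)
        y[drop] <- 0
        y
      },
      poisson = matrix(rpois(length(Fm), softplus(Fm)), nrow(Fm)))
    dimnames(out) <- dimnames(Fm)
    out
  }))
}
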