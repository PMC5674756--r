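#' Model hyperparameters
#'
#' @param fnr,fpr Assumed annotation false-negative / false-positive rates:
#'   the probability that the database omits a truly regulated gene (`fnr`)
#'   or includes an unregulated one (`fpr`). Defaults 0.001 and 0.01.
#' @param ard_a,ard_b Gamma shape/rate of the ARD prior on each factor's
#'   slab precision alpha_k; broad by default (1e-3, 1e-3).
#' @param noise_a,noise_b Gamma shape/rate of the prior on per-gene residual
#'   precisions (Gaussian/hurdle models).
#' @param prior_pi_annotated Prior inclusion probability of the regulatory
#'   indicator for annotated factors. Uninformative (0.5): the annotation
#'   enters through the likelihood, not the prior.
#' @param prior_pi_sparse,prior_pi_dense Indicator priors for sparse (0.01)
#'   and dense/confounder-like (0.99) unannotated factors.
#' @return A list of class `pf_hyper`.
#' @export
pf_hyper <- function(fnr = 0.001, fpr = 0.01,
                     ard_a = 1e-3, ard_b = 1e-3,
                     noise_a = 1e-3, noise_b = 1e-3,
                     prior_pi_annotated = 0.5,
                     prior_pi_sparse = 0.01, prior_pi_dense = 0.99) {
  rates <- c(fnr = fnr, fpr = fpr, prior_pi_annotated = prior_pi_annotated,
             prior_pi_sparse = prior_pi_sparse,
             prior_pi_dense = prior_pi_dense)
  if (any(rates <= 0 | rates >= 1))
    stop("probabilities must lie strictly in (0, 1): ",
         paste(names(rates)[rates <= 0 | rates >= 1], collapse = ", "))
  shapes <- c(ard_a = ard_a, ard_b = ard_b, noise_a = noise_a,
              noise_b = noise_b)
  if (any(shapes <= 0)) stop("Gamma shapes/rates must be positive")
  structure(list(fnr = fnr, fpr = fpr, ard_a = ard_a, ard_b = ard_b,
                 noise_a = noise_a, noise_b = noise_b,
                 prior_pi_annotated = prior_pi_annotated,
                 prior_pi_sparse = prior_pi_sparse,
                 prior_pi_dense = prior_pi_dense),
            class = "pf_hyper")
}

#' Annotation evidence term
#'
#' Log-likelihood of observing annotation state `I` given indicator state
#' `z`, replicated once per cell so that the relative weight of the
#' annotation against the expression likelihood (which also grows with the
#' number of cells) is independent of dataset size. With `z = 1` the
#' annotation is Bernoulli(1 - FPR); with `z = 0` it is Bernoulli(FNR).
#'
#' @param z Indicator state(s), 0/1 (vectorized).
#' @param I Observed annotation(s), 0/1 (vectorized).
#' @param hyper A [pf_hyper()] object (uses `fnr`, `fpr`).
#' @param n_cells Replication count N.
#' @return `n_cells * log P(I | z)`, vectorized over `z`/`I`.
#' @export
annotation_loglik <- function(z, I, hyper, n_cells) {
  stopifnot(all(z %in% 0:1), all(I %in% 0:1), n_cells >= 1)
  n <- max(length(z), length(I))
  z <- rep_len(z, n); I <- rep_len(I, n)
  l1 <- I * log1p(-hyper$fpr) + (1 - I) * log(hyper$fpr)
  l0 <- I * log(hyper$fnr) + (1 - I) * log1p(-hyper$fnr)
  n_cells * ifelse(z == 1, l1, l0)
}

# log P(I | z = 1) - log P(I | z = 0), replicated n_cells times.
annotation_logratio <- function(I, hyper, n_cells) {
  annotation_loglik(1, I, hyper, n_cells) -
    annotation_loglik(0, I, hyper, n_cells)
}

#' Assemble an (unfitted) model state
#'
#' Instantiates the factor layout in fixed order — covariates, annotated
#' factors (one per annotation column), sparse unannotated, dense
#' unannotated — and attaches priors. For the hurdle model with observed
#' zeros and for the Poisson model, a per-gene intercept is added as a fixed
#' covariate (per-gene centering, used by the Gaussian path, is undefined
#' for the zero process).
#'
#' @param Y Cells x genes expression matrix (see [pf_expression()]).
#' @param annotation Binary genes x sets matrix ([build_annotation_matrix()])
#'   or `NULL` for a purely unannotated model.
#' @param covariates Optional numeric N x C matrix of observed per-cell
#'   covariates (treated as fixed factor states with dense-type weight
#'   priors).
#' @param n_sparse,n_dense Numbers of sparse / dense unannotated factors.
#' @param hyper A [pf_hyper()] object.
#' @param noise One of `"gaussian"`, `"hurdle"`, `"poisson"`.
#' @return A list of class `pf_state` (unfitted; see [initialize_state()]).
#' @export
assemble_model <- function(Y, annotation = NULL, covariates = NULL,
                           n_sparse = 5L, n_dense = 3L,
                           hyper = pf_hyper(),
                           noise = c("gaussian", "hurdle", "poisson")) {
  noise <- match.arg(noise)
  stopifnot(n_sparse >= 0L, n_dense >= 0L)
  N <- nrow(Y); G <- ncol(Y)
  sc <- pf_scale(Y)
  if (noise == "poisson" && sc != "raw_counts")
    pf_stop(paste0("the Poisson model requires raw counts (scale = ",
                   "'raw_counts'), got '", sc, "'"), "pf_scale_error")
  if (noise == "hurdle" && any(Y < 0))
    pf_stop(paste0("the hurdle model requires non-negative (count-like) ",
                   "values; zeros are treated as dropout"), "pf_scale_error")
  if (!is.null(annotation)) {
    annotation <- as.matrix(annotation)
    if (nrow(annotation) != G)
      stop("annotation has ", nrow(annotation), " genes but Y has ", G)
    if (!is.null(rownames(annotation)) && !is.null(colnames(Y)) &&
        !identical(rownames(annotation), colnames(Y)))
      stop("annotation gene order does not match expression gene order")
    storage.mode(annotation) <- "double"
  }
  A <- if (is.null(annotation)) 0L else ncol(annotation)

  need_intercept <- noise == "poisson" || (noise == "hurdle" && any(Y == 0))
  cov_mat <- NULL
  cov_names <- character(0)
  if (need_intercept) {
    cov_mat <- matrix(1, N, 1L)
    cov_names <- "(intercept)"
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == N)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("covariate", seq_len(ncol(covariates)))
    cov_mat <- cbind(cov_mat, covariates)
    cov_names <- c(cov_names, colnames(covariates))
  }
  C <- length(cov_names)

  nms <- c(cov_names,
           if (A) colnames(annotation) %||% paste0("set", seq_len(A)),
           if (n_sparse) paste0("sparse", seq_len(n_sparse)),
           if (n_dense) paste0("dense", seq_len(n_dense)))
  if (anyDuplicated(nms))
    stop("duplicate factor names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  kind <- c(rep("covariate", C), rep("annotated", A),
            rep("sparse_unannotated", n_sparse),
            rep("dense_unannotated", n_dense))
  spec <- data.frame(
    name = nms, kind = kind,
    prior_pi = c(rep(hyper$prior_pi_dense, C),
                 rep(hyper$prior_pi_annotated, A),
                 rep(hyper$prior_pi_sparse, n_sparse),
                 rep(hyper$prior_pi_dense, n_dense)),
    annotation_column = c(rep(NA_integer_, C), seq_len(A),
                          rep(NA_integer_, n_sparse + n_dense)),
    stringsAsFactors = FALSE)

  structure(list(
    spec = spec, annotation = annotation, hyper = hyper, noise = noise,
    n_cells = N, n_genes = G, K = nrow(spec),
    covariate_values = cov_mat,
    cell_ids = rownames(Y), gene_ids = colnames(Y),
    initialized = FALSE), class = "pf_state")
}

#' Initialize the variational state
#'
#' Deterministic given `seed`. Annotated factor states start at the leading
#' principal component score of the (centered) annotated-gene submatrix,
#' scaled to unit variance, with sign fixed so the loading vector has
#' positive sum; dense unannotated factors start at successive leading
#' principal components of the full matrix (confounders are broad,
#' high-variance directions, and this shortens the otherwise slow phase in
#' which negative-control sets compete for confounder variance); sparse
#' unannotated factor states start at seeded standard normal
#' draws. Indicator posteriors start at the annotation-implied posterior
#' under the indicator prior; slab means at zero; ARD posteriors at mean
#' equal to the prior mean; residual precisions at the reciprocal empirical
#' gene variances.
#'
#' @param state A `pf_state` from [assemble_model()].
#' @param Y The expression matrix passed to [assemble_model()].
#' @param seed Integer seed.
#' @return The state, initialized (`state$initialized == TRUE`).
#' @export
initialize_state <- function(state, Y, seed = 1L) {
  stopifnot(inherits(state, "pf_state"))
  N <- state$n_cells; G <- state$n_genes; K <- state$K
  spec <- state$spec
  Yt <- if (state$noise == "gaussian") unclass(Y) else log1p(unclass(Y))
  gene_means <- colMeans(Yt)
  Tc <- sweep(Yt, 2L, gene_means)

  X_mean <- matrix(0, N, K, dimnames = list(state$cell_ids, spec$name))
  X_var <- matrix(1, N, K)
  is_cov <- spec$kind == "covariate"
  if (any(is_cov)) {
    X_mean[, is_cov] <- state$covariate_values
    X_var[, is_cov] <- 0
  }
  dense_k <- which(spec$kind == "dense_unannotated")
  pcs <- NULL
  if (length(dense_k)) {
    nd <- min(length(dense_k), dim(Tc) - c(1L, 0L))
    pcs <- tryCatch(svd(Tc, nu = nd, nv = nd), error = function(e) NULL)
  }
  # Annotated factors start on the submatrix signal that remains after the
  # *broad* directions claimed by the dense factors: a gene set lying inside
  # a confounder's support would otherwise initialize on the confounder
  # itself and stay entangled with it for many sweeps. A dense PC whose
  # loading mass is concentrated inside the set (> 50%) is a set-specific
  # signal, not a confounder, and is kept.
  annot_target <- function(genes) {
    sub <- Tc[, genes, drop = FALSE]
    if (is.null(pcs) || !length(dense_k)) return(sub)
    mass <- colSums(pcs$v[genes, , drop = FALSE]^2)
    broad <- which(mass < 0.5)
    if (!length(broad)) return(sub)
    U <- pcs$u[, broad, drop = FALSE]
    sub - U %*% crossprod(U, sub)
  }
  with_seed(seed, {
    for (k in seq_len(K)) {
      if (is_cov[k]) next
      ac <- spec$annotation_column[k]
      if (!is.na(ac)) {
        g <- which(state$annotation[, ac] == 1)
        sub <- annot_target(g)
        sv <- tryCatch(svd(sub, nu = 1L, nv = 1L), error = function(e) NULL)
        if (is.null(sv) || sv$d[1L] <= 1e-12) {
          X_mean[, k] <- rnorm(N)
        } else {
          score <- sv$u[, 1L] * sv$d[1L]
          if (sum(sv$v[, 1L]) < 0) score <- -score
          s <- sd(score)
          X_mean[, k] <- if (s > 0) score / s else rnorm(N)
        }
      } else if (k %in% dense_k && !is.null(pcs) &&
                 match(k, dense_k) <= ncol(pcs$u) &&
                 pcs$d[match(k, dense_k)] > 1e-12) {
        j <- match(k, dense_k)
        score <- pcs$u[, j] * pcs$d[j]
        if (sum(pcs$v[, j]) < 0) score <- -score
        s <- sd(score)
        X_mean[, k] <- if (s > 0) score / s else rnorm(N)
      } else {
        X_mean[, k] <- rnorm(N)
      }
    }
  })

  annot_lr <- matrix(0, G, K)   # cell-replicated annotation evidence, fixed
  annot_l0_total <- 0
  for (k in which(!is.na(spec$annotation_column))) {
    I <- state$annotation[, spec$annotation_column[k]]
    annot_lr[, k] <- annotation_logratio(I, state$hyper, N)
    annot_l0_total <- annot_l0_total +
      sum(annotation_loglik(0, I, state$hyper, N))
  }
  lo <- matrix(rep(qlogis(spec$prior_pi), each = G), G, K) + annot_lr
  gamma <- matrix(clip_prob(plogis(as.vector(lo))), G, K,
                  dimnames = list(state$gene_ids, spec$name))
  dimnames(lo) <- dimnames(gamma)

  vg <- pmax(apply(Yt, 2L, var), 1e-8)
  nz <- if (state$noise == "hurdle") colSums(Y > 0) else rep(N, G)

  state$X_mean <- X_mean
  state$X_var <- X_var
  state$gamma <- gamma
  state$logodds <- lo
  state$W_mean1 <- matrix(0, G, K, dimnames = dimnames(gamma))
  state$W_var1 <- matrix(1, G, K)
  state$alpha_shape <- rep(1, K)
  state$alpha_rate <- rep(1, K)
  state$tau_shape <- rep(1, G)
  state$tau_rate <- vg
  state$nonzero_per_gene <- nz
  state$gene_means <- gene_means
  state$annot_lr <- annot_lr
  state$annot_l0_total <- annot_l0_total
  # per-gene centering applies whenever the Gaussian path handles every
  # entry: always for gaussian noise, and for hurdle data without zeros
  state$center <- state$noise == "gaussian" ||
    (state$noise == "hurdle" && all(Y > 0))
  if (state$center) state$T_center <- Tc
  state$elbo_trace <- numeric(0)
  state$seed <- as.integer(seed)
  state$initialized <- TRUE
  state
}

clip_prob <- function(p, eps = 1e-10) pmin(pmax(p, eps), 1 - eps)

# Posterior moments of W implied by the coupled spike-and-slab posterior:
# E[w] = gamma * mu1, E[w^2] = gamma * (mu1^2 + s1^2).
pf_w_moments <- function(state) {
  Ew <- state$gamma * state$W_mean1
  Ew2 <- state$gamma * (state$W_mean1^2 + state$W_var1)
  list(Ew = Ew, Ew2 = Ew2)
}

#' @export
print.pf_state <- function(x, ...) {
  cat("pathfactor model state:", x$n_cells, "cells x", x$n_genes, "genes,",
      x$K, "factors\n")
  cat("Factors:", paste(sprintf("%d %s", table(x$spec$kind)[unique(x$spec$kind)],
                                unique(x$spec$kind)), collapse = ", "), "\n")
  cat("Noise model:", x$noise,
      if (isTRUE(x$initialized)) "(initialized)" else "(unfitted)", "\n")
  invisible(x)
}
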