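# Shared fixtures and independent oracles, all built in code.

write_tiny_gmt <- function(lines = c("SETA\tdesc\tg1\tg2\tg2",
                                     "SETB\tdesc\tg3\tg4\tg5")) {
  path <- tempfile(fileext = ".gmt")
  writeLines(lines, path)
  path
}

# small simulated dataset used across tests
tiny_sim <- function(seed = 7, n_cells = 60, n_genes = 400, n_active = 3,
                     n_negative = 4, sizes = c(15, 40), n_conf = 0, ...) {
  simulate_dataset(pf_sim_config(
    n_cells = n_cells, n_genes = n_genes, n_active_pathways = n_active,
    n_negative_pathways = n_negative, set_size_range = sizes,
    n_confounders = n_conf,
    confounder_gene_range = c(round(n_genes / 4), round(n_genes / 2)),
    seed = seed, ...))
}

quick_fit <- function(sim, n_dense = 1, n_sparse = 0, seed = 7,
                      max_iter = 80, tol = 1e-6, annotation = "true", ...) {
  ann <- switch(annotation, true = sim$true_annotation,
                corrupted = sim$corrupted_annotation, none = NULL)
  pathfactor(sim$Y, ann, n_sparse = n_sparse, n_dense = n_dense, seed = seed,
             control = pf_control(max_iter = max_iter, tol = tol), ...)
}

# independent AUC oracle: exhaustive concordant-pair counting with half
# credit for ties (Mann-Whitney)
auc_paircount <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# a 1-gene regression problem with degenerate (point-mass) alpha and tau
# posteriors so the coupled spike-and-slab update can be compared with
# exact enumeration over z
oracle_problem <- function(seed, N = 30, w_true = 0.8, noise_sd = 0.5,
                           alpha0 = 2, tau0 = 4, pi0 = 0.7,
                           annotated = FALSE, I_state = 1L,
                           hyper = pf_hyper()) {
  set.seed(seed)
  x <- rnorm(N)
  y <- w_true * x + rnorm(N, sd = noise_sd)
  Y <- pf_expression(matrix(y, N, 1), "log_counts")
  if (annotated) {
    # single annotated factor whose states are pinned to x (zero variance)
    # so the coupled update can be compared against exact enumeration
    ann <- matrix(I_state, 1L, 1L, dimnames = list(colnames(Y), "set1"))
    st <- assemble_model(Y, ann, NULL, n_sparse = 0, n_dense = 0,
                         hyper = hyper)
    st <- initialize_state(st, Y, seed)
    st$X_mean[, 1L] <- x
    st$X_var[, 1L] <- 0
  } else {
    st <- assemble_model(Y, NULL, covariates = matrix(x, N, 1),
                         n_sparse = 0, n_dense = 0, hyper = hyper)
    st <- initialize_state(st, Y, seed)
    st$spec$prior_pi[1L] <- pi0
  }
  S <- 1e12
  st$alpha_shape <- rep(S, st$K)
  st$alpha_rate <- rep(S, st$K) / alpha0
  st$tau_shape <- S
  st$tau_rate <- S / tau0
  list(state = st, Y = Y, x = x, y = y, alpha0 = alpha0, tau0 = tau0,
       pi0 = if (annotated) st$spec$prior_pi else pi0, N = N)
}

# exact posterior by enumeration over z with conjugate integration over w
# (slab marginal likelihood via numeric quadrature, independent of the
# implementation's algebra)
oracle_exact <- function(pb, k = 1L, I_state = NULL) {
  tt <- pb$y - mean(pb$y)
  x <- pb$x
  # slab marginal likelihood by quadrature in log space (the raw likelihood
  # underflows for mis-specified noise scales)
  logf <- function(w) vapply(w, function(wi)
    sum(dnorm(tt, wi * x, sqrt(1 / pb$tau0), log = TRUE)) +
      dnorm(wi, 0, sqrt(1 / pb$alpha0), log = TRUE), numeric(1L))
  centre <- sum(x * tt) / sum(x^2)
  hw <- 60 / sqrt(pb$tau0 * sum(x^2)) + 12 / sqrt(pb$alpha0) + abs(centre)
  m <- logf(centre)
  logL1 <- m + log(integrate(function(w) exp(logf(w) - m),
                             centre - hw, centre + hw, rel.tol = 1e-12,
                             subdivisions = 1000L)$value)
  logL0 <- sum(dnorm(tt, 0, sqrt(1 / pb$tau0), log = TRUE))
  pi0 <- pb$state$spec$prior_pi[k]
  lp1 <- log(pi0) + logL1
  lp0 <- log(1 - pi0) + logL0
  if (!is.null(I_state)) {
    h <- pb$state$hyper
    lp1 <- lp1 + annotation_loglik(1, I_state, h, pb$N)
    lp0 <- lp0 + annotation_loglik(0, I_state, h, pb$N)
  }
  gamma <- 1 / (1 + exp(lp0 - lp1))
  prec <- pb$tau0 * sum(x^2) + pb$alpha0
  list(gamma = gamma, mu1 = pb$tau0 * sum(x * tt) / prec, s1sq = 1 / prec)
}

fit_weights_once <- function(pb) {
  pd <- pathfactor:::compute_pseudo_data(pb$state, pb$Y)
  pathfactor:::update_weights(pb$state, pd)
}
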