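test_that("relevance is the inverse-ARD mean, ranked with stable ties", {
  sim <- tiny_sim(seed = 17)
  fit <- quick_fit(sim, max_iter = 20)
  K <- fit$state$K
  fit$state$alpha_shape <- rep(3, K)
  fit$state$alpha_rate <- rep(4, K)           # all tied: E[1/alpha] = 2
  fit$state$alpha_shape[K] <- 2e6 + 1
  fit$state$alpha_rate[K] <- 2                # concentrated at alpha = 1e6
  rel <- factor_relevance(fit)
  expect_equal(rel$relevance[rel$rank < K], rep(2, K - 1))
  # ties broken by assembly order
  expect_identical(rel$factor[rel$rank < K], fit$state$spec$name[-K])
  expect_equal(rel$relevance[rel$rank == K], 1e-6)
  expect_identical(rel$factor[rel$rank == K], fit$state$spec$name[K])
})

test_that("refinement applies the strict posterior threshold", {
  sim <- tiny_sim(seed = 19)
  fit <- quick_fit(sim, max_iter = 20)
  k <- which(!is.na(fit$state$spec$annotation_column))[1]
  I <- fit$state$annotation[, fit$state$spec$annotation_column[k]]
  # posterior equal to annotation -> empty refinement
  for (kk in which(!is.na(fit$state$spec$annotation_column)))
    fit$state$gamma[, kk] <- ifelse(
      fit$state$annotation[, fit$state$spec$annotation_column[kk]] == 1,
      0.9, 0.1)
  refin <- refine_gene_sets(fit)
  expect_true(all(vapply(refin, function(r)
    nrow(r$added) + nrow(r$removed) == 0L, logical(1))))
  # one gene each side of the threshold, plus exact ties
  out_g <- which(I == 0)[1:2]; in_g <- which(I == 1)[1:2]
  fit$state$gamma[out_g, k] <- c(0.6, 0.5)    # added; tie -> unchanged
  fit$state$gamma[in_g, k] <- c(0.4, 0.5)     # removed; tie -> unchanged
  r <- refine_gene_sets(fit)[[fit$state$spec$name[k]]]
  expect_identical(r$added$gene, fit$state$gene_ids[out_g[1]])
  expect_identical(r$removed$gene, fit$state$gene_ids[in_g[1]])
  expect_equal(r$added$posterior, 0.6)
})

test_that("residuals reconstruct, remove factors, and impute dropouts", {
  sim <- tiny_sim(seed = 23, n_conf = 1)
  fit <- quick_fit(sim, n_dense = 1, max_iter = 60)
  # removing nothing is the identity
  expect_equal(unclass(residual_expression(fit, sim$Y)),
               unclass(sim$Y), tolerance = 1e-12, ignore_attr = TRUE)
  # removed contributions plus residual reconstruct Y exactly
  res <- residual_expression(fit, sim$Y, remove = c("pathway1", "dense1"))
  Ew <- coef(fit)
  contrib <- fit$state$X_mean[, c("pathway1", "dense1")] %*%
    t(Ew[, c("pathway1", "dense1")])
  expect_equal(unclass(res) + contrib, unclass(sim$Y), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(residual_expression(fit, sim$Y, remove = "nope"),
               "known factors")
  # hurdle: zeros are imputed with the latent mean, others use log1p
  set.seed(23)
  Yc <- matrix(rpois(40 * 100, 5), 40, 100)
  colnames(Yc) <- paste0("gene", 1:100)
  I <- build_annotation_matrix(list(s = paste0("gene", 1:20)), colnames(Yc),
                               min_genes = 5)
  fh <- pathfactor(pf_expression(Yc, "raw_counts"), I, n_sparse = 0,
                   n_dense = 1, noise = "hurdle", seed = 23,
                   control = pf_control(max_iter = 20, tol = 1e-6))
  rh <- residual_expression(fh, fh$Y)
  zero <- Yc == 0
  expect_true(all(is.finite(unclass(rh))))
  expect_equal(unclass(rh)[!zero], log1p(Yc[!zero]), tolerance = 1e-12)
  expect_false(any(unclass(rh)[zero] == 0 &
                     predict(fh)[zero] != 0))
})

test_that("factor-state export matches the posterior and the covariates", {
  sim <- tiny_sim(seed = 29)
  cov <- matrix(rnorm(nrow(sim$Y)), ncol = 1,
                dimnames = list(NULL, "batch"))
  fit <- pathfactor(sim$Y, sim$true_annotation, covariates = cov,
                    n_sparse = 0, n_dense = 1, seed = 29,
                    control = pf_control(max_iter = 30, tol = 1e-6))
  st <- export_factor_states(fit, c("pathway1", "dense1"))
  expect_identical(dim(st), c(nrow(sim$Y), 4L))
  expect_identical(colnames(st), c("pathway1_mean", "pathway1_sd",
                                   "dense1_mean", "dense1_sd"))
  stc <- export_factor_states(fit, "batch")
  expect_equal(stc$batch_mean, cov[, 1])
  expect_equal(stc$batch_sd, rep(0, nrow(cov)))
  expect_error(export_factor_states(fit, "ghost"), "unknown")
})

test_that("a factor loaded on a binary group separates the groups", {
  set.seed(37)
  N <- 80; G <- 300
  grp <- rep(c(0, 1), each = N / 2)
  X <- cbind(scale(grp + rnorm(N, sd = 0.2)), rnorm(N))
  W <- matrix(0, G, 2)
  W[1:40, 1] <- rnorm(40); W[41:80, 2] <- rnorm(40)
  Y <- pf_expression(X %*% t(W) + matrix(rnorm(N * G, sd = 0.1), N, G),
                     "log_counts",
                     gene_ids = paste0("gene", 1:G))
  I <- build_annotation_matrix(list(grp_set = paste0("gene", 1:40),
                                    other = paste0("gene", 41:80)),
                               colnames(Y), min_genes = 5)
  fit <- pathfactor(Y, I, n_sparse = 0, n_dense = 1, seed = 37,
                    control = pf_control(max_iter = 80, tol = 1e-6))
  states <- export_factor_states(fit, "grp_set")
  expect_gt(max(auc_paircount(states$grp_set_mean, grp),
                1 - auc_paircount(states$grp_set_mean, grp)), 0.9)
})

test_that("the churn diagnostic fires at and above 100% churn", {
  sim <- tiny_sim(seed = 41, n_active = 1, n_negative = 1, n_genes = 200,
                  sizes = c(50, 50))
  fit <- quick_fit(sim, max_iter = 15)
  force_churn <- function(fit, k, gained, lost) {
    # pin every annotated factor to agreement, then perturb factor k
    for (kk in which(!is.na(fit$state$spec$annotation_column))) {
      I <- fit$state$annotation[, fit$state$spec$annotation_column[kk]]
      fit$state$gamma[, kk] <- ifelse(I == 1, 0.9, 0.1)
    }
    I <- fit$state$annotation[, fit$state$spec$annotation_column[k]]
    g <- fit$state$gamma[, k]
    g[sample(which(I == 0), gained)] <- 0.9
    g[sample(which(I == 1), lost)] <- 0.1
    fit$state$gamma[, k] <- g
    fit
  }
  set.seed(1)
  # 30 gained + 25 lost on a 50-gene set: churn 1.1 -> activate
  d1 <- diagnose_sparse_need(force_churn(fit, 1, 30, 25))
  expect_true(d1$activate)
  expect_equal(max(d1$churn$churn), 1.1)
  # churn exactly 1.0 is inclusive
  d2 <- diagnose_sparse_need(force_churn(fit, 1, 25, 25))
  expect_true(d2$activate)
  # zero churn -> no recommendation
  d3 <- diagnose_sparse_need(force_churn(fit, 1, 0, 0))
  expect_false(d3$activate)
  expect_equal(max(d3$churn$churn), 0)
})

test_that("model methods print, predict, simulate and plot", {
  sim <- tiny_sim(seed = 43)
  fit <- quick_fit(sim, max_iter = 30)
  expect_output(print(fit), "sparse factor model")
  expect_output(print(summary(fit)), "relevance")
  expect_identical(dim(coef(fit)), c(ncol(sim$Y), fit$state$K))
  rec <- predict(fit)
  expect_identical(dim(rec), dim(unclass(sim$Y)))
  expect_lt(mean((rec - unclass(sim$Y))^2), var(as.vector(unclass(sim$Y))))
  ys <- simulate(fit, nsim = 2, seed = 1)
  expect_length(ys, 2L)
  expect_identical(dim(ys[[1]]), dim(unclass(sim$Y)))
  pdf(NULL)
  expect_silent(plot(fit))
  expect_silent(plot(fit, type = "factors",
                     factors = c("pathway1", "pathway2")))
  dev.off()
})
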