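test_that("factor states revert to the prior when all weights are zero", {
  sim <- tiny_sim(seed = 3)
  st <- assemble_model(sim$Y, sim$true_annotation, n_sparse = 0, n_dense = 1)
  st <- initialize_state(st, sim$Y, 3)
  st$gamma[] <- 1e-10
  st$W_mean1[] <- 0
  st$W_var1[] <- 0
  pd <- pathfactor:::compute_pseudo_data(st, sim$Y)
  st <- pathfactor:::update_factor_states(st, pd)
  expect_equal(max(abs(st$X_mean)), 0, tolerance = 1e-8)
  expect_equal(unname(st$X_var[1, ]), rep(1, st$K), tolerance = 1e-10)
})

test_that("single-gene factor-state update matches conjugate regression", {
  set.seed(21)
  N <- 25
  w <- 1.3; tau0 <- 9
  y <- rnorm(N)
  Y <- pf_expression(matrix(y, N, 1), "log_counts")
  st <- assemble_model(Y, NULL, NULL, n_sparse = 1, n_dense = 0)
  st <- initialize_state(st, Y, 21)
  st$gamma[] <- 1 - 1e-10
  st$W_mean1[] <- w
  st$W_var1[] <- 0
  st$tau_shape <- 1e12; st$tau_rate <- 1e12 / tau0
  pd <- pathfactor:::compute_pseudo_data(st, Y)
  st <- pathfactor:::update_factor_states(st, pd)
  tt <- y - mean(y)
  v_ex <- 1 / (1 + tau0 * w^2)            # N(0,1) prior x conjugate likelihood
  m_ex <- v_ex * tau0 * w * tt
  expect_equal(unname(st$X_mean[, 1]), m_ex, tolerance = 1e-10)
  expect_equal(unname(st$X_var[1, 1]), v_ex, tolerance = 1e-10)
})

test_that("coupled weight update matches exact enumeration over z", {
  for (seed in c(9, 23)) {
    pb <- oracle_problem(seed, pi0 = c(0.7, 0.05)[1 + seed %% 2])
    st1 <- fit_weights_once(pb)
    ex <- oracle_exact(pb)
    expect_equal(st1$gamma[1, 1], ex$gamma, tolerance = 1e-8)
    expect_equal(st1$W_mean1[1, 1], ex$mu1, tolerance = 1e-8)
    expect_equal(st1$W_var1[1, 1], ex$s1sq, tolerance = 1e-8)
    # fixed point: a second update does not move the posterior
    pd <- pathfactor:::compute_pseudo_data(st1, pb$Y)
    st2 <- pathfactor:::update_weights(st1, pd)
    expect_equal(st2$gamma, st1$gamma, tolerance = 1e-12)
  }
})

test_that("strong ubiquitous signal drives dense-factor gamma to one", {
  set.seed(4)
  N <- 80; G <- 60
  f <- rnorm(N)
  Y <- pf_expression(f %*% t(rnorm(G, 2, 0.3)) +
                       matrix(rnorm(N * G, sd = 0.1), N, G), "log_counts")
  fit <- pathfactor(Y, NULL, n_sparse = 0, n_dense = 1, seed = 4,
                    control = pf_control(max_iter = 40, tol = 1e-8))
  expect_gt(min(fit$state$gamma[, 1]), 0.99)
})

test_that("ARD update follows its closed form and calibrates to truth", {
  sim <- tiny_sim(seed = 6, n_genes = 500)
  st <- assemble_model(sim$Y, sim$true_annotation, n_sparse = 0, n_dense = 1)
  st <- initialize_state(st, sim$Y, 6)
  a <- st$hyper$ard_a; b <- st$hyper$ard_b
  # all-inactive factor keeps the prior
  st$gamma[] <- 0
  st0 <- pathfactor:::update_ard(st)
  expect_equal(unname(st0$alpha_shape), rep(a, st$K))
  expect_equal(unname(st0$alpha_rate), rep(b, st$K))
  # fully active factor with E[w^2|z=1] = v
  G <- st$n_genes
  st$gamma[] <- 1
  st$W_mean1[] <- 2; st$W_var1[] <- 1    # v = 5
  st1 <- pathfactor:::update_ard(st)
  expect_equal(unname(st1$alpha_shape), rep(a + G / 2, st$K))
  expect_equal(unname(st1$alpha_rate), rep(b + G * 5 / 2, st$K))
  # slab weights simulated at unit variance -> E[1/alpha] within 20% of 1
  set.seed(61)
  st$W_mean1[] <- rnorm(length(st$W_mean1)); st$W_var1[] <- 0
  st2 <- pathfactor:::update_ard(st)
  rel <- st2$alpha_rate / (st2$alpha_shape - 1)
  expect_true(all(abs(rel - 1) < 0.2))
})

test_that("noise update recovers per-gene residual scales", {
  set.seed(31)
  N <- 500
  Y <- pf_expression(cbind(rnorm(N, sd = 0.1), rnorm(N, sd = 1)),
                     "log_counts")
  fit <- pathfactor(Y, NULL, n_sparse = 0, n_dense = 0, seed = 31,
                    control = pf_control(max_iter = 5, min_iter = 1,
                                         tol = 1e-3))
  s2 <- fit$state$tau_rate / (fit$state$tau_shape - 1)  # E[sigma_g^2]
  expect_lt(abs(sqrt(s2[1]) - 0.1) / 0.1, 0.1)
  ratio <- s2[2] / s2[1]
  expect_gt(ratio, 100 / 1.5)
  expect_lt(ratio, 100 * 1.5)
})

test_that("non-Gaussian bounds are tight at their expansion points", {
  # hurdle zero-process at f = 0: bound value equals -log 2
  expect_equal(pathfactor:::jj_lambda(0), 1 / 8)
  xi <- 0
  expect_equal(plogis(xi, log.p = TRUE) - (0 + xi) / 2, -log(2))
  # JJ bound is a true lower bound of log sigma(-f), tight at |f| = xi
  f <- seq(-4, 4, by = 0.25)
  for (xi in c(0.5, 2)) {
    lam <- pathfactor:::jj_lambda(xi)
    bound <- plogis(xi, log.p = TRUE) - (f + xi) / 2 - lam * (f^2 - xi^2)
    expect_true(all(bound <= plogis(-f, log.p = TRUE) + 1e-12))
    expect_equal(bound[f == xi], plogis(-xi, log.p = TRUE))
  }
  # poisson link at f = 0: rate log 2 and log P(0) = -log 2
  expect_equal(pathfactor:::softplus(0), log(2))
  expect_equal(dpois(0, pathfactor:::softplus(0), log = TRUE), -log(2))
})

test_that("ELBO with no factors equals the closed-form Gaussian bound", {
  set.seed(10)
  N <- 40; G <- 5
  Y <- pf_expression(matrix(rnorm(N * G), N, G), "log_counts")
  st <- assemble_model(Y, NULL, NULL, n_sparse = 0, n_dense = 0)
  st <- initialize_state(st, Y, 1)
  r <- fit_state(st, Y, pf_control(max_iter = 3, min_iter = 1, tol = 1e-12))
  a <- st$hyper$noise_a; b <- st$hyper$noise_b
  ss <- colSums(sweep(unclass(Y), 2, colMeans(Y))^2)
  closed <- sum(-N / 2 * log(2 * pi) + a * log(b) - lgamma(a) +
                  lgamma(a + N / 2) - (a + N / 2) * log(b + ss / 2))
  expect_equal(tail(r$state$elbo_trace, 1), closed, tolerance = 1e-10)
})

test_that("fitting a three-factor dataset recovers the drivers", {
  sim <- tiny_sim(seed = 13, n_cells = 100, n_genes = 500, n_active = 3,
                  n_negative = 4)
  fit <- quick_fit(sim, n_dense = 1, max_iter = 200, tol = 1e-6, seed = 13)
  rel <- factor_relevance(fit)
  top3 <- rel$factor[rel$kind == "annotated"][1:3]
  expect_setequal(top3, paste0("pathway", 1:3))
  # inactive sets deactivate far below the active factors
  act <- rel$relevance[rel$factor %in% paste0("pathway", 1:3)]
  neg <- rel$relevance[rel$factor %in% paste0("pathway", 4:7)]
  expect_lt(max(neg), 0.05 * median(act))
  # factor states recover the simulated states
  for (j in 1:3)
    expect_gt(abs(cor(fit$state$X_mean[, paste0("pathway", j)],
                      sim$X_true[, j])), 0.95)
})

test_that("a huge tolerance stops the fit at min_iter", {
  sim <- tiny_sim(seed = 8, n_cells = 30, n_genes = 120, n_active = 2,
                  n_negative = 2, sizes = c(10, 20))
  st <- assemble_model(sim$Y, sim$true_annotation, n_sparse = 0, n_dense = 1)
  st <- initialize_state(st, sim$Y, 8)
  r <- fit_state(st, sim$Y, pf_control(max_iter = 50, min_iter = 4,
                                       tol = 1e6))
  expect_identical(r$n_iter, 4L)
  expect_true(r$converged)
})

test_that("hurdle reduces exactly to the Gaussian model without zeros", {
  set.seed(3)
  N <- 50; G <- 200
  Yc <- matrix(rpois(N * G, 20) + 1, N, G)
  colnames(Yc) <- paste0("gene", 1:G)
  I <- build_annotation_matrix(list(s1 = paste0("gene", 1:30),
                                    s2 = paste0("gene", 31:60)),
                               colnames(Yc), min_genes = 5)
  ctl <- pf_control(max_iter = 40, tol = 1e-8)
  fg <- pathfactor(pf_expression(log1p(Yc), "log_counts"), I, n_sparse = 0,
                   n_dense = 1, noise = "gaussian", seed = 5, control = ctl)
  fh <- pathfactor(pf_expression(Yc, "raw_counts"), I, n_sparse = 0,
                   n_dense = 1, noise = "hurdle", seed = 5, control = ctl)
  expect_lt(max(abs(fg$state$X_mean - fh$state$X_mean)), 1e-6)
  expect_lt(max(abs(coef(fg) - coef(fh))), 1e-6)
})

test_that("hurdle with zeros keeps a finite, ascending bound", {
  set.seed(12)
  N <- 50; G <- 150
  Yc <- matrix(rpois(N * G, 8), N, G)
  colnames(Yc) <- paste0("gene", 1:G)
  I <- build_annotation_matrix(list(s1 = paste0("gene", 1:25)),
                               colnames(Yc), min_genes = 5)
  fit <- pathfactor(pf_expression(Yc, "raw_counts"), I, n_sparse = 0,
                    n_dense = 1, noise = "hurdle", seed = 12,
                    control = pf_control(max_iter = 30, tol = 1e-9))
  expect_true(all(is.finite(fit$elbo_trace)))
  expect_true(all(diff(fit$elbo_trace) >
                    -1e-8 * abs(head(fit$elbo_trace, -1))))
  # poisson path also runs to a finite bound on the same counts
  fp <- pathfactor(pf_expression(Yc, "raw_counts"), I, n_sparse = 0,
                   n_dense = 1, noise = "poisson", seed = 12,
                   control = pf_control(max_iter = 15, min_iter = 5,
                                        tol = 1e-6))
  expect_true(all(is.finite(fp$elbo_trace)))
})
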