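#' Fit-loop control parameters
#'
#' @param max_iter Maximum number of coordinate-ascent sweeps.
#' @param tol Relative ELBO convergence tolerance; the fit stops once the
#'   relative change is below `tol` on two consecutive checks.
#' @param min_iter Minimum number of sweeps before convergence may trigger.
#' @param elbo_every Sweeps between ELBO evaluations.
#' @param churn_check Record per-sweep annotation churn of annotated factors.
#' @param verbose Print per-sweep progress to stderr.
#' @return A list of class `pf_control`.
#' @export
pf_control <- function(max_iter = 1000L, tol = 1e-5, min_iter = 10L,
                       elbo_every = 1L, churn_check = TRUE, verbose = FALSE) {
  stopifnot(max_iter >= min_iter, min_iter >= 1L, tol > 0, elbo_every >= 1L)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 min_iter = as.integer(min_iter),
                 elbo_every = as.integer(elbo_every),
                 churn_check = isTRUE(churn_check),
                 verbose = isTRUE(verbose)),
            class = "pf_control")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Jaakkola-Jordan lambda(xi) = tanh(xi/2)/(4 xi), continuous at 0 (-> 1/8).
jj_lambda <- function(xi) {
  out <- rep(0.125, length(xi))
  nz <- xi > 1e-8
  out[nz] <- tanh(xi[nz] / 2) / (4 * xi[nz])
  out
}

pf_moments <- function(state) {
  wm <- pf_w_moments(state)
  list(Ex = state$X_mean, Ex2 = state$X_mean^2 + state$X_var,
       Ew = wm$Ew, Ew2 = wm$Ew2,
       tau = state$tau_shape / state$tau_rate,
       Elog_tau = digamma(state$tau_shape) - log(state$tau_rate),
       Ealpha = state$alpha_shape / pmax(state$alpha_rate, 1e-12),
       Elog_alpha = digamma(state$alpha_shape) -
         log(pmax(state$alpha_rate, 1e-12)))
}

#' Compute Gaussian pseudo-data for the current noise model
#'
#' Gaussian path: the (per-gene centered) observations themselves, with
#' per-gene precision E[tau_g]. Hurdle: positive observations contribute
#' `log(y+1)` targets at precision E[tau_g]; zero observations contribute a
#' Jaakkola-Jordan quadratic lower bound of the logistic dropout term
#' `-log(1+exp(f))`, tightened at `xi^2 = E[f^2]`. Poisson: a second-order
#' expansion of the softplus-link log-likelihood at `E[f]`, with curvature
#' clipped to `[1e-4, 1e4]`. Every update then reuses the conjugate path.
#'
#' @param state Initialized `pf_state`.
#' @param Y Expression matrix.
#' @return A list with targets `T`, and either a per-gene precision vector
#'   `tau` (`uniform = TRUE`) or an entrywise precision matrix `P`.
#' @keywords internal
compute_pseudo_data <- function(state, Y) {
  mo <- pf_moments(state)
  if (state$noise == "poisson" && any(Y < 0))
    stop("negative values are not valid Poisson counts")
  if (state$center) {
    Tm <- state$T_center
    if (is.null(Tm)) {
      Tm <- if (state$noise == "gaussian") unclass(Y) else log1p(unclass(Y))
      Tm <- sweep(Tm, 2L, state$gene_means)
    }
    return(list(T = Tm, tau = mo$tau, uniform = TRUE))
  }
  Fm <- mo$Ex %*% t(mo$Ew)
  Varf <- mo$Ex2 %*% t(mo$Ew2) - (mo$Ex^2) %*% t(mo$Ew^2)
  Varf[Varf < 0] <- 0
  if (state$noise == "hurdle") {
    zero <- unclass(Y) == 0
    Tm <- log1p(unclass(Y))
    P <- matrix(rep(mo$tau, each = nrow(Y)), nrow(Y), ncol(Y))
    xi <- sqrt(Fm[zero]^2 + Varf[zero])
    lam <- jj_lambda(xi)
    P[zero] <- 2 * lam
    Tm[zero] <- -1 / (4 * lam)
    return(list(T = Tm, P = P, uniform = FALSE, zero = zero, xi = xi))
  }
  # poisson: h(f) = y log(softplus(f)) - softplus(f); expand at E[f]
  yv <- unclass(Y)
  sig <- plogis(Fm)
  sp <- softplus(Fm)
  h1 <- sig * (yv / sp - 1)
  h2 <- sig * (1 - sig) * (yv / sp - 1) - sig^2 * yv / sp^2
  cc <- pmin(pmax(-h2, 1e-4), 1e4)
  list(T = Fm + h1 / cc, P = cc, uniform = FALSE)
}

#' Update the coupled spike-and-slab weight posteriors
#'
#' For each gene-factor pair, jointly updates the indicator posterior
#' `gamma[g,k]` and the conditional slab moments to the optimal coupled
#' posterior: slab moments from the conditional Gaussian regression against
#' the factor's state moments, and the indicator log-odds combining the
#' data-fit difference of slab versus spike, the indicator prior, and (for
#' annotated factors) the cell-replicated annotation evidence.
#'
#' @keywords internal
update_weights <- function(state, pd) {
  mo <- pf_moments(state)
  spec <- state$spec
  K <- state$K; G <- state$n_genes; N <- state$n_cells
  Ew <- mo$Ew
  lo_prior <- qlogis(spec$prior_pi)
  annot_lr <- state$annot_lr
  if (is.null(annot_lr)) {
    annot_lr <- matrix(0, G, K)
    for (k in which(!is.na(spec$annotation_column)))
      annot_lr[, k] <- annotation_logratio(
        state$annotation[, spec$annotation_column[k]], state$hyper, N)
  }

  state$Sg_cache <- NULL                 # moments are about to change
  if (pd$uniform) {
    B <- crossprod(pd$T, mo$Ex)          # G x K
    Gm <- crossprod(mo$Ex)               # K x K (on means)
    s2x <- colSums(mo$Ex2)
    for (k in seq_len(K)) {
      S2 <- pd$tau * s2x[k]
      S1 <- pd$tau * (B[, k] - Ew %*% Gm[, k] + Ew[, k] * Gm[k, k])
      state <- wz_update_k(state, k, drop(S1), S2, mo, lo_prior[k],
                           annot_lr[, k])
      Ew[, k] <- state$gamma[, k] * state$W_mean1[, k]
    }
  } else {
    Fm <- mo$Ex %*% t(Ew)
    for (k in seq_len(K)) {
      R <- pd$T - Fm + outer(mo$Ex[, k], Ew[, k])
      S2 <- drop(crossprod(pd$P, mo$Ex2[, k]))
      S1 <- drop(crossprod(pd$P * R, mo$Ex[, k]))
      old <- Ew[, k]
      state <- wz_update_k(state, k, S1, S2, mo, lo_prior[k], annot_lr[, k])
      Ew[, k] <- state$gamma[, k] * state$W_mean1[, k]
      Fm <- Fm + outer(mo$Ex[, k], Ew[, k] - old)
    }
  }
  if (!all(is.finite(state$W_mean1)))
    stop("non-finite slab moments in weight update")
  state
}

wz_update_k <- function(state, k, S1, S2, mo, lo_prior, annot_lr) {
  s1sq <- 1 / (S2 + mo$Ealpha[k])
  mu1 <- s1sq * S1
  lo <- lo_prior + annot_lr +
    0.5 * (mo$Elog_alpha[k] + log(s1sq)) + 0.5 * mu1^2 / s1sq
  state$logodds[, k] <- lo
  state$gamma[, k] <- clip_prob(plogis(lo))
  state$W_mean1[, k] <- mu1
  state$W_var1[, k] <- s1sq
  state
}

#' Update factor-state posteriors
#'
#' Each non-covariate column of `q(X)` is set to its conditional-Gaussian
#' optimum given the current weight moments, noise precisions and the
#' standard-normal prior; covariate columns are left untouched.
#'
#' @keywords internal
update_factor_states <- function(state, pd) {
  mo <- pf_moments(state)
  state$Sg_cache <- NULL
  free <- which(state$spec$kind != "covariate")
  if (!length(free)) return(state)
  Ex <- mo$Ex
  if (pd$uniform) {
    Wt <- mo$Ew * pd$tau                 # G x K, tau recycled per column
    D <- pd$T %*% Wt                     # N x K
    H <- crossprod(mo$Ew, Wt)            # K x K
    c2 <- colSums(pd$tau * mo$Ew2)
    for (k in free) {
      v <- 1 / (1 + c2[k])
      m <- v * (D[, k] - Ex %*% H[, k] + Ex[, k] * H[k, k])
      if (!all(is.finite(m)))
        stop("non-finite factor-state update for factor '",
             state$spec$name[k], "'")
      Ex[, k] <- m
      state$X_mean[, k] <- m
      state$X_var[, k] <- v
    }
  } else {
    Fm <- Ex %*% t(mo$Ew)
    for (k in free) {
      R <- pd$T - Fm + outer(Ex[, k], mo$Ew[, k])
      prec <- 1 + drop(pd$P %*% mo$Ew2[, k])
      m <- drop((pd$P * R) %*% mo$Ew[, k]) / prec
      if (!all(is.finite(m)))
        stop("non-finite factor-state update for factor '",
             state$spec$name[k], "'")
      Fm <- Fm + outer(m - Ex[, k], mo$Ew[, k])
      Ex[, k] <- m
      state$X_mean[, k] <- m
      state$X_var[, k] <- 1 / prec
    }
  }
  state
}

# Per-factor scale move: replace q(x_k) by q(c x_k) and the slab by
# q(w_k / c), choosing c to maximize the ELBO. The likelihood term is
# invariant (all products x*w keep their moments); only the state prior,
# slab prior and entropies change, giving the closed-form optimum
#   c^2 = ((N - sum(gamma)) + sqrt((N - sum(gamma))^2 + 4*Sx*A)) / (2*Sx)
# with Sx = sum(E[x^2]) and A = E[alpha] * sum(gamma * E[w^2|z=1]).
# Removes the slow drift along the X/W scale redundancy.
rescale_factors <- function(state) {
  state$Sg_cache <- NULL
  free <- which(state$spec$kind != "covariate")
  Ealpha <- state$alpha_shape / pmax(state$alpha_rate, 1e-12)
  for (k in free) {
    Sx <- sum(state$X_mean[, k]^2 + state$X_var[, k])
    if (Sx <= 0) next
    sg <- sum(state$gamma[, k])
    A <- Ealpha[k] * sum(state$gamma[, k] *
                           (state$W_mean1[, k]^2 + state$W_var1[, k]))
    d <- state$n_cells - sg
    c2 <- (d + sqrt(d^2 + 4 * Sx * A)) / (2 * Sx)
    if (!is.finite(c2) || c2 <= 0) next
    c2 <- min(max(c2, 1e-12), 1e12)
    state$X_mean[, k] <- state$X_mean[, k] * sqrt(c2)
    state$X_var[, k] <- state$X_var[, k] * c2
    state$W_mean1[, k] <- state$W_mean1[, k] / sqrt(c2)
    state$W_var1[, k] <- state$W_var1[, k] / c2
  }
  state
}

#' Update ARD precisions
#'
#' Gamma posterior of each factor's slab precision alpha_k from the expected
#' number of active links and expected sum of squared slab weights:
#' shape = a + sum(gamma)/2, rate = b + sum(gamma * E[w^2 | z=1])/2.
#'
#' @keywords internal
update_ard <- function(state) {
  h <- state$hyper
  sw2 <- state$W_mean1^2 + state$W_var1
  state$alpha_shape <- h$ard_a + 0.5 * colSums(state$gamma)
  state$alpha_rate <- pmax(h$ard_b + 0.5 * colSums(state$gamma * sw2), 1e-12)
  state
}

# Per-gene expected sum of squared residuals against the Gaussian targets,
# over observed (Gaussian-path) entries. Returns the G-vector S_g.
expected_residual_ss <- function(state, pd, mo) {
  if (pd$uniform) {
    Fm <- mo$Ex %*% t(mo$Ew)
    s2x <- colSums(mo$Ex2)
    sm2x <- colSums(mo$Ex^2)
    varsum <- drop(mo$Ew2 %*% s2x - (mo$Ew^2) %*% sm2x)
    colSums((pd$T - Fm)^2) + pmax(varsum, 0)
  } else {
    Fm <- mo$Ex %*% t(mo$Ew)
    Varf <- mo$Ex2 %*% t(mo$Ew2) - (mo$Ex^2) %*% t(mo$Ew^2)
    Varf[Varf < 0] <- 0
    M <- !pd$zero
    colSums(M * ((pd$T - Fm)^2 + Varf))
  }
}

#' Update residual noise precisions
#'
#' Gaussian: per-gene Gamma posterior on tau_g from expected squared
#' residuals over all cells. Hurdle: over nonzero observations only.
#' Poisson: no update (the variance is mean-determined).
#'
#' @keywords internal
update_noise <- function(state, pd) {
  if (state$noise == "poisson") return(state)
  mo <- pf_moments(state)
  h <- state$hyper
  Sg <- expected_residual_ss(state, pd, mo)
  state$tau_shape <- h$noise_a + 0.5 * state$nonzero_per_gene
  state$tau_rate <- h$noise_b + 0.5 * Sg
  # valid for ELBO evaluation until the W/X moments next change
  state$Sg_cache <- Sg
  state
}

#' Evidence lower bound
#'
#' Expected complete-data log-likelihood (exact for the Gaussian model,
#' bound-based for hurdle zeros and the Poisson link) plus annotation
#' evidence and prior expectations, minus entropies.
#'
#' @keywords internal
compute_elbo <- function(state, Y) {
  mo <- pf_moments(state)
  spec <- state$spec
  N <- state$n_cells; G <- state$n_genes
  h <- state$hyper
  pd <- compute_pseudo_data(state, Y)

  if (state$noise == "gaussian" || state$center) {
    Sg <- state$Sg_cache %||% expected_residual_ss(state, pd, mo)
    lik <- sum(0.5 * N * (mo$Elog_tau - log(2 * pi)) - 0.5 * mo$tau * Sg)
  } else if (state$noise == "hurdle") {
    Sg <- state$Sg_cache %||% expected_residual_ss(state, pd, mo)
    nz <- state$nonzero_per_gene
    lik <- sum(0.5 * nz * (mo$Elog_tau - log(2 * pi)) - 0.5 * mo$tau * Sg)
    Fm <- mo$Ex %*% t(mo$Ew)
    # JJ bound at xi^2 = E[f^2]: E[log sigma(-f)] >= log sigma(xi)-(E[f]+xi)/2
    lik <- lik + sum(plogis(pd$xi, log.p = TRUE) -
                       (Fm[pd$zero] + pd$xi) / 2)
  } else {
    Fm <- mo$Ex %*% t(mo$Ew)
    Varf <- mo$Ex2 %*% t(mo$Ew2) - (mo$Ex^2) %*% t(mo$Ew^2)
    sp <- softplus(Fm)
    lik <- sum(unclass(Y) * log(sp) - sp - lgamma(unclass(Y) + 1) -
                 0.5 * pd$P * pmax(Varf, 0))
  }

  free <- spec$kind != "covariate"
  m <- state$X_mean[, free, drop = FALSE]
  v <- state$X_var[, free, drop = FALSE]
  kl_x <- sum(0.5 * (log(v) - m^2 - v + 1))

  g <- state$gamma
  pi_m <- matrix(rep(spec$prior_pi, each = G), G, state$K)
  mu1 <- state$W_mean1; s1 <- state$W_var1
  Ea <- matrix(rep(mo$Ealpha, each = G), G, state$K)
  Ela <- matrix(rep(mo$Elog_alpha, each = G), G, state$K)
  kl_wz <- sum(g * (log(pi_m) - log(g) +
                      0.5 * (Ela + log(s1) + 1 - Ea * (mu1^2 + s1))) +
                 (1 - g) * (log1p(-pi_m) - log1p(-g)))

  annot <- if (!is.null(state$annot_lr))
    state$annot_l0_total + sum(g * state$annot_lr)
  else 0
  if (is.null(state$annot_lr))
    for (k in which(!is.na(spec$annotation_column))) {
      I <- state$annotation[, spec$annotation_column[k]]
      annot <- annot + sum(g[, k] * annotation_loglik(1, I, h, N) +
                             (1 - g[, k]) * annotation_loglik(0, I, h, N))
    }

  kl_gamma_fun <- function(a, b, ah, bh) {
    Elog <- digamma(ah) - log(bh); E <- ah / bh
    sum(a * log(b) - ah * log(bh) - lgamma(a) + lgamma(ah) +
          (a - ah) * Elog - (b - bh) * E)
  }
  kl_alpha <- kl_gamma_fun(h$ard_a, h$ard_b, state$alpha_shape,
                           pmax(state$alpha_rate, 1e-12))
  kl_tau <- if (state$noise == "poisson") 0 else
    kl_gamma_fun(h$noise_a, h$noise_b, state$tau_shape, state$tau_rate)

  terms <- c(likelihood = lik, factor_states = kl_x, weights = kl_wz,
             annotation = annot, ard = kl_alpha, noise = kl_tau)
  if (any(!is.finite(terms)))
    stop("non-finite ELBO term(s): ",
         paste(names(terms)[!is.finite(terms)], collapse = ", "))
  sum(terms)
}

# Gains/losses of each annotated factor at the 0.5 posterior threshold,
# relative to the annotated-set size.
annotation_churn <- function(state, threshold = 0.5) {
  ann_k <- which(!is.na(state$spec$annotation_column))
  if (!length(ann_k)) return(NULL)
  t(vapply(ann_k, function(k) {
    I <- state$annotation[, state$spec$annotation_column[k]]
    gained <- sum(I == 0 & state$gamma[, k] > threshold)
    lost <- sum(I == 1 & state$gamma[, k] < threshold)
    n_ann <- sum(I)
    c(n_annotated = n_ann, n_gained = gained, n_lost = lost,
      churn = (gained + lost) / max(n_ann, 1L))
  }, numeric(4L)))
}

#' Run coordinate-ascent variational inference
#'
#' Sweeps pseudo-data, weights (factors in fixed order), factor states, ARD
#' and noise updates until the relative ELBO change falls below
#' `control$tol` on two consecutive checks, or `max_iter` is reached. Each
#' sweep costs O(N G K). A Gaussian-model ELBO that decreases beyond
#' tolerance on three consecutive checks aborts with an error.
#'
#' @param state Initialized `pf_state` (see [initialize_state()]).
#' @param Y Expression matrix passed to [assemble_model()].
#' @param control A [pf_control()] list.
#' @return A list with the converged `state`, `converged` flag, `n_iter`,
#'   final `pseudo_data`, per-sweep `churn` history and per-factor
#'   `churn_flags` (churn >= 1 at any sweep), and `sweep_seconds`.
#' @export
fit_state <- function(state, Y, control = pf_control()) {
  stopifnot(inherits(state, "pf_state"), isTRUE(state$initialized))
  elbo_prev <- -Inf
  small_changes <- 0L
  decreases <- 0L
  converged <- FALSE
  churn_hist <- list()
  t0 <- proc.time()[["elapsed"]]
  iter <- 0L
  pd <- NULL
  for (iter in seq_len(control$max_iter)) {
    pd <- compute_pseudo_data(state, Y)
    state <- update_weights(state, pd)
    state <- update_factor_states(state, pd)
    state <- rescale_factors(state)
    state <- update_ard(state)
    state <- update_noise(state, pd)
    if (control$churn_check)
      churn_hist[[iter]] <- annotation_churn(state)
    if (iter %% control$elbo_every == 0L || iter == control$max_iter) {
      elbo <- compute_elbo(state, Y)
      state$elbo_trace <- c(state$elbo_trace, elbo)
      if (control$verbose)
        message(sprintf("sweep %d: ELBO %.6f", iter, elbo))
      if (is.finite(elbo_prev)) {
        rel <- (elbo - elbo_prev) / abs(elbo_prev)
        if (state$noise == "gaussian" || state$center) {
          decreases <- if (rel < -1e-8) decreases + 1L else 0L
          if (decreases >= 3L)
            stop("ELBO decreased on three consecutive checks; ",
                 "inference diverged")
        }
        if (abs(rel) < control$tol) {
          small_changes <- small_changes + 1L
          if (small_changes >= 2L && iter >= control$min_iter) {
            converged <- TRUE
            break
          }
        } else small_changes <- 0L
      }
      elbo_prev <- elbo
    }
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  churn <- if (length(churn_hist)) churn_hist[[length(churn_hist)]] else NULL
  flags <- if (length(churn_hist)) {
    mx <- Reduce(pmax, lapply(churn_hist, function(m) m[, "churn"]))
    mx >= 1
  } else NULL
  list(state = state, converged = converged, n_iter = iter,
       pseudo_data = pd, churn = churn, churn_flags = flags,
       sweep_seconds = elapsed / iter)
}
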