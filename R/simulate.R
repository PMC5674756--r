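#' Simulation-study configuration
#'
#' Defines a synthetic dataset generated from the linear additive model:
#' active pathway factors with annotation support, dense confounders, unit
#' normal factor states and non-zero weights, Gaussian residual noise, an
#' annotation corrupted at chosen false-negative/false-positive/swap rates,
#' and optional dropout.
#'
#' @param n_cells Number of cells.
#' @param n_genes Number of genes (default 6000).
#' @param n_active_pathways Number of active (driver) gene sets, typically
#'   3-10.
#' @param n_negative_pathways Number of inactive gene sets included in the
#'   annotation as a negative set (default 15).
#' @param set_size_range Gene-set sizes are drawn uniformly from this range
#'   (default 20-933, spanning the REACTOME size spread; see
#'   `size_source`).
#' @param overlap Fraction (0-0.7) of each new set's genes drawn from
#'   previously built sets.
#' @param n_confounders Number of dense confounding factors.
#' @param confounder_gene_range Each confounder affects a uniform-random
#'   number of genes in this range (default 400-3000).
#' @param noise_sd Residual noise standard deviation (default 0.1).
#' @param fnr_sim,fpr_sim Annotation corruption: fraction of each active
#'   set's genes deleted / inserted (each within 0-0.5 and 0-0.1).
#' @param swap_frac Fraction of genes swapped between pairs of active sets
#'   (0-0.25).
#' @param dropout `NULL`, or a list with `mechanism` (one of `"threshold"`,
#'   `"exponential"`, `"both"`), `threshold` and `lambda`.
#' @param size_source Optional GMT path; if given, set sizes are resampled
#'   from that collection's set sizes instead of uniformly from
#'   `set_size_range`.
#' @param seed Integer master seed.
#' @return A list of class `pf_sim_config`.
#' @export
pf_sim_config <- function(n_cells = 100L, n_genes = 6000L,
                          n_active_pathways = 5L, n_negative_pathways = 15L,
                          set_size_range = c(20L, 933L), overlap = 0,
                          n_confounders = 0L,
                          confounder_gene_range = c(400L, 3000L),
                          noise_sd = 0.1, fnr_sim = 0, fpr_sim = 0,
                          swap_frac = 0, dropout = NULL, size_source = NULL,
                          seed = 1L) {
  stopifnot(n_cells >= 2L, n_genes >= max(set_size_range),
            n_active_pathways >= 1L, n_negative_pathways >= 0L,
            length(set_size_range) == 2L,
            set_size_range[1L] <= set_size_range[2L],
            overlap >= 0, overlap <= 0.7,
            n_confounders >= 0L,
            noise_sd >= 0, fnr_sim >= 0, fnr_sim <= 1,
            fpr_sim >= 0, fpr_sim <= 1, swap_frac >= 0, swap_frac <= 0.25)
  if (!is.null(dropout)) {
    stopifnot(is.list(dropout),
              dropout$mechanism %in% c("threshold", "exponential", "both"))
    if (!is.null(dropout$lambda) && dropout$lambda < 0)
      stop("dropout lambda must be non-negative")
  }
  structure(as.list(environment()), class = "pf_sim_config")
}

# Sequential annotation builder (no RNG management; callers seed).
sim_annotation_impl <- function(config) {
  G <- config$n_genes
  nA <- config$n_active_pathways; nN <- config$n_negative_pathways
  sizes <- if (!is.null(config$size_source)) {
    pool <- lengths(read_gmt(config$size_source)$sets)
    pool <- pool[pool >= config$set_size_range[1L] &
                   pool <= config$set_size_range[2L]]
    if (!length(pool)) stop("size_source has no sets inside set_size_range")
    resample(pool, nA + nN, replace = TRUE)
  } else {
    resample(seq(config$set_size_range[1L], config$set_size_range[2L]),
             nA + nN, replace = TRUE)
  }
  # actives first, each group ordered by decreasing size
  sizes <- c(sort(sizes[seq_len(nA)], decreasing = TRUE),
             sort(sizes[nA + seq_len(nN)], decreasing = TRUE))
  active <- c(rep(TRUE, nA), rep(FALSE, nN))
  genes <- paste0("gene", seq_len(G))
  I <- matrix(0L, G, nA + nN,
              dimnames = list(genes, paste0("pathway", seq_len(nA + nN))))
  used <- integer(0)  # union of genes in earlier sets
  for (k in seq_len(nA + nN)) {
    sz <- sizes[k]
    n_over <- if (k == 1L) 0L else round(config$overlap * sz)
    if (n_over > length(used))
      stop("infeasible overlap: set ", k, " needs ", n_over,
           " genes from earlier sets but only ", length(used), " exist")
    fresh_pool <- setdiff(seq_len(G), used)
    n_fresh <- sz - n_over
    if (n_fresh > length(fresh_pool))
      stop("not enough unused genes for set ", k,
           "; reduce set sizes or increase n_genes")
    members <- c(if (n_over) resample(used, n_over),
                 resample(fresh_pool, n_fresh))
    I[members, k] <- 1L
    used <- union(used, members)
  }
  list(annotation = I, active_mask = active)
}

#' Simulate a gene-set annotation
#'
#' Builds active and negative gene sets sequentially, largest first: each
#' new set draws `round(overlap * size)` genes from the union of previously
#' built sets and the remainder from genes not yet used by any set, so at
#' `overlap = 0` all sets are pairwise disjoint.
#'
#' @param config A [pf_sim_config()].
#' @return A list with `annotation` (binary genes x sets matrix, active
#'   sets first) and `active_mask` (logical).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "pf_sim_config"))
  with_seed(config$seed, sim_annotation_impl(config))
}

corrupt_annotation_impl <- function(annotation, fnr_sim, fpr_sim, swap_frac,
                                    active_mask) {
  I <- annotation
  act <- which(active_mask)
  if (swap_frac > 0 && length(act) < 2L)
    stop("swap_frac > 0 requires at least two active sets")
  bg <- which(rowSums(annotation[, act, drop = FALSE]) == 0)  # outside actives
  ledger <- list()
  note <- function(set, gene, action, mech)
    ledger[[length(ledger) + 1L]] <<- data.frame(
      set = colnames(I)[set], gene = rownames(I)[gene], action = action,
      mechanism = mech, stringsAsFactors = FALSE)
  for (k in act) {
    members <- which(annotation[, k] == 1L)
    n_del <- round(fnr_sim * length(members))
    if (n_del > 0L) {
      del <- resample(members, n_del)
      I[del, k] <- 0L
      note(k, del, "deleted", "fnr")
    }
    n_ins <- round(fpr_sim * length(members))
    if (n_ins > 0L) {
      pool <- intersect(bg, which(I[, k] == 0L))
      ins <- resample(pool, min(n_ins, length(pool)))
      I[ins, k] <- 1L
      note(k, ins, "inserted", "fpr")
    }
  }
  if (swap_frac > 0) {
    pairs <- matrix(act[seq_len(2L * (length(act) %/% 2L))], ncol = 2L,
                    byrow = TRUE)
    for (p in seq_len(nrow(pairs))) {
      k1 <- pairs[p, 1L]; k2 <- pairs[p, 2L]
      only1 <- which(annotation[, k1] == 1L & annotation[, k2] == 0L)
      only2 <- which(annotation[, k2] == 1L & annotation[, k1] == 0L)
      n_swap <- round(swap_frac * min(sum(annotation[, k1]),
                                      sum(annotation[, k2])))
      n_swap <- min(n_swap, length(only1), length(only2))
      if (n_swap < 1L) next
      g1 <- resample(only1, n_swap); g2 <- resample(only2, n_swap)
      I[g1, k1] <- 0L; I[g1, k2] <- 1L
      I[g2, k2] <- 0L; I[g2, k1] <- 1L
      note(k1, g1, "deleted", "swap"); note(k2, g1, "inserted", "swap")
      note(k2, g2, "deleted", "swap"); note(k1, g2, "inserted", "swap")
    }
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(set = character(), gene = character(), action = character(),
               mechanism = character(), stringsAsFactors = FALSE)
  list(annotation = I, ledger = ledger)
}

#' Corrupt a gene-set annotation
#'
#' Per active set, deletes a `fnr_sim` fraction of member genes, inserts an
#' `fpr_sim` fraction (of the set size) of genes drawn from outside all
#' active sets, and exchanges membership of a `swap_frac` fraction of genes
#' between pairs of active sets. Every edit is recorded in a ledger so that
#' corruption is exactly invertible and evaluable.
#'
#' @param annotation Binary genes x sets matrix (the truth).
#' @param fnr_sim,fpr_sim,swap_frac Corruption fractions.
#' @param seed Integer seed.
#' @param active_mask Logical vector marking active sets (default: all).
#' @return A list with `annotation` (corrupted matrix) and `ledger`
#'   (data.frame set, gene, action in deleted/inserted, mechanism).
#' @export
corrupt_annotation <- function(annotation, fnr_sim = 0, fpr_sim = 0,
                               swap_frac = 0, seed = 1L,
                               active_mask = rep(TRUE, ncol(annotation))) {
  with_seed(seed, corrupt_annotation_impl(annotation, fnr_sim, fpr_sim,
                                          swap_frac, active_mask))
}

#' Apply dropout to a simulated expression matrix
#'
#' The `threshold` mechanism deterministically zeroes values below the
#' detection threshold; the `exponential` mechanism zeroes each entry
#' independently with probability `exp(-lambda * f^2)` where `f` is the
#' latent (noise-free) expression level; `both` applies the threshold first.
#'
#' @param Y Observed matrix.
#' @param mechanism One of `"threshold"`, `"exponential"`, `"both"`.
#' @param threshold Detection threshold.
#' @param lambda Exponential decay parameter (>= 0).
#' @param seed Integer seed for the stochastic mechanism.
#' @param latent Latent expression levels `f` (defaults to `Y`).
#' @return A list with `Y` (after dropout) and `mask` (logical matrix of
#'   zeroed positions).
#' @export
apply_dropout <- function(Y, mechanism = c("threshold", "exponential", "both"),
                          threshold = 0, lambda = 1, seed = 1L,
                          latent = Y) {
  mechanism <- match.arg(mechanism)
  if (lambda < 0) stop("lambda must be non-negative")
  mask <- matrix(FALSE, nrow(Y), ncol(Y))
  out <- unclass(Y)
  if (mechanism %in% c("threshold", "both")) {
    mask <- out < threshold
    out[mask] <- 0
  }
  if (mechanism %in% c("exponential", "both")) {
    p <- exp(-lambda * unclass(latent)^2)
    drop <- with_seed(seed, matrix(runif(length(out)) < p, nrow(out)))
    out[drop] <- 0
    mask <- mask | drop
  }
  list(Y = out, mask = mask)
}

#' Simulate a full dataset with ground truth
#'
#' Draws factor states and non-zero weights as i.i.d. standard normals:
#' active-pathway weights are non-zero exactly on the true annotation
#' support, each confounder affects a uniform-random number of genes in
#' `confounder_gene_range`, and `Y = X W' + eps` with
#' `eps ~ N(0, noise_sd^2)`. The annotation (active plus negative sets) is
#' optionally corrupted and dropout applied.
#'
#' @param config A [pf_sim_config()].
#' @return A list of class `pf_sim`: `Y`, `true_annotation`,
#'   `corrupted_annotation`, `corruption` (ledger), `X_true`, `W_true`,
#'   `active_mask`, `confounder_states`, `confounder_genes`,
#'   `dropout_mask`, `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "pf_sim_config"))
  with_seed(config$seed, {
    ann <- sim_annotation_impl(config)
    N <- config$n_cells; G <- config$n_genes
    nA <- config$n_active_pathways; nC <- config$n_confounders
    K <- nA + nC
    X <- matrix(rnorm(N * K), N, K)
    W <- matrix(0, G, K)
    act_cols <- which(ann$active_mask)
    for (j in seq_len(nA)) {
      sup <- which(ann$annotation[, act_cols[j]] == 1L)
      W[sup, j] <- rnorm(length(sup))
    }
    conf_genes <- vector("list", nC)
    for (j in seq_len(nC)) {
      m <- resample(seq(config$confounder_gene_range[1L],
                        min(config$confounder_gene_range[2L], G)), 1L)
      conf_genes[[j]] <- sort(sample.int(G, m))
      W[conf_genes[[j]], nA + j] <- rnorm(m)
    }
    Yv <- X %*% t(W) + matrix(rnorm(N * G, sd = config$noise_sd), N, G)
    corr <- corrupt_annotation_impl(ann$annotation, config$fnr_sim,
                                    config$fpr_sim, config$swap_frac,
                                    ann$active_mask)
    dropout_mask <- NULL
    if (!is.null(config$dropout)) {
      dr <- apply_dropout(Yv, config$dropout$mechanism,
                          threshold = config$dropout$threshold %||% 0,
                          lambda = config$dropout$lambda %||% 1,
                          seed = sample.int(.Machine$integer.max, 1L),
                          latent = X %*% t(W))
      Yv <- dr$Y
      dropout_mask <- dr$mask
    }
    colnames(X) <- c(colnames(ann$annotation)[act_cols],
                     if (nC) paste0("confounder", seq_len(nC)))
    Y <- pf_expression(Yv, "log_counts",
                       cell_ids = paste0("cell", seq_len(N)),
                       gene_ids = rownames(ann$annotation))
    structure(list(
      Y = Y, true_annotation = ann$annotation,
      corrupted_annotation = corr$annotation, corruption = corr$ledger,
      X_true = X, W_true = W, active_mask = ann$active_mask,
      confounder_states = if (nC) X[, nA + seq_len(nC), drop = FALSE],
      confounder_genes = conf_genes, dropout_mask = dropout_mask,
      config = config), class = "pf_sim")
  })
}

#' @export
print.pf_sim <- function(x, ...) {
  cat("Simulated dataset:", nrow(x$Y), "cells x", ncol(x$Y), "genes;",
      sum(x$active_mask), "active +", sum(!x$active_mask),
      "negative gene sets;", x$config$n_confounders, "confounder(s)\n")
  if (nrow(x$corruption))
    cat("Annotation corruption:", sum(x$corruption$action == "deleted"),
        "deletions,", sum(x$corruption$action == "inserted"),
        "insertions\n")
  invisible(x)
}

#' Derive independent replicate configurations
#'
#' Deterministically derives `n_reps` child seeds from the master seed via
#' a counter-based multiplicative hash, yielding mutually independent
#' replicate datasets.
#'
#' @param config A [pf_sim_config()].
#' @param n_reps Number of replicates (the full protocol uses 50).
#' @param simulate If `TRUE`, return the simulated datasets; otherwise the
#'   reseeded configurations (default).
#' @return A list of `pf_sim_config` (or `pf_sim`) objects.
#' @export
run_replicates <- function(config, n_reps = 50L, simulate = FALSE) {
  stopifnot(inherits(config, "pf_sim_config"), n_reps >= 1L)
  m <- 2147483647
  child <- vapply(seq_len(n_reps), function(i) {
    as.integer(((config$seed %% m) * 48271 + i * 16807) %% m)
  }, integer(1L))
  out <- lapply(child, function(s) { cf <- config; cf$seed <- s; cf })
  if (simulate) lapply(out, simulate_dataset) else out
}
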