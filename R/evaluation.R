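#' ROC curve and AUC for recovering simulated drivers
#'
#' Ranks factors by score (factor relevance in the standard pipeline) and
#' computes the receiver operating characteristic against the active/
#' inactive labels. Tied scores contribute averaged (diagonal) steps, so the
#' trapezoidal AUC equals the Mann-Whitney statistic with mid-rank tie
#' handling and is invariant to strictly monotone transforms of the scores.
#'
#' @param relevances Numeric vector of factor scores (higher = more likely
#'   a true driver), optionally named.
#' @param active_mask Logical vector: `TRUE` for true simulated drivers.
#' @return A list with `roc_points` (data.frame fpr, tpr), `auc` and
#'   `ranking` (factor names or indices by decreasing score).
#' @export
driver_recovery <- function(relevances, active_mask) {
  stopifnot(length(relevances) == length(active_mask))
  active_mask <- as.logical(active_mask)
  n_pos <- sum(active_mask); n_neg <- sum(!active_mask)
  if (n_pos == 0L || n_neg == 0L)
    stop("driver recovery needs at least one active and one inactive factor")
  ord <- order(relevances, decreasing = TRUE)
  sc <- relevances[ord]; lab <- active_mask[ord]
  # group tied scores into single (diagonal) ROC steps
  grp <- cumsum(!duplicated(sc))
  tp <- cumsum(tapply(lab, grp, sum)[as.character(seq_len(max(grp)))])
  fp <- cumsum(tapply(!lab, grp, sum)[as.character(seq_len(max(grp)))])
  roc <- data.frame(fpr = c(0, unname(fp) / n_neg),
                    tpr = c(0, unname(tp) / n_pos))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  ranking <- if (!is.null(names(relevances))) names(relevances)[ord] else ord
  list(roc_points = roc, auc = auc, ranking = ranking)
}

#' AUC of gene-set augmentation against a corruption ground truth
#'
#' Evaluates, separately, the recovery of genes deleted from the annotation
#' (`auc_added`: among genes absent from each corrupted set, rank by the
#' inclusion score; positives are genes present in the true set) and the
#' rejection of genes wrongly inserted (`auc_removed`: among genes present
#' in each corrupted set, rank by the negated inclusion score; positives
#' are the inserted genes). Candidates are pooled across the factors whose
#' annotation was corrupted; per-factor AUCs are also returned.
#'
#' The inclusion score can be the posterior probability `gamma` or any
#' monotone transform of it; the fitted log-odds are preferable because
#' `gamma` saturates to 1 in double precision for strongly supported genes.
#'
#' @param score Genes x sets matrix of inclusion scores for the annotated
#'   factors (same layout as the annotation).
#' @param corrupted_annotation,true_annotation Binary genes x sets matrices.
#' @return A list with `auc_added`, `auc_removed` and `per_factor`
#'   (data.frame set, auc_added, auc_removed; `NA` where a set has no
#'   corruption of that kind).
#' @export
augmentation_recovery <- function(score, corrupted_annotation,
                                  true_annotation) {
  stopifnot(all(dim(score) == dim(corrupted_annotation)),
            all(dim(corrupted_annotation) == dim(true_annotation)))
  diff_cols <- which(colSums(corrupted_annotation != true_annotation) > 0)
  if (!length(diff_cols))
    stop("corrupted and true annotations are identical: nothing to evaluate")
  pool_auc <- function(cand, pos, sc) {
    if (!sum(pos[cand]) || all(pos[cand])) return(NA_real_)
    driver_recovery(sc[cand], pos[cand])$auc
  }
  add_cand <- rem_cand <- matrix(FALSE, nrow(score), ncol(score))
  add_cand[, diff_cols] <- corrupted_annotation[, diff_cols] == 0
  rem_cand[, diff_cols] <- corrupted_annotation[, diff_cols] == 1
  add_pos <- true_annotation == 1   # deleted genes among absent candidates
  rem_pos <- true_annotation == 0   # inserted genes among present candidates
  out <- list(
    auc_added = pool_auc(add_cand, add_pos, score),
    auc_removed = pool_auc(rem_cand, rem_pos, -score))
  out$per_factor <- data.frame(
    set = colnames(score)[diff_cols] %||% diff_cols,
    auc_added = vapply(diff_cols, function(k)
      pool_auc(add_cand[, k], add_pos[, k], score[, k]), numeric(1L)),
    auc_removed = vapply(diff_cols, function(k)
      pool_auc(rem_cand[, k], rem_pos[, k], -score[, k]), numeric(1L)),
    stringsAsFactors = FALSE)
  out
}

#' Run a simulate-fit-evaluate benchmark
#'
#' For each replicate: simulate a dataset from `config`, fit the model on
#' the (corrupted, if corruption is configured) annotation, rank annotated
#' factors by relevance, and score driver recovery and — when the
#' annotation was corrupted — augmentation recovery.
#'
#' @param config A [pf_sim_config()].
#' @param n_reps Number of replicates (default 10 for desk scale; 50
#'   matches the full protocol).
#' @param n_sparse,n_dense Unannotated factor counts for the fit.
#' @param noise Observation model used in the fit.
#' @param hyper,control Passed to [pathfactor()]. The default control caps
#'   each fit at 200 sweeps: relevance rankings stabilize long before the
#'   ELBO's slow final drift (a scale redundancy between factor states and
#'   weights) meets the strict convergence tolerance.
#' @return A list with `replicates` (per-replicate data.frame: replicate,
#'   seed, auc_driver, auc_added, auc_removed, converged, n_iter) and
#'   `summary` (median and 25/75% quartiles of each AUC).
#' @export
pf_benchmark <- function(config, n_reps = 10L, n_sparse = 0L, n_dense = 3L,
                         noise = "gaussian", hyper = pf_hyper(),
                         control = pf_control(max_iter = 200L)) {
  configs <- run_replicates(config, n_reps)
  rows <- lapply(seq_along(configs), function(i) {
    cf <- configs[[i]]
    sim <- simulate_dataset(cf)
    corrupted <- nrow(sim$corruption) > 0
    ann <- if (corrupted) sim$corrupted_annotation else sim$true_annotation
    fit <- pathfactor(sim$Y, ann, n_sparse = n_sparse, n_dense = n_dense,
                      noise = noise, hyper = hyper, control = control,
                      seed = cf$seed)
    ann_k <- which(!is.na(fit$state$spec$annotation_column))
    rel <- factor_relevance(fit)
    scores <- rel$relevance[match(fit$state$spec$name[ann_k], rel$factor)]
    dr <- driver_recovery(setNames(scores, fit$state$spec$name[ann_k]),
                          sim$active_mask)
    aug <- if (corrupted)
      augmentation_recovery(fit$state$logodds[, ann_k, drop = FALSE],
                            sim$corrupted_annotation, sim$true_annotation)
    else list(auc_added = NA_real_, auc_removed = NA_real_)
    data.frame(replicate = i, seed = cf$seed, auc_driver = dr$auc,
               auc_added = aug$auc_added, auc_removed = aug$auc_removed,
               converged = fit$converged, n_iter = fit$n_iter)
  })
  reps <- do.call(rbind, rows)
  qs <- function(x) if (all(is.na(x))) rep(NA_real_, 3L) else
    unname(quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE))
  summ <- data.frame(
    metric = c("auc_driver", "auc_added", "auc_removed"),
    q25 = c(qs(reps$auc_driver)[1L], qs(reps$auc_added)[1L],
            qs(reps$auc_removed)[1L]),
    median = c(qs(reps$auc_driver)[2L], qs(reps$auc_added)[2L],
               qs(reps$auc_removed)[2L]),
    q75 = c(qs(reps$auc_driver)[3L], qs(reps$auc_added)[3L],
            qs(reps$auc_removed)[3L]),
    stringsAsFactors = FALSE)
  list(replicates = reps, summary = summ)
}
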