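# ---------------------------------------------------------------------------
# Evaluation protocol: randomized label-stratified 50/50 splits, multiruns,
# external-test scoring, multirun stability, convergence speed, average ranks.
# ---------------------------------------------------------------------------

#' Randomized label-stratified 50/50 split plans
#'
#' Each split assigns every record to the optimization half or the external
#' test half, stratified by activity label so both halves contain actives and
#' decoys.  With an odd label count the optimization half receives the extra
#' record (`ceiling(n/2)`).  Reproducible from the seed.
#'
#' @param dataset an `oa_dataset` with `>= 2` actives and `>= 2` decoys.
#' @param n_splits number of independent splits (default 10).
#' @param seed integer seed.
#' @return an object of class `oa_split_plan`: a logical matrix
#'   (records x splits), `TRUE` = optimization half, with the seed attached.
#' @export
make_splits <- function(dataset, n_splits = 10, seed = NULL) {
  stopifnot(inherits(dataset, "oa_dataset"))
  lab <- dataset$info$label
  if (sum(lab == "active") < 2 || sum(lab == "decoy") < 2)
    stop("dataset needs at least 2 actives and 2 decoys to split")
  if (!is.null(seed)) set.seed(seed)
  n <- length(lab)
  plan <- matrix(FALSE, n, n_splits)
  for (s in seq_len(n_splits)) {
    for (l in c("active", "decoy")) {
      idx <- which(lab == l)
      take <- sample(idx, ceiling(length(idx) / 2))
      plan[take, s] <- TRUE
    }
  }
  structure(plan, class = "oa_split_plan", seed = seed,
            ids = dataset$info$id)
}

# subset an oa_dataset by a logical/integer index
.subset_dataset <- function(dataset, keep) {
  oa_dataset(dataset$mols[keep], dataset$info$label[keep],
             dataset$info$cluster[keep])
}

#' Multirun stability: split-wise standard deviation, averaged
#'
#' @param results numeric matrix or list: rows/elements = splits, each holding
#'   the optimized metric values of the multiruns of that split (`>= 2` each).
#' @return mean over splits of the per-split sample standard deviation.
#' @export
multirun_stability <- function(results) {
  vals <- if (is.matrix(results)) split(results, row(results)) else results
  if (any(vapply(vals, length, 1L) < 2))
    stop("multirun stability requires at least 2 multiruns per split")
  mean(vapply(vals, stats::sd, 0))
}

#' Relative standard deviation (%RSD) of multiruns, averaged over splits
#'
#' @inheritParams multirun_stability
#' @return mean over splits of `100 * sd / mean`.
#' @export
relative_sd <- function(results) {
  vals <- if (is.matrix(results)) split(results, row(results)) else results
  if (any(vapply(vals, length, 1L) < 2))
    stop("relative SD requires at least 2 multiruns per split")
  mu <- vapply(vals, mean, 0)
  if (any(mu == 0)) stop("relative SD undefined for zero mean")
  mean(vapply(seq_along(vals), function(k) 100 * stats::sd(vals[[k]]) / mu[k], 0))
}

#' Convergence point of an optimization trace
#'
#' The smallest evaluation index whose best-so-far performance is within a
#' tolerance of the final best performance: relative mode uses
#' `tol * |final best|` (default 1%), absolute mode a fixed margin (default
#' 0.01).  A zero final best in relative mode falls back to absolute mode.
#'
#' @param trace numeric vector of best-so-far *performance* (maximized) per
#'   evaluation; monotone non-decreasing.
#' @param mode `"relative"` or `"absolute"`.
#' @param tol tolerance (default 0.01 in either mode).
#' @return 1-based evaluation index.
#' @export
convergence_point <- function(trace, mode = c("relative", "absolute"),
                              tol = 0.01) {
  mode <- match.arg(mode)
  if (length(trace) == 0) stop("empty trace")
  final <- trace[length(trace)]
  margin <- if (mode == "relative" && final != 0) tol * abs(final) else tol
  which(trace >= final - margin)[1]
}

#' Average ranks of competing methods across datasets
#'
#' Ranks the methods within each dataset (rank 1 = best) and averages across
#' datasets; tied values share the average rank.
#'
#' @param perf numeric matrix, methods x datasets, larger = better.
#' @return named numeric vector of average ranks per method.
#' @export
average_ranks <- function(perf) {
  stopifnot(is.matrix(perf))
  rk <- apply(perf, 2, function(col) rank(-col, ties.method = "average"))
  out <- rowMeans(rk)
  names(out) <- rownames(perf)
  out
}

#' Run the full split x multirun evaluation protocol
#'
#' For every split, optimizes the query's edge weights on the optimization
#' half (`n_multiruns` independent runs) and evaluates AUC, BEDROC and (when
#' clusters are annotated) awROCE on the external half, which never enters a
#' fitness evaluation.  Per split, the best multirun is selected by
#' optimization-split fitness and its external metrics reported; the external
#' metrics of the uniform-weight (unweighted) screening are included as the
#' baseline.
#'
#' @param dataset an `oa_dataset`.
#' @param query `oa_mol`.
#' @param config list: `n_splits` (default 2), `n_multiruns` (default 2),
#'   `budget` (default 1500), `method`, `metric`, `pop_size` (see [oa_fit()]).
#' @param seed integer seed; sub-seeds for each split x multirun are drawn
#'   from it, so the whole experiment is reproducible.
#' @return an object of class `oa_experiment`: `runs` (list of lists of
#'   `oa_fit`), `external` (data.frame per split x run of external metrics),
#'   `best_run` (index per split), `summary` (per-split external metrics of
#'   the selected run and of the uniform baseline), `split_plan`, `seeds`.
#' @export
run_experiment <- function(dataset, query, config = list(), seed = 1L) {
  n_splits <- if (is.null(config$n_splits)) 2L else config$n_splits
  n_multi <- if (is.null(config$n_multiruns)) 2L else config$n_multiruns
  budget <- if (is.null(config$budget)) 1500L else config$budget
  set.seed(seed)
  sub_seeds <- matrix(sample.int(.Machine$integer.max, n_splits * n_multi),
                      n_splits, n_multi)
  plan <- make_splits(dataset, n_splits, seed = seed)
  has_cl <- !any(is.na(dataset$info$cluster[dataset$info$label == "active"]))

  runs <- vector("list", n_splits)
  ext_rows <- list()
  best_run <- integer(n_splits)
  summ <- list()
  for (s in seq_len(n_splits)) {
    opt_ds <- .subset_dataset(dataset, plan[, s])
    ext_ds <- .subset_dataset(dataset, !plan[, s])
    stopifnot(length(intersect(opt_ds$info$id, ext_ds$info$id)) == 0)
    runs[[s]] <- vector("list", n_multi)
    ext_metrics <- vector("list", n_multi)
    for (r in seq_len(n_multi)) {
      fit <- run_optimization(query, opt_ds, config, budget = budget,
                              seed = sub_seeds[s, r])
      runs[[s]][[r]] <- fit
      ranked <- predict(fit, ext_ds)
      rep_r <- metric_report(ranked)
      ext_metrics[[r]] <- rep_r
      ext_rows[[length(ext_rows) + 1L]] <- data.frame(
        split = s, run = r, train_metric = fit$train_metric,
        ext_auc = rep_r$auc, ext_bedroc = rep_r$bedroc,
        ext_awroce_5 = if (has_cl) rep_r$awroce[["5%"]] else NA_real_)
    }
    best_run[s] <- which.max(vapply(runs[[s]], function(f) f$train_metric, 0))
    base_ranked <- oa_screen(query, ext_ds)
    base_rep <- metric_report(base_ranked)
    sel <- ext_metrics[[best_run[s]]]
    summ[[s]] <- data.frame(
      split = s, selected_run = best_run[s],
      ext_auc = sel$auc, ext_bedroc = sel$bedroc,
      ext_awroce_5 = if (has_cl) sel$awroce[["5%"]] else NA_real_,
      uniform_auc = base_rep$auc, uniform_bedroc = base_rep$bedroc,
      uniform_awroce_5 = if (has_cl) base_rep$awroce[["5%"]] else NA_real_)
  }
  structure(list(runs = runs, external = do.call(rbind, ext_rows),
                 best_run = best_run, summary = do.call(rbind, summ),
                 split_plan = plan, seeds = sub_seeds, seed = seed,
                 config = config),
            class = "oa_experiment")
}

#' @export
print.oa_experiment <- function(x, ...) {
  cat("Split x multirun weight-optimization experiment\n")
  cat("  ", nrow(x$summary), " splits, ", length(x$runs[[1]]),
      " multiruns each\n", sep = "")
  cat(sprintf("  mean external AUC: optimized %.4f vs uniform %.4f\n",
              mean(x$summary$ext_auc), mean(x$summary$uniform_auc)))
  invisible(x)
}
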