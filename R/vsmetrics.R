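# ---------------------------------------------------------------------------
# Virtual-screening metrics: ROC/AUC, BEDROC, ROC enrichment (ROCE) and its
# arithmetically weighted, chemotype-aware variant (awROCE).
#
# Tie policy (documented, deterministic): rank-based and cutoff metrics sort
# by descending score with decoys placed before actives within a tied score
# (pessimistic); the AUC uses the average-rank (Mann-Whitney, ties count 1/2)
# convention.  All metrics are therefore invariant to permutations of tied
# entries.
# ---------------------------------------------------------------------------

#' Construct a ranked screening result list
#'
#' @param id character vector of compound ids.
#' @param score numeric similarity scores (higher = more query-like).
#' @param label `"active"` or `"decoy"` per compound.
#' @param cluster optional chemotype cluster ids (`NA` for decoys).
#' @return a data.frame of class `oa_ranked`, sorted by descending score with
#'   decoys before actives within ties (the pessimistic tie policy).
#' @export
ranked_list <- function(id, score, label, cluster = NULL) {
  stopifnot(length(id) == length(score), length(score) == length(label))
  label <- match.arg(label, c("active", "decoy"), several.ok = TRUE)
  if (is.null(cluster)) cluster <- rep(NA_character_, length(id))
  ord <- order(-score, label != "decoy")  # decoys first within a tie
  out <- data.frame(id = as.character(id)[ord], score = score[ord],
                    label = label[ord], cluster = as.character(cluster)[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("oa_ranked", "data.frame")
  attr(out, "tie_policy") <- "pessimistic"
  out
}

.check_ranked <- function(r) {
  if (!inherits(r, "oa_ranked")) r <- ranked_list(r$id, r$score, r$label, r$cluster)
  if (!any(r$label == "active") || !any(r$label == "decoy"))
    stop("ranked list must contain at least one active and one decoy")
  r
}

#' ROC curve of a ranked list
#'
#' Stepwise curve over all decision thresholds (tied scores grouped), from
#' (0, 0) to (1, 1).
#'
#' @param r an [ranked_list()].
#' @return data.frame with columns `fpr` and `tpr`.
#' @export
roc_curve <- function(r) {
  r <- .check_ranked(r)
  nA <- sum(r$label == "active"); nD <- sum(r$label == "decoy")
  grp <- cumsum(!duplicated(r$score))      # threshold groups (scores sorted desc)
  tp <- cumsum(r$label == "active"); fp <- cumsum(r$label == "decoy")
  last <- !duplicated(grp, fromLast = TRUE)
  data.frame(fpr = c(0, fp[last] / nD), tpr = c(0, tp[last] / nA))
}

#' Area under the ROC curve
#'
#' Trapezoidal area; identical to the Mann-Whitney statistic, the fraction of
#' (active, decoy) pairs in which the active outscores the decoy with ties
#' counted 1/2.
#'
#' @param r an [ranked_list()].
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(r) {
  r <- .check_ranked(r)
  act <- r$label == "active"
  nA <- sum(act); nD <- sum(!act)
  rk <- rank(r$score, ties.method = "average")
  (sum(rk[act]) - nA * (nA + 1) / 2) / (nA * nD)
}

#' BEDROC early-enrichment score
#'
#' Exponentially rank-weighted enrichment: each active at (1-based) rank `r_i`
#' of `n` compounds contributes `exp(-alpha * r_i / n)`; the sum is min-max
#' rescaled between its best possible value (actives at ranks `1..n_A`) and its
#' worst (actives at the bottom), giving a score in `[0, 1]`.  Larger `alpha`
#' concentrates the weight on early ranks; at the default `alpha = 53.6`, 80%
#' of the weight mass lies in the top 3% of the ranked list (see
#' [bedroc_weight_mass()]).
#'
#' @param r an [ranked_list()].
#' @param alpha positive weighting parameter (default 53.6).
#' @return BEDROC in `[0, 1]`.
#' @export
bedroc <- function(r, alpha = 53.6) {
  stopifnot(alpha > 0)
  r <- .check_ranked(r)
  n <- nrow(r)
  ranks <- which(r$label == "active")      # pessimistic positions
  nA <- length(ranks)
  s <- sum(exp(-alpha * ranks / n))
  smax <- sum(exp(-alpha * seq_len(nA) / n))
  smin <- sum(exp(-alpha * seq.int(n - nA + 1L, n) / n))
  (s - smin) / (smax - smin)
}

#' Fraction of the BEDROC exponential weight mass in the top of the list
#'
#' For the continuous weighting density `alpha * exp(-alpha * x)` on `[0, 1]`,
#' the fraction of mass in the top `top_frac` of the ranked list is
#' `(1 - exp(-alpha * top_frac)) / (1 - exp(-alpha))`.
#'
#' @param alpha BEDROC weighting parameter.
#' @param top_frac fraction of the ranked list, in `(0, 1)`.
#' @return fraction of weight mass in `[0, 1]`.
#' @export
bedroc_weight_mass <- function(alpha, top_frac) {
  stopifnot(alpha > 0, top_frac > 0, top_frac < 1)
  (1 - exp(-alpha * top_frac)) / (1 - exp(-alpha))
}

# cutoff bookkeeping shared by roce/awroce: position of the ncut-th decoy in
# the pessimistic ordering and the logical vector of actives found above it
.roce_cutoff <- function(r, x_percent) {
  stopifnot(x_percent > 0, x_percent < 100)
  nD <- sum(r$label == "decoy")
  ncut <- as.integer(ceiling(x_percent / 100 * nD))
  if (ncut < 1L) stop("cutoff yields zero decoys")
  dpos <- which(r$label == "decoy")
  cutpos <- dpos[ncut]
  list(ncut = ncut, nD = nD, found = r$label == "active" &
         seq_len(nrow(r)) < cutpos)
}

#' ROC enrichment at a decoy-fraction cutoff
#'
#' `ROCE_x% = SE_x% / FPR_x%` where the sensitivity `SE_x%` is the fraction of
#' actives retrieved along with the top `x%` of the true decoys and
#' `FPR_x% = N_decoys^x% / N_decoys`.  The cutoff contains the first
#' `ceiling(x/100 * N_decoys)` decoys of the ranked list.
#'
#' @param r an [ranked_list()].
#' @param x_percent cutoff in `(0, 100)`.
#' @return enrichment `>= 0`.
#' @export
roce <- function(r, x_percent) {
  r <- .check_ranked(r)
  co <- .roce_cutoff(r, x_percent)
  se <- sum(co$found) / sum(r$label == "active")
  fpr <- co$ncut / co$nD
  se / fpr
}

#' Arithmetically weighted ROC enrichment (chemotype-aware)
#'
#' Each retrieved active is weighted inversely to the size of its chemotype
#' cluster: `SE^aw_x% = sum_j sum_i alpha_ij / N_j / N_clusters`, divided by
#' the same false positive rate as [roce()].  Retrieving one member of a rare
#' scaffold counts as much as retrieving a whole large cluster.
#'
#' @param r an [ranked_list()] with cluster annotations on every active.
#' @param x_percent cutoff in `(0, 100)`.
#' @return enrichment `>= 0`.
#' @export
awroce <- function(r, x_percent) {
  r <- .check_ranked(r)
  act <- r$label == "active"
  if (any(is.na(r$cluster[act]))) stop("active without cluster annotation")
  co <- .roce_cutoff(r, x_percent)
  sizes <- table(r$cluster[act])
  ncl <- length(sizes)
  found_cl <- r$cluster[co$found]
  se_aw <- if (length(found_cl) == 0) 0 else
    sum(1 / as.numeric(sizes[found_cl])) / ncl
  fpr <- co$ncut / co$nD
  se_aw / fpr
}

#' Chemotype discovery curve
#'
#' Walks the ranked list and records, at the first occurrence of each
#' chemotype cluster, the fraction of true decoys passed so far against the
#' fraction of clusters discovered.
#'
#' @param r an [ranked_list()] with cluster annotations on every active.
#' @return data.frame with columns `decoy_frac` and `cluster_frac`.
#' @export
chemotype_discovery_curve <- function(r) {
  r <- .check_ranked(r)
  act <- r$label == "active"
  if (any(is.na(r$cluster[act]))) stop("active without cluster annotation")
  ncl <- length(unique(r$cluster[act]))
  nD <- sum(!act)
  seen <- character(0)
  out <- data.frame(decoy_frac = numeric(0), cluster_frac = numeric(0))
  decoys <- 0L
  for (k in seq_len(nrow(r))) {
    if (r$label[k] == "decoy") decoys <- decoys + 1L
    else if (!(r$cluster[k] %in% seen)) {
      seen <- c(seen, r$cluster[k])
      out <- rbind(out, data.frame(decoy_frac = decoys / nD,
                                   cluster_frac = length(seen) / ncl))
    }
  }
  out
}

#' Full metric report for a ranked list
#'
#' @param r an [ranked_list()].
#' @param alpha BEDROC weighting parameter.
#' @param roce_at decoy-percentage cutoffs for ROCE (and awROCE when clusters
#'   are annotated).
#' @return list of class `oa_metric_report` with elements `auc`, `bedroc`,
#'   `alpha`, `roce` and (if clustered) `awroce` (named by cutoff).
#' @export
metric_report <- function(r, alpha = 53.6, roce_at = c(1, 2, 5)) {
  r <- .check_ranked(r)
  out <- list(auc = auc(r), bedroc = bedroc(r, alpha), alpha = alpha,
              roce = vapply(roce_at, function(x) roce(r, x), 0))
  names(out$roce) <- paste0(roce_at, "%")
  act <- r$label == "active"
  if (!any(is.na(r$cluster[act]))) {
    out$awroce <- vapply(roce_at, function(x) awroce(r, x), 0)
    names(out$awroce) <- paste0(roce_at, "%")
  }
  structure(out, class = "oa_metric_report")
}

#' @export
print.oa_metric_report <- function(x, ...) {
  cat("Virtual-screening metrics\n")
  cat(sprintf("  AUC:    %.4f\n", x$auc))
  cat(sprintf("  BEDROC: %.4f (alpha = %.1f)\n", x$bedroc, x$alpha))
  cat("  ROCE:   ", paste(names(x$roce),
                          sprintf("%.2f", x$roce), sep = " = ",
                          collapse = ", "), "\n", sep = "")
  if (!is.null(x$awroce))
    cat("  awROCE: ", paste(names(x$awroce),
                            sprintf("%.2f", x$awroce), sep = " = ",
                            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a metric report as JSON
#' @param x an `oa_metric_report`.
#' @param path output path.
#' @export
write_metric_report <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a ranked list as delimited text
#' @param r an [ranked_list()].
#' @param path output path.
#' @param sep field separator.
#' @export
write_ranked_list <- function(r, path, sep = "\t") {
  utils::write.table(as.data.frame(r), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a ranked list written by [write_ranked_list()]
#' @param path input path.
#' @param sep field separator.
#' @return an [ranked_list()].
#' @export
read_ranked_list <- function(path, sep = "\t") {
  d <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  ranked_list(d$id, d$score, d$label, d$cluster)
}
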