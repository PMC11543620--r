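#' Labeled score vector for ranking evaluation
#'
#' @param scores Numeric vector of model scores (higher = more likely
#'   positive).
#' @param labels Binary vector (0/1) of the same length.
#' @param ids Optional character identifiers (default index strings).
#' @return Object of class \code{labeled_scores}.
#' @export
labeled_scores <- function(scores, labels, ids = NULL) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)),
            all(is.finite(scores)))
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  stopifnot(length(ids) == length(scores))
  structure(list(scores = as.numeric(scores), labels = as.integer(labels),
                 ids = as.character(ids)),
            class = "labeled_scores")
}

.check_both_classes <- function(data) {
  if (length(unique(data$labels)) < 2L)
    stop("undefined curve: both classes must be present")
  invisible(TRUE)
}

# confusion counts at every distinct score threshold, descending;
# prediction is positive iff score >= threshold
.threshold_sweep <- function(data) {
  thr <- sort(unique(data$scores), decreasing = TRUE)
  P <- sum(data$labels == 1L); N <- sum(data$labels == 0L)
  tp <- vapply(thr, function(t) sum(data$scores >= t & data$labels == 1L), numeric(1))
  fp <- vapply(thr, function(t) sum(data$scores >= t & data$labels == 0L), numeric(1))
  data.frame(threshold = thr, tp = tp, fp = fp, fn = P - tp, tn = N - fp)
}

#' ROC curve and AUC
#'
#' Thresholds are the distinct observed scores in descending order; AUC is
#' the trapezoid area, which equals the Mann-Whitney pair statistic on
#' tie-free data.
#'
#' @param data A \code{\link{labeled_scores}}.
#' @return List with \code{auc} and \code{roc_points} (data frame
#'   \code{fpr}, \code{tpr}, \code{threshold}; includes the (0,0) origin with
#'   threshold Inf).
#' @export
roc_auc <- function(data) {
  .check_both_classes(data)
  sw <- .threshold_sweep(data)
  P <- sum(data$labels == 1L); N <- sum(data$labels == 0L)
  pts <- data.frame(fpr = c(0, sw$fp / N), tpr = c(0, sw$tp / P),
                    threshold = c(Inf, sw$threshold))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(auc = auc, roc_points = pts)
}

#' Average precision (step-wise PR summation)
#'
#' AP = sum_n (R_n - R_(n-1)) P_n over the descending distinct-score
#' thresholds, with R_0 = 0.
#'
#' @param data A \code{\link{labeled_scores}} with at least one positive.
#' @return List with \code{ap} and \code{pr_points} (data frame
#'   \code{recall}, \code{precision}, \code{threshold}).
#' @export
average_precision <- function(data) {
  if (sum(data$labels == 1L) == 0L) stop("undefined AP: no positive labels")
  sw <- .threshold_sweep(data)
  P <- sum(data$labels == 1L)
  recall <- sw$tp / P
  precision <- ifelse(sw$tp + sw$fp > 0, sw$tp / (sw$tp + sw$fp), 0)
  ap <- sum(diff(c(0, recall)) * precision)
  list(ap = ap, pr_points = data.frame(recall = recall, precision = precision,
                                       threshold = sw$threshold))
}

#' Maximum MCC and F1 over all score thresholds
#'
#' Sweeps every distinct score as a threshold (positive iff score >=
#' threshold) and reports the maxima with their achieving thresholds. MCC
#' with a zero denominator is defined as 0.
#'
#' @param data A \code{\link{labeled_scores}}.
#' @return List with \code{max_mcc}, \code{mcc_threshold}, \code{max_f1},
#'   \code{f1_threshold} and the full \code{sweep} data frame.
#' @export
max_mcc_f1 <- function(data) {
  .check_both_classes(data)
  sw <- .threshold_sweep(data)
  den <- sqrt((sw$tp + sw$fp) * (sw$tp + sw$fn) * (sw$tn + sw$fp) * (sw$tn + sw$fn))
  mcc <- ifelse(den > 0, (sw$tp * sw$tn - sw$fp * sw$fn) / den, 0)
  f1den <- 2 * sw$tp + sw$fp + sw$fn
  f1 <- ifelse(f1den > 0, 2 * sw$tp / f1den, 0)
  list(max_mcc = max(mcc), mcc_threshold = sw$threshold[which.max(mcc)],
       max_f1 = max(f1), f1_threshold = sw$threshold[which.max(f1)],
       sweep = cbind(sw, mcc = mcc, f1 = f1))
}

#' Hits among the top-N ranked decoys
#'
#' For each target (or all data as one target), sorts decoys by descending
#' score -- ties broken by stable input order -- and counts positives among
#' the N best for N = 1..M. The aggregate curve sums per-target hit counts at
#' each N (targets exhausted beyond their size contribute their total).
#'
#' @param data A \code{\link{labeled_scores}}.
#' @param per_target_grouping Optional map from id to target: a named
#'   character vector or a data frame with columns \code{id}, \code{target}.
#' @return List with \code{per_target} (named list of data frames \code{n},
#'   \code{hits}) and \code{aggregate}.
#' @export
topn_hits <- function(data, per_target_grouping = NULL) {
  if (is.null(per_target_grouping)) {
    grp <- rep("all", length(data$scores))
  } else if (is.data.frame(per_target_grouping)) {
    grp <- per_target_grouping$target[match(data$ids, per_target_grouping$id)]
  } else {
    grp <- unname(per_target_grouping[data$ids])
  }
  stopifnot(!anyNA(grp))
  per <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    ord <- idx[order(-data$scores[idx])]   # order() is stable: input order breaks ties
    hits <- cumsum(data$labels[ord])
    per[[g]] <- data.frame(n = seq_along(ord), hits = hits)
  }
  nmax <- max(vapply(per, nrow, integer(1)))
  agg <- vapply(seq_len(nmax), function(n)
    sum(vapply(per, function(d) d$hits[min(n, nrow(d))], numeric(1))), numeric(1))
  list(per_target = per, aggregate = data.frame(n = seq_len(nmax), hits = agg))
}

#' Ensemble-average scores from several scoring systems
#'
#' Each score vector is min-max normalized to [0, 1] (constant vectors map
#' to 0.5) and the element-wise mean is returned. Inputs must be aligned:
#' equal lengths and, when named, identical id order.
#'
#' @param score_sets List of numeric vectors of equal length.
#' @param mode Only "mean" is implemented.
#' @return Numeric vector of ensemble scores.
#' @export
ensemble_scores <- function(score_sets, mode = "mean") {
  stopifnot(mode == "mean", length(score_sets) >= 1L)
  len <- unique(vapply(score_sets, length, integer(1)))
  if (length(len) != 1L) stop("misaligned score sets: unequal lengths")
  nms <- lapply(score_sets, names)
  has <- !vapply(nms, is.null, logical(1))
  if (any(has)) {
    ref <- nms[has][[1L]]
    if (!all(vapply(nms[has], function(x) identical(x, ref), logical(1))))
      stop("misaligned score sets: id order differs")
  }
  norm <- lapply(score_sets, function(s) {
    rng <- range(s)
    if (diff(rng) < .Machine$double.eps) rep(0.5, length(s))
    else (s - rng[1L]) / diff(rng)
  })
  Reduce(`+`, norm) / length(norm)
}

#' DeLong test for two correlated (paired) AUCs
#'
#' Computes both AUCs via placement values, the DeLong variance of their
#' difference for the paired design, a two-sided normal p-value, and the
#' Bonferroni-corrected p-value.
#'
#' @param a,b \code{\link{labeled_scores}} objects over the same decoys:
#'   identical labels and ids.
#' @param n_comparisons Number of comparisons in the family (Bonferroni
#'   factor).
#' @return List with \code{auc_a}, \code{auc_b}, \code{var_diff}, \code{z},
#'   \code{p_raw}, \code{p_bonferroni}.
#' @export
delong_test <- function(a, b, n_comparisons = 1L) {
  if (!identical(a$labels, b$labels) || !identical(a$ids, b$ids))
    stop("unpaired inputs: DeLong comparison requires identical labels and ids")
  .check_both_classes(a)
  pos <- which(a$labels == 1L); neg <- which(a$labels == 0L)
  m <- length(pos); n <- length(neg)
  placement <- function(scores) {
    X <- scores[pos]; Y <- scores[neg]
    psi <- outer(X, Y, function(x, y) (x > y) + 0.5 * (x == y))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
  }
  pa <- placement(a$scores); pb <- placement(b$scores)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (var_diff <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- (pa$auc - pb$auc) / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, var_diff = var_diff, z = z,
       p_raw = p, p_bonferroni = min(1, p * n_comparisons))
}

#' Full ranking report
#'
#' Bundles ROC/AUC, PR/AP, threshold-swept MCC and F1, and the top-N hit
#' curve for one labeled score set.
#'
#' @param data A \code{\link{labeled_scores}}.
#' @param per_target_grouping Optional grouping for the hit curve (see
#'   \code{\link{topn_hits}}).
#' @return Object of class \code{ranking_report}: list with \code{auc},
#'   \code{roc_points}, \code{ap}, \code{pr_points}, \code{max_mcc},
#'   \code{max_f1}, \code{mcc_threshold}, \code{f1_threshold},
#'   \code{topn_hits}.
#' @export
ranking_report <- function(data, per_target_grouping = NULL) {
  roc <- roc_auc(data)
  pr <- average_precision(data)
  mf <- max_mcc_f1(data)
  tn <- topn_hits(data, per_target_grouping)
  structure(list(auc = roc$auc, roc_points = roc$roc_points, ap = pr$ap,
                 pr_points = pr$pr_points, max_mcc = mf$max_mcc,
                 max_f1 = mf$max_f1, mcc_threshold = mf$mcc_threshold,
                 f1_threshold = mf$f1_threshold, topn_hits = tn$aggregate,
                 topn_per_target = tn$per_target),
            class = "ranking_report")
}

#' @export
print.ranking_report <- function(x, ...) {
  cat(sprintf("<ranking_report: AUC %.3f, AP %.3f, max MCC %.3f, max F1 %.3f>\n",
              x$auc, x$ap, x$max_mcc, x$max_f1))
  invisible(x)
}

#' Score-distribution quantile summary by class
#'
#' Emits the quantile table used in place of violin plots: per class the
#' quartiles and the interquartile range of the scores.
#'
#' @param data A \code{\link{labeled_scores}}.
#' @return Data frame with one row per class.
#' @export
score_spread <- function(data) {
  do.call(rbind, lapply(c(0L, 1L), function(lab) {
    s <- data$scores[data$labels == lab]
    q <- stats::quantile(s, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(label = lab, n = length(s), q25 = q[1], median = q[2],
               q75 = q[3], iqr = q[3] - q[1])
  }))
}

#' Plot a ranking report
#'
#' ROC and PR curves as a two-panel ggplot. Requires ggplot2.
#' @param object A \code{\link{ranking_report}}.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_ranking_report <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  roc <- cbind(object$roc_points, panel = sprintf("ROC (AUC %.3f)", object$auc),
               x = object$roc_points$fpr, y = object$roc_points$tpr)
  pr <- cbind(object$pr_points, panel = sprintf("PR (AP %.3f)", object$ap),
              x = object$pr_points$recall, y = object$pr_points$precision)
  df <- rbind(roc[, c("panel", "x", "y")], pr[, c("panel", "x", "y")])
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "FPR / recall", y = "TPR / precision") +
    ggplot2::theme_minimal()
}
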