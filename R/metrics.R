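# Evaluation statistics: accuracy, pixel-level F1, the exact Wilcoxon
# signed-rank comparison, per-dataset report assembly and a generic k-fold
# splitter.

#' Classification accuracy
#'
#' The ratio between the number of true predictions and the total number
#' of samples.
#'
#' @param decisions,truth Equal-length label vectors (nonempty).
#' @return A number in \[0, 1\].
#' @export
accuracy <- function(decisions, truth) {
  if (length(decisions) == 0L || length(decisions) != length(truth))
    stop("`decisions` and `truth` must be nonempty and of equal length")
  mean(decisions == truth)
}

#' Pixel-level F1 score
#'
#' `2 tp / (2 tp + fn + fp)` with true/false positives and false negatives
#' counted over all pixels of all supplied masks jointly (pixel level, not
#' per-image averaged), so the score is independent of how the pixels are
#' split across images.  The degenerate case `tp = fp = fn = 0` (empty
#' truth, empty prediction) is defined as 1.
#'
#' @param pred_mask,gt_mask Binary masks (logical or 0/1), or lists of
#'   masks; shapes must match pairwise.
#' @return A number in \[0, 1\].
#' @export
pixel_f1 <- function(pred_mask, gt_mask) {
  if (!is.list(pred_mask)) pred_mask <- list(pred_mask)
  if (!is.list(gt_mask)) gt_mask <- list(gt_mask)
  if (length(pred_mask) != length(gt_mask))
    stop("`pred_mask` and `gt_mask` must pair up")
  tp <- fp <- fn <- 0
  for (i in seq_along(pred_mask)) {
    p <- pred_mask[[i]]; g <- gt_mask[[i]]
    if (!identical(dim(p), dim(g)))
      stop("mask ", i, ": shape mismatch")
    p <- p != 0; g <- g != 0
    tp <- tp + sum(p & g)
    fp <- fp + sum(p & !g)
    fn <- fn + sum(!p & g)
  }
  if (tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fn + fp)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided p-value of the paired signed-rank test, the statistic used to
#' compare methods across datasets.  Zero differences are dropped and tied
#' absolute differences receive mid-ranks.  For up to 12 nonzero pairs the
#' p-value is exact, computed from the full distribution of the
#' positive-rank sum over all `2^m` equiprobable sign assignments (a
#' convolution over the observed mid-ranks, so ties are handled exactly);
#' larger samples use the normal approximation with tie correction and
#' continuity correction.
#'
#' @param a,b Equal-length numeric vectors of paired measurements
#'   (`n >= 5`).
#' @return The two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  if (length(a) < 5L) stop("need at least 5 pairs")
  d <- a - b
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) {
    warning("all differences are zero; p = 1")
    return(1)
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (m <= 12L) {
    # exact: distribution of W+ over all sign assignments, via convolution
    # on doubled ranks (mid-ranks are multiples of 1/2)
    r2 <- round(2 * r)
    counts <- rep(0, sum(r2) + 1L)  # counts[s + 1] = #assignments with 2W+ = s
    counts[1L] <- 1
    for (rk in r2) {
      shifted <- c(rep(0, rk), counts[seq_len(length(counts) - rk)])
      counts <- counts + shifted
    }
    tot <- 2^m
    w2 <- round(2 * w)
    p_le <- sum(counts[seq_len(w2 + 1L)]) / tot
    p_ge <- sum(counts[(w2 + 1L):length(counts)]) / tot
    min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- m * (m + 1) / 4
    tie_tab <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

#' Assemble a per-dataset evaluation report
#'
#' Collects per-dataset metric values for several methods, their averages,
#' the rank of each method by average, and the matrix of pairwise Wilcoxon
#' signed-rank p-values across datasets.
#'
#' @param metrics Numeric matrix, methods in rows, datasets in columns,
#'   values in \[0, 1\]; row/column names label methods/datasets.
#' @return An object of class `eval_report`: list with `per_dataset`,
#'   `average`, `rank` and `pairwise_p`.
#' @export
eval_report <- function(metrics) {
  metrics <- as.matrix(metrics)
  if (any(metrics < 0 | metrics > 1)) stop("metric values must lie in [0, 1]")
  avg <- rowMeans(metrics)
  rk <- rank(-avg, ties.method = "min")
  nm <- length(avg)
  pw <- matrix(NA_real_, nm, nm, dimnames = list(rownames(metrics),
                                                 rownames(metrics)))
  if (ncol(metrics) >= 5L) {
    for (i in seq_len(nm)) for (j in seq_len(nm)) if (i != j)
      pw[i, j] <- suppressWarnings(
        wilcoxon_signed_rank(metrics[i, ], metrics[j, ]))
  }
  structure(list(per_dataset = metrics, average = avg, rank = rk,
                 pairwise_p = pw), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  tab <- cbind(x$per_dataset, Avg = x$average, Rank = x$rank)
  print(round(tab, 4))
  invisible(x)
}

#' Generic k-fold splitter
#'
#' Random (optionally stratified) partition of `n` samples into `k` folds.
#'
#' @param n Number of samples.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param strata Optional label vector of length `n`; folds then balance
#'   each label.
#' @return List of `k` integer index vectors (test folds).
#' @export
kfold_split <- function(n, k = 5L, seed = 1L, strata = NULL) {
  if (k < 2L || k > n) stop("`k` must lie in [2, n]")
  .with_seed(seed, {
    fold <- integer(n)
    if (is.null(strata)) {
      fold <- sample(rep_len(seq_len(k), n))
    } else {
      for (g in unique(strata)) {
        idx <- which(strata == g)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    }
    split(seq_len(n), fold)
  })
}
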