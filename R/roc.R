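#' Empirical ROC curve of a count channel against culture truth
#'
#' Sweeps the screen-positive rule `value >= threshold` over the candidate
#' thresholds -- the distinct observed values plus a `+Inf` sentinel -- and
#' records one operating point per threshold. Tied values collapse to a
#' single point, so the trapezoidal area equals the rank statistic
#' P(X_pos > X_neg) + 0.5 P(X_pos = X_neg) exactly.
#'
#' @param values Numeric marker values (counts/uL), one per sample.
#' @param truth Binary culture labels, same length; both classes must be
#'   present.
#' @return An object of class `roc_curve`: list with `points` (tibble of
#'   `threshold`, `se`, `fpr`, ordered by decreasing threshold), `auc`,
#'   `n_pos`, `n_neg`.
#' @examples
#' build_roc(c(3, 5, 1, 2, 3), c(1, 1, 0, 0, 0))
#' @export
build_roc <- function(values, truth) {
  truth <- as_binary01(truth, "truth")
  if (!is.numeric(values))
    abort_contract("`values` must be numeric")
  if (length(values) != length(truth))
    abort_contract("`values` and `truth` must have equal length")
  if (anyNA(values))
    abort_contract("`values` contains missing counts")
  n_pos <- sum(truth == 1L)
  n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L)
    abort_contract("ROC undefined: need at least one positive and one negative")

  uv <- sort(unique(values), decreasing = TRUE)
  idx <- match(values, uv)
  pos_counts <- tabulate(idx[truth == 1L], nbins = length(uv))
  neg_counts <- tabulate(idx[truth == 0L], nbins = length(uv))
  se <- c(0, cumsum(pos_counts)) / n_pos
  fpr <- c(0, cumsum(neg_counts)) / n_neg
  points <- tibble::tibble(threshold = c(Inf, uv), se = se, fpr = fpr)
  structure(list(points = points,
                 auc = trapezoid_auc(fpr, se),
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

trapezoid_auc <- function(fpr, se) {
  k <- length(fpr)
  sum(diff(fpr) * (se[-1] + se[-k]) / 2)
}

#' Area under an ROC curve
#'
#' Trapezoidal area under (FPR, Se); with the tie-collapsed point set of
#' [build_roc()] this equals the Mann-Whitney pair-counting statistic with
#' half credit for ties.
#'
#' @param curve A `roc_curve`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(curve) {
  if (!inherits(curve, "roc_curve"))
    abort_contract("`curve` must be a roc_curve")
  curve$auc
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> ", nrow(x$points), " operating points | ",
      x$n_pos, " pos / ", x$n_neg, " neg | AUC = ",
      format(round(x$auc, 3)), "\n", sep = "")
  invisible(x)
}

#' Export ROC operating points to CSV
#'
#' @param curve A `roc_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roc <- function(curve, path) {
  if (!inherits(curve, "roc_curve"))
    abort_contract("`curve` must be a roc_curve")
  readr::write_csv(curve$points, path)
  invisible(path)
}

#' Optimal single-marker cut-off
#'
#' Scans every candidate threshold (observed values plus `+Inf`) under one
#' of two criteria: `"youden"` maximizes Se + Sp - 1; `"se_floor"`
#' maximizes specificity subject to Se >= `se_target`, the form screening
#' guidelines ask for (sensitivity above 90--95% at 1e5 CFU/mL). Ties are
#' broken deterministically: higher sensitivity first, then higher
#' threshold (the stricter rule).
#'
#' @param values,truth As in [build_roc()].
#' @param criterion `"youden"` or `"se_floor"`.
#' @param se_target Sensitivity floor in `(0, 1]` (used by `"se_floor"`).
#' @return An object of class `cutoff_result`: list with `threshold`,
#'   `criterion`, `metrics` (a `metric_set`), and `confusion`.
#' @examples
#' best_single_cutoff(c(10, 60, 80, 200, 300), c(0, 0, 0, 1, 1), "youden")
#' @export
best_single_cutoff <- function(values, truth, criterion = c("youden", "se_floor"),
                               se_target = 0.95) {
  criterion <- match.arg(criterion)
  curve <- build_roc(values, truth)
  pts <- curve$points
  # integer cell counts at each candidate threshold: exact tie-breaking
  tp <- round(pts$se * curve$n_pos)
  fp <- round(pts$fpr * curve$n_neg)
  pick <- pick_threshold(tp, fp, curve$n_pos, curve$n_neg,
                         thr_rank = seq_along(tp),  # pts ordered by decreasing threshold
                         criterion = criterion, se_target = se_target)
  thr <- pts$threshold[pick]
  cm <- confusion_matrix(tp = tp[pick], fp = fp[pick],
                         tn = curve$n_neg - fp[pick], fn = curve$n_pos - tp[pick])
  structure(list(threshold = thr,
                 criterion = criterion,
                 se_target = if (criterion == "se_floor") se_target else NULL,
                 metrics = metrics_from_confusion(cm),
                 confusion = cm),
            class = "cutoff_result")
}

# Shared criterion logic over candidate operating points given as integer
# (tp, fp) with class sizes (P, N). thr_rank: 1 = highest threshold; the
# tie-break prefers higher se, then higher threshold (lower rank index).
# Comparisons use integers only, so ties are exact.
pick_threshold <- function(tp, fp, P, N, thr_rank, criterion, se_target = 0.95) {
  if (criterion == "youden") {
    # se + sp - 1 = tp/P - fp/N: compare on the common denominator P*N
    score <- tp * N - fp * P
    ord <- order(-score, -tp, thr_rank)
    return(ord[1L])
  }
  se_target <- check_scalar_number(se_target, "se_target")
  if (se_target <= 0 || se_target > 1)
    abort_contract("`se_target` must lie in (0, 1], got ", format(se_target))
  tp_min <- ceiling(se_target * P - 1e-9)
  ok <- tp >= tp_min
  if (!any(ok))
    abort_contract("sensitivity floor ", format(se_target),
                   " unachievable: max achievable se = ", format(max(tp) / P))
  ord <- order(-ok, fp, -tp, thr_rank)
  ord[1L]
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat("<cutoff_result> threshold ", format(x$threshold), "/uL (",
      x$criterion,
      if (!is.null(x$se_target)) paste0(", se >= ", x$se_target) else "",
      ")\n", sep = "")
  print(x$metrics)
  invisible(x)
}
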